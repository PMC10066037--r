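## Environment-specific ecotype detection.
##
## For every (oligotype, environment group) pair: the ingroup prevalence is
## the fraction of the group's samples carrying the oligotype; the threshold
## t is `quantile_shrink` times the `ingroup_quantile` sample quantile of the
## oligotype's non-zero proportions within the group; the oligotype is an
## ecotype of the group when prevalence >= `min_ingroup_prevalence` and, in
## every other group taken individually (default; a pooled-outgroup variant
## exists), at least `outgroup_pass_fraction` of that group's sample
## proportions fall strictly below t. Outgroup zeros count as below any
## positive t; an undefined t (no non-zero ingroup values) makes the call
## FALSE.

#' Relative oligotype proportions per sample
#'
#' Each count divided by its sample's taxon total; rows (samples) sum to 1.
#'
#' @param x An \code{OligotypeExperiment} or an oligotypes x samples count
#'   matrix.
#' @return Numeric matrix, samples x oligotypes.
#' @export
relativeProportions <- function(x) {
  m <- if (is(x, "OligotypeExperiment")) oligotypeCounts(x) else x
  tot <- colSums(m)
  if (any(tot <= 0))
    stop("zero taxon total for sample(s) ",
         paste(colnames(m)[tot <= 0], collapse = ", "),
         " (should be impossible after QC)")
  t(sweep(m, 2L, tot, "/"))
}

#' Prevalence of an oligotype within an environment group
#'
#' @param proportions Samples x oligotypes proportion matrix.
#' @param groups Group label per sample.
#' @param group Ingroup label.
#' @param oligotype Column name or index.
#' @return Fraction of the group's samples with a non-zero proportion.
#' @export
ingroupPrevalence <- function(proportions, groups, group, oligotype) {
  sel <- groups == group
  if (!any(sel)) stop("detection error: empty group '", group, "'")
  mean(proportions[sel, oligotype] > 0)
}

#' Quantile-derived outgroup suppression threshold
#'
#' t = \code{quantile_shrink} x Q(\code{ingroup_quantile}) of the non-zero
#' ingroup proportions, with Q the linear-interpolation sample quantile
#' (\code{stats::quantile} type 7: h = (n-1)p). Returns \code{NA} when no
#' non-zero values exist (the caller then records a FALSE call).
#'
#' @param values Non-zero ingroup proportions.
#' @param params An \code{EcotypeParams}.
#' @return The threshold t, or \code{NA_real_}.
#' @examples
#' quantileThreshold(c(0.10, 0.20, 0.30, 0.40))  # Q(0.10) = 0.13, t = 0.065
#' @export
quantileThreshold <- function(values, params = ecotypeParams()) {
  values <- values[values > 0]
  if (!length(values)) return(NA_real_)
  q <- as.numeric(stats::quantile(values, probs = params@ingroup_quantile,
                                  type = params@quantile_type, names = FALSE))
  params@quantile_shrink * q
}

#' Detect environment-specific ecotypes
#'
#' Evaluates the prevalence + outgroup-quantile rule for every (oligotype,
#' group) pair. Groups without samples are excluded from both ingroup and
#' outgroup roles with a warning; at least two non-empty groups are
#' required.
#'
#' @param x An \code{OligotypeExperiment} (proportions and groups derived
#'   internally), or a samples x oligotypes proportion matrix.
#' @param groups Group label per sample (ignored when \code{x} is an
#'   \code{OligotypeExperiment}).
#' @param params An \code{EcotypeParams}.
#' @return data.frame of calls, one row per oligotype x group:
#'   \code{oligotype_id}, \code{environment_group}, \code{n_ingroup},
#'   \code{ingroup_prevalence}, \code{q_nonzero} (the ingroup quantile),
#'   \code{threshold}, \code{min_outgroup_pass}, \code{outgroup_pass}
#'   (per-outgroup fractions packed as "group=frac;..."), \code{is_ecotype}.
#'   Run metadata (params, quantile type, outgroup semantics) is attached as
#'   the \code{"run_meta"} attribute.
#' @export
detectEcotypes <- function(x, groups = NULL, params = ecotypeParams()) {
  validObject(params)
  if (is(x, "OligotypeExperiment")) {
    groups <- environmentGroups(x)
    prop <- relativeProportions(x)
  } else prop <- x
  if (is.null(groups) || length(groups) != nrow(prop))
    stop("one group label per sample row is required")
  lvl <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  groups <- as.character(groups)
  counts <- table(factor(groups, levels = lvl))
  if (any(counts == 0L)) {
    warning("empty group(s) excluded: ",
            paste(names(counts)[counts == 0L], collapse = ", "))
    lvl <- names(counts)[counts > 0L]
  }
  if (length(lvl) < 2L)
    stop("detection error: at least two non-empty environment groups required")
  p <- ncol(prop)
  oligos <- colnames(prop)
  if (is.null(oligos)) oligos <- sprintf("OT%03d", seq_len(p))

  callList <- vector("list", length(lvl))
  for (gi in seq_along(lvl)) {
    g <- lvl[gi]
    inRows <- prop[groups == g, , drop = FALSE]
    nIn <- nrow(inRows)
    prev <- colMeans(inRows > 0)
    qv <- thr <- rep(NA_real_, p)
    for (j in seq_len(p)) {
      nzv <- inRows[, j]
      nzv <- nzv[nzv > 0]
      if (length(nzv)) {
        qv[j] <- as.numeric(stats::quantile(nzv, params@ingroup_quantile,
                                            type = params@quantile_type,
                                            names = FALSE))
        thr[j] <- params@quantile_shrink * qv[j]
      }
    }
    outLvl <- setdiff(lvl, g)
    if (params@outgroup_mode == "pooled") {
      pooled <- prop[groups %in% outLvl, , drop = FALSE]
      passMat <- matrix(colMeans(pooled < matrix(thr, nrow(pooled), p,
                                                 byrow = TRUE)), nrow = 1L,
                        dimnames = list("pooled", NULL))
    } else {
      passMat <- matrix(NA_real_, nrow = length(outLvl), ncol = p,
                        dimnames = list(outLvl, NULL))
      for (h in outLvl) {
        hr <- prop[groups == h, , drop = FALSE]
        passMat[h, ] <- colMeans(hr < matrix(thr, nrow(hr), p, byrow = TRUE))
      }
    }
    minPass <- apply(passMat, 2L, min)
    isEco <- !is.na(thr) & prev >= params@min_ingroup_prevalence &
      minPass >= params@outgroup_pass_fraction
    isEco[is.na(thr)] <- FALSE
    packed <- apply(passMat, 2L, function(col) paste(
      paste0(rownames(passMat), "=", formatC(col, digits = 6, format = "g")),
      collapse = ";"))
    callList[[gi]] <- data.frame(
      oligotype_id = oligos, environment_group = g, n_ingroup = nIn,
      ingroup_prevalence = as.numeric(prev), q_nonzero = qv, threshold = thr,
      min_outgroup_pass = ifelse(is.na(thr), NA_real_, as.numeric(minPass)),
      outgroup_pass = packed, is_ecotype = isEco,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  calls <- do.call(rbind, callList)
  attr(calls, "run_meta") <- list(
    min_ingroup_prevalence = params@min_ingroup_prevalence,
    outgroup_pass_fraction = params@outgroup_pass_fraction,
    ingroup_quantile = params@ingroup_quantile,
    quantile_shrink = params@quantile_shrink,
    quantile_method = paste0("type", params@quantile_type,
                             " (linear interpolation of order statistics)"),
    outgroup_mode = params@outgroup_mode)
  calls
}

#' Summarize ecotype calls
#'
#' Per-group ecotype counts, and (when proportions are supplied) the summed
#' per-sample proportion of each group's ecotypes — the per-sample fraction
#' of taxon reads belonging to ecotypes of that environment.
#'
#' @param calls Calls data.frame from \code{\link{detectEcotypes}}.
#' @param proportions Optional samples x oligotypes proportion matrix.
#' @return List with \code{per_group} (data.frame environment_group,
#'   n_ecotypes), \code{n_ecotypes} (total TRUE calls), and optionally
#'   \code{sample_ecotype_proportion} (samples x groups matrix).
#' @export
ecotypeSummary <- function(calls, proportions = NULL) {
  agg <- stats::aggregate(is_ecotype ~ environment_group, data = calls, sum)
  names(agg)[2L] <- "n_ecotypes"
  out <- list(per_group = agg, n_ecotypes = sum(calls$is_ecotype))
  if (!is.null(proportions)) {
    grpLvl <- agg$environment_group
    mat <- matrix(0, nrow = nrow(proportions), ncol = length(grpLvl),
                  dimnames = list(rownames(proportions), grpLvl))
    for (g in grpLvl) {
      eco <- calls$oligotype_id[calls$environment_group == g & calls$is_ecotype]
      if (length(eco))
        mat[, g] <- rowSums(proportions[, eco, drop = FALSE])
    }
    out$sample_ecotype_proportion <- mat
  }
  out
}

#' Evaluate recovery of planted ecotypes
#'
#' Maps each detected (oligotype, group) ecotype call onto the simulator's
#' ground truth — an oligotype corresponds to a planted template when the
#' majority of its member reads derive from that template — and computes
#' precision and recall of the planted (template, target-group) pairs over
#' all positive calls.
#'
#' @param calls Calls data.frame from \code{\link{detectEcotypes}}.
#' @param sim The generating \code{AmpliconSimulation}.
#' @param oligotypeTemplates Named character vector mapping oligotype ids to
#'   template ids. Defaults to the identity (use when calls were made
#'   directly on the ground-truth matrix).
#' @return List: \code{precision}, \code{recall}, \code{true_positive},
#'   \code{detected} (data.frame of positive calls with mapped templates).
#' @export
plantedRecovery <- function(calls, sim,
                            oligotypeTemplates = NULL) {
  target <- sim@config@planted_target_environment
  planted <- sim@templates$template_id[sim@templates$role == "planted-ecotype"]
  pos <- calls[calls$is_ecotype, , drop = FALSE]
  mapped <- if (is.null(oligotypeTemplates)) pos$oligotype_id else
    unname(oligotypeTemplates[pos$oligotype_id])
  pos$template_id <- mapped
  tp <- sum(!is.na(mapped) & mapped %in% planted &
              pos$environment_group == target)
  # each planted template counts once even if split across several calls
  recovered <- unique(mapped[!is.na(mapped) & mapped %in% planted &
                               pos$environment_group == target])
  precision <- if (nrow(pos)) tp / nrow(pos) else NA_real_
  recall <- if (length(planted)) length(recovered) / length(planted) else
    NA_real_
  list(precision = precision, recall = recall, true_positive = tp,
       detected = pos)
}

#' Map oligotypes of a decomposition to ground-truth templates
#'
#' Majority vote of the member reads' true template of origin.
#'
#' @param decomposition A \code{MedDecomposition}.
#' @param sim The generating \code{AmpliconSimulation}.
#' @return Named character vector node_id -> template_id.
#' @export
mapOligotypesToTemplates <- function(decomposition, sim) {
  gt <- sim@groundTruth
  tplOf <- setNames(gt$oligotype_id, gt$read_id)
  keep <- !is.na(decomposition@assignment)
  tab <- table(decomposition@assignment[keep],
               tplOf[decomposition@readIds[keep]])
  vapply(rownames(tab), function(r) colnames(tab)[which.max(tab[r, ])],
         character(1L))
}

#' Write ecotype outputs (calls TSV, summary TSV, run metadata JSON)
#'
#' @param calls Calls data.frame from \code{\link{detectEcotypes}}.
#' @param dir Output directory.
#' @param proportions Optional proportions matrix for the per-sample summary.
#' @return The directory, invisibly.
#' @export
writeEcotypeOutputs <- function(calls, dir, proportions = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(calls, file.path(dir, "ecotype_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- ecotypeSummary(calls, proportions)
  utils::write.table(summ$per_group, file.path(dir, "ecotype_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(attr(calls, "run_meta"),
                       file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
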