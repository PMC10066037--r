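## Sample-level quality control of the oligotype count matrix: samples whose
## taxon reads are plausibly carry-over from adjacent environments are
## excluded via sample-type-specific proportion floors (substrate-associated
## < 0.1%, water < 1%, strict inequalities), and samples below 1,000
## sequences are excluded to avoid low-depth bias. The depth rule counts the
## taxon sequence total by default ("taxon"); counting the total community
## instead is available via `depth_rule = "community"`, and the choice is
## recorded in the exclusion log.

#' Taxon proportion of each sample
#'
#' The sample's taxon sequence total (its column sum of the oligotype count
#' matrix) divided by its total community sequence count.
#'
#' @param x An \code{OligotypeExperiment}.
#' @return Named numeric vector in [0, 1].
#' @export
taxonProportions <- function(x) {
  stopifnot(is(x, "OligotypeExperiment"))
  tot <- SummarizedExperiment::colData(x)$total_community_sequences
  if (any(tot <= 0))
    stop("QC error: zero total community sequences for sample(s) ",
         paste(colnames(x)[tot <= 0], collapse = ", "))
  colSums(oligotypeCounts(x)) / tot
}

#' Apply the sample-exclusion rules
#'
#' A sample is excluded iff any of: (substrate-associated AND taxon
#' proportion < \code{substrate_min_prop}), (water AND taxon proportion <
#' \code{water_min_prop}), or sequence total < \code{min_total_sequences}
#' (strict inequalities throughout). Oligotype rows that become all-zero
#' after exclusion are dropped so downstream prevalence denominators stay
#' well defined; the drops are logged.
#'
#' @param x An \code{OligotypeExperiment}.
#' @param min_total_sequences Depth floor (default 1000).
#' @param substrate_min_prop,water_min_prop Contamination floors (defaults
#'   0.001 and 0.01).
#' @param depth_rule Count "taxon" (default) or "community" sequences against
#'   the depth floor.
#' @return The retained \code{OligotypeExperiment}; the exclusion log, the
#'   dropped oligotype ids and the depth rule are stored in
#'   \code{S4Vectors::metadata(x)$qc}.
#' @examples
#' # see tests for boundary behaviour at 999/1000 reads and 0.9%/1.0%
#' @export
qcSamples <- function(x, min_total_sequences = 1000,
                      substrate_min_prop = 0.001, water_min_prop = 0.01,
                      depth_rule = c("taxon", "community")) {
  stopifnot(is(x, "OligotypeExperiment"))
  depth_rule <- match.arg(depth_rule)
  cd <- SummarizedExperiment::colData(x)
  taxon <- colSums(oligotypeCounts(x))
  prop <- taxonProportions(x)
  depth <- if (depth_rule == "taxon") taxon else
    cd$total_community_sequences
  substr_fail <- cd$sample_type == "substrate-associated" &
    prop < substrate_min_prop
  water_fail <- cd$sample_type == "water" & prop < water_min_prop
  depth_fail <- depth < min_total_sequences
  rule <- mapply(function(s, w, d) paste(
    c(if (s) "substrate_contamination", if (w) "water_contamination",
      if (d) "low_depth"), collapse = ","),
    substr_fail, water_fail, depth_fail)
  excluded <- nzchar(rule)
  log <- data.frame(sample_id = colnames(x),
                    excluded = excluded,
                    rule = rule,
                    taxon_sequences = as.integer(taxon),
                    total_community_sequences =
                      as.integer(cd$total_community_sequences),
                    taxon_proportion = as.numeric(prop),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- x[, !excluded]
  zero <- rowSums(oligotypeCounts(out)) == 0
  dropped <- rownames(out)[zero]
  out <- out[!zero, ]
  S4Vectors::metadata(out)$qc <- list(
    log = log, dropped_oligotypes = dropped, depth_rule = depth_rule,
    thresholds = c(min_total_sequences = min_total_sequences,
                   substrate_min_prop = substrate_min_prop,
                   water_min_prop = water_min_prop))
  out
}

#' Headline counts of an oligotype matrix
#'
#' @param x An \code{OligotypeExperiment}.
#' @return Named numeric vector: \code{n_samples}, \code{n_sequences}
#'   (summed taxon counts), \code{n_oligotypes}.
#' @export
matrixSummary <- function(x) {
  stopifnot(is(x, "OligotypeExperiment"))
  c(n_samples = ncol(x),
    n_sequences = sum(oligotypeCounts(x)),
    n_oligotypes = nrow(x))
}
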