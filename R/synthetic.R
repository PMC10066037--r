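## Synthetic multi-environment amplicon scenario generator.
##
## Emulates the statistical structure the downstream analysis assumes: a
## panel of environment groups built from categorical sample descriptors, a
## pool of amplicon templates over the V3-V4 length window, planted
## environment-specific templates that dominate taxon reads in their target
## group while leaking at contamination level elsewhere, per-base
## substitution noise, and a fabricated BLAST-style hit table against the
## template references.

#' Environment group presets
#'
#' The default panel of environment groups used by the simulator: each group
#' is a combination of salinity (marine/brackish/fresh), zone
#' (pelagic/benthic/subsurface), water depth class (coastal/deep-sea),
#' hydrothermal-vent influence and artificial-environment flags, with a
#' derived sample type (water vs substrate-associated). Shipped as a
#' plain-text presets table rather than hard-coded so alternative groupings
#' can be supplied.
#'
#' @param path Optional path to a custom presets TSV with the same columns.
#' @return data.frame with columns environment_group, salinity, zone,
#'   water_depth_class, vent_influence, artificial, sample_type.
#' @examples
#' head(environmentPresets())
#' @export
environmentPresets <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "environment_presets.tsv",
                        package = "medEcotyper", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$vent_influence <- as.logical(df$vent_influence)
  df$artificial <- as.logical(df$artificial)
  df
}

#' Generate per-sample metadata for a synthetic scenario
#'
#' Builds the sample panel: \code{n_environments} groups (drawn from the
#' presets table, recycled with numeric suffixes if more groups are requested
#' than presets exist), \code{samples_per_environment} samples per group,
#' each with its categorical descriptors, a taxon sequencing depth drawn
#' uniformly from \code{depth_range}, and a total community sequence count
#' derived from the sample type's taxon fraction (hence always >= the taxon
#' depth).
#'
#' @param config A \code{ScenarioConfig}.
#' @param presets Optional presets table (see \code{\link{environmentPresets}}).
#' @return data.frame with one row per sample: sample_id, salinity, zone,
#'   water_depth_class, vent_influence, artificial, environment_group,
#'   sample_type, total_community_sequences, taxon_depth.
#' @examples
#' meta <- generateMetadata(scenarioConfig(n_environments = 3,
#'                                         samples_per_environment = 2))
#' table(meta$environment_group)
#' @export
generateMetadata <- function(config, presets = environmentPresets()) {
  validObject(config)
  nEnv <- config@n_environments
  if (nEnv < 1L) stop("configuration error in 'n_environments': must be >= 1")
  if (config@samples_per_environment < 1L)
    stop("configuration error in 'samples_per_environment': must be >= 1")
  reps <- ceiling(nEnv / nrow(presets))
  pool <- presets[rep(seq_len(nrow(presets)), reps), , drop = FALSE]
  if (reps > 1L) {
    suffix <- rep(seq_len(reps), each = nrow(presets))
    pool$environment_group <- ifelse(
      suffix == 1L, pool$environment_group,
      paste0(pool$environment_group, "_", suffix))
  }
  envs <- pool[seq_len(nEnv), , drop = FALSE]
  if (!config@planted_target_environment %in% envs$environment_group)
    stop("configuration error in 'planted_target_environment': '",
         config@planted_target_environment,
         "' is not among the generated environment groups")
  perEnv <- config@samples_per_environment
  meta <- envs[rep(seq_len(nEnv), each = perEnv), , drop = FALSE]
  n <- nrow(meta)
  meta <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                     meta[c("salinity", "zone", "water_depth_class",
                            "vent_influence", "artificial",
                            "environment_group", "sample_type")],
                     stringsAsFactors = FALSE, row.names = NULL)
  withSeed(childSeed(config@rng_seed, 1L), {
    depth <- as.integer(round(runif(n, config@depth_range[1L],
                                    config@depth_range[2L])))
  })
  frac <- config@taxon_fraction_of_community[meta$sample_type]
  meta$total_community_sequences <- as.integer(ceiling(depth / frac))
  meta$taxon_depth <- depth
  meta
}

#' Generate the template pool of a synthetic scenario
#'
#' Draws \code{n_background_oligotypes} background and
#' \code{n_planted_ecotypes} planted template sequences over \{A,C,G,T\} with
#' lengths uniform on \code{read_length_range}. Planted templates are
#' guaranteed to differ from every background template at >= 2 positions of
#' the padded frame (resampled if not, which for amplicon-scale lengths
#' essentially never triggers).
#'
#' @param config A \code{ScenarioConfig}.
#' @return data.frame: template_id, role ("planted-ecotype" or "background"),
#'   sequence, length.
#' @examples
#' tpl <- generateTemplates(scenarioConfig(n_background_oligotypes = 3))
#' table(tpl$role)
#' @export
generateTemplates <- function(config) {
  validObject(config)
  nBg <- config@n_background_oligotypes
  nPl <- config@n_planted_ecotypes
  nTot <- nBg + nPl
  if (nTot < 1L) stop("generation error: no templates requested")
  minLen <- config@read_length_range[1L]
  # distinct-sequence capacity 4^minLen (checked on log scale)
  if (minLen * log(4) < log(nTot))
    stop("generation error: ", nTot,
         " templates exceed the distinct-sequence capacity at length ", minLen)
  bases <- c("A", "C", "G", "T")
  withSeed(childSeed(config@rng_seed, 2L), {
    lens <- as.integer(round(runif(nTot, config@read_length_range[1L],
                                   config@read_length_range[2L])))
    draw <- function(L) paste(sample(bases, L, replace = TRUE), collapse = "")
    seqs <- vapply(lens, draw, character(1L))
    if (nBg > 0L && nPl > 0L) {
      width <- max(lens)
      padTo <- function(s) {
        strsplit(paste0(s, strrep("-", width - nchar(s))), "")[[1L]]
      }
      bgMat <- vapply(seqs[seq_len(nBg)], padTo, character(width))
      for (i in (nBg + 1L):nTot) {
        for (tries in seq_len(100L)) {
          dmin <- min(colSums(bgMat != padTo(seqs[i])))
          if (dmin >= 2L) break
          seqs[i] <- draw(lens[i])
        }
        if (dmin < 2L)
          stop("generation error: could not place a planted template at ",
               "Hamming distance >= 2 from the background pool")
      }
    }
  })
  role <- rep(c("background", "planted-ecotype"), c(nBg, nPl))
  id <- character(nTot)
  if (nBg > 0L) id[seq_len(nBg)] <- sprintf("BG%02d", seq_len(nBg))
  if (nPl > 0L) id[nBg + seq_len(nPl)] <- sprintf("ECO%02d", seq_len(nPl))
  data.frame(template_id = id, role = role, sequence = seqs, length = lens,
             stringsAsFactors = FALSE)
}

#' Simulate amplicon reads, ground truth, and an alignment-hit table
#'
#' Per sample, taxon reads are drawn multinomially over the template pool:
#' in target-environment samples each planted template receives
#' \code{ingroup_mean_proportion} of taxon reads in expectation, elsewhere
#' \code{outgroup_contamination_proportion}; background templates share the
#' remaining mass according to a lognormal baseline (with a uniform floor so
#' no background template is vanishingly rare). Each read is a copy of its
#' template with i.i.d. per-base substitutions at \code{per_base_error_rate}.
#' Every read also receives one fabricated alignment hit against its
#' template's reference record, with identity = 100 x (1 - observed
#' substitution fraction), query coordinates spanning the read, and subject
#' coordinates placing the amplicon at columns 280-720 of the full-length
#' reference frame.
#'
#' @param metadata Sample table from \code{\link{generateMetadata}}.
#' @param templates Template table from \code{\link{generateTemplates}}.
#' @param config The shared \code{ScenarioConfig}.
#' @return An \code{AmpliconSimulation}.
#' @examples
#' cfg <- scenarioConfig(n_environments = 2, samples_per_environment = 2,
#'                       n_background_oligotypes = 3, n_planted_ecotypes = 1,
#'                       planted_target_environment = "hydrothermal_plume",
#'                       depth_range = c(100, 200))
#' sim <- simulateReads(generateMetadata(cfg), generateTemplates(cfg), cfg)
#' sim
#' @export
simulateReads <- function(metadata, templates, config) {
  validObject(config)
  if (nrow(metadata) == 0L) stop("generation error: empty metadata")
  if (nrow(templates) == 0L) stop("generation error: empty template pool")
  nTpl <- nrow(templates)
  isPl <- templates$role == "planted-ecotype"
  nBg <- sum(!isPl)
  code2ascii <- utf8ToInt("ACGT")
  asciiMap <- asciiCodeMap()
  tplInt <- lapply(templates$sequence,
                   function(s) asciiMap[utf8ToInt(s)])

  allSeq <- allId <- allSample <- allTpl <- character(0L)
  hitList <- vector("list", nrow(metadata))
  gtList <- vector("list", nrow(metadata))
  seqList <- vector("list", nrow(metadata))

  withSeed(childSeed(config@rng_seed, 3L), {
    # shared background baseline: uniform floor + lognormal variation
    if (nBg > 0L) {
      ln <- rlnorm(nBg, meanlog = 0, sdlog = 1)
      wBg <- 0.3 / nBg + 0.7 * ln / sum(ln)
      wBg <- wBg / sum(wBg)
    } else wBg <- numeric(0L)

    for (i in seq_len(nrow(metadata))) {
      sm <- metadata[i, ]
      target <- sm$environment_group == config@planted_target_environment
      pPl <- if (target) config@ingroup_mean_proportion else
        config@outgroup_contamination_proportion
      probs <- numeric(nTpl)
      probs[isPl] <- pPl
      if (nBg > 0L) probs[!isPl] <- (1 - sum(probs[isPl])) * wBg
      if (sum(probs) <= 0)
        stop("generation error: zero total template probability for sample ",
             sm$sample_id)
      depth <- sm$taxon_depth
      cnt <- as.vector(rmultinom(1L, depth, probs))
      readTpl <- rep(seq_len(nTpl), cnt)

      seqs <- character(depth)
      nSubs <- integer(depth)
      lens <- templates$length[readTpl]
      pos <- 0L
      for (t in which(cnt > 0L)) {
        k <- cnt[t]
        L <- templates$length[t]
        tpl <- tplInt[[t]]
        m <- matrix(rep(tpl, k), nrow = k, byrow = TRUE)
        ns <- rbinom(k, L, config@per_base_error_rate)
        tot <- sum(ns)
        if (tot > 0L) {
          rows <- rep(seq_len(k), ns)
          cols <- unlist(lapply(ns[ns > 0L], function(n) sample.int(L, n)),
                         use.names = FALSE)
          idx <- cbind(rows, cols)
          shift <- sample.int(3L, tot, replace = TRUE)
          m[idx] <- ((m[idx] - 1L + shift) %% 4L) + 1L
        }
        seqs[pos + seq_len(k)] <-
          vapply(seq_len(k),
                 function(r) intToUtf8(code2ascii[m[r, ]]), character(1L))
        nSubs[pos + seq_len(k)] <- ns
        pos <- pos + k
      }
      ids <- sprintf("%s_Read%d", sm$sample_id, seq_len(depth))
      seqList[[i]] <- seqs
      gtList[[i]] <- data.frame(read_id = ids,
                                oligotype_id = templates$template_id[readTpl],
                                sample_id = sm$sample_id,
                                stringsAsFactors = FALSE)
      hitList[[i]] <- data.frame(
        query_id = ids,
        subject_id = paste0("REF_", templates$template_id[readTpl]),
        identity = round(100 * (1 - nSubs / lens), 3L),
        align_length = lens,
        mismatches = nSubs,
        gap_opens = 0L,
        qstart = 1L,
        qend = lens,
        sstart = 280L,
        send = 720L,
        evalue = 0,
        bitscore = round(1.9 * lens, 1L),
        stringsAsFactors = FALSE)
    }
  })

  gt <- do.call(rbind, gtList)
  reads <- Biostrings::DNAStringSet(unlist(seqList, use.names = FALSE))
  names(reads) <- gt$read_id
  new("AmpliconSimulation", reads = reads, metadata = metadata,
      hits = do.call(rbind, hitList), templates = templates,
      groundTruth = gt, config = config)
}

#' Run the whole simulator and optionally write its artifacts
#'
#' Convenience wrapper chaining \code{\link{generateMetadata}},
#' \code{\link{generateTemplates}} and \code{\link{simulateReads}}. When
#' \code{dir} is given, writes reads.fasta, metadata.tsv, hits.b6,
#' ground_truth.tsv and config.json there.
#'
#' @param config A \code{ScenarioConfig}.
#' @param dir Optional output directory.
#' @return An \code{AmpliconSimulation}, invisibly when \code{dir} is set.
#' @examples
#' sim <- simulateScenario(scenarioConfig(n_environments = 2,
#'                                        samples_per_environment = 2,
#'                                        n_background_oligotypes = 3,
#'                                        depth_range = c(100, 200)))
#' @export
simulateScenario <- function(config, dir = NULL) {
  meta <- generateMetadata(config)
  tpl <- generateTemplates(config)
  sim <- simulateReads(meta, tpl, config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(sim@reads, file.path(dir, "reads.fasta"),
                                width = 20000L)
    writeSampleMetadata(sim@metadata, file.path(dir, "metadata.tsv"))
    writeAlignmentHits(sim@hits, file.path(dir, "hits.b6"))
    utils::write.table(sim@groundTruth, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(scenarioConfigAsList(config),
                         file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(sim))
  }
  sim
}

# Plain-list echo of a ScenarioConfig (for manifests / config.json).
scenarioConfigAsList <- function(config) {
  sl <- slotNames(config)
  out <- lapply(sl, function(s) slot(config, s))
  names(out) <- sl
  out$taxon_fraction_of_community <-
    as.list(config@taxon_fraction_of_community)
  out
}

#' Ground-truth oligotype count matrix of a simulation
#'
#' Cross-tabulates the simulator's read-level ground truth into a template x
#' sample count matrix and wraps it as an \code{OligotypeExperiment} (row
#' annotation carries the template role). This is the matrix the pipeline
#' would recover under perfect filtering and decomposition, and serves as the
#' reference when evaluating planted-ecotype recovery.
#'
#' @param sim An \code{AmpliconSimulation}.
#' @return An \code{OligotypeExperiment} with one row per template.
#' @export
groundTruthExperiment <- function(sim) {
  gt <- sim@groundTruth
  tab <- table(factor(gt$oligotype_id, levels = sim@templates$template_id),
               factor(gt$sample_id, levels = sim@metadata$sample_id))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  rd <- S4Vectors::DataFrame(
    node_id = sim@templates$template_id,
    representative = sim@templates$sequence,
    max_entropy = NA_real_,
    role = sim@templates$role,
    row.names = sim@templates$template_id)
  cd <- S4Vectors::DataFrame(sim@metadata,
                             row.names = sim@metadata$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd,
    colData = cd[colnames(counts), ])
  new("OligotypeExperiment", se)
}
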