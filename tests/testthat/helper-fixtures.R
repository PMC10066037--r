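# Shared fixture builders (everything generated in code).

# A small, fast scenario used across module tests.
tinyScenario <- function(seed = 11, ...) {
  args <- list(n_environments = 3, samples_per_environment = 3,
               n_background_oligotypes = 4, n_planted_ecotypes = 1,
               read_length_range = c(60, 70), depth_range = c(1200, 1600),
               per_base_error_rate = 0, rng_seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scenarioConfig, args)
}

# Build an OligotypeExperiment straight from a samples x oligotypes count
# matrix plus group labels.
toyExperiment <- function(counts_by_sample, groups,
                          sample_type = "water",
                          total_community = NULL) {
  counts <- t(counts_by_sample)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("OT%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  if (is.null(total_community))
    total_community <- pmax(colSums(counts), 1L) * 20L
  meta <- data.frame(sample_id = colnames(counts),
                     environment_group = as.character(groups),
                     sample_type = rep(sample_type,
                                       length.out = ncol(counts)),
                     total_community_sequences = total_community,
                     stringsAsFactors = FALSE)
  makeOligotypeExperiment(counts, meta)
}

# Deterministic read set: `counts` copies of each sequence in `variants`,
# read ids carrying the given sample id.
variantReads <- function(variants, counts, sample_id = "S1") {
  seqs <- rep(variants, counts)
  names(seqs) <- sprintf("%s_Read%d", sample_id, seq_along(seqs))
  seqs
}

# Random toy dataset for MED oracle-equivalence checks: <= 8 unique
# sequences over a short window, random multiplicities summing to <= 200.
randomMedDataset <- function(seed) {
  set.seed(seed)
  width <- sample(8:14, 1)
  nuniq <- sample(2:8, 1)
  bases <- c("A", "C", "G", "T")
  # build variants around a common backbone so entropy structure is varied
  backbone <- sample(bases, width, replace = TRUE)
  variants <- vapply(seq_len(nuniq), function(i) {
    v <- backbone
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      at <- sample(width, nmut)
      v[at] <- sample(bases, nmut, replace = TRUE)
    }
    # occasional shorter variant exercises padding columns
    L <- if (runif(1) < 0.3) width - sample(1:2, 1) else width
    paste(v[seq_len(L)], collapse = "")
  }, character(1))
  variants <- unique(variants)
  counts <- sample(1:40, length(variants), replace = TRUE)
  while (sum(counts) > 200) counts <- pmax(1L, counts - 5L)
  M <- sample(c(1, 2, 5, 10, 20), 1)
  m <- sample(c(0.05, 0.0965, 0.3), 1)
  list(reads = variantReads(variants, counts), M = M, m = m)
}
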