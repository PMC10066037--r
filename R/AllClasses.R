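#' @import methods
#' @importFrom stats quantile rbinom rlnorm rmultinom runif sd setNames
#' @importFrom utils read.table write.table packageVersion
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Scenario configuration for the synthetic amplicon community simulator
#'
#' Holds every knob of the synthetic multi-environment scenario: the sample
#' panel (environment groups and samples per group), the template pool
#' (background oligotypes plus planted environment-specific ecotypes), the
#' abundance structure (ingroup proportion of planted templates and their
#' cross-environment contamination level), sequencing depth, the per-base
#' substitution error rate, and the master RNG seed. A fixed seed makes every
#' generated artifact byte-identical across runs.
#'
#' @slot n_environments Number of environment groups.
#' @slot samples_per_environment Samples generated per group.
#' @slot n_background_oligotypes Number of background (non-specific) templates.
#' @slot n_planted_ecotypes Number of planted environment-specific templates.
#' @slot planted_target_environment Group label the planted templates are
#'   specific to.
#' @slot read_length_range Integer vector of length 2, template/read length
#'   bounds in bp.
#' @slot ingroup_mean_proportion Expected proportion of taxon reads each
#'   planted template receives in target-environment samples.
#' @slot outgroup_contamination_proportion Expected proportion each planted
#'   template receives in every other sample (cross-environment carry-over).
#' @slot taxon_fraction_of_community Named numeric, fraction of the total
#'   community the focal taxon makes up, per sample type
#'   (\code{substrate-associated}, \code{water}).
#' @slot depth_range Integer vector of length 2, taxon reads per sample.
#' @slot per_base_error_rate Substitution probability per base.
#' @slot indel_rate Insertion/deletion probability per base (default 0; the
#'   default noise model is substitution-only so padded alignment is exact).
#' @slot rng_seed Master seed; one derived stream per output artifact.
setClass("ScenarioConfig", representation(
  n_environments = "integer",
  samples_per_environment = "integer",
  n_background_oligotypes = "integer",
  n_planted_ecotypes = "integer",
  planted_target_environment = "character",
  read_length_range = "integer",
  ingroup_mean_proportion = "numeric",
  outgroup_contamination_proportion = "numeric",
  taxon_fraction_of_community = "numeric",
  depth_range = "integer",
  per_base_error_rate = "numeric",
  indel_rate = "numeric",
  rng_seed = "integer"
))

setValidity("ScenarioConfig", function(object) {
  chkCount <- function(x, field) {
    if (length(x) != 1L || is.na(x) || x < 0L)
      return(sprintf("'%s' must be a single non-negative count", field))
    TRUE
  }
  chkFrac <- function(x, field) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      return(sprintf("'%s' must lie in [0, 1]", field))
    TRUE
  }
  for (f in c("n_environments", "samples_per_environment",
              "n_background_oligotypes", "n_planted_ecotypes")) {
    ok <- chkCount(slot(object, f), f)
    if (!isTRUE(ok)) return(ok)
  }
  for (f in c("ingroup_mean_proportion", "outgroup_contamination_proportion",
              "taxon_fraction_of_community", "per_base_error_rate",
              "indel_rate")) {
    ok <- chkFrac(slot(object, f), f)
    if (!isTRUE(ok)) return(ok)
  }
  rl <- object@read_length_range
  if (length(rl) != 2L || any(is.na(rl)) || rl[1L] < 1L || rl[2L] > 10000L ||
      rl[1L] > rl[2L])
    return("'read_length_range' must satisfy 1 <= min <= max <= 10000")
  dr <- object@depth_range
  if (length(dr) != 2L || any(is.na(dr)) || dr[1L] < 1L || dr[1L] > dr[2L])
    return("'depth_range' must satisfy 1 <= min <= max")
  if (object@n_environments >= 1L && length(object@planted_target_environment) != 1L)
    return("'planted_target_environment' must be a single group label")
  tf <- object@taxon_fraction_of_community
  if (!all(c("substrate-associated", "water") %in% names(tf)))
    return("'taxon_fraction_of_community' needs entries 'substrate-associated' and 'water'")
  if (object@n_planted_ecotypes * object@ingroup_mean_proportion > 1)
    return("'ingroup_mean_proportion' times 'n_planted_ecotypes' exceeds 1")
  if (length(object@rng_seed) != 1L || is.na(object@rng_seed))
    return("'rng_seed' must be a single integer")
  TRUE
})

#' Construct a synthetic scenario configuration
#'
#' Defaults describe the package's reference scenario: 11 environment groups
#' of 3 samples, 30 background oligotypes, and 2 ecotypes planted into the
#' hydrothermal-plume group at 30% of taxon reads each, leaking into all other
#' samples at 0.2% (a >= 10-fold ingroup-to-outgroup proportion ratio).
#' Template/read lengths span the 380-450 bp V3-V4 amplicon window; taxon
#' sequencing depth per sample is uniform on 800-4000 reads, so occasional
#' samples fall below the 1,000-sequence quality-control cutoff by design.
#'
#' @param n_environments,samples_per_environment Sample panel shape.
#' @param n_background_oligotypes,n_planted_ecotypes Template pool shape.
#' @param planted_target_environment Group label that receives the planted
#'   ecotypes (must be one of the configured groups).
#' @param read_length_range Length-2 numeric, bp.
#' @param ingroup_mean_proportion,outgroup_contamination_proportion Planted
#'   template abundance inside vs outside the target group.
#' @param taxon_fraction_of_community Named fraction per sample type.
#' @param depth_range Length-2 numeric, taxon reads per sample.
#' @param per_base_error_rate,indel_rate Noise model (indels default off).
#' @param rng_seed Master seed.
#' @return A validated \code{ScenarioConfig}.
#' @examples
#' cfg <- scenarioConfig(n_environments = 3, samples_per_environment = 2)
#' cfg
#' @export
scenarioConfig <- function(n_environments = 11,
                           samples_per_environment = 3,
                           n_background_oligotypes = 30,
                           n_planted_ecotypes = 2,
                           planted_target_environment = "hydrothermal_plume",
                           read_length_range = c(380, 450),
                           ingroup_mean_proportion = 0.30,
                           outgroup_contamination_proportion = 0.002,
                           taxon_fraction_of_community = c(
                             "substrate-associated" = 0.02, "water" = 0.05),
                           depth_range = c(800, 4000),
                           per_base_error_rate = 0.005,
                           indel_rate = 0,
                           rng_seed = 1) {
  new("ScenarioConfig",
      n_environments = as.integer(n_environments),
      samples_per_environment = as.integer(samples_per_environment),
      n_background_oligotypes = as.integer(n_background_oligotypes),
      n_planted_ecotypes = as.integer(n_planted_ecotypes),
      planted_target_environment = as.character(planted_target_environment),
      read_length_range = as.integer(read_length_range),
      ingroup_mean_proportion = as.numeric(ingroup_mean_proportion),
      outgroup_contamination_proportion =
        as.numeric(outgroup_contamination_proportion),
      taxon_fraction_of_community = taxon_fraction_of_community,
      depth_range = as.integer(depth_range),
      per_base_error_rate = as.numeric(per_base_error_rate),
      indel_rate = as.numeric(indel_rate),
      rng_seed = as.integer(rng_seed))
}

#' Retention criteria for the taxon-targeted sequence filter
#'
#' Read-level bounds (length window, no ambiguous bases) plus the six
#' alignment-hit criteria a query must satisfy on at least one of its hits
#' against the curated taxon reference database. All bounds are inclusive.
#'
#' @slot min_identity Minimum percent identity (default 87).
#' @slot min_align_length Minimum alignment length in bp (380).
#' @slot max_qstart Latest allowed query start (10).
#' @slot min_qend Earliest allowed query end (380).
#' @slot sstart_window Closed interval for the subject start (280-380).
#' @slot min_send Earliest allowed subject end (690).
#' @slot min_read_len,max_read_len Read length window in bp (380-450).
setClass("FilterCriteria", representation(
  min_identity = "numeric",
  min_align_length = "numeric",
  max_qstart = "numeric",
  min_qend = "numeric",
  sstart_window = "numeric",
  min_send = "numeric",
  min_read_len = "numeric",
  max_read_len = "numeric"
))

setValidity("FilterCriteria", function(object) {
  if (object@min_identity < 0 || object@min_identity > 100)
    return("'min_identity' must lie in [0, 100]")
  if (length(object@sstart_window) != 2L ||
      object@sstart_window[1L] > object@sstart_window[2L])
    return("'sstart_window' must be a closed interval [lo, hi]")
  if (object@min_read_len > object@max_read_len)
    return("'min_read_len' must not exceed 'max_read_len'")
  TRUE
})

#' Construct sequence-retention filter criteria
#'
#' @param min_identity Percent identity floor for alignment hits.
#' @param min_align_length Alignment length floor, bp.
#' @param max_qstart Query start ceiling (hit must start at or before this).
#' @param min_qend Query end floor.
#' @param sstart_window Closed interval the subject start must fall in.
#' @param min_send Subject end floor.
#' @param min_read_len,max_read_len Inclusive read-length window, bp.
#' @return A \code{FilterCriteria} object.
#' @examples
#' filterCriteria()
#' @export
filterCriteria <- function(min_identity = 87, min_align_length = 380,
                           max_qstart = 10, min_qend = 380,
                           sstart_window = c(280, 380), min_send = 690,
                           min_read_len = 380, max_read_len = 450) {
  new("FilterCriteria",
      min_identity = as.numeric(min_identity),
      min_align_length = as.numeric(min_align_length),
      max_qstart = as.numeric(max_qstart),
      min_qend = as.numeric(min_qend),
      sstart_window = as.numeric(sstart_window),
      min_send = as.numeric(min_send),
      min_read_len = as.numeric(min_read_len),
      max_read_len = as.numeric(max_read_len))
}

#' Minimum entropy decomposition parameters
#'
#' Mirrors the flags of the decomposition: minimum positional entropy
#' \code{m} below which a node is final, number of discriminant positions
#' \code{d} used per split, minimum substantive abundance \code{M} (the
#' required count of a node's most abundant unique sequence), and whether
#' reads from pruned nodes are relocated to the closest surviving oligotype
#' (\code{R}).
#'
#' @slot m Minimum entropy in bits (default 0.0965).
#' @slot d Discriminant positions per split (default 1).
#' @slot M Minimum substantive abundance (default 50).
#' @slot R Relocate outliers (default TRUE).
setClass("MedParams", representation(
  m = "numeric", d = "integer", M = "integer", R = "logical"
))

setValidity("MedParams", function(object) {
  if (object@m < 0) return("'m' must be >= 0")
  if (object@d < 1L) return("'d' must be >= 1")
  if (object@M < 1L) return("'M' must be >= 1")
  TRUE
})

#' Construct minimum entropy decomposition parameters
#'
#' @param m Minimum entropy threshold, bits.
#' @param d Number of discriminant positions per decomposition step.
#' @param M Minimum substantive abundance.
#' @param R Logical, relocate outlier reads to surviving oligotypes.
#' @return A \code{MedParams} object.
#' @examples
#' medParams(M = 10)
#' @export
medParams <- function(m = 0.0965, d = 1, M = 50, R = TRUE) {
  new("MedParams", m = as.numeric(m), d = as.integer(d), M = as.integer(M),
      R = as.logical(R))
}

#' Ecotype detection parameters
#'
#' An oligotype is an ecotype of an environment group when it occurs in at
#' least \code{min_ingroup_prevalence} of the group's samples and, in every
#' other group, at least \code{outgroup_pass_fraction} of the sample
#' proportions fall strictly below \code{quantile_shrink} times the
#' \code{ingroup_quantile} quantile of the ingroup's non-zero proportions.
#'
#' @slot min_ingroup_prevalence Prevalence floor (default 0.5).
#' @slot outgroup_pass_fraction Required outgroup pass fraction (0.9).
#' @slot ingroup_quantile Quantile of non-zero ingroup proportions (0.10).
#' @slot quantile_shrink Multiplier applied to that quantile (0.5).
#' @slot outgroup_mode "each" tests every outgroup separately (default);
#'   "pooled" pools all outgroup samples.
#' @slot quantile_type Sample quantile estimator, \code{stats::quantile} type
#'   (7 = linear interpolation of order statistics).
setClass("EcotypeParams", representation(
  min_ingroup_prevalence = "numeric",
  outgroup_pass_fraction = "numeric",
  ingroup_quantile = "numeric",
  quantile_shrink = "numeric",
  outgroup_mode = "character",
  quantile_type = "integer"
))

setValidity("EcotypeParams", function(object) {
  for (f in c("min_ingroup_prevalence", "outgroup_pass_fraction",
              "ingroup_quantile", "quantile_shrink")) {
    x <- slot(object, f)
    if (length(x) != 1L || is.na(x) || x <= 0 || x > 1)
      return(sprintf("'%s' must lie in (0, 1]", f))
  }
  if (!object@outgroup_mode %in% c("each", "pooled"))
    return("'outgroup_mode' must be 'each' or 'pooled'")
  if (object@quantile_type < 1L || object@quantile_type > 9L)
    return("'quantile_type' must be in 1..9")
  TRUE
})

#' Construct ecotype detection parameters
#'
#' @param min_ingroup_prevalence Fraction of ingroup samples that must carry
#'   the oligotype.
#' @param outgroup_pass_fraction Fraction of each outgroup's samples that must
#'   fall below the threshold.
#' @param ingroup_quantile Quantile of the non-zero ingroup proportions.
#' @param quantile_shrink Shrink factor applied to that quantile.
#' @param outgroup_mode "each" (every outgroup individually) or "pooled".
#' @param quantile_type \code{stats::quantile} estimator type.
#' @return An \code{EcotypeParams} object.
#' @examples
#' ecotypeParams()
#' @export
ecotypeParams <- function(min_ingroup_prevalence = 0.5,
                          outgroup_pass_fraction = 0.9,
                          ingroup_quantile = 0.10,
                          quantile_shrink = 0.5,
                          outgroup_mode = c("each", "pooled"),
                          quantile_type = 7) {
  new("EcotypeParams",
      min_ingroup_prevalence = as.numeric(min_ingroup_prevalence),
      outgroup_pass_fraction = as.numeric(outgroup_pass_fraction),
      ingroup_quantile = as.numeric(ingroup_quantile),
      quantile_shrink = as.numeric(quantile_shrink),
      outgroup_mode = match.arg(outgroup_mode),
      quantile_type = as.integer(quantile_type))
}

## ---------------------------------------------------------------------------
## Data classes
## ---------------------------------------------------------------------------

#' Padded left-anchored amplicon alignment
#'
#' Reads sharing a primer-anchored start are stacked left-anchored and padded
#' on the right with '-' to a common width, giving the positional alignment
#' on which column entropies are computed. Internally each row is encoded as
#' integers 1..5 over the symbol alphabet A, C, G, T, '-'.
#'
#' @slot mat Integer matrix, reads x positions, values in 1..5.
#' @slot readIds Character, one id per row.
setClass("PaddedAlignment", representation(
  mat = "matrix", readIds = "character"
))

setValidity("PaddedAlignment", function(object) {
  if (nrow(object@mat) != length(object@readIds))
    return("row count must equal number of read ids")
  if (nrow(object@mat) > 0L) {
    rng <- range(object@mat)
    if (is.na(rng[1L]) || rng[1L] < 1L || rng[2L] > 5L)
      return("alignment cells must be integer codes in 1..5")
  }
  TRUE
})

#' Result of a minimum entropy decomposition
#'
#' @slot nodes data.frame with one row per final oligotype: \code{node_id}
#'   (path of split symbols from the root), \code{size} (member reads after
#'   relocation), \code{size_core} (members before relocation),
#'   \code{n_relocated}, \code{max_entropy} (residual maximum positional
#'   entropy, below the threshold), \code{representative} (most abundant
#'   unique member sequence, padding stripped).
#' @slot assignment Character, one final node id per input read (NA for
#'   unrelocated outliers when relocation is off).
#' @slot readIds Character, input read ids in input order.
#' @slot params The \code{MedParams} used.
setClass("MedDecomposition", representation(
  nodes = "data.frame", assignment = "character", readIds = "character",
  params = "MedParams"
))

setValidity("MedDecomposition", function(object) {
  if (length(object@assignment) != length(object@readIds))
    return("one assignment per read required")
  assigned <- object@assignment[!is.na(object@assignment)]
  if (!all(assigned %in% object@nodes$node_id))
    return("assignments must reference final node ids")
  TRUE
})

#' Oligotype count container
#'
#' A thin \linkS4class{SummarizedExperiment}: one assay \code{"counts"} with
#' oligotypes as rows and samples as columns, oligotype annotation (node id,
#' representative sequence, residual entropy) as \code{rowData}, and sample
#' metadata (environment categories, environment group, sample type, total
#' community sequence count) as \code{colData}.
#'
#' @import SummarizedExperiment
setClass("OligotypeExperiment", contains = "SummarizedExperiment")

setValidity("OligotypeExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("an assay named 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    return("counts must be non-negative integers")
  cd <- SummarizedExperiment::colData(object)
  need <- c("environment_group", "sample_type", "total_community_sequences")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if (any(cd$total_community_sequences < colSums(cnt)))
    return("total_community_sequences must be >= per-sample taxon counts")
  TRUE
})

#' A simulated multi-environment amplicon scenario
#'
#' Bundles everything one simulator run emits: the reads, the sample
#' metadata, the fabricated alignment-hit table, the template pool, and the
#' read-level ground truth linking each read to its template and sample.
#'
#' @slot reads \code{DNAStringSet}, names follow \code{{sample}_Read{n}}.
#' @slot metadata data.frame of per-sample metadata.
#' @slot hits data.frame, 12-column BLAST-style tabular hits.
#' @slot templates data.frame: template_id, role (planted-ecotype or
#'   background), sequence, length.
#' @slot groundTruth data.frame: read_id, oligotype_id (template), sample_id.
#' @slot config The generating \code{ScenarioConfig}.
setClass("AmpliconSimulation", representation(
  reads = "ANY", metadata = "data.frame", hits = "data.frame",
  templates = "data.frame", groundTruth = "data.frame",
  config = "ScenarioConfig"
))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig:",
      object@n_environments, "environments x",
      object@samples_per_environment, "samples;",
      object@n_background_oligotypes, "background +",
      object@n_planted_ecotypes, "planted templates (target:",
      paste0(object@planted_target_environment, ")"), "\n")
  cat("  read length", paste(object@read_length_range, collapse = "-"),
      "bp; depth", paste(object@depth_range, collapse = "-"),
      "; error", object@per_base_error_rate, "; seed", object@rng_seed, "\n")
})

setMethod("show", "FilterCriteria", function(object) {
  cat("FilterCriteria: identity >=", object@min_identity,
      "| align len >=", object@min_align_length,
      "| qstart <=", object@max_qstart,
      "| qend >=", object@min_qend, "\n")
  cat("  sstart in [", paste(object@sstart_window, collapse = ", "),
      "] | send >=", object@min_send,
      "| read length in [", object@min_read_len, ",", object@max_read_len,
      "]\n")
})

setMethod("show", "MedParams", function(object) {
  cat("MedParams: m =", object@m, "| d =", object@d, "| M =", object@M,
      "| relocate =", object@R, "\n")
})

setMethod("show", "EcotypeParams", function(object) {
  cat("EcotypeParams: prevalence >=", object@min_ingroup_prevalence,
      "| outgroup pass >=", object@outgroup_pass_fraction,
      "| threshold =", object@quantile_shrink, "x Q(",
      object@ingroup_quantile, ") of nonzero ingroup;",
      "outgroups:", object@outgroup_mode, "\n")
})

setMethod("show", "PaddedAlignment", function(object) {
  cat("PaddedAlignment:", nrow(object@mat), "reads x", ncol(object@mat),
      "positions\n")
})

setMethod("show", "MedDecomposition", function(object) {
  cat("MedDecomposition:", nrow(object@nodes), "final oligotypes over",
      length(object@readIds), "reads\n")
  if (nrow(object@nodes)) {
    o <- order(-object@nodes$size)
    top <- utils::head(object@nodes[o, c("node_id", "size", "max_entropy")], 5L)
    print(top, row.names = FALSE)
  }
})

setMethod("show", "AmpliconSimulation", function(object) {
  cat("AmpliconSimulation:", length(object@reads), "reads,",
      nrow(object@metadata), "samples,",
      nrow(object@templates), "templates\n")
})
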