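## Internal helpers shared across modules.

# Derive a reproducible child seed (< 2^31) from a master seed and a stream
# index, so each generated artifact draws from its own stream and
# regenerating one artifact does not perturb the others.
childSeed <- function(seed, stream) {
  as.integer(((as.numeric(seed) %% 2147483399) * 48271 +
                stream * 7919) %% 2147483399)
}

# Evaluate an expression under a local RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Symbol alphabet of the padded alignment, in code order 1..5.
alignmentAlphabet <- function() c("A", "C", "G", "T", "-")

# ASCII -> symbol-code lookup (A=1, C=2, G=3, T=4, '-'=5, 0 otherwise).
asciiCodeMap <- function() {
  map <- integer(128L)
  map[utf8ToInt("ACGT-")] <- 1:5
  map
}

# Parse sample ids from read ids under the `{sample}_Read{n}` header dialect:
# the sample id is everything before the last underscore-delimited token.
#' Parse sample attribution from read identifiers
#'
#' Read headers follow the \code{{sample_id}_Read{n}} dialect: the sample id
#' is everything before the last underscore-delimited token.
#'
#' @param read_ids Character vector of read identifiers.
#' @return Character vector of sample ids.
#' @examples
#' parseSampleIds(c("S001_Read1", "plume_A_Read20"))
#' @export
parseSampleIds <- function(read_ids) {
  bad <- !grepl("_", read_ids, fixed = TRUE)
  if (any(bad))
    stop("read ids not parseable under the '{sample}_Read{n}' dialect: ",
         paste(utils::head(read_ids[bad], 5L), collapse = ", "),
         if (sum(bad) > 5L) " ..." else "")
  sub("_[^_]*$", "", read_ids)
}
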