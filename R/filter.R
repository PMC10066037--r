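## Pre-oligotyping retention rules: a read-level length/ambiguity screen and
## the alignment-criteria taxon filter on BLAST tabular hits. A query is
## retained by the alignment stage when ANY of its hits satisfies all six
## criteria (the any-hit rule; hit-level resolution is not prescribed by a
## best-hit search, and this choice is flagged in the filter report header).

#' Length and ambiguity read filter
#'
#' Retains reads whose length lies inclusively within the configured window
#' and whose sequence contains only unambiguous bases A/C/G/T. Input order is
#' preserved; the filter is idempotent.
#'
#' @param reads A \code{DNAStringSet} (or named character vector).
#' @param criteria A \code{FilterCriteria}.
#' @return \code{DNAStringSet} of retained reads.
#' @examples
#' reads <- Biostrings::DNAStringSet(c(
#'   S1_Read1 = paste(rep("ACGT", 95), collapse = "")))
#' length(lengthAmbiguityFilter(reads))  # 380 bp, retained
#' @export
lengthAmbiguityFilter <- function(reads, criteria = filterCriteria()) {
  if (!is(reads, "XStringSet"))
    reads <- Biostrings::DNAStringSet(toupper(reads))
  if (length(reads) == 0L) return(reads)
  w <- Biostrings::width(reads)
  clean <- rowSums(Biostrings::letterFrequency(reads, c("A", "C", "G", "T"))) == w
  keep <- w >= criteria@min_read_len & w <= criteria@max_read_len & clean
  reads[keep]
}

#' Alignment-criteria taxon filter
#'
#' A query is retained when at least one of its hits simultaneously
#' satisfies: identity >= \code{min_identity}, alignment length >=
#' \code{min_align_length}, query start <= \code{max_qstart}, query end >=
#' \code{min_qend}, subject start inside \code{sstart_window}, and subject
#' end >= \code{min_send} (all bounds inclusive). Multiple hits per query are
#' allowed; the returned set is invariant to row order and duplication.
#'
#' @param hits Hits data.frame (see \code{\link{readAlignmentHits}}).
#' @param criteria A \code{FilterCriteria}.
#' @return Sorted character vector of retained query ids.
#' @export
alignmentCriteriaFilter <- function(hits, criteria = filterCriteria()) {
  validateHits(hits)
  pass <- hits$identity >= criteria@min_identity &
    hits$align_length >= criteria@min_align_length &
    hits$qstart <= criteria@max_qstart &
    hits$qend >= criteria@min_qend &
    hits$sstart >= criteria@sstart_window[1L] &
    hits$sstart <= criteria@sstart_window[2L] &
    hits$send >= criteria@min_send
  sort(unique(hits$query_id[pass]))
}

#' Run both retention stages on a read set
#'
#' Applies the length/ambiguity screen, then keeps reads whose id is in the
#' alignment-retained query set, then (optionally) an arbitrary taxonomy
#' predicate on read ids standing in for an external classifier cross-check
#' (default: pass-through).
#'
#' @param reads \code{DNAStringSet}.
#' @param hits Hits data.frame.
#' @param criteria A \code{FilterCriteria}.
#' @param taxonomyPredicate Optional \code{function(read_ids) -> logical};
#'   \code{NULL} means keep everything.
#' @return List: \code{retained} (DNAStringSet), \code{rejected}
#'   (data.frame read_id, stage), \code{report} (see
#'   \code{\link{filterReport}}).
#' @export
filterReads <- function(reads, hits, criteria = filterCriteria(),
                        taxonomyPredicate = NULL) {
  if (!is(reads, "XStringSet"))
    reads <- Biostrings::DNAStringSet(toupper(reads))
  ids0 <- names(reads)
  if (is.null(ids0)) stop("reads must be named with read ids")
  s1 <- lengthAmbiguityFilter(reads, criteria)
  keepAln <- alignmentCriteriaFilter(hits, criteria)
  s2 <- s1[names(s1) %in% keepAln]
  if (!is.null(taxonomyPredicate)) {
    ok <- taxonomyPredicate(names(s2))
    s3 <- s2[ok]
  } else s3 <- s2
  rej <- function(ids, stage) data.frame(
    read_id = ids, stage = rep(stage, length(ids)), stringsAsFactors = FALSE)
  rejected <- rbind(
    rej(setdiff(ids0, names(s1)), "length_ambiguity"),
    rej(setdiff(names(s1), names(s2)), "alignment_criteria"),
    rej(setdiff(names(s2), names(s3)), "taxonomy"))
  report <- filterReport(ids0, names(s1), names(s2), names(s3))
  list(retained = s3, rejected = rejected, report = report)
}

#' Per-sample and total filter accounting
#'
#' Counts reads entering and surviving each retention stage, per sample and
#' in total; input equals retained plus rejected at every stage by
#' construction.
#'
#' @param input,after_length,after_alignment,after_taxonomy Character vectors
#'   of read ids present at each stage (\code{after_taxonomy} defaults to
#'   \code{after_alignment}).
#' @return data.frame with one row per sample plus a TOTAL row; the any-hit
#'   decision is recorded in the \code{"note"} attribute (written as a header
#'   comment by \code{\link{writeFilterReport}}).
#' @export
filterReport <- function(input, after_length, after_alignment,
                         after_taxonomy = after_alignment) {
  samples <- parseSampleIds(input)
  lvl <- unique(samples)
  cnt <- function(ids) {
    if (!length(ids)) return(setNames(integer(length(lvl)), lvl))
    table(factor(parseSampleIds(ids), levels = lvl))
  }
  df <- data.frame(sample_id = lvl,
                   n_input = as.integer(cnt(input)),
                   n_after_length = as.integer(cnt(after_length)),
                   n_after_alignment = as.integer(cnt(after_alignment)),
                   n_retained = as.integer(cnt(after_taxonomy)),
                   stringsAsFactors = FALSE)
  total <- data.frame(sample_id = "TOTAL", n_input = length(input),
                      n_after_length = length(after_length),
                      n_after_alignment = length(after_alignment),
                      n_retained = length(after_taxonomy),
                      stringsAsFactors = FALSE)
  out <- rbind(df, total)
  attr(out, "note") <-
    "hit semantics: a query is retained if ANY of its hits passes all criteria"
  out
}

#' Write a filter report TSV (with its decision note as a header comment)
#'
#' @param report data.frame from \code{\link{filterReport}}.
#' @param path Output TSV.
#' @export
writeFilterReport <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  note <- attr(report, "note")
  if (!is.null(note)) writeLines(paste0("# ", note), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
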