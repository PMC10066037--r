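## Readers and writers for the plain-text formats the pipeline exchanges:
## FASTA reads (Biostrings), 12-column BLAST tabular hits, sample metadata
## TSV, and the samples x oligotypes count matrix TSV.

blastColumns <- function() c(
  "query_id", "subject_id", "identity", "align_length", "mismatches",
  "gap_opens", "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read amplicon sequences from FASTA
#'
#' Sequences are ingested upper-cased; headers must follow the
#' \code{{sample}_Read{n}} dialect (checked lazily by consumers that need
#' sample attribution).
#'
#' @param path FASTA file.
#' @return A \code{DNAStringSet}.
#' @export
readAmpliconFasta <- function(path) {
  reads <- Biostrings::readDNAStringSet(path)
  names(reads) <- sub("\\s.*$", "", names(reads))
  reads
}

#' Read a 12-column BLAST-style tabular hits file
#'
#' Standard outfmt-6 column order: query, subject, identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, evalue,
#' bitscore. Malformed rows raise an error naming the line.
#'
#' @param path Tab-separated hits file.
#' @return data.frame with typed columns named as in
#'   \code{medEcotyper:::blastColumns()}.
#' @export
readAlignmentHits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(stats::setNames(
      data.frame(matrix(nrow = 0L, ncol = 12L)), blastColumns()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("malformed alignment hit row (expected 12 tab-separated fields) ",
         "at line ", which(nf != 12L)[1L])
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 12L, byrow = TRUE)
  df <- data.frame(m, stringsAsFactors = FALSE)
  names(df) <- blastColumns()
  numCols <- setdiff(blastColumns(), c("query_id", "subject_id"))
  for (cc in numCols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      stop("malformed alignment hit value in column '", cc, "' at line ",
           which(is.na(v))[1L])
    df[[cc]] <- v
  }
  validateHits(df)
  df
}

# Structural checks shared by the reader and in-memory hit tables.
validateHits <- function(hits) {
  need <- blastColumns()
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hits table lacks columns: ", paste(miss, collapse = ", "))
  if (any(hits$identity < 0 | hits$identity > 100))
    stop("hit identity outside [0, 100]")
  if (any(hits$qstart > hits$qend))
    stop("hit with qstart > qend")
  if (any(hits$align_length < 1))
    stop("hit with alignment length < 1")
  invisible(hits)
}

#' Write a hits table in 12-column tabular format
#'
#' @param hits data.frame as returned by \code{\link{readAlignmentHits}}.
#' @param path Output file.
#' @export
writeAlignmentHits <- function(hits, path) {
  utils::write.table(hits[blastColumns()], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns sample_id, salinity, zone, water_depth_class,
#'   vent_influence, artificial, environment_group, sample_type,
#'   total_community_sequences (plus optional simulator columns).
#' @return data.frame.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "environment_group", "sample_type",
            "total_community_sequences")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' Write a sample metadata table
#'
#' @param metadata data.frame as produced by \code{\link{generateMetadata}}.
#' @param path Output TSV.
#' @export
writeSampleMetadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an oligotype count matrix as TSV (samples as rows)
#'
#' @param x An \code{OligotypeExperiment} or an oligotypes x samples matrix.
#' @param path Output TSV.
#' @export
writeOligotypeMatrix <- function(x, path) {
  m <- if (is(x, "OligotypeExperiment")) oligotypeCounts(x) else x
  out <- data.frame(sample_id = colnames(m), t(m), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an oligotype count matrix TSV (samples as rows)
#'
#' @param path TSV written by \code{\link{writeOligotypeMatrix}}.
#' @return Integer matrix, oligotypes x samples.
#' @export
readOligotypeMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(m) <- df$sample_id
  storage.mode(m) <- "integer"
  m
}

#' Assemble an OligotypeExperiment from a count matrix and metadata
#'
#' @param counts Oligotypes x samples integer matrix.
#' @param metadata data.frame with one row per sample (matched by
#'   \code{sample_id}).
#' @param rowData Optional per-oligotype annotation data.frame.
#' @return An \code{OligotypeExperiment}.
#' @export
makeOligotypeExperiment <- function(counts, metadata, rowData = NULL) {
  miss <- setdiff(colnames(counts), metadata$sample_id)
  if (length(miss))
    stop("samples present in counts but absent from metadata: ",
         paste(miss, collapse = ", "))
  md <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(md, row.names = md$sample_id)
  if (is.null(rowData))
    rowData <- S4Vectors::DataFrame(node_id = rownames(counts),
                                    row.names = rownames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rowData, colData = cd)
  new("OligotypeExperiment", se)
}
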