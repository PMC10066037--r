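## Minimum entropy decomposition of a padded amplicon alignment.
##
## Reads are partitioned recursively: at each node the Shannon entropy
## (base 2, over the five symbols A, C, G, T, '-') of every alignment column
## is computed from the node's members; if the maximum falls below the
## threshold m the node is a final oligotype, otherwise the node splits on
## the symbol(s) at the d highest-entropy columns. Children whose most
## abundant unique sequence occurs fewer than M times are pruned as
## outliers; their reads are optionally relocated to the closest surviving
## oligotype representative by Hamming distance. The implementation
## collapses identical padded sequences to weighted unique rows, which
## leaves the partition unchanged but makes entropy profiles cheap.

#' Stack reads into a padded left-anchored alignment
#'
#' Reads share a primer-anchored start, so they are aligned by stacking
#' left-anchored rows and padding each on the right with '-' up to the
#' longest read. Under the substitution-only noise model this padding-based
#' alignment is exact.
#'
#' @param reads \code{DNAStringSet} or named character vector of A/C/G/T
#'   sequences.
#' @return A \code{PaddedAlignment}.
#' @examples
#' aln <- padReads(c(r1 = "ACGT", r2 = "ACG"))
#' aln
#' @export
padReads <- function(reads) {
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  if (length(reads) == 0L) stop("decomposition error: empty read set")
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
  w <- nchar(reads)
  width <- max(w)
  padded <- paste0(reads, strrep("-", width - w))
  map <- asciiCodeMap()
  mat <- matrix(map[utf8ToInt(paste(padded, collapse = ""))],
                nrow = length(reads), ncol = width, byrow = TRUE)
  if (any(mat == 0L))
    stop("decomposition error: sequences contain symbols outside A/C/G/T")
  new("PaddedAlignment", mat = mat, readIds = ids)
}

# Entropy (bits) of each column for the unique rows `rows` of U weighted by
# `wv`; returns a numeric vector of length ncol(U).
entropyProfileWeighted <- function(U, rows, wv) {
  sub <- U[rows, , drop = FALSE]
  n <- sum(wv)
  H <- numeric(ncol(U))
  for (s in 1:5) {
    p <- as.vector(wv %*% (sub == s)) / n
    nz <- p > 0
    H[nz] <- H[nz] - p[nz] * log2(p[nz])
  }
  H
}

#' Shannon entropy of one alignment column
#'
#' Base-2 entropy of the empirical symbol frequencies (A, C, G, T, '-') in
#' the given column, bounded by log2(5).
#'
#' @param alignment A \code{PaddedAlignment}.
#' @param column 1-based column index.
#' @return Entropy in bits.
#' @examples
#' aln <- padReads(c(a = "AA", b = "AG"))
#' columnEntropy(aln, 2)  # 1 bit
#' @export
columnEntropy <- function(alignment, column) {
  stopifnot(is(alignment, "PaddedAlignment"))
  if (column < 1L || column > ncol(alignment@mat))
    stop("column index out of range")
  cnt <- tabulate(alignment@mat[, column], 5L)
  p <- cnt / sum(cnt)
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Entropy profile of a padded alignment
#'
#' @param alignment A \code{PaddedAlignment}.
#' @return Numeric vector of per-column entropies in bits.
#' @export
entropyProfile <- function(alignment) {
  stopifnot(is(alignment, "PaddedAlignment"))
  n <- nrow(alignment@mat)
  entropyProfileWeighted(alignment@mat, seq_len(n), rep(1, n))
}

# Strip terminal padding from a padded sequence string.
stripPadding <- function(s) sub("-+$", "", s)

#' Decompose a padded alignment into oligotypes
#'
#' Runs the recursive minimum entropy decomposition under the given
#' parameters. Ties between equal-entropy columns resolve to the lowest
#' column index; a node splits into one child per observed symbol (tuple)
#' at the discriminant column(s). Children whose most abundant unique
#' sequence count falls below \code{M} are pruned; with \code{R = TRUE}
#' their reads are relocated afterwards (single pass) to the final node
#' whose representative is nearest by Hamming distance on the padded rows,
#' ties going to the larger (pre-relocation) node, then the
#' lexicographically smaller node id.
#'
#' @param alignment A \code{PaddedAlignment}.
#' @param params A \code{MedParams}.
#' @return A \code{MedDecomposition}.
#' @examples
#' reads <- c(rep("AAAA", 6), rep("AGAA", 5))
#' names(reads) <- sprintf("S1_Read%d", seq_along(reads))
#' decomposeReads(padReads(reads), medParams(M = 2))
#' @export
decomposeReads <- function(alignment, params = medParams()) {
  stopifnot(is(alignment, "PaddedAlignment"), is(params, "MedParams"))
  validObject(params)
  mat <- alignment@mat
  ids <- alignment@readIds
  n <- nrow(mat)
  ascii <- utf8ToInt("ACGT-")
  rowStr <- vapply(seq_len(n), function(i) intToUtf8(ascii[mat[i, ]]),
                   character(1L))
  uStr <- unique(rowStr)
  uidx <- match(rowStr, uStr)              # read -> unique row
  U <- mat[match(uStr, rowStr), , drop = FALSE]
  w <- as.numeric(tabulate(uidx, length(uStr)))
  symbols <- alignmentAlphabet()

  finals <- list()
  outliers <- list()

  recurse <- function(rows, id) {
    prof <- entropyProfileWeighted(U, rows, w[rows])
    mx <- max(prof)
    if (mx < params@m) {
      finals[[length(finals) + 1L]] <<- list(id = id, rows = rows, maxH = mx)
      return(invisible(NULL))
    }
    ord <- order(-prof)                    # stable: ties -> lowest index
    dcols <- ord[seq_len(min(params@d, sum(prof > 0)))]
    keyCodes <- U[rows, dcols, drop = FALSE]
    keyNum <- apply(keyCodes, 1L, paste, collapse = "")   # sortable code key
    keySym <- apply(matrix(symbols[keyCodes], nrow = length(rows)), 1L,
                    paste, collapse = "")
    for (k in sort(unique(keyNum))) {
      sel <- rows[keyNum == k]
      childId <- paste(id, keySym[match(k, keyNum)], sep = "|")
      if (max(w[sel]) < params@M) {
        outliers[[length(outliers) + 1L]] <<- sel
      } else {
        recurse(sel, childId)
      }
    }
    invisible(NULL)
  }
  recurse(seq_along(uStr), "root")

  if (!length(finals)) {
    warning("all nodes fell below the minimum substantive abundance; ",
            "zero oligotypes", if (params@R) "; relocation skipped" else "")
    nodes <- data.frame(node_id = character(0L), size = integer(0L),
                        size_core = integer(0L), n_relocated = integer(0L),
                        max_entropy = numeric(0L),
                        representative = character(0L),
                        stringsAsFactors = FALSE)
    return(new("MedDecomposition", nodes = nodes,
               assignment = rep(NA_character_, n), readIds = ids,
               params = params))
  }

  nodeIds <- vapply(finals, `[[`, character(1L), "id")
  coreSize <- vapply(finals, function(f) sum(w[f$rows]), numeric(1L))
  repStr <- vapply(finals, function(f) {
    cand <- f$rows[w[f$rows] == max(w[f$rows])]
    sort(uStr[cand])[1L]                   # tie -> lexicographically smallest
  }, character(1L))
  maxH <- vapply(finals, `[[`, numeric(1L), "maxH")

  # unique row -> final node (NA = outlier)
  nodeOfUnique <- rep(NA_character_, length(uStr))
  for (i in seq_along(finals)) nodeOfUnique[finals[[i]]$rows] <- nodeIds[i]

  relocated <- setNames(integer(length(nodeIds)), nodeIds)
  if (params@R && length(outliers)) {
    outRows <- unlist(outliers, use.names = FALSE)
    target <- relocateOutliers(uStr[outRows], repStr, coreSize, nodeIds)
    nodeOfUnique[outRows] <- target
    tab <- tapply(w[outRows], target, sum)
    relocated[names(tab)] <- as.integer(tab)
  }

  assignment <- nodeOfUnique[uidx]
  sizeTotal <- coreSize + relocated
  nodes <- data.frame(node_id = nodeIds,
                      size = as.integer(sizeTotal),
                      size_core = as.integer(coreSize),
                      n_relocated = as.integer(relocated),
                      max_entropy = maxH,
                      representative = vapply(repStr, stripPadding,
                                              character(1L),
                                              USE.NAMES = FALSE),
                      stringsAsFactors = FALSE)
  new("MedDecomposition", nodes = nodes, assignment = assignment,
      readIds = ids, params = params)
}

#' Assign outlier sequences to their nearest oligotype representative
#'
#' Hamming distance on padded rows (the padding symbol counts as a
#' mismatch); ties break toward the node with the larger pre-relocation read
#' count, then toward the lexicographically smaller node id.
#'
#' @param sequences Character vector of (padded or unpadded) outlier
#'   sequences.
#' @param representatives Character vector of node representative sequences.
#' @param sizes Numeric vector of pre-relocation node read counts.
#' @param node_ids Character vector of node ids.
#' @return Character vector: the chosen node id for each input sequence.
#' @export
relocateOutliers <- function(sequences, representatives, sizes, node_ids) {
  if (!length(node_ids)) {
    warning("no final oligotypes; relocation skipped")
    return(rep(NA_character_, length(sequences)))
  }
  width <- max(nchar(sequences), nchar(representatives))
  pad <- function(s) paste0(s, strrep("-", width - nchar(s)))
  map <- asciiCodeMap()
  toMat <- function(ss) matrix(map[utf8ToInt(paste(pad(ss), collapse = ""))],
                               nrow = length(ss), ncol = width, byrow = TRUE)
  om <- toMat(sequences)
  rm_ <- toMat(representatives)
  tOut <- t(om)
  D <- matrix(0L, nrow = length(sequences), ncol = length(node_ids))
  for (j in seq_along(node_ids))
    D[, j] <- colSums(tOut != rm_[j, ])
  pref <- order(-sizes, node_ids)          # tie-break preference order
  rank <- integer(length(node_ids)); rank[pref] <- seq_along(pref)
  vapply(seq_len(nrow(D)), function(i) {
    cand <- which(D[i, ] == min(D[i, ]))
    node_ids[cand[which.min(rank[cand])]]
  }, character(1L))
}

#' Cross-tabulate a decomposition into an oligotype count container
#'
#' Builds the oligotypes x samples count matrix from the per-read node
#' assignments (sample attribution parsed from read ids) and wraps it with
#' the per-node annotation and the sample metadata as an
#' \code{OligotypeExperiment}. Reads whose sample is missing from the
#' metadata raise a consistency error; metadata samples without reads are
#' dropped with a message.
#'
#' @param decomposition A \code{MedDecomposition}.
#' @param metadata Sample metadata data.frame (needs \code{sample_id},
#'   \code{environment_group}, \code{sample_type},
#'   \code{total_community_sequences}).
#' @return An \code{OligotypeExperiment}.
#' @export
oligotypeTable <- function(decomposition, metadata) {
  stopifnot(is(decomposition, "MedDecomposition"))
  samples <- parseSampleIds(decomposition@readIds)
  miss <- setdiff(unique(samples), metadata$sample_id)
  if (length(miss))
    stop("samples present in reads but absent from metadata: ",
         paste(miss, collapse = ", "))
  lvl <- metadata$sample_id[metadata$sample_id %in% samples]
  if (length(lvl) < nrow(metadata))
    message(nrow(metadata) - length(lvl),
            " metadata sample(s) have no retained reads and are dropped")
  nodes <- decomposition@nodes
  tab <- table(factor(decomposition@assignment, levels = nodes$node_id),
               factor(samples, levels = lvl))
  counts <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  rd <- S4Vectors::DataFrame(nodes, row.names = nodes$node_id)
  makeOligotypeExperiment(counts, metadata, rowData = rd)
}

#' Write decomposition outputs (matrix TSV, representatives FASTA, node report)
#'
#' @param x An \code{OligotypeExperiment} built by \code{\link{oligotypeTable}}.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
writeOligotypeOutputs <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeOligotypeMatrix(x, file.path(dir, "oligotype_matrix.tsv"))
  reps <- Biostrings::DNAStringSet(representatives(x))
  names(reps) <- paste0("OT_", rownames(x))
  Biostrings::writeXStringSet(reps, file.path(dir, "representatives.fasta"),
                              width = 20000L)
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  utils::write.table(rd, file.path(dir, "node_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
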