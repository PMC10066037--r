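# Independent reference implementations used as oracles. Deliberately
# naive: per-read character matrices, entropy recomputed from scratch at
# every node, no unique-sequence collapsing or vectorized shortcuts.

oracleAlphabet <- c("A", "C", "G", "T", "-")

oracleEntropy <- function(chars) {
  p <- as.vector(table(factor(chars, levels = oracleAlphabet))) / length(chars)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

# Naive recursive minimum entropy decomposition (d = 1). Returns the final
# node ids, per-read assignment (NA for unrelocated outliers) and core sizes.
oracleMED <- function(seqs, ids = names(seqs), m = 0.0965, M = 50,
                      relocate = TRUE) {
  width <- max(nchar(seqs))
  padded <- vapply(seqs, function(s)
    paste0(s, strrep("-", width - nchar(s))), character(1), USE.NAMES = FALSE)
  cm <- do.call(rbind, strsplit(padded, ""))
  finals <- list()
  outliers <- integer(0)
  recurse <- function(rows, id) {
    ent <- vapply(seq_len(ncol(cm)),
                  function(j) oracleEntropy(cm[rows, j]), numeric(1))
    mx <- max(ent)
    if (mx < m) {
      finals[[length(finals) + 1L]] <<- list(id = id, rows = rows, maxH = mx)
      return(invisible(NULL))
    }
    j <- which(ent == mx)[1L]              # ties: lowest column index
    for (s in oracleAlphabet) {
      sel <- rows[cm[rows, j] == s]
      if (!length(sel)) next
      if (max(table(padded[sel])) < M) {
        outliers <<- c(outliers, sel)
      } else recurse(sel, paste(id, s, sep = "|"))
    }
  }
  recurse(seq_along(seqs), "root")
  assign <- rep(NA_character_, length(seqs))
  if (!length(finals))
    return(list(node_ids = character(0), assignment = assign,
                representatives = character(0)))
  nid <- vapply(finals, `[[`, character(1), "id")
  sizes <- vapply(finals, function(f) length(f$rows), numeric(1))
  reps <- vapply(finals, function(f) {
    tab <- table(padded[f$rows])
    sort(names(tab)[tab == max(tab)])[1L]
  }, character(1))
  for (i in seq_along(finals)) assign[finals[[i]]$rows] <- nid[i]
  if (relocate && length(outliers)) {
    for (r in outliers) {
      d <- vapply(reps, function(rp)
        sum(strsplit(rp, "")[[1L]] != cm[r, ]), numeric(1))
      cand <- which(d == min(d))
      pick <- cand[order(-sizes[cand], nid[cand])][1L]
      assign[r] <- nid[pick]
    }
  }
  list(node_ids = nid, assignment = assign, representatives = reps)
}

# Canonical form of a partition induced by an assignment vector: a sorted
# list of sorted member-id vectors (NA members collected separately).
canonicalPartition <- function(ids, assignment) {
  parts <- split(ids, assignment)
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[[`, character(1), 1L))]
}

# Brute-force ecotype caller materializing every (oligotype, group,
# outgroup-sample) comparison, with the hand-coded interpolation quantile
# Q = x[floor(h)+1] + (h - floor(h)) * (x[floor(h)+2] - x[floor(h)+1]),
# h = (n-1)p on the sorted values.
oracleQuantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

oracleEcotypes <- function(prop, groups, min_prev = 0.5, pass_frac = 0.9,
                           q = 0.10, shrink = 0.5) {
  groups <- as.character(groups)
  lvl <- unique(groups)
  out <- list()
  for (g in lvl) {
    for (j in seq_len(ncol(prop))) {
      vals <- prop[groups == g, j]
      prev <- sum(vals > 0) / length(vals)
      nz <- vals[vals > 0]
      if (!length(nz)) {
        eco <- FALSE; thr <- NA_real_
      } else {
        thr <- shrink * oracleQuantile(nz, q)
        eco <- prev >= min_prev
        for (h in setdiff(lvl, g)) {
          below <- 0L; tot <- 0L
          for (s in which(groups == h)) {
            tot <- tot + 1L
            if (prop[s, j] < thr) below <- below + 1L
          }
          if (below / tot < pass_frac) eco <- FALSE
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        oligotype_id = colnames(prop)[j], environment_group = g,
        threshold = thr, is_ecotype = eco, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Exhaustive-enumeration expected richness for subsets of size k.
oracleExpectedRichness <- function(presence, k) {
  n <- nrow(presence)
  subsets <- utils::combn(n, k)
  mean(apply(subsets, 2L, function(idx)
    sum(colSums(presence[idx, , drop = FALSE]) > 0)))
}

oracleRichnessSD <- function(presence, k) {
  n <- nrow(presence)
  subsets <- utils::combn(n, k)
  vals <- apply(subsets, 2L, function(idx)
    sum(colSums(presence[idx, , drop = FALSE]) > 0))
  if (length(vals) < 2L) 0 else stats::sd(vals)
}
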