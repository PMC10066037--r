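## Sample-based rarefaction of oligotype richness (gamma diversity): for
## each sampling effort k, subsets of k samples are drawn uniformly without
## replacement (independently across draws) and the number of oligotypes
## present in at least one drawn sample is recorded. Presence/absence
## richness only.

#' Oligotype richness of a sample subset
#'
#' @param x An \code{OligotypeExperiment} or a samples x oligotypes matrix.
#' @param subset Sample names or indices (default: all samples).
#' @return Number of oligotypes with a non-zero count in at least one
#'   subset sample.
#' @export
richness <- function(x, subset = NULL) {
  m <- if (is(x, "OligotypeExperiment")) t(oligotypeCounts(x)) else x
  if (is.null(subset)) subset <- seq_len(nrow(m))
  if (!length(subset)) stop("subset must be non-empty")
  sub <- m[subset, , drop = FALSE]
  sum(colSums(sub > 0) > 0)
}

#' Sample-based rarefaction curve of oligotype richness
#'
#' For each effort k = 1 .. n_samples, \code{n_draws} uniform subsets of k
#' samples are drawn (without replacement within a draw, independently
#' across draws) and the mean and standard deviation of richness recorded.
#' At k = n_samples every draw is the full sample set, so the mean equals
#' the total observed richness with zero variance. A fixed seed yields an
#' identical curve.
#'
#' @param x An \code{OligotypeExperiment} or a samples x oligotypes matrix.
#' @param n_draws Random subsets per effort (default 100).
#' @param seed RNG seed.
#' @return data.frame: \code{k}, \code{mean_richness}, \code{sd_richness},
#'   \code{n_draws}.
#' @export
rarefyOligotypes <- function(x, n_draws = 100, seed = 1) {
  if (n_draws < 1) stop("parameter error: 'n_draws' must be >= 1")
  m <- if (is(x, "OligotypeExperiment")) t(oligotypeCounts(x)) else x
  pres <- m > 0
  n <- nrow(pres)
  withSeed(seed, {
    res <- lapply(seq_len(n), function(k) {
      r <- vapply(seq_len(n_draws), function(i) {
        idx <- sample.int(n, k)
        sum(colSums(pres[idx, , drop = FALSE]) > 0)
      }, numeric(1L))
      c(mean = mean(r), sd = stats::sd(r))
    })
  })
  out <- data.frame(k = seq_len(n),
                    mean_richness = vapply(res, `[[`, numeric(1L), "mean"),
                    sd_richness = vapply(res, `[[`, numeric(1L), "sd"),
                    n_draws = as.integer(n_draws))
  out
}

#' Exact expected rarefaction curve (hypergeometric inclusion formula)
#'
#' E[richness at k] = sum over oligotypes j of 1 - C(n - n_j, k) / C(n, k),
#' with n_j the number of samples containing oligotype j. Exact but only
#' practical for small n; used to validate the Monte-Carlo curve.
#'
#' @param x An \code{OligotypeExperiment} or a samples x oligotypes matrix.
#' @return data.frame: \code{k}, \code{expected_richness}.
#' @export
expectedRarefaction <- function(x) {
  m <- if (is(x, "OligotypeExperiment")) t(oligotypeCounts(x)) else x
  pres <- m > 0
  n <- nrow(pres)
  nj <- colSums(pres)
  expR <- vapply(seq_len(n), function(k)
    sum(1 - exp(lchoose(n - nj, k) - lchoose(n, k))), numeric(1L))
  data.frame(k = seq_len(n), expected_richness = expR)
}

#' Plot a rarefaction curve
#'
#' Mean richness against sampling effort with a +/- 1 sd band.
#'
#' @param curve data.frame from \code{\link{rarefyOligotypes}}.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, the curve.
#' @export
plotRarefaction <- function(curve, ...) {
  graphics::plot(curve$k, curve$mean_richness, type = "l",
                 xlab = "samples drawn", ylab = "oligotype richness", ...)
  lo <- curve$mean_richness - curve$sd_richness
  hi <- curve$mean_richness + curve$sd_richness
  graphics::polygon(c(curve$k, rev(curve$k)), c(lo, rev(hi)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.4))
  graphics::lines(curve$k, curve$mean_richness)
  invisible(curve)
}
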