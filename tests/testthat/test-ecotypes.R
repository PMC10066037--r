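# The hand-worked detection example: ingroup of 6 samples, the oligotype
# present in 4 with proportions {0.10, 0.20, 0.30, 0.40}; one outgroup of
# 10 samples. Q(0.10) of the non-zero values interpolates at h = 0.3 to
# 0.13, so t = 0.065.
workedMatrix <- function(outgroup_vals) {
  ing <- c(0, 0, 0.10, 0.20, 0.30, 0.40)
  vals <- c(ing, outgroup_vals)
  prop <- cbind(vals, 1 - vals)
  colnames(prop) <- c("OTx", "OTrest")
  rownames(prop) <- sprintf("S%03d", seq_along(vals))
  list(prop = prop,
       groups = rep(c("ingroup", "outgroup"), c(6, length(outgroup_vals))))
}

test_that("proportions normalize each sample to 1", {
  oe <- toyExperiment(rbind(c(30, 70), c(100, 0)), groups = c("a", "b"))
  prop <- relativeProportions(oe)
  expect_equal(unname(prop[1, ]), c(0.3, 0.7))
  expect_equal(unname(prop[2, ]), c(1, 0))
  expect_true(all(abs(rowSums(prop) - 1) < 1e-12))
})

test_that("prevalence counts non-zero ingroup samples", {
  wm <- workedMatrix(rep(0, 10))
  expect_equal(ingroupPrevalence(wm$prop, wm$groups, "ingroup", "OTx"), 4 / 6)
  expect_equal(ingroupPrevalence(wm$prop, wm$groups, "outgroup", "OTx"), 0)
  expect_equal(ingroupPrevalence(wm$prop, wm$groups, "ingroup", "OTrest"), 1)
  expect_error(ingroupPrevalence(wm$prop, wm$groups, "nowhere", "OTx"),
               "empty group")
})

test_that("the quantile threshold interpolates order statistics", {
  expect_equal(quantileThreshold(c(0.10, 0.20, 0.30, 0.40)), 0.065)
  expect_equal(quantileThreshold(0.2), 0.1)          # one-point quantile
  expect_equal(quantileThreshold(rep(0.3, 7)), 0.15) # constant -> c/2
  expect_true(is.na(quantileThreshold(numeric(0))))
  expect_true(is.na(quantileThreshold(c(0, 0))))     # zeros are dropped
  # matches the hand-coded h = (n-1)p interpolation on random draws
  set.seed(9)
  for (i in 1:20) {
    x <- runif(sample(1:15, 1))
    expect_equal(quantileThreshold(x), 0.5 * oracleQuantile(x, 0.10))
  }
})

test_that("the worked detection example calls true then false", {
  # outgroup {0, 0.01, 0.5, 0 x 7}: 9 of 10 values below t = 0.065
  wm <- workedMatrix(c(0, 0.01, 0.5, rep(0, 7)))
  calls <- detectEcotypes(wm$prop, wm$groups)
  row <- calls[calls$oligotype_id == "OTx" &
                 calls$environment_group == "ingroup", ]
  expect_equal(row$threshold, 0.065)
  expect_equal(row$q_nonzero, 0.13)
  expect_equal(row$ingroup_prevalence, 4 / 6)
  expect_equal(row$min_outgroup_pass, 0.9)
  expect_true(row$is_ecotype)

  # two outgroup values at or above t: pass fraction 0.8 < 0.9 -> false
  wm2 <- workedMatrix(c(0, 0.07, 0.5, rep(0, 7)))
  calls2 <- detectEcotypes(wm2$prop, wm2$groups)
  row2 <- calls2[calls2$oligotype_id == "OTx" &
                   calls2$environment_group == "ingroup", ]
  expect_equal(row2$min_outgroup_pass, 0.8)
  expect_false(row2$is_ecotype)

  # absence from the ingroup: prevalence 0, never an ecotype
  row3 <- calls[calls$oligotype_id == "OTx" &
                  calls$environment_group == "outgroup", ]
  expect_false(row3$is_ecotype)

  # every (oligotype, group) pair receives a call
  expect_equal(nrow(calls), 2L * 2L)
  # run metadata records the decisions
  meta <- attr(calls, "run_meta")
  expect_match(meta$quantile_method, "type7")
  expect_identical(meta$outgroup_mode, "each")
})

test_that("boundary values sit exactly on the rule's comparisons", {
  # prevalence exactly 0.5 passes (>=); outgroup value exactly t is NOT
  # below t (strict <)
  prop <- cbind(c(0.2, 0, 0.2, 0, 0.1, 0.1, 0.1, 0.1),
                c(0.8, 1, 0.8, 1, 0.9, 0.9, 0.9, 0.9))
  colnames(prop) <- c("OTx", "OTrest")
  groups <- rep(c("g1", "g2"), each = 4)
  calls <- detectEcotypes(prop, groups)
  r <- calls[calls$oligotype_id == "OTx" & calls$environment_group == "g1", ]
  expect_equal(r$ingroup_prevalence, 0.5)
  expect_equal(r$threshold, 0.1)        # both values 0.2 -> Q = 0.2, t = 0.1
  # outgroup values all exactly 0.1 == t -> none below -> pass 0
  expect_equal(r$min_outgroup_pass, 0)
  expect_false(r$is_ecotype)
})

test_that("detection agrees with the brute-force oracle on random matrices", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 50; p <- 50
    counts <- matrix(rpois(n * p, 2) * rbinom(n * p, 1, 0.4), nrow = n)
    counts[rowSums(counts) == 0, 1] <- 1L
    rownames(counts) <- sprintf("S%03d", seq_len(n))
    colnames(counts) <- sprintf("OT%03d", seq_len(p))
    groups <- sample(rep(c("g1", "g2", "g3", "g4", "g5"), each = 10))
    prop <- counts / rowSums(counts)
    calls <- detectEcotypes(prop, groups)
    ora <- oracleEcotypes(prop, groups)
    key <- function(df) df[order(df$oligotype_id, df$environment_group),
                           c("oligotype_id", "environment_group",
                             "is_ecotype")]
    expect_identical(key(calls)$is_ecotype, key(ora)$is_ecotype)
    merged <- merge(calls, ora, by = c("oligotype_id", "environment_group"))
    expect_equal(merged$threshold.x, merged$threshold.y, tolerance = 1e-12)
  }
})

test_that("calls are invariant to per-sample scaling and relabeling", {
  set.seed(5)
  counts <- matrix(rpois(20 * 8, 3), nrow = 20)
  counts[rowSums(counts) == 0, 1] <- 1L
  colnames(counts) <- sprintf("OT%d", 1:8)
  rownames(counts) <- sprintf("S%03d", 1:20)
  groups <- rep(c("g1", "g2", "g3", "g4"), each = 5)
  propA <- counts / rowSums(counts)
  callsA <- detectEcotypes(propA, groups)
  # scale one sample's counts 17-fold: proportions unchanged
  scaled <- counts; scaled[3, ] <- scaled[3, ] * 17L
  propB <- scaled / rowSums(scaled)
  expect_identical(detectEcotypes(propB, groups)$is_ecotype,
                   callsA$is_ecotype)
  # permute samples within groups
  perm <- unlist(lapply(split(seq_len(20), groups), sample))
  callsC <- detectEcotypes(propA[perm, ], groups[perm])
  ord <- order(callsA$oligotype_id, callsA$environment_group)
  ordC <- order(callsC$oligotype_id, callsC$environment_group)
  expect_identical(callsC$is_ecotype[ordC], callsA$is_ecotype[ord])
})

test_that("pooled outgroup mode pools all non-ingroup samples", {
  wm <- workedMatrix(c(0, 0.01, 0.5, rep(0, 7)))
  calls <- detectEcotypes(wm$prop, wm$groups,
                          ecotypeParams(outgroup_mode = "pooled"))
  row <- calls[calls$oligotype_id == "OTx" &
                 calls$environment_group == "ingroup", ]
  expect_equal(row$min_outgroup_pass, 0.9)  # single outgroup: identical here
  expect_match(row$outgroup_pass, "^pooled=")
})

test_that("ecotype summary counts per group and sums sample proportions", {
  wm <- workedMatrix(c(0, 0.01, 0.5, rep(0, 7)))
  calls <- detectEcotypes(wm$prop, wm$groups)
  summ <- ecotypeSummary(calls, wm$prop)
  expect_equal(summ$n_ecotypes,
               sum(calls$is_ecotype))
  pg <- summ$per_group
  expect_equal(pg$n_ecotypes[pg$environment_group == "ingroup"],
               sum(calls$is_ecotype[calls$environment_group == "ingroup"]))
  # the summed ecotype proportion of the ingroup's ecotypes per sample
  eco <- calls$oligotype_id[calls$is_ecotype &
                              calls$environment_group == "ingroup"]
  expect_equal(summ$sample_ecotype_proportion[, "ingroup"],
               rowSums(wm$prop[, eco, drop = FALSE]))
  # no true calls -> all zero counts
  none <- detectEcotypes(
    matrix(0.5, 4, 2, dimnames = list(paste0("S", 1:4), c("A", "B"))),
    c("g1", "g1", "g2", "g2"))
  expect_equal(ecotypeSummary(none)$n_ecotypes, 0)
})

test_that("degenerate groupings are handled", {
  prop <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
                 dimnames = list(c("S1", "S2"), c("A", "B")))
  expect_error(detectEcotypes(prop, c("g1", "g1")), "at least two")
  f <- factor(c("g1", "g2"), levels = c("g1", "g2", "ghost"))
  expect_warning(calls <- detectEcotypes(prop, f), "empty group")
  expect_setequal(unique(calls$environment_group), c("g1", "g2"))
})

test_that("planted ecotypes are recovered with perfect precision and recall", {
  # >= 6 ingroup samples and a 10x+ ingroup-to-outgroup ratio
  cfg <- tinyScenario(n_environments = 4, samples_per_environment = 6,
                      n_planted_ecotypes = 2, per_base_error_rate = 0.005,
                      rng_seed = 77)
  sim <- simulateScenario(cfg)
  gt <- groundTruthExperiment(sim)
  qc <- qcSamples(gt)
  calls <- detectEcotypes(qc)
  rec <- plantedRecovery(calls, sim)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  expect_equal(ecotypeSummary(calls)$n_ecotypes, 2)
})
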