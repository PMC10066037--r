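test_that("padding is left-anchored with terminal gaps only", {
  aln <- padReads(c(S1_Read1 = paste(rep("A", 380), collapse = ""),
                    S1_Read2 = paste(rep("G", 382), collapse = "")))
  expect_equal(ncol(aln@mat), 382L)
  expect_equal(nrow(aln@mat), 2L)
  expect_identical(aln@mat[1, 381:382], c(5L, 5L))  # two terminal '-'
  expect_true(all(aln@mat[2, ] == 3L))
  equal <- padReads(c(a = "ACGT", b = "TGCA"))
  expect_false(any(equal@mat == 5L))
  expect_error(padReads(character(0)), "empty")
})

test_that("column entropy matches closed forms", {
  pure <- padReads(variantReads("AAAA", 10))
  expect_equal(columnEntropy(pure, 1), 0)
  half <- padReads(variantReads(c("A", "G"), c(5, 5)))
  expect_equal(columnEntropy(half, 1), 1)
  sixty <- padReads(variantReads(c("A", "G"), c(6, 4)))
  expect_equal(columnEntropy(sixty, 1),
               -0.6 * log2(0.6) - 0.4 * log2(0.4), tolerance = 1e-12)
  # bounded by log2(5): all five symbols equally frequent
  five <- padReads(c(a = "A", b = "C", c = "G", d = "T",
                     e = "AA"))  # row 'e' contributes A then others pad '-'
  expect_lte(columnEntropy(five, 1), log2(5))
  prof <- entropyProfile(sixty)
  expect_equal(prof[1], columnEntropy(sixty, 1))
})

test_that("two-variant worked examples decompose as traced by hand", {
  v <- c(paste0("AAAAC", strrep("T", 20)), paste0("AAAAG", strrep("T", 20)))
  # 60/55 with M=50: entropy at the variant column 0.9940 > m, both
  # children substantive -> two oligotypes
  reads <- variantReads(v, c(60, 55))
  dec <- decomposeReads(padReads(reads), medParams(M = 50))
  expect_equal(nrow(dec@nodes), 2L)
  expect_setequal(dec@nodes$size, c(60L, 55L))
  expect_setequal(dec@nodes$node_id, c("root|C", "root|G"))
  expect_false(any(is.na(dec@assignment)))

  # 60/40 with M=50 and relocation: the 40-read child is pruned and its
  # reads relocate into the surviving node -> one oligotype of size 100
  reads2 <- variantReads(v, c(60, 40))
  dec2 <- decomposeReads(padReads(reads2), medParams(M = 50, R = TRUE))
  expect_equal(nrow(dec2@nodes), 1L)
  expect_equal(dec2@nodes$size, 100L)
  expect_equal(dec2@nodes$size_core, 60L)
  expect_equal(dec2@nodes$n_relocated, 40L)
  expect_equal(sum(table(dec2@assignment)), 100L)  # conservation

  # without relocation the pruned reads stay unassigned
  dec3 <- decomposeReads(padReads(reads2), medParams(M = 50, R = FALSE))
  expect_equal(dec3@nodes$size, 60L)
  expect_equal(sum(is.na(dec3@assignment)), 40L)

  # identical reads only: a single root oligotype, no splits
  dec4 <- decomposeReads(padReads(variantReads(v[1], 30)), medParams(M = 10))
  expect_equal(dec4@nodes$node_id, "root")
  expect_equal(dec4@nodes$max_entropy, 0)
})

test_that("all-outlier decomposition warns and yields zero oligotypes", {
  v <- c("AAAA", "AGAA")
  reads <- variantReads(v, c(30, 29))
  expect_warning(dec <- decomposeReads(padReads(reads), medParams(M = 50)),
                 "zero oligotypes")
  expect_equal(nrow(dec@nodes), 0L)
  expect_true(all(is.na(dec@assignment)))
})

test_that("outlier relocation follows distance then size then id", {
  # outlier identical to a representative -> that node, distance 0
  expect_identical(
    relocateOutliers("AAAA", c("AAAA", "TTTT"), c(10, 90), c("n1", "n2")),
    "n1")
  # equidistant from nodes of sizes 80 and 20 -> the larger node
  expect_identical(
    relocateOutliers("AATT", c("AAAA", "TTTT"), c(20, 80), c("n1", "n2")),
    "n2")
  # equal distance and size -> lexicographically smaller node id
  expect_identical(
    relocateOutliers("AATT", c("AAAA", "TTTT"), c(50, 50), c("nB", "nA")),
    "nA")
  # padding counts as mismatch: "AA" pads to "AA--", distance 2 to AAAA
  expect_identical(
    relocateOutliers("AA", c("AAAA", "AATT"), c(10, 10), c("n1", "n2")),
    "n1")
})

test_that("optimized decomposition equals the naive oracle on random toys", {
  for (seed in 1:50) {
    ds <- randomMedDataset(seed)
    dec <- decomposeReads(padReads(ds$reads),
                          medParams(m = ds$m, M = ds$M, R = TRUE))
    ora <- oracleMED(ds$reads, m = ds$m, M = ds$M, relocate = TRUE)
    expect_setequal(dec@nodes$node_id, ora$node_ids)
    expect_identical(canonicalPartition(names(ds$reads), dec@assignment),
                     canonicalPartition(names(ds$reads), ora$assignment),
                     label = sprintf("seed %d", seed))
  }
})

test_that("the oracle also agrees when relocation is disabled", {
  for (seed in 51:60) {
    ds <- randomMedDataset(seed)
    dec <- decomposeReads(padReads(ds$reads),
                          medParams(m = ds$m, M = ds$M, R = FALSE))
    ora <- oracleMED(ds$reads, m = ds$m, M = ds$M, relocate = FALSE)
    keep <- !is.na(ora$assignment)
    expect_identical(is.na(dec@assignment), !keep)
    if (any(keep))
      expect_identical(
        canonicalPartition(names(ds$reads)[keep], dec@assignment[keep]),
        canonicalPartition(names(ds$reads)[keep], ora$assignment[keep]))
  }
})

test_that("final nodes partition the read set when relocating", {
  for (seed in c(3, 17, 29)) {
    ds <- randomMedDataset(seed)
    dec <- decomposeReads(padReads(ds$reads),
                          medParams(m = ds$m, M = ds$M, R = TRUE))
    if (nrow(dec@nodes) == 0) next
    expect_false(any(is.na(dec@assignment)))
    expect_equal(sum(dec@nodes$size), length(ds$reads))
    expect_equal(as.vector(table(dec@assignment)[dec@nodes$node_id]),
                 dec@nodes$size)
  }
})

test_that("raising the entropy threshold never increases oligotype count", {
  ds <- randomMedDataset(42)
  ms <- c(0.01, 0.0965, 0.3, 0.8, 1.5)
  counts <- vapply(ms, function(m)
    nrow(decomposeReads(padReads(ds$reads),
                        medParams(m = m, M = 1))@nodes), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("noisy simulations recover every template as one oligotype", {
  # per-base error 0.005, every template with comfortable substantive
  # abundance: all templates recovered one-to-one in >= 95% of 20 runs
  ok <- 0L
  for (seed in 1:20) {
    cfg <- tinyScenario(n_environments = 2, samples_per_environment = 4,
                        n_background_oligotypes = 3, n_planted_ecotypes = 1,
                        read_length_range = c(80, 90),
                        depth_range = c(900, 1100),
                        ingroup_mean_proportion = 0.4,
                        per_base_error_rate = 0.005, rng_seed = seed)
    sim <- simulateScenario(cfg)
    dec <- decomposeReads(padReads(sim@reads), medParams())
    map <- mapOligotypesToTemplates(dec, sim)
    oneToOne <- nrow(dec@nodes) == nrow(sim@templates) &&
      setequal(map, sim@templates$template_id)
    if (oneToOne) ok <- ok + 1L
  }
  expect_gte(ok / 20, 0.95)
})

test_that("zero-noise oligotypes are exactly the ground-truth templates", {
  cfg <- tinyScenario(per_base_error_rate = 0)
  sim <- simulateScenario(cfg)
  dec <- decomposeReads(padReads(sim@reads), medParams())
  expect_equal(nrow(dec@nodes), nrow(sim@templates))
  expect_setequal(dec@nodes$representative, sim@templates$sequence)
  oe <- oligotypeTable(dec, sim@metadata)
  gt <- groundTruthExperiment(sim)
  # same counts after matching oligotypes to templates by sequence
  ord <- match(sim@templates$sequence, dec@nodes$representative)
  expect_equal(unname(oligotypeCounts(oe)[ord, colnames(gt)]),
               unname(oligotypeCounts(gt)))
})

test_that("the count table is consistent with metadata and conserves reads", {
  cfg <- tinyScenario()
  sim <- simulateScenario(cfg)
  dec <- decomposeReads(padReads(sim@reads), medParams())
  oe <- oligotypeTable(dec, sim@metadata)
  expect_equal(sum(oligotypeCounts(oe)), length(sim@reads))
  expect_equal(unname(colSums(oligotypeCounts(oe))),
               sim@metadata$taxon_depth[match(colnames(oe),
                                              sim@metadata$sample_id)])
  # a read from an unknown sample is a consistency error
  bad <- dec
  bad@readIds[1] <- "GHOST_Read1"
  expect_error(oligotypeTable(bad, sim@metadata), "absent from metadata")
})
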