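test_that("replicate aggregation applies the CV dismissal rule", {
  spots <- tripletTable(list(ab1 = c(100, 100, 100),
                             ab2 = c(100, 102, 140),
                             ab3 = c(100, 110, 112)))
  sheet <- makeSheet("s1", "PDAC", subsite = "head")
  agg <- aggregateReplicates(spots, sheet, cvCutoff = 15)
  rs <- agg$replicateStats
  rownames(rs) <- rs$antibody_id
  v <- exprValues(agg$matrix)

  # identical replicates: CV 0, mean kept, all 3 used
  expect_equal(rs["ab1", "cv"], 0)
  expect_equal(v["ab1", "s1"], 100)
  expect_equal(rs["ab1", "n_used"], 3L)

  # sd([100,102,140]) = 22.54, CV 19.8% > 15: dismiss 140, mean(100,102)
  expect_equal(rs["ab2", "cv"], 100 * sd(c(100, 102, 140)) / 114,
               tolerance = 1e-12)
  expect_equal(rs["ab2", "dismissed_replicate"], 3L)
  expect_equal(v["ab2", "s1"], 101)
  expect_equal(rs["ab2", "n_used"], 2L)

  # CV 6.0% <= 15: all three averaged
  expect_equal(v["ab3", "s1"], mean(c(100, 110, 112)), tolerance = 1e-12)
  expect_equal(rs["ab3", "n_used"], 3L)
  expect_identical(arrayStage(agg$matrix), "raw_aggregated")
})

test_that("dismissal always removes the replicate farthest from the mean", {
  sheet <- makeSheet("s1", "PDAC", subsite = "head")
  for (i in 1:40) {
    set.seed(i)
    vals <- round(runif(3, 50, 200), 2)
    agg <- aggregateReplicates(tripletTable(list(ab = vals)), sheet)
    rs <- agg$replicateStats
    cv <- 100 * sd(vals) / mean(vals)
    expect_equal(rs$n_used, if (cv > 15) 2L else 3L)
    if (cv > 15) {
      expect_equal(rs$dismissed_replicate,
                   which.max(abs(vals - mean(vals))))
      expect_equal(exprValues(agg$matrix)[1, 1],
                   mean(vals[-which.max(abs(vals - mean(vals)))]),
                   tolerance = 1e-12)
    } else {
      expect_true(is.na(rs$dismissed_replicate))
    }
  }
})

test_that("aggregation handles missing replicates and background", {
  # two replicates only: averaged, never dismissed
  df <- makeTriplet(c(100, 140), background = 10)
  agg <- aggregateReplicates(SpotTable(df),
                             makeSheet("s1", "PDAC", subsite = "head"))
  expect_equal(exprValues(agg$matrix)[1, 1], 120)
  expect_equal(agg$replicateStats$n_used, 2L)
  # single replicate: flagged missing
  df1 <- makeTriplet(55)
  agg1 <- aggregateReplicates(SpotTable(df1),
                              makeSheet("s1", "PDAC", subsite = "head"))
  expect_true(is.na(exprValues(agg1$matrix)[1, 1]))
  # background exceeding the signal: subtraction floors at 1
  df2 <- makeTriplet(c(5, 5, 5))
  df2$background <- 50
  agg2 <- aggregateReplicates(SpotTable(df2),
                              makeSheet("s1", "PDAC", subsite = "head"))
  expect_equal(exprValues(agg2$matrix)[1, 1], 1)
})

test_that("failed-sample flagging finds exactly the planted failures", {
  sim <- plantedCohort(nPdac = 15L, nNpc = 10L, nOpd = 15L, nAb = 20L, k = 0L)
  agg <- aggregateReplicates(sim$spots, sim$sheet)
  flagged <- flagFailedSamples(agg$matrix)
  expect_setequal(flagged, sim$failedSamples)

  # homogeneous cohort: nothing flagged
  sim0 <- plantedCohort(nPdac = 10L, nNpc = 10L, nAb = 15L, k = 0L)
  agg0 <- aggregateReplicates(sim0$spots, sim0$sheet)
  expect_length(flagFailedSamples(agg0$matrix), 0L)

  # all samples identical: MAD = 0 fallback must not flag anything
  v <- matrix(100, 5, 6, dimnames = list(antibodyIds(5), sprintf("S%d", 1:6)))
  m <- makeSet(v, rep("PDAC", 6), stage = "raw_aggregated")
  expect_length(flagFailedSamples(m), 0L)
})

test_that("log transform floors at 1 and inverts cleanly", {
  v <- matrix(c(1000, 1, 0.2, 31.6227766), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  m <- makeSet(v, c("PDAC", "NPC"), stage = "raw_aggregated")
  lg <- logTransform(m)
  expect_equal(exprValues(lg)["a", "s1"], 3)
  expect_equal(exprValues(lg)["b", "s1"], 0)   # floored at 1
  expect_equal(exprValues(lg)["a", "s2"], 0)   # 0.2 -> 1 -> 0
  set.seed(4)
  x <- matrix(runif(20, 0.5, 5), 4, 5,
              dimnames = list(antibodyIds(4), sprintf("S%d", 1:5)))
  m2 <- makeSet(10^x, rep("PDAC", 5), stage = "raw_aggregated")
  expect_equal(exprValues(logTransform(m2)), x, tolerance = 1e-12)
})

test_that("round normalization equalizes round means exactly", {
  # hand-checked: antibody values round A [1,3], round B [5,7]
  v <- matrix(c(1, 3, 5, 7), 1, 4,
              dimnames = list("ab1", sprintf("S%d", 1:4)))
  m <- makeSet(v, rep("PDAC", 4), stage = "logged")
  rounds <- setNames(c(1L, 1L, 2L, 2L), colnames(v))
  out <- normalizeRoundMeans(m, rounds)
  expect_equal(unname(exprValues(out)[1, ]), c(3, 5, 3, 5))
  expect_equal(mean(exprValues(out)), 4)

  # single round: identity
  out1 <- normalizeRoundMeans(m, setNames(rep(1L, 4), colnames(v)))
  expect_equal(exprValues(out1), exprValues(m))

  # exactness invariant on simulated data with planted round offsets
  sim <- plantedCohort(nPdac = 20L, nNpc = 16L, nAb = 12L, k = 0L)
  lg <- logTransform(aggregateReplicates(sim$spots, sim$sheet)$matrix)
  rn <- normalizeRoundMeans(lg)
  v2 <- exprValues(rn)
  r <- sampleData(rn)$round
  for (rr in unique(r)) {
    diffs <- abs(rowMeans(v2[, r == rr, drop = FALSE]) - rowMeans(v2))
    expect_lt(max(diffs), 1e-9)
  }
})

test_that("array scaling equalizes reference-set means exactly", {
  # 2 samples with reference means 3 and 5 -> both moved to 4
  v <- matrix(c(3, 3, 5, 5), 2, 2,
              dimnames = list(c("ab1", "ab2"), c("s1", "s2")))
  m <- makeSet(v, c("PDAC", "NPC"), stage = "round_normalized")
  out <- normalizeArrayScale(m, lowcvFraction = 1)
  expect_equal(unname(exprValues(out)), matrix(4, 2, 2), ignore_attr = TRUE)

  # identical samples: zero offsets
  v2 <- matrix(c(1, 2, 1, 2, 1, 2), 2, 3,
               dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  m2 <- makeSet(v2, rep("PDAC", 3), stage = "round_normalized")
  expect_equal(exprValues(normalizeArrayScale(m2, 0.5)), v2)

  expect_error(normalizeArrayScale(m, lowcvFraction = 0.0), "reference")

  # planted per-array offsets shrink the reference-mean variance >= 10x
  sim <- plantedCohort(nPdac = 25L, nNpc = 20L, nAb = 30L, k = 0L,
                       arrayScaleSigma = 0.3)
  rn <- normalizeRoundMeans(logTransform(
    aggregateReplicates(sim$spots, sim$sheet)$matrix))
  fn <- normalizeArrayScale(rn)
  ref <- S4Vectors::metadata(fn)$scaling_reference
  before <- var(colMeans(exprValues(rn)[ref, ]))
  after <- var(colMeans(exprValues(fn)[ref, ]))
  expect_lt(max(after / before, 0), 0.1)
  expect_lt(max(abs(colMeans(exprValues(fn)[ref, ]) -
                    mean(colMeans(exprValues(fn)[ref, ])))), 1e-9)
})

test_that("preanalytical screening is calibrated and detects planted effects", {
  sim <- plantedCohort(nPdac = 40L, nNpc = 40L, nAb = 150L, k = 0L)
  prep <- runPreprocessing(sim$spots, sim$sheet)
  pre <- prep$preanalytical
  # null data: fractions near alpha = 0.01 (binomial 99% bound at n = 150)
  for (f in pre$factor[!is.na(pre$fraction_significant)])
    expect_lt(pre$fraction_significant[pre$factor == f], 0.06)

  # planted hospital effect shows up only for the center factor
  sim2 <- plantedCohort(nPdac = 30L, nNpc = 30L, nAb = 40L, k = 0L)
  lg <- logTransform(aggregateReplicates(sim2$spots, sim2$sheet)$matrix)
  v <- exprValues(lg)
  hosp <- sampleData(lg)$hospital
  v[, hosp == "H01"] <- v[, hosp == "H01"] + 0.5
  SummarizedExperiment::assay(lg, "exprs") <- v
  pre2 <- checkPreanalyticalFactors(lg)
  expect_gt(pre2$fraction_significant[pre2$factor == "center"], 0.5)
  expect_lt(pre2$fraction_significant[pre2$factor == "gender"], 0.2)

  # constant matrix: p = 1 convention, all fractions 0
  vc <- matrix(2, 6, 10, dimnames = list(antibodyIds(6), sprintf("S%d", 1:10)))
  mc <- makeSet(vc, rep(c("PDAC", "NPC"), 5), stage = "fully_normalized")
  prec <- checkPreanalyticalFactors(mc)
  expect_true(all(prec$fraction_significant[!is.na(prec$fraction_significant)] == 0))
})

test_that("full preprocessing pipeline is ordered, counted and deterministic", {
  sim <- plantedCohort(nPdac = 12L, nNpc = 8L, nOpd = 12L, nAb = 15L, k = 0L)
  prep <- runPreprocessing(sim$spots, sim$sheet)
  expect_identical(arrayStage(prep$matrix), "fully_normalized")
  expect_equal(ncol(prep$matrix), 30L)           # 32 samples - 2 failed
  expect_setequal(excludedSamples(prep$matrix)$sample_id, sim$failedSamples)
  expect_equal(prep$stats$n_excluded, 2L)

  prep2 <- runPreprocessing(sim$spots, sim$sheet)
  expect_identical(exprValues(prep$matrix), exprValues(prep2$matrix))

  # row order of the spot table must not change any value (sample order
  # follows first appearance, so align columns before comparing)
  df <- spotData(sim$spots)
  perm <- withr::with_seed(1, sample.int(nrow(df)))
  prep3 <- runPreprocessing(SpotTable(df[perm, ]), sim$sheet)
  expect_equal(exprValues(prep3$matrix)[, colnames(prep$matrix)],
               exprValues(prep$matrix), tolerance = 1e-12)

  # zero-noise cohort: every value from 3 replicates, all CVs zero
  sim0 <- plantedCohort(nPdac = 5L, nNpc = 5L, nAb = 6L, k = 0L,
                        sigmaReplicate = 0, outlierRate = 0,
                        backgroundSigma = 0)
  prep0 <- suppressWarnings(runPreprocessing(sim0$spots, sim0$sheet))
  expect_equal(prep0$stats$pct_from_3_replicates, 100)
  expect_true(all(prep0$replicateStats$cv < 1e-9))
})
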