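test_that("stratified splits honor the per-group floor(2n/3) rule", {
  sheet <- data.frame(sample_id = sprintf("S%03d", 1:186),
                      group = rep(c("PDAC", "NPC"), c(156, 30)),
                      stringsAsFactors = FALSE)
  sp <- stratifiedSplit(sheet, c("PDAC", "NPC"), nRepeats = 10L, seed = 5L)
  for (a in sp@assignments) {
    grp <- ifelse(match(names(a), sheet$sample_id) <= 156, "PDAC", "NPC")
    expect_equal(sum(a == "train" & grp == "PDAC"), 104L)  # floor(2*156/3)
    expect_equal(sum(a == "train" & grp == "NPC"), 20L)    # floor(2*30/3)
    expect_equal(sum(a == "test" & grp == "PDAC"), 52L)
    expect_equal(sum(a == "test" & grp == "NPC"), 10L)
  }
  # distinct repeats, reproducible under the same seed
  expect_gt(length(unique(lapply(sp@assignments, function(a)
    sort(names(a)[a == "train"])))), 1L)
  sp2 <- stratifiedSplit(sheet, c("PDAC", "NPC"), nRepeats = 10L, seed = 5L)
  expect_identical(sp@assignments, sp2@assignments)
  expect_error(stratifiedSplit(sheet[c(1, 157, 158), ], c("PDAC", "NPC")),
               "fewer than 3")
})

test_that("backward elimination yields a full permutation and finds signal", {
  set.seed(41)
  n <- 80
  nAb <- 10
  v <- matrix(rnorm(nAb * n), nAb, n,
              dimnames = list(antibodyIds(nAb), sprintf("S%02d", 1:n)))
  y <- rep(c("PDAC", "NPC"), each = n / 2)
  informative <- c("Ab002", "Ab005", "Ab009")
  v[informative, y == "PDAC"] <- v[informative, y == "PDAC"] + 1.0
  m <- makeSet(v, y)
  tr <- backwardEliminate(m, c("PDAC", "NPC"), seed = 7L)
  expect_setequal(removalOrder(tr), rownames(v))
  expect_length(klCurve(tr), nAb)
  expect_true(all(is.finite(klCurve(tr))))
  # the three strongly informative antibodies survive into the last three
  expect_setequal(utils::tail(removalOrder(tr), 3), informative)

  # the weight-ranked fast mode is a valid approximation: still a full
  # permutation, and the strong markers still outlast the noise
  trw <- backwardEliminate(m, c("PDAC", "NPC"), seed = 7L,
                           method = "weight")
  expect_setequal(removalOrder(trw), rownames(v))
  expect_setequal(utils::tail(removalOrder(trw), 3), informative)
})

test_that("elimination matches the naive brute-force oracle", {
  for (seed in c(101L, 202L)) {
    set.seed(seed)
    n <- 40
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(sprintf("S%02d", 1:n), antibodyIds(5)))
    y <- rep(c(1L, -1L), each = n / 2)
    x[y > 0, 2] <- x[y > 0, 2] + 1.5
    lab <- setNames(ifelse(y > 0, "PDAC", "NPC"), rownames(x))
    tr <- backwardEliminate(t(x), c("PDAC", "NPC"), labels = lab,
                            kFolds = 5L, seed = seed)
    oracle <- eliminationOracle(x, y, kFolds = 5L, cost = 1, seed = seed)
    expect_identical(removalOrder(tr), oracle$removalOrder)
    # warm starts leave the K-L values within solver tolerance of the
    # cold-started oracle without changing the removal ranking
    expect_equal(klCurve(tr)[1:4], oracle$klCurve[1:4], tolerance = 1e-2)
  }
})

test_that("duplicated antibodies are recognized as redundant", {
  set.seed(53)
  n <- 60
  v <- matrix(rnorm(6 * n), 6, n,
              dimnames = list(antibodyIds(6), sprintf("S%02d", 1:n)))
  y <- rep(c("PDAC", "NPC"), each = n / 2)
  v["Ab001", y == "PDAC"] <- v["Ab001", y == "PDAC"] + 2.5
  v["Ab002", ] <- v["Ab001", ]            # identical duplicate
  lab <- setNames(y, colnames(v))
  kl_full <- klError(cvDecisionValues(v, c("PDAC", "NPC"), labels = lab,
                                      seed = 9L),
                     ifelse(y == "PDAC", 1, -1))
  kl_drop <- klError(cvDecisionValues(v, c("PDAC", "NPC"),
                                      panel = setdiff(rownames(v), "Ab002"),
                                      labels = lab, seed = 9L),
                     ifelse(y == "PDAC", 1, -1))
  # removing one copy of a duplicated informative antibody barely moves K-L
  expect_lt(abs(kl_drop - kl_full), 0.15 * kl_full + 0.5)
  # removing the underlying signal entirely hurts much more
  kl_none <- klError(cvDecisionValues(v, c("PDAC", "NPC"),
                                      panel = antibodyIds(6)[3:6],
                                      labels = lab, seed = 9L),
                     ifelse(y == "PDAC", 1, -1))
  expect_gt(kl_none, kl_drop + 5)
})

test_that("endurance scores aggregate removal positions", {
  mktrace <- function(order, r) new("EliminationTrace",
    removalOrder = order, klCurve = seq_along(order) * 1.0,
    repeatIndex = r)
  t1 <- mktrace(c("a", "b", "c"), 1L)
  s1 <- antibodyScores(list(t1))
  expect_equal(s1@scores, c(a = 1, b = 2, c = 3))
  # positions 1 and 3 over two traces average to 2
  t2 <- mktrace(c("c", "b", "a"), 2L)
  s2 <- antibodyScores(list(t1, t2))
  expect_equal(s2@scores[["a"]], 2)
  expect_equal(s2@scores[["b"]], 2)
  # permutation-mean invariant: scores always sum to N(N+1)/2
  expect_equal(sum(s2@scores), 6)
  set.seed(3)
  traces <- lapply(1:5, function(r)
    mktrace(sample(antibodyIds(12)), as.integer(r)))
  expect_equal(sum(antibodyScores(traces)@scores), 12 * 13 / 2)
  expect_error(antibodyScores(list(t1, mktrace(c("a", "b", "z"), 2L))),
               "different antibody sets")
})

test_that("consensus panel counts nonredundant antigens", {
  scores <- new("AntibodyScore",
                scores = setNames(c(25:1), sprintf("clone%02d", 1:25)),
                endurances = matrix(25:1, 25, 1,
                                    dimnames = list(sprintf("clone%02d", 1:25),
                                                    "repeat1")))
  # 25 clones covering 20 antigens
  ann <- data.frame(antibody_id = sprintf("clone%02d", 1:25),
                    antigen = c(sprintf("Ag%02d", 1:20),
                                sprintf("Ag%02d", 1:5)),
                    stringsAsFactors = FALSE)
  cp <- consensusPanel(scores, k = 25L, annotation = ann)
  expect_length(cp$panel, 25L)
  expect_equal(cp$n_nonredundant, 20L)
  expect_error(consensusPanel(scores, k = 26L), "exceeds")

  # score ties break lexicographically
  tied <- new("AntibodyScore", scores = c(b = 2, a = 2, c = 1),
              endurances = matrix(c(2, 2, 1), 3, 1,
                                  dimnames = list(c("b", "a", "c"), "repeat1")))
  expect_equal(consensusPanel(tied, k = 2L)$panel, c("a", "b"))
})

test_that("K-L minimum panel sizing is parsimonious under ties", {
  mk <- function(curve) new("EliminationTrace",
    removalOrder = antibodyIds(length(curve)), klCurve = curve,
    repeatIndex = 1L)
  # sizes 1..5 carry K-L [4, 2.6, 2.5, 3, 5]: minimum at size 3
  r <- klMinimumPanel(mk(c(4, 2.6, 2.5, 3, 5)))
  expect_equal(r$panel_size, 3L)
  expect_equal(r$kl_min, 2.5)
  expect_equal(r$panel, antibodyIds(5)[3:5])  # survivors at size 3
  # K-L improving monotonically toward small panels: size 1 wins
  expect_equal(klMinimumPanel(mk(1:5))$panel_size, 1L)
  # tie between sizes 3 and 4 resolves to the smaller panel
  expect_equal(klMinimumPanel(mk(c(5, 4, 2, 2, 6)))$panel_size, 3L)
})

test_that("signature discovery is reproducible end to end", {
  sim <- plantedCohort(nPdac = 20L, nNpc = 12L, nAb = 12L, k = 3L,
                       delta = 0.8, seed = 77L)
  prep <- runPreprocessing(sim$spots, sim$sheet)
  run1 <- runSignatureDiscovery(prep$matrix, c("PDAC", "NPC"),
                                nRepeats = 2L, panelSize = 6L, seed = 19L)
  run2 <- runSignatureDiscovery(prep$matrix, c("PDAC", "NPC"),
                                nRepeats = 2L, panelSize = 6L, seed = 19L)
  expect_identical(run1$summary, run2$summary)
  expect_identical(run1$consensus, run2$consensus)
  expect_identical(lapply(run1$traces, removalOrder),
                   lapply(run2$traces, removalOrder))
  expect_length(run1$traces, 2L)
  expect_length(run1$evaluations, 2L)
  # trained on 2/3, evaluated on the held-out third
  a <- run1$split@assignments[[1]]
  expect_equal(sum(a == "train"), floor(2 * 20 / 3) + floor(2 * 12 / 3))
})
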