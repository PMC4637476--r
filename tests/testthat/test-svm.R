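test_that("linear SVM separates, is symmetric and deterministic", {
  # two separable points at +/-1 on one antibody
  v <- matrix(c(1, -1), 1, 2, dimnames = list("ab1", c("s1", "s2")))
  m <- makeSet(v, c("PDAC", "NPC"))
  fit <- trainLinearSvm(m, c("PDAC", "NPC"))
  d <- decisionValues(fit, m)
  expect_gt(d[["s1"]], 0)
  expect_lt(d[["s2"]], 0)

  # symmetric data: the midpoint scores zero
  v2 <- matrix(c(2, 1, 0, -1, -2, 1, 2, 0, -2, -1), 2, 5, byrow = TRUE,
               dimnames = list(c("a", "b"), sprintf("s%d", 1:5)))
  m2 <- makeSet(v2[, c(1, 2, 4, 5)], c("PDAC", "PDAC", "NPC", "NPC"))
  fit2 <- trainLinearSvm(m2, c("PDAC", "NPC"))
  mid <- decisionValues(fit2, v2[, 3, drop = FALSE])
  expect_lt(abs(mid), 1e-6)

  # refitting on identical input reproduces the weights exactly
  set.seed(2)
  v3 <- matrix(rnorm(8 * 20), 8, 20,
               dimnames = list(antibodyIds(8), sprintf("S%d", 1:20)))
  m3 <- makeSet(v3, rep(c("PDAC", "NPC"), 10))
  fa <- trainLinearSvm(m3, c("PDAC", "NPC"))
  fb <- trainLinearSvm(m3, c("PDAC", "NPC"))
  expect_identical(fa@weights, fb@weights)
  expect_identical(fa@bias, fb@bias)

  expect_error(trainLinearSvm(makeSet(v3, rep("PDAC", 20)),
                              c("PDAC", "NPC")), "single class")
})

test_that("SMO solution agrees with the e1071 reference solver", {
  skip_if_not_installed("e1071")
  set.seed(13)
  for (i in 1:5) {
    n <- 30 + 4 * i
    x <- matrix(rnorm(n * 10), n, 10)
    y <- rep(c(1L, -1L), length.out = n)
    x[y > 0, 1] <- x[y > 0, 1] + i / 3
    z <- scale(x)
    fit <- sigpanel:::smoFromFeatures(z, y, cost = 1, eps = 1e-5)
    ref <- e1071::svm(z, factor(y, levels = c(1, -1)), kernel = "linear",
                      cost = 1, scale = FALSE)
    w_ref <- drop(t(ref$coefs) %*% ref$SV)
    expect_lt(max(abs(fit$w - w_ref)), 1e-2)
    expect_lt(abs(-fit$rho - (-ref$rho)), 1e-2)
    d_ref <- drop(z %*% w_ref) - ref$rho
    d_fit <- drop(z %*% fit$w) - fit$rho
    expect_lt(max(abs(d_ref - d_fit)), 2e-2)
  }
})

test_that("cross-validated decision values are honest and seeded", {
  set.seed(17)
  n <- 40
  v <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(antibodyIds(5), sprintf("S%02d", 1:n)))
  v[1, ] <- 0.3 * v[1, ] + rep(c(4, -4), each = n / 2)  # wide separation
  m <- makeSet(v, rep(c("PDAC", "NPC"), each = n / 2))
  d <- cvDecisionValues(m, c("PDAC", "NPC"), kFolds = 5L, seed = 3L)
  expect_true(all(d[1:(n / 2)] > 0))
  expect_true(all(d[(n / 2 + 1):n] < 0))

  # leave-one-out is supported
  dloo <- cvDecisionValues(m, c("PDAC", "NPC"), kFolds = n, seed = 3L)
  expect_true(all(sign(dloo) == rep(c(1, -1), each = n / 2)))

  expect_identical(d, cvDecisionValues(m, c("PDAC", "NPC"), kFolds = 5L,
                                       seed = 3L))
  d2 <- cvDecisionValues(m, c("PDAC", "NPC"), kFolds = 5L, seed = 4L)
  expect_false(identical(d, d2))
})

test_that("K-L error matches its closed forms", {
  # maximal uncertainty: d = 0 contributes ln 2 each
  expect_equal(klError(rep(0, 10), rep(1, 10)), 10 * log(2),
               tolerance = 1e-12)
  # clipped-perfect: |d| >= 14 gives ~1e-6 per sample
  expect_lt(klError(c(20, -20, 30), c(1, -1, 1)), 1e-5)
  # hand evaluation: d = [2, -1], y = [+1, -1]
  expect_equal(klError(c(2, -1), c(1, -1)),
               -log(plogis(2)) - log(1 - plogis(-1)), tolerance = 1e-12)
  expect_equal(klError(c(2, -1), c(1, -1)), 0.4402, tolerance = 1e-4)
  expect_error(klError(numeric(0), integer(0)), "empty")
  expect_error(klError(c(1, Inf), c(1, -1)), "finite")
})

test_that("rank AUC matches hand values and is transform-invariant", {
  expect_equal(aucRank(c(1, -1, 0.5, -0.5), c(1, -1, 1, -1)), 1.0)
  # pairs won: (1 > -1), (1 > 0.5), (-0.5 > -1); lost: (-0.5 < 0.5)
  expect_equal(aucRank(c(1, -1, 0.5, -0.5), c(1, -1, -1, 1)), 0.75)
  set.seed(23)
  d <- rnorm(40); y <- rep(c(1, -1), 20)
  expect_equal(aucRank(d, y), aucRank(2 * d + 5, y), tolerance = 1e-12)
  expect_error(aucRank(d, rep(1, 40)), "both classes")
})

test_that("panel evaluation reproduces confusion-matrix arithmetic", {
  # build a trivial identity model so decision values equal the data
  mkmodel <- function(ids) new("SvmModel", panel = "ab1",
    weights = c(ab1 = 1), bias = 0, cost = 1,
    center = c(ab1 = 0), scale = c(ab1 = 1),
    positiveClass = "PDAC", negativeClass = "NPC",
    trainingSamples = character(0))
  # TP=49 FP=2 TN=18 FN=1 -> SN 98.0, SP 90.0, PPV 96.1, NPV 94.7
  d <- c(rep(1, 49), rep(-1, 1), rep(1, 2), rep(-1, 18))
  y <- c(rep("PDAC", 50), rep("NPC", 20))
  ids <- sprintf("t%02d", seq_along(d))
  v <- matrix(d, 1, length(d), dimnames = list("ab1", ids))
  ev <- evaluatePanel(mkmodel(ids), v, labels = setNames(y, ids))
  expect_equal(ev@confusion, c(TP = 49, FP = 2, TN = 18, FN = 1))
  expect_equal(ev@sensitivity, 98.0, tolerance = 1e-9)
  expect_equal(ev@specificity, 90.0, tolerance = 1e-9)
  expect_equal(ev@ppv, 100 * 49 / 51, tolerance = 1e-9)
  expect_equal(ev@npv, 100 * 18 / 19, tolerance = 1e-9)

  # perfectly separated values
  v2 <- matrix(c(2, 3, -2, -3), 1, 4,
               dimnames = list("ab1", sprintf("u%d", 1:4)))
  ev2 <- evaluatePanel(mkmodel(colnames(v2)), v2,
                       labels = setNames(c("PDAC", "PDAC", "NPC", "NPC"),
                                         colnames(v2)))
  expect_equal(ev2@auc, 1.0)
  expect_equal(ev2@sensitivity, 100)
  expect_equal(ev2@specificity, 100)

  # missing class: AUC NA with warning, point metrics still there
  v3 <- v2[, 1:2, drop = FALSE]
  expect_warning(
    ev3 <- evaluatePanel(mkmodel(colnames(v3)), v3,
                         labels = setNames(c("PDAC", "PDAC"), colnames(v3))),
    "lacks one class")
  expect_true(is.na(ev3@auc))
  expect_equal(ev3@sensitivity, 100)
})

test_that("frozen models never change under evaluation", {
  set.seed(31)
  v <- matrix(rnorm(6 * 30), 6, 30,
              dimnames = list(antibodyIds(6), sprintf("S%02d", 1:30)))
  v[1, 1:15] <- v[1, 1:15] + 2
  m <- makeSet(v, rep(c("PDAC", "NPC"), each = 15))
  trainIds <- colnames(v)[c(1:10, 16:25)]
  testIds <- colnames(v)[c(11:15, 26:30)]
  fit <- trainLinearSvm(m[, trainIds], c("PDAC", "NPC"))
  before <- list(fit@weights, fit@bias, fit@center, fit@scale)
  e1 <- evaluatePanel(fit, m[, testIds])
  e2 <- evaluatePanel(fit, m[, testIds])
  expect_identical(list(fit@weights, fit@bias, fit@center, fit@scale), before)
  expect_identical(e1@decisionValues, e2@decisionValues)
  expect_identical(e1@auc, e2@auc)
})
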