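# Independent brute-force oracles. These deliberately avoid the code paths
# they check: literal formula translations, naive loops, or stats::
# reference fits.

# Benjamini-Hochberg step-up by its definition:
# q_i = min over { j : p_(j) >= p_i } of p_(j) * m / j, clipped at 1.
bhOracle <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    js <- which(sp >= pi - 1e-15)
    min(1, min(sp[js] * m / js))
  }, numeric(1))
}

# ROC curve by threshold sweep, integrated with the trapezoid rule
# (diagonal segments handle ties in the decision values).
aucTrapezoid <- function(d, y) {
  pos <- d[y > 0]; neg <- d[y < 0]
  th <- c(Inf, sort(unique(d), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# K-L error written out literally
klOracle <- function(d, y) {
  total <- 0
  for (i in seq_along(d)) {
    p <- 1 / (1 + exp(-d[i]))
    p <- max(min(p, 1 - 1e-6), 1e-6)
    total <- total + if (y[i] > 0) -log(p) else -log(1 - p)
  }
  total
}

# one-way ANOVA through stats::aov
anovaOracle <- function(values, groups) {
  tab <- summary(stats::aov(values ~ factor(groups)))[[1]]
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1])
}

# Naive backward elimination: no Gram downdating, no warm starts — every
# candidate panel is restandardized and refit from scratch. Shares the SMO
# solver and the fold-assignment streams with the implementation (solver
# agreement is checked separately against e1071), so it exercises the
# elimination logic: candidate enumeration, CV plumbing, K-L ranking and
# tie-breaking.
eliminationOracle <- function(x, y, kFolds, cost, seed) {
  current <- colnames(x)
  n <- nrow(x)
  removed <- character(0)
  klc <- rep(NA_real_, length(current))
  round <- 0L
  while (length(current) > 1L) {
    round <- round + 1L
    folds <- sigpanel:::stratifiedFolds(y, kFolds,
                                        sigpanel:::childSeed(seed, "folds", round))
    kl <- setNames(rep(NA_real_, length(current)), current)
    for (cand in current) {
      pan <- setdiff(current, cand)
      d <- rep(NA_real_, n)
      for (f in sort(unique(folds))) {
        tr <- folds != f
        xt <- x[tr, pan, drop = FALSE]
        ctr <- colMeans(xt)
        scl <- apply(xt, 2, sd); scl[scl == 0] <- 1
        ztr <- sweep(sweep(xt, 2, ctr), 2, scl, "/")
        zte <- sweep(sweep(x[!tr, pan, drop = FALSE], 2, ctr), 2, scl, "/")
        fit <- sigpanel:::.smo_solve(tcrossprod(ztr), y[tr], cost)
        d[!tr] <- drop(zte %*% t(ztr) %*% (fit$alpha * y[tr])) - fit$rho
      }
      kl[cand] <- klOracle(d, y)
    }
    best <- names(kl)[order(kl, names(kl))][1]
    klc[length(current) - 1L] <- kl[[best]]
    removed <- c(removed, best)
    current <- setdiff(current, best)
  }
  list(removalOrder = c(removed, current), klCurve = klc)
}
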