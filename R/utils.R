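#' @useDynLib sigpanel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats aggregate anova aov ar complete.cases cutree mad median
#'   pf prcomp pt quantile rbinom rnorm runif sd setNames var
#' @importFrom utils read.delim write.table
NULL

# Deterministic seed streams: every stochastic component draws from a seed
# derived from (master seed, stream name, index), so components are
# independently reproducible and insensitive to evaluation order elsewhere.
childSeed <- function(seed, tag, index = 0L) {
  h <- as.double(seed %% 2147483629L)
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483629
  h <- (h * 131 + as.double(index)) %% 2147483629
  as.integer(h %% 2147483646) + 1L
}

# Run code under a seed without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Stratified fold assignment: within each class, a seeded permutation is
# dealt round-robin into k folds, so folds are balanced to within one
# sample per class. Returns an integer vector of fold ids in input order.
stratifiedFolds <- function(labels, k, seed) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Lexicographic-stable order: ties in the primary key broken by id.
orderWithIdTies <- function(primary, ids, decreasing = FALSE) {
  order(if (decreasing) -primary else primary, as.character(ids))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
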