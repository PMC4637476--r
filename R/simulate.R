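## Synthetic cohort generator. Emulates the statistical and technical
## structure of a multicenter serum antibody-microarray study: fixed group
## sizes with a tumor-subsite breakdown for the cancer group, samples laid
## out on subarrays across slides and analysis rounds, additive log10
## group effects, per-round batch offsets (round 1 inflated), per-array
## offsets, linear-scale replicate noise with occasional outlier spots,
## local background, and a couple of near-signal-free failed samples.

# Demographic composition used by the default design (share of males and
# age mean/sd per diagnosis group).
GROUP_MALE_FRACTION <- c(PDAC = 92 / 156, OPD = 117 / 152, NPC = 20 / 30)
GROUP_AGE <- list(PDAC = c(66, 13), OPD = c(52, 14), NPC = c(62, 14))
DEFAULT_SUBSITES <- c(head = 97L, body = 16L, tail = 10L, other = 16L,
                      unspecified = 17L)

scaleSubsiteCounts <- function(nPdac) {
  if (nPdac == sum(DEFAULT_SUBSITES)) return(DEFAULT_SUBSITES)
  prop <- DEFAULT_SUBSITES / sum(DEFAULT_SUBSITES)
  counts <- floor(prop * nPdac)
  # distribute the remainder to the largest fractional parts (head first)
  rem <- nPdac - sum(counts)
  ord <- order(-(prop * nPdac - counts), names(prop))
  counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  as.integer(counts) |> setNames(names(DEFAULT_SUBSITES))
}

#' Cohort design configuration
#'
#' Defaults reproduce the emulated study design: 156 PDAC (97 head / 16
#' body / 10 tail / 16 other / 17 unspecified), 152 OPD and 30 NPC samples
#' from 5 hospitals, arrayed over 5 rounds x 8 slides x 13 subarrays on
#' 293-antibody arrays printed in triplicate.
#'
#' @param nPdac,nOpd,nNpc group sizes
#' @param subsiteCounts named integer vector over head/body/tail/other/
#'   unspecified summing to \code{nPdac}; by default the study proportions
#'   scaled to \code{nPdac}
#' @param nHospitals,nRounds,slidesPerRound,subarraysPerSlide design shape
#' @param nAntibodies,replicates array content
#' @param seed master seed for the design draw
#' @return a \linkS4class{CohortConfig}
#' @export
cohortConfig <- function(nPdac = 156L, nOpd = 152L, nNpc = 30L,
                         subsiteCounts = scaleSubsiteCounts(nPdac),
                         nHospitals = 5L, nRounds = 5L, slidesPerRound = 8L,
                         subarraysPerSlide = 13L, nAntibodies = 293L,
                         replicates = 3L, seed = 1L) {
  new("CohortConfig", nPdac = as.integer(nPdac), nOpd = as.integer(nOpd),
      nNpc = as.integer(nNpc),
      subsiteCounts = setNames(as.integer(subsiteCounts), names(subsiteCounts)),
      nHospitals = as.integer(nHospitals), nRounds = as.integer(nRounds),
      slidesPerRound = as.integer(slidesPerRound),
      subarraysPerSlide = as.integer(subarraysPerSlide),
      nAntibodies = as.integer(nAntibodies),
      replicates = as.integer(replicates), seed = as.integer(seed))
}

#' Technical noise model
#'
#' Defaults are calibrated so that the simulated replicate coefficient of
#' variation is in the high-single-digit percent range typical of printed
#' triplicate spots (the emulated platform reported a mean replicate CV of
#' 8.3\%), and so that round 1 carries a three-fold inflated batch offset,
#' mimicking a printing-day humidity artifact.
#'
#' @param baselineMu,baselineSigmaAntibody log10 mean intensity and
#'   between-antibody spread of baselines
#' @param sigmaBiological between-sample within-group sd, log10 units
#' @param sigmaReplicate linear-scale replicate noise sd (approximately the
#'   replicate CV)
#' @param roundOffsets explicit per-round log10 offsets; if empty, drawn
#'   N(0, \code{roundOffsetSigma}) with round 1 multiplied by
#'   \code{round1Inflation}
#' @param roundOffsetSigma,round1Inflation see \code{roundOffsets}
#' @param arrayScaleSigma per-array log10 offset sd
#' @param outlierRate,outlierFactor fraction of replicate spots multiplied
#'   by \code{outlierFactor}
#' @param failedSampleIds explicit near-signal-free samples; if empty,
#'   \code{nFailedSamples} samples of \code{failedGroup} are picked by seed
#' @param nFailedSamples,failedGroup,failedAttenuation failed-sample rule
#' @param backgroundMu,backgroundSigma local background level (linear units)
#' @return a \linkS4class{NoiseModel}
#' @export
noiseModel <- function(baselineMu = 3.0, baselineSigmaAntibody = 0.5,
                       sigmaBiological = 0.15, sigmaReplicate = 0.08,
                       roundOffsets = numeric(0), roundOffsetSigma = 0.05,
                       round1Inflation = 3.0, arrayScaleSigma = 0.1,
                       outlierRate = 0.02, outlierFactor = 1.4,
                       failedSampleIds = character(0), nFailedSamples = 2L,
                       failedGroup = "OPD", failedAttenuation = 0.01,
                       backgroundMu = 100, backgroundSigma = 15) {
  new("NoiseModel", baselineMu = baselineMu,
      baselineSigmaAntibody = baselineSigmaAntibody,
      sigmaBiological = sigmaBiological, sigmaReplicate = sigmaReplicate,
      roundOffsets = roundOffsets, roundOffsetSigma = roundOffsetSigma,
      round1Inflation = round1Inflation, arrayScaleSigma = arrayScaleSigma,
      outlierRate = outlierRate, outlierFactor = outlierFactor,
      failedSampleIds = failedSampleIds,
      nFailedSamples = as.integer(nFailedSamples), failedGroup = failedGroup,
      failedAttenuation = failedAttenuation, backgroundMu = backgroundMu,
      backgroundSigma = backgroundSigma)
}

#' Build a randomized cohort design
#'
#' Assigns diagnosis groups and (for PDAC) tumor subsites by the configured
#' counts, draws hospital, gender and age per group, and places every
#' sample on a distinct (round, slide, subarray) array position by a seeded
#' permutation of the available slots.
#'
#' @param cfg a \linkS4class{CohortConfig}
#' @return a \linkS4class{SampleSheet} (deterministic given the config seed)
#' @export
buildDesign <- function(cfg) {
  validObject(cfg)
  groups <- rep(GROUP_LEVELS, c(cfg@nPdac, cfg@nOpd, cfg@nNpc))
  n <- length(groups)
  ids <- sprintf("%s_%03d", groups, unlist(lapply(
    c(cfg@nPdac, cfg@nOpd, cfg@nNpc), seq_len)))
  subsite <- rep(NA_character_, n)
  subsite[groups == "PDAC"] <-
    rep(names(cfg@subsiteCounts), cfg@subsiteCounts)

  icd <- c(head = "ICD9 157.0 head of pancreas",
           body = "ICD9 157.1 body of pancreas",
           tail = "ICD9 157.2 tail of pancreas",
           other = "ICD9 157.8 other pancreas",
           unspecified = "ICD9 157.9 pancreas unspecified")
  opd_dx <- c("acute pancreatitis", "chronic pancreatitis",
              "islet cell neoplasm", "benign pancreatic neoplasm")

  withSeed(childSeed(cfg@seed, "design"), {
    hospital <- sprintf("H%02d", sample.int(cfg@nHospitals, n, replace = TRUE))
    gender <- character(n); age <- integer(n); detail <- character(n)
    for (g in GROUP_LEVELS) {
      idx <- which(groups == g)
      gender[idx] <- ifelse(runif(length(idx)) < GROUP_MALE_FRACTION[[g]],
                            "M", "F")
      age[idx] <- pmin(pmax(round(rnorm(length(idx), GROUP_AGE[[g]][1],
                                        GROUP_AGE[[g]][2])), 18L), 95L)
    }
    detail[groups == "PDAC"] <- icd[subsite[groups == "PDAC"]]
    detail[groups == "OPD"] <- sample(opd_dx, sum(groups == "OPD"),
                                      replace = TRUE,
                                      prob = c(33, 110, 3, 6) / 152)
    detail[groups == "NPC"] <- "nonpancreatic condition"
    slots <- expand.grid(subarray = seq_len(cfg@subarraysPerSlide),
                         slide = seq_len(cfg@slidesPerRound),
                         round = seq_len(cfg@nRounds))
    pick <- slots[sample.int(nrow(slots), n), ]
    SampleSheet(data.frame(
      sample_id = ids, group = groups, subsite = subsite,
      diagnosis_detail = detail, hospital = hospital,
      round = pick$round, slide = pick$slide, subarray = pick$subarray,
      gender = gender, age = age, stringsAsFactors = FALSE))
  })
}

#' Default antibody identifiers
#' @param n number of antibodies
#' @return character vector \code{Ab001 ...}
#' @export
antibodyIds <- function(n) sprintf("Ab%03d", seq_len(n))

#' Plant a differential-expression effect profile
#'
#' Selects (per contrast) a seeded random subset of antibodies to carry a
#' nonzero log10 shift of magnitude \code{delta}; a fraction
#' \code{directionMix} of each informative set gets a negative sign.
#'
#' @param antibodies character vector of antibody ids
#' @param kNpc,kOpd,kSite number of informative antibodies for the PDAC vs
#'   NPC, PDAC vs OPD and head vs body/tail contrasts
#' @param delta effect magnitude in log10 units
#' @param directionMix fraction of informative antibodies shifted downwards
#' @param seed RNG seed
#' @return an \linkS4class{EffectProfile}
#' @export
plantEffectProfile <- function(antibodies, kNpc = 10L, kOpd = 10L,
                               kSite = 0L, delta = 0.5, directionMix = 0.5,
                               seed = 1L) {
  n <- length(antibodies)
  ks <- c(kNpc, kOpd, kSite)
  if (any(ks > n))
    stopf("informative set size (%d) exceeds antibody count (%d)", max(ks), n)
  deltas <- data.frame(antibody_id = antibodies,
                       delta_pdac_vs_npc = 0, delta_pdac_vs_opd = 0,
                       delta_head_vs_bodytail = 0, stringsAsFactors = FALSE)
  cols <- c("delta_pdac_vs_npc", "delta_pdac_vs_opd", "delta_head_vs_bodytail")
  sets <- list()
  withSeed(childSeed(seed, "effects"), {
    for (i in 1:3) {
      if (ks[i] == 0) { sets[[cols[i]]] <- character(0); next }
      chosen <- sample(antibodies, ks[i])
      nNeg <- round(ks[i] * directionMix)
      neg <- if (nNeg > 0) sample(chosen, nNeg) else character(0)
      deltas[match(chosen, antibodies), cols[i]] <-
        ifelse(chosen %in% neg, -delta, delta)
      sets[[cols[i]]] <- sort(chosen)
    }
  })
  names(sets) <- c("pdac_vs_npc", "pdac_vs_opd", "head_vs_bodytail")
  new("EffectProfile", deltas = deltas, informativeSets = sets)
}

# Resolve which samples fail (near-signal-free): explicit ids win,
# otherwise a seeded draw of nFailedSamples from failedGroup.
resolveFailedSamples <- function(noise, sheet, seed) {
  if (length(noise@failedSampleIds)) return(noise@failedSampleIds)
  if (noise@nFailedSamples == 0L) return(character(0))
  df <- sampleData(sheet)
  pool <- df$sample_id[df$group == noise@failedGroup]
  if (!length(pool)) return(character(0))
  withSeed(childSeed(seed, "failed"),
           sort(sample(pool, min(noise@nFailedSamples, length(pool)))))
}

#' Simulate a spot-level intensity table
#'
#' For each (sample, antibody) the true log10 level is antibody baseline +
#' group/subsite effect + biological noise + round offset + array offset.
#' Each replicate spot then measures \code{10^level * (1 + e)} with
#' linear-scale noise \code{e ~ N(0, sigmaReplicate)}, outlier spots
#' multiplied by \code{outlierFactor}, failed samples attenuated, and local
#' background added on top (the background column carries the same draw, so
#' subtraction is exact in expectation).
#'
#' Group effects are parameterized as contrasts: NPC sits at baseline, PDAC
#' at +\code{delta_pdac_vs_npc}, OPD at \code{delta_pdac_vs_npc -
#' delta_pdac_vs_opd}; PDAC head-tumor samples additionally carry
#' +\code{delta_head_vs_bodytail}.
#'
#' @param sheet a \linkS4class{SampleSheet}
#' @param effects an \linkS4class{EffectProfile}
#' @param noise a \linkS4class{NoiseModel}
#' @param seed master seed (all draws come from named derived streams)
#' @param replicates replicate spots per antibody
#' @return a \linkS4class{SpotTable}, rows ordered by sample, antibody,
#'   replicate
#' @export
simulateSpotTable <- function(sheet, effects, noise = noiseModel(),
                              seed = 1L, replicates = 3L) {
  df <- sampleData(sheet)
  abs <- effects@deltas$antibody_id
  n <- nrow(df); nAb <- length(abs); reps <- as.integer(replicates)
  nRounds <- max(df$round)

  baseline <- withSeed(childSeed(seed, "baseline"),
                       rnorm(nAb, noise@baselineMu, noise@baselineSigmaAntibody))
  roundOff <- if (length(noise@roundOffsets) >= nRounds)
    noise@roundOffsets[seq_len(nRounds)]
  else withSeed(childSeed(seed, "rounds"), {
    off <- rnorm(nRounds, 0, noise@roundOffsetSigma)
    off[1] <- off[1] * noise@round1Inflation
    off
  })
  arrayOff <- withSeed(childSeed(seed, "arrays"),
                       rnorm(n, 0, noise@arrayScaleSigma))

  # per-sample group/subsite shift applied to each antibody
  shift <- matrix(0, nAb, n)
  isP <- df$group == "PDAC"; isO <- df$group == "OPD"
  shift[, isP] <- effects@deltas$delta_pdac_vs_npc
  shift[, isO] <- effects@deltas$delta_pdac_vs_npc -
                  effects@deltas$delta_pdac_vs_opd
  isHead <- isP & !is.na(df$subsite) & df$subsite == "head"
  shift[, isHead] <- shift[, isHead] + effects@deltas$delta_head_vs_bodytail

  bio <- withSeed(childSeed(seed, "biology"),
                  matrix(rnorm(nAb * n, 0, noise@sigmaBiological), nAb, n))
  level <- baseline + shift + bio +
    rep(roundOff[df$round] + arrayOff, each = nAb)

  failed <- resolveFailedSamples(noise, sheet, seed)
  atten <- ifelse(df$sample_id %in% failed, noise@failedAttenuation, 1)

  # flatten in (sample, antibody, replicate) order
  si <- rep(seq_len(n), each = nAb * reps)
  ai <- rep(rep(seq_len(nAb), each = reps), times = n)
  ri <- rep(seq_len(reps), times = n * nAb)
  m <- n * nAb * reps
  eps <- withSeed(childSeed(seed, "replicates"),
                  rnorm(m, 0, noise@sigmaReplicate))
  out <- withSeed(childSeed(seed, "outliers"),
                  runif(m) < noise@outlierRate)
  bg <- withSeed(childSeed(seed, "background"),
                 pmax(rnorm(m, noise@backgroundMu, noise@backgroundSigma), 0))
  signal <- 10^level[cbind(ai, si)] * pmax(1 + eps, 0.01) *
    ifelse(out, noise@outlierFactor, 1) * atten[si]

  SpotTable(data.frame(
    sample_id = df$sample_id[si], round = df$round[si], slide = df$slide[si],
    subarray = df$subarray[si], antibody_id = abs[ai], replicate_index = ri,
    segment = ri, intensity = signal + bg, background = bg,
    stringsAsFactors = FALSE))
}

#' Simulate a complete cohort (design + spots + ground truth)
#'
#' @param cfg a \linkS4class{CohortConfig}
#' @param effects planted effects; defaults to a null profile (no group
#'   differences)
#' @param noise a \linkS4class{NoiseModel}
#' @param seed master seed; defaults to the config seed
#' @return list with \code{sheet}, \code{spots}, \code{effects},
#'   \code{failedSamples} (the planted near-signal-free sample ids)
#' @export
simulateCohort <- function(cfg = cohortConfig(), effects = NULL,
                           noise = noiseModel(), seed = cfg@seed) {
  sheet <- buildDesign(cfg)
  if (is.null(effects))
    effects <- plantEffectProfile(antibodyIds(cfg@nAntibodies),
                                  kNpc = 0L, kOpd = 0L, kSite = 0L,
                                  seed = seed)
  spots <- simulateSpotTable(sheet, effects, noise, seed = seed,
                             replicates = cfg@replicates)
  list(sheet = sheet, spots = spots, effects = effects,
       failedSamples = resolveFailedSamples(noise, sheet, seed))
}
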