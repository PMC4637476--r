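# Fixture builders used across the suite. Everything is generated in code;
# no data files.

# minimal valid sample sheet with distinct array positions
makeSheet <- function(ids, groups, subsite = NA_character_,
                      hospital = "H01", gender = "M", age = 60L) {
  n <- length(ids)
  slot <- seq_len(n) - 1L
  SampleSheet(data.frame(
    sample_id = ids, group = groups,
    subsite = rep_len(subsite, n),
    diagnosis_detail = "synthetic", hospital = rep_len(hospital, n),
    round = slot %/% 104L + 1L, slide = (slot %% 104L) %/% 13L + 1L,
    subarray = slot %% 13L + 1L,
    gender = rep_len(gender, n), age = rep_len(age, n),
    stringsAsFactors = FALSE))
}

# wrap a bare antibodies x samples matrix into an ArrayExpressionSet
makeSet <- function(values, groups, stage = "fully_normalized") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("Ab%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  ArrayExpressionSet(values, sheet = makeSheet(colnames(values), groups),
                     stage = stage)
}

# one (sample, antibody) spot triplet as data.frame rows
makeTriplet <- function(values, sample_id = "s1", antibody_id = "ab1",
                        background = 0) {
  data.frame(sample_id = sample_id, round = 1L, slide = 1L, subarray = 1L,
             antibody_id = antibody_id,
             replicate_index = seq_along(values), segment = seq_along(values),
             intensity = values + background, background = background,
             stringsAsFactors = FALSE)
}

# spot table from a named list of triplets (one sample, many antibodies)
tripletTable <- function(triplets, sample_id = "s1") {
  rows <- lapply(names(triplets), function(ab)
    makeTriplet(triplets[[ab]], sample_id = sample_id, antibody_id = ab))
  SpotTable(do.call(rbind, rows))
}

# the standard small planted cohort used by several tests
plantedCohort <- function(nPdac = 30L, nNpc = 15L, nAb = 30L, k = 5L,
                          delta = 0.6, seed = 42L, nOpd = 0L, ...) {
  cfg <- cohortConfig(nPdac = nPdac, nOpd = nOpd, nNpc = nNpc,
                      nAntibodies = nAb, seed = seed)
  eff <- plantEffectProfile(antibodyIds(nAb), kNpc = k, kOpd = 0L,
                            kSite = 0L, delta = delta, seed = seed)
  noi <- noiseModel(nFailedSamples = if (nOpd > 0) 2L else 0L, ...)
  sim <- simulateCohort(cfg, effects = eff, noise = noi, seed = seed)
  sim$cfg <- cfg
  sim
}
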