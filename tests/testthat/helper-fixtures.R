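# Shared fixtures. Recovery tests run under the low-noise validation
# condition (pressure noise SD 0.02 cmH2O); durations are kept to the fewest
# cycles/contractions the check needs.

lowNoiseSd <- 0.02

# sham-phenotype recording in the 5000 Hz acquisition arm (EMG recorded),
# two micturition cycles
shamEmgParams <- function(seed, ...) {
  simParams("sham", preset = "sci-5000hz", durationS = 600,
            noiseSd = lowNoiseSd, emgPattern = "vshape", seed = seed, ...)
}

# SCI recording long enough for five plateau oscillations
sciParams <- function(seed, ...) {
  simParams("SCI", durationS = 160, riseTimeS = 60,
            noiseSd = lowNoiseSd, seed = seed, ...)
}

# SectionEnergies with prescribed section energies
makeSection <- function(b, d, a, startS = 0, endS = 1) {
  tot <- b + d + a
  new("SectionEnergies", eBefore = b, eDuring = d, eAfter = a,
      pctBefore = 100 * b / tot, pctDuring = 100 * d / tot,
      pctAfter = 100 * a / tot,
      sectionBounds = seq(startS, endS, length.out = 6), flagged = FALSE)
}

# independent brute-force scan for the threshold rule: window indices
# i0..i1 (1-based), differences left-assigned, earliest crossing wins
bruteThreshIndex <- function(x, i0, i1, fraction = 0.65) {
  best <- -Inf
  for (i in i0:(i1 - 1L)) best <- max(best, x[i + 1L] - x[i])
  if (best <= 0) return(NA_integer_)
  for (i in i0:(i1 - 1L)) {
    if (x[i + 1L] - x[i] >= fraction * best) return(i)
  }
  NA_integer_
}
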