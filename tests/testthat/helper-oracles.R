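# Independent brute-force oracles, deliberately implemented differently from
# the package internals.

# double-loop pairwise dissimilarity between two pitch sets
oracle_dissimilarity <- function(n, n_prime) {
  total <- 0
  for (a in n) for (b in n_prime) total <- total + abs(a - b)
  total
}

# all voicings of a chord in a window, by subset enumeration: choose
# |tones| pitches from the chord-tone realizations and keep those covering
# every pitch class exactly once
oracle_enumerate_voicings <- function(chord, window) {
  pcs <- chord$tones
  pool <- seq(window[[1]], window[[2]])
  pool <- pool[(pool %% 12) %in% pcs]
  if (length(pool) < length(pcs)) return(list())
  combos <- utils::combn(pool, length(pcs), simplify = FALSE)
  keep <- Filter(function(v) setequal(v %% 12, pcs), combos)
  lapply(keep, function(v) as.integer(sort(v)))
}

# argmin voicing with (lowest bass, lexicographic) tie-break
oracle_best_voicing <- function(chord, previous, window) {
  cands <- oracle_enumerate_voicings(chord, window)
  d <- vapply(cands, oracle_dissimilarity, 0, n_prime = previous)
  best <- cands[d == min(d)]
  key <- vapply(best, function(v) paste(sprintf("%03d", v), collapse = ""), "")
  best[[order(key)[[1]]]]
}

# dissonant-pair count straight from the definition
oracle_dissonance <- function(tones, quality) {
  cnt <- 0
  pairs <- utils::combn(tones, 2, simplify = FALSE)
  for (pr in pairs) {
    d <- abs(pr[[1]] - pr[[2]]) %% 12
    ic <- min(d, 12 - d)
    if (ic %in% c(1, 6)) cnt <- cnt + 1
  }
  cnt + as.integer(quality %in% c("diminished", "augmented"))
}

random_affect_grid <- function(n, seed) {
  set.seed(seed)
  data.frame(valence = runif(n), arousal = runif(n))
}
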