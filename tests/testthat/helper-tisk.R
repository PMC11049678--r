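# Shared fixtures and independent oracles for the test suite.

tiny_inventory <- function() phoneme_inventory(c("p", "b", "t", "d", "k",
                                                 "g", "s", "a", "i", "u"))

# Independent oracle for graded diphone weights: plain double loop over all
# index pairs, accumulating into a named vector.
oracle_graded <- function(word, gamma, rho) {
  ph <- phonemes(word)
  n <- length(ph)
  w <- numeric(0)
  bump <- function(w, key, amt) {
    w[key] <- (if (key %in% names(w)) w[[key]] else 0) + amt
    w
  }
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        w <- bump(w, paste0(ph[i], ph[j]), gamma^(j - i - 1))
        if (rho > 0) {
          w <- bump(w, paste0(ph[j], ph[i]), rho * gamma^(j - i - 1))
        }
      }
    }
  }
  w
}

# Independent oracle for the recognition criterion: exhaustive scan over
# candidate onset cycles, re-checking the margin window and the argmax
# suffix cycle by cycle.
oracle_recognition <- function(m, target, threshold, hold) {
  n <- nrow(m)
  ti <- match(target, colnames(m))
  for (c in seq_len(n)) {
    if (c + hold - 1L > n) break
    ok <- TRUE
    for (h in c:(c + hold - 1L)) {
      others <- m[h, -ti]
      if (length(others) && m[h, ti] - max(others) < threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok && c + hold <= n) {
      for (h in (c + hold):n) {
        others <- m[h, -ti]
        if (length(others) && m[h, ti] <= max(others)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) return(c - 1L)
  }
  NA_integer_
}

# Random word-activation trace matrices for recognition-criterion tests
random_trace <- function(n_cycles, n_words) {
  m <- matrix(runif(n_cycles * n_words), n_cycles, n_words)
  colnames(m) <- paste0("w", seq_len(n_words))
  # smooth a little so margins persist occasionally
  m <- apply(m, 2, function(x) stats::filter(x, rep(1 / 3, 3), sides = 1))
  m[is.na(m)] <- 0.5
  colnames(m) <- paste0("w", seq_len(n_words))
  m
}

# Independent DAS-neighbor oracle via generic edit distance (utils::adist
# with equal-cost deletion/addition/substitution).
oracle_das <- function(wstr, tstr) {
  wstr != tstr && utils::adist(wstr, tstr) <= 1
}

# Independent contiguous-substring oracle via explicit sliding window.
oracle_substring <- function(needle, hay) {
  n <- length(needle)
  h <- length(hay)
  if (n > h) return(FALSE)
  for (s in 0:(h - n)) {
    if (all(hay[(s + 1):(s + n)] == needle)) return(TRUE)
  }
  FALSE
}

# A small competitor-rich lexicon used by several network tests.
doll_lexicon <- function() {
  lexicon(c(doll = "dal", dock = "dak", dot = "dat", ball = "bal",
            tall = "tal", soot = "sut", dollar = "dal^r", log = "lag",
            kat = "kat", tak = "tak"))
}
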