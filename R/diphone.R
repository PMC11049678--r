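#' Ordered open-diphone code of a word
#'
#' The open-diphone code of a phoneme string is the multiset of all ordered
#' phoneme pairs (x, y) such that some occurrence of x precedes some
#' occurrence of y, adjacent or not. For a word of n phonemes the total
#' multiplicity is n(n-1)/2. This fixed-dimension code (a phoneme x phoneme
#' count matrix) is a string kernel: words of any length become comparable
#' vectors, order is preserved (/kat/, /tak/ and /akt/ get different codes),
#' and repeated elements are distinguished (/sol/ vs /solo/, whose code
#' contains /so/ twice plus /oo/).
#'
#' @param word Phoneme string or character vector of phoneme symbols
#'   (length >= 1). Symbols need not belong to any particular inventory.
#' @return Named integer vector of diphone counts; names are the
#'   two-symbol diphones (e.g. `"so"`). A single phoneme yields an empty
#'   code.
#' @examples
#' open_diphones("solo")  # so x 2, sl, ol, oo
#' open_diphones("akt")
#' @export
open_diphones <- function(word) {
  ph <- phonemes(word)
  n <- length(ph)
  if (n < 1L) stop("word must have at least one phoneme", call. = FALSE)
  if (n == 1L) {
    out <- integer(0)
    names(out) <- character(0)
    return(out)
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- paste0(ph[idx[, "row"]], ph[idx[, "col"]])
  tab <- table(pairs)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Graded (distance-weighted, order-asymmetric) diphone weights
#'
#' The mapping from a phoneme sequence to time-invariant diphone nodes is
#' graded rather than flat: an ordered pair contributes `gamma^(j - i - 1)`
#' for occurrence positions i < j (so an adjacent pair contributes exactly
#' 1 and the contribution decays with the gap), and the reversed pair
#' receives the same gap-decayed amount scaled by `rho < 1`. Hence /st/ is
#' activated more by STOP than by SPOT, and /sa/ more by sock than stock
#' than strong.
#'
#' @param word Phoneme string or character vector.
#' @param gamma Gap-decay factor, in (0, 1).
#' @param rho Reverse-order factor, in `[0, 1)`.
#' @return Named numeric vector of weights over the diphones receiving
#'   nonzero weight, with attributes `gamma` and `rho`.
#' @examples
#' graded_weights("ba", gamma = 0.5, rho = 0.1)  # ba = 1.0, ab = 0.1
#' @export
graded_weights <- function(word, gamma = 0.5, rho = 0.1) {
  if (!is_number(gamma) || gamma <= 0 || gamma >= 1) {
    stop("gamma must be in (0, 1)", call. = FALSE)
  }
  if (!is_number(rho) || rho < 0 || rho >= 1) {
    stop("rho must be in [0, 1)", call. = FALSE)
  }
  ph <- phonemes(word)
  n <- length(ph)
  w <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        g <- gamma^(j - i - 1L)
        fwd <- paste0(ph[i], ph[j])
        rev <- paste0(ph[j], ph[i])
        w[fwd] <- (if (fwd %in% names(w)) w[[fwd]] else 0) + g
        if (rho > 0) {
          w[rev] <- (if (rev %in% names(w)) w[[rev]] else 0) + rho * g
        }
      }
    }
  }
  attr(w, "gamma") <- gamma
  attr(w, "rho") <- rho
  w
}

# Dense P x P graded-weight kernel over an inventory's symbol set; rows are
# the first member, columns the second. Used to wire diphone -> word input.
kernel_matrix <- function(word, symbols, gamma, rho) {
  P <- length(symbols)
  K <- matrix(0, P, P, dimnames = list(symbols, symbols))
  ph <- phonemes(word)
  n <- length(ph)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        g <- gamma^(j - i - 1L)
        K[ph[i], ph[j]] <- K[ph[i], ph[j]] + g
        K[ph[j], ph[i]] <- K[ph[j], ph[i]] + rho * g
      }
    }
  }
  K
}

new_schedule <- function(ext, inventory, cpp, word_len, n_cycles, slots) {
  structure(list(ext = ext, inventory = inventory, cpp = cpp,
                 word_len = word_len, n_cycles = n_cycles, slots = slots),
            class = "tisk_schedule")
}

#' @export
print.tisk_schedule <- function(x, ...) {
  cat("<tisk_schedule> ", x$n_cycles, " cycles, ", x$slots, " slots (",
      x$cpp, " cycles/phoneme), word length ", x$word_len, "\n", sep = "")
  invisible(x)
}

# 1-based cycle indices during which input at `position` is applied
slot_cycles <- function(schedule, position) {
  a <- (position - 1L) * schedule$cpp + 1L
  b <- min(position * schedule$cpp, schedule$n_cycles)
  if (a > schedule$n_cycles) integer(0) else seq(a, b)
}

#' Per-cycle input schedule for a word
#'
#' Builds the external-input array for the time-specific phoneme layer:
#' the node (word\[s\], slot s) receives input amplitude 1.0 during that
#' slot's active block of `cycles_per_phoneme` cycles (phoneme s arrives at
#' cycle (s-1) * cpp, counting slots from 1), and all other entries are 0.
#'
#' @param word Phoneme string or character vector over the inventory.
#' @param params A [tisk_params()] (supplies `cycles_per_phoneme`,
#'   `n_slots`, and the default `total_cycles`).
#' @param total_cycles Length of the schedule in cycles.
#' @param inventory A [phoneme_inventory()].
#' @return A `tisk_schedule`: external input array of dimension
#'   (phoneme, slot, cycle) plus architecture constants.
#' @examples
#' sch <- word_schedule("pl^g", tisk_params("OPT_FB"))
#' sch$ext["p", 1, 1:10]  # amplitude 1 on the first ten cycles
#' @export
word_schedule <- function(word, params = tisk_params(),
                          total_cycles = params$total_cycles,
                          inventory = default_inventory()) {
  ph <- phonemes(word)
  check_phonemes(ph, inventory)
  S <- params$n_slots
  if (length(ph) > S) {
    stop(sprintf("word of length %d exceeds the %d available slots",
                 length(ph), S), call. = FALSE)
  }
  cpp <- params$cycles_per_phoneme
  P <- length(inventory$symbols)
  ext <- array(0, dim = c(P, S, total_cycles),
               dimnames = list(inventory$symbols, NULL, NULL))
  sch <- new_schedule(ext, inventory, cpp, length(ph), total_cycles, S)
  for (s in seq_along(ph)) {
    sch$ext[ph[s], s, slot_cycles(sch, s)] <- 1
  }
  sch
}

#' Blend two phonemes at one position of a schedule
#'
#' Implements identification continua: during the position's active cycles,
#' the node for `phonA` receives `1 - alpha` and the node for `phonB`
#' receives `alpha`. `alpha = 0` reproduces the base schedule; `alpha = 0.5`
#' is the maximally ambiguous stimulus (e.g. the /#/ onset halfway between
#' /p/ and /b/); `alpha = 1` is the full replacement.
#'
#' @param base A `tisk_schedule`.
#' @param position Position (1-based slot) within the word span.
#' @param phonA,phonB The continuum endpoint phonemes (A is the base/lexical
#'   phoneme, B the replacement).
#' @param alpha Blend proportion in `[0, 1]`.
#' @return A new `tisk_schedule`.
#' @export
blend_schedule <- function(base, position, phonA, phonB, alpha) {
  stopifnot(inherits(base, "tisk_schedule"))
  if (!is_number(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be in [0, 1]", call. = FALSE)
  }
  if (position < 1L || position > base$word_len) {
    stop("position outside the word span", call. = FALSE)
  }
  check_phonemes(c(phonA, phonB), base$inventory)
  cyc <- slot_cycles(base, position)
  base$ext[, position, cyc] <- 0
  base$ext[phonA, position, cyc] <- 1 - alpha
  base$ext[phonB, position, cyc] <- alpha
  base
}

#' Replace one position's input with silence or noise
#'
#' Silence zeroes all input at the position's active cycles. Noise zeroes
#' the position and then adds i.i.d. Gaussian(0, `noise_sd`) input to every
#' phoneme node at that position, truncated at 0 (inputs are nonnegative
#' evidence). By default one noise value is drawn per phoneme and held for
#' the whole active block (`resample = "block"`); `resample = "cycle"`
#' redraws every cycle. Deterministic given `seed`.
#'
#' @param base A `tisk_schedule`.
#' @param position Position (1-based) within the word span.
#' @param mode `"silence"` or `"noise"`.
#' @param noise_sd Standard deviation of the Gaussian noise (>= 0).
#' @param seed Integer seed for the noise draw.
#' @param resample `"block"` (one draw per phoneme, default) or `"cycle"`.
#' @return A new `tisk_schedule`.
#' @export
degrade_schedule <- function(base, position, mode = c("silence", "noise"),
                             noise_sd = 0, seed = NULL,
                             resample = c("block", "cycle")) {
  stopifnot(inherits(base, "tisk_schedule"))
  mode <- match.arg(mode)
  resample <- match.arg(resample)
  if (position < 1L || position > base$word_len) {
    stop("position outside the word span", call. = FALSE)
  }
  if (!is_number(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be nonnegative", call. = FALSE)
  }
  cyc <- slot_cycles(base, position)
  base$ext[, position, cyc] <- 0
  if (mode == "noise" && noise_sd > 0) {
    P <- dim(base$ext)[1]
    noise <- with_seed(seed, {
      if (resample == "block") {
        matrix(rep(rnorm(P, 0, noise_sd), length(cyc)), nrow = P)
      } else {
        matrix(rnorm(P * length(cyc), 0, noise_sd), nrow = P)
      }
    })
    base$ext[, position, cyc] <- pmax(noise, 0)
  }
  base
}

#' Add global Gaussian noise to a schedule
#'
#' Adds i.i.d. Gaussian(0, `noise_sd`) input to every phoneme node at every
#' position of the word's span, truncated below at 0 (no upper clipping of
#' the schedule itself; node activations are bounded later by the network).
#' One value is drawn per (phoneme, position) and held over that position's
#' active block by default.
#'
#' @inheritParams degrade_schedule
#' @return A new `tisk_schedule`.
#' @export
add_global_noise <- function(base, noise_sd, seed = NULL,
                             resample = c("block", "cycle")) {
  stopifnot(inherits(base, "tisk_schedule"))
  resample <- match.arg(resample)
  if (!is_number(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be nonnegative", call. = FALSE)
  }
  if (noise_sd == 0) return(base)
  P <- dim(base$ext)[1]
  with_seed(seed, {
    for (s in seq_len(base$word_len)) {
      cyc <- slot_cycles(base, s)
      noise <- if (resample == "block") {
        matrix(rep(rnorm(P, 0, noise_sd), length(cyc)), nrow = P)
      } else {
        matrix(rnorm(P * length(cyc), 0, noise_sd), nrow = P)
      }
      base$ext[, s, cyc] <- pmax(base$ext[, s, cyc] + noise, 0)
    }
  })
  base
}

#' Export a schedule as a tidy data frame
#'
#' Long format with one row per nonzero external input entry:
#' `cycle` (0-based), `phoneme`, `slot` (1-based), `value`. Useful for
#' debugging and CSV export.
#'
#' @param x A `tisk_schedule`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.tisk_schedule <- function(x, ...) {
  nz <- which(x$ext != 0, arr.ind = TRUE)
  data.frame(cycle = nz[, 3] - 1L,
             phoneme = dimnames(x$ext)[[1]][nz[, 1]],
             slot = nz[, 2],
             value = x$ext[nz],
             stringsAsFactors = FALSE)[order(nz[, 3], nz[, 2]), ]
}
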