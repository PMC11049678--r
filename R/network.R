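#' TISK model parameters
#'
#' All rates and weights of the interactive-activation dynamics plus the
#' architecture constants. Three named presets are shipped:
#'
#' * `"ORIGINAL"` — the original no-feedback parameter set (input phoneme
#'   decay 0.010, N-phone decay 0.001, word decay 0.010, phoneme-to-N-phone
#'   1.000, diphone-to-word 0.050, single-phone-to-word 0.010, word-word
#'   inhibition -0.005, no feedback).
#' * `"OPT_NOFB"` — parameters optimized for noise robustness without
#'   feedback (input decay 0.001, word decay 0.050, phoneme-to-N-phone
#'   0.100; rest as ORIGINAL).
#' * `"OPT_FB"` — parameters optimized for feedback (as OPT_NOFB but
#'   N-phone decay 0.100, word-word inhibition -0.010, positive
#'   word-to-N-phone feedback 0.150, negative feedback -0.050).
#'
#' Feedback weights are 0 in the no-feedback presets; the `feedback_on`
#' flag of [run_trial()] additionally gates the feedback path at run time,
#' so the OPT_FB parameter set can also be run with feedback disabled.
#'
#' @param preset One of `"OPT_FB"`, `"OPT_NOFB"`, `"ORIGINAL"`.
#' @param ... Named overrides for any field below.
#'
#' @section Fields:
#' * `input_phoneme_decay`, `nphone_decay`, `word_decay`: per-cycle decay
#'   rates in `[0, 1)`.
#' * `w_phoneme_to_nphone`, `w_diphone_to_word`, `w_singlephone_to_word`:
#'   feedforward weights.
#' * `w_word_word_inhibition`: nonpositive lateral weight at the word layer.
#' * `fb_positive`, `fb_negative`: word-to-N-phone feedback weights
#'   (`fb_negative <= 0 <= fb_positive`).
#' * `gamma`, `rho`: diphone grading constants (gap decay, reverse factor).
#' * `kernel_norm_power`: exponent q in `[0, 1]` of the word-kernel
#'   normalization (bottom-up word weights are divided by the kernel mass
#'   raised to q; default 0.5, the cosine-style compromise).
#' * `nphone_threshold`, `word_threshold`: transmission thresholds (a node
#'   influences the next layer only by its activation surplus above the
#'   threshold; defaults 0.2 and 0.2). The word threshold gates both
#'   lateral inhibition and feedback.
#' * `word_input_gain`: global multiplier on the normalized bottom-up word
#'   drive (default 1; a sensitivity knob).
#' * `cycles_per_phoneme` (default 10), `n_slots` (default 10),
#'   `total_cycles` (default 100).
#' * `act_min`, `act_max`, `rest`: activation bounds and resting level
#'   (defaults -0.2, 1, 0). The floor sits below rest so that lateral and
#'   top-down inhibition can hold losing nodes strictly silent (only
#'   supra-rest activation is transmitted); this is the standard
#'   interactive-activation arrangement.
#'
#' @return An object of class `tisk_params`.
#' @examples
#' p <- tisk_params("OPT_FB")
#' p$fb_positive
#' tisk_params("ORIGINAL", total_cycles = 60)
#' @export
tisk_params <- function(preset = c("OPT_FB", "OPT_NOFB", "ORIGINAL"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    ORIGINAL = list(input_phoneme_decay = 0.010, nphone_decay = 0.001,
                    word_decay = 0.010, w_phoneme_to_nphone = 1.000,
                    w_diphone_to_word = 0.050, w_singlephone_to_word = 0.010,
                    w_word_word_inhibition = -0.005,
                    fb_positive = 0, fb_negative = 0),
    OPT_NOFB = list(input_phoneme_decay = 0.001, nphone_decay = 0.001,
                    word_decay = 0.050, w_phoneme_to_nphone = 0.100,
                    w_diphone_to_word = 0.050, w_singlephone_to_word = 0.010,
                    w_word_word_inhibition = -0.005,
                    fb_positive = 0, fb_negative = 0),
    OPT_FB   = list(input_phoneme_decay = 0.001, nphone_decay = 0.100,
                    word_decay = 0.050, w_phoneme_to_nphone = 0.100,
                    w_diphone_to_word = 0.050, w_singlephone_to_word = 0.010,
                    w_word_word_inhibition = -0.010,
                    fb_positive = 0.150, fb_negative = -0.050)
  )
  p <- c(base, list(gamma = 0.5, rho = 0.1, kernel_norm_power = 0.5,
                    nphone_threshold = 0.2, word_threshold = 0.2,
                    word_input_gain = 1,
                    cycles_per_phoneme = 10L, n_slots = 10L,
                    total_cycles = 100L,
                    act_min = -0.2, act_max = 1, rest = 0,
                    preset = preset))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  validate_params(structure(p, class = "tisk_params"))
}

validate_params <- function(p) {
  for (d in c("input_phoneme_decay", "nphone_decay", "word_decay")) {
    if (!is_number(p[[d]]) || p[[d]] < 0 || p[[d]] >= 1) {
      stop(d, " must be in [0, 1)", call. = FALSE)
    }
  }
  if (p$w_word_word_inhibition > 0) {
    stop("w_word_word_inhibition must be nonpositive", call. = FALSE)
  }
  if (p$fb_negative > 0 || p$fb_positive < 0) {
    stop("need fb_negative <= 0 <= fb_positive", call. = FALSE)
  }
  if (!(p$act_min <= p$rest && p$rest <= p$act_max)) {
    stop("need act_min <= rest <= act_max", call. = FALSE)
  }
  if (p$gamma <= 0 || p$gamma >= 1) stop("gamma must be in (0, 1)", call. = FALSE)
  if (p$rho < 0 || p$rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (p$kernel_norm_power < 0 || p$kernel_norm_power > 1) {
    stop("kernel_norm_power must be in [0, 1]", call. = FALSE)
  }
  p$cycles_per_phoneme <- as.integer(p$cycles_per_phoneme)
  p$n_slots <- as.integer(p$n_slots)
  p$total_cycles <- as.integer(p$total_cycles)
  p
}

#' @export
print.tisk_params <- function(x, ...) {
  cat("<tisk_params> preset:", x$preset, "\n")
  flds <- setdiff(names(x), "preset")
  for (f in flds) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read / write a parameter set as YAML
#'
#' @param path File path.
#' @return For `load_params`, a [tisk_params()].
#' @export
load_params <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- y$preset %||% "OPT_FB"
  y$preset <- NULL
  do.call(tisk_params, c(list(preset = preset), y))
}

#' @rdname load_params
#' @param params A [tisk_params()].
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "tisk_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

# N-phone layer ordering: the P single phones first, then the P^2 diphones
# in column-major (x, y) order, i.e. index P + x + (y - 1) * P for pair
# (x, y) of symbol indices.
nphone_names <- function(symbols) {
  c(symbols, as.vector(outer(symbols, symbols, paste0)))
}

#' Build a TISK network from a lexicon
#'
#' Wires the three-layer architecture: time-specific phoneme inputs feed
#' single-phone nodes and (via the graded order-sensitive pairing of
#' time-specific activations) diphone nodes in the time-invariant N-phone
#' layer; N-phone nodes feed word nodes through each word's graded diphone
#' kernel (`w_diphone_to_word` x grade, with each word's kernel
#' L1-normalized so words of different lengths have equal total input
#' capacity) and constituent single phones (`w_singlephone_to_word`,
#' likewise normalized over the word's constituent phones); word nodes
#' inhibit each other laterally; and,
#' when feedback is enabled, each word excites its constituent N-phones
#' (`fb_positive`) and weakly inhibits all non-constituent N-phones
#' (`fb_negative`).
#'
#' @param lexicon A `tisk_lexicon`.
#' @param params A [tisk_params()].
#' @return An object of class `tisk_network`.
#' @examples
#' net <- build_network(lexicon(c(doll = "dal", dog = "dag")),
#'                      tisk_params("OPT_FB"))
#' @export
build_network <- function(lexicon, params = tisk_params()) {
  stopifnot(inherits(lexicon, "tisk_lexicon"),
            inherits(params, "tisk_params"))
  inventory <- lexicon$inventory
  syms <- inventory$symbols
  P <- length(syms)
  S <- params$n_slots
  too_long <- lengths(lexicon$phonemes) > S
  if (any(too_long)) {
    stop(sprintf("word '%s' exceeds the %d available slots",
                 lexicon$labels[which(too_long)[1]], S), call. = FALSE)
  }
  W <- length(lexicon)
  nN <- P + P * P
  # Bottom-up word weights: W x nN, columns ordered as nphone_names()
  W_word <- matrix(0, W, nN, dimnames = list(lexicon$labels,
                                             nphone_names(syms)))
  # 0/1 constituency (single phones present; ordered open diphones)
  C_const <- matrix(0, W, nN)
  for (w in seq_len(W)) {
    ph <- lexicon$phonemes[[w]]
    K <- kernel_matrix(ph, syms, params$gamma, params$rho)
    # Kernel normalization (cosine-style): dividing by |K|^q with
    # q = kernel_norm_power keeps matched evidence growing with word
    # length while shrinking spurious partial matches on long words and
    # bounding the word->N-phone->word feedback loop gain. q = 0 is the
    # raw kernel, q = 1 gives every word equal total input capacity.
    q <- params$kernel_norm_power
    if (sum(K) > 0) K <- K / sum(K)^q
    sing <- as.numeric(syms %in% ph)
    if (sum(sing) > 0) sing <- sing / sum(sing)^q
    g <- params$word_input_gain
    W_word[w, ] <- g * c(params$w_singlephone_to_word * sing,
                         params$w_diphone_to_word * as.vector(K))
    ord <- matrix(0, P, P, dimnames = list(syms, syms))
    if (length(ph) >= 2L) {
      for (i in seq_len(length(ph) - 1L)) {
        for (j in seq((i + 1L), length(ph))) ord[ph[i], ph[j]] <- 1
      }
    }
    C_const[w, ] <- c(as.numeric(syms %in% ph), as.vector(ord))
  }
  # Positive feedback is a per-word budget: each word's fb_positive is
  # spread over its constituents with the same normalization exponent as
  # the forward kernel, so words with many constituents (and cliques of
  # similar words) cannot inject unboundedly more top-down excitation.
  # Negative feedback stays uniform: it is the global brake on
  # non-constituents.
  C_fb <- C_const / pmax(rowSums(C_const), 1)^params$kernel_norm_power
  # Per-gap slot pairings for the running diphone input
  gaps <- lapply(seq_len(S - 1L), function(g) {
    list(early = seq_len(S - g), late = seq(g + 1L, S),
         weight = params$gamma^(g - 1L))
  })
  structure(list(lexicon = lexicon, inventory = inventory, params = params,
                 P = P, S = S, W = W, n_nphone = nN,
                 symbols = syms, W_word = W_word, C_const = C_const,
                 C_fb = C_fb, gaps = gaps),
            class = "tisk_network")
}

#' @export
print.tisk_network <- function(x, ...) {
  cat("<tisk_network> ", x$W, " words, ", x$P, " phonemes, ",
      x$n_nphone, " N-phone nodes (", x$P, " single + ", x$P * x$P,
      " diphone), preset ", x$params$preset, "\n", sep = "")
  invisible(x)
}

#' Constituent N-phone nodes of a word
#'
#' A word's constituents at the N-phone layer are its single phones plus
#' its ordered open diphones; these receive positive feedback, everything
#' else receives negative feedback.
#'
#' @param network A `tisk_network`.
#' @param label Word label.
#' @return Character vector of N-phone node names.
#' @examples
#' net <- build_network(lexicon(c(doll = "dal")))
#' sort(word_constituents(net, "doll"))  # al, a, d, da, dl, l
#' @export
word_constituents <- function(network, label) {
  w <- word_index(network$lexicon, label)
  nphone_names(network$symbols)[network$C_const[w, ] > 0]
}

#' Initial (resting) network state
#'
#' @param network A `tisk_network`.
#' @return A `tisk_state`: input-layer matrix (phoneme x slot), single-phone
#'   vector, diphone matrix, word vector, all at `rest`, with `cycle = 0`.
#' @export
initial_state <- function(network) {
  p <- network$params
  structure(list(
    a_input = matrix(p$rest, network$P, network$S,
                     dimnames = list(network$symbols, NULL)),
    a_single = stats::setNames(rep(p$rest, network$P), network$symbols),
    a_diphone = matrix(p$rest, network$P, network$P,
                       dimnames = list(network$symbols, network$symbols)),
    a_word = stats::setNames(rep(p$rest, network$W), network$lexicon$labels),
    cycle = 0L
  ), class = "tisk_state")
}

#' One synchronous update cycle
#'
#' All layers update simultaneously from the pre-update snapshot. Only
#' supra-rest activation is transmitted. External input clamps time-specific
#' input nodes from below during their scheduled cycles (an input node's
#' activation is the larger of its decayed previous activation and the
#' scheduled stimulus value). The N-phone and word layers use the classic
#' interactive-activation (shunting) update: on top of decayed activation,
#' excitatory input is scaled by the distance to the ceiling and inhibitory
#' input by the distance to the floor,
#' `a' = a (1 - decay) + exc (act_max - a) - inh (a - act_min)`,
#' then clipped to `[act_min, act_max]`. This keeps equilibria graded in the
#' evidence, so a fully-supported embedded word settles strictly below its
#' better-supported carrier instead of tying with it at ceiling. The terms:
#'
#' * single phone x: net = `w_phoneme_to_nphone` * sum over slots of
#'   input-layer activation of x.
#' * diphone (x, y): net = `w_phoneme_to_nphone` * sum over slot pairs
#'   i < j of `a_in[x, i] * a_in[y, j] * gamma^(j-i-1)` plus `rho` times the
#'   reversed pairing — the order-sensitive graded gate.
#' * word w: net = sum of its graded diphone weights times diphone
#'   activations, plus single-phone input, plus
#'   `w_word_word_inhibition * sum_{v != w} a_v`.
#' * with feedback on, each N-phone additionally receives
#'   `fb_positive * sum(words containing it)` plus
#'   `fb_negative * sum(words not containing it)` (word activations above
#'   rest).
#'
#' @param network A `tisk_network`.
#' @param state A `tisk_state`.
#' @param schedule A `tisk_schedule` (supplies this cycle's external input).
#' @param feedback_on Logical flag gating the word-to-N-phone path.
#' @return The updated `tisk_state` (cycle advanced by one).
#' @export
tisk_step <- function(network, state, schedule, feedback_on = TRUE) {
  p <- network$params
  cyc <- state$cycle + 1L            # 1-based index into the schedule
  if (cyc > schedule$n_cycles) stop("schedule exhausted", call. = FALSE)
  A <- pmax(state$a_input - p$rest, 0)          # transmitted input activity
  # --- N-phone nets -------------------------------------------------------
  sing_exc <- p$w_phoneme_to_nphone * rowSums(A)
  M <- matrix(0, network$P, network$P)
  for (g in network$gaps) {
    M <- M + g$weight * (A[, g$early, drop = FALSE] %*%
                           t(A[, g$late, drop = FALSE]))
  }
  dip_exc <- p$w_phoneme_to_nphone * (M + p$rho * t(M))
  nph_exc <- c(sing_exc, as.vector(dip_exc))
  nph_inh <- 0
  if (feedback_on && (p$fb_positive != 0 || p$fb_negative != 0)) {
    posw <- pmax(state$a_word - p$word_threshold, 0)
    nph_exc <- nph_exc + p$fb_positive * drop(crossprod(network$C_fb, posw))
    nph_inh <- -p$fb_negative *
      (sum(posw) - drop(crossprod(network$C_const, posw)))
  }
  # --- word nets ----------------------------------------------------------
  # transmission thresholds: a node must exceed its layer threshold before
  # it influences the next layer, so weakly (e.g. feedback-) activated
  # nodes do not propagate
  nph_act <- c(pmax(state$a_single - p$nphone_threshold, 0),
               as.vector(pmax(state$a_diphone - p$nphone_threshold, 0)))
  posw <- pmax(state$a_word - p$word_threshold, 0)
  word_exc <- drop(network$W_word %*% nph_act)
  word_inh <- -p$w_word_word_inhibition * (sum(posw) - posw)
  # --- synchronous commit (shunting: excitation scaled by distance to
  # ceiling, inhibition by distance to floor, so equal evidence differences
  # map to graded, tie-breakable activation differences) ------------------
  clip <- function(x) pmin(pmax(x, p$act_min), p$act_max)
  shunt <- function(a, decay, exc, inh) {
    clip(a * (1 - decay) + exc * (p$act_max - a) - inh * (a - p$act_min))
  }
  nph_a <- c(state$a_single, as.vector(state$a_diphone))
  nph_new <- shunt(nph_a, p$nphone_decay, nph_exc, nph_inh)
  state$a_single <- stats::setNames(nph_new[seq_len(network$P)],
                                    network$symbols)
  state$a_diphone <- matrix(nph_new[-seq_len(network$P)], network$P,
                            network$P,
                            dimnames = list(network$symbols, network$symbols))
  state$a_word <- shunt(state$a_word, p$word_decay, word_exc, word_inh)
  state$a_input <- clip(pmax(state$a_input * (1 - p$input_phoneme_decay),
                             schedule$ext[, , cyc]))
  state$cycle <- cyc
  state
}

#' Run a full trial
#'
#' Iterates [tisk_step()] from the resting state over the whole schedule.
#' Deterministic given the schedule: all stochasticity lives in schedule
#' construction.
#'
#' @param network A `tisk_network`.
#' @param schedule A `tisk_schedule`.
#' @param feedback_on Logical; gate the word-to-N-phone feedback path.
#' @param record Which activations to keep per cycle: `"word"` and
#'   `"single"` histories are always kept; add `"diphone"` and/or `"input"`
#'   for full traces.
#' @return A `tisk_trace`: list with matrices `word` (cycle x word) and
#'   `single` (cycle x phoneme), optionally `diphone` (cycle x P^2) and
#'   `input` (cycle x P*S), plus `n_cycles`, `feedback_on`, and the
#'   network's preset name. Rows are cycles 1..total; cycle c row holds the
#'   state after update c (cycle index c-1 at stimulus onset convention).
#' @examples
#' lex <- lexicon(c(plug = "pl^g", blush = "bl^S"))
#' net <- build_network(lex, tisk_params("OPT_FB"))
#' tr <- run_trial(net, word_schedule("pl^g", net$params))
#' names(which.max(tr$word[nrow(tr$word), ]))
#' @export
run_trial <- function(network, schedule, feedback_on = TRUE,
                      record = c("word", "single")) {
  stopifnot(inherits(network, "tisk_network"),
            inherits(schedule, "tisk_schedule"))
  n <- schedule$n_cycles
  keep_dip <- "diphone" %in% record
  keep_in <- "input" %in% record
  word_h <- matrix(NA_real_, n, network$W,
                   dimnames = list(NULL, network$lexicon$labels))
  single_h <- matrix(NA_real_, n, network$P,
                     dimnames = list(NULL, network$symbols))
  dip_h <- if (keep_dip) matrix(NA_real_, n, network$P^2) else NULL
  in_h <- if (keep_in) matrix(NA_real_, n, network$P * network$S) else NULL
  state <- initial_state(network)
  for (c in seq_len(n)) {
    state <- tisk_step(network, state, schedule, feedback_on)
    word_h[c, ] <- state$a_word
    single_h[c, ] <- state$a_single
    if (keep_dip) dip_h[c, ] <- as.vector(state$a_diphone)
    if (keep_in) in_h[c, ] <- as.vector(state$a_input)
  }
  structure(list(word = word_h, single = single_h, diphone = dip_h,
                 input = in_h, n_cycles = n, feedback_on = feedback_on,
                 preset = network$params$preset),
            class = "tisk_trace")
}

#' @export
print.tisk_trace <- function(x, ...) {
  top <- sort(x$word[nrow(x$word), ], decreasing = TRUE)
  cat("<tisk_trace> ", x$n_cycles, " cycles, ", ncol(x$word), " words, ",
      "feedback ", if (x$feedback_on) "on" else "off", "\n",
      "  final top words: ",
      paste(sprintf("%s=%.3f", names(top)[seq_len(min(3, length(top)))],
                    top[seq_len(min(3, length(top)))]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Export a trace as a tidy data frame
#'
#' Long format: `cycle` (0-based), `layer` (`"word"` or `"single"`, plus
#' `"diphone"`/`"input"` when recorded), `node`, `activation`.
#'
#' @param x A `tisk_trace`.
#' @param ... Unused.
#' @export
as.data.frame.tisk_trace <- function(x, ...) {
  pieces <- list()
  for (layer in c("word", "single")) {
    m <- x[[layer]]
    pieces[[layer]] <- data.frame(
      cycle = rep(seq_len(nrow(m)) - 1L, ncol(m)),
      layer = layer,
      node = rep(colnames(m), each = nrow(m)),
      activation = as.vector(m),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, pieces)
}

#' Simple grid search over parameter values
#'
#' Utility for small parameter-space explorations: evaluates a scoring
#' function over the Cartesian product of candidate parameter values.
#'
#' @param base A [tisk_params()] to start from.
#' @param grid Named list of candidate value vectors, e.g.
#'   `list(fb_positive = c(0.1, 0.15), nphone_decay = c(0.05, 0.1))`.
#' @param score Function taking a `tisk_params` and returning a single
#'   numeric score (larger is better).
#' @return Data frame of parameter combinations and scores, sorted by
#'   decreasing score.
#' @export
param_grid_search <- function(base, grid, score) {
  stopifnot(inherits(base, "tisk_params"), is.function(score))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  combos$score <- vapply(seq_len(nrow(combos)), function(i) {
    p <- base
    p[names(grid)] <- as.list(combos[i, names(grid), drop = FALSE])
    score(validate_params(p))
  }, numeric(1))
  combos[order(-combos$score), , drop = FALSE]
}
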