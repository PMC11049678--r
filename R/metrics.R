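#' Recognition criterion and recognition time
#'
#' A word counts as recognized at the first cycle c such that its
#' activation exceeds every other word's activation by at least `threshold`
#' on all cycles of the hold window `[c, c + hold)` (the window includes c),
#' and it subsequently remains the most activated word until the end of the
#' trial. Ties never count: the margin must be >= `threshold` over all
#' non-targets, and the target must be the strict argmax after the hold
#' window.
#'
#' @param trace A `tisk_trace` (or a plain cycle x word activation matrix
#'   with column names).
#' @param target Target word label.
#' @param threshold Required margin (default 0.05).
#' @param hold Number of consecutive cycles the margin must hold
#'   (default 10); must not exceed the trace length.
#' @return A list of class `recognition_outcome`: `recognized` (flag),
#'   `rt_cycle` (0-based cycle index, or `NA` when not recognized),
#'   `final_winner` (label of the most active word at the last cycle).
#' @examples
#' m <- cbind(a = rep(0.6, 20), b = rep(0.5, 20))
#' recognition_time(m, "a", hold = 10)$rt_cycle  # 0
#' @export
recognition_time <- function(trace, target, threshold = 0.05, hold = 10L) {
  m <- if (inherits(trace, "tisk_trace")) trace$word else trace
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  n <- nrow(m)
  if (hold > n) stop("hold exceeds trace length", call. = FALSE)
  ti <- match(target, colnames(m))
  if (is.na(ti)) stop(sprintf("word '%s' not in trace", target), call. = FALSE)
  tgt <- m[, ti]
  best_other <- if (ncol(m) > 1L) {
    apply(m[, -ti, drop = FALSE], 1, max)
  } else {
    rep(-Inf, n)
  }
  margin <- tgt - best_other
  ok_margin <- margin >= threshold
  is_max <- margin > 0
  # run[c]: length of the consecutive margin streak starting at cycle c
  run <- integer(n)
  acc <- 0L
  for (c in n:1) {
    acc <- if (ok_margin[c]) acc + 1L else 0L
    run[c] <- acc
  }
  # suffix: target is argmax from cycle c to the end
  argmax_suffix <- rev(cumprod(rev(is_max))) > 0
  rt <- NA_integer_
  for (c in seq_len(n - hold + 1L)) {
    if (run[c] >= hold &&
        (c + hold > n || argmax_suffix[c + hold])) {
      rt <- c - 1L                       # report 0-based cycle
      break
    }
  }
  structure(list(recognized = !is.na(rt), rt_cycle = rt,
                 final_winner = colnames(m)[which.max(m[n, ])]),
            class = "recognition_outcome")
}

#' Accuracy over a set of recognition outcomes
#'
#' @param outcomes List of [recognition_time()] outcomes (or a logical
#'   vector of recognized flags).
#' @return Fraction of trials recognized.
#' @export
accuracy <- function(outcomes) {
  if (length(outcomes) == 0L) stop("no outcomes supplied", call. = FALSE)
  if (is.logical(outcomes)) return(mean(outcomes))
  mean(vapply(outcomes, function(o) isTRUE(o$recognized), logical(1)))
}

#' Cohort and rhyme competitors of a target word
#'
#' Cohorts share the target's first two phonemes; rhymes are same-length
#' words mismatching the target only at the first phoneme. Cohort
#' classification takes precedence, the target itself belongs to neither
#' class, and all remaining words contribute only to the all-word baseline.
#' A one-phoneme target has no defined cohort (empty set).
#'
#' @param lexicon A `tisk_lexicon`.
#' @param target Target word label.
#' @return List of class `competitor_classes` with character vectors
#'   `cohorts`, `rhymes`, `unrelated` (all remaining non-target words).
#' @examples
#' lex <- lexicon(c(doll = "dal", dock = "dak", ball = "bal", soot = "sut"))
#' competitor_classes(lex, "doll")
#' @export
competitor_classes <- function(lexicon, target) {
  stopifnot(inherits(lexicon, "tisk_lexicon"))
  ti <- word_index(lexicon, target)
  tp <- lexicon$phonemes[[ti]]
  cohorts <- character(0)
  rhymes <- character(0)
  unrelated <- character(0)
  for (j in seq_along(lexicon$labels)) {
    if (j == ti) next
    wp <- lexicon$phonemes[[j]]
    lab <- lexicon$labels[j]
    if (length(tp) >= 2 && length(wp) >= 2 &&
        wp[1] == tp[1] && wp[2] == tp[2]) {
      cohorts <- c(cohorts, lab)
    } else if (length(wp) == length(tp) && wp[1] != tp[1] &&
               (length(tp) == 1L || identical(wp[-1], tp[-1]))) {
      rhymes <- c(rhymes, lab)
    } else {
      unrelated <- c(unrelated, lab)
    }
  }
  structure(list(cohorts = cohorts, rhymes = rhymes, unrelated = unrelated),
            class = "competitor_classes")
}

# first-position-only mismatch, admitting deletion/addition/substitution
is_das_rhyme <- function(wp, tp) {
  n <- length(tp)
  (length(wp) == n && wp[1] != tp[1] &&
     (n == 1L || identical(wp[-1], tp[-1]))) ||          # substitution
    (length(wp) == n - 1L && n >= 2L && identical(wp, tp[-1])) ||  # deletion
    (length(wp) == n + 1L && identical(wp[-1], tp))       # addition
}

# edit distance <= 1 under deletion/addition/substitution
is_das_neighbor <- function(wp, tp) {
  nw <- length(wp); nt <- length(tp)
  if (abs(nw - nt) > 1L) return(FALSE)
  if (nw == nt) {
    sum(wp != tp) <= 1L
  } else {
    long <- if (nw > nt) wp else tp
    short <- if (nw > nt) tp else wp
    for (drop in seq_along(long)) {
      if (identical(long[-drop], short)) return(TRUE)
    }
    FALSE
  }
}

#' Lexical dimensions of a target word
#'
#' The six item-level dimensions used to relate recognition time to lexical
#' structure:
#'
#' * `length`: number of phonemes.
#' * `embeddings`: number of other words occurring as a contiguous
#'   substring of the target (AT embeds in CAT).
#' * `onset_competitors`: cohort count (words sharing the first two
#'   phonemes).
#' * `ex_embeddings`: number of other words the target occurs in as a
#'   contiguous substring (CAB embeds in CABINET).
#' * `das_neighbors`: words within one phoneme deletion, addition, or
#'   substitution of the target.
#' * `rhymes`: words mismatching the target only at the first phoneme, by
#'   substitution, deletion, or addition (for CAT: BAT, AT, SCAT). This is
#'   deliberately broader than the same-length rhyme class used by
#'   [competitor_classes()] for time-course averaging.
#'
#' Words with the same phoneme string but different labels count once per
#' entry; the target itself never counts.
#'
#' @param lexicon A `tisk_lexicon`.
#' @param target Target word label.
#' @return Named numeric vector with the six dimensions.
#' @export
lexical_dimensions <- function(lexicon, target) {
  stopifnot(inherits(lexicon, "tisk_lexicon"))
  ti <- word_index(lexicon, target)
  tp <- lexicon$phonemes[[ti]]
  tstr <- paste(tp, collapse = "")
  emb <- 0L; onset <- 0L; exemb <- 0L; das <- 0L; rhy <- 0L
  for (j in seq_along(lexicon$labels)) {
    if (j == ti) next
    wp <- lexicon$phonemes[[j]]
    wstr <- paste(wp, collapse = "")
    if (length(wp) < length(tp) && grepl(wstr, tstr, fixed = TRUE)) {
      emb <- emb + 1L
    }
    if (length(tp) >= 2 && length(wp) >= 2 &&
        wp[1] == tp[1] && wp[2] == tp[2]) {
      onset <- onset + 1L
    }
    if (length(wp) > length(tp) && grepl(tstr, wstr, fixed = TRUE)) {
      exemb <- exemb + 1L
    }
    if (is_das_neighbor(wp, tp)) das <- das + 1L
    if (is_das_rhyme(wp, tp)) rhy <- rhy + 1L
  }
  c(length = length(tp), embeddings = emb, onset_competitors = onset,
    ex_embeddings = exemb, das_neighbors = das, rhymes = rhy)
}

#' Mean activation time course per competitor class
#'
#' Averages, cycle by cycle, the activation of the target, its cohorts, its
#' same-length rhymes, and the all-word baseline, over a set of per-word
#' trials (one trace per lexicon word, each with its own word as target).
#' Words lacking a class do not contribute to that class's mean. Standard
#' errors are over items.
#'
#' @param traces Named list of `tisk_trace` objects, one per word, names
#'   are the target labels.
#' @param lexicon The `tisk_lexicon` the traces were run on.
#' @return Data frame with columns `cycle` (0-based), `class` (target /
#'   cohort / rhyme / unrelated), `mean`, `se`, `n_items`.
#' @export
class_timecourse <- function(traces, lexicon) {
  stopifnot(inherits(lexicon, "tisk_lexicon"), length(traces) >= 1L)
  n_cycles <- nrow(traces[[1]]$word)
  acc <- list(target = list(), cohort = list(), rhyme = list(),
              unrelated = list())
  for (target in names(traces)) {
    m <- traces[[target]]$word
    cls <- competitor_classes(lexicon, target)
    acc$target[[target]] <- m[, target]
    if (length(cls$cohorts)) {
      acc$cohort[[target]] <- rowMeans(m[, cls$cohorts, drop = FALSE])
    }
    if (length(cls$rhymes)) {
      acc$rhyme[[target]] <- rowMeans(m[, cls$rhymes, drop = FALSE])
    }
    acc$unrelated[[target]] <- rowMeans(m)   # all-word baseline
  }
  out <- list()
  for (cl in names(acc)) {
    if (!length(acc[[cl]])) next
    mm <- do.call(cbind, acc[[cl]])
    out[[cl]] <- data.frame(
      cycle = seq_len(n_cycles) - 1L,
      class = cl,
      mean = rowMeans(mm),
      se = apply(mm, 1, stats::sd) / sqrt(ncol(mm)),
      n_items = ncol(mm),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate two recognition-time vectors
#'
#' Pearson correlation over the items recognized in both conditions.
#'
#' @param rt_a,rt_b Named numeric vectors of RTs (NA = not recognized);
#'   names are word labels.
#' @return List with `r`, `n` (shared recognized items), and the shared
#'   label vector.
#' @export
rt_correlation <- function(rt_a, rt_b) {
  shared <- intersect(names(rt_a)[!is.na(rt_a)], names(rt_b)[!is.na(rt_b)])
  r <- if (length(shared) >= 3L) {
    stats::cor(rt_a[shared], rt_b[shared])
  } else {
    NA_real_
  }
  list(r = r, n = length(shared), labels = shared)
}
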