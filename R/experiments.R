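# Simulation harnesses: competitor time course (sim1), Ganong effect (sim2),
# right-context disambiguation (sim3), phoneme restoration (sim4), and
# graceful degradation under input noise (sim5).

default_variants <- function() {
  list(
    TISKfb     = list(params = tisk_params("OPT_FB"),   feedback = TRUE),
    TISK_opt   = list(params = tisk_params("OPT_NOFB"), feedback = FALSE),
    TISK_orig  = list(params = tisk_params("ORIGINAL"), feedback = FALSE),
    TISKfb_off = list(params = tisk_params("OPT_FB"),   feedback = FALSE)
  )
}

# One trial for a lexicon word, optionally with global input noise.
word_trial <- function(network, label, feedback_on = TRUE, noise_sd = 0,
                       seed = NULL, record = c("word", "single")) {
  w <- word_index(network$lexicon, label)
  sch <- word_schedule(network$lexicon$phonemes[[w]], network$params,
                       inventory = network$inventory)
  if (noise_sd > 0) sch <- add_global_noise(sch, noise_sd, seed = seed)
  run_trial(network, sch, feedback_on = feedback_on, record = record)
}

# Run every word of a lexicon once; returns outcomes (and traces on request).
run_lexicon <- function(network, feedback_on = TRUE, noise_sd = 0,
                        seeds = NULL, keep_traces = FALSE,
                        threshold = 0.05, hold = 10L) {
  labs <- network$lexicon$labels
  traces <- if (keep_traces) vector("list", length(labs)) else NULL
  rec <- logical(length(labs))
  rt <- rep(NA_integer_, length(labs))
  for (i in seq_along(labs)) {
    tr <- word_trial(network, labs[i], feedback_on = feedback_on,
                     noise_sd = noise_sd,
                     seed = if (is.null(seeds)) NULL else seeds[i])
    out <- recognition_time(tr, labs[i], threshold = threshold, hold = hold)
    rec[i] <- out$recognized
    rt[i] <- out$rt_cycle
    if (keep_traces) traces[[i]] <- tr
  }
  if (keep_traces) names(traces) <- labs
  list(outcomes = data.frame(word = labs, recognized = rec, rt = rt,
                             stringsAsFactors = FALSE),
       traces = traces)
}

#' Simulation 1: competitor time course and lexical dimensions
#'
#' Runs one noise-free trial per lexicon word for each model variant,
#' computes the class time course (target / cohort / rhyme / all-word
#' baseline), per-word recognition outcomes and accuracy, the six lexical
#' dimensions per word, and the correlation of each dimension with
#' recognition time, plus pairwise RT correlations between variants over
#' shared recognized words.
#'
#' @param lexicon A `tisk_lexicon` (defaults to the bundled synthetic
#'   211-word lexicon).
#' @param variants Named list of model variants, each
#'   `list(params = tisk_params(...), feedback = flag)`. Defaults to the
#'   feedback model (`TISKfb`) and the optimized no-feedback model
#'   (`TISK_opt`).
#' @param threshold,hold Recognition criterion (margin 0.05 held 10 cycles).
#' @return List of class `sim1_result`: per-variant `timecourse`,
#'   `outcomes`, `accuracy`; shared `dimensions` table; `dimension_cors`
#'   (variant x dimension Pearson r with RT); `rt_cors` (pairwise variant
#'   RT correlations).
#' @export
sim1_timecourse <- function(lexicon = bundled_lexicon(),
                            variants = default_variants()[c("TISKfb",
                                                            "TISK_opt")],
                            threshold = 0.05, hold = 10L) {
  dims <- t(vapply(lexicon$labels,
                   function(w) lexical_dimensions(lexicon, w),
                   numeric(6)))
  dims <- data.frame(word = lexicon$labels, dims, stringsAsFactors = FALSE,
                     row.names = NULL)
  res <- list()
  rts <- list()
  for (v in names(variants)) {
    net <- build_network(lexicon, variants[[v]]$params)
    run <- run_lexicon(net, feedback_on = variants[[v]]$feedback,
                       keep_traces = TRUE, threshold = threshold,
                       hold = hold)
    tc <- class_timecourse(run$traces, lexicon)
    rt <- stats::setNames(run$outcomes$rt, run$outcomes$word)
    rt[!run$outcomes$recognized] <- NA
    rts[[v]] <- rt
    dim_cor <- vapply(colnames(dims)[-1], function(d) {
      ok <- !is.na(rt)
      if (sum(ok) >= 3 && stats::sd(dims[[d]][ok]) > 0) {
        stats::cor(rt[ok], dims[[d]][ok])
      } else {
        NA_real_
      }
    }, numeric(1))
    res[[v]] <- list(timecourse = tc, outcomes = run$outcomes,
                     accuracy = accuracy(run$outcomes$recognized),
                     dimension_cors = dim_cor)
  }
  rt_cors <- list()
  vs <- names(variants)
  if (length(vs) >= 2) {
    for (i in seq_len(length(vs) - 1)) {
      for (j in seq((i + 1), length(vs))) {
        rt_cors[[paste(vs[i], vs[j], sep = "_vs_")]] <-
          rt_correlation(rts[[vs[i]]], rts[[vs[j]]])
      }
    }
  }
  structure(list(variants = res, dimensions = dims, rt_cors = rt_cors),
            class = "sim1_result")
}

#' Simulation 2: the Ganong effect
#'
#' For each item word, each phoneme position, and each step of a 7-step
#' identification continuum (blend proportion alpha = 0, 1/6, ..., 1 from
#' the lexical phoneme to its nonword replacement), runs one trial per
#' feedback condition and records the peak activation of the two endpoint
#' single-phone nodes. The predicted proportion of lexical-phoneme choices
#' is peak(lexical) / (peak(lexical) + peak(replacement)). The lexical
#' shift at a position is the mean over items and steps of the
#' feedback-minus-no-feedback difference in choice proportion.
#'
#' @param lexicon A `tisk_lexicon` containing the item words.
#' @param words Named character vector of 4-phoneme item words (labels ->
#'   phoneme strings); defaults to [ganong_word_fixture()].
#' @param replacements Character matrix (items x positions) of replacement
#'   phonemes; defaults to [ganong_replacements()]. A replacement that
#'   creates a real word of the lexicon triggers a warning (continua must
#'   end in nonwords).
#' @param params_fb,params_nofb Parameter sets for the two models
#'   (defaults: `OPT_FB` with feedback, `OPT_NOFB` without).
#' @param n_steps Number of continuum steps (default 7).
#' @param threshold Unused placeholder for config compatibility.
#' @return List of class `sim2_result`: `trials` (word x position x step x
#'   feedback rows with peaks and choice proportion), `by_position`
#'   (mean +- se per position x step x feedback), `shift` (per-position
#'   mean lexical shift).
#' @export
sim2_ganong <- function(lexicon = bundled_lexicon(),
                        words = ganong_word_fixture(),
                        replacements = ganong_replacements(),
                        params_fb = tisk_params("OPT_FB"),
                        params_nofb = tisk_params("OPT_NOFB"),
                        n_steps = 7L, threshold = 0.05) {
  stopifnot(all(names(words) %in% lexicon$labels))
  alphas <- seq(0, 1, length.out = n_steps)
  strings <- lexicon_strings(lexicon)
  nets <- list(fb = build_network(lexicon, params_fb),
               nofb = build_network(lexicon, params_nofb))
  fb_flags <- c(fb = TRUE, nofb = FALSE)
  rows <- list()
  for (wlab in names(words)) {
    ph <- phonemes(words[[wlab]])
    for (pos in seq_along(ph)) {
      lex_ph <- ph[pos]
      rep_ph <- replacements[wlab, pos]
      nonword <- ph
      nonword[pos] <- rep_ph
      if (paste(nonword, collapse = "") %in% strings) {
        warning(sprintf(
          "replacement /%s/ at position %d of '%s' creates a real word",
          rep_ph, pos, wlab), call. = FALSE)
      }
      for (cond in names(nets)) {
        net <- nets[[cond]]
        base <- word_schedule(ph, net$params, inventory = net$inventory)
        for (k in seq_along(alphas)) {
          sch <- blend_schedule(base, pos, lex_ph, rep_ph, alphas[k])
          tr <- run_trial(net, sch, feedback_on = fb_flags[[cond]])
          pk_lex <- max(tr$single[, lex_ph])
          pk_rep <- max(tr$single[, rep_ph])
          choice <- if (pk_lex + pk_rep > 0) pk_lex / (pk_lex + pk_rep) else 0.5
          rows[[length(rows) + 1L]] <- data.frame(
            word = wlab, position = pos, step = k, alpha = alphas[k],
            feedback = fb_flags[[cond]], peak_lexical = pk_lex,
            peak_replacement = pk_rep, choice = choice,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  trials <- do.call(rbind, rows)
  agg <- stats::aggregate(choice ~ position + step + alpha + feedback,
                          data = trials, FUN = mean)
  agg$se <- stats::aggregate(choice ~ position + step + alpha + feedback,
                             data = trials,
                             FUN = function(x) stats::sd(x) / sqrt(length(x))
                             )$choice
  # lexical shift: feedback minus no-feedback, averaged over items and steps
  on <- trials[trials$feedback, ]
  off <- trials[!trials$feedback, ]
  key <- function(d) paste(d$word, d$position, d$step)
  off <- off[match(key(on), key(off)), ]
  on$shift <- on$choice - off$choice
  shift <- stats::aggregate(shift ~ position, data = on, FUN = mean)
  structure(list(trials = trials, by_position = agg, shift = shift),
            class = "sim2_result")
}

#' Simulation 3: retroactive right-context disambiguation
#'
#' Presents the contexts `_lug` (intact /pl^g/, ambiguous /#l^g/) and
#' `_lush` (intact /bl^S/, ambiguous /#l^S/), where /#/ is an onset halfway
#' between /p/ and /b/ (both endpoint nodes receive 0.5). Each context runs
#' with and without feedback; the /p/ and /b/ single-phone trajectories are
#' recorded. The lexicon must contain plug and blush, while blug and plush
#' must be nonwords, so that the final phoneme retroactively disambiguates
#' the onset.
#'
#' @param lexicon A `tisk_lexicon` (default: the bundled lexicon, which
#'   contains plug and blush).
#' @param params_fb,params_nofb Parameter sets for the feedback and
#'   no-feedback models.
#' @return List of class `sim3_result`: `traces` (long data frame: context,
#'   input, feedback, cycle, phoneme, activation) and `words` (the item
#'   transcriptions used).
#' @export
sim3_right_context <- function(lexicon = bundled_lexicon(),
                               params_fb = tisk_params("OPT_FB"),
                               params_nofb = tisk_params("OPT_NOFB")) {
  for (need in c("plug", "blush")) {
    if (!(need %in% lexicon$labels)) {
      stop(sprintf("lexicon must contain '%s'", need), call. = FALSE)
    }
  }
  strings <- lexicon_strings(lexicon)
  if ("pl^S" %in% strings || "bl^g" %in% strings) {
    warning("plush/blug present in the lexicon; right-context items are not nonwords",
            call. = FALSE)
  }
  items <- list(lug = "pl^g", lush = "bl^S")
  nets <- list(`TRUE` = build_network(lexicon, params_fb),
               `FALSE` = build_network(lexicon, params_nofb))
  rows <- list()
  for (context in names(items)) {
    ph <- phonemes(items[[context]])
    for (fb in c(TRUE, FALSE)) {
      net <- nets[[as.character(fb)]]
      base <- word_schedule(ph, net$params, inventory = net$inventory)
      schedules <- list(intact = base,
                        ambiguous = blend_schedule(base, 1L, "p", "b", 0.5))
      for (input in names(schedules)) {
        tr <- run_trial(net, schedules[[input]], feedback_on = fb)
        for (phon in c("p", "b")) {
          rows[[length(rows) + 1L]] <- data.frame(
            context = context, input = input, feedback = fb,
            cycle = seq_len(tr$n_cycles) - 1L, phoneme = phon,
            activation = tr$single[, phon], stringsAsFactors = FALSE)
        }
      }
    }
  }
  traces <- do.call(rbind, rows)
  rownames(traces) <- NULL
  structure(list(traces = traces, words = unlist(items)),
            class = "sim3_result")
}

#' Simulation 4: phoneme restoration
#'
#' For each item word, each phoneme position is presented intact, replaced
#' by silence, or replaced by truncated Gaussian noise (SD 0.2, 0.3, 0.4,
#' 0.8), under both the feedback and the no-feedback model: 2 models x 4
#' positions x 6 input types per item. The dependent measure is the peak
#' activation of the expected (replaced) phoneme's single-phone node.
#' Restoration is feedback-driven activation of that node when its
#' bottom-up input has been replaced by noise — but not by silence.
#'
#' @param lexicon A `tisk_lexicon` containing the item words.
#' @param words Named character vector of item words (default the 10-word
#'   fixture).
#' @param noise_sds Noise standard deviations (default 0.2, 0.3, 0.4, 0.8).
#' @param params_fb,params_nofb Parameter sets for the two models.
#' @param seed Master seed for the noise draws.
#' @return List of class `sim4_result`: `trials` (one row per simulation)
#'   and `summary` (mean +- se of the expected phoneme's peak per feedback
#'   x input type).
#' @export
sim4_restoration <- function(lexicon = bundled_lexicon(),
                             words = ganong_word_fixture(),
                             noise_sds = c(0.2, 0.3, 0.4, 0.8),
                             params_fb = tisk_params("OPT_FB"),
                             params_nofb = tisk_params("OPT_NOFB"),
                             seed = 1L) {
  stopifnot(all(names(words) %in% lexicon$labels))
  nets <- list(`TRUE` = build_network(lexicon, params_fb),
               `FALSE` = build_network(lexicon, params_nofb))
  types <- c("intact", "silence", paste0("noise_", noise_sds))
  rows <- list()
  trial_id <- 0L
  for (wlab in names(words)) {
    ph <- phonemes(words[[wlab]])
    for (pos in seq_along(ph)) {
      for (fb in c(TRUE, FALSE)) {
        net <- nets[[as.character(fb)]]
        base <- word_schedule(ph, net$params, inventory = net$inventory)
        for (type in types) {
          trial_id <- trial_id + 1L
          sch <- if (type == "intact") {
            base
          } else if (type == "silence") {
            degrade_schedule(base, pos, "silence")
          } else {
            sd <- as.numeric(sub("noise_", "", type))
            # same noise sample for the two models at a given item/position
            degrade_schedule(base, pos, "noise", noise_sd = sd,
                             seed = derive_seeds(seed, 1L,
                                                 stream = trial_id %/% 2L))
          }
          tr <- run_trial(net, sch, feedback_on = fb)
          rows[[length(rows) + 1L]] <- data.frame(
            word = wlab, position = pos, feedback = fb, type = type,
            noise_sd = if (grepl("^noise", type)) {
              as.numeric(sub("noise_", "", type))
            } else {
              NA_real_
            },
            peak_expected = max(tr$single[, ph[pos]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  trials <- do.call(rbind, rows)
  summ <- stats::aggregate(peak_expected ~ feedback + type, data = trials,
                           FUN = mean)
  summ$se <- stats::aggregate(peak_expected ~ feedback + type, data = trials,
                              FUN = function(x) stats::sd(x) / sqrt(length(x))
                              )$peak_expected
  structure(list(trials = trials, summary = summ), class = "sim4_result")
}

#' Simulation 5: graceful degradation under input noise
#'
#' Full-lexicon runs at increasing levels of global input noise, for
#' several model variants. At each noise level and run, every word is
#' presented once with truncated Gaussian noise added to all external
#' inputs over the word's span; noise samples are shared across variants
#' (derived from the master seed per level x run x word) so matched-item
#' comparisons pair identical stimuli. Reports accuracy and mean RT per
#' variant x level x run, and a matched-item analysis restricted to words
#' recognized by both the feedback and the optimized no-feedback model.
#'
#' @param lexicon A `tisk_lexicon`.
#' @param noise_levels Noise SDs (default 0.01..0.15 in steps of 0.01; the
#'   scaled acceptance runs use a coarser grid).
#' @param runs Full-lexicon runs per level (default 15).
#' @param variants Named list of model variants (see
#'   [sim1_timecourse()]); defaults to all four: feedback, optimized
#'   no-feedback, original no-feedback, and the feedback parameters with
#'   feedback off.
#' @param seed Master seed.
#' @param matched Character vector of two variant names for the
#'   matched-item RT analysis (default `c("TISKfb", "TISK_opt")`).
#' @param threshold,hold Recognition criterion.
#' @return List of class `sim5_result`: `summary` (variant x level x run
#'   accuracy and mean RT over recognized words), `level_summary` (means +-
#'   se over runs), `outcomes` (per-word outcomes), `matched` (per level x
#'   run matched-item RT means, pair counts and proportion faster with
#'   feedback).
#' @export
sim5_noise_sweep <- function(lexicon,
                             noise_levels = seq(0.01, 0.15, by = 0.01),
                             runs = 15L,
                             variants = default_variants(),
                             seed = 1L,
                             matched = c("TISKfb", "TISK_opt"),
                             threshold = 0.05, hold = 10L) {
  stopifnot(inherits(lexicon, "tisk_lexicon"), runs >= 1L)
  nets <- lapply(variants, function(v) build_network(lexicon, v$params))
  n_words <- length(lexicon)
  summary_rows <- list()
  outcome_rows <- list()
  for (li in seq_along(noise_levels)) {
    lev <- noise_levels[li]
    for (run in seq_len(runs)) {
      seeds <- derive_seeds(seed, n_words, stream = li * 1000L + run)
      for (v in names(variants)) {
        res <- run_lexicon(nets[[v]], feedback_on = variants[[v]]$feedback,
                           noise_sd = lev, seeds = seeds,
                           threshold = threshold, hold = hold)
        oc <- res$outcomes
        oc$variant <- v
        oc$noise_sd <- lev
        oc$run <- run
        outcome_rows[[length(outcome_rows) + 1L]] <- oc
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          variant = v, noise_sd = lev, run = run,
          accuracy = mean(oc$recognized),
          mean_rt = if (any(oc$recognized)) {
            mean(oc$rt[oc$recognized])
          } else {
            NA_real_
          },
          stringsAsFactors = FALSE)
      }
    }
  }
  summary <- do.call(rbind, summary_rows)
  outcomes <- do.call(rbind, outcome_rows)
  level_summary <- stats::aggregate(accuracy ~ variant + noise_sd,
                                    data = summary, FUN = mean)
  level_summary$accuracy_se <-
    stats::aggregate(accuracy ~ variant + noise_sd, data = summary,
                     FUN = function(x) stats::sd(x) / sqrt(length(x))
                     )$accuracy
  rt_agg <- stats::aggregate(mean_rt ~ variant + noise_sd, data = summary,
                             FUN = mean, na.action = stats::na.omit)
  level_summary$mean_rt <- rt_agg$mean_rt[
    match(paste(level_summary$variant, level_summary$noise_sd),
          paste(rt_agg$variant, rt_agg$noise_sd))]
  # matched-item analysis over the intersection of recognized words
  matched_rows <- list()
  if (all(matched %in% names(variants))) {
    for (lev in noise_levels) {
      for (run in seq_len(runs)) {
        a <- outcomes[outcomes$variant == matched[1] &
                        outcomes$noise_sd == lev & outcomes$run == run, ]
        b <- outcomes[outcomes$variant == matched[2] &
                        outcomes$noise_sd == lev & outcomes$run == run, ]
        shared <- intersect(a$word[a$recognized], b$word[b$recognized])
        rta <- a$rt[match(shared, a$word)]
        rtb <- b$rt[match(shared, b$word)]
        matched_rows[[length(matched_rows) + 1L]] <- data.frame(
          noise_sd = lev, run = run,
          n_valid_a = sum(a$recognized), n_valid_b = sum(b$recognized),
          n_pairs = length(shared),
          mean_rt_a = if (length(shared)) mean(rta) else NA_real_,
          mean_rt_b = if (length(shared)) mean(rtb) else NA_real_,
          prop_a_faster = if (length(shared)) mean(rta < rtb) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(summary = summary, level_summary = level_summary,
                 outcomes = outcomes,
                 matched = if (length(matched_rows)) {
                   do.call(rbind, matched_rows)
                 } else {
                   NULL
                 },
                 matched_variants = matched),
            class = "sim5_result")
}
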