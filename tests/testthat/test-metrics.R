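test_that("the recognition criterion implements margin, hold, and suffix", {
  m <- cbind(a = rep(0.6, 30), b = rep(0.5, 30))
  out <- recognition_time(m, "a", threshold = 0.05, hold = 10)
  expect_true(out$recognized)
  expect_identical(out$rt_cycle, 0L)
  expect_identical(out$final_winner, "a")

  # margin below threshold throughout
  m2 <- cbind(a = rep(0.54, 30), b = rep(0.5, 30))
  expect_false(recognition_time(m2, "a")$recognized)

  # leads by a recognizable margin but is later overtaken
  m3 <- cbind(a = c(rep(0.6, 15), rep(0.4, 15)),
              b = c(rep(0.5, 15), rep(0.5, 15)))
  out3 <- recognition_time(m3, "a", hold = 10)
  expect_false(out3$recognized)
  expect_identical(out3$final_winner, "b")

  # hold must fit in the trace
  expect_error(recognition_time(m[1:5, ], "a", hold = 10), "hold")
  expect_error(recognition_time(m, "c"), "not in trace")

  # margin must hold against all competitors simultaneously
  m4 <- cbind(a = rep(0.6, 20), b = rep(0.5, 20), c = rep(0.57, 20))
  expect_false(recognition_time(m4, "a")$recognized)
})

test_that("the criterion matches the exhaustive scanner on random traces", {
  set.seed(99)
  for (rep in 1:1000) {
    m <- random_trace(n_cycles = 25, n_words = 4)
    thr <- sample(c(0.01, 0.05, 0.1), 1)
    hold <- sample(c(1, 5, 10), 1)
    got <- recognition_time(m, "w1", threshold = thr, hold = hold)
    want <- oracle_recognition(m, "w1", thr, hold)
    expect_identical(got$rt_cycle, want)
    expect_identical(got$recognized, !is.na(want))
  }
})

test_that("raising threshold or hold never helps recognition", {
  set.seed(5)
  for (rep in 1:50) {
    m <- random_trace(n_cycles = 30, n_words = 3)
    lo <- recognition_time(m, "w1", threshold = 0.02, hold = 5)
    hi_thr <- recognition_time(m, "w1", threshold = 0.08, hold = 5)
    hi_hold <- recognition_time(m, "w1", threshold = 0.02, hold = 15)
    if (hi_thr$recognized) {
      expect_true(lo$recognized)
      expect_gte(hi_thr$rt_cycle, lo$rt_cycle)
    }
    if (hi_hold$recognized) {
      expect_true(lo$recognized)
      expect_gte(hi_hold$rt_cycle, lo$rt_cycle)
    }
  }
})

test_that("accuracy is the fraction recognized", {
  mk <- function(rec) structure(list(recognized = rec), class = "recognition_outcome")
  expect_equal(accuracy(lapply(1:5, function(i) mk(TRUE))), 1)
  expect_equal(accuracy(lapply(1:5, function(i) mk(FALSE))), 0)
  expect_equal(accuracy(c(rep(TRUE, 209), rep(FALSE, 2))), 209 / 211)
  expect_equal(round(accuracy(c(rep(TRUE, 209), rep(FALSE, 2))), 4), 0.9905)
  expect_error(accuracy(list()), "no outcomes")
})

test_that("competitor classes follow the cohort/rhyme taxonomy", {
  lex <- lexicon(c(doll = "dal", dock = "dak", dolly = "dali", ball = "bal",
                   tall = "tal", soot = "sut", pa = "pa"))
  cls <- competitor_classes(lex, "doll")
  expect_setequal(cls$cohorts, c("dock", "dolly"))   # share /da/
  expect_setequal(cls$rhymes, c("ball", "tall"))     # 3-phoneme _al words
  expect_setequal(cls$unrelated, c("soot", "pa"))
  expect_false("doll" %in% unlist(cls))
  # sets are disjoint
  expect_length(intersect(cls$cohorts, cls$rhymes), 0)
  # a one-phoneme target has no cohort
  lex1 <- lexicon(c(a = "a", ba = "ba"))
  expect_length(competitor_classes(lex1, "a")$cohorts, 0)
})

test_that("lexical dimensions reproduce the CAT worked example", {
  lex <- lexicon(c(kat = "kat", at = "at", skat = "skat", bat = "bat",
                   katalag = "katalag", dal = "dal"))
  d <- lexical_dimensions(lex, "kat")
  expect_equal(d[["length"]], 3)
  expect_equal(d[["embeddings"]], 1)        # AT embeds within CAT
  expect_equal(d[["ex_embeddings"]], 2)     # CAT embeds in CATALOG and SCAT
  # rhymes admit first-position substitution, deletion, and addition:
  # BAT, AT, SCAT
  expect_equal(d[["rhymes"]], 3)
  # DAS neighbors: BAT (substitution), AT (deletion), SCAT (addition)
  expect_equal(d[["das_neighbors"]], 3)
  expect_equal(d[["onset_competitors"]], 1) # KATALAG shares /ka/
  # no same-prefix words for AT
  expect_equal(lexical_dimensions(lex, "at")[["onset_competitors"]], 0)
})

test_that("dimension counts agree with brute-force pairwise predicates", {
  lex <- generate_synthetic_lexicon(
    synthetic_lexicon_spec(120, length_range = c(2, 6), seed = 13))
  strs <- vapply(lex$phonemes, paste, "", collapse = "")
  for (ti in seq(1, 120, by = 7)) {
    target <- lex$labels[ti]
    tp <- lex$phonemes[[ti]]
    got <- lexical_dimensions(lex, target)
    emb <- onset <- exemb <- das <- rhy <- 0
    for (j in seq_along(lex$labels)) {
      if (j == ti) next
      wp <- lex$phonemes[[j]]
      if (length(wp) < length(tp) && oracle_substring(wp, tp)) emb <- emb + 1
      if (length(wp) > length(tp) && oracle_substring(tp, wp)) {
        exemb <- exemb + 1
      }
      if (length(tp) >= 2 && length(wp) >= 2 && all(wp[1:2] == tp[1:2])) {
        onset <- onset + 1
      }
      if (oracle_das(strs[j], strs[ti])) das <- das + 1
      # rhyme variants of the target: substitute, delete, or add at onset
      tails_match <-
        (length(wp) == length(tp) && wp[1] != tp[1] &&
           (length(tp) == 1 || all(wp[-1] == tp[-1]))) ||
        (length(wp) == length(tp) - 1 && all(wp == tp[-1])) ||
        (length(wp) == length(tp) + 1 && all(wp[-1] == tp))
      if (tails_match) rhy <- rhy + 1
    }
    expect_equal(unname(got), c(length(tp), emb, onset, exemb, das, rhy))
  }
})

test_that("class time courses average per class with items that have one", {
  lex <- lexicon(c(doll = "dal", dock = "dak", ball = "bal"))
  net <- build_network(lex, tisk_params("OPT_NOFB", total_cycles = 30L))
  traces <- lapply(stats::setNames(lex$labels, lex$labels), function(w) {
    run_trial(net, word_schedule(lex$phonemes[[match(w, lex$labels)]],
                                 net$params), feedback_on = FALSE)
  })
  tc <- class_timecourse(traces, lex)
  expect_setequal(unique(tc$class), c("target", "cohort", "rhyme",
                                      "unrelated"))
  # doll has cohort dock and rhyme ball; ball has rhymes doll (and no
  # cohort); the cohort mean pools only items with cohorts
  expect_equal(unique(tc$n_items[tc$class == "target"]), 3)
  expect_equal(unique(tc$n_items[tc$class == "cohort"]), 2)
  # the all-word baseline never exceeds the per-cycle maximum word mean
  base <- tc$mean[tc$class == "unrelated"]
  tgt <- tc$mean[tc$class == "target"]
  expect_true(all(base <= tgt + 1e-12))

  # single-word lexicon: target curve only
  lex1 <- lexicon(c(solo = "sal"))
  net1 <- build_network(lex1, tisk_params("OPT_NOFB", total_cycles = 20L))
  tr1 <- list(solo = run_trial(net1, word_schedule("sal", net1$params),
                               feedback_on = FALSE))
  tc1 <- class_timecourse(tr1, lex1)
  expect_setequal(unique(tc1$class), c("target", "unrelated"))
})

test_that("RT correlations use the shared recognized items", {
  a <- c(w1 = 10, w2 = 20, w3 = NA, w4 = 40)
  b <- c(w1 = 12, w2 = 19, w3 = 30, w4 = 45)
  rc <- rt_correlation(a, b)
  expect_identical(rc$n, 3L)
  expect_setequal(rc$labels, c("w1", "w2", "w4"))
  expect_gt(rc$r, 0.9)
})
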