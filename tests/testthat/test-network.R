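test_that("parameter presets carry the published values", {
  orig <- tisk_params("ORIGINAL")
  expect_equal(orig$input_phoneme_decay, 0.010)
  expect_equal(orig$w_phoneme_to_nphone, 1.000)
  expect_equal(orig$fb_positive, 0)
  fb <- tisk_params("OPT_FB")
  expect_equal(fb$nphone_decay, 0.100)
  expect_equal(fb$w_word_word_inhibition, -0.010)
  expect_equal(fb$fb_positive, 0.150)
  expect_equal(fb$fb_negative, -0.050)
  nofb <- tisk_params("OPT_NOFB")
  expect_equal(nofb$word_decay, 0.050)
  expect_equal(nofb$w_phoneme_to_nphone, 0.100)
  expect_error(tisk_params("OPT_FB", nphone_decay = 1.2), "\\[0, 1\\)")
  expect_error(tisk_params("OPT_FB", w_word_word_inhibition = 0.1),
               "nonpositive")
  expect_error(tisk_params("OPT_FB", nonsense = 1), "unknown parameter")
})

test_that("parameter YAML presets round-trip", {
  for (preset in c("ORIGINAL", "OPT_NOFB", "OPT_FB")) {
    path <- system.file("extdata", "presets",
                        paste0(tolower(preset), ".yaml"), package = "tisk")
    expect_true(nzchar(path))
    p <- load_params(path)
    expect_equal(unclass(p), unclass(tisk_params(preset)))
  }
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(tisk_params("OPT_FB", gamma = 0.7), path)
  expect_equal(load_params(path)$gamma, 0.7)
})

test_that("network construction wires the documented architecture", {
  lex <- doll_lexicon()
  net <- build_network(lex, tisk_params("OPT_FB"))
  P <- length(lex$inventory$symbols)
  expect_equal(net$n_nphone, P + P^2)           # 14 + 196 = 210
  expect_identical(net$n_nphone, 210L)
  expect_setequal(word_constituents(net, "doll"),
                  c("d", "a", "l", "da", "dl", "al"))
  # constituents + non-constituents partition the N-phone layer
  n_const <- sum(net$C_const[match("doll", lex$labels), ] > 0)
  expect_identical(n_const + (net$n_nphone - n_const), net$n_nphone)
  expect_identical(n_const, 6L)
  # a word longer than the slot count is rejected
  long <- lexicon(c(toolong = strrep("pa", 6)))
  expect_error(build_network(long, tisk_params("OPT_FB")), "slots")
})

test_that("the resting state is a fixed point under zero input", {
  net <- build_network(doll_lexicon(), tisk_params("OPT_FB"))
  sch <- word_schedule("dal", net$params)
  sch$ext[] <- 0
  tr <- run_trial(net, sch, feedback_on = TRUE)
  expect_equal(max(abs(tr$word)), 0)
  expect_equal(max(abs(tr$single)), 0)
})

test_that("a single input propagates one layer per cycle as computed by hand", {
  p <- tisk_params("OPT_FB", nphone_decay = 0, input_phoneme_decay = 0)
  net <- build_network(doll_lexicon(), p)
  sch <- word_schedule("d", p, total_cycles = 5)
  st <- initial_state(net)
  st <- tisk_step(net, st, sch, feedback_on = FALSE)
  expect_equal(unname(st$a_input["d", 1]), 1)   # input clamps this cycle
  expect_equal(unname(st$a_single[["d"]]), 0)   # snapshot was at rest
  st <- tisk_step(net, st, sch, feedback_on = FALSE)
  # shunting: a' = 0 + w_phoneme_to_nphone * 1 * (act_max - 0) = 0.1
  expect_equal(unname(st$a_single[["d"]]), p$w_phoneme_to_nphone * 1 *
                 (p$act_max - 0))
  expect_equal(max(abs(st$a_diphone)), 0)       # no second phoneme yet
})

test_that("without feedback the sublexical layers ignore the lexicon", {
  p <- tisk_params("OPT_FB")
  net_a <- build_network(doll_lexicon(), p)
  net_b <- build_network(lexicon(c(alpha = "pi", beta = "guk")), p)
  sch <- word_schedule("dal", p)
  tr_a <- run_trial(net_a, sch, feedback_on = FALSE)
  tr_b <- run_trial(net_b, sch, feedback_on = FALSE)
  expect_equal(tr_a$single, tr_b$single, tolerance = 1e-12)
})

test_that("activations stay within bounds for arbitrary schedules", {
  p <- tisk_params("OPT_FB", total_cycles = 40L)
  net <- build_network(doll_lexicon(), p)
  set.seed(11)
  for (rep in 1:5) {
    sch <- word_schedule("dal", p)
    sch$ext <- array(runif(length(sch$ext), 0, 2), dim = dim(sch$ext),
                     dimnames = dimnames(sch$ext))
    tr <- run_trial(net, sch, feedback_on = TRUE,
                    record = c("word", "single", "diphone", "input"))
    for (layer in c("word", "single", "diphone", "input")) {
      expect_true(all(tr[[layer]] >= p$act_min - 1e-12))
      expect_true(all(tr[[layer]] <= p$act_max + 1e-12))
    }
  }
})

test_that("input-layer nodes decay monotonically to rest after offset", {
  p <- tisk_params("ORIGINAL", total_cycles = 80L)
  net <- build_network(doll_lexicon(), p)
  sch <- word_schedule("dal", p, total_cycles = 80)
  tr <- run_trial(net, sch, feedback_on = FALSE, record = c("word", "single",
                                                            "input"))
  d_idx <- match("d", net$symbols)   # input node (d, slot 1), offset cycle 10
  d_traj <- tr$input[, d_idx]
  post <- d_traj[11:80]
  expect_true(all(diff(post) <= 0))
  expect_lt(post[70 - 10], post[1])
  expect_gte(min(post), 0)
})

test_that("trials are deterministic given the schedule", {
  net <- build_network(doll_lexicon(), tisk_params("OPT_FB"))
  sch <- word_schedule("dal", net$params)
  tr1 <- run_trial(net, sch, feedback_on = TRUE)
  tr2 <- run_trial(net, sch, feedback_on = TRUE)
  expect_identical(tr1$word, tr2$word)
  expect_identical(tr1$single, tr2$single)
})

test_that("the target word wins its own clear presentation", {
  lex <- bundled_lexicon()
  net <- build_network(lex, tisk_params("OPT_FB"))
  tr <- run_trial(net, word_schedule("pl^g", net$params), feedback_on = TRUE)
  expect_identical(names(which.max(tr$word[nrow(tr$word), ])), "plug")
  out <- recognition_time(tr, "plug")
  expect_true(out$recognized)
})

test_that("feedback favors constituents and suppresses runaway competitors", {
  net <- build_network(doll_lexicon(), tisk_params("OPT_FB"))
  sch <- word_schedule("dal", net$params)
  tr <- run_trial(net, sch, feedback_on = TRUE,
                  record = c("word", "single", "diphone"))
  const <- word_constituents(net, "doll")
  singles <- const[nchar(const) == 1]
  others <- setdiff(net$symbols, singles)
  late <- 30:100
  mean_const <- rowMeans(tr$single[late, singles])
  mean_other <- rowMeans(tr$single[late, others])
  expect_true(all(mean_const > mean_other))
  # at full lexicon scale, lateral inhibition plus negative feedback keep
  # every other word below half the target's sustained activation
  big <- build_network(bundled_lexicon(), tisk_params("OPT_FB"))
  tr2 <- run_trial(big, word_schedule("pl^g", big$params), feedback_on = TRUE)
  fin <- tr2$word[nrow(tr2$word), ]
  expect_true(all(fin[setdiff(names(fin), "plug")] <= 0.5 * fin[["plug"]]))
})

test_that("recognition is order-sensitive end to end", {
  net <- build_network(doll_lexicon(), tisk_params("OPT_FB"))
  tr <- run_trial(net, word_schedule("kat", net$params), feedback_on = TRUE)
  fin <- tr$word[nrow(tr$word), ]
  expect_gt(fin[["kat"]], fin[["tak"]])   # same multiset, different order
  tr2 <- run_trial(net, word_schedule("tak", net$params), feedback_on = TRUE)
  fin2 <- tr2$word[nrow(tr2$word), ]
  expect_gt(fin2[["tak"]], fin2[["kat"]])
})

test_that("traces export to tidy long form", {
  net <- build_network(doll_lexicon(), tisk_params("OPT_FB",
                                                   total_cycles = 20L))
  tr <- run_trial(net, word_schedule("dal", net$params), feedback_on = TRUE)
  df <- as.data.frame(tr)
  expect_named(df, c("cycle", "layer", "node", "activation"))
  expect_setequal(unique(df$layer), c("word", "single"))
  expect_equal(nrow(df), 20 * (length(doll_lexicon()) + 14))
})

test_that("grid search ranks parameter combinations by score", {
  base <- tisk_params("OPT_FB")
  res <- param_grid_search(base, list(gamma = c(0.3, 0.5)),
                           score = function(p) -abs(p$gamma - 0.5))
  expect_equal(res$gamma[1], 0.5)
  expect_equal(nrow(res), 2)
})
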