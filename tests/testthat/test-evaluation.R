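test_that("block split: 360 trials -> 36 blocks -> 180/180, blocks intact", {
  sp <- split_trials(360, seed = 3)
  expect_length(sp$train, 180)
  expect_length(sp$test, 180)
  expect_length(intersect(sp$train, sp$test), 0)
  block_of <- function(ids) unique((ids - 1) %/% 10 + 1)
  expect_length(intersect(block_of(sp$train), block_of(sp$test)), 0)
  # every block's 10 trials land on the same side
  for (b in block_of(sp$train)) {
    expect_true(all(((b - 1) * 10 + 1):(b * 10) %in% sp$train))
  }
  expect_identical(sp, split_trials(360, seed = 3))
  expect_false(identical(sp, split_trials(360, seed = 4)))
  expect_error(split_trials(365), "divisible")
})

test_that("rank-sum comparison matches the exact enumeration oracle", {
  # identical groups: no evidence of a shift
  p_same <- compare_groups(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(p_same[["p_raw"]], 0.05)
  # Bonferroni is plain multiplication, capped at 1
  p <- compare_groups(1:10, 11:20, n_comparisons = 5)
  expect_equal(p[["p_adjusted"]], min(1, p[["p_raw"]] * 5))
  # disjoint groups {1..10} vs {11..20}: the exact two-sided tail
  # probability is 2 / choose(20, 10) (the two most extreme orderings)
  expect_equal(p[["p_raw"]], 2 / choose(20, 10), tolerance = 1e-12)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("protocols produce complete, bounded, deterministic tables", {
  ds <- small_dataset()
  own <- run_protocol(ds, "OWN")
  expect_equal(nrow(own), 3 * 3)  # 3 subjects x 3 grid configurations
  expect_true(all(own$accuracy >= 0 & own$accuracy <= 100))
  oth <- run_protocol(ds, "OTHER", n_train_subjects = 2)
  expect_equal(nrow(oth), 3 * 3)  # C(2,2)=1 combination per held-out subject
  expect_true(all(oth$combination %in% c("1+2", "1+3", "2+3")))
  # held-out subject never appears in its own training combination
  for (i in seq_len(nrow(oth))) {
    expect_false(as.character(oth$test_subject[i]) %in%
                   strsplit(oth$combination[i], "+", fixed = TRUE)[[1]])
  }
  expect_identical(run_protocol(ds, "OWN"), own)
  expect_error(run_protocol(ds, "OTHER", n_train_subjects = 5), "n_subjects")
})

test_that("combination cap subsamples deterministically", {
  ds <- small_dataset()
  oth <- run_protocol(ds, "OTHER", n_train_subjects = 1,
                      keys = ds$grid$key[1])
  expect_equal(nrow(oth), 3 * 2)  # C(2,1) = 2 per held-out subject
  capped <- run_protocol(ds, "OTHER", n_train_subjects = 1,
                         max_combinations = 1, keys = ds$grid$key[1])
  expect_equal(nrow(capped), 3)
  expect_identical(capped,
                   run_protocol(ds, "OTHER", n_train_subjects = 1,
                                max_combinations = 1, keys = ds$grid$key[1]))
})

test_that("subject-count sweep has one summary cell per (k, method)", {
  ds <- small_dataset()
  sw <- sweep_subject_counts(ds, ks = 1:2, keys = ds$grid$key[1:2],
                             max_combinations = 1)
  sm <- summarize_evaluation(sw)
  expect_equal(nrow(sm), 2 * 2)
  expect_setequal(sm$n_train_subjects, c(1, 2))
})

test_that("homogeneous subjects make OTHER match OWN within sampling error", {
  ds <- homog_dataset()
  own <- summarize_evaluation(run_protocol(ds, "OWN"))
  oth <- summarize_evaluation(run_protocol(ds, "OTHER", n_train_subjects = 2))
  gap <- function(sm, m) sm$mean[sm$method == m]
  # exchangeable subjects: transfer costs at most small-cohort sampling
  # error (3 subjects x 40 trials), for every method
  for (m in c("swn", "zscore", "none")) {
    expect_lt(abs(gap(own, m) - gap(oth, m)), 8)
  }
  # and the amplitude-sensitive baseline loses far more under gain
  # heterogeneity than under exchangeability
  ds_het <- small_dataset()
  own_h <- summarize_evaluation(run_protocol(ds_het, "OWN"))
  oth_h <- summarize_evaluation(run_protocol(ds_het, "OTHER",
                                             n_train_subjects = 2))
  expect_lt(gap(own, "none") - gap(oth, "none") + 3,
            gap(own_h, "none") - gap(oth_h, "none"))
})

test_that("no training signal leaks from the test split", {
  ds <- small_dataset()
  s <- 1L
  sub <- ds$subjects[[s]]
  test_trials <- ds$splits[[s]]$test
  # z-score statistics are computed from training trials only: recompute
  # them with the test-split preprocessed data replaced by garbage
  cfg <- ds$config
  prof <- subject_profile(s, cfg)
  sch <- emgswn:::movement_schedule(cfg, s)
  pre <- lapply(seq_len(cfg$n_trials), function(tr) {
    preprocess_emg(emgswn:::simulate_trial(cfg, prof, tr, sch)$emg)$samples
  })
  stats_clean <- zscore_stats(pre[ds$splits[[s]]$train])
  pre_garbled <- pre
  for (tr in test_trials) pre_garbled[[tr]] <- pre_garbled[[tr]] * 1e6 + 5
  stats_garbled <- zscore_stats(pre_garbled[ds$splits[[s]]$train])
  expect_identical(stats_clean, stats_garbled)
  expect_identical(stats_clean$mean, sub$zscore_stats$mean)
  # classifier fit depends on training rows only: garbling test-row
  # features leaves the fitted coefficients unchanged
  key <- ds$grid$key[1]
  tr_idx <- emgswn:::subject_rows(sub, ds$splits[[s]]$train)
  te_idx <- emgswn:::subject_rows(sub, test_trials)
  f1 <- train_classifier(sub$features[[key]][tr_idx, ], sub$labels[tr_idx])
  feats2 <- sub$features[[key]]
  feats2[te_idx, ] <- -99
  f2 <- train_classifier(feats2[tr_idx, ], sub$labels[tr_idx])
  expect_identical(f1$coef, f2$coef)
})

test_that("SD-vs-MAV diagnostic: proportional series correlate perfectly without normalization", {
  # amplitude-modulated signal whose window SD is proportional to MAV
  set.seed(6)
  env <- 1 + sin(2 * pi * (1:3000) / 1500)^2
  x <- matrix(rnorm(3000) * env, ncol = 1)
  rec <- emg_recording(x, 500, stage = "preprocessed")
  sd_w <- windowed_sd(rec)
  fm <- assemble_features(emgswn:::advance_stage(rec, "normalized"),
                          feature_spec("MAV"))
  expect_gt(cor(sd_w[, 1], fm[, 1]), 0.99)
})

test_that("sd_feature_correlation separates raw from SWN-normalized features", {
  ds <- small_dataset()
  r_none <- sd_feature_correlation(ds, "none")
  r_swn <- sd_feature_correlation(ds, "swn")
  expect_gt(r_none$mean_correlation, 0.8)
  # window-normalized MAV decouples from (in fact anti-correlates with)
  # the raw window SD
  expect_lt(r_swn$mean_correlation, 0.1)
  expect_equal(nrow(r_none$table), 3 * ds$config$n_channels)
  # the streaming-feature reading keeps a mild transition coupling but is
  # still far below the raw correlation
  r_stream <- sd_feature_correlation(ds, "swn", mav = "stream")
  expect_lt(r_stream$mean_correlation, r_none$mean_correlation - 0.3)
  # both readings coincide for the unnormalized signal
  expect_equal(sd_feature_correlation(ds, "none", mav = "stream")$mean_correlation,
               r_none$mean_correlation, tolerance = 1e-9)
})

test_that("best-over-grid selection maximizes within subject then averages", {
  df <- data.frame(
    test_subject = rep(1:2, each = 4),
    model_type = "OWN", method = "swn", feature = "ALL",
    window_norm_ms = rep(c(100, 100, 500, 500), 2),
    window_feature_ms = rep(c(100, 500), 4),
    n_train_subjects = NA, combination = NA,
    accuracy = c(50, 60, 70, 80, 40, 90, 55, 65))
  class(df) <- c("emg_evaluation", class(df))
  best <- best_window_accuracy(df)
  expect_equal(best$mean, mean(c(80, 90)))
})
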