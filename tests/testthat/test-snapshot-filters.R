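test_that("signed fold change follows the +/- ratio convention", {
  expect_equal(signed_fold_change(50, 100), -2)
  expect_equal(signed_fold_change(100, 50), 2)
  expect_equal(signed_fold_change(123, 123), 1)
  # antisymmetry over random pairs
  set.seed(7)
  a <- runif(200, 1, 1e4); b <- runif(200, 1, 1e4)
  expect_equal(signed_fold_change(a, b), -signed_fold_change(b, a))
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
  # zero intensities are floored at epsilon before the ratio
  expect_equal(signed_fold_change(0, 100, epsilon = 1), -100)
  expect_error(signed_fold_change(0, 100, epsilon = 0), "epsilon")
})

test_that("printed all-tissue exclusion example reproduces its consistent fold cells", {
  s <- depdc6_study()
  sfc <- sfc_matrix(s)
  expect_equal(signed_fold_change(947, 14), 947 / 14)
  expect_equal(round(sfc["Depdc6", "MES"]), 68)
  expect_equal(round(sfc["Depdc6", "LIV"]), 44)
  # excluded from every depot list by any non-adipose window at or below
  # the magnitude of its liver fold (the table's stated purpose)
  for (w in c(1.5, 2)) {
    cfg <- filter_config(adipose_threshold = 1.5, nonadipose_window = w)
    for (d in c("SC", "EPI", "MES")) {
      lists <- depot_filter(s, d, cfg)
      expect_length(lists$up_F, 0)
      expect_length(lists$up_L, 0)
    }
  }
  # without the window the probe is a (spurious) depot hit
  cfg0 <- filter_config(adipose_threshold = 1.5, nonadipose_window = NULL)
  expect_identical(depot_filter(s, "SC", cfg0)$up_F, "Depdc6")
})

test_that("depot filter applies threshold and non-adipose window as stated", {
  folds <- rbind(
    pass_sc   = c(3.0, 1.0, 1.0, 1.1, -1.05, 1.0),
    win_fail  = c(3.0, 1.0, 1.0, 1.6, 1.0, 1.0),
    lean_hit  = c(-2.5, 1.0, 1.0, 1.0, 1.2, -1.3),
    below_thr = c(1.4, 1.0, 1.0, 1.0, 1.0, 1.0)
  )
  s <- study_from_folds(folds)
  lists <- depot_filter(s, "SC", filter_config(1.5, 1.5))
  expect_identical(lists$up_F, "pass_sc")
  expect_identical(lists$up_L, "lean_hit")
})

test_that("identical F and L columns yield empty candidate lists", {
  s <- study_from_folds(matrix(1, 3, 6))
  for (d in c("SC", "EPI", "MES")) {
    lists <- depot_filter(s, d, filter_config())
    expect_length(lists$up_F, 0)
    expect_length(lists$up_L, 0)
  }
})

test_that("coordinate 3-WAT filter requires all depots with a common sign", {
  folds <- rbind(
    all_up    = c(3.0, 2.8, 2.6, 1.1, -1.1, 1.0),
    two_up    = c(3.0, 2.8, 1.0, 1.0, 1.0, 1.0),
    discord   = c(2.0, -2.0, 2.0, 1.0, 1.0, 1.0),
    all_down  = c(-3.0, -2.2, -1.8, 1.1, 1.0, -1.2)
  )
  s <- study_from_folds(folds)
  lists <- coordinate_3wat_filter(s, filter_config(1.5, 1.5))
  expect_identical(lists$up_F, "all_up")
  expect_identical(lists$up_L, "all_down")
})

test_that("stringent filter uses >=2 boundary, window and intensity floor", {
  # fold exactly 2.0 in all WATs is retained (criterion is >=2)
  s <- study_from_folds(rbind(boundary = c(2, 2, 2, 1, 1, 1)), base = 300)
  ct <- stringent_candidates(s)
  expect_identical(ct$up_F, "boundary")
  expect_equal(unname(ct$mean_3wat_fold["boundary"]), 2)
  # ... but not at the relaxed stage run with a strict > threshold of 2
  strict2 <- filter_config(adipose_threshold = 2, nonadipose_window = 2)
  expect_length(coordinate_3wat_filter(s, strict2)$up_F, 0)

  # 4-fold candidate at comfortable intensity is retained with mean fold ~4
  s <- study_from_folds(rbind(strong = c(4, 4, 4, 1.1, 1.0, -1.1)), base = 125)
  ct <- stringent_candidates(s)
  expect_identical(ct$up_F, "strong")
  expect_equal(unname(ct$mean_3wat_fold["strong"]), 4)

  # same fold pattern but mean 3-WAT intensity 60 AU in the higher line
  s_dim <- study_from_folds(rbind(dim = c(4, 4, 4, 1.1, 1.0, -1.1)), base = 15)
  expect_length(stringent_candidates(s_dim)$up_F, 0)
})

test_that("mean 3-WAT fold is the arithmetic mean of sign-consistent folds", {
  s <- study_from_folds(rbind(p1 = c(6, 8, 7, 1, 1, 1),
                              p2 = c(3.4, 3.4, 3.4, 1, 1, 1),
                              bad = c(2, -2, 2, 1, 1, 1)))
  expect_equal(mean_3wat_fold(s, "p1"), 7)
  expect_equal(mean_3wat_fold(s, "p2"), 3.4)
  expect_error(mean_3wat_fold(s, "bad"), "sign-discordant")
  expect_error(mean_3wat_fold(s, "nope"), "unknown probe")
})

test_that("a strongly planted WAT gene lands near its generating fold", {
  cfg <- generator_config(n_probes = 300,
                          class_counts = c(adipose_F_up = 30),
                          effects = list(adipose_F_up = 2.8),
                          noise_sd = 0.1)
  out <- generate_snapshot(cfg, seed = 42)
  planted <- out$truth$probe_id[out$truth$class == "adipose_F_up"]
  folds <- vapply(planted, function(p) mean_3wat_fold(out$study, p), 1)
  expect_true(all(folds > 6 & folds < 8))
})

test_that("swapping the F and L lines mirrors every candidate list", {
  s <- random_snapshot_study(60, seed = 31)
  sw <- swap_lines(s)
  for (cfg in list(filter_config(1.5, 1.5), filter_config(1.5, NULL),
                   stringent_config())) {
    a <- coordinate_3wat_filter(s, cfg)
    b <- coordinate_3wat_filter(sw, cfg)
    expect_setequal(a$up_F, b$up_L)
    expect_setequal(a$up_L, b$up_F)
  }
})

test_that("tightening thresholds never adds a probe to a list", {
  s <- random_snapshot_study(80, seed = 13)
  base <- coordinate_3wat_filter(s, filter_config(1.3, 2.5))
  for (thr in c(1.5, 2, 3)) {
    tighter <- coordinate_3wat_filter(s, filter_config(thr, 2.5))
    expect_true(all(tighter$up_F %in% base$up_F))
    expect_true(all(tighter$up_L %in% base$up_L))
  }
  for (win in c(2, 1.5, 1.2)) {
    tighter <- coordinate_3wat_filter(s, filter_config(1.3, win))
    expect_true(all(tighter$up_F %in% base$up_F))
    expect_true(all(tighter$up_L %in% base$up_L))
  }
})

test_that("stringent candidates nest inside the relaxed list at matched windows", {
  set.seed(99)
  for (seed in c(101, 202)) {
    s <- random_snapshot_study(120, seed = seed)
    relaxed_w2 <- coordinate_3wat_filter(s, filter_config(1.5, 2))
    strin <- stringent_candidates(s)
    expect_true(all(strin$up_F %in% relaxed_w2$up_F))
    expect_true(all(strin$up_L %in% relaxed_w2$up_L))
  }
})

test_that("filter lists equal a brute-force evaluation of the printed predicates", {
  for (seed in c(1, 17, 23)) {
    s <- random_snapshot_study(50, seed = seed)
    for (d in c("SC", "EPI", "MES")) {
      got <- depot_filter(s, d, filter_config(1.5, 1.5))
      want <- brute_depot_lists(s, d, 1.5, 1.5)
      expect_setequal(got$up_F, want$up_F)
      expect_setequal(got$up_L, want$up_L)
      got <- depot_filter(s, d, filter_config(1.5, NULL))
      want <- brute_depot_lists(s, d, 1.5, NULL)
      expect_setequal(got$up_F, want$up_F)
      expect_setequal(got$up_L, want$up_L)
    }
  }
})
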