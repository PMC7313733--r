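test_that("fBm generation is deterministic and validates H", {
  expect_identical(gen_fbm(0.3, 1000, seed = 5), gen_fbm(0.3, 1000, seed = 5))
  expect_false(identical(gen_fbm(0.3, 1000, seed = 5),
                         gen_fbm(0.3, 1000, seed = 6)))
  expect_error(gen_fbm(0, 100), "inside")
  expect_error(gen_fbm(1.2, 100), "inside")
  expect_error(gen_fbm(0.5, 1), ">= 2")
})

test_that("H = 0.5 increments are uncorrelated on average", {
  ac1 <- vapply(1:50, function(s) {
    dx <- diff(gen_fbm(0.5, 2^12, seed = s))
    stats::cor(dx[-1], dx[-length(dx)])
  }, numeric(1))
  expect_lt(abs(mean(ac1)), 0.05)
})

test_that("fBm variance grows as t^(2H)", {
  H <- 0.8
  paths <- vapply(1:50, function(s) gen_fbm(H, 2^12, seed = 100 + s),
                  numeric(2^12))
  t_idx <- 2^(2:12)
  v <- apply(paths[t_idx, ], 1L, stats::var)   # ensemble variance at time t
  slope <- stats::coef(stats::lm(log(v) ~ log(t_idx)))[[2]]
  expect_lt(abs(slope - 2 * H), 0.15)
})

test_that("Weierstrass fixture is deterministic with known smooth limit", {
  w1 <- gen_weierstrass(0.5, 3, n_terms = 20, n = 4096)
  expect_identical(w1, gen_weierstrass(0.5, 3, n_terms = 20, n = 4096))
  cosine <- gen_weierstrass(0.5, 3, n_terms = 1, n = 2^12)
  expect_equal(record_fd(cosine)$D, 1, tolerance = 0.05)
  expect_error(gen_weierstrass(1.2, 3), "in \\(0, 1\\)")
  expect_error(gen_weierstrass(0.2, 3, n_terms = 5), "a \\* b > 1")
})

test_that("gen_study produces the full factorial design deterministically", {
  cfg <- tiny_study_config(seed = 8)
  ds <- gen_study(cfg)
  expect_length(ds$records, 3 * 6 * 2 * (2 + 1))
  expect_equal(nrow(ds$answers), 3 * 6 * 3)
  expect_false(anyNA(ds$answers$correct))

  fss <- vapply(ds$records, function(r) r$fs, numeric(1))
  mods <- vapply(ds$records, function(r) r$modality, character(1))
  expect_true(all(fss[mods == "EEG"] == 128))
  expect_true(all(fss[mods == "EMG"] == 256))

  ds2 <- gen_study(tiny_study_config(seed = 8))
  expect_identical(ds, ds2)

  # default design: 9 x 6 x 2 x (12 + 5) records
  dcfg <- study_config()
  expect_equal(dcfg$n_subjects * 6 * dcfg$sessions *
                 (dcfg$n_channels_eeg + dcfg$n_channels_emg), 1836)
})

test_that("substream seeding insulates records from config order", {
  cfg_a <- tiny_study_config(seed = 4)
  cfg_b <- tiny_study_config(seed = 4, n_channels_emg = 2)
  a <- gen_study(cfg_a); b <- gen_study(cfg_b)
  key <- function(r) paste(r$subject_id, r$stimulus_id, r$session,
                           r$modality, r$channel)
  kb <- vapply(b$records, key, "")
  for (r in a$records[1:10]) {
    expect_identical(r$samples, b$records[[match(key(r), kb)]]$samples)
  }
})

test_that("certain questionnaire probabilities give certain answers", {
  ds <- gen_study(tiny_study_config(seed = 2, duration_s = 2,
                                    p_correct_2d = 1, p_correct_3d = 1))
  expect_true(all(ds$answers$correct == 1))
  ds0 <- gen_study(tiny_study_config(seed = 2, duration_s = 2,
                                     p_correct_2d = 0, p_correct_3d = 0))
  expect_true(all(ds0$answers$correct == 0))
})

test_that("study_config rejects invalid parameters", {
  expect_error(study_config(h_eeg_2d = 1.5), "Hurst")
  expect_error(study_config(p_correct_2d = 1.2), "probabilities")
  expect_error(study_config(n_subjects = 0), "positive")
  expect_error(study_config(n_channels_eeg = 0, n_channels_emg = 0),
               "at least one channel")
})
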