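test_that("binned proportions pool AOI samples and flag empty bins as missing", {
  # one trial, target LEFT, all samples on the target: p = 1 in every bin
  n <- 420
  gaze <- tibble::tibble(participant_id = "p1", trial_id = "t1",
                         t_ms = seq(0, by = 1000 / 60, length.out = n),
                         label = "LEFT_AOI")
  design <- tibble::tibble(participant_id = "p1", trial_id = "t1",
                           pair_id = "pair01", target_word = "bottle",
                           target_side = "LEFT", target_onset_ms = 3000,
                           half = 1L)
  pairs <- tibble::tibble(pair_id = "pair01", word_a = "bottle", word_b = "hat")
  d <- lwl_dataset(gaze, design, pairs)
  series <- bin_proportions(d)
  expect_identical(nrow(series), 140L)  # 7,000 / 50
  expect_identical(unique(series$n_aoi), 3L)  # 3 samples per 50 ms bin at 60 Hz
  expect_true(all(series$p_target == 1))
  expect_equal(series$bin_start_ms, seq(0, 6950, by = 50))

  # mixed bin: 2 target + 1 distractor -> 2/3; off-screen bins are absent
  gaze2 <- gaze
  gaze2$label <- rep("OFFSCREEN_OR_INVALID", n)
  gaze2$label[1:3] <- c("LEFT_AOI", "LEFT_AOI", "RIGHT_AOI")
  series2 <- bin_proportions(lwl_dataset(gaze2, design, pairs))
  expect_identical(nrow(series2), 1L)
  expect_equal(series2$p_target, 2 / 3)
  expect_equal(series2$y, asin(sqrt(2 / 3)))
  expect_equal(series2$deviation, asin(sqrt(2 / 3)) - pi / 4)
})

test_that("per-bin t matches the direct formula and skips degenerate bins", {
  series <- withr::with_seed(7, {
    tidyr::expand_grid(participant_id = sprintf("p%d", 1:8),
                       bin_start_ms = seq(0, 450, 50)) |>
      dplyr::mutate(p_target = runif(dplyr::n(), 0.2, 0.8),
                    y = asin(sqrt(p_target)),
                    deviation = y - pi / 4)
  })
  tt <- per_bin_t(series)
  for (b in unique(series$bin_start_ms)) {
    devs <- series$deviation[series$bin_start_ms == b]
    expect_equal(tt$t[tt$bin_start_ms == b], direct_t(devs), tolerance = 1e-12)
  }
  expect_identical(unique(tt$df), 7)

  # all participants exactly at chance: zero variance, bin skipped
  at_chance <- series
  at_chance$y <- pi / 4
  expect_warning(tt0 <- per_bin_t(at_chance), "zero variance")
  expect_true(all(is.na(tt0$t)))
  # a single-participant bin is skipped silently
  one <- series[series$participant_id == "p1" & series$bin_start_ms == 0, ]
  tt1 <- per_bin_t(rbind(series[series$bin_start_ms > 0, ], one))
  expect_true(is.na(tt1$t[tt1$bin_start_ms == 0]))
})

test_that("cluster scanning follows the sign, threshold and adjacency rules", {
  ts <- tibble::tibble(bin_start_ms = seq(0, 200, 50),
                       t = c(0.5, 2.5, 3.0, 1.0, -2.5))
  cl <- find_clusters(ts, threshold = 2.02)
  expect_identical(nrow(cl), 2L)
  expect_equal(cl$start_ms, c(50, 200))
  expect_equal(cl$end_ms, c(150, 250))
  expect_identical(cl$sign, c("POSITIVE", "NEGATIVE"))
  expect_equal(cl$mass, c(5.5, -2.5))
  expect_identical(cl$n_bins, c(2L, 1L))

  expect_identical(nrow(find_clusters(
    tibble::tibble(bin_start_ms = seq(0, 200, 50), t = c(1, -2, 0, 2, 1.5)))), 0L)

  # a skipped bin breaks adjacency
  broken <- find_clusters(tibble::tibble(bin_start_ms = c(0, 50, 100),
                                         t = c(2.5, NA, 2.5)))
  expect_identical(nrow(broken), 2L)
  expect_identical(broken$n_bins, c(1L, 1L))
  # so does a gap in the bin grid
  gap <- find_clusters(tibble::tibble(bin_start_ms = c(0, 100), t = c(2.5, 2.5)))
  expect_identical(nrow(gap), 2L)
})

test_that("permutation p-values are reproducible and ordered by cluster mass", {
  d <- cached_dataset("effect12", sim_config(n_per_group = 4, delta = 0.25,
                                             fuss_prob = 0, seed = 88))
  retained <- filter_trials(summarize_trials(d))$summaries
  series <- bin_proportions(d, retained)
  r1 <- permutation_null(series, n_resamples = 150, seed = 99)
  r2 <- permutation_null(series, n_resamples = 150, seed = 99)
  expect_identical(r1$clusters$p, r2$clusters$p)
  expect_identical(r1$null_max, r2$null_max)
  cl <- r1$clusters
  ord <- order(-abs(cl$mass))
  expect_true(all(diff(cl$p[ord]) >= 0))
  expect_true(all(cl$p >= 0 & cl$p <= 1))
  # counting convention: p = (# null maxima >= |mass|) / B
  expect_equal(cl$p, vapply(abs(cl$mass),
                            function(m) mean(r1$null_max >= m), numeric(1)))
  r3 <- permutation_null(series, n_resamples = 150, seed = 99, p_mode = "add_one")
  expect_equal(r3$clusters$p,
               (cl$p * 150 + 1) / 151, tolerance = 1e-12)
  expect_error(permutation_null(series, n_resamples = 150), "seed")
  expect_error(permutation_null(series, n_resamples = 0, seed = 1), "resamples")
})

test_that("a strong localized post-naming bias is detected where it occurs", {
  # bias active only 1,000-2,000 ms after naming: the significant positive
  # cluster should overlap that interval (in absolute trial time)
  hits <- 0L
  reps <- 25L
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_per_group = 8, delta = 0.3, fuss_prob = 0,
                      latency_mean_ms = 1000, latency_sd_ms = 0,
                      bias_duration_ms = 1000, seed = 7000 + i)
    d <- simulate_dataset(cfg)
    retained <- filter_trials(summarize_trials(d))$summaries
    res <- cluster_permutation(d, retained, n_resamples = 100, seed = i)
    cl <- res$clusters
    onset <- mean(d$design$target_onset_ms)
    sig <- cl[cl$p < 0.05 & cl$sign == "POSITIVE", ]
    if (nrow(sig) && any(sig$start_ms < onset + 2000 & sig$end_ms > onset + 1000)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / reps, 0.8)
})

test_that("the bootstrap resampling mode runs and is reproducible", {
  d <- cached_dataset("effect12", sim_config(n_per_group = 4, delta = 0.25,
                                             fuss_prob = 0, seed = 88))
  retained <- filter_trials(summarize_trials(d))$summaries
  series <- bin_proportions(d, retained)
  b1 <- permutation_null(series, n_resamples = 60, seed = 3, mode = "bootstrap")
  b2 <- permutation_null(series, n_resamples = 60, seed = 3, mode = "bootstrap")
  expect_identical(b1$null_max, b2$null_max)
  expect_true(all(b1$clusters$p >= 0 & b1$clusters$p <= 1))
})
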