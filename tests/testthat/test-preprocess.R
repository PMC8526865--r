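test_that("raw coordinates are classified by AOI geometry", {
  geo <- aoi_geometry()
  expect_identical(classify_sample(460, 540, TRUE, geo), "LEFT_AOI")
  expect_identical(classify_sample(1460, 540, TRUE, geo), "RIGHT_AOI")
  expect_identical(classify_sample(960, 540, TRUE, geo), "ONSCREEN_OTHER")
  expect_identical(classify_sample(460, 540, FALSE, geo), "OFFSCREEN_OR_INVALID")
  expect_identical(classify_sample(-10, 540, TRUE, geo), "OFFSCREEN_OR_INVALID")
  expect_identical(classify_sample(NA, NA, TRUE, geo), "OFFSCREEN_OR_INVALID")
  expect_error(aoi_geometry(left = c(100, 100, 1200, 900),
                            right = c(1100, 100, 1800, 900)), "overlap")
})

# hand-built single-participant dataset with known window composition
manual_dataset <- function(labels, t_ms = NULL, onset = 1000,
                           target_side = "LEFT") {
  n <- length(labels)
  if (is.null(t_ms)) t_ms <- seq(0, by = 1000 / 60, length.out = n)
  gaze <- tibble::tibble(participant_id = "p1", trial_id = "t1",
                         t_ms = t_ms, label = labels)
  design <- tibble::tibble(participant_id = "p1", trial_id = "t1",
                           pair_id = "pair01", target_word = "bottle",
                           target_side = target_side, target_onset_ms = onset,
                           half = 1L)
  pairs <- tibble::tibble(pair_id = "pair01", word_a = "bottle", word_b = "hat")
  lwl_dataset(gaze, design, pairs)
}

test_that("trial summaries count the window with a half-open boundary", {
  # 40 window samples: 30 target, 10 distractor -> p_target 0.75
  labs <- c(rep("OFFSCREEN_OR_INVALID", 60),
            rep("LEFT_AOI", 30), rep("RIGHT_AOI", 10),
            rep("OFFSCREEN_OR_INVALID", 320))
  t_ms <- c(seq(0, by = 1000 / 60, length.out = 60),
            seq(1368, by = 1000 / 60, length.out = 40),
            seq(4505, 6990, length.out = 320))
  s <- summarize_trials(manual_dataset(labs, t_ms))
  expect_identical(s$n_target, 30L)
  expect_identical(s$n_distractor, 10L)
  expect_equal(s$p_target, 0.75)
  expect_equal(s$attention, 40 / 420)

  # samples exactly at onset + 368 are in; at onset + 3505 are out
  edge <- manual_dataset(c("LEFT_AOI", "LEFT_AOI"), t_ms = c(1368, 4505))
  se <- summarize_trials(edge)
  expect_identical(se$n_target, 1L)

  # all off-screen: p undefined, attention zero
  off <- summarize_trials(manual_dataset(rep("OFFSCREEN_OR_INVALID", 420)))
  expect_true(is.na(off$p_target))
  expect_identical(off$attention, 0)
})

test_that("the attention filter is a strict less-than at 12.5 percent", {
  s <- tibble::tibble(participant_id = "p1", trial_id = c("t1", "t2", "t3"),
                      pair_id = "pair01", n_target = c(5L, 5L, 0L),
                      n_distractor = 0L, n_other_onscreen = 0L, n_off = 0L,
                      attention = c(40 / 420, 0.125, 0.9),
                      p_target = c(1, 1, NA))
  flt <- filter_trials(s)
  expect_identical(flt$summaries$trial_id, "t2")
  expect_setequal(flt$log$trial_id, c("t1", "t3"))
  expect_match(flt$log$reason[flt$log$trial_id == "t3"], "no AOI looks")
  # idempotent, and the log accounts exactly for the dropped rows
  again <- filter_trials(flt$summaries)
  expect_identical(again$summaries, flt$summaries)
  expect_identical(nrow(again$log), 0L)
  expect_identical(nrow(s) - nrow(flt$summaries), nrow(flt$log))
})

test_that("infants need at least four computable pairs", {
  pp <- tibble::tibble(
    participant_id = rep(c("a", "b"), c(3, 4)),
    pair_id = sprintf("pair%02d", c(1:3, 1:4)),
    pi = 0)
  flt <- filter_infants(pp)
  expect_identical(unique(flt$pair_pis$participant_id), "b")
  expect_identical(flt$log$participant_id, "a")
  expect_identical(filter_infants(flt$pair_pis)$pair_pis, flt$pair_pis)
})

test_that("fussiness-driven infant exclusions match the generator ground truth", {
  d <- cached_dataset("fussy", sim_config(n_per_group = 5, fuss_prob = 0.5,
                                          fuss_p_off = 0.9,
                                          fuss_p_return = 0.01, seed = 303))
  summ <- summarize_trials(d)
  flt <- filter_trials(summ)
  pis <- compute_pair_pis(flt$summaries)$pair_pis
  counts <- table(factor(pis$participant_id,
                         levels = d$participants$participant_id))
  flt_inf <- filter_infants(pis)
  # retained infants are exactly those whose ground-truth pair count is >= 4
  expect_setequal(unique(flt_inf$pair_pis$participant_id),
                  names(counts)[counts >= 4])
  # the log names every infant that contributed some, but too few, pairs
  expect_setequal(flt_inf$log$participant_id,
                  names(counts)[counts > 0 & counts < 4])
  expect_gt(nrow(flt_inf$log), 0)
  expect_gt(length(unique(flt_inf$pair_pis$participant_id)), 0)
})

test_that("window counts always add up to the number of window samples", {
  d <- cached_dataset("tiny", tiny_config())
  s <- summarize_trials(d)
  totals <- s$n_target + s$n_distractor + s$n_other_onscreen + s$n_off
  rel <- dplyr::inner_join(d$gaze,
                           d$design[c("participant_id", "trial_id",
                                      "target_onset_ms")],
                           by = c("participant_id", "trial_id"))
  rel <- rel$t_ms - rel$target_onset_ms
  expect_identical(sum(totals), sum(rel >= 368 & rel < 3505))
})

test_that("rarely-heard pairs are dropped per infant, not globally", {
  d <- cached_dataset("tiny", tiny_config())
  q <- d$questionnaire
  q$exposure <- pmax(q$exposure, 2L)
  inf_a <- d$participants$participant_id[1]
  inf_b <- d$participants$participant_id[2]
  q$exposure[q$participant_id == inf_a & q$word == "bottle"] <- 1L
  d2 <- lwl_dataset(d$gaze, d$design, d$pairs, d$participants, q)
  res <- exclude_rare_pairs(d2)
  expect_identical(res$log$participant_id, inf_a)
  expect_identical(res$log$pair_id, "pair01")
  des <- res$dataset$design
  expect_false(any(des$participant_id == inf_a & des$pair_id == "pair01"))
  expect_true(any(des$participant_id == inf_b & des$pair_id == "pair01"))
  # gaze rows of dropped trials are gone too
  expect_identical(nrow(res$dataset$gaze),
                   nrow(res$dataset$design) * 481L)
  # pairs with ratings (2, 2) are untouched
  expect_identical(nrow(res$dataset$design), nrow(d$design) - 2L)
})
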