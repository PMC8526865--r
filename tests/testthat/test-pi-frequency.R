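test_that("the pair proportion index follows p1 + p2 - 1 with its bounds", {
  expect_equal(pair_pi(0.75, 0.5), 0.25)
  expect_equal(pair_pi(0.5, 0.5), 0)
  expect_equal(pair_pi(1, 1), 1)
  expect_equal(pair_pi(0, 0), -1)
  expect_error(pair_pi(1.2, 0.5))
})

test_that("yoked redundancy: anchoring on either image gives the same index", {
  d <- cached_dataset("tiny", tiny_config(delta = 0.15, tau = 0.1))
  summ <- filter_trials(summarize_trials(d))$summaries
  two <- summ |>
    dplyr::inner_join(d$design[c("participant_id", "trial_id", "half")],
                      by = c("participant_id", "trial_id")) |>
    dplyr::filter(!is.na(p_target)) |>
    dplyr::group_by(participant_id, pair_id) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::arrange(half, .by_group = TRUE)
  p1 <- two$p_target[c(TRUE, FALSE)]
  p2 <- two$p_target[c(FALSE, TRUE)]
  # image named in half 1: looking at it when named vs when distractor
  anchored_first <- p1 - (1 - p2)
  # anchored on the other image of the pair
  anchored_second <- p2 - (1 - p1)
  expect_equal(anchored_first, anchored_second)
  expect_equal(anchored_first, pair_pi(p1, p2))
  # order of the two trials never matters
  expect_equal(pair_pi(p1, p2), pair_pi(p2, p1))
})

test_that("pairs with a single valid trial are skipped and logged", {
  s <- tibble::tibble(
    participant_id = "p1",
    trial_id = c("t1", "t2", "t3"),
    pair_id = c("pair01", "pair01", "pair02"),
    p_target = c(0.75, 0.5, 0.8))
  res <- compute_pair_pis(s)
  expect_identical(res$pair_pis$pair_id, "pair01")
  expect_equal(res$pair_pis$pi, 0.25)
  expect_identical(res$log$pair_id, "pair02")
})

test_that("aggregation to infants and items is the unweighted mean", {
  pp <- tibble::tibble(participant_id = c("a", "a", "b"),
                       pair_id = c("pair01", "pair02", "pair01"),
                       pi = c(0.2, -0.2, 0.25))
  byi <- pi_by_infant(pp)
  expect_equal(byi$pi_mean[byi$participant_id == "a"], 0)
  expect_equal(byi$pi_mean[byi$participant_id == "b"], 0.25)
  expect_identical(byi$n_pairs, c(2L, 1L))
  byt <- pi_by_item(pp)
  expect_equal(byt$pi_mean[byt$pair_id == "pair01"], mean(c(0.2, 0.25)))
  expect_identical(byt$n_infants, c(2L, 1L))
})

test_that("every proportion index lies in [-1, 1] on simulated data", {
  d <- cached_dataset("fussy", sim_config(n_per_group = 5, fuss_prob = 0.5,
                                          fuss_p_off = 0.9,
                                          fuss_p_return = 0.01, seed = 303))
  pp <- pair_pis_of(d)
  expect_true(all(pp$pi >= -1 & pp$pi <= 1))
  expect_true(all(abs(pi_by_infant(pp)$pi_mean) <= 1))
  expect_true(all(abs(pi_by_item(pp)$pi_mean) <= 1))
})

test_that("understood-word counts follow the questionnaire statuses exactly", {
  q <- tibble::tibble(
    participant_id = "p1",
    word = c("a", "b", "c"),
    status = c("UNDERSTANDS", "DOES_NOT_UNDERSTAND", "UNDERSTANDS_AND_SPEAKS"),
    exposure = 3L)
  expect_identical(count_understood(q)$n_understood, 2L)
  q$status <- "DOES_NOT_UNDERSTAND"
  expect_identical(count_understood(q)$n_understood, 0L)
  # generator ground truth is recovered exactly
  d <- cached_dataset("tiny", tiny_config())
  truth <- d$questionnaire |>
    dplyr::summarise(n_true = sum(true_understands), .by = "participant_id")
  counted <- count_understood(d$questionnaire)
  joined <- dplyr::inner_join(truth, counted, by = "participant_id")
  expect_identical(joined$n_understood, joined$n_true)
})

test_that("parental imbalance reproduces the published worked examples", {
  expect_equal(pair_imbalance(4.68, 2.26), 2.42, tolerance = 1e-12)
  expect_equal(pair_imbalance(3.72, 3.67), 0.05, tolerance = 1e-12)
  expect_equal(pair_imbalance(3, 3), 0)
  expect_equal(pair_imbalance(2.26, 4.68), pair_imbalance(4.68, 2.26))
})

test_that("word means and pair imbalances come from the questionnaire", {
  q <- tibble::tibble(participant_id = rep(c("p1", "p2"), each = 2),
                      word = rep(c("bottle", "hat"), 2),
                      status = "UNDERSTANDS",
                      exposure = c(4L, 3L, 5L, 4L))
  expect_equal(word_mean_rating(q, "bottle"), 4.5)
  expect_error(word_mean_rating(q, "xyz"), "xyz")
  pairs <- tibble::tibble(pair_id = "pair01", word_a = "bottle", word_b = "hat")
  imb <- pair_imbalances(q, pairs)
  expect_equal(imb$imbalance, 1)
})

test_that("corpus counts exclude the target child and respect the age cutoff", {
  docs <- c(
    make_chat_fixture(list(ball = c(MOT = 3, CHI = 1),
                           car = c(MOT = 2, FAT = 4)), 24),
    make_chat_fixture(list(ball = c(MOT = 7)), 40),   # too old
    make_chat_fixture(list(car = c(MOT = 5)), 30)
  )
  counts <- childes_word_counts(docs, c("ball", "car", "plate"))
  expect_identical(unname(counts["ball"]), 3)
  expect_identical(unname(counts["car"]), 11)
  expect_identical(unname(counts["plate"]), 0)
  # matching is case-insensitive on orthographic forms
  doc <- make_chat_fixture(list(Ball = c(MOT = 2)), 20)
  expect_identical(unname(childes_word_counts(doc, "ball")["ball"]), 2)
})

test_that("corpus imbalance is the absolute count difference", {
  counts <- c(car = 5300, plate = 22, fork = 20, soup = 38)
  expect_equal(pair_childes_imbalance(counts, "car", "plate"), 5278)
  expect_equal(pair_childes_imbalance(counts, "fork", "soup"), 18)
  expect_equal(pair_childes_imbalance(counts, "car", "car"), 0)
  expect_error(pair_childes_imbalance(counts, "car", "dog"), "missing")
})
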