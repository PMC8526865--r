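# Synthetic LWL data generator.
#
# Looking is modelled as a two-state (target/distractor) first-order dwell
# chain at the 60 Hz sample level, with superimposed off-screen excursions.
# Naming-locked bias enters through the chain's stationary distribution: after
# target-word onset plus a saccade latency, the stationary probability of the
# target state shifts from 0.5 to 0.5 + delta_ij. Modelling bias through the
# stationary distribution (rather than per-sample independence) preserves the
# dwell-time autocorrelation that makes participant-level resampling in the
# cluster permutation test meaningful.

#' Default yoked stimulus pairs for the synthetic design
#'
#' Fourteen pairs covering 28 early-acquired nouns, each with a latent
#' exposure value on the 1-5 Likert scale. The exposure spread emulates a
#' parental word-frequency distribution whose pair imbalances range from
#' near 0 to about 2.4 Likert points.
#'
#' @return Tibble with `pair_id`, `word_a`, `word_b`, `true_exposure_a`,
#'   `true_exposure_b`.
#' @export
default_pairs <- function() {
  tibble::tribble(
    ~word_a, ~word_b, ~true_exposure_a, ~true_exposure_b,
    "bottle", "hat",    3.7, 3.7,
    "brush",  "diaper", 2.3, 4.7,
    "car",    "plate",  4.5, 2.9,
    "baby",   "bird",   4.2, 3.0,
    "fork",   "soup",   2.8, 3.0,
    "ball",   "shoe",   4.0, 3.3,
    "dog",    "cat",    4.4, 3.4,
    "cup",    "spoon",  3.9, 3.2,
    "book",   "banana", 4.1, 3.5,
    "nose",   "foot",   4.3, 2.8,
    "bed",    "door",   4.6, 3.8,
    "milk",   "bread",  4.4, 3.1,
    "sock",   "chair",  3.4, 3.2,
    "apple",  "duck",   3.6, 2.4
  ) |>
    dplyr::mutate(pair_id = sprintf("pair%02d", dplyr::row_number()),
                  .before = 1)
}

#' Configuration of the synthetic gaze generator
#'
#' @param n_per_group Infants per age group (three groups: 6-7, 8-10 and
#'   11-14 months); default 14, i.e. 42 infants in total.
#' @param pairs Tibble as returned by [default_pairs()].
#' @param delta Population target bias: post-naming shift of the dwell
#'   chain's stationary target probability away from 0.5. Must lie in
#'   \[-0.5, 0.5\].
#' @param tau SD of the per-infant bias deviation.
#' @param beta Item effect per Likert point of pair frequency imbalance.
#' @param latency_mean_ms,latency_sd_ms Naming-to-bias onset lag,
#'   truncated-normal with lower bound 0 (saccade latencies are positive).
#' @param stay_prob Per-sample probability of remaining in the current AOI
#'   when the chain is unbiased; governs dwell length (default 0.95, i.e.
#'   mean dwell of 20 samples, about 333 ms).
#' @param p_off,p_return Per-sample hazards of going off-screen and of
#'   returning.
#' @param fuss_prob Probability that a trial is "fussy": its off-screen
#'   hazards are replaced by `fuss_p_off`/`fuss_p_return`, inflating
#'   off-screen occupancy so that the trial typically fails the 12.5 percent
#'   attention filter.
#' @param fuss_p_off,fuss_p_return Off-screen hazards on fussy trials.
#' @param rating_sd SD of the noise added to latent exposures before
#'   rounding to the reported 1-5 Likert rating.
#' @param onset_mean_ms,onset_sd_ms Acoustic onset of the target word
#'   relative to picture onset (the word sits at the end of a carrier
#'   phrase; onsets vary across recordings).
#' @param transition_other Number of samples emitted as `ONSCREEN_OTHER`
#'   while the gaze moves between the two AOIs (default 1; 0 disables).
#' @param bias_duration_ms How long the naming-locked bias stays active
#'   after `target_onset + latency` (default `Inf`: until the trial ends).
#'   Finite values create a localized bias, useful for power studies of the
#'   cluster permutation test.
#' @param seed Integer seed; identical config + seed gives an identical
#'   dataset.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 14,
                       pairs = default_pairs(),
                       delta = 0,
                       tau = 0,
                       beta = 0,
                       latency_mean_ms = 300,
                       latency_sd_ms = 100,
                       stay_prob = 0.95,
                       p_off = 0.02,
                       p_return = 0.15,
                       fuss_prob = 0.15,
                       fuss_p_off = 0.5,
                       fuss_p_return = 0.05,
                       rating_sd = 0.8,
                       onset_mean_ms = 3000,
                       onset_sd_ms = 100,
                       transition_other = 1L,
                       bias_duration_ms = Inf,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(p_off = p_off, p_return = p_return, fuss_prob = fuss_prob,
             fuss_p_off = fuss_p_off, fuss_p_return = fuss_p_return)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (stay_prob <= 0 || stay_prob >= 1) {
    stop("config error: stay_prob must lie in (0, 1)", call. = FALSE)
  }
  if (abs(delta) > 0.5) stop("config error: |delta| must be <= 0.5", call. = FALSE)
  if (latency_mean_ms < 0 || latency_sd_ms < 0) {
    stop("config error: latency parameters must be nonnegative", call. = FALSE)
  }
  stopifnot(all(c("pair_id", "word_a", "word_b",
                  "true_exposure_a", "true_exposure_b") %in% names(pairs)))
  class(cfg) <- "sim_config"
  cfg
}

# 60 Hz sample grid spanning the trial; endpoints exact
.t_grid <- function() seq(-1000, 7000, length.out = 481)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# truncated normal via redraw of negative values
.rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  x <- rnorm(n, mean, sd)
  while (any(x < 0)) x[x < 0] <- rnorm(sum(x < 0), mean, sd)
  x
}

#' Simulate a full LWL dataset
#'
#' Generates, per infant, 28 trials (14 yoked pairs presented once per
#' experiment half, sides and naming order counterbalanced across infants)
#' of 60 Hz gaze samples over -1,000 to 7,000 ms, plus a matching vocabulary
#' questionnaire. Before `target_onset + latency` the AOI dwell chain is
#' symmetric; afterwards its stationary target probability is
#' `0.5 + delta_ij` with `delta_ij = delta + infant_effect_i +
#' beta * imbalance_j` (clamped so the probability stays in \[0.01, 0.99\]).
#' Fussy trials spend most samples off-screen.
#'
#' @param config A [sim_config()].
#' @return An [lwl_dataset()]. The design table carries the per-trial
#'   ground-truth columns `latency_ms`, `fussy` and `delta_true` (preserved
#'   as extra columns by the IO layer).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(config$seed), .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  n_groups <- 3L
  n <- cfg$n_per_group * n_groups
  pairs <- tibble::as_tibble(cfg$pairs)
  n_pairs <- nrow(pairs)

  age_lo <- c(180L, 240L, 330L)[rep(1:3, each = cfg$n_per_group)]
  age_hi <- c(239L, 329L, 449L)[rep(1:3, each = cfg$n_per_group)]
  participants <- tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    age_days = age_lo + floor(runif(n) * (age_hi - age_lo + 1L))
  )
  infant_effect <- if (cfg$tau > 0) rnorm(n, 0, cfg$tau) else numeric(n)

  imbalance <- abs(pairs$true_exposure_a - pairs$true_exposure_b)

  # per-participant design: counterbalancing order, sides, trial sequence
  design <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- sample.int(4L, 1L)
    side_a <- rep(c("LEFT", "RIGHT"), length.out = n_pairs)
    if (ord %in% c(2L, 4L)) side_a <- ifelse(side_a == "LEFT", "RIGHT", "LEFT")
    a_first <- ord <= 2L
    half1 <- sample.int(n_pairs)
    half2 <- sample.int(n_pairs)
    pair_seq <- c(half1, half2)
    named_a <- c(rep(a_first, n_pairs)[half1], rep(!a_first, n_pairs)[half2])
    design[[i]] <- tibble::tibble(
      participant_id = participants$participant_id[i],
      trial_id = sprintf("t%02d", seq_len(2L * n_pairs)),
      pair_id = pairs$pair_id[pair_seq],
      target_word = ifelse(named_a, pairs$word_a[pair_seq], pairs$word_b[pair_seq]),
      target_side = ifelse(named_a, side_a[pair_seq],
                           ifelse(side_a[pair_seq] == "LEFT", "RIGHT", "LEFT")),
      half = rep(1:2, each = n_pairs),
      pair_index = pair_seq,
      infant_index = i
    )
  }
  design <- dplyr::bind_rows(design)
  n_trials <- nrow(design)

  design$target_onset_ms <- round(.clamp(
    rnorm(n_trials, cfg$onset_mean_ms, cfg$onset_sd_ms), 2000, 3400))
  design$latency_ms <- .rtnorm_pos(n_trials, cfg$latency_mean_ms, cfg$latency_sd_ms)
  design$fussy <- runif(n_trials) < cfg$fuss_prob
  design$delta_true <- .clamp(
    cfg$delta + infant_effect[design$infant_index] + cfg$beta * imbalance[design$pair_index],
    -0.49, 0.49)

  labels <- .simulate_chain(design, cfg)

  tg <- .t_grid()
  gaze <- tibble::tibble(
    participant_id = rep(design$participant_id, each = length(tg)),
    trial_id = rep(design$trial_id, each = length(tg)),
    t_ms = rep(tg, times = n_trials),
    label = GAZE_LABELS[as.vector(t(labels))]
  )

  questionnaire <- .simulate_questionnaire(participants, pairs, cfg)

  design$pair_index <- NULL
  design$infant_index <- NULL
  lwl_dataset(gaze = gaze, design = design,
              pairs = pairs[c("pair_id", "word_a", "word_b")],
              participants = participants, questionnaire = questionnaire)
}

# vectorised dwell-chain simulation over all trials at once;
# returns an integer matrix [trial, sample] of indices into GAZE_LABELS
.simulate_chain <- function(design, cfg) {
  tg <- .t_grid()
  n_trials <- nrow(design)
  q <- 1 - cfg$stay_prob

  p_off_t <- ifelse(design$fussy, cfg$fuss_p_off, cfg$p_off)
  p_ret_t <- ifelse(design$fussy, cfg$fuss_p_return, cfg$p_return)
  bias_from <- design$target_onset_ms + design$latency_ms
  target_left <- design$target_side == "LEFT"

  labels <- matrix(0L, n_trials, length(tg))
  in_target <- runif(n_trials) < 0.5
  off_stat <- ifelse(p_off_t + p_ret_t > 0, p_off_t / (p_off_t + p_ret_t), 0)
  off <- runif(n_trials) < off_stat

  emit <- function(off, switched, in_target) {
    lab <- ifelse(xor(in_target, target_left), 2L, 1L)  # LEFT_AOI=1, RIGHT_AOI=2
    if (cfg$transition_other > 0) lab[switched] <- 3L
    lab[off] <- 4L
    lab
  }
  labels[, 1L] <- emit(off, rep(FALSE, n_trials), in_target)

  for (k in 2:length(tg)) {
    active <- tg[k] >= bias_from & tg[k] < bias_from + cfg$bias_duration_ms
    p_star <- .clamp(0.5 + ifelse(active, design$delta_true, 0), 0.01, 0.99)
    leave_t <- pmin(2 * q * (1 - p_star), 0.99)
    leave_d <- pmin(2 * q * p_star, 0.99)
    switched <- runif(n_trials) < ifelse(in_target, leave_t, leave_d)
    in_target <- xor(in_target, switched)
    u <- runif(n_trials)
    off <- ifelse(off, u >= p_ret_t, u < p_off_t)
    labels[, k] <- emit(off, switched, in_target)
  }
  labels
}

.simulate_questionnaire <- function(participants, pairs, cfg) {
  words <- c(pairs$word_a, pairs$word_b)
  true_exp <- c(pairs$true_exposure_a, pairs$true_exposure_b)
  n <- nrow(participants)
  q <- tidyr::expand_grid(participant_id = participants$participant_id,
                          word = words)
  q$true_exposure <- rep(true_exp, times = n)
  age_m <- rep(participants$age_days / 30, each = length(words))
  q$exposure <- as.integer(.clamp(
    round(q$true_exposure + rnorm(nrow(q), 0, cfg$rating_sd)), 1, 5))
  p_und <- stats::plogis(0.25 * (age_m - 10) + 0.5 * (q$true_exposure - 3))
  und <- runif(nrow(q)) < p_und
  speaks <- und & (runif(nrow(q)) < stats::plogis(0.8 * (age_m - 13)))
  q$status <- ifelse(!und, "DOES_NOT_UNDERSTAND",
                     ifelse(speaks, "UNDERSTANDS_AND_SPEAKS", "UNDERSTANDS"))
  q$true_understands <- und
  q[c("participant_id", "word", "status", "exposure",
      "true_exposure", "true_understands")]
}

#' Analytic expectation of the proportion index under a homogeneous config
#'
#' Closed-form (up to a 1 ms quadrature over the latency distribution) oracle
#' for the mean pair proportion index produced by [simulate_dataset()] when
#' `tau = 0` and `beta = 0`. The expectation is `2 * delta * w`, where `w`
#' is the effective fraction of window-of-interest samples at which the dwell
#' chain has both activated (past `target_onset + latency`) and relaxed
#' toward its biased stationary distribution; relaxation is geometric with
#' rate `1 - 2 * (1 - stay_prob)` per sample. Samples emitted as
#' `ONSCREEN_OTHER` during AOI transitions are excluded from the AOI counts,
#' which is also accounted for.
#'
#' @param config A homogeneous [sim_config()] (`tau = 0`, `beta = 0`).
#' @param window Scoring window in ms relative to target-word onset.
#' @return Expected pair proportion index (scalar).
#' @export
expected_pi <- function(config, window = c(368, 3505)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$tau != 0 || config$beta != 0) {
    stop("unsupported case: expected_pi requires a homogeneous config (tau = 0, beta = 0)",
         call. = FALSE)
  }
  if (is.finite(config$bias_duration_ms)) {
    stop("unsupported case: expected_pi requires a persistent bias (bias_duration_ms = Inf)",
         call. = FALSE)
  }
  delta <- config$delta
  if (delta == 0) return(0)

  dt_ms <- 1000 / 60
  q <- 1 - config$stay_prob
  lam <- 1 - 2 * q
  p_star <- .clamp(0.5 + delta, 0.01, 0.99)
  leave_t <- min(2 * q * (1 - p_star), 0.99)
  leave_d <- min(2 * q * p_star, 0.99)

  r <- seq(window[1], window[2] - 1e-9, by = dt_ms)  # sample times after onset

  # latency quadrature (truncated normal, 1 ms grid)
  L <- seq(0, config$latency_mean_ms + 5 * config$latency_sd_ms, by = 1)
  wL <- dnorm(L, config$latency_mean_ms, config$latency_sd_ms)
  if (config$latency_sd_ms == 0) { L <- config$latency_mean_ms; wL <- 1 }
  wL <- wL / sum(wL)

  # k = biased transitions completed at each window sample, per latency value
  kmat <- outer(r, L, function(r, l) pmax(0, floor((r - l) / dt_ms) + 1))
  p_now <- p_star + (0.5 - p_star) * lam^kmat          # P(state = target)
  p_prev <- p_star + (0.5 - p_star) * lam^pmax(kmat - 1, 0)
  p_now[kmat == 0] <- 0.5
  p_prev[kmat == 0] <- 0.5
  lt <- ifelse(kmat > 0, leave_t, q)
  ld <- ifelse(kmat > 0, leave_d, q)
  s <- p_prev * lt + (1 - p_prev) * ld                 # P(switch sample)
  into_t <- (1 - p_prev) * ld                          # P(switched into target)
  if (config$transition_other > 0) {
    num <- sum((p_now - into_t) %*% wL)
    den <- sum((1 - s) %*% wL)
  } else {
    num <- sum(p_now %*% wL)
    den <- length(r)
  }
  2 * (num / den - 0.5)
}

#' Write a minimal CHAT (.cha) transcript fixture
#'
#' Emits a small, synthetic but structurally valid CHAT document: `@UTF8`,
#' `@Begin`, `@Participants` and `@ID` headers (the target child's `@ID`
#' carries the age in `y;mm.dd` form) followed by one utterance tier per
#' speaker embedding each requested word exactly the requested number of
#' times.
#'
#' @param word_counts Named list mapping a word to a named integer vector of
#'   per-speaker counts, e.g. `list(ball = c(MOT = 3, CHI = 1))`.
#' @param child_age_months Age of the target child in months.
#' @param path Optional path; when given the text is written there.
#' @return The CHAT document as a single string (invisibly when `path` is
#'   given).
#' @export
make_chat_fixture <- function(word_counts, child_age_months, path = NULL) {
  if (!is.numeric(child_age_months) || length(child_age_months) != 1 ||
      is.na(child_age_months) || child_age_months < 0) {
    stop("invalid child age", call. = FALSE)
  }
  stopifnot(all(vapply(word_counts, function(x) all(x >= 0), logical(1))))
  years <- floor(child_age_months / 12)
  months <- floor(child_age_months %% 12)
  days <- round((child_age_months %% 1) * 30)
  age_str <- sprintf("%d;%02d.%02d", years, months, days)

  speakers <- unique(c("CHI", unlist(lapply(word_counts, names))))
  roles <- c(CHI = "Target_Child", MOT = "Mother", FAT = "Father",
             INV = "Investigator")
  role_of <- function(s) ifelse(is.na(roles[s]), "Adult", roles[s])

  lines <- c(
    "@UTF8", "@Begin", "@Languages:\tdeu",
    paste0("@Participants:\t",
           paste(sprintf("%s %s", speakers, role_of(speakers)), collapse = ", ")),
    sprintf("@ID:\tdeu|synthcorp|CHI|%s|||||Target_Child||", age_str),
    vapply(setdiff(speakers, "CHI"),
           function(s) sprintf("@ID:\tdeu|synthcorp|%s||||||%s||", s, role_of(s)),
           character(1))
  )
  for (word in names(word_counts)) {
    counts <- word_counts[[word]]
    for (s in names(counts)) {
      if (counts[[s]] > 0) {
        lines <- c(lines, sprintf("*%s:\t%s .", s,
                                  paste(rep(word, counts[[s]]), collapse = " ")))
      }
    }
  }
  lines <- c(lines, "@End")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}
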