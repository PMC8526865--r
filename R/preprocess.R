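# Look classification, window-of-interest scoring and exclusion rules.

#' Area-of-interest geometry
#'
#' Screen bounds and the two AOI rectangles. The default mirrors a 1920 x
#' 1080 display with 700 px square pictures centred 500 px left and right of
#' the screen centre.
#'
#' @param screen `c(width, height)` in px.
#' @param left,right AOI rectangles as `c(xmin, ymin, xmax, ymax)`.
#' @return A list of class `aoi_geometry`.
#' @export
aoi_geometry <- function(screen = c(1920, 1080),
                         left = c(110, 190, 810, 890),
                         right = c(1110, 190, 1810, 890)) {
  overlap <- left[1] < right[3] && right[1] < left[3] &&
    left[2] < right[4] && right[2] < left[4]
  if (overlap) stop("configuration error: AOI rectangles overlap", call. = FALSE)
  structure(list(screen = screen, left = left, right = right),
            class = "aoi_geometry")
}

#' Classify raw gaze samples into look categories
#'
#' Invalid samples and samples outside the screen are `OFFSCREEN_OR_INVALID`;
#' samples inside the left (right) AOI rectangle are `LEFT_AOI`
#' (`RIGHT_AOI`); remaining on-screen samples are `ONSCREEN_OTHER`.
#'
#' @param x,y Screen coordinates in px.
#' @param valid Logical validity flags from the tracker.
#' @param geometry An [aoi_geometry()].
#' @return Character vector of labels.
#' @export
classify_sample <- function(x, y, valid, geometry = aoi_geometry()) {
  inside <- function(r) x >= r[1] & x <= r[3] & y >= r[2] & y <= r[4]
  on_screen <- valid & !is.na(x) & !is.na(y) &
    x >= 0 & x <= geometry$screen[1] & y >= 0 & y <= geometry$screen[2]
  out <- rep("OFFSCREEN_OR_INVALID", length(x))
  out[on_screen] <- "ONSCREEN_OTHER"
  out[on_screen & inside(geometry$left)] <- "LEFT_AOI"
  out[on_screen & inside(geometry$right)] <- "RIGHT_AOI"
  out
}

#' Score every trial over the window of interest
#'
#' For each trial, counts target, distractor, other on-screen and off-screen
#' samples whose time relative to the target-word onset falls in
#' `[window[1], window[2])` (half-open, on the sample grid), computes
#' `p_target = n_target / (n_target + n_distractor)` (NA when no AOI sample
#' falls in the window), and the attention ratio: the share of on-screen
#' samples (any of the three on-screen labels) among all samples with
#' `t_ms` in `[0, 7000)` - the stimulus-presentation period, excluding the
#' 1 s preview before picture onset.
#'
#' @param dataset An [lwl_dataset()] whose gaze table has labels (run
#'   [classify_sample()] first if it has raw coordinates).
#' @param window Window of interest in ms relative to target-word onset.
#' @return Tibble with one row per trial: `participant_id`, `trial_id`,
#'   `pair_id`, `n_target`, `n_distractor`, `n_other_onscreen`, `n_off`,
#'   `p_target`, `attention`.
#' @export
summarize_trials <- function(dataset, window = c(368, 3505)) {
  stopifnot(inherits(dataset, "lwl_dataset"))
  gaze <- dataset$gaze
  if (!("label" %in% names(gaze))) {
    gaze$label <- classify_sample(gaze$x, gaze$y, gaze$valid)
  }
  if (nrow(gaze) == 0) stop("empty-trial error: no gaze samples", call. = FALSE)
  design <- dataset$design[c("participant_id", "trial_id", "pair_id",
                             "target_side", "target_onset_ms")]
  g <- dplyr::inner_join(gaze, design, by = c("participant_id", "trial_id"))
  rel <- g$t_ms - g$target_onset_ms
  in_win <- rel >= window[1] & rel < window[2]
  is_target <- (g$label == "LEFT_AOI" & g$target_side == "LEFT") |
    (g$label == "RIGHT_AOI" & g$target_side == "RIGHT")
  is_distr <- (g$label %in% c("LEFT_AOI", "RIGHT_AOI")) & !is_target
  in_trial <- g$t_ms >= 0 & g$t_ms < 7000

  g |>
    dplyr::mutate(in_win = in_win, is_target = is_target, is_distr = is_distr,
                  in_trial = in_trial) |>
    dplyr::summarise(
      n_target = sum(.data$in_win & .data$is_target),
      n_distractor = sum(.data$in_win & .data$is_distr),
      n_other_onscreen = sum(.data$in_win & .data$label == "ONSCREEN_OTHER"),
      n_off = sum(.data$in_win & .data$label == "OFFSCREEN_OR_INVALID"),
      attention = sum(.data$in_trial & .data$label != "OFFSCREEN_OR_INVALID") /
        sum(.data$in_trial),
      .by = c("participant_id", "trial_id", "pair_id")
    ) |>
    dplyr::mutate(p_target = ifelse(.data$n_target + .data$n_distractor > 0,
                                    .data$n_target / (.data$n_target + .data$n_distractor),
                                    NA_real_))
}

#' Discard inattentive and degenerate trials
#'
#' Retains trials whose attention ratio is at least `min_attention` (the
#' filter is a strict "less than", so exactly 12.5 percent is kept) and
#' whose `p_target` is defined. Every exclusion is logged with a reason.
#'
#' @param summaries Output of [summarize_trials()].
#' @param min_attention Minimum share of on-screen looking (default 0.125).
#' @return List with `summaries` (retained rows) and `log` (tibble
#'   `participant_id`, `trial_id`, `reason`).
#' @export
filter_trials <- function(summaries, min_attention = 0.125) {
  low <- summaries$attention < min_attention
  no_aoi <- !low & is.na(summaries$p_target)
  log <- dplyr::bind_rows(
    summaries[low, c("participant_id", "trial_id")] |>
      dplyr::mutate(reason = sprintf("attention below %g", min_attention)),
    summaries[no_aoi, c("participant_id", "trial_id")] |>
      dplyr::mutate(reason = "no AOI looks in window")
  )
  list(summaries = summaries[!low & !no_aoi, , drop = FALSE], log = log)
}

#' Exclude infants contributing too few yoked pairs
#'
#' Infants providing a computable proportion index for fewer than
#' `min_pairs` of the stimulus pairs are removed ("fewer than 4" excluded,
#' exactly 4 retained).
#'
#' @param pair_pis Output of [compute_pair_pis()].
#' @param min_pairs Minimum number of computable pairs (default 4).
#' @return List with `pair_pis` (retained rows) and `log` (tibble
#'   `participant_id`, `n_pairs`, `reason`).
#' @export
filter_infants <- function(pair_pis, min_pairs = 4) {
  counts <- dplyr::count(pair_pis, .data$participant_id, name = "n_pairs")
  drop <- counts[counts$n_pairs < min_pairs, , drop = FALSE]
  log <- dplyr::mutate(drop, reason = sprintf("fewer than %d computable pairs", min_pairs))
  list(pair_pis = pair_pis[!(pair_pis$participant_id %in% drop$participant_id), ,
                           drop = FALSE],
       log = log)
}

#' Drop pairs containing words the infant "rarely" hears
#'
#' Per infant, removes every stimulus pair for which the parent rated either
#' word's exposure as 1 ("rarely"). Pairs with a missing rating are retained
#' and logged with a warning.
#'
#' @param dataset An [lwl_dataset()] with a questionnaire.
#' @return List with `dataset` (design and gaze rows of dropped pairs
#'   removed) and `log` (tibble `participant_id`, `pair_id`, `reason`).
#' @export
exclude_rare_pairs <- function(dataset) {
  stopifnot(inherits(dataset, "lwl_dataset"))
  if (is.null(dataset$questionnaire)) {
    stop("exclude_rare_pairs needs a questionnaire", call. = FALSE)
  }
  q <- dataset$questionnaire[c("participant_id", "word", "exposure")]
  pp <- tidyr::expand_grid(participant_id = unique(dataset$design$participant_id),
                           dataset$pairs[c("pair_id", "word_a", "word_b")])
  pp <- pp |>
    dplyr::left_join(q, by = c(participant_id = "participant_id", word_a = "word")) |>
    dplyr::rename(exp_a = "exposure") |>
    dplyr::left_join(q, by = c(participant_id = "participant_id", word_b = "word")) |>
    dplyr::rename(exp_b = "exposure")
  missing <- is.na(pp$exp_a) | is.na(pp$exp_b)
  if (any(missing)) {
    warning(sum(missing), " participant-pair(s) lack an exposure rating; retained")
  }
  rare <- !missing & (pp$exp_a == 1 | pp$exp_b == 1)
  log <- pp[rare, c("participant_id", "pair_id")] |>
    dplyr::mutate(reason = "word rated 'rarely' (exposure = 1)")

  key <- function(p, pr) paste(p, pr, sep = "\r")
  drop_design <- key(dataset$design$participant_id, dataset$design$pair_id) %in%
    key(log$participant_id, log$pair_id)
  dropped_trials <- dataset$design[drop_design, c("participant_id", "trial_id")]
  keep_gaze <- !(paste(dataset$gaze$participant_id, dataset$gaze$trial_id, sep = "\r") %in%
                   paste(dropped_trials$participant_id, dropped_trials$trial_id, sep = "\r"))
  out <- dataset
  out$design <- dataset$design[!drop_design, , drop = FALSE]
  out$gaze <- dataset$gaze[keep_gaze, , drop = FALSE]
  list(dataset = out, log = log)
}
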