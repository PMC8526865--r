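# Proportion-index statistics and word-frequency-imbalance measures.

#' Proportion index of one yoked pair
#'
#' `pi = p1 + p2 - 1`, where `p1` and `p2` are the target-looking
#' proportions of the pair's two trials (each word named once). Because the
#' denominator is AOI looks only, anchoring the index on either image of the
#' pair gives the same value: looking at image A when it is named minus
#' looking at A when it is the distractor equals `p1 - (1 - p2)`.
#'
#' @param p1,p2 Target-looking proportions of the two trials, in \[0, 1\].
#' @return Proportion index in \[-1, 1\].
#' @export
pair_pi <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1, na.rm = TRUE),
            all(p2 >= 0 & p2 <= 1, na.rm = TRUE))
  p1 + p2 - 1
}

#' Proportion indices for all yoked pairs of a dataset
#'
#' A pair yields an index only when both of its trials survived filtering
#' with a defined `p_target`; pairs with a single surviving trial are
#' skipped and logged.
#'
#' @param summaries Retained trial summaries (see [filter_trials()]).
#' @return List with `pair_pis` (tibble `participant_id`, `pair_id`, `p1`,
#'   `p2`, `pi`) and `log` of skipped pairs.
#' @export
compute_pair_pis <- function(summaries) {
  grouped <- summaries |>
    dplyr::filter(!is.na(.data$p_target)) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     p1 = dplyr::first(.data$p_target),
                     p2 = dplyr::last(.data$p_target),
                     .by = c("participant_id", "pair_id"))
  incomplete <- grouped$n_trials != 2
  log <- grouped[incomplete, c("participant_id", "pair_id")] |>
    dplyr::mutate(reason = "only one valid trial for this pair")
  pair_pis <- grouped[!incomplete, , drop = FALSE] |>
    dplyr::mutate(pi = pair_pi(.data$p1, .data$p2)) |>
    dplyr::select("participant_id", "pair_id", "p1", "p2", "pi")
  list(pair_pis = pair_pis, log = log)
}

#' Mean proportion index per infant
#'
#' Unweighted arithmetic mean of an infant's pair indices.
#'
#' @param pair_pis Tibble from [compute_pair_pis()].
#' @return Tibble `participant_id`, `pi_mean`, `n_pairs`.
#' @export
pi_by_infant <- function(pair_pis) {
  pair_pis |>
    dplyr::summarise(pi_mean = mean(.data$pi), n_pairs = dplyr::n(),
                     .by = "participant_id")
}

#' Mean proportion index per stimulus pair
#'
#' Unweighted arithmetic mean over the infants contributing the pair.
#'
#' @param pair_pis Tibble from [compute_pair_pis()].
#' @return Tibble `pair_id`, `pi_mean`, `n_infants`.
#' @export
pi_by_item <- function(pair_pis) {
  pair_pis |>
    dplyr::summarise(pi_mean = mean(.data$pi), n_infants = dplyr::n(),
                     .by = "pair_id")
}

#' Count target words reported as understood
#'
#' A word counts as understood when its questionnaire status is
#' `UNDERSTANDS` or `UNDERSTANDS_AND_SPEAKS`; missing words count as not
#' understood.
#'
#' @param questionnaire Questionnaire table.
#' @param target_words Optional character vector restricting the count to
#'   the experiment's target words.
#' @return Tibble `participant_id`, `n_understood`.
#' @export
count_understood <- function(questionnaire, target_words = NULL) {
  q <- questionnaire
  if (!is.null(target_words)) q <- q[q$word %in% target_words, , drop = FALSE]
  q |>
    dplyr::summarise(
      n_understood = sum(.data$status %in% c("UNDERSTANDS", "UNDERSTANDS_AND_SPEAKS")),
      .by = "participant_id")
}

#' Mean parental exposure rating of one word
#'
#' Arithmetic mean of the 1-5 Likert exposure ratings over all responding
#' parents.
#'
#' @param questionnaire Questionnaire table.
#' @param word Orthographic word form.
#' @return Mean rating (scalar).
#' @export
word_mean_rating <- function(questionnaire, word) {
  ratings <- questionnaire$exposure[questionnaire$word == word &
                                      !is.na(questionnaire$exposure)]
  if (!length(ratings)) stop("no ratings for word: ", word, call. = FALSE)
  mean(ratings)
}

#' Frequency imbalance of a pair from mean ratings
#'
#' @param mean_a,mean_b Mean exposure ratings of the two words (1-5 scale).
#' @return `|mean_a - mean_b|` in Likert points.
#' @export
pair_imbalance <- function(mean_a, mean_b) abs(mean_a - mean_b)

#' Parental frequency imbalance for every stimulus pair
#'
#' @param questionnaire Questionnaire table.
#' @param pairs Stimulus-pair table (`pair_id`, `word_a`, `word_b`).
#' @return Tibble `pair_id`, `word_a`, `word_b`, `mean_a`, `mean_b`,
#'   `imbalance`.
#' @export
pair_imbalances <- function(questionnaire, pairs) {
  pairs |>
    dplyr::rowwise() |>
    dplyr::mutate(mean_a = word_mean_rating(questionnaire, .data$word_a),
                  mean_b = word_mean_rating(questionnaire, .data$word_b),
                  imbalance = pair_imbalance(.data$mean_a, .data$mean_b)) |>
    dplyr::ungroup() |>
    dplyr::select("pair_id", "word_a", "word_b", "mean_a", "mean_b", "imbalance")
}

#' Corpus frequency imbalance of a pair
#'
#' @param counts Named vector of corpus token counts (see
#'   [childes_word_counts()]).
#' @param word_a,word_b The pair's words.
#' @return `|count_a - count_b|` in tokens.
#' @export
pair_childes_imbalance <- function(counts, word_a, word_b) {
  if (is.na(counts[word_a]) || is.na(counts[word_b])) {
    stop("missing corpus count for pair (", word_a, ", ", word_b, ")", call. = FALSE)
  }
  unname(abs(counts[word_a] - counts[word_b]))
}
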