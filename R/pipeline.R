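# End-to-end orchestration: simulate/load -> preprocess -> proportion
# indices -> inference -> cluster permutation -> result tables and a
# plain-text summary.

#' Pipeline run configuration
#'
#' Defaults mirror the reference LWL analysis: window of interest 368-3,505
#' ms after target-word onset, trials kept at >= 12.5 percent on-screen
#' looking, infants kept at >= 4 computable pairs, 50 ms bins, cluster
#' threshold 2.02 with 1,000 resamples, Cauchy prior scale sqrt(2)/2 and
#' stretched-beta scale 1/3.
#'
#' @param simulate A [sim_config()] to generate the input data, or `NULL`
#'   when `paths` is given.
#' @param paths Named list of file paths for [load_dataset()] (`gaze`,
#'   `design`, and optionally `questionnaire`, `participants`, `pairs`).
#' @param window Window of interest (ms after target onset).
#' @param min_attention Trial filter threshold.
#' @param min_pairs Infant filter threshold.
#' @param rare_word_exclusion Drop, per infant, pairs containing a word
#'   rated "rarely" (exposure 1) before analysis.
#' @param bin_ms,threshold,n_resamples Cluster permutation settings.
#' @param conf Confidence level for the signed-rank intervals.
#' @param r_scale,kappa Bayes-factor prior scales.
#' @param seed Master seed for every stochastic step.
#' @return List of class `lwl_run_config`.
#' @export
lwl_config <- function(simulate = NULL, paths = NULL,
                       window = c(368, 3505), min_attention = 0.125,
                       min_pairs = 4, rare_word_exclusion = FALSE,
                       bin_ms = 50, threshold = 2.02, n_resamples = 1000,
                       conf = 0.95, r_scale = sqrt(2) / 2, kappa = 1 / 3,
                       seed = 1L) {
  if (is.null(simulate) && is.null(paths)) {
    stop("either a simulate block or input paths must be given", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "lwl_run_config"
  cfg
}

.fmt_wilcoxon_line <- function(label, w, d, bf) {
  sprintf("%s: V = %.2f, %d%% CI [%.3f, %.3f], p = %.3g, d = %.3g, BF01 = %.3g (%s)",
          label, w$V, round(100 * w$conf), w$ci_low, w$ci_high, w$p, d,
          bf$bf01, bf$evidence_label)
}

.fmt_cor_line <- function(label, ct, bf) {
  sprintf("%s: r(%d) = %.3f, p = %.3g, BF01 = %.3g (%s)",
          label, ct$df, ct$r, ct$p, bf$bf01, bf$evidence_label)
}

.wilcoxon_block <- function(values, conf, r_scale) {
  w <- wilcoxon_signed_rank(values, conf = conf)
  d <- cohens_d_one_sample(values)
  bf <- bf01_ttest(values, r_scale = r_scale)
  list(w = w, d = d, bf = bf)
}

.cor_block <- function(x, y, alternative, kappa) {
  ct <- pearson_r(x, y, alternative)
  dir <- switch(alternative, greater = "POSITIVE", less = "NEGATIVE", "TWO_SIDED")
  bf <- bf01_correlation(ct$r, ct$n, kappa = kappa, direction = dir)
  list(ct = ct, bf = bf)
}

#' Run the full LWL analysis pipeline
#'
#' Executes load/simulate, preprocessing with the trial and infant filters,
#' proportion indices at both aggregation levels, the inferential battery
#' (signed-rank tests with effect sizes and Bayes factors overall and per
#' age group, Kruskal-Wallis across groups, age/vocabulary/imbalance
#' correlations), and the cluster permutation analysis overall and per age
#' group. All result tables, exclusion logs and a plain-text summary are
#' returned and optionally written to `out_dir`.
#'
#' @param config An [lwl_config()].
#' @param out_dir Optional output directory for the result tables
#'   (`*.tsv`) and `summary.txt`.
#' @param chat_documents Optional CHAT transcripts for corpus word counts
#'   (paths or document strings).
#' @return List of class `lwl_run` with elements `dataset`, `pair_pis`,
#'   `pi_infant`, `pi_item`, `imbalance`, `tests`, `clusters`, `logs`,
#'   `summary` (character vector of report lines).
#' @export
run_pipeline <- function(config, out_dir = NULL, chat_documents = NULL) {
  stopifnot(inherits(config, "lwl_run_config"))
  dataset <- if (!is.null(config$simulate)) {
    simulate_dataset(config$simulate)
  } else {
    do.call(load_dataset, list(
      gaze_path = config$paths$gaze, design_path = config$paths$design,
      questionnaire_path = config$paths$questionnaire,
      participants_path = config$paths$participants,
      pairs_path = config$paths$pairs))
  }
  logs <- list()

  if (isTRUE(config$rare_word_exclusion)) {
    rare <- exclude_rare_pairs(dataset)
    dataset <- rare$dataset
    logs$rare_pairs <- rare$log
  }

  summaries <- summarize_trials(dataset, window = config$window)
  trial_filter <- filter_trials(summaries, min_attention = config$min_attention)
  logs$trials <- trial_filter$log

  pis <- compute_pair_pis(trial_filter$summaries)
  logs$pairs <- pis$log
  infant_filter <- filter_infants(pis$pair_pis, min_pairs = config$min_pairs)
  logs$infants <- infant_filter$log
  pair_pis <- infant_filter$pair_pis

  pi_infant <- pi_by_infant(pair_pis) |>
    dplyr::left_join(dataset$participants, by = "participant_id")
  pi_item <- pi_by_item(pair_pis)

  tests <- list()
  s <- character(0)
  s <- c(s, "Looking-while-listening analysis report", "")
  s <- c(s, sprintf("Infants analysed: %d (excluded: %d); pairs: %d",
                    nrow(pi_infant), nrow(logs$infants), nrow(dataset$pairs)))

  tests$pi_infant_overall <- .wilcoxon_block(pi_infant$pi_mean, config$conf,
                                             config$r_scale)
  s <- c(s, .fmt_wilcoxon_line("PI-by-infant vs 0",
                               tests$pi_infant_overall$w,
                               tests$pi_infant_overall$d,
                               tests$pi_infant_overall$bf))
  tests$pi_item_overall <- .wilcoxon_block(pi_item$pi_mean, config$conf,
                                           config$r_scale)
  s <- c(s, .fmt_wilcoxon_line("PI-by-item vs 0",
                               tests$pi_item_overall$w,
                               tests$pi_item_overall$d,
                               tests$pi_item_overall$bf))

  groups <- split(pi_infant$pi_mean, pi_infant$age_group)
  if (length(groups) >= 2 && all(lengths(groups) >= 2)) {
    tests$kw_infant <- kruskal_wallis(groups)
    s <- c(s, sprintf("PI-by-infant across age groups: chi-squared(%d, N = %d) = %.2f, p = %.3g",
                      tests$kw_infant$df, tests$kw_infant$n,
                      tests$kw_infant$H, tests$kw_infant$p))
    item_by_group <- lapply(names(groups), function(gname) {
      ids <- pi_infant$participant_id[pi_infant$age_group == gname]
      pi_by_item(pair_pis[pair_pis$participant_id %in% ids, ])$pi_mean
    })
    if (all(lengths(item_by_group) >= 2)) {
      tests$kw_item <- kruskal_wallis(item_by_group)
      s <- c(s, sprintf("PI-by-item across age groups: chi-squared(%d) = %.2f, p = %.3g",
                        tests$kw_item$df, tests$kw_item$H, tests$kw_item$p))
    }
    for (gname in names(groups)) {
      if (length(groups[[gname]]) >= 4) {
        blk <- .wilcoxon_block(groups[[gname]], config$conf, config$r_scale)
        tests[[paste0("pi_infant_", gname)]] <- blk
        s <- c(s, .fmt_wilcoxon_line(sprintf("  PI-by-infant (%s) vs 0", gname),
                                     blk$w, blk$d, blk$bf))
      }
    }
  }

  tests$age_vs_pi <- .cor_block(pi_infant$age_days, pi_infant$pi_mean,
                                "two.sided", config$kappa)
  s <- c(s, .fmt_cor_line("Age (days) vs PI-by-infant",
                          tests$age_vs_pi$ct, tests$age_vs_pi$bf))

  if (!is.null(dataset$questionnaire)) {
    target_words <- c(dataset$pairs$word_a, dataset$pairs$word_b)
    understood <- count_understood(dataset$questionnaire, target_words)
    voc <- dplyr::inner_join(pi_infant, understood, by = "participant_id")
    s <- c(s, sprintf("Words understood: mean %.2f of %d (SD %.2f)",
                      mean(understood$n_understood), length(target_words),
                      sd(understood$n_understood)))
    tests$understood_vs_pi <- .cor_block(voc$n_understood, voc$pi_mean,
                                         "two.sided", config$kappa)
    s <- c(s, .fmt_cor_line("Understood words vs PI-by-infant",
                            tests$understood_vs_pi$ct, tests$understood_vs_pi$bf))
    voc_age <- dplyr::inner_join(dataset$participants, understood,
                                 by = "participant_id")
    tests$understood_vs_age <- .cor_block(voc_age$age_days, voc_age$n_understood,
                                          "two.sided", config$kappa)
    s <- c(s, .fmt_cor_line("Age (days) vs understood words",
                            tests$understood_vs_age$ct, tests$understood_vs_age$bf))

    imbalance <- pair_imbalances(dataset$questionnaire, dataset$pairs)
    imb_item <- dplyr::inner_join(imbalance, pi_item, by = "pair_id")
    s <- c(s, sprintf("Parental frequency imbalance: mean %.2f Likert points (SD %.2f)",
                      mean(imbalance$imbalance), sd(imbalance$imbalance)))
    tests$imbalance_vs_pi_item <- .cor_block(imb_item$imbalance, imb_item$pi_mean,
                                             "greater", config$kappa)
    s <- c(s, .fmt_cor_line("Frequency imbalance vs PI-by-item (rho > 0)",
                            tests$imbalance_vs_pi_item$ct,
                            tests$imbalance_vs_pi_item$bf))
  } else {
    imbalance <- NULL
  }

  if (!is.null(chat_documents)) {
    target_words <- c(dataset$pairs$word_a, dataset$pairs$word_b)
    counts <- childes_word_counts(chat_documents, target_words)
    imbalance$childes_count_a <- counts[imbalance$word_a]
    imbalance$childes_count_b <- counts[imbalance$word_b]
    imbalance$childes_imbalance <- abs(imbalance$childes_count_a -
                                         imbalance$childes_count_b)
    imb_item <- dplyr::inner_join(imbalance, pi_item, by = "pair_id")
    tests$childes_vs_pi_item <- .cor_block(imb_item$childes_imbalance,
                                           imb_item$pi_mean, "greater",
                                           config$kappa)
    s <- c(s, .fmt_cor_line("Corpus frequency imbalance vs PI-by-item (rho > 0)",
                            tests$childes_vs_pi_item$ct,
                            tests$childes_vs_pi_item$bf))
  }

  clusters <- list()
  clusters$overall <- cluster_permutation(
    dataset, trial_filter$summaries, bin_ms = config$bin_ms,
    threshold = config$threshold, n_resamples = config$n_resamples,
    seed = config$seed)
  s <- c(s, "", sprintf("Cluster permutation (whole sample, %d resamples, threshold %.2f):",
                        config$n_resamples, config$threshold))
  s <- c(s, .cluster_lines(clusters$overall))
  for (gname in unique(dataset$participants$age_group)) {
    ids <- dataset$participants$participant_id[
      dataset$participants$age_group == gname]
    retained_g <- trial_filter$summaries[
      trial_filter$summaries$participant_id %in% ids, ]
    if (length(unique(retained_g$participant_id)) >= 2) {
      clusters[[gname]] <- cluster_permutation(
        dataset, retained_g, bin_ms = config$bin_ms,
        threshold = config$threshold, n_resamples = config$n_resamples,
        seed = config$seed)
      s <- c(s, sprintf("Cluster permutation (%s):", gname))
      s <- c(s, .cluster_lines(clusters[[gname]]))
    }
  }

  run <- structure(list(dataset = dataset, pair_pis = pair_pis,
                        pi_infant = pi_infant, pi_item = pi_item,
                        imbalance = imbalance, tests = tests,
                        clusters = clusters, logs = logs, summary = s,
                        config = config),
                   class = "lwl_run")

  if (!is.null(out_dir)) {
    tables <- list(
      pair_pis = pair_pis,
      pi_by_infant = pi_infant[c("participant_id", "pi_mean", "n_pairs",
                                 "age_days", "age_group")],
      pi_by_item = pi_item,
      clusters_overall = clusters$overall$clusters,
      excluded_trials = logs$trials,
      excluded_infants = logs$infants
    )
    if (!is.null(imbalance)) tables$pair_imbalance <- imbalance
    write_results(tables, out_dir)
    writeLines(s, file.path(out_dir, "summary.txt"))
  }
  run
}

.cluster_lines <- function(cl) {
  if (!nrow(cl$clusters)) return("  no supra-threshold clusters")
  vapply(seq_len(nrow(cl$clusters)), function(i) {
    x <- cl$clusters[i, ]
    sprintf("  %s cluster %g-%g ms, mass %.2f, p = %.3f%s",
            tolower(x$sign), x$start_ms, x$end_ms, x$mass, x$p,
            if (x$p < 0.05) " *" else "")
  }, character(1))
}

#' @export
print.lwl_run <- function(x, ...) {
  writeLines(x$summary)
  invisible(x)
}
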