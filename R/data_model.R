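#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats dt dcauchy dnorm integrate median rnorm runif sd setNames
#' @importFrom utils head
NULL

GAZE_LABELS <- c("LEFT_AOI", "RIGHT_AOI", "ONSCREEN_OTHER", "OFFSCREEN_OR_INVALID")

# required columns per table; extra columns are preserved on load
.schemas <- list(
  gaze          = c("participant_id", "trial_id", "t_ms"),
  design        = c("participant_id", "trial_id", "pair_id", "target_word",
                    "target_side", "target_onset_ms", "half"),
  questionnaire = c("participant_id", "word", "status", "exposure"),
  participants  = c("participant_id", "age_days"),
  pairs         = c("pair_id", "word_a", "word_b")
)

#' Assign infants to age groups
#'
#' Age in months is computed as `age_days / 30` (30-day months). Groups are
#' `G6_7` (< 8 months), `G8_10` (8 to < 11 months) and `G11_14` (>= 11 months).
#'
#' @param age_days Integer vector of ages in days.
#' @return Character vector of group labels.
#' @export
age_group <- function(age_days) {
  m <- age_days / 30
  dplyr::case_when(m < 8 ~ "G6_7", m < 11 ~ "G8_10", TRUE ~ "G11_14")
}

#' Construct a validated LWL dataset
#'
#' Bundles the five tidy tables of an LWL experiment (gaze samples, trial
#' design, yoked stimulus pairs, participants, vocabulary questionnaire) and
#' checks referential integrity: every gaze row must point at a designed
#' trial, every designed trial at a known pair and participant.
#'
#' @param gaze Tibble with `participant_id`, `trial_id`, `t_ms` and either a
#'   `label` column (one of `LEFT_AOI`, `RIGHT_AOI`, `ONSCREEN_OTHER`,
#'   `OFFSCREEN_OR_INVALID`) or raw `x`, `y`, `valid` columns to be
#'   classified later with [classify_sample()].
#' @param design Tibble with `participant_id`, `trial_id`, `pair_id`,
#'   `target_word`, `target_side` (`LEFT`/`RIGHT`), `target_onset_ms`, `half`.
#' @param pairs Tibble with `pair_id`, `word_a`, `word_b`. If `NULL`, it is
#'   reconstructed from the design table.
#' @param participants Tibble with `participant_id`, `age_days`.
#' @param questionnaire Tibble with `participant_id`, `word`, `status`
#'   (`UNDERSTANDS`, `UNDERSTANDS_AND_SPEAKS`, `DOES_NOT_UNDERSTAND`) and
#'   `exposure` (Likert 1-5), or `NULL`.
#' @return An object of class `lwl_dataset` (a named list of tibbles with
#'   `age_months` and `age_group` added to `participants`).
#' @export
lwl_dataset <- function(gaze, design, pairs = NULL, participants = NULL,
                        questionnaire = NULL) {
  gaze <- tibble::as_tibble(gaze)
  design <- tibble::as_tibble(design)
  .check_schema(gaze, "gaze")
  if (!("label" %in% names(gaze)) && !all(c("x", "y", "valid") %in% names(gaze))) {
    stop("gaze table needs either a 'label' column or raw 'x', 'y', 'valid' columns",
         call. = FALSE)
  }
  .check_schema(design, "design")
  if (!is.numeric(gaze$t_ms)) stop("gaze column 't_ms' must be numeric", call. = FALSE)
  if (any(gaze$t_ms < -1000 | gaze$t_ms > 7000)) {
    stop("gaze timestamps outside the trial span [-1000, 7000] ms", call. = FALSE)
  }
  if ("label" %in% names(gaze) && !all(gaze$label %in% GAZE_LABELS)) {
    bad <- setdiff(unique(gaze$label), GAZE_LABELS)
    stop("unknown gaze labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(design$target_side %in% c("LEFT", "RIGHT"))) {
    stop("design column 'target_side' must be LEFT or RIGHT", call. = FALSE)
  }

  if (is.null(pairs)) {
    pairs <- design |>
      dplyr::distinct(.data$pair_id, .data$target_word) |>
      dplyr::group_by(.data$pair_id) |>
      dplyr::summarise(word_a = min(.data$target_word),
                       word_b = max(.data$target_word), .groups = "drop")
  }
  pairs <- tibble::as_tibble(pairs)
  .check_schema(pairs, "pairs")
  if (any(pairs$word_a == pairs$word_b)) {
    stop("a stimulus pair must contain two distinct words", call. = FALSE)
  }

  if (is.null(participants)) {
    participants <- tibble::tibble(participant_id = unique(design$participant_id),
                                   age_days = NA_integer_)
  }
  participants <- tibble::as_tibble(participants)
  .check_schema(participants, "participants")
  participants$age_months <- participants$age_days / 30
  participants$age_group <- age_group(participants$age_days)

  if (!is.null(questionnaire)) {
    questionnaire <- tibble::as_tibble(questionnaire)
    .check_schema(questionnaire, "questionnaire")
    if (!all(is.na(questionnaire$exposure) | questionnaire$exposure %in% 1:5)) {
      stop("questionnaire 'exposure' ratings must lie on the 1-5 Likert scale",
           call. = FALSE)
    }
  }

  key <- function(p, t) paste(p, t, sep = "\r")
  orphan <- !(key(gaze$participant_id, gaze$trial_id) %in%
                key(design$participant_id, design$trial_id))
  if (any(orphan)) {
    stop("integrity error: gaze references unknown trial(s): ",
         paste(head(unique(gaze$trial_id[orphan]), 3), collapse = ", "),
         call. = FALSE)
  }
  if (!all(design$pair_id %in% pairs$pair_id)) {
    stop("integrity error: design references unknown pair_id", call. = FALSE)
  }
  if (!all(design$participant_id %in% participants$participant_id)) {
    stop("integrity error: design references unknown participant_id", call. = FALSE)
  }

  structure(list(gaze = gaze, design = design, pairs = pairs,
                 participants = participants, questionnaire = questionnaire),
            class = "lwl_dataset")
}

.check_schema <- function(tbl, what) {
  missing <- setdiff(.schemas[[what]], names(tbl))
  if (length(missing)) {
    stop(sprintf("schema error: %s table lacks column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.lwl_dataset <- function(x, ...) {
  cat("<lwl_dataset>\n")
  cat(sprintf("  %d participants, %d trials, %d gaze samples\n",
              nrow(x$participants), nrow(x$design), nrow(x$gaze)))
  cat(sprintf("  %d stimulus pairs; questionnaire: %s\n",
              nrow(x$pairs), if (is.null(x$questionnaire)) "absent" else
                sprintf("%d records", nrow(x$questionnaire))))
  invisible(x)
}

.read_table <- function(path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

#' Load an LWL dataset from delimited text tables
#'
#' Reads the tidy tables (TSV, or CSV when the file extension is `.csv`),
#' validates their schemas and referential integrity, and returns an
#' [lwl_dataset()]. Unknown extra columns are preserved.
#'
#' @param gaze_path,design_path Paths to the gaze and trial-design tables.
#' @param questionnaire_path,participants_path,pairs_path Optional paths to
#'   the questionnaire, participants and stimulus-pair tables.
#' @return An `lwl_dataset`.
#' @export
load_dataset <- function(gaze_path, design_path, questionnaire_path = NULL,
                         participants_path = NULL, pairs_path = NULL) {
  gaze <- .read_table(gaze_path)
  design <- .read_table(design_path)
  if ("t_ms" %in% names(gaze) && !is.numeric(gaze$t_ms)) {
    bad <- which(is.na(suppressWarnings(as.numeric(gaze$t_ms))))[1]
    stop(sprintf("parse error: non-numeric timestamp in gaze row %d", bad),
         call. = FALSE)
  }
  lwl_dataset(
    gaze = gaze, design = design,
    pairs = if (!is.null(pairs_path)) .read_table(pairs_path),
    participants = if (!is.null(participants_path)) .read_table(participants_path),
    questionnaire = if (!is.null(questionnaire_path)) .read_table(questionnaire_path)
  )
}

#' Write result tables as delimited text
#'
#' Writes one UTF-8 tab-separated file per table with a fixed column order and
#' full floating-point precision; output is byte-identical across runs for
#' identical inputs.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tables[[nm]], path, progress = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write a full dataset to a directory of delimited tables
#'
#' Companion of [load_dataset()]; `load_dataset()` on the written files
#' round-trips the dataset.
#'
#' @param dataset An `lwl_dataset`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "lwl_dataset"))
  tables <- dataset[!vapply(dataset, is.null, logical(1))]
  tables$participants <- tables$participants[
    setdiff(names(tables$participants), c("age_months", "age_group"))]
  write_results(tables, out_dir)
}
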