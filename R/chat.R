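# Minimal CHAT (.cha) transcript reading and word counting.
#
# Only the features needed for corpus word-frequency counting are parsed:
# the @ID header of the target child (for the age filter) and the main
# utterance tiers. No installed R package reads CHAT, so this small parser
# is part of the package; it handles the subset of CHAT that
# make_chat_fixture() emits plus ordinary CHILDES main tiers.

#' Parse a CHAT transcript
#'
#' Extracts the target child's age from its `@ID` header (field 4, in
#' `y;mm.dd` form) and the main speaker tiers (`*SPK:` lines, with
#' tab-indented continuation lines appended).
#'
#' @param x Path to a `.cha` file, or the document itself as a single
#'   string containing newlines.
#' @return List with `child_age_months` (numeric or NA) and `utterances`
#'   (tibble `speaker`, `text`).
#' @export
read_chat <- function(x) {
  lines <- if (length(x) == 1 && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(x, warn = FALSE)
  }

  age <- NA_real_
  for (ln in grep("^@ID:", lines, value = TRUE)) {
    fields <- strsplit(sub("^@ID:\\s*", "", ln), "|", fixed = TRUE)[[1]]
    if (length(fields) >= 4 && fields[3] == "CHI" && nzchar(fields[4])) {
      m <- regmatches(fields[4],
                      regexec("^(\\d+);(\\d+)(?:\\.(\\d+))?", fields[4]))[[1]]
      if (length(m) >= 3) {
        days <- if (length(m) >= 4 && nzchar(m[4])) as.numeric(m[4]) else 0
        age <- as.numeric(m[2]) * 12 + as.numeric(m[3]) + days / 30
      }
    }
  }

  speakers <- character(0)
  texts <- character(0)
  for (ln in lines) {
    if (grepl("^\\*", ln)) {
      colon <- regexpr(":", ln, fixed = TRUE)
      speakers <- c(speakers, substr(ln, 2, colon - 1))
      texts <- c(texts, trimws(substr(ln, colon + 1, nchar(ln))))
    } else if (grepl("^\\t", ln) && length(texts)) {
      texts[length(texts)] <- paste(texts[length(texts)], trimws(ln))
    }
  }
  list(child_age_months = age,
       utterances = tibble::tibble(speaker = speakers, text = texts))
}

.chat_tokens <- function(text) {
  tokens <- unlist(strsplit(tolower(text), "[^\\p{L}\\p{N}'-]+", perl = TRUE))
  tokens[nzchar(tokens)]
}

#' Count target-word tokens heard by young children in CHAT transcripts
#'
#' For every transcript whose target child is younger than
#' `max_age_months`, counts case-insensitive exact orthographic token
#' matches of each target word in the utterance tiers of all speakers
#' except the target child (the measure is how often the child *heard* the
#' word). Counts are summed over transcripts. Unparseable documents and
#' documents without a child age are skipped with a warning.
#'
#' @param chat_documents Character vector of file paths and/or document
#'   strings accepted by [read_chat()].
#' @param target_words Words in orthographic form.
#' @param max_age_months Corpus age cutoff (default 33 months).
#' @return Named numeric vector of token counts, one per target word.
#' @export
childes_word_counts <- function(chat_documents, target_words,
                                max_age_months = 33) {
  counts <- setNames(numeric(length(target_words)), target_words)
  targets <- tolower(target_words)
  for (doc in chat_documents) {
    parsed <- tryCatch(read_chat(doc), error = function(e) NULL)
    if (is.null(parsed)) {
      warning("skipping unparseable CHAT document")
      next
    }
    if (is.na(parsed$child_age_months)) {
      warning("skipping CHAT document without a child age")
      next
    }
    if (parsed$child_age_months >= max_age_months) next
    utt <- parsed$utterances[parsed$utterances$speaker != "CHI", , drop = FALSE]
    if (!nrow(utt)) next
    tokens <- .chat_tokens(paste(utt$text, collapse = " "))
    tab <- table(tokens[tokens %in% targets])
    idx <- match(names(tab), targets)
    counts[idx] <- counts[idx] + as.numeric(tab)
  }
  counts
}
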