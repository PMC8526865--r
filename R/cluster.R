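# Cluster-based permutation analysis of target looking against chance over
# the 0-7,000 ms trial time course.
#
# Testing "data vs a chance dataset fixed at 0.50" with paired t-tests is
# algebraically the one-sample t of the deviations y - asin(sqrt(0.5)),
# which is what is computed here. The permutation null flips the sign of
# each participant's entire deviation series (the standard exchangeability
# argument for a one-sample test against a constant), preserving temporal
# autocorrelation; a participant-resampling bootstrap mode is available as
# an alternative.

#' Binned target-looking proportions per participant
#'
#' Pools target and distractor AOI samples of the retained trials into
#' `bin_ms` bins tiling `[span[1], span[2])`, per participant. The
#' proportion uses the AOI denominator (`target / (target + distractor)`);
#' bins without AOI samples are missing, not zero. The arcsine-square-root
#' transform `y = asin(sqrt(p))` stabilises the variance of the proportion;
#' it maps chance (0.5) to pi/4.
#'
#' @param dataset An [lwl_dataset()].
#' @param retained Retained trial summaries (see [filter_trials()]); only
#'   their trials contribute. `NULL` uses all trials.
#' @param bin_ms Bin width (default 50 ms; 3 samples per bin per trial at
#'   60 Hz).
#' @param span Time range in ms relative to picture onset.
#' @return Tibble `participant_id`, `bin_start_ms`, `n_target`, `n_aoi`,
#'   `p_target`, `y`, `deviation` (y minus pi/4).
#' @export
bin_proportions <- function(dataset, retained = NULL, bin_ms = 50,
                            span = c(0, 7000)) {
  stopifnot(inherits(dataset, "lwl_dataset"))
  gaze <- dataset$gaze
  design <- dataset$design[c("participant_id", "trial_id", "target_side")]
  if (!is.null(retained)) {
    key <- function(p, t) paste(p, t, sep = "\r")
    keep <- key(gaze$participant_id, gaze$trial_id) %in%
      key(retained$participant_id, retained$trial_id)
    gaze <- gaze[keep, , drop = FALSE]
  }
  g <- dplyr::inner_join(gaze, design, by = c("participant_id", "trial_id"))
  g <- g[g$t_ms >= span[1] & g$t_ms < span[2] &
           g$label %in% c("LEFT_AOI", "RIGHT_AOI"), , drop = FALSE]
  g$bin_start_ms <- floor(g$t_ms / bin_ms) * bin_ms
  g$is_target <- (g$label == "LEFT_AOI") == (g$target_side == "LEFT")
  g |>
    dplyr::summarise(n_target = sum(.data$is_target), n_aoi = dplyr::n(),
                     .by = c("participant_id", "bin_start_ms")) |>
    dplyr::mutate(p_target = .data$n_target / .data$n_aoi,
                  y = asin(sqrt(.data$p_target)),
                  deviation = .data$y - asin(sqrt(0.5))) |>
    dplyr::arrange(.data$participant_id, .data$bin_start_ms)
}

# participant x bin deviation matrix (NA where a participant has no bin)
.deviation_matrix <- function(series, chance = 0.5) {
  dev <- series$y - asin(sqrt(chance))
  participants <- unique(series$participant_id)
  bins <- sort(unique(series$bin_start_ms))
  M <- matrix(NA_real_, length(participants), length(bins),
              dimnames = list(participants, bins))
  M[cbind(match(series$participant_id, participants),
          match(series$bin_start_ms, bins))] <- dev
  M
}

.t_from_matrix <- function(M0, W, nb, S2, s) {
  v <- as.vector(crossprod(M0, s))
  m <- v / nb
  va <- (S2 - v^2 / nb) / (nb - 1)
  tt <- m / sqrt(va / nb)
  tt[nb < 2 | va <= 1e-24] <- NA_real_
  unname(tt)
}

#' Per-bin one-sample t statistics against chance
#'
#' Across participants, per time bin, the one-sample t of the transformed
#' deviation `y - asin(sqrt(chance))`; df = participants in the bin minus
#' one. Bins with fewer than two participants, or zero variance, are
#' skipped (t = NA) with a warning for the zero-variance case.
#'
#' @param series Output of [bin_proportions()].
#' @param chance Chance proportion (default 0.5).
#' @return Tibble `bin_start_ms`, `t`, `df`, `n`.
#' @export
per_bin_t <- function(series, chance = 0.5) {
  M <- .deviation_matrix(series, chance)
  M0 <- ifelse(is.na(M), 0, M)
  W <- !is.na(M)
  nb <- colSums(W)
  S2 <- colSums(M0^2)
  tt <- .t_from_matrix(M0, W, nb, S2, rep(1, nrow(M)))
  v <- as.vector(crossprod(M0, rep(1, nrow(M))))
  zero_var <- nb >= 2 & (S2 - v^2 / nb) / (nb - 1) <= 1e-24
  if (any(zero_var)) {
    warning(sum(zero_var), " bin(s) with zero variance skipped")
  }
  tibble::tibble(bin_start_ms = as.numeric(colnames(M)), t = tt,
                 df = pmax(nb - 1, 0), n = nb)
}

#' Find supra-threshold clusters in a t series
#'
#' Maximal runs of adjacent bins with `t > threshold` (positive clusters)
#' or `t < -threshold` (negative clusters). Missing or skipped bins break
#' adjacency, as do gaps in the bin grid. The cluster mass is the sum of
#' the per-bin t statistics over the run.
#'
#' @param t_series Tibble with `bin_start_ms` and `t` (NA = skipped).
#' @param threshold Cluster-forming threshold on |t| (default 2.02).
#' @param bin_ms Bin width used to define adjacency (default 50).
#' @return Tibble `start_ms`, `end_ms`, `sign`, `mass`, `n_bins`.
#' @export
find_clusters <- function(t_series, threshold = 2.02, bin_ms = 50) {
  .scan_clusters(t_series$bin_start_ms, t_series$t, threshold, bin_ms)
}

.scan_clusters <- function(starts, tt, threshold, bin_ms) {
  code <- ifelse(is.na(tt), 0L, ifelse(tt > threshold, 1L,
                                       ifelse(tt < -threshold, -1L, 0L)))
  gap <- c(TRUE, diff(starts) != bin_ms)
  grp <- cumsum(gap | c(TRUE, diff(code) != 0L))
  keep <- code != 0L
  if (!any(keep)) {
    return(tibble::tibble(start_ms = numeric(0), end_ms = numeric(0),
                          sign = character(0), mass = numeric(0),
                          n_bins = integer(0)))
  }
  agg <- tapply(seq_along(tt)[keep], grp[keep], function(idx) {
    c(starts[idx[1]], starts[idx[length(idx)]] + bin_ms,
      sum(tt[idx]), length(idx))
  })
  m <- do.call(rbind, agg)
  dimnames(m) <- NULL
  tibble::tibble(start_ms = m[, 1], end_ms = m[, 2],
                 sign = ifelse(m[, 3] > 0, "POSITIVE", "NEGATIVE"),
                 mass = m[, 3], n_bins = as.integer(m[, 4]))
}

#' Permutation null distribution and cluster p-values
#'
#' Each resample multiplies every participant's whole deviation series by
#' an independent random sign (default), or draws participants with
#' replacement (`mode = "bootstrap"`), recomputes the per-bin t series and
#' its clusters, and records the maximum absolute cluster mass (0 when no
#' cluster forms). Each observed cluster's p-value is the fraction of
#' resamples whose maximum |mass| is at least the observed |mass|
#' (`p_mode = "raw"`, the default `b/B` convention; `"add_one"` uses
#' `(b+1)/(B+1)`). Clusters with `p < 0.05` are conventionally called
#' significant. The two-sided test uses this single max-|mass| null for
#' both signs.
#'
#' @param series Output of [bin_proportions()].
#' @param threshold Cluster-forming threshold (default 2.02).
#' @param n_resamples Number of resamples (default 1000).
#' @param seed Mandatory integer seed.
#' @param bin_ms Bin width (default 50).
#' @param chance Chance proportion (default 0.5).
#' @param mode `"signflip"` (default) or `"bootstrap"`.
#' @param p_mode `"raw"` or `"add_one"`.
#' @return List of class `lwl_clusters`: `clusters` (observed clusters with
#'   `p`), `t_series`, `null_max` (the resampled maxima), plus the settings.
#' @export
permutation_null <- function(series, threshold = 2.02, n_resamples = 1000,
                             seed, bin_ms = 50, chance = 0.5,
                             mode = c("signflip", "bootstrap"),
                             p_mode = c("raw", "add_one")) {
  mode <- match.arg(mode)
  p_mode <- match.arg(p_mode)
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory for reproducibility", call. = FALSE)
  }
  if (n_resamples < 1) stop("n_resamples must be >= 1", call. = FALSE)

  M <- .deviation_matrix(series, chance)
  M0 <- ifelse(is.na(M), 0, M)
  W <- !is.na(M)
  nP <- nrow(M)
  starts <- as.numeric(colnames(M))

  t_obs <- .t_from_matrix(M0, W, colSums(W), colSums(M0^2), rep(1, nP))
  t_series <- tibble::tibble(bin_start_ms = starts, t = t_obs)
  clusters <- .scan_clusters(starts, t_obs, threshold, bin_ms)

  null_max <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_resamples), function(b) {
      if (mode == "signflip") {
        s <- sample(c(-1, 1), nP, replace = TRUE)
        Mb <- M0; Wb <- W
        tt <- .t_from_matrix(Mb, Wb, colSums(Wb), colSums(Mb^2), s)
      } else {
        idx <- sample.int(nP, nP, replace = TRUE)
        Mb <- M0[idx, , drop = FALSE]
        # bootstrap tests deviation of the resampled mean from the observed
        # grand mean rather than from zero
        ctr <- colSums(M0) / pmax(colSums(W), 1)
        Mb <- sweep(Mb, 2, ctr)
        Mb[!W[idx, , drop = FALSE]] <- 0
        Wb <- W[idx, , drop = FALSE]
        tt <- .t_from_matrix(Mb, Wb, colSums(Wb), colSums(Mb^2), rep(1, nP))
      }
      cl <- .scan_clusters(starts, tt, threshold, bin_ms)
      if (nrow(cl)) max(abs(cl$mass)) else 0
    }, numeric(1))
  })

  if (nrow(clusters)) {
    hits <- vapply(abs(clusters$mass),
                   function(m) sum(null_max >= m), numeric(1))
    clusters$p <- if (p_mode == "raw") hits / n_resamples else
      (hits + 1) / (n_resamples + 1)
  } else {
    clusters$p <- numeric(0)
  }

  structure(list(clusters = clusters, t_series = t_series,
                 null_max = null_max, threshold = threshold,
                 n_resamples = n_resamples, seed = seed, bin_ms = bin_ms,
                 mode = mode, p_mode = p_mode),
            class = "lwl_clusters")
}

#' @export
print.lwl_clusters <- function(x, ...) {
  cat(sprintf("Cluster permutation (%s, %d resamples, threshold %.2f):\n",
              x$mode, x$n_resamples, x$threshold))
  if (!nrow(x$clusters)) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      cat(sprintf("  %s cluster %g-%g ms, mass %.2f, p = %.3f\n",
                  tolower(cl$sign), cl$start_ms, cl$end_ms, cl$mass, cl$p))
    }
  }
  invisible(x)
}

#' Full cluster permutation analysis of a preprocessed dataset
#'
#' Convenience wrapper: [bin_proportions()] on the retained trials, then
#' [permutation_null()].
#'
#' @inheritParams bin_proportions
#' @inheritParams permutation_null
#' @return An `lwl_clusters` object.
#' @export
cluster_permutation <- function(dataset, retained = NULL, bin_ms = 50,
                                span = c(0, 7000), threshold = 2.02,
                                n_resamples = 1000, seed,
                                mode = c("signflip", "bootstrap"),
                                p_mode = c("raw", "add_one")) {
  series <- bin_proportions(dataset, retained, bin_ms, span)
  permutation_null(series, threshold = threshold, n_resamples = n_resamples,
                   seed = seed, bin_ms = bin_ms, mode = match.arg(mode),
                   p_mode = match.arg(p_mode))
}
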