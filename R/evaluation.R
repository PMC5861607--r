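#' Match predicted steps against annotated swing phases
#'
#' A prediction is a true positive when it lies inside an annotated
#' swing-phase interval (final contact to next initial contact). Matching
#' is one-to-one and greedy: each annotation takes the earliest unused
#' prediction inside its interval. Predictions left unmatched - whether
#' outside every interval or surplus within one - are false positives;
#' unmatched annotations are false negatives.
#'
#' @param predicted_times Numeric vector of predicted step times (s),
#'   sorted, on the same clock as the annotations.
#' @param annotations An [annotation_set()].
#' @return An object of class `detection_report` with fields `tp`, `fp`,
#'   `fn`, `ppv` (`NA` when no predictions were made) and
#'   `detection_rate`.
#' @export
match_steps <- function(predicted_times, annotations) {
  if (is.unsorted(predicted_times)) {
    stop("`predicted_times` must be sorted", call. = FALSE)
  }
  n_pred <- length(predicted_times)
  n_ann <- nrow(annotations)
  used <- logical(n_pred)
  tp <- 0L
  for (a in seq_len(n_ann)) {
    hit <- which(!used & predicted_times >= annotations$start_s[a] &
                   predicted_times <= annotations$end_s[a])
    if (length(hit) > 0L) {
      used[hit[1L]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- n_pred - tp
  fn <- n_ann - tp
  structure(list(tp = tp, fp = fp, fn = fn,
                 ppv = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
                 detection_rate = if (n_ann == 0L) NA_real_ else tp / n_ann),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> TP %d, FP %d, FN %d | PPV %s, detection rate %s\n",
    x$tp, x$fp, x$fn,
    ifelse(is.na(x$ppv), "undefined", sprintf("%.3f", x$ppv)),
    ifelse(is.na(x$detection_rate), "undefined",
           sprintf("%.3f", x$detection_rate))))
  invisible(x)
}

#' @export
glance.detection_report <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, ppv = x$ppv,
                 detection_rate = x$detection_rate)
}

#' Bland-Altman agreement between two paired series
#'
#' Differences are taken as `a - b`; the critical difference is 1.96 times
#' the sample standard deviation of the differences, and the limits of
#' agreement are the mean difference plus/minus the critical difference.
#' The product-moment correlation of the two series is reported alongside.
#'
#' @param a,b Equal-length numeric vectors, length >= 2.
#' @return An object of class `agreement_stats` with fields `mean_diff`,
#'   `sd_diff`, `critical_difference`, `loa_lower`, `loa_upper`,
#'   `pearson_r`, `n`, and the input series (for plotting).
#' @examples
#' fx <- study_fixtures()
#' bland_altman(fx$table1$steps_video, fx$table1$steps_algorithm)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  sd_d <- stats::sd(d)
  r <- if (length(a) >= 3L && stats::sd(a) > 0 && stats::sd(b) > 0) {
    stats::cor(a, b)
  } else {
    NA_real_
  }
  structure(list(mean_diff = mean(d), sd_diff = sd_d,
                 critical_difference = 1.96 * sd_d,
                 loa_lower = mean(d) - 1.96 * sd_d,
                 loa_upper = mean(d) + 1.96 * sd_d,
                 pearson_r = r, n = length(a), a = a, b = b),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> n = %d | mean diff %.3g, critical difference %.3g (LoA %.3g to %.3g), r = %.3f\n",
    x$n, x$mean_diff, x$critical_difference, x$loa_lower, x$loa_upper,
    x$pearson_r))
  invisible(x)
}

#' @export
glance.agreement_stats <- function(x, ...) {
  tibble::tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 critical_difference = x$critical_difference,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 pearson_r = x$pearson_r)
}

#' @export
tidy.agreement_stats <- function(x, ...) {
  tibble::tibble(mean = (x$a + x$b) / 2, diff = x$a - x$b)
}

#' Bland-Altman scatter of an agreement fit
#'
#' @param object An `agreement_stats` object from [bland_altman()].
#' @param ... Ignored.
#' @return A ggplot: pair means against differences with the mean
#'   difference and limits of agreement as horizontal lines.
#' @export
autoplot.agreement_stats <- function(object, ...) {
  df <- tidy.agreement_stats(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff,
                        colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = "pair mean", y = "difference (a - b)")
}

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper around [stats::cor()] for the paired
#' validation series used throughout (counts vs counts, metres vs metres).
#'
#' @param a,b Equal-length numeric vectors, length >= 3, both with
#'   non-zero variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in a series", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Mean similarity between GPS and algorithm distances
#'
#' The per-walk similarity is `1 - |gps - algo| / gps`, averaged over walks
#' and expressed as a percentage. Walks overestimated by more than 100%
#' yield negative similarity; these are not clipped by default (set
#' `clip = TRUE` to floor per-walk similarity at 0).
#'
#' @param gps_dists,algo_dists Equal-length vectors of walk distances (m);
#'   GPS distances must be positive.
#' @param clip Floor per-walk similarity at zero before averaging.
#' @return Mean similarity in percent.
#' @export
mean_similarity <- function(gps_dists, algo_dists, clip = FALSE) {
  if (length(gps_dists) != length(algo_dists)) {
    stop("series lengths differ", call. = FALSE)
  }
  if (any(gps_dists <= 0)) {
    stop("GPS distances must be positive", call. = FALSE)
  }
  sim <- 1 - abs(gps_dists - algo_dists) / gps_dists
  if (clip) sim <- pmax(sim, 0)
  mean(sim) * 100
}

#' Aggregate summary of the packaged validation tables
#'
#' Recomputes the headline aggregates of the two study tables: total, mean
#' and sample standard deviation of the annotated video step counts
#' (table 1); walk count, maximum and mean GPS walk distance (table 2); and
#' the allometric stride-frequency band endpoints at the cohort's extreme
#' weights.
#'
#' @param fixtures Output of [study_fixtures()].
#' @return A one-row tibble.
#' @export
fixture_summary <- function(fixtures = study_fixtures()) {
  t1 <- fixtures$table1
  gps <- unlist(fixtures$table2$gps_dists_m)
  tibble::tibble(
    total_video_steps = sum(t1$steps_video),
    mean_video_steps = mean(t1$steps_video),
    sd_video_steps = stats::sd(t1$steps_video),
    n_walks = length(gps),
    max_gps_km = max(gps) / 1000,
    mean_gps_km = mean(gps) / 1000,
    band_lo_hz = stride_frequency_hz(max(t1$weight_kg)),
    band_hi_hz = stride_frequency_hz(min(t1$weight_kg))
  )
}
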