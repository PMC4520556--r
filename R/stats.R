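#' Pearson correlation with two-sided t test
#'
#' Thin wrapper around [stats::cor.test()] for the linearity analyses,
#' guarding against degenerate input.
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return A tibble with `r`, `p`, `n`.
#' @examples
#' pearson(1:6, c(2, 4, 6.1, 7.9, 10, 12))
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation undefined: an input has zero variance",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Build a repeatability table
#'
#' A subjects-by-measurements matrix of mean velocities feeding the VC and
#' ICC analyses. Rows with any missing cell are dropped (complete-case, as
#' when corrupted recordings are excluded from a repeatability study).
#'
#' @param values A numeric matrix or data frame, one row per subject and one
#'   column per repeated measurement.
#' @param subjects Optional subject labels.
#' @return A numeric matrix of class `ldf_reptable` with complete cases only.
#' @export
repeatability_table <- function(values, subjects = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (!is.null(subjects)) rownames(m) <- subjects
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("repeatability table needs >= 2 complete subjects and >= 2 ",
         "measurements; got ", nrow(m), " x ", ncol(m), call. = FALSE)
  }
  structure(m, class = c("ldf_reptable", "matrix", "array"),
            n_dropped = sum(!keep))
}

#' Intraclass correlation ICC(A,1): two-way random, absolute agreement, single measure
#'
#' Two-way random-effects ANOVA decomposition of a subjects-by-measurements
#' table into subject (`ms_rows`), measurement (`ms_cols`) and residual
#' (`ms_error`) mean squares, giving the single-measure absolute-agreement
#' intraclass correlation
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with the McGraw-Wong F-based 95% confidence interval and a p-value from
#' the F test of `MS_R / MS_E`. This is the "single, two-way random, absolute
#' agreement" coefficient of standard statistical packages.
#'
#' @param table A [repeatability_table()] (or coercible matrix/data frame).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `ldf_icc` with fields `icc`, `ci_low`,
#'   `ci_high`, `p`, `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`,
#'   `agreement` (the conventional poor/fair/good label) and `degenerate`.
#' @examples
#' m <- cbind(a = c(10, 12, 14, 16), b = c(11, 12.5, 13.5, 16.5))
#' icc_a1(m)
#' @export
icc_a1 <- function(table, conf_level = 0.95) {
  m <- if (inherits(table, "ldf_reptable")) table else repeatability_table(table)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  if (ss_total <= .Machine$double.eps * max(1, abs(grand))^2) {
    return(structure(
      list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           p = NA_real_, ms_rows = ms_rows, ms_cols = ms_cols,
           ms_error = ms_error, n = n, k = k, conf_level = conf_level,
           agreement = NA_character_, degenerate = TRUE),
      class = "ldf_icc"
    ))
  }
  icc <- (ms_rows - ms_error) /
    (ms_rows + (k - 1) * ms_error + (k / n) * (ms_cols - ms_error))
  # McGraw-Wong interval for ICC(A,1)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * ms_cols + b * ms_error)^2 /
    ((a * ms_cols)^2 / (k - 1) + (b * ms_error)^2 / ((n - 1) * (k - 1)))
  f_low <- stats::qf(1 - alpha / 2, n - 1, v)
  f_up <- stats::qf(1 - alpha / 2, v, n - 1)
  denom_c <- k * ms_cols + (k * n - k - n) * ms_error
  ci_low <- n * (ms_rows - f_low * ms_error) /
    (f_low * denom_c + n * ms_rows)
  ci_high <- n * (f_up * ms_rows - ms_error) /
    (denom_c + n * f_up * ms_rows)
  f_obs <- ms_rows / ms_error
  p <- stats::pf(f_obs, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(
    list(icc = icc, ci_low = ci_low, ci_high = ci_high, p = p,
         ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_error,
         n = n, k = k, conf_level = conf_level,
         agreement = icc_agreement_label(icc), degenerate = FALSE),
    class = "ldf_icc"
  )
}

#' Conventional agreement label for an ICC value
#'
#' 0-0.49 poor, 0.5-0.69 fair, above 0.69 good-to-strong agreement.
#' @param icc Numeric ICC value(s).
#' @return Character vector of labels.
#' @export
icc_agreement_label <- function(icc) {
  dplyr::case_when(
    is.na(icc) ~ NA_character_,
    icc < 0.5 ~ "poor",
    icc < 0.7 ~ "fair",
    TRUE ~ "good-to-strong"
  )
}

#' @export
print.ldf_icc <- function(x, ...) {
  if (x$degenerate) {
    cat("<ldf_icc> degenerate table (no variance); ICC undefined\n")
    return(invisible(x))
  }
  cat(sprintf("ICC(A,1) = %.3f  %g%% CI [%.3f, %.3f]  p = %.3g  (%s)\n",
              x$icc, 100 * x$conf_level, x$ci_low, x$ci_high, x$p,
              x$agreement))
  cat(sprintf("  n = %d subjects, k = %d measurements | MS rows %.3g, cols %.3g, error %.3g\n",
              x$n, x$k, x$ms_rows, x$ms_cols, x$ms_error))
  invisible(x)
}

#' Per-subject variation coefficients
#'
#' `VC_i = 100 * SD(row_i) / mean(row_i)` (sample SD), summarised as
#' mean +/- SD across subjects. Subjects with non-positive mean are excluded
#' with a warning.
#'
#' @param table A subjects-by-measurements matrix or data frame.
#' @return A list with `per_subject` (tibble: `subject`, `mean`, `sd`,
#'   `vc`), `vc_mean`, `vc_sd` and `n_excluded`.
#' @examples
#' variation_coefficient(rbind(c(90, 100, 110), c(200, 200, 200)))
#' @export
variation_coefficient <- function(table) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  mu <- rowMeans(m, na.rm = TRUE)
  bad <- !is.finite(mu) | mu <= 0
  if (any(bad)) {
    warning(sum(bad), " subject(s) with non-positive mean excluded from VC",
            call. = FALSE)
  }
  keep <- which(!bad)
  per <- tibble::tibble(
    subject = if (!is.null(rownames(m))) rownames(m)[keep] else
      as.character(keep),
    mean = mu[keep],
    sd = apply(m[keep, , drop = FALSE], 1, stats::sd, na.rm = TRUE),
    vc = 100 * .data$sd / .data$mean
  )
  list(per_subject = per,
       vc_mean = mean(per$vc), vc_sd = stats::sd(per$vc),
       n_excluded = sum(bad))
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are excluded, absolute differences receive mid-ranks
#' under ties, and `W` is the sum of ranks of the positive differences. For
#' n <= `exact_max` (default 25) the two-sided p-value is exact, computed by
#' enumerating the full sign-flip distribution of the (possibly tied) rank
#' vector with a generating-function convolution - equivalent to the 2^n
#' enumeration but polynomial-time. Above `exact_max` a normal approximation
#' with tie correction is used.
#'
#' @param before,after Paired numeric vectors.
#' @param exact_max Largest n for which the exact distribution is enumerated.
#' @return A tibble with `w`, `p`, `n` (pairs used), `method`.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5)) # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(before, after, exact_max = 25) {
  stopifnot(length(before) == length(after))
  d <- before - after
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all paired differences are zero; signed-rank test undefined",
         call. = FALSE)
  }
  if (n < 3) {
    stop("need at least 3 nonzero paired differences, got ", n,
         call. = FALSE)
  }
  r <- rank(abs(d)) # mid-ranks under ties
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, w)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  tibble::tibble(w = w, p = min(p, 1), n = n, method = method)
}

# Exact two-sided p for the sign-flip distribution of rank vector r at
# statistic w: doubles the smaller tail (observed value included), capped at
# 1. Ranks are doubled to integers so mid-ranks (x.5) convolve exactly.
signed_rank_exact_p <- function(r, w) {
  r2 <- round(2 * r)
  total <- sum(r2)
  counts <- rep(0, total + 1) # counts[v + 1] = #assignments with 2W = v
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  w2 <- round(2 * w)
  lower <- sum(probs[seq_len(w2 + 1)])
  upper <- sum(probs[(w2 + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Sample median of repositioning displacements
#'
#' Standard sample median (midpoint of the two middle order statistics for
#' even n); used to summarise day-to-day laser-beam repositioning distances
#' measured on a counting chamber.
#'
#' @param values Non-empty numeric vector, micrometres.
#' @return The median displacement, micrometres.
#' @examples
#' median_displacement(c(20, 50, 75, 20, 100)) # 50
#' @export
median_displacement <- function(values) {
  stopifnot(length(values) >= 1)
  stats::median(values)
}
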