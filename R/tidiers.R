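#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for experiment and statistic results
#'
#' `tidy()` returns the per-unit table of a result (per speed, per rat, per
#' timescale); `glance()` returns a one-row summary.
#'
#' @param x A result object (`ldf_linearity`, `ldf_baseline`,
#'   `ldf_repeatability`, `ldf_protocol`, `ldf_icc`).
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name ldfsim-tidiers
NULL

#' @rdname ldfsim-tidiers
#' @export
tidy.ldf_linearity <- function(x, ...) x$summary

#' @rdname ldfsim-tidiers
#' @export
glance.ldf_linearity <- function(x, ...) {
  tibble::tibble(
    scene_kind = x$scene_kind, n_speeds = nrow(x$summary),
    pearson_r = x$pearson_r, pearson_p = x$pearson_p,
    slope = x$slope, intercept = x$intercept,
    vol_cv = x$vol_cv, dc_cv = x$dc_cv
  )
}

#' @rdname ldfsim-tidiers
#' @export
tidy.ldf_baseline <- function(x, ...) x$per_rat

#' @rdname ldfsim-tidiers
#' @export
glance.ldf_baseline <- function(x, ...) {
  tibble::tibble(site = x$site, n_rats = x$n_rats,
                 vel_mean = x$mean, vel_sd = x$sd)
}

#' @rdname ldfsim-tidiers
#' @export
tidy.ldf_repeatability <- function(x, ...) x$table_rows

#' @rdname ldfsim-tidiers
#' @export
glance.ldf_repeatability <- function(x, ...) {
  inter <- dplyr::filter(x$table_rows, .data$timescale == "inter-session")
  tibble::tibble(site = x$site, n_rats = x$n_rats, sessions = x$sessions,
                 icc_intersession = inter$icc,
                 vc_intersession = inter$vc_mean)
}

#' @rdname ldfsim-tidiers
#' @export
tidy.ldf_protocol <- function(x, ...) x$per_rat

#' @rdname ldfsim-tidiers
#' @export
glance.ldf_protocol <- function(x, ...) {
  tibble::tibble(protocol = x$protocol, site = x$site, n_rats = x$n_rats,
                 mean_change = x$mean_change, sd_change = x$sd_change,
                 wilcoxon_w = x$wilcoxon$w, wilcoxon_p = x$wilcoxon$p)
}

#' @rdname ldfsim-tidiers
#' @export
tidy.ldf_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 p = x$p, agreement = x$agreement)
}

#' @rdname ldfsim-tidiers
#' @export
glance.ldf_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 p = x$p, ms_rows = x$ms_rows, ms_cols = x$ms_cols,
                 ms_error = x$ms_error, n = x$n, k = x$k,
                 degenerate = x$degenerate)
}
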