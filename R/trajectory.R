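#' Allele-frequency trajectory of one SNP over birth dates
#'
#' Regresses frequency-coded genotypes (dosage / 2, i.e. 0, 0.5, 1) on
#' birth date. The linear slope gives the per-year frequency change; a
#' tricube-weighted local linear smoother ([stats::loess] with
#' `degree = 1`) gives the visualized frequency history, clipped to
#' \[0, 1\] and evaluated only on the observed date range.
#'
#' @param dosage numeric vector of 0/1/2 dosages (NA allowed).
#' @param birthdate numeric vector of birth dates / ages (years).
#' @param span loess span (default 0.75).
#' @param n_grid number of points on the smoothed curve.
#' @param min_n,min_span_years minimum samples (30) and date span
#'   (2 years) required for a stable fit.
#' @return object of class `af_trajectory`: `slope_per_year`, `slope_se`,
#'   `curve` (data.frame `time`, `freq`), `n`.
#' @export
allele_frequency_trajectory <- function(dosage, birthdate, span = 0.75,
                                        n_grid = 50L, min_n = 30L,
                                        min_span_years = 2) {
  ok <- !is.na(dosage) & !is.na(birthdate)
  f <- dosage[ok] / 2
  t <- birthdate[ok]
  if (length(f) < min_n) stop("need at least ", min_n, " samples")
  if (diff(range(t)) == 0) stop("all samples share one birth date")
  if (diff(range(t)) < min_span_years)
    stop("birth dates span less than ", min_span_years, " years")
  fit <- stats::lm(f ~ t)
  sl <- summary(fit)$coefficients
  grid <- seq(min(t), max(t), length.out = n_grid)
  lo <- stats::loess(f ~ t, span = span, degree = 1,
                     control = stats::loess.control(surface = "direct"))
  curve <- data.frame(time = grid,
                      freq = pmin(pmax(stats::predict(lo, grid), 0), 1))
  structure(list(slope_per_year = sl["t", "Estimate"],
                 slope_se = sl["t", "Std. Error"],
                 curve = curve, n = length(f), span = span),
            class = "af_trajectory")
}

#' @export
print.af_trajectory <- function(x, ...) {
  cat(sprintf("allele-frequency trajectory (n = %d): %+.4g per year (SE %.3g)\n",
              x$n, x$slope_per_year, x$slope_se))
  invisible(x)
}

#' Per-generation allele frequency change
#'
#' Converts the per-year frequency slope into a per-generation change
#' using the generation interval (default 5 years, consistent with
#' roughly ten cattle generations in fifty years).
#'
#' @param trajectory an [allele_frequency_trajectory()] object, or a
#'   numeric per-year slope.
#' @param generation_interval_years years per generation (default 5).
#' @return delta AF per generation (signed).
#' @export
delta_af_per_generation <- function(trajectory,
                                    generation_interval_years = 5) {
  slope <- if (inherits(trajectory, "af_trajectory"))
    trajectory$slope_per_year else trajectory
  slope * generation_interval_years
}
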