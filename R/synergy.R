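#' Fit the median-effect model to a dose-response curve
#'
#' The median-effect equation \eqn{fa/(1-fa) = (D/D_m)^m} linearizes as
#' \eqn{\log_{10}(fa/(1-fa)) = m \log_{10} D - m \log_{10} D_m}; the fit is
#' ordinary least squares on that line. `Dm` is the median-effect dose (the
#' dose giving 50% effect, e.g. the IC50 for growth inhibition), `m` the
#' sigmoidicity slope, and `r` the linear correlation of the median-effect
#' plot. Points with fa exactly 0 or 1 are excluded from the fit (the logit
#' is undefined there) and counted.
#'
#' @param dr A tibble with columns `dose` (positive, uM) and `fa` (fraction
#'   affected in \[0, 1\]); optional `drug` and `cell_line` columns are
#'   carried through.
#' @return An object of class `np_medfx`: list with `Dm`, `m`, `r`,
#'   `n_points_used`, `n_excluded`, `drug`, `cell_line`.
#' @export
median_effect_fit <- function(dr) {
  stopifnot(all(c("dose", "fa") %in% names(dr)))
  if (any(dr$dose <= 0)) abort("doses must be strictly positive")
  if (any(dr$fa < 0 | dr$fa > 1)) abort("fa must lie in [0, 1]")
  usable <- dr$fa > 0 & dr$fa < 1
  n_excl <- sum(!usable)
  if (n_excl > 0) inform(sprintf("excluded %d point(s) with fa at 0 or 1", n_excl))
  d <- dr[usable, ]
  if (nrow(d) < 2) abort("need >= 2 points with 0 < fa < 1 to fit")
  x <- log10(d$dose)
  y <- log10(d$fa / (1 - d$fa))
  if (length(unique(x)) < 2) abort("zero variance in doses")
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  if (!is.finite(m) || m == 0) abort("degenerate slope in median-effect fit")
  structure(
    list(
      Dm = 10^(-b / m), m = m,
      r = if (length(unique(y)) < 2) 1 else cor(x, y),
      n_points_used = nrow(d), n_excluded = n_excl,
      drug = if ("drug" %in% names(dr)) dr$drug[1] else NA_character_,
      cell_line = if ("cell_line" %in% names(dr)) dr$cell_line[1] else NA_character_
    ),
    class = "np_medfx"
  )
}

#' @export
print.np_medfx <- function(x, ...) {
  cat(sprintf("<np_medfx> Dm = %.4g uM, m = %.4g, r = %.4f (%d points, %d excluded)\n",
              x$Dm, x$m, x$r, x$n_points_used, x$n_excluded))
  invisible(x)
}

#' @describeIn median_effect_fit Fitted parameters as a tibble.
#' @param x An `np_medfx`.
#' @param ... Unused.
#' @export
tidy.np_medfx <- function(x, ...) {
  tibble::tibble(drug = x$drug, cell_line = x$cell_line,
                 Dm = x$Dm, m = x$m, r = x$r)
}

#' @describeIn median_effect_fit One-row fit summary.
#' @export
glance.np_medfx <- function(x, ...) {
  tibble::tibble(Dm = x$Dm, m = x$m, r = x$r,
                 n_points_used = x$n_points_used, n_excluded = x$n_excluded)
}

#' Dose required for a given effect level
#'
#' Inverts the fitted median-effect curve:
#' \eqn{D_x = D_m (fa / (1 - fa))^{1/m}}. At fa = 0.5 this returns Dm (the
#' IC50 when the effect is growth inhibition).
#'
#' @param fit An `np_medfx`.
#' @param fa Effect level in (0, 1).
#' @return Dose (same units as the fit).
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "np_medfx"))
  if (any(fa <= 0 | fa >= 1)) abort("fa must lie strictly in (0, 1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Combination index and dose-reduction index at one point
#'
#' For a fixed-ratio mixture delivering total dose \eqn{D} split as
#' \eqn{D_1 = D w_1/(w_1+w_2)}, \eqn{D_2 = D w_2/(w_1+w_2)}, the
#' (mutually exclusive, classic) combination index at effect level fa is
#' \deqn{CI = D_1 / D_{x1}(fa) + D_2 / D_{x2}(fa)}
#' where \eqn{D_{xi}(fa)} is the dose of drug i alone producing fa.
#' CI < 1, = 1, > 1 indicate synergism, an additive effect, and antagonism.
#' The dose-reduction index \eqn{DRI_i = D_{xi}(fa)/D_i} is the fold
#' reduction in each drug's dose permitted by the combination at equal
#' effect. A mutually nonexclusive variant adds the cross term
#' \eqn{D_1 D_2 / (D_{x1} D_{x2})}.
#'
#' @param fit1,fit2 `np_medfx` fits for the two single drugs.
#' @param total_dose Positive total mixture dose.
#' @param fa Observed effect level in (0, 1).
#' @param ratio Positive weights `c(w1, w2)` of the fixed dose ratio.
#' @param exclusive If TRUE (default) use the classic mutually exclusive
#'   form; FALSE adds the nonexclusive cross term.
#' @return A one-row tibble: `total_dose`, `fa`, `d1`, `d2`, `ci`, `dri1`,
#'   `dri2`, `classification`.
#' @export
combination_index <- function(fit1, fit2, total_dose, fa, ratio = c(1, 1),
                              exclusive = TRUE) {
  stopifnot(inherits(fit1, "np_medfx"), inherits(fit2, "np_medfx"),
            length(ratio) == 2, all(ratio > 0))
  if (total_dose <= 0) abort("total_dose must be > 0")
  if (fa <= 0 || fa >= 1) abort("fa must lie strictly in (0, 1)")
  d1 <- total_dose * ratio[1] / sum(ratio)
  d2 <- total_dose * ratio[2] / sum(ratio)
  dx1 <- dose_for_effect(fit1, fa)
  dx2 <- dose_for_effect(fit2, fa)
  ci <- d1 / dx1 + d2 / dx2
  if (!exclusive) ci <- ci + (d1 * d2) / (dx1 * dx2)
  tibble::tibble(
    total_dose = total_dose, fa = fa, d1 = d1, d2 = d2, ci = ci,
    dri1 = dx1 / d1, dri2 = dx2 / d2,
    classification = classify_ci(ci)
  )
}

classify_ci <- function(ci) {
  dplyr::case_when(
    is.na(ci) ~ NA_character_,
    ci < 1 ~ "synergism",
    ci > 1 ~ "antagonism",
    TRUE ~ "additive"
  )
}

#' CI-versus-Fa table for a measured fixed-ratio mixture
#'
#' For each measured (total dose, fa) point of the mixture, computes the
#' combination point via [combination_index()] using the observed fa. Rows
#' with fa at exactly 0 or 1 are kept with CI/DRI undefined (NA) and
#' flagged, matching the layout of combination experiment tables (sorted by
#' total dose descending).
#'
#' @param combo_dr A tibble with columns `total_dose` and `fa` for the
#'   mixture.
#' @inheritParams combination_index
#' @return A tibble with one row per measured point: `total_dose`, `fa`,
#'   `d1`, `d2`, `ci`, `dri1`, `dri2`, `classification`, `defined`.
#' @export
ci_fa_table <- function(fit1, fit2, combo_dr, ratio = c(1, 1),
                        exclusive = TRUE) {
  stopifnot(all(c("total_dose", "fa") %in% names(combo_dr)))
  if (nrow(combo_dr) == 0) {
    return(tibble::tibble(
      total_dose = numeric(0), fa = numeric(0), d1 = numeric(0),
      d2 = numeric(0), ci = numeric(0), dri1 = numeric(0), dri2 = numeric(0),
      classification = character(0), defined = logical(0)
    ))
  }
  rows <- purrr::pmap(list(combo_dr$total_dose, combo_dr$fa), function(td, fa) {
    if (fa <= 0 || fa >= 1) {
      tibble::tibble(
        total_dose = td, fa = fa,
        d1 = td * ratio[1] / sum(ratio), d2 = td * ratio[2] / sum(ratio),
        ci = NA_real_, dri1 = NA_real_, dri2 = NA_real_,
        classification = NA_character_, defined = FALSE
      )
    } else {
      dplyr::mutate(
        combination_index(fit1, fit2, td, fa, ratio, exclusive),
        defined = TRUE
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  if (any(!out$defined)) {
    warn(sprintf("%d point(s) with fa at 0 or 1: CI undefined there",
                 sum(!out$defined)))
  }
  dplyr::arrange(out, dplyr::desc(.data$total_dose))
}

#' Simulate a median-effect dose-response curve
#'
#' Generates fraction-affected values from the median-effect curve
#' \eqn{fa = D^m / (D^m + D_m^m)} with optional Gaussian noise, clipped to
#' \[0, 1\].
#'
#' @param Dm Median-effect dose (> 0).
#' @param m Slope.
#' @param doses Positive dose vector.
#' @param noise_sd Gaussian noise standard deviation (0 for exact points).
#' @param seed Seed used when noise is drawn.
#' @return A tibble with columns `dose` and `fa`.
#' @export
simulate_dose_response <- function(Dm, m, doses, noise_sd = 0, seed = 1) {
  stopifnot(Dm > 0, all(doses > 0))
  fa <- doses^m / (doses^m + Dm^m)
  if (noise_sd > 0) {
    fa <- withr::with_seed(seed, fa + stats::rnorm(length(fa), 0, noise_sd))
    fa <- pmin(pmax(fa, 0), 1)
  }
  tibble::tibble(dose = doses, fa = fa)
}

#' Median-effect plot of a fitted dose-response
#'
#' Shows the median-effect linearization (log10 dose against
#' log10(fa/(1-fa))) with the fitted line.
#'
#' @param object An `np_medfx`.
#' @param dr Optionally, the dose-response tibble used for the fit, to show
#'   the points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.np_medfx <- function(object, dr = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$m,
                         intercept = -object$m * log10(object$Dm)) +
    ggplot2::labs(
      x = "log10 dose", y = "log10(fa / (1 - fa))",
      title = sprintf("Median-effect plot (Dm = %.3g, m = %.3g, r = %.3f)",
                      object$Dm, object$m, object$r)
    )
  if (!is.null(dr)) {
    d <- dr[dr$fa > 0 & dr$fa < 1, ]
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(x = log10(d$dose), y = log10(d$fa / (1 - d$fa))),
      ggplot2::aes(x = .data$x, y = .data$y)
    )
  }
  p
}

#' CI-versus-Fa scatter plot
#'
#' The standard synergy display: combination index against fraction
#' affected, with the additive line CI = 1.
#'
#' @param ci_table A tibble from [ci_fa_table()].
#' @return A ggplot.
#' @export
plot_ci_fa <- function(ci_table) {
  df <- ci_table[!is.na(ci_table$ci), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fa, y = .data$ci)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Fraction affected (Fa)", y = "Combination index (CI)")
}
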