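#' Cell viability and cytotoxicity percentages
#'
#' MTT-style readout: viability is the treated-well absorbance as a
#' percentage of the untreated-well absorbance; cytotoxicity is its
#' complement, `100 - viability`.
#'
#' @param treated Absorbance of the treated well(s), non-negative.
#' @param untreated Absorbance of the untreated control, strictly positive.
#' @return Percentage(s).
#' @examples
#' viability_percent(0.25, 0.5) # 50
#' cytotoxicity_percent(0.25, 0.5) # 50
#' @export
viability_percent <- function(treated, untreated) {
  if (any(untreated <= 0)) {
    abort_undefined("untreated absorbance must be positive")
  }
  if (any(treated < 0)) abort_validation("treated absorbance must be >= 0")
  treated / untreated * 100
}

#' @rdname viability_percent
#' @export
cytotoxicity_percent <- function(treated, untreated) {
  100 - viability_percent(treated, untreated)
}

# Four-parameter logistic in log-concentration form:
# v(c) = lower + (upper - lower) / (1 + exp(hill * (log c - log midpoint))).
# With hill > 0 the curve falls from `upper` (low dose) to `lower`.
fpl <- function(conc, lower, upper, hill, midpoint) {
  lower + (upper - lower) / (1 + exp(hill * (log(conc) - log(midpoint))))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `v(c) = lower + (upper - lower) / (1 + (c / midpoint)^hill)`
#' to viability percentages over a concentration series, the standard model
#' behind IC50/CC50 readouts. Concentrations are log-transformed internally
#' for conditioning; starting values are `lower = min(v)`,
#' `upper = max(v)`, `hill = +/-1` (sign from the observed trend) and
#' `midpoint` at the geometric centre of the series; optimisation is
#' bounded Levenberg-Marquardt with tolerance 1e-8.
#'
#' The IC50 (or CC50: same computation on a normal-cell curve) is solved
#' from the fitted parameters as the concentration where the curve crosses
#' 50% viability, and is reported only when 50 lies strictly between the
#' fitted asymptotes; otherwise `ic50` is `NA` with `ic50_defined = FALSE`.
#'
#' @param data Either a data frame with columns `concentration` and
#'   `viability`, or a numeric vector of concentrations.
#' @param viability Numeric viability percentages (when `data` is a vector).
#' @return Object of class `dose_response_fit` with elements `data`,
#'   `par` (named vector `lower`, `upper`, `hill`, `midpoint`), `ic50`,
#'   `ic50_defined`, `sigma` (residual standard error), `converged`, and
#'   the underlying `nls` fit. Has [tidy()], [glance()], `predict()` and
#'   [autoplot()] methods.
#' @examples
#' conc <- c(1, 5, 25, 50, 125, 250, 500)
#' v <- 100 / (1 + (conc / 41.75))
#' fit <- fit_dose_response(conc, v)
#' glance(fit)$ic50
#' @export
fit_dose_response <- function(data, viability = NULL) {
  if (is.data.frame(data)) {
    required <- c("concentration", "viability")
    missing <- setdiff(required, names(data))
    if (length(missing) > 0) {
      abort_schema(paste0("dose-response table is missing column(s): ",
                          paste(missing, collapse = ", ")))
    }
    conc <- data$concentration
    viab <- data$viability
  } else {
    conc <- data
    viab <- viability
  }
  if (any(conc <= 0)) abort_validation("concentrations must be positive")
  if (length(unique(conc)) < 4) {
    rlang::abort("need at least 4 distinct concentrations",
                 class = "endodiv_insufficient_data")
  }
  if (any(!is.finite(viab))) abort_validation("viability must be finite")

  d <- tibble::tibble(concentration = conc, viability = viab) |>
    dplyr::arrange(.data$concentration)
  lc <- log(d$concentration)
  span <- max(d$viability) - min(d$viability)

  if (span < 1e-8) {
    # flat data: degenerate fit, no crossing of 50 unless exactly at 50
    par <- c(lower = min(d$viability), upper = max(d$viability),
             hill = 1, midpoint = exp(mean(lc)))
    return(new_dose_response_fit(d, par, fit = NULL, sigma = 0,
                                 converged = TRUE))
  }

  hill0 <- if (stats::cor(lc, d$viability) <= 0) 1 else -1
  start <- c(lower = min(d$viability), upper = max(d$viability),
             hill = hill0, lmid = mean(range(lc)))
  resid_fn <- function(p) {
    d$viability - (p["lower"] + (p["upper"] - p["lower"]) /
                     (1 + exp(p["hill"] * (lc - p["lmid"]))))
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(lower = -100, upper = -100, hill = -50, lmid = min(lc) - 10),
    upper = c(lower = 300, upper = 300, hill = 50, lmid = max(lc) + 10),
    control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                         maxiter = 500)
  )
  cf <- fit$par
  par <- c(lower = unname(cf["lower"]), upper = unname(cf["upper"]),
           hill = unname(cf["hill"]), midpoint = unname(exp(cf["lmid"])))
  sigma <- sqrt(fit$deviance / max(nrow(d) - 4, 1))
  new_dose_response_fit(d, par, fit = fit, sigma = sigma,
                        converged = fit$info %in% 1:4)
}

new_dose_response_fit <- function(d, par, fit, sigma, converged) {
  lo <- min(par["lower"], par["upper"])
  hi <- max(par["lower"], par["upper"])
  ic50 <- NA_real_
  defined <- is.finite(lo) && is.finite(hi) && lo < 50 && 50 < hi &&
    abs(par["hill"]) > 1e-12
  if (defined) {
    # solve lower + (upper - lower)/(1 + (c/m)^h) = 50
    ratio <- (par["upper"] - 50) / (50 - par["lower"])
    ic50 <- unname(par["midpoint"] * ratio^(1 / par["hill"]))
    defined <- is.finite(ic50) && ic50 > 0
    if (!defined) ic50 <- NA_real_
  }
  structure(
    list(data = d, par = par, ic50 = ic50, ic50_defined = defined,
         sigma = sigma, converged = converged, fit = fit),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> 4PL over", nrow(x$data), "points\n")
  cat(sprintf("  lower %.2f  upper %.2f  hill %.3f  midpoint %.3f\n",
              x$par["lower"], x$par["upper"], x$par["hill"],
              x$par["midpoint"]))
  if (x$ic50_defined) {
    cat(sprintf("  IC50 %.4g (same units as concentration)\n", x$ic50))
  } else {
    cat("  IC50 undefined (50% not between fitted asymptotes)\n")
  }
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) {
    object$data$concentration
  } else if (is.data.frame(newdata)) {
    newdata$concentration
  } else {
    newdata
  }
  fpl(conc, object$par[["lower"]], object$par[["upper"]],
      object$par[["hill"]], object$par[["midpoint"]])
}

#' Fit dose-response curves per cell line from an MTT plate table
#'
#' Convenience wrapper for tables with columns `cell_line`,
#' `concentration_ug_ml`, `replicate`, `absorbance`,
#' `untreated_absorbance`: computes [viability_percent()] per well, then
#' fits [fit_dose_response()] within each cell line.
#'
#' @param data MTT-format data frame.
#' @return A tibble with one row per cell line: `cell_line`, `fit` (list
#'   column of `dose_response_fit`), `ic50`, `ic50_defined`.
#' @export
fit_mtt <- function(data) {
  required <- c("cell_line", "concentration_ug_ml", "absorbance",
                "untreated_absorbance")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort_schema(paste0("MTT table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  data |>
    tibble::as_tibble() |>
    dplyr::mutate(viability = viability_percent(
      .data$absorbance, .data$untreated_absorbance
    )) |>
    dplyr::rename(concentration = "concentration_ug_ml") |>
    tidyr::nest(.by = "cell_line") |>
    dplyr::mutate(
      fit = purrr::map(.data$data, fit_dose_response),
      ic50 = purrr::map_dbl(.data$fit, "ic50"),
      ic50_defined = purrr::map_lgl(.data$fit, "ic50_defined")
    ) |>
    dplyr::select("cell_line", "fit", "ic50", "ic50_defined")
}

#' Selectivity index
#'
#' `SI = CC50(normal cells) / IC50(tumour cells)`; values above 3 are
#' conventionally read as high tumour selectivity. The full-precision ratio
#' is returned alongside `si_printed`, the value truncated (not rounded) to
#' two decimals, the convention used when quoting SI figures.
#'
#' @param cc50 CC50 of the normal cell line (same units as `ic50`).
#' @param ic50 IC50 of the tumour cell line, strictly positive.
#' @return One-row tibble: `selectivity_index` (full precision),
#'   `si_printed` (truncated to 2 decimals), `high_selectivity`
#'   (`selectivity_index > 3`, strict).
#' @examples
#' selectivity_index(196.2, 41.75)
#' @export
selectivity_index <- function(cc50, ic50) {
  if (any(ic50 <= 0) || any(cc50 <= 0)) {
    abort_undefined("cc50 and ic50 must be positive")
  }
  si <- cc50 / ic50
  tibble::tibble(
    selectivity_index = si,
    si_printed = round_fixed(si, 2, "truncate"),
    high_selectivity = si > 3
  )
}
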