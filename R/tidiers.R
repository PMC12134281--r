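# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a four-parameter logistic fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`lower`, `upper`, `hill`,
#'   `midpoint`): `term`, `estimate`, `std.error` (midpoint standard error
#'   via the delta method from the log-midpoint parameterisation; `NA` for
#'   degenerate fits).
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  est <- x$par
  se <- rep(NA_real_, 4)
  if (!is.null(x$fit)) {
    s <- summary(x$fit)$coefficients
    se <- c(s["lower", "Std. Error"], s["upper", "Std. Error"],
            s["hill", "Std. Error"],
            # midpoint = exp(lmid): delta method
            unname(est["midpoint"]) * s["lmid", "Std. Error"])
  }
  tibble::tibble(
    term = c("lower", "upper", "hill", "midpoint"),
    estimate = unname(est[c("lower", "upper", "hill", "midpoint")]),
    std.error = se
  )
}

#' Glance at a four-parameter logistic fit
#'
#' @inheritParams tidy.dose_response_fit
#' @return One-row tibble: the four parameter estimates, `ic50`,
#'   `ic50_defined`, `sigma`, `df.residual`, `nobs`, `converged`.
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(
    lower = unname(x$par["lower"]), upper = unname(x$par["upper"]),
    hill = unname(x$par["hill"]), midpoint = unname(x$par["midpoint"]),
    ic50 = x$ic50, ic50_defined = x$ic50_defined,
    sigma = x$sigma, df.residual = nrow(x$data) - 4L,
    nobs = nrow(x$data), converged = x$converged
  )
}

#' Tidy a Duncan letter display
#'
#' @param x A `duncan_mrt`.
#' @param ... Unused.
#' @return The group/mean/n/letters tibble (groups sorted by decreasing
#'   mean).
#' @method tidy duncan_mrt
#' @export
tidy.duncan_mrt <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "duncan_mrt")
  attr(out, "alpha") <- NULL
  attr(out, "df_within") <- NULL
  attr(out, "ms_within") <- NULL
  attr(out, "n_h") <- NULL
  attr(out, "lsr") <- NULL
  out
}

#' Tidy an ordination
#'
#' @param x An `endo_ordination`.
#' @param matrix Which table to return: `"scores"` (genera; default),
#'   `"loadings"` (tissues) or `"eigenvalues"` (variance fractions).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy endo_ordination
#' @export
tidy.endo_ordination <- function(x, matrix = c("scores", "loadings",
                                               "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = x$loadings,
    eigenvalues = tibble::tibble(
      component = seq_along(x$var_explained),
      var_explained = x$var_explained,
      cumulative = cumsum(x$var_explained)
    )
  )
}
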