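#' DPPH radical-scavenging percentage
#'
#' Colorimetric antioxidant readout: `(C - T) / C * 100` from the control
#' absorbance `C` and sample absorbance `T` at 517 nm. Values are computed
#' per replicate, never from pre-averaged absorbances, since the order of
#' operations changes the replicate spread. Negative values (sample more
#' absorbent than the control, a pro-oxidant artifact) are retained and
#' flagged with a warning, not clipped.
#'
#' @param t_abs Sample absorbance(s), non-negative.
#' @param c_abs Control absorbance(s), strictly positive.
#' @return Scavenging percentage(s) in `(-Inf, 100]`.
#' @examples
#' dpph_scavenging(0.2, 0.8) # 75
#' @export
dpph_scavenging <- function(t_abs, c_abs) {
  if (any(c_abs <= 0)) abort_undefined("control absorbance must be positive")
  if (any(t_abs < 0)) abort_validation("sample absorbance must be >= 0")
  out <- (c_abs - t_abs) / c_abs * 100
  if (any(out < 0)) {
    rlang::warn("negative scavenging value(s) retained (pro-oxidant artifact)",
                class = "endodiv_negative_scavenging")
  }
  out
}

#' Summarise a DPPH assay table
#'
#' Takes per-replicate absorbance records (columns `sample_id`, `replicate`,
#' `absorbance`, `control_absorbance`), transforms each replicate with
#' [dpph_scavenging()] and summarises per sample.
#'
#' @param data Data frame of DPPH records.
#' @return A tibble per sample: `n`, `mean_scavenging`, `sd_scavenging`,
#'   `any_negative`.
#' @export
summarize_dpph <- function(data) {
  required <- c("sample_id", "replicate", "absorbance", "control_absorbance")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort_schema(paste0("DPPH table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  data |>
    tibble::as_tibble() |>
    dplyr::mutate(scavenging = suppressWarnings(
      dpph_scavenging(.data$absorbance, .data$control_absorbance)
    )) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_scavenging = mean(.data$scavenging),
      sd_scavenging = stats::sd(.data$scavenging),
      any_negative = any(.data$scavenging < 0),
      .by = "sample_id"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_scavenging))
}
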