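# ggplot2 views of the result objects. Numeric exports are the contract;
# these figures are conveniences for interactive work and reports.

#' Plot a fitted dose-response curve
#'
#' Observed viability points and the fitted four-parameter logistic on a
#' log10 concentration axis, with the IC50 crossing marked when defined.
#'
#' @param object A `dose_response_fit`.
#' @param n_grid Number of curve evaluation points (default 200).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, n_grid = 200, ...) {
  rng <- range(object$data$concentration)
  grid <- tibble::tibble(
    concentration = exp(seq(log(rng[1]), log(rng[2]), length.out = n_grid))
  )
  grid$viability <- predict(object, grid)
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$concentration,
                                    y = .data$viability)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration", y = "Viability (%)") +
    ggplot2::theme_minimal()
  if (object$ic50_defined) {
    p <- p +
      ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed") +
      ggplot2::annotate("text", x = object$ic50, y = Inf,
                        label = sprintf("IC50 = %.3g", object$ic50),
                        vjust = 1.5, hjust = -0.05, size = 3)
  }
  p
}

#' Biplot of a genus-by-tissue ordination
#'
#' Genus scores with tissue loading arrows on the first two components.
#'
#' @param object An `endo_ordination`.
#' @param scale_arrows Multiplier applied to the loading arrows so they
#'   share the score scale (default: auto).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot endo_ordination
#' @export
autoplot.endo_ordination <- function(object, scale_arrows = NULL, ...) {
  sc <- object$scores
  ld <- object$loadings
  if (is.null(scale_arrows)) {
    scale_arrows <- 0.8 * max(abs(c(sc$PC1, sc$PC2))) /
      max(abs(c(ld$PC1, ld$PC2)))
  }
  ve <- object$var_explained
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * scale_arrows,
                   yend = .data$PC2 * scale_arrows),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * scale_arrows * 1.08,
                   y = .data$PC2 * scale_arrows * 1.08,
                   label = .data$tissue),
      colour = "firebrick", size = 3
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$genus),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2])
    ) +
    ggplot2::theme_minimal()
}

#' Bar view of tissue-overlap regions
#'
#' Region sizes of the Venn partition, labelled by the tissue combination
#' each region belongs to (an UpSet-style reading of the Venn diagram).
#'
#' @param object A `tissue_overlaps`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tissue_overlaps
#' @export
autoplot.tissue_overlaps <- function(object, ...) {
  tissues <- names(object$sets)
  d <- object$regions |>
    dplyr::mutate(label = purrr::pmap_chr(
      dplyr::pick(dplyr::all_of(tissues)),
      function(...) paste(tissues[c(...)], collapse = " & ")
    )) |>
    dplyr::filter(.data$size > 0) |>
    dplyr::arrange(dplyr::desc(.data$size))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$size), y = .data$size
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Tissue combination (exclusive region)",
                  y = "Morphospecies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a diversity profile
#'
#' Faceted per-index bars, one bar per plant; "no data" plants are dropped
#' from the panels.
#'
#' @param profile A [diversity_profile()] tibble.
#' @param indices Which index columns to facet over.
#' @return A ggplot object.
#' @export
plot_diversity_profile <- function(profile,
                                   indices = c("shannon", "simpson",
                                               "berger_parker",
                                               "evenness")) {
  d <- profile |>
    dplyr::filter(!.data$no_data) |>
    tidyr::pivot_longer(dplyr::all_of(indices), names_to = "index",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$plant, y = .data$value)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
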