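# Inhibition-zone statistics: one-way ANOVA and Duncan's multiple range
# test, the classical screening analysis for well-diffusion assays.

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    required <- c("group", "value")
    missing <- setdiff(required, names(groups))
    if (length(missing) > 0) {
      abort_schema(paste0("group table is missing column(s): ",
                          paste(missing, collapse = ", ")))
    }
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2) {
    rlang::abort("need at least 2 groups",
                 class = "endodiv_insufficient_replication")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    rlang::abort(
      paste0("every group needs >= 2 replicates; offending group(s): ",
             paste(names(groups)[sizes < 2], collapse = ", ")),
      class = "endodiv_insufficient_replication"
    )
  }
  groups
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition over independent replicate groups,
#' computed through a linear-model fit. Accepts either a named list of
#' numeric replicate vectors or a data frame with columns `group` and
#' `value`.
#'
#' @param groups Named list of numeric vectors (each length >= 2), or a
#'   data frame with `group`/`value` columns.
#' @return One-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, plus `ms_within` (the pooled error mean square used by
#'   [duncan_mrt()]).
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  d <- tibble::tibble(
    group = factor(rep(names(groups), lengths(groups))),
    value = unlist(groups, use.names = FALSE)
  )
  tab <- withCallingHandlers(
    stats::anova(stats::lm(value ~ group, data = d)),
    warning = function(w) {
      # zero-residual data: the F statistic is redefined below, the fit is fine
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  msb <- tab$`Mean Sq`[1]
  msw <- tab$`Mean Sq`[2]
  if (msw == 0) {
    # degenerate replicates: define F = 0 when groups coincide, Inf otherwise
    f <- if (msb == 0) 0 else Inf
    p <- if (msb == 0) 1 else 0
  }
  tibble::tibble(
    statistic = f,
    df_between = tab$Df[1],
    df_within = tab$Df[2],
    p_value = p,
    ms_within = msw
  )
}

# Least significant range for a span of p ranked means under Duncan's
# protection level alpha_p = 1 - (1 - alpha)^(p - 1), via the studentized
# range quantile.
duncan_lsr <- function(p, alpha, df_within, ms_within, n_h) {
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  stats::qtukey(1 - alpha_p, p, df_within) * sqrt(ms_within / n_h)
}

#' Duncan's multiple range test
#'
#' Stepwise post-hoc comparison of ranked group means. Means are sorted in
#' decreasing order; a span of `p` consecutive ranked means is declared
#' homogeneous when its observed range falls below the least significant
#' range `R_p = q(1 - (1 - alpha)^(p-1); p, df_within) *
#' sqrt(MS_within / n_h)`, where `q` is the studentized-range quantile
#' (computed numerically, no table lookup) and `n_h` the harmonic mean of
#' the replicate counts. Maximal homogeneous spans receive letters from
#' `"a"` downward; groups sharing any letter are not significantly
#' different. The letter display does not depend on the input order of the
#' groups.
#'
#' @inheritParams one_way_anova
#' @param alpha Protection level per pairwise comparison (default 0.05).
#' @return Object of class `duncan_mrt`: tibble with one row per group
#'   (`group`, `mean`, `n`, `letters`) sorted by decreasing mean, with the
#'   ANOVA inputs (`alpha`, `df_within`, `ms_within`, `n_h`, the `lsr`
#'   vector) stored as attributes. [tidy()] returns the tibble.
#' @examples
#' duncan_mrt(list(a = c(10, 11, 12), b = c(10.5, 11.5, 12.5),
#'                 c = c(30, 31, 32)))
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort_validation("alpha must be in (0, 1)")
  groups <- as_group_list(groups)
  aov_row <- one_way_anova(groups)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  # decreasing means; group-name tie-break keeps the display deterministic
  ord <- order(-means, names(groups))
  means <- means[ord]
  ns <- ns[ord]
  n_h <- k / sum(1 / ns)
  lsr <- c(NA_real_, vapply(
    2:k, duncan_lsr, numeric(1),
    alpha = alpha, df_within = aov_row$df_within,
    ms_within = aov_row$ms_within, n_h = n_h
  ))

  # raw non-significance of the contiguous span [i, j]
  nonsig <- function(i, j) {
    if (i == j) return(TRUE)
    # significance requires the observed range to exceed the least
    # significant range; ties at zero range are never significant
    (means[i] - means[j]) <= lsr[j - i + 1] + 1e-12
  }
  # for each start, the widest non-significant span (Duncan's protection:
  # a non-significant wide span shields everything it contains)
  jmax <- vapply(seq_len(k), function(i) {
    js <- i:k
    hits <- js[vapply(js, function(j) nonsig(i, j), logical(1))]
    max(hits)
  }, integer(1))
  # letters = maximal non-significant spans; a span starting later is new
  # only if it reaches beyond everything already lettered
  letters_per_group <- vector("list", k)
  letter_idx <- 0L
  best_cover <- 0L
  for (i in seq_len(k)) {
    j <- jmax[i]
    if (j > best_cover) {
      letter_idx <- letter_idx + 1L
      lab <- make_letter(letter_idx)
      for (g in i:j) {
        letters_per_group[[g]] <- c(letters_per_group[[g]], lab)
      }
      best_cover <- j
    }
  }
  out <- tibble::tibble(
    group = names(groups)[ord],
    mean = unname(means),
    n = unname(ns),
    letters = vapply(letters_per_group, paste, character(1), collapse = "")
  )
  structure(out,
            class = c("duncan_mrt", class(out)),
            alpha = alpha, df_within = aov_row$df_within,
            ms_within = aov_row$ms_within, n_h = n_h, lsr = lsr)
}

# a, b, ..., z, aa, ab, ... for pathological numbers of distinct spans
make_letter <- function(i) {
  out <- ""
  while (i > 0) {
    out <- paste0(letters[(i - 1) %% 26 + 1], out)
    i <- (i - 1) %/% 26
  }
  out
}

#' Summarise an inhibition-zone screen
#'
#' Per (extract, pathogen): replicate count, mean and standard deviation of
#' the zone diameter, Duncan letters computed within each pathogen across
#' extracts, and the rank of each extract by mean zone (1 = widest).
#' Solvent-control rows (matching `control_id`) keep their summaries and
#' letters but are excluded from the ranking. Ties at the top rank are
#' broken lexicographically and flagged via `tied_top`.
#'
#' @param records Data frame with columns `extract_id`, `pathogen_id`,
#'   `replicate`, `zone_mm`.
#' @param alpha Significance level for [duncan_mrt()] (default 0.05).
#' @param control_id Extract label treated as the solvent control
#'   (default `"control"`, matched case-insensitively).
#' @return A tibble with columns `pathogen_id`, `extract_id`, `n`,
#'   `mean_zone`, `sd_zone`, `letters`, `rank`, `is_control`, `tied_top`.
#'   Empty input gives an empty tibble.
#' @export
summarize_zones <- function(records, alpha = 0.05, control_id = "control") {
  required <- c("extract_id", "pathogen_id", "replicate", "zone_mm")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort_schema(paste0("zone table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(
      pathogen_id = character(), extract_id = character(), n = integer(),
      mean_zone = numeric(), sd_zone = numeric(), letters = character(),
      rank = integer(), is_control = logical(), tied_top = logical()
    ))
  }
  if (any(records$zone_mm < 0)) abort_validation("zone_mm must be >= 0")

  summ <- records |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_zone = mean(.data$zone_mm),
      sd_zone = stats::sd(.data$zone_mm),
      .by = c("pathogen_id", "extract_id")
    ) |>
    dplyr::mutate(
      is_control = tolower(.data$extract_id) == tolower(control_id)
    )

  letter_tbl <- records |>
    dplyr::group_by(.data$pathogen_id) |>
    dplyr::group_modify(function(d, key) {
      gl <- split(d$zone_mm, d$extract_id)
      if (length(gl) < 2 || any(lengths(gl) < 2)) {
        return(tibble::tibble(extract_id = names(gl),
                              letters = NA_character_))
      }
      mrt <- duncan_mrt(gl, alpha = alpha)
      tibble::tibble(extract_id = mrt$group, letters = mrt$letters)
    }) |>
    dplyr::ungroup()

  summ |>
    dplyr::left_join(letter_tbl, by = c("pathogen_id", "extract_id")) |>
    dplyr::group_by(.data$pathogen_id) |>
    dplyr::arrange(dplyr::desc(.data$mean_zone), .data$extract_id,
                   .by_group = TRUE) |>
    dplyr::mutate(
      rank = ifelse(.data$is_control, NA_integer_,
                    cumsum(!.data$is_control)),
      tied_top = !.data$is_control & !is.na(.data$rank) &
        .data$mean_zone == max(.data$mean_zone[!.data$is_control])
    ) |>
    dplyr::mutate(tied_top = .data$tied_top & sum(.data$tied_top) > 1) |>
    dplyr::ungroup()
}
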