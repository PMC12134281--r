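#' Consistency checks on a published index table
#'
#' Screens a per-plant table of printed diversity indices for violations of
#' the mathematical constraints the indices must satisfy: Shannon cannot
#' exceed `log(S)`, the Simpson complement cannot exceed `1 - 1/S`,
#' Berger-Parker cannot fall below `1/S`, and Camargo's `1/S` must agree
#' with the stated richness. Printed tables occasionally break these (a
#' symptom of rounding or transcription slips); the checks flag, never fix.
#'
#' @param indices Data frame with columns `plant` and any of `shannon`,
#'   `simpson`, `camargo`, `berger_parker`.
#' @param richness Optional data frame with columns `plant` and
#'   `richness_s` giving the independently known richness per plant.
#' @param tol Slack allowed for rounding of printed values (default 0.01,
#'   about half a unit in the second printed decimal).
#' @return A tibble of violations (`plant`, `check`, `detail`); zero rows
#'   when the table is internally consistent.
#' @examples
#' idx <- readr::read_csv(endo_example("table3_indices.csv"),
#'                        show_col_types = FALSE)
#' rich <- data.frame(plant = "Agathophora alopecuroides", richness_s = 4)
#' check_index_table(idx, rich)
#' @export
check_index_table <- function(indices, richness = NULL, tol = 0.01) {
  if (!("plant" %in% names(indices))) {
    abort_schema("index table needs a 'plant' column")
  }
  indices <- tibble::as_tibble(indices)
  out <- list()
  flag <- function(plant, check, detail) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      plant = plant, check = check, detail = detail
    )
  }
  for (i in seq_len(nrow(indices))) {
    row <- indices[i, ]
    s <- NA_real_
    if (!is.null(richness)) {
      hit <- richness$richness_s[richness$plant == row$plant]
      if (length(hit) == 1) s <- hit
    }
    if (is.na(s) && !is.null(row$camargo) && !is.na(row$camargo) &&
        row$camargo > 0) {
      s <- round(1 / row$camargo)
    }
    if (is.na(s)) next
    if (!is.null(row$shannon) && !is.na(row$shannon) &&
        row$shannon > log(s) + tol) {
      flag(row$plant, "shannon_exceeds_max",
           sprintf("H' = %.3f > log(S = %d) = %.3f", row$shannon, s, log(s)))
    }
    if (!is.null(row$simpson) && !is.na(row$simpson) && s >= 1 &&
        row$simpson > 1 - 1 / s + tol) {
      flag(row$plant, "simpson_exceeds_max",
           sprintf("1-D = %.3f > 1 - 1/%d = %.3f", row$simpson, s, 1 - 1 / s))
    }
    if (!is.null(row$berger_parker) && !is.na(row$berger_parker) && s >= 1 &&
        row$berger_parker < 1 / s - tol) {
      flag(row$plant, "berger_parker_below_min",
           sprintf("BP = %.3f < 1/%d = %.3f", row$berger_parker, s, 1 / s))
    }
    if (!is.null(row$camargo) && !is.na(row$camargo) &&
        !is.null(richness) && !is.na(s) &&
        length(richness$richness_s[richness$plant == row$plant]) == 1 &&
        abs(row$camargo - 1 / s) > tol) {
      flag(row$plant, "camargo_richness_mismatch",
           sprintf("1/S printed %.3f but 1/%d = %.3f", row$camargo, s, 1 / s))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(plant = character(), check = character(),
                          detail = character()))
  }
  dplyr::bind_rows(out)
}

#' Run the full survey analysis pipeline
#'
#' Reads a community table (plus any bioassay tables named in the config),
#' computes the diversity profile, genus and location tallies, tissue
#' overlaps and ordination, runs the index consistency checks, and writes
#' CSV/JSON reports to an output directory. Outputs are deterministic for
#' fixed inputs and seed; rerunning with the same config reproduces them
#' byte for byte. Invariant violations found in the inputs are reported as
#' warnings in the validation section, never as failures.
#'
#' @param config A named list, or path to a YAML file, with fields:
#'   `isolates` (path, required), `tallies`, `indices_table` (printed
#'   per-plant indices to validate), `plants` (extra plant names forced
#'   into the profile as "no data" rows), `zones`, `dpph`, `mtt` (bioassay
#'   CSV paths), `outdir` (required), `digits` (named list of decimal
#'   places per index), `rounding` (`"half_up"` or `"truncate"`), `alpha`
#'   (Duncan level, default 0.05), `figures` (write PDF figures? default
#'   `FALSE`).
#' @return Invisibly, a tibble manifest of the files written (`file`,
#'   `bytes`), with the validation tibble attached as attribute
#'   `"validation"`.
#' @examples
#' out <- file.path(tempdir(), "endodiv-report")
#' run_pipeline(list(isolates = endo_example("table1_isolates.csv"),
#'                   outdir = out))
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort_io(paste0("config not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$isolates)) abort_schema("config needs 'isolates' path")
  if (is.null(config$outdir)) abort_schema("config needs 'outdir'")
  alpha <- config$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) abort_validation("alpha must be in (0, 1)")
  digits <- utils::modifyList(as.list(default_digits),
                              as.list(config$digits %||% list()))
  rounding <- config$rounding %||% "half_up"
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  ct <- read_community(config$isolates, tallies = config$tallies)
  manifest <- list()
  emit_csv <- function(d, name) {
    path <- file.path(config$outdir, name)
    readr::write_csv(d, path, progress = FALSE)
    manifest[[length(manifest) + 1L]] <<- path
  }
  emit_json <- function(obj, name) {
    path <- file.path(config$outdir, name)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    manifest[[length(manifest) + 1L]] <<- path
  }

  profile <- diversity_profile(
    ct, plants = union(sort(unique(c(ct$isolates$plant, ct$tallies$plant))),
                       config$plants %||% character())
  )
  formatted <- format_diversity_profile(profile, digits = digits,
                                        mode = rounding)
  emit_csv(formatted, "diversity_profile.csv")
  emit_json(formatted, "diversity_profile.json")
  if (nrow(ct$isolates) > 0) {
    emit_csv(genus_tally(ct), "genus_tally.csv")
    emit_csv(location_tally(ct), "location_tally.csv")
    ov <- tissue_overlaps(ct)
    emit_csv(
      dplyr::select(ov$regions, -"species") |>
        dplyr::mutate(union_size = ov$union_size),
      "tissue_overlap_regions.csv"
    )
    if (length(unique(ct$isolates$genus)) >= 2 &&
        length(unique(ct$isolates$tissue)) >= 2) {
      ord <- pca_ordination(ct)
      emit_csv(tidy(ord, "eigenvalues"), "ordination_variance.csv")
      emit_csv(tidy(ord, "scores"), "ordination_scores.csv")
    }
  }
  if (nrow(ct$tallies) > 0) {
    cf <- ct$tallies |>
      dplyr::mutate(cf_percent = colonization_frequency(
        .data$segments_colonized, .data$segments_examined
      ))
    emit_csv(cf, "colonization_frequency.csv")
  }

  if (!is.null(config$zones)) {
    zones <- read_delim_checked(config$zones, "auto")
    emit_csv(summarize_zones(zones, alpha = alpha), "zone_summary.csv")
  }
  if (!is.null(config$dpph)) {
    dpph <- read_delim_checked(config$dpph, "auto")
    emit_csv(summarize_dpph(dpph), "dpph_summary.csv")
  }
  if (!is.null(config$mtt)) {
    mtt <- read_delim_checked(config$mtt, "auto")
    fits <- fit_mtt(mtt)
    emit_csv(dplyr::select(fits, -"fit"), "dose_response_ic50.csv")
  }

  validation <- tibble::tibble(plant = character(), check = character(),
                               detail = character())
  if (!is.null(config$indices_table)) {
    printed <- read_delim_checked(config$indices_table, "auto")
    rich <- profile |>
      dplyr::filter(!.data$no_data) |>
      dplyr::select("plant", "richness_s")
    validation <- check_index_table(printed, richness = rich)
    if (nrow(validation) > 0) {
      rlang::warn(sprintf(
        "index table: %d invariant violation(s); see validation.json",
        nrow(validation)
      ), class = "endodiv_invariant_violation")
    }
  }
  emit_json(validation, "validation.json")

  files <- unlist(manifest)
  res <- tibble::tibble(file = files, bytes = file.size(files))
  attr(res, "validation") <- validation
  invisible(res)
}
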