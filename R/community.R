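#' Assemble and validate a community table
#'
#' The community table is the unit every diversity operation consumes: a
#' long-format inventory of morphospecies observed per plant tissue
#' (one row per plant x tissue x morphospecies, with a colony count) plus an
#' optional table of segment tallies (how many surface-sterilised tissue
#' segments were examined and how many yielded at least one endophyte),
#' which feed colonization-frequency percentages.
#'
#' Isolate columns: `plant`, `location` (`"PAWD"` or `"NCAH"`), `tissue`
#' (`"flower"`, `"leaf"`, `"stem"`, `"root"`), `morphospecies`, `genus`
#' (the marker `"unclassified"` flags sterile, unidentifiable mycelia),
#' `colony_count` (non-negative integer; zero-count rows are kept but never
#' contribute to richness). Optional `phylum` and `class_name` default to
#' `"unknown"`. Tally columns: `plant`, `tissue`, `segments_examined` (> 0),
#' `segments_colonized` (between 0 and `segments_examined`).
#'
#' @param isolates Data frame of isolate records.
#' @param tallies Optional data frame of segment tallies.
#' @param provenance Free-text note on where the records came from.
#' @return An object of class `community_table`: a list with tibbles
#'   `$isolates` and `$tallies` and the `$provenance` string.
#' @seealso [read_community()], [diversity_profile()]
#' @examples
#' ct <- community_table(data.frame(
#'   plant = "P1", location = "PAWD", tissue = "leaf",
#'   morphospecies = c("Aspergillus sp.1", "Fusarium sp.1"),
#'   genus = c("Aspergillus", "Fusarium"), colony_count = c(3, 1)
#' ))
#' ct
#' @export
community_table <- function(isolates, tallies = NULL, provenance = "in-memory") {
  isolates <- validate_isolates(isolates)
  tallies <- validate_tallies(tallies)
  structure(
    list(isolates = isolates, tallies = tallies, provenance = provenance),
    class = "community_table"
  )
}

validate_isolates <- function(isolates) {
  if (is.null(isolates)) {
    isolates <- tibble::tibble(
      plant = character(), location = character(), tissue = character(),
      morphospecies = character(), genus = character(),
      colony_count = integer()
    )
  }
  isolates <- tibble::as_tibble(isolates)
  required <- c("plant", "location", "tissue", "morphospecies", "genus",
                "colony_count")
  missing <- setdiff(required, names(isolates))
  if (length(missing) > 0) {
    abort_schema(paste0(
      "isolate table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (!("phylum" %in% names(isolates))) isolates$phylum <- "unknown"
  if (!("class_name" %in% names(isolates))) isolates$class_name <- "unknown"

  isolates <- isolates |>
    dplyr::mutate(
      plant = squish(.data$plant),
      location = squish(.data$location),
      tissue = squish(.data$tissue),
      morphospecies = squish(.data$morphospecies),
      genus = squish(.data$genus),
      phylum = squish(.data$phylum),
      class_name = squish(.data$class_name),
      classified = .data$genus != "unclassified"
    )

  if (nrow(isolates) > 0) {
    bad_loc <- setdiff(unique(isolates$location), endo_locations)
    if (length(bad_loc) > 0) {
      abort_validation(paste0(
        "unknown location code(s): ", paste(bad_loc, collapse = ", "),
        " (expected ", paste(endo_locations, collapse = " or "), ")"
      ))
    }
    bad_tis <- setdiff(unique(isolates$tissue), endo_tissues)
    if (length(bad_tis) > 0) {
      abort_validation(paste0(
        "unknown tissue value(s): ", paste(bad_tis, collapse = ", "),
        " (expected one of ", paste(endo_tissues, collapse = ", "), ")"
      ))
    }
    if (any(is.na(isolates$colony_count)) || any(isolates$colony_count < 0)) {
      abort_validation("colony_count must be a non-negative integer")
    }
    if (any(isolates$colony_count != floor(isolates$colony_count))) {
      abort_validation("colony_count must be a whole number")
    }
    dup <- isolates |>
      dplyr::count(.data$plant, .data$tissue, .data$morphospecies) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort_validation(paste0(
        "duplicated (plant, tissue, morphospecies) triple(s): ",
        paste(paste(dup$plant, dup$tissue, dup$morphospecies, sep = " / "),
              collapse = "; ")
      ))
    }
    # one morphospecies must not carry two conflicting genus labels
    conf <- isolates |>
      dplyr::distinct(.data$morphospecies, .data$genus) |>
      dplyr::count(.data$morphospecies) |>
      dplyr::filter(.data$n > 1)
    if (nrow(conf) > 0) {
      abort_validation(paste0(
        "morphospecies mapped to more than one genus: ",
        paste(conf$morphospecies, collapse = ", ")
      ))
    }
  }
  isolates$colony_count <- as.integer(isolates$colony_count)
  isolates
}

validate_tallies <- function(tallies) {
  if (is.null(tallies)) {
    return(tibble::tibble(
      plant = character(), tissue = character(),
      segments_examined = integer(), segments_colonized = integer()
    ))
  }
  tallies <- tibble::as_tibble(tallies)
  required <- c("plant", "tissue", "segments_examined", "segments_colonized")
  missing <- setdiff(required, names(tallies))
  if (length(missing) > 0) {
    abort_schema(paste0(
      "tally table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  tallies <- tallies |>
    dplyr::mutate(plant = squish(.data$plant), tissue = squish(.data$tissue))
  if (nrow(tallies) > 0) {
    bad_tis <- setdiff(unique(tallies$tissue), endo_tissues)
    if (length(bad_tis) > 0) {
      abort_validation(paste0("unknown tissue value(s) in tallies: ",
                              paste(bad_tis, collapse = ", ")))
    }
    if (any(tallies$segments_examined <= 0)) {
      abort_validation("segments_examined must be positive")
    }
    if (any(tallies$segments_colonized < 0 |
              tallies$segments_colonized > tallies$segments_examined)) {
      abort_validation(
        "segments_colonized must lie between 0 and segments_examined"
      )
    }
    dup <- tallies |>
      dplyr::count(.data$plant, .data$tissue) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort_validation(paste0(
        "duplicated (plant, tissue) tally pair(s): ",
        paste(paste(dup$plant, dup$tissue, sep = " / "), collapse = "; ")
      ))
    }
  }
  tallies$segments_examined <- as.integer(tallies$segments_examined)
  tallies$segments_colonized <- as.integer(tallies$segments_colonized)
  tallies
}

#' @export
print.community_table <- function(x, ...) {
  cat("<community_table> ", nrow(x$isolates), " isolate record(s), ",
      nrow(x$tallies), " segment tally row(s)\n", sep = "")
  cat("provenance: ", x$provenance, "\n", sep = "")
  if (nrow(x$isolates) > 0) {
    cat("plants: ", paste(sort(unique(x$isolates$plant)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read a community table from delimited files
#'
#' Reads the long-format isolate inventory (and optionally a sibling segment
#' tally file) and returns a validated [community_table()]. Row order never
#' affects downstream results.
#'
#' @param path Path to the isolate CSV/TSV (header columns `plant`,
#'   `location`, `tissue`, `morphospecies`, `genus`, `colony_count`; optional
#'   `phylum`, `class_name`).
#' @param tallies Optional path to a tally CSV/TSV (`plant`, `tissue`,
#'   `segments_examined`, `segments_colonized`).
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return A `community_table`.
#' @examples
#' ct <- read_community(endo_example("table1_isolates.csv"))
#' nrow(ct$isolates)
#' @export
read_community <- function(path, tallies = NULL,
                           format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  iso <- read_delim_checked(path, format)
  tal <- if (!is.null(tallies)) read_delim_checked(tallies, format) else NULL
  community_table(iso, tal, provenance = path)
}

read_delim_checked <- function(path, format) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  reader(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a community table to delimited files
#'
#' Inverse of [read_community()]: writing then re-reading any valid table
#' reproduces it field by field.
#'
#' @param x A `community_table`.
#' @param path Output path for the isolate records.
#' @param tallies_path Optional output path for the segment tallies.
#' @return `x`, invisibly.
#' @export
write_community <- function(x, path, tallies_path = NULL) {
  stopifnot(inherits(x, "community_table"))
  readr::write_csv(x$isolates, path, progress = FALSE)
  if (!is.null(tallies_path)) {
    readr::write_csv(x$tallies, tallies_path, progress = FALSE)
  }
  invisible(x)
}

#' Count isolate records per genus
#'
#' Tallies morphospecies records by genus. With
#' `include_unclassified = FALSE`, records whose genus is the marker
#' `"unclassified"` (sterile mycelia that never sporulated) are dropped,
#' leaving only named genera.
#'
#' @param x A `community_table`.
#' @param include_unclassified Keep unclassified records? Default `TRUE`.
#' @return A tibble with columns `genus` and `n_records`, sorted by
#'   decreasing count then genus.
#' @examples
#' ct <- read_community(endo_example("table1_isolates.csv"))
#' genus_tally(ct, include_unclassified = FALSE)
#' @export
genus_tally <- function(x, include_unclassified = TRUE) {
  stopifnot(inherits(x, "community_table"))
  iso <- x$isolates
  if (!include_unclassified) iso <- dplyr::filter(iso, .data$classified)
  iso |>
    dplyr::count(.data$genus, name = "n_records") |>
    dplyr::arrange(dplyr::desc(.data$n_records), .data$genus)
}

#' Count isolate records per sampling location
#'
#' @param x A `community_table`.
#' @return A tibble with columns `location` and `n_records`; the counts sum
#'   to the total number of isolate records.
#' @examples
#' ct <- read_community(endo_example("table1_isolates.csv"))
#' location_tally(ct)
#' @export
location_tally <- function(x) {
  stopifnot(inherits(x, "community_table"))
  x$isolates |>
    dplyr::count(.data$location, name = "n_records") |>
    dplyr::arrange(dplyr::desc(.data$n_records), .data$location)
}

#' Path to a packaged example data file
#'
#' The package ships small plain-text fixtures: `table1_isolates.csv` (the
#' published isolate inventory, one colony per record), `table2_cf.csv`
#' (published per-tissue colonization frequencies),
#' `table3_indices.csv` (published per-plant diversity indices) and
#' `reconstructed_abundances.csv` (integer abundance vectors recovered by
#' [reconstruct_abundances()] from the rounded published indices; the
#' `matched_indices` column records which printed values each plant's vector
#' reproduces).
#'
#' @param file File name; with no argument, lists available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' endo_example()
#' @export
endo_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "endodiv")))
  }
  path <- system.file("extdata", file, package = "endodiv")
  if (path == "") abort_io(paste0("no packaged file named ", file))
  path
}
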