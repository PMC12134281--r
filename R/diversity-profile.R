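#' Per-plant abundance vectors
#'
#' Sums colony counts per morphospecies within each plant (across tissues)
#' and returns one abundance vector per plant. Zero-count records are
#' excluded, so they contribute neither to richness nor abundance.
#'
#' @param x A `community_table`.
#' @return A tibble with columns `plant` and `abundances` (a list column of
#'   named integer vectors, sorted decreasing).
#' @export
abundance_vectors <- function(x) {
  stopifnot(inherits(x, "community_table"))
  x$isolates |>
    dplyr::filter(.data$colony_count > 0) |>
    dplyr::summarise(
      colony_count = sum(.data$colony_count),
      .by = c("plant", "morphospecies")
    ) |>
    dplyr::arrange(.data$plant, dplyr::desc(.data$colony_count),
                   .data$morphospecies) |>
    tidyr::nest(.by = "plant", .key = "records") |>
    dplyr::mutate(abundances = purrr::map(.data$records, function(d) {
      stats::setNames(d$colony_count, d$morphospecies)
    })) |>
    dplyr::select("plant", "abundances")
}

#' Per-plant diversity profile
#'
#' Assembles, for every plant (or a chosen subset), total abundance `N`,
#' richness `S`, Shannon `H'` (nats), Simpson complement, Camargo `1/S`,
#' Berger-Parker dominance and evenness `H'/log(S)`. Values are stored at
#' full precision; use [format_diversity_profile()] to apply the per-index
#' rounding convention of a published table. Plants named in `plants` that
#' have no positive-count record are reported as "no data" rows
#' (`no_data = TRUE`, all indices `NA`) rather than as zero diversity.
#'
#' @param x A `community_table`.
#' @param plants Optional character vector of plants to report (and to force
#'   into the output even when they have no isolates). Default: every plant
#'   present in the isolate or tally records.
#' @return A tibble of class `diversity_profile` with one row per plant:
#'   `plant`, `abundance_n`, `richness_s`, `shannon`, `simpson`, `camargo`,
#'   `berger_parker`, `evenness`, `no_data`.
#' @examples
#' ct <- read_community(endo_example("reconstructed_abundances.csv"))
#' diversity_profile(ct)
#' @export
diversity_profile <- function(x, plants = NULL) {
  stopifnot(inherits(x, "community_table"))
  av <- abundance_vectors(x)
  all_plants <- union(av$plant, x$tallies$plant)
  if (is.null(plants)) {
    plants <- sort(all_plants)
  } else {
    # plants absent from the records are reported as "no data" rows
    plants <- squish(plants)
  }
  rows <- purrr::map(plants, function(p) {
    v <- av$abundances[av$plant == p]
    if (length(v) == 0) {
      return(tibble::tibble(
        plant = p, abundance_n = NA_integer_, richness_s = NA_integer_,
        shannon = NA_real_, simpson = NA_real_, camargo = NA_real_,
        berger_parker = NA_real_, evenness = NA_real_, no_data = TRUE
      ))
    }
    v <- v[[1]]
    s <- length(v)
    tibble::tibble(
      plant = p,
      abundance_n = sum(v),
      richness_s = s,
      shannon = shannon_index(v),
      simpson = simpson_complement(v),
      camargo = camargo_index(s),
      berger_parker = berger_parker_index(v),
      evenness = evenness_index(shannon_index(v), s),
      no_data = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("diversity_profile", class(out))
  out
}

#' Format a diversity profile like a published index table
#'
#' Applies per-index decimal places (and a rounding mode) to the
#' full-precision columns of [diversity_profile()].
#'
#' @param profile A `diversity_profile`.
#' @param digits Named vector of decimal places per index; defaults to
#'   `c(shannon = 2, simpson = 3, camargo = 3, berger_parker = 2,
#'   evenness = 3)`.
#' @param mode Rounding convention, `"half_up"` or `"truncate"`; see
#'   [round_fixed()].
#' @return A tibble with the same rows, index columns rounded; "no data"
#'   rows keep `NA`.
#' @export
format_diversity_profile <- function(profile, digits = default_digits,
                                     mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  digits <- utils::modifyList(as.list(default_digits), as.list(digits))
  out <- tibble::as_tibble(profile)
  for (col in c("shannon", "simpson", "camargo", "berger_parker", "evenness")) {
    out[[col]] <- ifelse(
      is.na(out[[col]]), NA_real_,
      round_fixed(out[[col]], digits[[col]], mode)
    )
  }
  out
}

#' Species sets and overlap regions across tissues
#'
#' Computes the set of morphospecies recovered from each tissue and the
#' cardinality of every region of the resulting Venn partition (all
#' `2^k - 1` membership patterns over the tissues present). Region sizes sum
#' to the size of the union.
#'
#' @param x A `community_table`.
#' @return An object of class `tissue_overlaps`: list with `$sets` (named
#'   list of species-id vectors per tissue), `$regions` (tibble with one
#'   logical column per tissue, `size` and a `species` list column) and
#'   `$union_size`.
#' @examples
#' ct <- read_community(endo_example("table1_isolates.csv"))
#' tissue_overlaps(ct)$regions
#' @export
tissue_overlaps <- function(x) {
  stopifnot(inherits(x, "community_table"))
  iso <- dplyr::filter(x$isolates, .data$colony_count > 0)
  tissues <- intersect(endo_tissues, unique(iso$tissue))
  sets <- purrr::map(
    stats::setNames(tissues, tissues),
    function(t) sort(unique(iso$morphospecies[iso$tissue == t]))
  )
  universe <- sort(unique(iso$morphospecies))
  membership <- purrr::map(sets, function(s) universe %in% s)
  if (length(tissues) == 0) {
    regions <- tibble::tibble(size = integer(), species = list())
  } else {
    patterns <- tidyr::expand_grid(
      !!!stats::setNames(rep(list(c(TRUE, FALSE)), length(tissues)), tissues)
    ) |>
      dplyr::filter(dplyr::if_any(dplyr::all_of(tissues)))
    regions <- patterns |>
      dplyr::mutate(species = purrr::pmap(
        patterns,
        function(...) {
          want <- c(...)
          keep <- rep(TRUE, length(universe))
          for (t in tissues) {
            keep <- keep & (membership[[t]] == want[[t]])
          }
          universe[keep]
        }
      )) |>
      dplyr::mutate(size = lengths(.data$species), .before = "species")
  }
  structure(
    list(sets = sets, regions = regions, union_size = length(universe)),
    class = "tissue_overlaps"
  )
}

#' @export
print.tissue_overlaps <- function(x, ...) {
  cat("<tissue_overlaps> union of", x$union_size, "morphospecies across",
      length(x$sets), "tissue(s)\n")
  sizes <- vapply(x$sets, length, integer(1))
  cat(paste0("  ", names(sizes), ": ", sizes, collapse = "\n"), "\n")
  invisible(x)
}

#' Reconstruct integer abundance vectors from rounded published indices
#'
#' Published diversity tables print rounded index values but rarely the
#' underlying abundance vectors. This enumerates every non-increasing
#' positive integer vector of length `richness_s` whose total lies in
#' `n_range`, scores each with [shannon_index()], [simpson_complement()] and
#' [berger_parker_index()], rounds per the stated convention and keeps the
#' vectors that reproduce every supplied target. An exhaustive search; with
#' the default `n_range` of 1..30 it runs in milliseconds.
#'
#' @param richness_s Species richness (length of the vectors).
#' @param targets Named list/vector of rounded printed values; any subset of
#'   `shannon`, `simpson`, `berger_parker`.
#' @param n_range Integer vector of admissible totals `N` (default `1:30`).
#' @param digits Named decimal places used when rounding computed indices
#'   before comparison (default `c(shannon = 2, simpson = 3,
#'   berger_parker = 2)`).
#' @param mode Rounding convention for the comparison; see [round_fixed()].
#' @return A tibble with columns `n` (total abundance) and `abundances`
#'   (list of non-increasing integer vectors), deduplicated and sorted by
#'   `n`; zero rows when no vector is consistent with the targets.
#' @examples
#' reconstruct_abundances(
#'   8, list(shannon = 1.79, simpson = 0.789, berger_parker = 0.35),
#'   n_range = 1:20
#' )
#' @export
reconstruct_abundances <- function(richness_s, targets, n_range = 1:30,
                                   digits = c(shannon = 2, simpson = 3,
                                              berger_parker = 2),
                                   mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  if (length(n_range) == 0) abort_validation("n_range must be non-empty")
  if (richness_s < 1) abort_undefined("richness_s must be >= 1")
  targets <- as.list(targets)
  bad <- setdiff(names(targets), c("shannon", "simpson", "berger_parker"))
  if (length(bad) > 0) {
    abort_validation(paste0("unknown target name(s): ",
                            paste(bad, collapse = ", ")))
  }
  digits <- utils::modifyList(
    list(shannon = 2, simpson = 3, berger_parker = 2), as.list(digits)
  )
  scorers <- list(shannon = shannon_index, simpson = simpson_complement,
                  berger_parker = berger_parker_index)
  hits <- list()
  ns <- integer()
  for (n in sort(unique(as.integer(n_range)))) {
    for (v in partitions_exact(n, richness_s)) {
      ok <- TRUE
      for (nm in names(targets)) {
        got <- round_fixed(scorers[[nm]](v), digits[[nm]], mode)
        if (abs(got - targets[[nm]]) > 1e-9) { ok <- FALSE; break }
      }
      if (ok) {
        hits[[length(hits) + 1L]] <- as.integer(v)
        ns <- c(ns, n)
      }
    }
  }
  keep <- !duplicated(purrr::map_chr(hits, paste, collapse = ","))
  tibble::tibble(n = ns[keep], abundances = hits[keep]) |>
    dplyr::arrange(.data$n)
}

# All partitions of n into exactly k positive non-increasing parts, each
# part <= maxp. Returned as a list of integer vectors.
partitions_exact <- function(n, k, maxp = n) {
  if (k == 0) {
    if (n == 0) return(list(integer(0)))
    return(list())
  }
  if (n < k) return(list())
  out <- list()
  for (p in seq(min(n - k + 1, maxp), 1)) {
    for (rest in partitions_exact(n - p, k - 1, p)) {
      out[[length(out) + 1L]] <- c(p, rest)
    }
  }
  out
}

#' Principal component ordination of the genus-by-tissue count matrix
#'
#' Builds the genus x tissue colony-count matrix, centres each tissue column
#' (no scaling: all entries share the same count units) and extracts
#' principal components. Component signs follow a deterministic convention:
#' within each component the loading of largest magnitude is made positive,
#' so figures are reproducible run to run.
#'
#' @param x A `community_table`.
#' @param include_unclassified Include the `"unclassified"` genus row?
#'   Default `TRUE`.
#' @return Object of class `endo_ordination`: list with `$scores` (tibble,
#'   genus x component), `$loadings` (tibble, tissue x component),
#'   `$var_explained` (non-increasing fractions summing to <= 1) and
#'   `$matrix` (the raw count matrix).
#' @examples
#' ct <- read_community(endo_example("table1_isolates.csv"))
#' pca_ordination(ct)$var_explained
#' @export
pca_ordination <- function(x, include_unclassified = TRUE) {
  stopifnot(inherits(x, "community_table"))
  iso <- dplyr::filter(x$isolates, .data$colony_count > 0)
  if (!include_unclassified) iso <- dplyr::filter(iso, .data$classified)
  wide <- iso |>
    dplyr::summarise(n = sum(.data$colony_count),
                     .by = c("genus", "tissue")) |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "n",
                       values_fill = 0L)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$genus
  mat <- mat[, intersect(endo_tissues, colnames(mat)), drop = FALSE]
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    abort_undefined("need at least 2 genera and 2 tissues for ordination")
  }
  if (all(apply(mat, 2, stats::var) == 0)) {
    rlang::abort("genus x tissue matrix is constant in every column",
                 class = "endodiv_degenerate_input")
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = tibble::as_tibble(pc$x, rownames = "genus"),
      loadings = tibble::as_tibble(pc$rotation, rownames = "tissue"),
      var_explained = ve,
      matrix = mat
    ),
    class = "endo_ordination"
  )
}

#' @export
print.endo_ordination <- function(x, ...) {
  cat("<endo_ordination> ", nrow(x$scores), " genera x ",
      nrow(x$loadings), " tissues\n", sep = "")
  cat("variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}
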