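# Scalar/vector alpha-diversity statistics. All abundance-vector functions
# drop zero entries, are permutation invariant, and are invariant to uniform
# scaling of the vector.

check_abundances <- function(x) {
  if (length(x) == 0 || all(is.na(x))) {
    abort_undefined("abundance vector is empty")
  }
  if (any(is.na(x)) || any(x < 0)) {
    abort_validation("abundances must be non-negative and non-missing")
  }
  x <- x[x > 0]
  if (length(x) == 0) {
    abort_undefined("abundance vector has no positive entries")
  }
  x
}

#' Occurrence percentage of a species
#'
#' A species' colony count as a percentage of all colonies isolated in the
#' study. Over all species of one study the values sum to 100.
#'
#' @param species_count Non-negative colony count for the species.
#' @param total_count Positive total colony count of the study.
#' @return `100 * species_count / total_count`, vectorised over
#'   `species_count`.
#' @examples
#' occurrence_percent(3, 12)
#' @export
occurrence_percent <- function(species_count, total_count) {
  if (any(total_count <= 0)) {
    abort_undefined("total_count must be positive")
  }
  if (any(species_count < 0) || any(species_count > total_count)) {
    abort_validation("need 0 <= species_count <= total_count")
  }
  100 * species_count / total_count
}

#' Colonization frequency percentage
#'
#' Percentage of surface-sterilised tissue segments that yielded at least one
#' endophyte colony.
#'
#' @param colonized Number of colonized segments (0..`examined`).
#' @param examined Number of segments examined (> 0).
#' @param digits Decimal places for the returned percentage (default 1, the
#'   usual reporting convention); use `NULL` for full precision.
#' @return `100 * colonized / examined`, rounded half-up to `digits`.
#' @examples
#' colonization_frequency(9, 36)
#' @export
colonization_frequency <- function(colonized, examined, digits = 1) {
  if (any(examined <= 0)) abort_undefined("examined must be positive")
  if (any(colonized < 0) || any(colonized > examined)) {
    abort_validation("need 0 <= colonized <= examined")
  }
  cf <- 100 * colonized / examined
  if (!is.null(digits)) cf <- round_fixed(cf, digits)
  cf
}

#' Shannon-Wiener diversity
#'
#' Entropy of the relative-abundance distribution in nats
#' (natural logarithm): `H' = -sum(p_i log p_i)` with `p_i = n_i / N`.
#' Bounded above by `log(S)`, attained exactly at perfect evenness.
#'
#' @param abundances Vector of non-negative counts; zeros are dropped.
#' @return `H'` in nats.
#' @examples
#' shannon_index(c(6, 4, 2, 1, 1, 1, 1, 1)) # 1.7931
#' @export
shannon_index <- function(abundances) {
  x <- check_abundances(abundances)
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Simpson complement
#'
#' `1 - sum(p_i^2)`: the probability that two randomly drawn isolates belong
#' to different species. Zero for a single species; `1 - 1/S` at perfect
#' evenness. (Some tables label the same quantity "1 - D".)
#'
#' @inheritParams shannon_index
#' @return Value in `[0, 1 - 1/S]`.
#' @examples
#' simpson_complement(c(2, 1, 1)) # 0.625
#' @export
simpson_complement <- function(abundances) {
  x <- check_abundances(abundances)
  p <- x / sum(x)
  1 - sum(p^2)
}

#' Camargo's index as reciprocal richness
#'
#' Implemented literally as `1/S`, the convention used alongside the other
#' indices here (not Camargo's original evenness statistic).
#'
#' @param richness_s Species richness, a positive integer.
#' @return `1 / richness_s`.
#' @examples
#' camargo_index(8)
#' @export
camargo_index <- function(richness_s) {
  if (any(richness_s < 1)) abort_undefined("richness must be >= 1")
  1 / richness_s
}

#' Berger-Parker dominance
#'
#' Relative abundance of the single most abundant species,
#' `max(n_i) / N`. Always at least `1/S`, with equality exactly at perfect
#' evenness.
#'
#' @inheritParams shannon_index
#' @return Value in `[1/S, 1]`.
#' @examples
#' berger_parker_index(c(6, 4, 2, 1, 1, 1, 1, 1)) # 0.3529
#' @export
berger_parker_index <- function(abundances) {
  x <- check_abundances(abundances)
  max(x) / sum(x)
}

#' Species evenness
#'
#' Shannon entropy scaled to `[0, 1]`: `E = H' / log(S)`. Undefined for
#' `S < 2` (a single species has no evenness); a typed `NA` is returned
#' rather than an error so profile tables stay rectangular.
#'
#' @param shannon_h Shannon index in nats.
#' @param richness_s Species richness.
#' @return `H' / log(S)`, or `NA_real_` when `richness_s < 2`.
#' @examples
#' evenness_index(1.79, 8) # 0.8608 -> prints as 0.861
#' @export
evenness_index <- function(shannon_h, richness_s) {
  if (any(shannon_h < 0, na.rm = TRUE)) {
    abort_validation("shannon_h must be non-negative")
  }
  out <- shannon_h / log(richness_s)
  out[richness_s < 2] <- NA_real_
  out
}
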