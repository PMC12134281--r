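# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Fixed-convention rounding used when comparing computed indices against
#' published tables. Base `round()` rounds half to even, which disagrees with
#' the half-up convention most printed tables use (e.g. 0.125 -> 0.13).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @param mode `"half_up"` (default) or `"truncate"` (drop digits beyond
#'   `digits`, the convention behind printed values like 1/6 -> 0.16).
#' @return Numeric vector rounded per `mode`.
#' @examples
#' round_fixed(0.125, 2)            # 0.13
#' round_fixed(1 / 6, 2, "truncate") # 0.16
#' @export
round_fixed <- function(x, digits, mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  scale <- 10^digits
  # epsilon guards against 0.35 stored as 0.34999999...
  eps <- 1e-9
  if (mode == "half_up") {
    sign(x) * floor(abs(x) * scale + 0.5 + eps) / scale
  } else {
    sign(x) * floor(abs(x) * scale + eps) / scale
  }
}

# Fixed vocabularies of the data model.
endo_tissues <- c("flower", "leaf", "stem", "root")
endo_locations <- c("PAWD", "NCAH")

# Default decimal places per index, matching the mixed precision of the
# published table layout (Shannon 2 dp, Simpson complement 3 dp, ...).
default_digits <- c(
  shannon = 2, simpson = 3, camargo = 3, berger_parker = 2, evenness = 3
)

abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "endodiv_schema_error", ...)
}
abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "endodiv_validation_error", ...)
}
abort_undefined <- function(msg, ...) {
  rlang::abort(msg, class = "endodiv_undefined_input", ...)
}
abort_io <- function(msg, ...) {
  rlang::abort(msg, class = "endodiv_io_error", ...)
}

# Collapse whitespace runs and trim; labels are compared after this
# normalization (case-sensitive).
squish <- function(x) gsub("\\s+", " ", trimws(x))
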