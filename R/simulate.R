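# Seeded generators. Each is a pure function of its parameters and seed:
# the RNG state is scoped with withr::with_seed so no generator touches the
# caller's random stream.

species_probs <- function(species_pool, abundance_model, model_param) {
  switch(abundance_model,
    even = rep(1 / species_pool, species_pool),
    geometric = {
      if (model_param <= 0 || model_param >= 1) {
        abort_validation("geometric ratio must lie in (0, 1)")
      }
      p <- model_param^(seq_len(species_pool) - 1)
      p / sum(p)
    },
    log_series = {
      if (model_param <= 0) abort_validation("log-series alpha must be > 0")
      x <- model_param / (1 + model_param)
      p <- x^seq_len(species_pool) / seq_len(species_pool)
      p / sum(p)
    },
    abort_validation(paste0("unknown abundance model: ", abundance_model))
  )
}

#' Simulate a multi-plant, multi-tissue endophyte community
#'
#' Emulates the sampling design of a culture-based endophyte survey: per
#' plant and tissue, the number of colonized segments is drawn
#' `Binomial(segments_per_tissue, p_tissue)`, and each colonized segment
#' yields one colony whose species identity is drawn from a skewed (or
#' even) species-abundance distribution over a fixed pool. Species are
#' grouped three-per-genus so genus-level summaries and ordination have
#' structure to find. The returned table always passes
#' [community_table()] validation.
#'
#' @param n_plants Number of plants (default 9).
#' @param tissues Tissues sampled per plant (subset of flower, leaf, stem,
#'   root; default all four).
#' @param species_pool Number of species in the regional pool (default 20).
#' @param abundance_model `"geometric"` (relative abundance proportional to
#'   `ratio^(k-1)`), `"log_series"` (proportional to `x^k / k` with
#'   `x = alpha / (1 + alpha)`), or `"even"`.
#' @param model_param Ratio of the geometric model (default 0.7) or alpha
#'   of the log-series.
#' @param segments_per_tissue Segments examined per plant x tissue
#'   (default 12).
#' @param colonization_p Per-tissue colonization probability: a single
#'   value or a vector named by tissue (default 0.3).
#' @param seed Integer seed; the same seed always reproduces the same
#'   table.
#' @return A `community_table`.
#' @examples
#' sim <- simulate_community(n_plants = 3, seed = 1)
#' diversity_profile(sim)
#' @export
simulate_community <- function(n_plants = 9,
                               tissues = endo_tissues,
                               species_pool = 20,
                               abundance_model = c("geometric", "log_series",
                                                   "even"),
                               model_param = 0.7,
                               segments_per_tissue = 12,
                               colonization_p = 0.3,
                               seed = 1) {
  abundance_model <- match.arg(abundance_model)
  if (n_plants < 1) abort_validation("n_plants must be >= 1")
  if (species_pool < 1) abort_validation("species_pool must be >= 1")
  if (segments_per_tissue < 1) {
    abort_validation("segments_per_tissue must be >= 1")
  }
  tissues <- match.arg(tissues, endo_tissues, several.ok = TRUE)
  if (length(colonization_p) == 1 && is.null(names(colonization_p))) {
    colonization_p <- stats::setNames(rep(colonization_p, length(tissues)),
                                      tissues)
  }
  if (!all(tissues %in% names(colonization_p))) {
    abort_validation("colonization_p must cover every sampled tissue")
  }
  if (any(colonization_p < 0 | colonization_p > 1)) {
    abort_validation("colonization probabilities must lie in [0, 1]")
  }
  probs <- species_probs(species_pool, abundance_model, model_param)
  species <- sprintf("Species sp.%d", seq_len(species_pool))
  genus <- sprintf("Genus%d", (seq_len(species_pool) - 1) %/% 3 + 1)
  plants <- sprintf("Plant%02d", seq_len(n_plants))
  # deterministic location assignment, roughly 3:1 like a two-area survey
  locs <- ifelse(seq_len(n_plants) %% 4 == 0, "NCAH", "PAWD")

  withr::with_seed(seed, {
    iso <- list()
    tal <- list()
    for (i in seq_len(n_plants)) {
      for (t in tissues) {
        colonized <- stats::rbinom(1, segments_per_tissue,
                                   colonization_p[[t]])
        tal[[length(tal) + 1L]] <- tibble::tibble(
          plant = plants[i], tissue = t,
          segments_examined = segments_per_tissue,
          segments_colonized = colonized
        )
        if (colonized > 0) {
          idx <- sample.int(species_pool, colonized, replace = TRUE,
                            prob = probs)
          cnt <- table(idx)
          ks <- as.integer(names(cnt))
          iso[[length(iso) + 1L]] <- tibble::tibble(
            plant = plants[i], location = locs[i], tissue = t,
            morphospecies = species[ks], genus = genus[ks],
            phylum = "unknown", class_name = "unknown",
            colony_count = as.integer(cnt)
          )
        }
      }
    }
    community_table(
      if (length(iso) > 0) dplyr::bind_rows(iso) else NULL,
      dplyr::bind_rows(tal),
      provenance = sprintf("simulate_community(seed = %d)", seed)
    )
  })
}

#' Simulate an MTT dose-response plate
#'
#' Samples viability from a four-parameter logistic curve with
#' multiplicative Gaussian noise, `v = 4PL(c) * (1 + e)`,
#' `e ~ N(0, noise_sd_pct / 100)`, then back-computes well absorbances
#' against a fixed untreated absorbance so that [viability_percent()]
#' round-trips the sampled viability exactly at zero noise. The curve is
#' parameterised by its 50%-crossing `true_ic50` (which requires
#' `true_lower < 50 < true_upper`).
#'
#' @param true_lower,true_upper Asymptotic viabilities in percent
#'   (defaults 0 and 100).
#' @param true_hill Hill slope (default 1; positive = viability falls with
#'   dose).
#' @param true_ic50 Concentration at 50% viability (default 41.75).
#' @param concentrations Concentration series (default
#'   `c(1, 5, 25, 50, 125, 250, 500)`, a 1-500 range).
#' @param noise_sd_pct Multiplicative noise standard deviation in percent
#'   of the true viability (default 5).
#' @param replicates Wells per concentration (default 3).
#' @param cell_line Label for the output (default "A549").
#' @param untreated_absorbance Absorbance of the untreated control
#'   (default 0.8).
#' @param seed Integer seed.
#' @return A tibble in MTT format: `cell_line`, `concentration_ug_ml`,
#'   `replicate`, `absorbance`, `untreated_absorbance`.
#' @examples
#' mtt <- simulate_dose_response(noise_sd_pct = 0, seed = 1)
#' fit_mtt(mtt)$ic50
#' @export
simulate_dose_response <- function(true_lower = 0, true_upper = 100,
                                   true_hill = 1, true_ic50 = 41.75,
                                   concentrations = c(1, 5, 25, 50, 125,
                                                      250, 500),
                                   noise_sd_pct = 5, replicates = 3,
                                   cell_line = "A549",
                                   untreated_absorbance = 0.8,
                                   seed = 1) {
  if (true_ic50 <= 0) abort_validation("true_ic50 must be positive")
  if (noise_sd_pct < 0) abort_validation("noise_sd_pct must be >= 0")
  if (replicates < 1) abort_validation("replicates must be >= 1")
  if (any(concentrations <= 0)) {
    abort_validation("concentrations must be positive")
  }
  if (!(min(true_lower, true_upper) < 50 && 50 < max(true_lower, true_upper))) {
    abort_validation("true_ic50 requires 50 between true_lower and true_upper")
  }
  # midpoint such that the 4PL crosses 50% exactly at true_ic50
  ratio <- (true_upper - 50) / (50 - true_lower)
  midpoint <- true_ic50 / ratio^(1 / true_hill)
  grid <- tidyr::expand_grid(
    concentration_ug_ml = sort(concentrations),
    replicate = seq_len(replicates)
  )
  withr::with_seed(seed, {
    v_true <- fpl(grid$concentration_ug_ml, true_lower, true_upper,
                  true_hill, midpoint)
    eps <- stats::rnorm(nrow(grid), 0, noise_sd_pct / 100)
    viability <- v_true * (1 + eps)
    tibble::tibble(
      cell_line = cell_line,
      concentration_ug_ml = grid$concentration_ug_ml,
      replicate = grid$replicate,
      absorbance = viability / 100 * untreated_absorbance,
      untreated_absorbance = untreated_absorbance
    )
  })
}

#' Simulate DPPH absorbance pairs
#'
#' Builds sample/control absorbance pairs whose noise-free
#' [dpph_scavenging()] transform returns the requested scavenging targets
#' exactly: `T = C * (1 - s/100)`, optionally perturbed with additive
#' Gaussian absorbance noise.
#'
#' @param scavenging_pct Target scavenging percentages (each <= 100);
#'   names become sample ids (defaults `S1`, `S2`, ...).
#' @param replicates Replicates per sample (default 3).
#' @param noise_sd Additive absorbance noise SD (default 0).
#' @param control_absorbance Control absorbance `C` (default 0.8).
#' @param seed Integer seed.
#' @return A tibble in DPPH format: `sample_id`, `replicate`,
#'   `absorbance`, `control_absorbance`.
#' @examples
#' rec <- simulate_dpph(c(78.17, 76.8, 75.42, 45.1))
#' summarize_dpph(rec)
#' @export
simulate_dpph <- function(scavenging_pct, replicates = 3, noise_sd = 0,
                          control_absorbance = 0.8, seed = 1) {
  if (any(scavenging_pct > 100)) {
    abort_validation("scavenging targets cannot exceed 100%")
  }
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  if (control_absorbance <= 0) {
    abort_validation("control_absorbance must be positive")
  }
  ids <- names(scavenging_pct)
  if (is.null(ids)) ids <- sprintf("S%d", seq_along(scavenging_pct))
  grid <- tidyr::expand_grid(
    sample_id = ids, replicate = seq_len(replicates)
  ) |>
    dplyr::mutate(target = rep(unname(scavenging_pct),
                               each = replicates))
  withr::with_seed(seed, {
    t_abs <- control_absorbance * (1 - grid$target / 100) +
      stats::rnorm(nrow(grid), 0, noise_sd)
    tibble::tibble(
      sample_id = grid$sample_id,
      replicate = grid$replicate,
      absorbance = pmax(t_abs, 0),
      control_absorbance = control_absorbance
    )
  })
}
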