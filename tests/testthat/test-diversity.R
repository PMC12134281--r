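# Index computations, profiles, overlaps, reconstruction and ordination.

test_that("occurrence percentages behave and conserve to 100", {
  expect_equal(occurrence_percent(3, 12), 25)
  expect_equal(occurrence_percent(0, 12), 0)
  expect_error(occurrence_percent(1, 0), class = "endodiv_undefined_input")
  set.seed(11)
  counts <- rmultinom(1, 200, prob = runif(12))[, 1]
  expect_equal(sum(occurrence_percent(counts, sum(counts))), 100,
               tolerance = 1e-9)
})

test_that("colonization frequency matches the closed form and recovers p", {
  expect_equal(colonization_frequency(9, 36), 25)
  expect_equal(colonization_frequency(0, 36), 0)
  expect_error(colonization_frequency(37, 36),
               class = "endodiv_validation_error")
  # Monte-Carlo: binomial draws recover 100 p within 3 standard errors
  set.seed(42)
  p <- 0.3
  n <- 36
  cf <- colonization_frequency(rbinom(1000, n, p), n, digits = NULL)
  se <- 100 * sqrt(p * (1 - p) / n) / sqrt(1000)
  expect_lt(abs(mean(cf) - 100 * p), 3 * se)
})

test_that("index values match independent references on known vectors", {
  v <- c(6, 4, 2, 1, 1, 1, 1, 1)
  # closed-form oracle
  p <- v / sum(v)
  expect_equal(shannon_index(v), -sum(p * log(p)))
  expect_equal(shannon_index(c(2, 2, 2, 2)), log(4))
  expect_equal(shannon_index(5), 0)
  expect_equal(simpson_complement(c(2, 1, 1)), 0.625)
  expect_equal(simpson_complement(7), 0)
  expect_equal(camargo_index(8), 0.125)
  expect_equal(berger_parker_index(c(5, 5)), 0.5)
  expect_equal(berger_parker_index(c(2, 1, 1)), 0.5)
  expect_equal(evenness_index(log(4), 4), 1)
  expect_equal(evenness_index(0, 5), 0)
  expect_true(is.na(evenness_index(0, 1)))
  # cross-check against vegan on a batch of random vectors
  skip_if_not_installed("vegan")
  set.seed(7)
  for (i in 1:20) {
    x <- sample(1:9, sample(2:8, 1), replace = TRUE)
    expect_equal(shannon_index(x),
                 unname(vegan::diversity(x, index = "shannon")))
    expect_equal(simpson_complement(x),
                 unname(vegan::diversity(x, index = "simpson")))
  }
})

test_that("degenerate abundance inputs raise typed errors", {
  expect_error(shannon_index(c(0, 0)), class = "endodiv_undefined_input")
  expect_error(shannon_index(numeric(0)), class = "endodiv_undefined_input")
  expect_error(simpson_complement(c(0, 0)),
               class = "endodiv_undefined_input")
  expect_error(berger_parker_index(c(-1, 2)),
               class = "endodiv_validation_error")
  expect_error(camargo_index(0), class = "endodiv_undefined_input")
})

test_that("entropy/dominance bounds hold exhaustively with equality iff even", {
  vectors <- oracle_small_vectors(max_s = 5, max_n = 12)
  for (v in vectors) {
    s <- length(v)
    even <- length(unique(v)) == 1
    h <- shannon_index(v)
    expect_lte(h, log(s) + 1e-12)
    expect_equal(h == log(s) || abs(h - log(s)) < 1e-12, even)
    d <- simpson_complement(v)
    expect_lte(d, 1 - 1 / s + 1e-12)
    expect_equal(abs(d - (1 - 1 / s)) < 1e-12, even)
    b <- berger_parker_index(v)
    expect_gte(b, 1 / s - 1e-12)
    expect_equal(abs(b - 1 / s) < 1e-12, even)
  }
})

test_that("indices are invariant to permutation and uniform scaling", {
  set.seed(5)
  for (i in 1:10) {
    v <- sample(1:20, sample(2:8, 1), replace = TRUE)
    perm <- sample(v)
    for (f in list(shannon_index, simpson_complement,
                   berger_parker_index)) {
      expect_equal(f(v), f(perm))
      expect_equal(f(v), f(7 * v))
    }
  }
})

test_that("per-plant profiles reproduce the published rows after rounding", {
  rc <- read_community(endo_example("reconstructed_abundances.csv"))
  prof <- format_diversity_profile(diversity_profile(rc))
  aset <- prof[prof$plant == "Anabasis setifera", ]
  expect_equal(aset$shannon, 1.79)
  expect_equal(aset$simpson, 0.789)
  expect_equal(aset$camargo, 0.125)
  expect_equal(aset$berger_parker, 0.35)
  expect_identical(aset$abundance_n, 17L)
  expect_identical(aset$richness_s, 8L)
  expect_equal(prof$shannon[prof$plant == "Halocnemum strobitaceum"], 1.39)
  expect_equal(prof$shannon[prof$plant == "Suaeda vermiculata"], 1.74)
  expect_equal(prof$simpson[prof$plant == "Lantana camara L"], 0.625)
})

test_that("plants without isolates get a typed no-data profile, not zeros", {
  rc <- read_community(endo_example("reconstructed_abundances.csv"))
  prof <- diversity_profile(rc, plants = c("Anabasis setifera",
                                           "Atriplex halimus L"))
  halimus <- prof[prof$plant == "Atriplex halimus L", ]
  expect_true(halimus$no_data)
  expect_true(is.na(halimus$shannon))
  expect_true(is.na(halimus$abundance_n))
  expect_false(prof$no_data[prof$plant == "Anabasis setifera"])
})

test_that("single-species plants yield zero diversity and full dominance", {
  ct <- community_table(data.frame(
    plant = "P", location = "PAWD", tissue = "leaf",
    morphospecies = "Only sp.", genus = "Only", colony_count = 5
  ))
  prof <- diversity_profile(ct)
  expect_equal(prof$shannon, 0)
  expect_equal(prof$simpson, 0)
  expect_equal(prof$berger_parker, 1)
  expect_true(is.na(prof$evenness))
})

test_that("merging a disjoint plant never decreases union richness", {
  ct <- make_toy_community()
  union_before <- length(unique(ct$isolates$morphospecies))
  extra <- data.frame(
    plant = "P3", location = "PAWD", tissue = "leaf",
    morphospecies = c("Delta sp.1", "Alpha sp.1"),
    genus = c("Delta", "Alpha"), colony_count = 1
  )
  merged <- community_table(rbind(ct$isolates[names(extra)], extra))
  union_after <- length(unique(merged$isolates$morphospecies))
  expect_gte(union_after, union_before)
})

test_that("tissue overlap regions partition the union", {
  ct <- read_community(endo_example("table1_isolates.csv"))
  ov <- tissue_overlaps(ct)
  expect_identical(sum(ov$regions$size), ov$union_size)
  # exhaustive membership oracle: every species is in exactly one region
  all_species <- sort(unique(ct$isolates$morphospecies))
  region_species <- sort(unlist(ov$regions$species))
  expect_identical(region_species, all_species)
  # set sizes bound the intersections
  for (t in names(ov$sets)) {
    expect_lte(
      ov$regions$size[ov$regions[[t]] &
                        rowSums(ov$regions[names(ov$sets)]) == length(ov$sets)],
      length(ov$sets[[t]])
    )
  }
  # a species cultured from several plants' tissues appears once per set
  sp3_tissues <- unique(
    ct$isolates$tissue[ct$isolates$morphospecies == "Aspergillus sp.3"]
  )
  expect_gte(length(sp3_tissues), 2)
  for (t in sp3_tissues) {
    expect_identical(sum(ov$sets[[t]] == "Aspergillus sp.3"), 1L)
  }
})

test_that("species confined to single tissues produce no higher-order regions", {
  ct <- community_table(data.frame(
    plant = "P", location = "PAWD",
    tissue = c("leaf", "stem", "root"),
    morphospecies = paste0("Sp", 1:3, " sp."),
    genus = paste0("G", 1:3), colony_count = 1
  ))
  ov <- tissue_overlaps(ct)
  multi <- rowSums(ov$regions[names(ov$sets)]) >= 2
  expect_true(all(ov$regions$size[multi] == 0))
})

test_that("abundance reconstruction recovers the published vectors", {
  hits <- reconstruct_abundances(
    8, list(shannon = 1.79, simpson = 0.789, berger_parker = 0.35),
    n_range = 1:20
  )
  expect_true(any(vapply(
    hits$abundances,
    function(v) identical(v, c(6L, 4L, 2L, 1L, 1L, 1L, 1L, 1L)),
    logical(1)
  )))
  expect_true(17 %in% hits$n)
  even4 <- reconstruct_abundances(
    4, list(shannon = 1.39, simpson = 0.75, berger_parker = 0.25)
  )
  expect_gt(nrow(even4), 0)
  for (v in even4$abundances) expect_identical(length(unique(v)), 1L)
  # full dominance is unreachable with two species at modest N
  none <- reconstruct_abundances(2, list(berger_parker = 1.0))
  expect_identical(nrow(none), 0L)
  expect_error(reconstruct_abundances(3, list(shannon = 1), n_range = integer()),
               class = "endodiv_validation_error")
})

test_that("reconstructed vectors round-trip through their own targets", {
  targets <- list(shannon = 1.74, berger_parker = 0.22)
  hits <- reconstruct_abundances(6, targets, n_range = 1:15)
  expect_gt(nrow(hits), 0)
  for (v in hits$abundances) {
    expect_equal(round_fixed(shannon_index(v), 2), targets$shannon)
    expect_equal(round_fixed(berger_parker_index(v), 2),
                 targets$berger_parker)
  }
})

test_that("truncation rounding mode reproduces 1/6 printed as 0.16", {
  expect_equal(round_fixed(1 / 6, 2, "truncate"), 0.16)
  expect_equal(round_fixed(1 / 6, 2, "half_up"), 0.17)
  expect_equal(round_fixed(0.125, 2, "half_up"), 0.13)
})

test_that("ordination matches an independent eigendecomposition", {
  set.seed(13)
  iso <- expand.grid(
    genus_i = 1:6, tissue = c("flower", "leaf", "stem", "root"),
    stringsAsFactors = FALSE
  )
  iso$plant <- "P"
  iso$location <- "PAWD"
  iso$genus <- paste0("G", iso$genus_i)
  iso$morphospecies <- paste0("G", iso$genus_i, " sp.", iso$tissue)
  iso$colony_count <- rpois(nrow(iso), 4)
  iso$colony_count[iso$colony_count == 0] <- 1
  ct <- community_table(iso[, c("plant", "location", "tissue",
                                "morphospecies", "genus", "colony_count")])
  ord <- pca_ordination(ct)
  # oracle: eigendecomposition of the covariance of the centered matrix
  m <- ord$matrix
  cen <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(cen) / (nrow(cen) - 1))
  expect_equal(ord$var_explained, eig$values / sum(eig$values),
               tolerance = 1e-8)
  scores_oracle <- cen %*% eig$vectors
  got <- as.matrix(ord$scores[, -1])
  for (j in seq_len(ncol(got))) {
    expect_equal(abs(unname(got[, j])), abs(unname(scores_oracle[, j])),
                 tolerance = 1e-8)
  }
  # spectral sanity on the packaged data
  ct2 <- read_community(endo_example("table1_isolates.csv"))
  ve <- pca_ordination(ct2)$var_explained
  expect_true(all(diff(ve) <= 1e-9))
  expect_lte(sum(ve), 1 + 1e-9)
  expect_true(all(ve >= -1e-12))
})

test_that("a single informative tissue loads everything on one component", {
  iso <- data.frame(
    plant = "P", location = "PAWD",
    tissue = rep(c("leaf", "stem"), each = 3),
    morphospecies = paste0("G", c(1:3, 1:3), " sp.",
                           rep(c("l", "s"), each = 3)),
    genus = paste0("G", c(1:3, 1:3)),
    colony_count = c(5, 9, 2, 3, 3, 3) # stem column constant
  )
  ord <- pca_ordination(community_table(iso))
  expect_equal(ord$var_explained[1], 1)
  expect_error(
    pca_ordination(community_table(within(iso, colony_count <- 3))),
    class = "endodiv_degenerate_input"
  )
})

test_that("ordination sign convention is deterministic", {
  ct <- read_community(endo_example("table1_isolates.csv"))
  o1 <- pca_ordination(ct)
  o2 <- pca_ordination(ct)
  expect_equal(o1$scores, o2$scores)
  for (j in c("PC1", "PC2")) {
    expect_gt(max(o1$loadings[[j]]), 0)
  }
})
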