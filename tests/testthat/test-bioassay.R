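# DPPH, dose-response fitting, selectivity index, ANOVA and Duncan's MRT.

test_that("DPPH scavenging matches the closed form and flags negatives", {
  expect_equal(dpph_scavenging(0.2, 0.8), 75)
  expect_equal(dpph_scavenging(0.5, 0.5), 0)
  # forward evaluation at the absorbance that inverts the top published value
  expect_equal(round_fixed(dpph_scavenging(0.8 * (1 - 0.7817), 0.8), 2),
               78.17)
  expect_error(dpph_scavenging(0.2, 0), class = "endodiv_undefined_input")
  expect_warning(dpph_scavenging(0.9, 0.8),
                 class = "endodiv_negative_scavenging")
  # strictly decreasing in T for fixed C
  t_grid <- seq(0, 1, by = 0.1)
  vals <- dpph_scavenging(t_grid, 1)
  expect_true(all(diff(vals) < 0))
})

test_that("DPPH summaries are computed per replicate, not on mean absorbance", {
  rec <- data.frame(
    sample_id = "A", replicate = 1:2,
    absorbance = c(0.2, 0.6), control_absorbance = c(0.8, 0.8)
  )
  s <- summarize_dpph(rec)
  expect_equal(s$mean_scavenging, mean(c(75, 25)))
  expect_equal(s$sd_scavenging, sd(c(75, 25)))
})

test_that("viability and cytotoxicity are complementary percentages", {
  expect_equal(viability_percent(0.5, 0.5), 100)
  expect_equal(viability_percent(0.25, 0.5), 50)
  expect_equal(cytotoxicity_percent(0.5, 0.5), 0)
  expect_error(viability_percent(0.5, 0), class = "endodiv_undefined_input")
  set.seed(3)
  tr <- runif(10)
  expect_equal(viability_percent(tr, 0.7) + cytotoxicity_percent(tr, 0.7),
               rep(100, 10))
})

test_that("noise-free 4PL samples return the generating parameters", {
  conc <- c(1, 5, 25, 50, 125, 250, 500)
  v <- 100 / (1 + (conc / 41.75)^1)
  fit <- fit_dose_response(conc, v)
  expect_true(fit$ic50_defined)
  expect_equal(fit$ic50, 41.75, tolerance = 1e-6)
  expect_equal(unname(fit$par["lower"]), 0, tolerance = 1e-4)
  expect_equal(unname(fit$par["upper"]), 100, tolerance = 1e-4)
  # fitted value at the midpoint is the asymptote average
  mid_v <- predict(fit, fit$par[["midpoint"]])
  expect_equal(mid_v, (fit$par[["lower"]] + fit$par[["upper"]]) / 2,
               tolerance = 1e-6)
})

test_that("IC50 is typed undefined when 50% lies outside the fitted span", {
  conc <- c(1, 5, 25, 50, 125)
  fit <- fit_dose_response(conc, rep(100, 5))
  expect_false(fit$ic50_defined)
  expect_true(is.na(fit$ic50))
  # shallow curve living entirely above 50%
  v <- 80 + 15 / (1 + (conc / 30))
  fit2 <- fit_dose_response(conc, v)
  expect_false(fit2$ic50_defined)
  expect_error(fit_dose_response(c(1, 5, 25), c(90, 50, 10)),
               class = "endodiv_insufficient_data")
})

test_that("IC50 estimates are equivariant under concentration rescaling", {
  conc <- c(1, 5, 25, 50, 125, 250, 500)
  set.seed(9)
  v <- 100 / (1 + (conc / 60)^1.3) * (1 + rnorm(7, 0, 0.02))
  f1 <- fit_dose_response(conc, v)
  f2 <- fit_dose_response(conc * 10, v)
  expect_equal(f2$ic50 / f1$ic50, 10, tolerance = 1e-4)
})

test_that("tidiers expose 4PL parameters and fit diagnostics", {
  mtt <- simulate_dose_response(noise_sd_pct = 2, seed = 21)
  fits <- fit_mtt(mtt)
  expect_identical(fits$cell_line, "A549")
  fit <- fits$fit[[1]]
  td <- tidy(fit)
  expect_identical(td$term, c("lower", "upper", "hill", "midpoint"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$ic50, fit$ic50)
})

test_that("selectivity index reproduces the printed figure by truncation", {
  si <- selectivity_index(196.2, 41.75)
  expect_equal(si$si_printed, 4.69)
  expect_equal(si$selectivity_index, 196.2 / 41.75)
  expect_true(si$high_selectivity)
  expect_equal(selectivity_index(5, 5)$selectivity_index, 1)
  expect_false(selectivity_index(5, 5)$high_selectivity)
  # boundary is strict
  b <- selectivity_index(90, 30)
  expect_equal(b$si_printed, 3)
  expect_false(b$high_selectivity)
  # scale invariance
  expect_equal(selectivity_index(7 * 196.2, 7 * 41.75)$selectivity_index,
               selectivity_index(196.2, 41.75)$selectivity_index)
  expect_error(selectivity_index(10, 0), class = "endodiv_undefined_input")
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  # groups (1,2,3) and (4,5,6): SSB = 13.5, MSW = 1 -> F = 13.5, df (1, 4)
  a <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(a$statistic, 13.5)
  expect_identical(a$df_between, 1L)
  expect_identical(a$df_within, 4L)
  expect_equal(a$ms_within, 1)
  expect_equal(a$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
  # all values identical -> F defined as 0
  z <- one_way_anova(list(g1 = c(2, 2), g2 = c(2, 2)))
  expect_equal(z$statistic, 0)
  expect_error(one_way_anova(list(g1 = 1, g2 = c(1, 2))),
               class = "endodiv_insufficient_replication")
  expect_error(one_way_anova(list(g1 = c(1, 2))),
               class = "endodiv_insufficient_replication")
  # data-frame interface agrees with the list interface
  d <- data.frame(group = rep(c("g1", "g2"), each = 3),
                  value = c(1, 2, 3, 4, 5, 6))
  expect_equal(one_way_anova(d), a)
})

test_that("Duncan letters collapse ties and split clear separations", {
  all_same <- duncan_mrt(list(a = c(5, 5, 5), b = c(5, 5, 5),
                              c = c(5, 5, 5)))
  expect_true(all(all_same$letters == "a"))
  far <- duncan_mrt(list(lo = c(0, 0, 0.1), hi = c(100, 100, 100.1)))
  expect_identical(sort(unique(far$letters)), c("a", "b"))
  expect_identical(far$group[far$letters == "a"], "hi")
})

test_that("Duncan letter display agrees with the brute-force span oracle", {
  cases <- list(
    list(a = c(10, 11, 12), b = c(10.5, 11.5, 12.5),
         c = c(14, 15, 16), d = c(30, 31, 32)),
    list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5), d = c(4, 5, 6)),
    list(a = c(5, 6), b = c(5.1, 6.1), c = c(20, 21), d = c(20.2, 21.2)),
    list(w = c(8, 9, 10, 11), x = c(9, 10, 11), y = c(12, 13, 14),
         z = c(25, 26, 27))
  )
  for (groups in cases) {
    mrt <- duncan_mrt(groups)
    nsd <- oracle_duncan_nsd(groups)
    ids <- names(groups)
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        expect_identical(
          shares_letter(mrt, ids[i], ids[j]),
          unname(nsd[ids[i], ids[j]]),
          label = sprintf("pair %s/%s", ids[i], ids[j])
        )
      }
    }
  }
})

test_that("Duncan displays are invariant to group input order", {
  groups <- list(a = c(10, 11, 12), b = c(10.5, 11.5, 12.5),
                 c = c(14, 15, 16), d = c(30, 31, 32))
  m1 <- tidy(duncan_mrt(groups))
  m2 <- tidy(duncan_mrt(rev(groups)))
  expect_equal(m1, m2)
})

test_that("zone summaries rank extracts and keep the control out of ranking", {
  set.seed(17)
  pathogens <- c("S. aureus", "E. coli")
  extracts <- c("E1", "E2", "E3")
  rec <- expand.grid(extract_id = extracts, pathogen_id = pathogens,
                     replicate = 1:3, stringsAsFactors = FALSE)
  base <- c(E1 = 20, E2 = 12, E3 = 10)
  rec$zone_mm <- base[rec$extract_id] + rnorm(nrow(rec), 0, 0.5)
  ctrl <- expand.grid(extract_id = "control", pathogen_id = pathogens,
                      replicate = 1:3, stringsAsFactors = FALSE)
  ctrl$zone_mm <- 0
  summ <- summarize_zones(rbind(rec, ctrl))
  for (p in pathogens) {
    sp <- summ[summ$pathogen_id == p, ]
    expect_identical(sp$extract_id[which(sp$rank == 1)], "E1")
    expect_true(all(is.na(sp$rank[sp$is_control])))
    expect_identical(nrow(sp), 4L) # control retained in the output
  }
  # degenerate: single extract, perfect replicates
  single <- summarize_zones(data.frame(
    extract_id = "E1", pathogen_id = "P", replicate = 1:3,
    zone_mm = c(10, 10, 10)
  ))
  expect_equal(single$mean_zone, 10)
  expect_equal(single$sd_zone, 0)
  expect_true(is.na(single$letters))
  # empty input -> empty summary
  expect_identical(nrow(summarize_zones(
    data.frame(extract_id = character(), pathogen_id = character(),
               replicate = integer(), zone_mm = numeric())
  )), 0L)
})
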