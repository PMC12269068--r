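test_that("a system without glyphosate adsorbs none", {
  pt <- simulate_point(batch_system(pH = 6, ionic_strength = 0.1,
                                    pmg_total = 0, ha_loading = 1.1),
                       db = cached_default_db())
  expect_equal(pt$pmg_dissolved, 0)
  expect_equal(pt$pmg_adsorbed, 0)
})

test_that("glyphosate mass balance closes at every isotherm point", {
  db <- cached_default_db()
  des <- generate_design(design_spec(ha_levels = 1.1, ph_targets = c(5, 7),
                                     ionic_strengths = 0.1, seed = 3))
  sim <- simulate_isotherm(des, db = db)
  area <- sim$ssa_m2_g * sim$goethite_g_L
  recon <- sim$pmg_dissolved_M + sim$pmg_adsorbed_umol_m2 * 1e-6 * area
  expect_equal(recon, sim$pmg_total_M, tolerance = 1e-8)
})

test_that("the model nests: no HA and no blocking reduce to bare goethite", {
  db <- cached_default_db()
  pt <- simulate_point(batch_system(pH = 5.5, ionic_strength = 0.1,
                                    pmg_total = 2e-4, ha_loading = 0),
                       db = db, steric = steric_params(s_max = 0))
  # direct solve without NOM or steric components at all
  direct <- solve_equilibrium(
    strip_steric(db),
    system_composition(totals = c(Na = 0.1, NO3 = 0.1, PMG = 2e-4),
                       fixed_activities = c(H = 10^-5.5),
                       ionic_strength = 0.1))
  diss <- sum(direct$species_amounts[c("PMG", "HPMG", "H2PMG", "H3PMG")])
  expect_equal(pt$pmg_dissolved, diss, tolerance = 1e-10)
  expect_equal(pt$result$edl$sigma0, direct$edl$sigma0, tolerance = 1e-9)
})

test_that("switching the steric term off reproduces the basic NOM-CD model", {
  db <- cached_default_db()
  plain <- strip_steric(db)   # no S0 component, no mirror species
  for (pH in c(4.5, 7)) {
    pt <- simulate_point(batch_system(pH = pH, ionic_strength = 0.1,
                                      pmg_total = 2e-4, ha_loading = 1.6),
                         db = db, steric = steric_params(s_max = 0))
    hn <- hnom_surface_density(1.6) * 1e-6
    basic <- solve_equilibrium(
      plain,
      system_composition(totals = c(Na = 0.1, NO3 = 0.1, PMG = 2e-4,
                                    HNOM = hn),
                         fixed_activities = c(H = 10^-pH),
                         ionic_strength = 0.1))
    diss <- sum(basic$species_amounts[c("PMG", "HPMG", "H2PMG", "H3PMG")])
    expect_equal(pt$pmg_dissolved, diss, tolerance = 1e-10)
  }
})

test_that("HA loading monotonically releases glyphosate into solution", {
  db <- cached_default_db()
  diss <- vapply(c(0.5, 0.8, 1.1, 1.3, 1.6), function(ha) {
    simulate_point(batch_system(pH = 5.5, ionic_strength = 0.1,
                                pmg_total = 2e-4, ha_loading = ha),
                   db = db)$pmg_dissolved
  }, numeric(1))
  expect_true(all(diff(diss) > 0))
})

test_that("glyphosate sorption drops at lower ionic strength with HA present", {
  db <- cached_default_db()
  for (pH in c(6.5, 7.5)) {
    hi <- simulate_point(batch_system(pH = pH, ionic_strength = 0.1,
                                      pmg_total = 7.25e-4,
                                      ha_loading = 1.6), db = db)
    lo <- simulate_point(batch_system(pH = pH, ionic_strength = 0.01,
                                      pmg_total = 7.25e-4,
                                      ha_loading = 1.6), db = db)
    expect_lt(lo$pmg_adsorbed, hi$pmg_adsorbed)
  }
})

test_that("isotherms are nonlinear with a log-log slope at most one", {
  db <- cached_default_db()
  # the 9-dose dilution series at fixed pH, extended to trace doses
  # where the isotherm must straighten to the Henry slope of one
  des <- data.frame(pH = 6, ionic_strength_M = 0.1,
                    ha_loading_mg_m2 = 1.1,
                    pmg_total_M = c(10^seq(-7, -5, by = 1),
                                    1.45e-3 * c(0.05, 0.10, 0.15, 0.20,
                                                0.25, 0.30, 0.35, 0.40,
                                                0.50)))
  sim <- simulate_isotherm(des, db = db)
  sim <- sim[order(sim$pmg_total_M), ]
  lq <- log10(sim$pmg_adsorbed_umol_m2)
  lc <- log10(sim$pmg_dissolved_M)
  slopes <- diff(lq) / diff(lc)
  expect_true(all(slopes <= 1 + 1e-6))
  # approaching unit slope at the lowest loadings, bending over at the top
  expect_gt(slopes[1], 0.9)
  expect_lt(slopes[length(slopes)], slopes[1])
})

test_that("isotherm simulation is pure: order does not matter", {
  db <- cached_default_db()
  des <- generate_design(design_spec(ha_levels = 1.6, ph_targets = 5,
                                     ionic_strengths = 0.1, seed = 2))
  fwd <- simulate_isotherm(des, db = db)
  rev_ <- simulate_isotherm(des[rev(seq_len(nrow(des))), ], db = db)
  expect_equal(fwd$pmg_dissolved_M,
               rev(rev_$pmg_dissolved_M), tolerance = 0)
})

test_that("interface statistics map outer-sphere fraction to the R ratio", {
  expect_equal(r_ratio_from_fos(0.025), 0.4875)
  expect_equal(r_ratio_from_fos(0.35), 0.325)
  expect_equal(r_ratio_from_fos(1), 0)
  db <- cached_default_db()
  # no NOM -> not applicable
  pt <- simulate_point(batch_system(pH = 6, ionic_strength = 0.1,
                                    pmg_total = 1e-4, ha_loading = 0),
                       db = db)
  expect_true(is.na(pt$nom_outer_sphere_fraction))
  expect_true(is.na(pt$r_ratio))
  # internal consistency of the computed pair
  pt2 <- simulate_point(batch_system(pH = 7, ionic_strength = 0.1,
                                     pmg_total = 1e-4, ha_loading = 1.1),
                        db = db)
  expect_equal(pt2$r_ratio,
               r_ratio_from_fos(pt2$nom_outer_sphere_fraction))
})

test_that("outer-sphere NOM complexation gains importance toward high pH", {
  db <- cached_default_db()
  fos <- vapply(seq(4, 8, by = 1), function(pH) {
    simulate_point(batch_system(pH = pH, ionic_strength = 0.1,
                                pmg_total = 1e-4, ha_loading = 1.1),
                   db = db)$nom_outer_sphere_fraction
  }, numeric(1))
  expect_true(all(diff(fos) > 0))
  expect_true(all(fos > 0 & fos < 1))
})

test_that("the log-RMSE objective matches hand arithmetic", {
  expect_equal(rmse_log10(c(1e-5, 2e-6), c(1e-5, 2e-6)), 0)
  expect_equal(rmse_log10(10 * c(1e-6, 3e-5), c(1e-6, 3e-5)), 1)
  expect_equal(rmse_log10(c(1e-5, 1e-6), c(2e-5, 5e-7)), 0.30103,
               tolerance = 1e-6)
  expect_error(rmse_log10(1:3 * 1e-6, 1:2 * 1e-6), "length")
  expect_error(rmse_log10(c(1e-6, 0), c(1e-6, 1e-6)), "positive")
})

test_that("a noise-free dataset returns the generating steric parameter", {
  db <- cached_default_db()
  des <- recovery_design(seed = 5)
  des <- des[des$pmg_total_M > 2e-4, ]   # 3 doses x 12 isotherms
  ds <- simulate_observations(des, truth = list(s_max = 2.56),
                              noise_sigma = 0, seed = 5, db = db)
  fit <- fit_parameters(ds$points, free = "s_max", db = db)
  expect_true(fit$converged)
  expect_equal(fit$estimates$estimate, 2.56, tolerance = 1e-3)
  expect_lt(fit$rmse, 1e-6)
  expect_false(fit$estimates$at_bound)
})

test_that("fitting refuses datasets with too few usable observations", {
  db <- cached_default_db()
  des <- recovery_design(seed = 1)[1:4, ]
  ds <- simulate_observations(des, truth = list(s_max = 2.56),
                              noise_sigma = 0, seed = 1, db = db)
  ds$points$pmg_dissolved_M <- 1e-9   # everything below the LOD
  expect_error(fit_parameters(ds$points, db = db),
               "detection limit")
})
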