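test_that("Davies model reproduces hand-computed coefficients", {
  expect_equal(davies_log_gamma(1, 0), 0)
  expect_equal(davies_log_gamma(0, 0.5), 0)
  # z = 1, I = 0.1: -0.509 (0.316/1.316 - 0.03) = -0.107019
  expect_equal(davies_log_gamma(1, 0.1), -0.1070188, tolerance = 1e-6)
  expect_equal(10^davies_log_gamma(1, 0.1), 0.78159, tolerance = 1e-4)
  # z^2 scaling
  expect_equal(davies_log_gamma(2, 0.05), 4 * davies_log_gamma(1, 0.05))
})

test_that("Gouy-Chapman closure is odd and matches direct evaluation", {
  expect_equal(gouy_chapman_sigma(0, 0.1), 0)
  psi <- seq(-0.2, 0.2, by = 0.05)
  expect_equal(gouy_chapman_sigma(-psi, 0.03), -gouy_chapman_sigma(psi, 0.03))
  # psi = -0.1 V, c = 0.1 M: 0.1174 sqrt(0.1) sinh(1.9461) = 0.12731
  expect_equal(gouy_chapman_sigma(-0.1, 0.1), 0.12731, tolerance = 1e-4)
})

test_that("an inert electrolyte without surface stays trivial", {
  db <- cached_default_db()
  res <- solve_equilibrium(
    db,
    system_composition(totals = c(Na = 0.05, NO3 = 0.05),
                       fixed_activities = c(H = 1e-7),
                       ionic_strength = 0.05),
    edl_parameters(solid_concentration = 0))
  expect_true(res$converged)
  expect_equal(unname(res$species_amounts["Na"]), 0.05, tolerance = 1e-9)
  expect_equal(unname(res$species_amounts["NO3"]), 0.05, tolerance = 1e-9)
  expect_equal(res$edl$sigma0, 0)
  expect_equal(res$edl$psi0, 0)
})

test_that("with electrostatics off the solver matches the Langmuir closed form", {
  for (logK in c(3, 5, 7)) {
    db <- langmuir_db(logK = logK, site_density = 2)
    edlp <- edl_parameters(specific_surface_area = 94,
                           solid_concentration = 10)
    XT <- 2 / 0.60221 * 1e-6 * 940     # site total, mol/L
    for (LT in c(1e-5, 1e-3)) {
      res <- solve_equilibrium(
        db, system_composition(totals = c(L = LT), ionic_strength = 0.1),
        edlp)
      expect_true(res$converged)
      expect_equal(unname(res$species_amounts["XL"]),
                   langmuir_oracle(10^logK, XT, LT),
                   tolerance = 1e-8)
    }
  }
})

test_that("the solver agrees with an independent fixed-point oracle", {
  db <- noelec_db(logK_XL = 4, logK_HL = 6)
  edlp <- edl_parameters(specific_surface_area = 90,
                         solid_concentration = 5)
  XT <- 1 / 0.60221 * 1e-6 * 450
  for (pH in c(5, 7)) {
    for (LT in c(2e-5, 5e-4)) {
      res <- solve_equilibrium(
        db, system_composition(totals = c(L = LT),
                               fixed_activities = c(H = 10^-pH),
                               ionic_strength = 1e-4),
        edlp)
      orc <- noelec_oracle(1e4, 1e6, XT, LT, 10^-pH, 1e-4)
      expect_equal(unname(res$species_amounts["XL"]), orc$XL,
                   tolerance = 1e-8)
      expect_equal(unname(res$species_amounts["HL"]), orc$HL,
                   tolerance = 1e-8)
    }
  }
})

test_that("bare goethite charge reverses at the point of zero charge 9.3", {
  db <- cached_default_db()
  sig0 <- function(pH) {
    solve_equilibrium(db, bare_composition(pH))$edl$sigma0
  }
  expect_gt(sig0(7), 0)
  expect_lt(sig0(10.5), 0)
  pzc <- stats::uniroot(sig0, c(7, 10.5), tol = 1e-9)$root
  expect_equal(pzc, 9.3, tolerance = 1e-6)
})

test_that("charge and mass balances close on a grid of converged systems", {
  db <- cached_default_db()
  grid <- expand.grid(pH = c(4, 6, 8, 10), I = c(0.1, 0.01),
                      pmg = c(0, 1e-4), ha = c(0, 1.6))
  for (i in seq_len(nrow(grid))) {
    hn <- hnom_surface_density(grid$ha[i]) * 1e-6
    s0 <- s0_surface_density(theta_s(10^-grid$pH[i], grid$I[i]), 2.56) * 1e-6
    res <- solve_equilibrium(
      db,
      system_composition(
        totals = c(Na = grid$I[i], NO3 = grid$I[i], PMG = grid$pmg[i],
                   HNOM = hn, S0 = s0),
        fixed_activities = c(H = 10^-grid$pH[i]),
        ionic_strength = grid$I[i]))
    expect_true(res$converged)
    expect_lt(abs(res$edl$sigma0 + res$edl$sigma1 + res$edl$sigma2 +
                    res$edl$sigma_d), 1e-10)
    recon <- drop(crossprod(res$stoich, res$species_amounts))
    for (nm in names(res$totals)) {
      if (res$totals[nm] > 0) {
        expect_lt(abs(recon[nm] - res$totals[nm]) / res$totals[nm], 1e-10)
      }
    }
  }
})

test_that("steric occupation leaves primary charging untouched without PMG", {
  db <- cached_default_db()
  plain <- strip_steric(db)
  for (pH in c(4.5, 7, 9)) {
    s0 <- s0_surface_density(theta_s(10^-pH, 0.1), 2.56) * 1e-6
    a <- solve_equilibrium(db, system_composition(
      totals = c(Na = 0.1, NO3 = 0.1, S0 = s0),
      fixed_activities = c(H = 10^-pH), ionic_strength = 0.1))
    b <- solve_equilibrium(plain, system_composition(
      totals = c(Na = 0.1, NO3 = 0.1),
      fixed_activities = c(H = 10^-pH), ionic_strength = 0.1))
    expect_lt(abs(a$edl$sigma0 - b$edl$sigma0), 1e-10)
    expect_lt(abs(a$edl$psi0 - b$edl$psi0), 1e-10)
  }
})

test_that("the solver is deterministic and order-independent", {
  db <- cached_default_db()
  comp <- system_composition(
    totals = c(Na = 0.1, NO3 = 0.1, PMG = 1e-4, HNOM = 1.2e-6,
               S0 = 1.5e-6),
    fixed_activities = c(H = 1e-6), ionic_strength = 0.1)
  r1 <- solve_equilibrium(db, comp)
  r2 <- solve_equilibrium(db, comp)
  expect_identical(r1$species_amounts, r2$species_amounts)
  expect_identical(r1$edl, r2$edl)
})

test_that("dissolved glyphosate grows monotonically with the total", {
  db <- cached_default_db()
  tots <- 10^seq(-5.5, -3.2, length.out = 8)
  diss <- vapply(tots, function(tt) {
    simulate_point(batch_system(pH = 6, ionic_strength = 0.1,
                                pmg_total = tt, ha_loading = 1.1),
                   db = db)$pmg_dissolved
  }, numeric(1))
  expect_true(all(diff(diss) > 0))
})

test_that("infeasible surface-component demand names the site balance", {
  db <- cached_default_db()
  expect_error(
    solve_equilibrium(db, system_composition(
      totals = c(Na = 0.1, NO3 = 0.1, HNOM = 4e-6, S0 = 3e-6),
      fixed_activities = c(H = 1e-6), ionic_strength = 0.1)),
    "infeasible site balance for FeOH")
})

test_that("non-convergence is reported honestly", {
  db <- cached_default_db()
  opts <- solver_options(max_iter = 1, on_fail = "return")
  expect_warning(
    res <- solve_equilibrium(db, bare_composition(4), options = opts),
    "did not converge")
  expect_false(res$converged)
  opts2 <- solver_options(max_iter = 1)
  expect_error(solve_equilibrium(db, bare_composition(4), options = opts2),
               "did not converge")
})

test_that("computed ionic strength converges to the electrolyte level", {
  db <- cached_default_db()
  res <- solve_equilibrium(
    db,
    system_composition(totals = c(Na = 0.05, NO3 = 0.05),
                       fixed_activities = c(H = 1e-7)),
    edl_parameters(solid_concentration = 0))
  expect_true(res$converged)
  expect_equal(res$ionic_strength, 0.05, tolerance = 1e-3)
})
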