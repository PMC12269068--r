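# Multicomponent chemical equilibrium with extended-Stern three-plane
# electrostatics. Unknowns are the log10 free activities of the
# non-fixed components plus the log10 Boltzmann factors
# B_p = exp(-F psi_p / RT) of planes 0, 1 and 2; residuals are the
# component mass/site balances and the three charge-potential relations
#   sigma0                = C1 (psi0 - psi1)
#   sigma0 + sigma1       = C2 (psi1 - psi2)
#   sigma0 + sigma1 + sigma2 + sigma_d(psi2) = 0
# solved by damped Newton iteration with an analytic Jacobian.

#' Davies activity-coefficient model
#'
#' `log10(gamma) = -A z^2 (sqrt(I)/(1+sqrt(I)) - 0.3 I)` with A = 0.509
#' at 25 C. Applied to aqueous species only; surface species carry no
#' activity correction.
#'
#' @param charge species valence.
#' @param ionic_strength mol L-1, >= 0.
#' @return log10 of the activity coefficient.
#' @examples
#' davies_log_gamma(1, 0.1)   # ~ -0.107
#' @export
davies_log_gamma <- function(charge, ionic_strength) {
  stopifnot(all(ionic_strength >= 0))
  sI <- sqrt(ionic_strength)
  -.const$a_davies * charge^2 * (sI / (1 + sI) - 0.3 * ionic_strength)
}

#' Gouy-Chapman diffuse-layer charge
#'
#' Charge density at the head of the diffuse layer for a symmetric 1:1
#' electrolyte at 25 C:
#' `sigma_d = -0.1174 sqrt(c) sinh(F psi_d / (2RT))` (C m-2). The sign
#' is opposite to the potential: the diffuse layer screens the surface.
#'
#' @param psi_d diffuse-layer potential, V.
#' @param electrolyte_conc 1:1 electrolyte concentration, mol L-1.
#' @return C m-2.
#' @examples
#' gouy_chapman_sigma(-0.1, 0.1)   # ~ +0.127
#' @export
gouy_chapman_sigma <- function(psi_d, electrolyte_conc) {
  stopifnot(all(electrolyte_conc >= 0))
  -.const$gc_coef * sqrt(electrolyte_conc) *
    sinh(.const$faraday * psi_d / (2 * .const$rt))
}

#' Extended-Stern electrostatic parameters of a suspension
#'
#' @param c1,c2 inner and outer Stern-layer capacitances, F m-2.
#' @param specific_surface_area m2 g-1.
#' @param solid_concentration g L-1 (0 switches the surface off).
#' @return list of class `edl_parameters`.
#' @export
edl_parameters <- function(c1 = 0.85, c2 = 0.75,
                           specific_surface_area = 94,
                           solid_concentration = 10) {
  stopifnot(c1 > 0, c2 > 0, specific_surface_area > 0,
            solid_concentration >= 0)
  structure(list(c1 = c1, c2 = c2,
                 specific_surface_area = specific_surface_area,
                 solid_concentration = solid_concentration),
            class = "edl_parameters")
}

#' System composition for an equilibrium problem
#'
#' @param totals named numeric: total concentrations. Aqueous masters in
#'   mol L-1; surface components (HNOM, S0) in mol m-2. Surface-site
#'   totals are derived from the database site densities and need not be
#'   given.
#' @param fixed_activities named numeric: components with imposed
#'   activity instead of a total (typically `H` when pH is measured);
#'   their mass balance is dropped.
#' @param ionic_strength nominal ionic strength in mol L-1, or `NULL`
#'   to compute it from the aqueous speciation (fixed-point iteration).
#' @return list of class `system_composition`.
#' @export
system_composition <- function(totals = numeric(0),
                               fixed_activities = numeric(0),
                               ionic_strength = NULL) {
  stopifnot(all(totals >= 0), all(fixed_activities > 0))
  both <- intersect(names(totals), names(fixed_activities))
  if (length(both) > 0) {
    stop("component(s) appear in both totals and fixed_activities: ",
         paste(both, collapse = ", "))
  }
  structure(list(totals = totals, fixed_activities = fixed_activities,
                 ionic_strength = ionic_strength),
            class = "system_composition")
}

#' Solver options
#'
#' @param tol convergence tolerance: relative on mass balances,
#'   absolute (C m-2, after capacitance scaling) on the electrostatic
#'   relations.
#' @param max_iter maximum Newton iterations.
#' @param max_step cap on the infinity-norm of a Newton step in log10
#'   units.
#' @param max_halvings backtracking halvings per step.
#' @param on_fail `"error"` to stop on non-convergence, `"return"` to
#'   return the unconverged result with `converged = FALSE`.
#' @return list of class `solver_options`.
#' @export
solver_options <- function(tol = 1e-10, max_iter = 200, max_step = 3,
                           max_halvings = 30,
                           on_fail = c("error", "return")) {
  structure(list(tol = tol, max_iter = max_iter, max_step = max_step,
                 max_halvings = max_halvings,
                 on_fail = match.arg(on_fail)),
            class = "solver_options")
}

#' Solve a multicomponent surface-complexation equilibrium
#'
#' Assembles the mass-action and balance equations from the database
#' tableau, adds the three-plane extended-Stern electrostatic
#' sub-model when surface species are present, and solves by damped
#' Newton iteration on log10 free activities and log10 Boltzmann
#' factors. Components with zero totals are pruned together with their
#' species. The solver is deterministic: identical inputs give
#' identical output.
#'
#' @param db a validated `snomcd_db`.
#' @param comp a [system_composition()].
#' @param edlp an [edl_parameters()].
#' @param options a [solver_options()].
#' @param init optional warm start: the `solver_state` element of a
#'   previous result for the same set of unknowns (ignored when the
#'   unknown set differs).
#' @return list of class `speciation_result` with elements
#'   `free_activities`, `species_amounts` (mol L-1),
#'   `species_surface_density` (umol m-2, surface species only), `edl`
#'   (psi0/1/2, sigma0/1/2, sigma_d), `ionic_strength`, `converged`,
#'   `iterations`, `residual_norm`.
#' @export
solve_equilibrium <- function(db, comp, edlp = edl_parameters(),
                              options = solver_options(), init = NULL) {
  stopifnot(inherits(db, "snomcd_db"))
  area_l <- edlp$specific_surface_area * edlp$solid_concentration  # m2 L-1

  cmp <- db$components
  totals <- rep(0, nrow(cmp))
  names(totals) <- cmp$name
  # surface-site totals from crystallographic densities
  is_site <- cmp$kind == "surface_site"
  totals[is_site] <- cmp$site_density[is_site] /
    .const$sites_per_umol * 1e-6 * area_l                      # mol L-1
  # user totals: aqueous in mol/L, surface components in mol/m2
  for (nm in names(comp$totals)) {
    if (!nm %in% cmp$name) stop("totals name not a component: ", nm)
    k <- match(nm, cmp$name)
    totals[k] <- if (cmp$kind[k] == "aqueous_master") comp$totals[[nm]]
    else comp$totals[[nm]] * area_l
  }
  fixed <- comp$fixed_activities
  if (length(fixed) > 0 && !all(names(fixed) %in% cmp$name)) {
    stop("fixed_activities name not a component")
  }

  # steric/NOM feasibility: surface components occupy FeOH-type sites
  for (st in cmp$name[is_site]) {
    consumers <- cmp$name[cmp$kind == "surface_component"]
    demand <- 0
    for (sc in consumers) {
      js <- which(db$stoich[, sc] != 0)
      if (length(js) > 0 && all(db$stoich[js, st] > 0)) {
        demand <- demand + totals[sc]
      }
    }
    if (demand >= totals[st] && demand > 0) {
      stop(sprintf(
        "infeasible site balance for %s: surface components demand %.4g mol/L but only %.4g mol/L of sites are available",
        st, demand, totals[st]))
    }
  }

  # prune components that are neither fixed nor present
  active <- cmp$name %in% names(fixed) | totals > 0
  if (area_l == 0) active <- active & cmp$kind == "aqueous_master"
  drop_comp <- cmp$name[!active]
  keep_sp <- rep(TRUE, nrow(db$species))
  if (length(drop_comp) > 0) {
    keep_sp <- rowSums(abs(db$stoich[, drop_comp, drop = FALSE])) == 0
  }
  nu <- db$stoich[keep_sp, active, drop = FALSE]
  sp <- db$species[keep_sp, , drop = FALSE]
  cmpA <- cmp[active, , drop = FALSE]
  totals <- totals[active]
  surf <- sp$phase == "surface"
  has_surface <- any(surf) && area_l > 0

  # unknown components: active, not fixed
  is_fixed <- cmpA$name %in% names(fixed)
  ui <- which(!is_fixed)
  for (i in ui) {
    if (sum(abs(nu[, i])) == 0) {
      stop("component ", cmpA$name[i],
           " has a nonzero total but no species containing it")
    }
  }
  la_fixed <- rep(NA_real_, nrow(cmpA))
  la_fixed[is_fixed] <- log10(fixed[cmpA$name[is_fixed]])

  dzm <- as.matrix(sp[, c("dz0", "dz1", "dz2")])
  ref0 <- species_ref0(db)[keep_sp]
  w <- dzm
  w[, 1] <- w[, 1] + ref0
  w[surf == FALSE, ] <- 0        # aqueous species carry no plane charge

  zaq <- species_charge(db)[keep_sp]
  f_over_rt <- .const$faraday / .const$rt
  psi_per_logb <- -.const$rt * log(10) / .const$faraday   # V per log10(B)

  solve_at_I <- function(ionic_strength) {
    # effective logK folds the aqueous activity correction (fixed I)
    logg <- ifelse(surf, 0, davies_log_gamma(zaq, ionic_strength))
    logk_eff <- sp$logK - logg
    n_u <- length(ui)
    n_e <- if (has_surface) 3L else 0L
    x <- numeric(n_u + n_e)
    x[seq_len(n_u)] <- log10(pmax(0.1 * totals[ui], 1e-25))
    if (!is.null(init) && identical(init$unknowns, cmpA$name[ui]) &&
        length(init$x) == n_u + n_e) {
      x <- init$x
    }
    tol <- options$tol
    scale_t <- pmax(totals[ui], 1e-30)

    calc <- function(x) {
      la <- la_fixed
      la[ui] <- x[seq_len(n_u)]
      lb <- if (has_surface) x[n_u + 1:3] else c(0, 0, 0)
      lc <- logk_eff + drop(nu %*% la) + drop(dzm %*% lb)
      lc <- pmin(lc, 280)  # overflow guard; damping keeps us far below
      cvec <- 10^lc
      fm <- (drop(crossprod(nu[, ui, drop = FALSE], cvec)) - totals[ui]) /
        scale_t
      if (!has_surface) {
        return(list(cvec = cvec, f = fm, lb = lb,
                    psi = c(0, 0, 0), sig = c(0, 0, 0), sig_d = 0))
      }
      psi <- psi_per_logb * lb
      sig <- .const$faraday / area_l * drop(crossprod(w, cvec))
      sig_d <- gouy_chapman_sigma(psi[3], ionic_strength)
      g <- c(sig[1] - edlp$c1 * (psi[1] - psi[2]),
             sig[1] + sig[2] - edlp$c2 * (psi[2] - psi[3]),
             sig[1] + sig[2] + sig[3] + sig_d)
      list(cvec = cvec, f = c(fm, g), lb = lb, psi = psi, sig = sig,
           sig_d = sig_d)
    }

    jac <- function(st) {
      cvec <- st$cvec
      D <- cbind(nu[, ui, drop = FALSE],
                 if (has_surface) dzm else NULL)     # d(log c)/dx
      ln10 <- log(10)
      Jm <- ln10 * crossprod(nu[, ui, drop = FALSE] * cvec, D) / scale_t
      if (!has_surface) return(Jm)
      Js <- .const$faraday / area_l * ln10 * crossprod(w * cvec, D)
      Je <- rbind(Js[1, ],
                  Js[1, ] + Js[2, ],
                  Js[1, ] + Js[2, ] + Js[3, ])
      # potential terms
      dpsi <- psi_per_logb
      Je[1, n_u + 1] <- Je[1, n_u + 1] - edlp$c1 * dpsi
      Je[1, n_u + 2] <- Je[1, n_u + 2] + edlp$c1 * dpsi
      Je[2, n_u + 2] <- Je[2, n_u + 2] - edlp$c2 * dpsi
      Je[2, n_u + 3] <- Je[2, n_u + 3] + edlp$c2 * dpsi
      dsig_d <- -.const$gc_coef * sqrt(ionic_strength) *
        cosh(.const$faraday * st$psi[3] / (2 * .const$rt)) *
        .const$faraday / (2 * .const$rt)
      Je[3, n_u + 3] <- Je[3, n_u + 3] + dsig_d * dpsi
      rbind(Jm, Je)
    }

    st <- calc(x)
    iter <- 0L
    repeat {
      rnorm <- max(abs(st$f))
      if (rnorm <= tol || iter >= options$max_iter) break
      J <- jac(st)
      delta <- tryCatch(solve(J, -st$f), error = function(e) {
        solve(J + diag(1e-10, nrow(J)), -st$f)
      })
      mx <- max(abs(delta))
      if (mx > options$max_step) delta <- delta * options$max_step / mx
      lambda <- 1
      old_norm <- sqrt(sum(st$f^2))
      for (h in seq_len(options$max_halvings)) {
        cand <- calc(x + lambda * delta)
        if (all(is.finite(cand$f)) &&
            sqrt(sum(cand$f^2)) < old_norm * (1 - 1e-4 * lambda)) break
        lambda <- lambda / 2
      }
      x <- x + lambda * delta
      st <- calc(x)
      iter <- iter + 1L
    }
    list(x = x, st = st, iter = iter, rnorm = max(abs(st$f)),
         converged = max(abs(st$f)) <= tol)
  }

  if (is.null(comp$ionic_strength)) {
    # computed ionic strength: fixed-point outer loop
    aqm <- cmpA$kind == "aqueous_master"
    I <- max(0.5 * sum(abs(totals[aqm]) *
                         cmpA$charge[aqm]^2), 1e-4)
    for (k in 1:30) {
      res <- solve_at_I(I)
      aq <- !surf
      Inew <- 0.5 * sum(res$st$cvec[aq] * zaq[aq]^2)
      if (abs(Inew - I) <= 1e-6 * max(I, 1e-12)) { I <- Inew; break }
      I <- Inew
    }
  } else {
    I <- comp$ionic_strength
    res <- solve_at_I(I)
  }

  if (!res$converged) {
    msg <- sprintf(
      "equilibrium solver did not converge in %d iterations (residual %.3g)",
      res$iter, res$rnorm)
    if (options$on_fail == "error") stop(msg) else warning(msg)
  }

  la <- la_fixed
  la[ui] <- res$x[seq_len(length(ui))]
  free_act <- 10^la
  names(free_act) <- cmpA$name
  amounts <- res$st$cvec
  names(amounts) <- sp$name
  surf_dens <- amounts[surf] / max(area_l, .Machine$double.eps) * 1e6
  edl <- list(psi0 = res$st$psi[1], psi1 = res$st$psi[2],
              psi2 = res$st$psi[3],
              sigma0 = res$st$sig[1], sigma1 = res$st$sig[2],
              sigma2 = res$st$sig[3], sigma_d = res$st$sig_d)
  structure(list(free_activities = free_act,
                 species_amounts = amounts,
                 species_surface_density = surf_dens,
                 species_phase = sp$phase,
                 stoich = nu, totals = totals,
                 component_names = cmpA$name,
                 edl = edl, ionic_strength = I,
                 area_per_litre = area_l,
                 solver_state = list(x = res$x,
                                     unknowns = cmpA$name[ui]),
                 converged = res$converged, iterations = res$iter,
                 residual_norm = res$rnorm),
            class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("<speciation_result> ", if (x$converged) "converged" else
    "NOT CONVERGED", " in ", x$iterations, " iterations (residual ",
    format(x$residual_norm, digits = 3), ")\n", sep = "")
  cat("  psi0/1/2 [V]: ",
      paste(format(c(x$edl$psi0, x$edl$psi1, x$edl$psi2), digits = 4),
            collapse = " / "), "\n", sep = "")
  cat("  sigma0+1+2+d [C m-2]: ",
      format(x$edl$sigma0 + x$edl$sigma1 + x$edl$sigma2 + x$edl$sigma_d,
             digits = 3), "\n", sep = "")
  tab <- data.frame(species = names(x$species_amounts),
                    phase = x$species_phase,
                    mol_per_L = unname(x$species_amounts))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tabulate a speciation result
#'
#' @param result a `speciation_result`.
#' @return data.frame with species name, phase, concentration (mol L-1)
#'   and, for surface species, surface density (umol m-2).
#' @export
speciation_table <- function(result) {
  stopifnot(inherits(result, "speciation_result"))
  d <- data.frame(species = names(result$species_amounts),
                  phase = result$species_phase,
                  mol_per_L = unname(result$species_amounts),
                  umol_per_m2 = NA_real_,
                  stringsAsFactors = FALSE)
  is_s <- d$phase == "surface"
  d$umol_per_m2[is_s] <- result$species_surface_density[d$species[is_s]]
  d
}
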