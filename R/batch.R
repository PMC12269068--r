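# Batch systems: one goethite + PMG + HA + electrolyte equilibrium
# problem per experimental point; isotherm simulation; interpretation
# quantities; RMSE objective and least-squares estimation of the steric
# parameter.

#' Describe one batch adsorption system
#'
#' @param pH measured pH of the point (2-12).
#' @param ionic_strength mol L-1 NaNO3.
#' @param pmg_total total glyphosate, mol L-1.
#' @param ha_loading HA surface loading Gamma_NOM, mg HA m-2.
#' @param goethite_conc g L-1.
#' @param ssa specific surface area, m2 g-1.
#' @return list of class `batch_system`.
#' @export
batch_system <- function(pH, ionic_strength, pmg_total, ha_loading = 0,
                         goethite_conc = 10, ssa = 94) {
  stopifnot(pH >= 2, pH <= 12, ionic_strength > 0, pmg_total >= 0,
            ha_loading >= 0, goethite_conc > 0, ssa > 0)
  structure(list(pH = pH, ionic_strength = ionic_strength,
                 pmg_total = pmg_total, ha_loading = ha_loading,
                 goethite_conc = goethite_conc, ssa = ssa),
            class = "batch_system")
}

# identify aqueous vs surface PMG species in a result
.pmg_partition <- function(result, component = "PMG") {
  if (!component %in% result$component_names) {
    return(list(dissolved = 0, adsorbed_mol_l = 0))
  }
  nu_p <- result$stoich[, component]
  sel <- nu_p != 0
  amt <- result$species_amounts[sel] * nu_p[sel]
  ph <- result$species_phase[sel]
  list(dissolved = sum(amt[ph == "aqueous"]),
       adsorbed_mol_l = sum(amt[ph == "surface"]))
}

#' Simulate one batch adsorption point
#'
#' Computes the NOM surface-component density from the HA loading, the
#' steric blocker density from pH and ionic strength, injects both as
#' surface-component totals, solves the equilibrium, and extracts the
#' dissolved and adsorbed glyphosate together with the NOM interface
#' statistics.
#'
#' @param sys a [batch_system()].
#' @param db database (steric-augmented); default [default_database()].
#' @param nom a [nomcd_params()].
#' @param steric a [steric_params()].
#' @param edlp an [edl_parameters()]; its surface area and solid
#'   concentration are overridden by the system's.
#' @param options a [solver_options()].
#' @param init optional solver warm start (see [solve_equilibrium()]).
#' @return list of class `isotherm_point`: the system, `pmg_dissolved`
#'   (mol L-1), `pmg_adsorbed` (umol m-2), `theta_s`, `s0`, `hnom`
#'   (umol m-2), `nom_outer_sphere_fraction`, `r_ratio`, and the full
#'   `result`.
#' @export
simulate_point <- function(sys, db = default_database(),
                           nom = nomcd_params(), steric = steric_params(),
                           edlp = edl_parameters(),
                           options = solver_options(), init = NULL) {
  stopifnot(inherits(sys, "batch_system"))
  edlp <- edl_parameters(c1 = edlp$c1, c2 = edlp$c2,
                         specific_surface_area = sys$ssa,
                         solid_concentration = sys$goethite_conc)
  hnom <- hnom_surface_density(sys$ha_loading, nom)          # umol m-2
  th <- theta_s(10^(-sys$pH), sys$ionic_strength, steric)
  s0 <- s0_surface_density(th, steric$s_max)                 # umol m-2
  totals <- c(Na = sys$ionic_strength, NO3 = sys$ionic_strength,
              PMG = sys$pmg_total,
              HNOM = hnom * 1e-6, S0 = s0 * 1e-6)            # mol m-2
  totals <- totals[names(totals) %in% db$components$name]
  res <- tryCatch(
    solve_equilibrium(db,
                      system_composition(
                        totals = totals,
                        fixed_activities = c(H = 10^(-sys$pH)),
                        ionic_strength = sys$ionic_strength),
                      edlp, options, init = init),
    error = function(e) {
      stop(sprintf(
        "point (pH %.2f, I %.3g M, PMG %.3g M, HA %.2f mg/m2): %s",
        sys$pH, sys$ionic_strength, sys$pmg_total, sys$ha_loading,
        conditionMessage(e)), call. = FALSE)
    })
  part <- .pmg_partition(res)
  iface <- nom_interface_stats(res)
  structure(list(system = sys,
                 pmg_dissolved = part$dissolved,
                 pmg_adsorbed = part$adsorbed_mol_l /
                   max(res$area_per_litre, .Machine$double.eps) * 1e6,
                 theta_s = th, s0 = s0, hnom = hnom,
                 nom_outer_sphere_fraction = iface[["outer_sphere_fraction"]],
                 r_ratio = iface[["r_ratio"]],
                 result = res),
            class = "isotherm_point")
}

#' NOM interface statistics of a speciation result
#'
#' The fraction of outer-sphere NOM complexes,
#' `f_OS = [FeOH2NOM] / ([FeNOM] + [FeNOMH] + [FeOH2NOM])`, and its
#' translation into the carboxyl distribution ratio over the first
#' Stern layer, `R = 0.5 (1 - f_OS)`: a fully inner-sphere NOM layer
#' (FeNOM, one of its two carboxylates in plane 1) has R = 0.5, a fully
#' outer-sphere layer (FeOH2-NOM, no carboxylates in plane 1) has
#' R = 0.
#'
#' @param x a `speciation_result` or `isotherm_point`.
#' @param outer_species name(s) of the outer-sphere NOM species.
#' @param component name of the NOM surface component.
#' @return named numeric `c(outer_sphere_fraction, r_ratio)`; both `NA`
#'   when the system contains no NOM.
#' @export
nom_interface_stats <- function(x, outer_species = "FeOH2NOM",
                                component = "HNOM") {
  res <- if (inherits(x, "isotherm_point")) x$result else x
  stopifnot(inherits(res, "speciation_result"))
  if (!component %in% res$component_names) {
    return(c(outer_sphere_fraction = NA_real_, r_ratio = NA_real_))
  }
  sel <- res$stoich[, component] != 0
  tot <- sum(res$species_amounts[sel])
  if (tot <= 0) {
    return(c(outer_sphere_fraction = NA_real_, r_ratio = NA_real_))
  }
  os <- sum(res$species_amounts[sel][names(res$species_amounts[sel]) %in%
                                       outer_species])
  f_os <- os / tot
  c(outer_sphere_fraction = f_os, r_ratio = 0.5 * (1 - f_os))
}

#' Carboxyl distribution ratio from an outer-sphere fraction
#'
#' @param f_os fraction of outer-sphere NOM complexes, in \[0, 1\].
#' @return `R = 0.5 (1 - f_os)`.
#' @export
r_ratio_from_fos <- function(f_os) {
  stopifnot(all(f_os >= 0), all(f_os <= 1))
  0.5 * (1 - f_os)
}

#' Simulate an isotherm (a list of batch points)
#'
#' Each point is solved with its own pH, ionic strength and loading.
#' Order is preserved. Individual failures are collected; the call
#' fails only if every point fails.
#'
#' @param systems list of [batch_system()] objects, or a data.frame
#'   with columns `pH`, `ionic_strength_M`, `pmg_total_M`,
#'   `ha_loading_mg_m2` and optionally `goethite_g_L`, `ssa_m2_g`.
#' @inheritParams simulate_point
#' @return data.frame with one row per point: the system columns plus
#'   `pmg_dissolved_M`, `pmg_adsorbed_umol_m2`, `theta_s`, `s0_umol_m2`,
#'   `hnom_umol_m2`, `f_os`, `r_ratio`, `error` (NA when solved).
#' @export
simulate_isotherm <- function(systems, db = default_database(),
                              nom = nomcd_params(),
                              steric = steric_params(),
                              edlp = edl_parameters(),
                              options = solver_options()) {
  if (is.data.frame(systems)) systems <- batch_systems_from_df(systems)
  stopifnot(length(systems) > 0)
  rows <- lapply(systems, function(sys) {
    pt <- tryCatch(simulate_point(sys, db, nom, steric, edlp, options),
                   error = function(e) e)
    if (inherits(pt, "error")) {
      data.frame(pH = sys$pH, ionic_strength_M = sys$ionic_strength,
                 goethite_g_L = sys$goethite_conc, ssa_m2_g = sys$ssa,
                 ha_loading_mg_m2 = sys$ha_loading,
                 pmg_total_M = sys$pmg_total,
                 pmg_dissolved_M = NA_real_,
                 pmg_adsorbed_umol_m2 = NA_real_,
                 theta_s = NA_real_, s0_umol_m2 = NA_real_,
                 hnom_umol_m2 = NA_real_, f_os = NA_real_,
                 r_ratio = NA_real_,
                 error = conditionMessage(pt),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pH = sys$pH, ionic_strength_M = sys$ionic_strength,
                 goethite_g_L = sys$goethite_conc, ssa_m2_g = sys$ssa,
                 ha_loading_mg_m2 = sys$ha_loading,
                 pmg_total_M = sys$pmg_total,
                 pmg_dissolved_M = pt$pmg_dissolved,
                 pmg_adsorbed_umol_m2 = pt$pmg_adsorbed,
                 theta_s = pt$theta_s, s0_umol_m2 = pt$s0,
                 hnom_umol_m2 = pt$hnom,
                 f_os = pt$nom_outer_sphere_fraction,
                 r_ratio = pt$r_ratio,
                 error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (all(!is.na(out$error))) {
    stop("all isotherm points failed; first error: ", out$error[1])
  }
  out
}

#' @rdname simulate_isotherm
#' @param df data.frame in the input-CSV dialect.
#' @export
batch_systems_from_df <- function(df) {
  need <- c("pH", "ionic_strength_M", "pmg_total_M")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  g <- if ("goethite_g_L" %in% names(df)) df$goethite_g_L else 10
  a <- if ("ssa_m2_g" %in% names(df)) df$ssa_m2_g else 94
  ha <- if ("ha_loading_mg_m2" %in% names(df)) df$ha_loading_mg_m2 else 0
  lapply(seq_len(nrow(df)), function(i) {
    batch_system(pH = df$pH[i], ionic_strength = df$ionic_strength_M[i],
                 pmg_total = df$pmg_total_M[i],
                 ha_loading = rep(ha, length.out = nrow(df))[i],
                 goethite_conc = rep(g, length.out = nrow(df))[i],
                 ssa = rep(a, length.out = nrow(df))[i])
  })
}

#' Root-mean-square error on log10 concentrations
#'
#' @param model,observed concentrations in mol L-1, equal length, all
#'   strictly positive (censored observations are excluded upstream).
#' @return RMSE in log10 units.
#' @examples
#' rmse_log10(c(1e-5, 1e-6), c(2e-5, 5e-7))   # 0.30103
#' @export
rmse_log10 <- function(model, observed) {
  if (length(model) != length(observed)) {
    stop("model and observed have different lengths")
  }
  if (any(model <= 0) || any(observed <= 0)) {
    stop("rmse_log10 requires strictly positive concentrations")
  }
  sqrt(mean((log10(model) - log10(observed))^2))
}

#' Fit the steric parameter (and optionally FeNOM_T) to adsorption data
#'
#' Bounded Levenberg-Marquardt least squares on the residuals
#' `log10(modelled dissolved PMG) - log10(observed dissolved PMG)`,
#' the objective used throughout: RMSE on the logarithm of the
#' solution concentration. Confidence intervals are first-order
#' (Jacobian-based) 0.95 intervals; `r_squared` is computed on the
#' log10 concentrations.
#'
#' @param data data.frame in the input-CSV dialect with an additional
#'   column `pmg_dissolved_M` of observed dissolved concentrations.
#'   Rows with `pmg_dissolved_M` at or below `lod` (or NA) are excluded
#'   from the objective.
#' @param free character subset of `c("s_max", "fenomt")`.
#' @param start,lower,upper named numeric start values and box bounds
#'   for the free parameters (defaults: s_max start 1, bounds
#'   \[0, 6\]; fenomt start 1.77, bounds \[0, 6\]).
#' @param lod detection limit, mol L-1 (default 6e-7).
#' @inheritParams simulate_point
#' @return list of class `fit_result`: `estimates` (data.frame with
#'   estimate, se, ci_lower, ci_upper), `rmse`, `r_squared`, `n`,
#'   `objective_trace`, `converged`, `at_bound`.
#' @export
fit_parameters <- function(data, free = "s_max",
                           db = default_database(),
                           nom = nomcd_params(), steric = steric_params(),
                           edlp = edl_parameters(),
                           options = solver_options(),
                           start = NULL, lower = NULL, upper = NULL,
                           lod = 6e-7) {
  free <- match.arg(free, c("s_max", "fenomt"), several.ok = TRUE)
  defaults <- list(start = c(s_max = 1, fenomt = 1.77),
                   lower = c(s_max = 0, fenomt = 0),
                   upper = c(s_max = 6, fenomt = 6))
  pick <- function(user, what) {
    v <- defaults[[what]][free]
    if (!is.null(user)) v[names(user)] <- user
    v
  }
  p0 <- pick(start, "start")
  lo <- pick(lower, "lower")
  hi <- pick(upper, "upper")

  obs <- data$pmg_dissolved_M
  usable <- !is.na(obs) & obs > lod
  if (sum(usable) < 2 * length(free)) {
    stop("not enough observations above the detection limit (",
         sum(usable), ") to fit ", length(free), " parameter(s)")
  }
  dat <- data[usable, , drop = FALSE]
  obs <- obs[usable]
  systems <- batch_systems_from_df(dat)
  trace <- list()
  warm <- vector("list", length(systems))   # per-point solver warm starts

  residual_fn <- function(p) {
    nom2 <- nom
    steric2 <- steric
    if ("fenomt" %in% names(p)) nom2$fenomt <- p[["fenomt"]]
    if ("s_max" %in% names(p)) steric2$s_max <- p[["s_max"]]
    model <- vapply(seq_along(systems), function(i) {
      pt <- simulate_point(systems[[i]], db, nom2, steric2, edlp, options,
                           init = warm[[i]])
      warm[[i]] <<- pt$result$solver_state
      pt$pmg_dissolved
    }, numeric(1))
    r <- log10(pmax(model, 1e-30)) - log10(obs)
    trace[[length(trace) + 1]] <<- c(p, rmse = sqrt(mean(r^2)))
    r
  }

  fit <- minpack.lm::nls.lm(par = p0, lower = lo, upper = hi,
                            fn = residual_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-10, ptol = 1e-8))
  est <- fit$par
  r <- fit$fvec
  n <- length(r)
  df_resid <- n - length(free)
  sigma2 <- sum(r^2) / df_resid
  cov <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) {
    matrix(NA_real_, length(free), length(free))
  })
  se <- sqrt(pmax(diag(cov), 0))
  tq <- stats::qt(0.975, df_resid)
  at_bound <- abs(est - lo) < 1e-8 | abs(est - hi) < 1e-8
  lobs <- log10(obs)
  r2 <- 1 - sum(r^2) / sum((lobs - mean(lobs))^2)
  estimates <- data.frame(parameter = names(est),
                          estimate = unname(est), se = unname(se),
                          ci_lower = unname(est - tq * se),
                          ci_upper = unname(est + tq * se),
                          at_bound = unname(at_bound),
                          stringsAsFactors = FALSE)
  structure(list(estimates = estimates,
                 rmse = sqrt(mean(r^2)), r_squared = r2, n = n,
                 objective_trace = do.call(rbind, trace),
                 converged = fit$info %in% 1:4,
                 message = fit$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> n = ", x$n, ", RMSE = ", format(x$rmse, digits = 4),
      " log10 units, r^2 = ", format(x$r_squared, digits = 4), "\n",
      sep = "")
  print(x$estimates, row.names = FALSE, digits = 4)
  if (any(x$estimates$at_bound)) cat("  note: parameter at bound\n")
  invisible(x)
}
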