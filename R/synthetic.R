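# Synthetic competitive-adsorption datasets emulating the batch design:
# HA-goethite composites at several HA loadings and target pH values in
# two NaNO3 backgrounds, each receiving a 9-step glyphosate dilution
# series, with per-isotherm pH scatter, log-normal measurement noise and
# detection-limit censoring.

#' Describe a synthetic experimental design
#'
#' Defaults reproduce the structure of the batch experiments the model
#' is built for: HA loadings 0.5-1.6 mg m-2, target pH 4-8 with within-
#' isotherm scatter of at most 0.3 units, NaNO3 at 0.1 and 0.01 M, a
#' 1.45 mM glyphosate stock dosed at 0.05-0.50 of the 1 mL final
#' volume (so the top total is 0.725 mM), 10 g L-1 goethite of
#' 94 m2 g-1.
#'
#' @param ha_levels HA loadings, mg HA m-2.
#' @param ph_targets target pH values.
#' @param ph_jitter maximum within-isotherm pH spread (total width).
#' @param ionic_strengths mol L-1.
#' @param pmg_stock glyphosate stock concentration, mol L-1.
#' @param stock_volumes dose volumes as fractions of the final volume.
#' @param goethite goethite concentration, g L-1.
#' @param ssa specific surface area, m2 g-1.
#' @param seed integer seed driving the pH jitter.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(ha_levels = c(0.5, 1.1, 1.3, 1.6),
                        ph_targets = c(4, 5, 6, 7, 8),
                        ph_jitter = 0.3,
                        ionic_strengths = c(0.1, 0.01),
                        pmg_stock = 1.45e-3,
                        stock_volumes = c(0.50, 0.40, 0.35, 0.30, 0.25,
                                          0.20, 0.15, 0.10, 0.05),
                        goethite = 10, ssa = 94, seed = 1L) {
  stopifnot(all(ha_levels > 0), all(ionic_strengths > 0), pmg_stock > 0,
            all(stock_volumes > 0), all(stock_volumes <= 1),
            ph_jitter >= 0, ph_jitter <= 0.3, goethite > 0, ssa > 0)
  structure(list(ha_levels = ha_levels, ph_targets = ph_targets,
                 ph_jitter = ph_jitter, ionic_strengths = ionic_strengths,
                 pmg_stock = pmg_stock, stock_volumes = stock_volumes,
                 goethite = goethite, ssa = ssa, seed = as.integer(seed)),
            class = "design_spec")
}

# run fn with a private RNG stream, leaving the caller's stream intact
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate the batch systems of a synthetic design
#'
#' Full crossing of HA level, target pH and ionic strength; within each
#' isotherm every dilution point receives its own pH drawn uniformly in
#' `target +/- ph_jitter/2`, reproducibly from the design seed.
#'
#' @param spec a [design_spec()].
#' @return data.frame, one row per point: `isotherm` id, `ph_target`,
#'   `pH`, `ionic_strength_M`, `ha_loading_mg_m2`, `pmg_total_M`,
#'   `goethite_g_L`, `ssa_m2_g`.
#' @export
generate_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  grid <- expand.grid(ha = spec$ha_levels, ph = spec$ph_targets,
                      I = spec$ionic_strengths, KEEP.OUT.ATTRS = FALSE)
  nv <- length(spec$stock_volumes)
  .with_seed(spec$seed, function() {
    rows <- lapply(seq_len(nrow(grid)), function(k) {
      ph_pts <- grid$ph[k] +
        stats::runif(nv, -spec$ph_jitter / 2, spec$ph_jitter / 2)
      data.frame(isotherm = k,
                 ph_target = grid$ph[k], pH = ph_pts,
                 ionic_strength_M = grid$I[k],
                 ha_loading_mg_m2 = grid$ha[k],
                 pmg_total_M = spec$pmg_stock * spec$stock_volumes,
                 goethite_g_L = spec$goethite, ssa_m2_g = spec$ssa)
    })
    do.call(rbind, rows)
  })
}

#' The 16-isotherm reference design
#'
#' Assembles the layout of the batch study the model was developed on:
#' the high HA level (1.6 mg m-2 at pH 4, 5 and 6; 1.3 mg m-2 at pH 7
#' and 8), the intermediate level (1.1 mg m-2 at pH 4-8), and the low
#' level (0.5 mg m-2 at pH 4, 6 and 8) in both 0.1 M and 0.01 M NaNO3
#' backgrounds: 16 isotherms of 9 glyphosate dilution points each. The
#' within-isotherm pH scatter is drawn from `seed` as in
#' [generate_design()].
#'
#' @param seed integer seed for the pH jitter.
#' @param ph_jitter maximum within-isotherm pH spread.
#' @return data.frame in the dialect of [generate_design()].
#' @export
reference_design <- function(seed = 1L, ph_jitter = 0.3) {
  blocks <- list(
    list(ha = 1.6, ph = c(4, 5, 6), I = 0.1),
    list(ha = 1.3, ph = c(7, 8), I = 0.1),
    list(ha = 1.1, ph = c(4, 5, 6, 7, 8), I = 0.1),
    list(ha = 0.5, ph = c(4, 6, 8), I = 0.1),
    list(ha = 0.5, ph = c(4, 6, 8), I = 0.01))
  out <- lapply(seq_along(blocks), function(b) {
    d <- generate_design(design_spec(
      ha_levels = blocks[[b]]$ha, ph_targets = blocks[[b]]$ph,
      ionic_strengths = blocks[[b]]$I, ph_jitter = ph_jitter,
      seed = seed + b - 1L))
    d$isotherm <- paste0(b, ".", d$isotherm)
    d
  })
  do.call(rbind, out)
}

#' Simulate noisy observations on a design
#'
#' Runs the steric NOM-CD model at the "true" parameter values for each
#' design point, then perturbs the dissolved concentration with
#' multiplicative log-normal noise (`log10 observed = log10 true +
#' N(0, sigma^2)`) and flags observations below the detection limit as
#' censored. The truth is recorded so recovery studies can compare
#' against it.
#'
#' @param design data.frame from [generate_design()] (or any data.frame
#'   in the same dialect).
#' @param truth list with elements `s_max` and optionally `fenomt`
#'   overriding the defaults of [steric_params()] / [nomcd_params()].
#' @param noise_sigma standard deviation of the log10 noise.
#' @param lod detection limit, mol L-1 (default 6e-7, the lowest
#'   measurable dissolved concentration of the emulated assay).
#' @param seed integer seed for the noise.
#' @inheritParams simulate_point
#' @return list of class `synthetic_dataset`: `points` (the design plus
#'   `pmg_true_M`, `pmg_dissolved_M`, `censored`), `truth`,
#'   `noise_sigma`, `lod`, `seed`.
#' @export
simulate_observations <- function(design, truth = list(s_max = 2.56),
                                  noise_sigma = 0.2, lod = 6e-7,
                                  seed = 1L,
                                  db = default_database(),
                                  nom = nomcd_params(),
                                  steric = steric_params(),
                                  edlp = edl_parameters(),
                                  options = solver_options()) {
  stopifnot(is.data.frame(design), noise_sigma >= 0, lod > 0)
  if (!is.null(truth$s_max)) steric$s_max <- truth$s_max
  if (!is.null(truth$fenomt)) nom$fenomt <- truth$fenomt
  sim <- simulate_isotherm(design, db, nom, steric, edlp, options)
  if (any(!is.na(sim$error))) {
    stop("solver failed for ", sum(!is.na(sim$error)),
         " design point(s); first: ", sim$error[!is.na(sim$error)][1])
  }
  true_c <- sim$pmg_dissolved_M
  obs <- .with_seed(as.integer(seed), function() {
    10^(log10(pmax(true_c, 1e-30)) +
          stats::rnorm(length(true_c), 0, noise_sigma))
  })
  points <- design
  points$pmg_true_M <- true_c
  points$pmg_dissolved_M <- obs
  points$censored <- obs < lod
  structure(list(points = points,
                 truth = list(s_max = steric$s_max, fenomt = nom$fenomt),
                 noise_sigma = noise_sigma, lod = lod,
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$points), " points (",
      sum(x$points$censored), " censored at LOD ",
      format(x$lod, digits = 3), " M)\n", sep = "")
  cat("  truth: s_max = ", x$truth$s_max, " umol/m2, fenomt = ",
      x$truth$fenomt, " umol/m2; noise sigma = ", x$noise_sigma,
      " log10 units; seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
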