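# Shared fixtures and independent oracles. Everything is built in code;
# the only file fixture is the shipped tableau inst/extdata/table1.tsv.

table1_path <- function() {
  system.file("extdata", "table1.tsv", package = "snomcd", mustWork = TRUE)
}

# default database built once per test run (deterministic)
cached_default_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- default_database()
    db
  }
})

# a single uncharged site + uncharged ligand, no electrostatics: the
# adsorbed amount has the closed-form Langmuir solution
langmuir_db <- function(logK = 5, site_density = 2) {
  components <- rbind(
    component("X", "surface_site", 0, site_density),
    component("L", "aqueous_master", 0))
  tab <- data.frame(name = c("X", "L", "XL"),
                    X = c(1, 0, 1), L = c(0, 1, 1),
                    dz0 = 0, dz1 = 0, dz2 = 0,
                    logK = c(0, 0, logK))
  model_database(components, tab)
}

# closed-form Langmuir: XL from totals XT, LT and K (concentration basis)
langmuir_oracle <- function(K, XT, LT) {
  b <- XT + LT + 1 / K
  (b - sqrt(b^2 - 4 * XT * LT)) / 2
}

# independent non-electrostatic speciation oracle for a site + ligand +
# proton system (all dz = 0): nested fixed-point on the two balances,
# never touching the Newton solver. HL carries charge +1, so its
# concentration picks up a Davies activity factor (recomputed inline).
noelec_oracle <- function(K_XL, K_HL, XT, LT, aH, I, tol = 1e-14) {
  g1 <- 10^(-0.509 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I))
  kh <- K_HL * aH / g1
  free_L <- function(X) {
    stats::uniroot(function(L) L + kh * L + K_XL * X * L - LT,
                   c(0, LT), tol = tol)$root
  }
  X <- stats::uniroot(function(X) X + K_XL * X * free_L(X) - XT,
                      c(0, XT), tol = tol)$root
  L <- free_L(X)
  list(X = X, L = L, XL = K_XL * X * L, HL = kh * L)
}

# database for the oracle system above, with optional charge switched on
noelec_db <- function(logK_XL = 4, logK_HL = 6) {
  components <- rbind(
    component("X", "surface_site", 0, 1),
    component("L", "aqueous_master", 0),
    component("H", "aqueous_master", 1))
  tab <- data.frame(name = c("X", "L", "XL", "HL"),
                    X = c(1, 0, 1, 0), L = c(0, 1, 1, 1),
                    H = c(0, 0, 0, 1),
                    dz0 = 0, dz1 = 0, dz2 = 0,
                    logK = c(0, 0, logK_XL, logK_HL))
  model_database(components, tab)
}

# strip the steric mirror species (and the S0 component) from a database
strip_steric <- function(db) {
  s0 <- db$components$charge == 0 & db$components$kind == "surface_component"
  keep_c <- !s0
  keep_s <- db$stoich[, db$components$name[s0]] == 0
  tab <- cbind(data.frame(name = db$species$name[keep_s]),
               as.data.frame(db$stoich[keep_s, keep_c, drop = FALSE]),
               db$species[keep_s, c("dz0", "dz1", "dz2", "logK")])
  rownames(tab) <- NULL
  model_database(db$components[keep_c, , drop = FALSE], tab,
                 metadata = db$metadata)
}

# recovery-study design: measurable window of the batch layout (HA 1.1
# and 1.6 mg/m2, pH 6-8, both ionic strengths; 108 dilution points)
recovery_design <- function(seed) {
  generate_design(design_spec(ha_levels = c(1.1, 1.6),
                              ph_targets = c(6, 7, 8),
                              ionic_strengths = c(0.1, 0.01),
                              seed = seed))
}

bare_composition <- function(pH, I = 0.1) {
  system_composition(totals = c(Na = I, NO3 = I),
                     fixed_activities = c(H = 10^-pH),
                     ionic_strength = I)
}
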