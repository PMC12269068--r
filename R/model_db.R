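# Chemical model database: components, species tableau, charge-distribution
# bookkeeping. A database is a plain list with three parts:
#   components: data.frame(name, kind, charge, site_density)
#   species:    data.frame(name, dz0, dz1, dz2, logK, phase)
#   stoich:     species x components matrix of signed integers/fractions
# Conventions:
#   * every surface component's reference charge is counted in plane 0;
#   * dz0/dz1/dz2 are the charges ADDED to planes 0/1/2 by the formation
#     reaction, so dz0+dz1+dz2 equals the summed charge of the aqueous
#     reactants (H+, Na+, ...);
#   * the total plane-0 charge of a surface species is therefore
#     (sum of surface-component reference charges) + dz0.

COMPONENT_KINDS <- c("aqueous_master", "surface_site", "surface_component")

#' Create a model component
#'
#' @param name unique identifier (e.g. `"FeOH"`, `"HNOM"`, `"H"`).
#' @param kind one of `"aqueous_master"`, `"surface_site"`,
#'   `"surface_component"`.
#' @param charge reference charge in valence units (e.g. -0.5 for the
#'   singly coordinated goethite site FeOH).
#' @param site_density crystallographic site density in sites nm-2;
#'   required for `surface_site` components, absent otherwise. Densities
#'   of `surface_component` kinds (adsorbed NOM, steric blocker) are
#'   system inputs, not database properties, and stay `NA` here.
#' @return one-row data.frame.
#' @export
component <- function(name, kind, charge, site_density = NA_real_) {
  kind <- match.arg(kind, COMPONENT_KINDS)
  data.frame(name = as.character(name), kind = kind,
             charge = as.numeric(charge),
             site_density = as.numeric(site_density),
             stringsAsFactors = FALSE)
}

#' Assemble a model database from a components table and a species tableau
#'
#' @param components data.frame as returned by (rows of) [component()].
#' @param tableau data.frame with columns `name`, one column per component
#'   name holding the stoichiometric coefficient, `dz0`, `dz1`, `dz2`,
#'   `logK`. Missing component columns are taken as zero.
#' @param metadata free-text provenance string.
#' @param check if `TRUE` (default) stop when [validate_database()]
#'   reports violations.
#' @return object of class `snomcd_db`.
#' @export
model_database <- function(components, tableau, metadata = "", check = TRUE) {
  stopifnot(is.data.frame(components), is.data.frame(tableau))
  comp_names <- components$name
  stoich <- matrix(0, nrow(tableau), length(comp_names),
                   dimnames = list(tableau$name, comp_names))
  for (cn in comp_names) {
    if (cn %in% names(tableau)) stoich[, cn] <- as.numeric(tableau[[cn]])
  }
  extra <- setdiff(names(tableau),
                   c("name", comp_names, "dz0", "dz1", "dz2", "logK", "phase"))
  if (length(extra) > 0) {
    stop("tableau references unknown component(s): ",
         paste(extra, collapse = ", "))
  }
  surface_cols <- comp_names[components$kind != "aqueous_master"]
  is_surface <- if (length(surface_cols) > 0 && nrow(tableau) > 0) {
    rowSums(abs(stoich[, surface_cols, drop = FALSE])) > 0
  } else rep(FALSE, nrow(tableau))
  species <- data.frame(
    name = as.character(tableau$name),
    dz0 = as.numeric(tableau$dz0), dz1 = as.numeric(tableau$dz1),
    dz2 = as.numeric(tableau$dz2), logK = as.numeric(tableau$logK),
    phase = ifelse(is_surface, "surface", "aqueous"),
    stringsAsFactors = FALSE)
  db <- structure(list(components = components, species = species,
                       stoich = stoich, metadata = metadata),
                  class = "snomcd_db")
  if (check) {
    v <- validate_database(db)
    if (length(v) > 0) {
      stop("invalid model database:\n  ", paste(v, collapse = "\n  "))
    }
  }
  db
}

#' @export
print.snomcd_db <- function(x, ...) {
  cat("<snomcd_db> ", nrow(x$components), " components, ",
      nrow(x$species), " species\n", sep = "")
  if (nzchar(x$metadata)) cat("  ", x$metadata, "\n", sep = "")
  kinds <- table(x$components$kind)
  cat("  components: ",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  surface species: ", sum(x$species$phase == "surface"),
      ", aqueous species: ", sum(x$species$phase == "aqueous"), "\n", sep = "")
  invisible(x)
}

# charge of each species summed over its components (aqueous valence for
# dissolved species; formal component-sum for surface species)
species_charge <- function(db) {
  drop(db$stoich %*% db$components$charge)
}

# plane-0 reference charge carried by the surface components of each species
species_ref0 <- function(db) {
  surf <- db$components$kind != "aqueous_master"
  if (!any(surf)) return(rep(0, nrow(db$species)))
  drop(db$stoich[, surf, drop = FALSE] %*% db$components$charge[surf])
}

# summed charge of the aqueous-master reactants of each species; the CD
# convention requires dz0+dz1+dz2 to equal this for surface species
species_aq_charge <- function(db) {
  aq <- db$components$kind == "aqueous_master"
  if (!any(aq)) return(rep(0, nrow(db$species)))
  drop(db$stoich[, aq, drop = FALSE] %*% db$components$charge[aq])
}

# the steric blocker component, if present: a zero-charged surface component
steric_component <- function(db) {
  i <- which(db$components$kind == "surface_component" &
               db$components$charge == 0)
  if (length(i) == 0) return(NA_character_)
  db$components$name[i[1]]
}

#' Validate a model database
#'
#' Checks every structural invariant of the tableau and returns the
#' violations as character descriptions (an empty vector means the
#' database is valid). Violations are data, not errors: callers decide
#' whether to stop.
#'
#' Rules checked: unique component and species names; known component
#' kinds; positive site densities for surface sites and none for aqueous
#' masters; aqueous species carry no plane charge; for surface species
#' the charge-distribution triplet sums to the total charge of the
#' aqueous reactants; steric mirror species are exact copies (logK and
#' dz) of their parents.
#'
#' @param db a `snomcd_db`.
#' @return character vector of violation descriptions.
#' @export
validate_database <- function(db) {
  v <- character(0)
  cmp <- db$components
  sp <- db$species
  if (anyDuplicated(cmp$name)) {
    v <- c(v, paste0("duplicate component name(s): ",
                     paste(unique(cmp$name[duplicated(cmp$name)]),
                           collapse = ", ")))
  }
  if (anyDuplicated(sp$name)) {
    v <- c(v, paste0("duplicate species name(s): ",
                     paste(unique(sp$name[duplicated(sp$name)]),
                           collapse = ", ")))
  }
  bad_kind <- !cmp$kind %in% COMPONENT_KINDS
  for (nm in cmp$name[bad_kind]) {
    v <- c(v, paste0("component ", nm, ": unknown kind"))
  }
  need_sd <- cmp$kind == "surface_site"
  for (nm in cmp$name[need_sd & !(is.finite(cmp$site_density) &
                                    cmp$site_density > 0)]) {
    v <- c(v, paste0("component ", nm,
                     ": surface_site requires site_density > 0"))
  }
  for (nm in cmp$name[cmp$kind == "aqueous_master" &
                        is.finite(cmp$site_density)]) {
    v <- c(v, paste0("component ", nm,
                     ": aqueous_master must not carry a site_density"))
  }
  if (nrow(sp) == 0) return(v)

  dzsum <- sp$dz0 + sp$dz1 + sp$dz2
  aqz <- species_aq_charge(db)
  for (j in seq_len(nrow(sp))) {
    if (sp$phase[j] == "aqueous") {
      if (any(abs(c(sp$dz0[j], sp$dz1[j], sp$dz2[j])) > 1e-12)) {
        v <- c(v, paste0("species ", sp$name[j],
                         ": aqueous species must have dz0=dz1=dz2=0"))
      }
    } else if (abs(dzsum[j] - aqz[j]) > 1e-9) {
      v <- c(v, sprintf(
        "species %s: dz0+dz1+dz2 = %g does not equal the summed charge of its aqueous reactants (%g)",
        sp$name[j], dzsum[j], aqz[j]))
    }
  }

  # steric mirrors must copy their parent exactly
  s0 <- steric_component(db)
  if (!is.na(s0)) {
    has_s <- db$stoich[, s0] != 0
    for (j in which(has_s)) {
      parent_stoich <- db$stoich[j, ]
      parent_stoich[s0] <- 0
      hit <- which(!has_s &
                     apply(db$stoich, 1, function(r)
                       all(abs(r - parent_stoich) < 1e-12)))
      for (k in hit) {
        same <- abs(sp$logK[j] - sp$logK[k]) < 1e-12 &&
          all(abs(c(sp$dz0[j] - sp$dz0[k], sp$dz1[j] - sp$dz1[k],
                    sp$dz2[j] - sp$dz2[k])) < 1e-12)
        if (!same) {
          v <- c(v, paste0("species ", sp$name[j],
                           ": steric mirror differs from parent ",
                           sp$name[k], " in logK or dz"))
        }
      }
    }
  }
  v
}

#' Save a model database as a tab-separated tableau file
#'
#' The file has two sections, `[components]` and `[species]`, each a
#' TSV table. Leading lines starting with `#` hold the metadata.
#' [load_database()] reads the same dialect back;
#' `save_database(load_database(f), f2)` reproduces `f` up to
#' whitespace.
#'
#' @param db a `snomcd_db`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_database <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(db$metadata)) {
    writeLines(paste0("# ", strsplit(db$metadata, "\n")[[1]]), con)
  }
  writeLines("[components]", con)
  cmp <- db$components
  writeLines(paste(c("name", "kind", "charge", "site_density"),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(cmp))) {
    writeLines(paste(cmp$name[i], cmp$kind[i],
                     format(cmp$charge[i], digits = 15),
                     ifelse(is.na(cmp$site_density[i]), "NA",
                            format(cmp$site_density[i], digits = 15)),
                     sep = "\t"), con)
  }
  writeLines("[species]", con)
  writeLines(paste(c("name", cmp$name, "dz0", "dz1", "dz2", "logK"),
                   collapse = "\t"), con)
  sp <- db$species
  for (j in seq_len(nrow(sp))) {
    writeLines(paste(c(sp$name[j],
                       format(db$stoich[j, ], digits = 15),
                       format(c(sp$dz0[j], sp$dz1[j], sp$dz2[j],
                                sp$logK[j]), digits = 15)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Load a model database from a tableau file
#'
#' @param path file written by [save_database()] (tab-separated,
#'   `[components]` / `[species]` sections).
#' @param check validate after parsing (default `TRUE`).
#' @return a `snomcd_db`.
#' @export
load_database <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("no such tableau file: ", path)
  lines <- readLines(path)
  trimmed <- trimws(lines)
  meta_idx <- which(startsWith(trimmed, "#"))
  metadata <- paste(sub("^#\\s?", "", trimmed[meta_idx]), collapse = "\n")
  ci <- which(trimmed == "[components]")
  si <- which(trimmed == "[species]")
  if (length(ci) != 1 || length(si) != 1 || si <= ci) {
    stop("tableau parse error in ", path,
         ": need one [components] section followed by one [species] section")
  }
  keep <- function(idx) idx[nzchar(trimmed[idx]) & !startsWith(trimmed[idx], "#")]
  crange <- keep(seq(ci + 1, si - 1))
  srange <- keep(seq(si + 1, length(lines)))
  parse_tsv <- function(idx, what) {
    if (length(idx) < 2) {
      stop("tableau parse error in ", path, ": empty ", what,
           " section (line ", if (length(idx)) idx[1] else NA, ")")
    }
    header <- strsplit(lines[idx[1]], "\t", fixed = TRUE)[[1]]
    rows <- lapply(idx[-1], function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != length(header)) {
        stop("tableau parse error at line ", i, " of ", path, ": expected ",
             length(header), " fields, found ", length(f))
      }
      f
    })
    m <- do.call(rbind, rows)
    colnames(m) <- header
    as.data.frame(m, stringsAsFactors = FALSE)
  }
  cdf <- parse_tsv(crange, "[components]")
  sdf <- parse_tsv(srange, "[species]")
  components <- data.frame(
    name = cdf$name, kind = cdf$kind,
    charge = as.numeric(cdf$charge),
    site_density = suppressWarnings(as.numeric(cdf$site_density)),
    stringsAsFactors = FALSE)
  num_cols <- setdiff(names(sdf), "name")
  for (cn in num_cols) sdf[[cn]] <- as.numeric(sdf[[cn]])
  unknown <- setdiff(names(sdf), c("name", components$name,
                                   "dz0", "dz1", "dz2", "logK"))
  if (length(unknown) > 0) {
    stop("tableau parse error in ", path, ": species column(s) ",
         paste(unknown, collapse = ", "), " do not match any component")
  }
  model_database(components, sdf, metadata = metadata, check = check)
}

#' Literature-default configuration for the goethite-PMG-NOM model
#'
#' The printed core of the model (singly coordinated site density
#' 3.45 nm-2, the goethite PZC of 9.3 used as the FeOH2 protonation
#' constant, and the three NOM surface species with logK 0 / logK_H /
#' 0.6 and their charge-distribution triplets) is fixed in
#' [default_database()]. Everything else is a literature-sourced
#' default collected here so it can be overridden or swapped without
#' touching code: goethite Stern capacitances, the triply coordinated
#' site density, electrolyte pair constants, the aqueous protonation
#' ladder of glyphosate, and the glyphosate surface complexes. The
#' glyphosate surface-complex constants are representative values for a
#' monodentate phosphonate complex on goethite (with and without a
#' protonated carboxylate), not verbatim published numbers.
#'
#' @param overrides named list (or path to a JSON file when `jsonlite`
#'   is available) replacing individual defaults. Unknown names are an
#'   error.
#' @return named list of configuration values.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    pzc = 9.3,                 # FeOH2/Fe3OH protonation logK, = PZC
    site_density_singly = 3.45,  # sites nm-2
    site_density_triply = 2.70,  # sites nm-2
    c1 = 0.85, c2 = 0.75,      # Stern capacitances, F m-2
    logk_na = -0.60,           # FeOH-Na+ pair
    logk_no3 = -0.60,          # NO3- pair offset relative to pzc
    logk_h_nom = 6.0,          # FeNOMH protonation (NOM-specific)
    logk_fenom = 0.0,          # inner-sphere FeNOM
    logk_feoh2nom = 0.6,       # outer-sphere FeOH2-NOM
    pmg_aq_logk = c(HPMG = 10.14, H2PMG = 15.60, H3PMG = 17.83),
    logk_fepmg = 22.5,         # FeOH + PMG3- + 2H+ -> FePMGH(-1)
    dz_fepmg = c(0.30, -1.30, 0.0),
    logk_fepmgh = 25.5,        # FeOH + PMG3- + 3H+ -> FePMGH2(0)
    dz_fepmgh = c(0.30, -0.30, 0.0)
  )
  if (is.character(overrides) && length(overrides) == 1) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("reading a JSON config file requires the jsonlite package")
    }
    overrides <- jsonlite::read_json(overrides, simplifyVector = TRUE)
  }
  stopifnot(is.list(overrides))
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Build the default goethite-glyphosate-NOM-steric database
#'
#' Constructs the full surface speciation tableau: goethite's singly
#' (FeOH, -0.5 v.u., 3.45 sites nm-2) and triply (Fe3O, -0.5 v.u.)
#' coordinated sites with their proton and NaNO3 ion-pair species, the
#' aqueous speciation of glyphosate (master PMG3-), its two surface
#' complexes, and the three NOM surface species (inner-sphere FeNOM and
#' FeNOMH, outer-sphere FeOH2-NOM) plus the zero-charged steric
#' component S0. Call [augment_with_steric_sites()] to add the steric
#' mirror species.
#'
#' @param config list from [default_config()]; a bare named list of
#'   overrides is also accepted.
#' @param augment add the steric mirror species (default `TRUE`).
#' @return a validated `snomcd_db`.
#' @export
default_database <- function(config = list(), augment = TRUE) {
  cfg <- if (identical(sort(names(config)), sort(names(default_config())))) {
    config
  } else {
    default_config(config)
  }
  components <- rbind(
    component("H", "aqueous_master", +1),
    component("Na", "aqueous_master", +1),
    component("NO3", "aqueous_master", -1),
    component("PMG", "aqueous_master", -3),
    component("FeOH", "surface_site", -0.5, cfg$site_density_singly),
    component("Fe3O", "surface_site", -0.5, cfg$site_density_triply),
    component("HNOM", "surface_component", -1),
    component("S0", "surface_component", 0)
  )
  row <- function(name, H = 0, Na = 0, NO3 = 0, PMG = 0, FeOH = 0,
                  Fe3O = 0, HNOM = 0, S0 = 0, dz = c(0, 0, 0), logK = 0) {
    data.frame(name = name, H = H, Na = Na, NO3 = NO3, PMG = PMG,
               FeOH = FeOH, Fe3O = Fe3O, HNOM = HNOM, S0 = S0,
               dz0 = dz[1], dz1 = dz[2], dz2 = dz[3], logK = logK,
               stringsAsFactors = FALSE)
  }
  aqk <- cfg$pmg_aq_logk
  tableau <- rbind(
    row("H", H = 1),
    row("OH", H = -1, logK = -13.997),
    row("Na", Na = 1),
    row("NO3", NO3 = 1),
    row("PMG", PMG = 1),
    row("HPMG", PMG = 1, H = 1, logK = unname(aqk["HPMG"])),
    row("H2PMG", PMG = 1, H = 2, logK = unname(aqk["H2PMG"])),
    row("H3PMG", PMG = 1, H = 3, logK = unname(aqk["H3PMG"])),
    row("FeOH", FeOH = 1),
    row("FeOH2", FeOH = 1, H = 1, dz = c(1, 0, 0), logK = cfg$pzc),
    row("FeOHNa", FeOH = 1, Na = 1, dz = c(0, 1, 0), logK = cfg$logk_na),
    row("FeOH2NO3", FeOH = 1, H = 1, NO3 = 1, dz = c(1, -1, 0),
        logK = cfg$pzc + cfg$logk_no3),
    row("Fe3O", Fe3O = 1),
    row("Fe3OH", Fe3O = 1, H = 1, dz = c(1, 0, 0), logK = cfg$pzc),
    row("Fe3ONa", Fe3O = 1, Na = 1, dz = c(0, 1, 0), logK = cfg$logk_na),
    row("Fe3OHNO3", Fe3O = 1, H = 1, NO3 = 1, dz = c(1, -1, 0),
        logK = cfg$pzc + cfg$logk_no3),
    row("FeNOM", FeOH = 1, HNOM = 1, dz = c(1.5, -1.0, -0.5),
        logK = cfg$logk_fenom),
    row("FeNOMH", FeOH = 1, HNOM = 1, H = 1, dz = c(1.5, -0.5, 0),
        logK = cfg$logk_h_nom),
    row("FeOH2NOM", FeOH = 1, HNOM = 1, dz = c(2, -1.5, -0.5),
        logK = cfg$logk_feoh2nom),
    row("FePMG", FeOH = 1, PMG = 1, H = 2, dz = cfg$dz_fepmg,
        logK = cfg$logk_fepmg),
    row("FePMGH", FeOH = 1, PMG = 1, H = 3, dz = cfg$dz_fepmgh,
        logK = cfg$logk_fepmgh)
  )
  db <- model_database(components, tableau,
                       metadata = "goethite-PMG-NOM-steric default database")
  if (augment) db <- augment_with_steric_sites(db) else db
}

#' Add steric mirror species for the blocked singly coordinated sites
#'
#' The steric component S0 occupies singly coordinated FeOH sites and
#' makes them unavailable to sterically hindered adsorbates (glyphosate
#' and the NOM component itself) while leaving proton and electrolyte
#' reactions untouched. For every FeOH surface species that involves no
#' hindered component, a mirror species with one extra S0 in its
#' stoichiometry and identical logK and charge-distribution triplet is
#' added (named `S_<parent>`). The mirrored sub-pool then charges
#' exactly like the unblocked pool, so surface charging in the absence
#' of hindered adsorbates is unaffected.
#'
#' @param db a `snomcd_db` containing a zero-charged surface component.
#' @param site name of the blockable site component (default `"FeOH"`).
#' @param hindered component names whose species must NOT be mirrored.
#' @return the augmented database (idempotent: existing mirrors are kept,
#'   not duplicated).
#' @export
augment_with_steric_sites <- function(db, site = "FeOH",
                                      hindered = c("PMG", "HNOM")) {
  s0 <- steric_component(db)
  if (is.na(s0)) {
    stop("database has no steric component ",
         "(zero-charged surface_component)")
  }
  if (!site %in% db$components$name) stop("no such site component: ", site)
  hindered <- intersect(hindered, db$components$name)
  other_surface <- setdiff(
    db$components$name[db$components$kind != "aqueous_master"],
    c(site, s0))
  cand <- which(
    db$stoich[, site] > 0 &
      db$stoich[, s0] == 0 &
      rowSums(abs(db$stoich[, c(hindered, setdiff(other_surface, hindered)),
                            drop = FALSE])) == 0)
  if (length(cand) == 0) return(db)
  # skip parents whose mirror already exists
  has_s <- db$stoich[, s0] != 0
  new_rows <- list()
  for (j in cand) {
    mirror_stoich <- db$stoich[j, ]
    mirror_stoich[s0] <- 1
    exists <- any(vapply(which(has_s), function(k)
      all(abs(db$stoich[k, ] - mirror_stoich) < 1e-12), logical(1)))
    if (exists) next
    r <- c(list(name = paste0("S_", db$species$name[j])),
           as.list(mirror_stoich),
           list(dz0 = db$species$dz0[j], dz1 = db$species$dz1[j],
                dz2 = db$species$dz2[j], logK = db$species$logK[j]))
    new_rows[[length(new_rows) + 1]] <- as.data.frame(r,
                                                      stringsAsFactors = FALSE)
  }
  if (length(new_rows) == 0) return(db)
  old <- cbind(data.frame(name = db$species$name, stringsAsFactors = FALSE),
               as.data.frame(db$stoich),
               db$species[, c("dz0", "dz1", "dz2", "logK")])
  rownames(old) <- NULL
  tableau <- rbind(old, do.call(rbind, new_rows))
  model_database(db$components, tableau, metadata = db$metadata)
}
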