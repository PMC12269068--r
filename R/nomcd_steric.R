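# NOM-CD and steric sub-model arithmetic: the NOM surface-component
# density as a linear function of the HA loading, its carboxyl-normalised
# competitive strength, and the conditional steric site-blocking density.

#' Parameters of the NOM-CD surface-component scaling
#'
#' `fenomt` is the total HNOM surface-species density at the reference
#' NOM loading `gamma_ref`; it quantifies the competitive strength of a
#' given NOM material. For the humic acid studied here it is derived
#' from the carboxyl density Q_RCOO = 2.5 mol kg-1 through the nearly
#' 1:1 proportionality between surface-associated carboxylates and
#' Q_RCOO (slope 0.89 +/- 0.10), giving 1.77 umol m-2. The 0.95
#' confidence half-widths are carried as metadata (`fenomt_ci`,
#' `slope_ci`), not used in fitting.
#'
#' @param fenomt FeNOM_T, umol m-2 at the reference loading.
#' @param gamma_ref reference HA loading, mg HA m-2 (default 1.6, the
#'   maximum loading of the experimental design).
#' @param q_rcoo carboxyl density of the NOM, mol RCOO- kg-1.
#' @param slope proportionality constant between FeNOM_T* and Q_RCOO.
#' @param fenomt_ci,slope_ci 0.95 CI half-widths (metadata).
#' @return list of class `nomcd_params`.
#' @export
nomcd_params <- function(fenomt = 1.77, gamma_ref = 1.6, q_rcoo = 2.5,
                         slope = 0.89, fenomt_ci = 0.20, slope_ci = 0.10) {
  stopifnot(fenomt >= 0, gamma_ref > 0, q_rcoo >= 0, slope >= 0)
  structure(list(fenomt = fenomt, gamma_ref = gamma_ref, q_rcoo = q_rcoo,
                 slope = slope, fenomt_ci = fenomt_ci, slope_ci = slope_ci),
            class = "nomcd_params")
}

#' Parameters of the steric site-blocking sub-model
#'
#' `theta_s` (the conditional maximum degree of Stern-layer filling by
#' adsorbed NOM) is an empirical saturating function of proton activity
#' and ionic strength with coefficients `K`, `a`, `b`; `s_max` is the
#' maximum steric site density reached at full Stern-layer filling and
#' is the model's single adjustable parameter. `gamma_mst0` documents
#' the physical maximum Stern-layer NOM loading (1 mg m-2) that defines
#' theta_s; it is not used in computation.
#'
#' @param s_max S_max0, umol m-2.
#' @param K,a,b empirical coefficients of the theta_s relation
#'   (defaults 80, 0.32, -0.33).
#' @param gamma_mst0 physical maximum Stern-layer NOM loading, mg m-2.
#' @return list of class `steric_params`.
#' @export
steric_params <- function(s_max = 2.56, K = 80, a = 0.32, b = -0.33,
                          gamma_mst0 = 1) {
  stopifnot(K > 0, s_max >= 0)
  structure(list(s_max = s_max, K = K, a = a, b = b,
                 gamma_mst0 = gamma_mst0),
            class = "steric_params")
}

#' NOM surface-component density at a given HA loading
#'
#' The HNOM surface density scales linearly with the relative HA
#' loading: `[HNOM] = (gamma_nom / gamma_ref) * fenomt`, reaching
#' FeNOM_T at the reference loading.
#'
#' @param gamma_nom HA surface loading, mg HA m-2 (>= 0).
#' @param p a [nomcd_params()] object.
#' @return HNOM surface density, umol m-2.
#' @examples
#' hnom_surface_density(1.6, nomcd_params())   # 1.77
#' @export
hnom_surface_density <- function(gamma_nom, p = nomcd_params()) {
  stopifnot(all(gamma_nom >= 0))
  (gamma_nom / p$gamma_ref) * p$fenomt
}

#' Carboxyl-normalised competitive strength FeNOM_T*
#'
#' Each HNOM surface component represents two carboxylate groups, so
#' normalising FeNOM_T by the reference loading and doubling yields the
#' surface-associated carboxylates per kg of NOM:
#' `FeNOM_T* = 2 * fenomt / gamma_ref` (umol m-2 over mg m-2 gives
#' mol kg-1 directly).
#'
#' @param fenomt FeNOM_T, umol m-2.
#' @param gamma_ref reference loading, mg m-2.
#' @return mol RCOO- per kg NOM.
#' @examples
#' fenomt_star(1.77, 1.6)   # 2.2125
#' @export
fenomt_star <- function(fenomt, gamma_ref) {
  stopifnot(gamma_ref > 0, all(fenomt >= 0))
  2 * fenomt / gamma_ref
}

#' FeNOM_T from the carboxyl density of a NOM material
#'
#' Inverts the proportionality `FeNOM_T* = slope * Q_RCOO`:
#' `FeNOM_T = slope * q_rcoo * gamma_ref / 2` (umol m-2).
#'
#' @param q_rcoo carboxyl density, mol RCOO- kg-1 NOM.
#' @param gamma_ref reference loading, mg m-2.
#' @param slope proportionality constant (default 0.89).
#' @return FeNOM_T, umol m-2.
#' @examples
#' fenomt_from_qrcoo(2.5, 1.6)   # 1.78
#' @export
fenomt_from_qrcoo <- function(q_rcoo, gamma_ref = 1.6, slope = 0.89) {
  stopifnot(all(q_rcoo >= 0), gamma_ref > 0, slope >= 0)
  slope * q_rcoo * gamma_ref / 2
}

#' Conditional maximum Stern-layer occupation theta_S
#'
#' `theta_S = x / (1 + x)` with `x = K * H^a * I^b`, where H is the
#' dimensionless proton activity (10^-pH) and I the ionic strength in
#' mol L-1. With the default coefficients (K = 80, a = 0.32,
#' b = -0.33) theta_S decreases with pH and with ionic strength:
#' adsorbed NOM can nearly saturate the Stern layer under acidic
#' conditions and occupies about half of it at neutral pH.
#'
#' @param proton_activity dimensionless proton activity, > 0.
#' @param ionic_strength mol L-1, > 0.
#' @param p a [steric_params()] object.
#' @return fraction in (0, 1).
#' @examples
#' theta_s(1e-7, 0.1)      # ~0.50
#' theta_s(10^-4.5, 0.1)   # ~0.86
#' @export
theta_s <- function(proton_activity, ionic_strength, p = steric_params()) {
  stopifnot(all(proton_activity > 0), all(ionic_strength > 0))
  x <- p$K * proton_activity^p$a * ionic_strength^p$b
  x / (1 + x)
}

#' Steric surface-component density
#'
#' The steric blocker density is proportional to the conditional
#' Stern-layer occupation: `[S0] = theta * s_max`.
#'
#' @param theta fraction in \[0, 1\] (from [theta_s()]).
#' @param s_max maximum steric site density, umol m-2.
#' @return umol m-2.
#' @examples
#' s0_surface_density(theta_s(1e-7, 0.1), 2.56)   # ~1.3
#' @export
s0_surface_density <- function(theta, s_max) {
  stopifnot(all(theta >= 0), all(theta <= 1), all(s_max >= 0))
  theta * s_max
}
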