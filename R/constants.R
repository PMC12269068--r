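# Physical constants at 25 degrees C. The whole package is isothermal:
# no temperature correction of equilibrium constants is attempted.

#' @keywords internal
.const <- list(
  faraday = 96485.33212,   # C mol-1
  rgas    = 8.31446262,    # J mol-1 K-1
  temp    = 298.15,        # K
  rt      = 8.31446262 * 298.15,      # J mol-1
  a_davies = 0.509,        # Davies A coefficient, 25 C, base-10
  gc_coef  = 0.1174,       # C m-2 per sqrt(mol L-1), Gouy-Chapman 1:1, 25 C
  # 1 umol m-2 expressed in sites nm-2: 1e-6 * 6.02214e23 / 1e18
  sites_per_umol = 0.60221
)

#' Convert between surface site density units
#'
#' Surface densities appear in two conventions: micromoles per square
#' metre (the unit of the NOM and steric surface components) and sites
#' per square nanometre (the crystallographic unit of goethite site
#' densities). One micromole per square metre equals 0.60221 sites per
#' square nanometre; the conversion is exact both ways.
#'
#' @param value numeric vector, non-negative.
#' @param from,to either `"umol_m2"` or `"sites_nm2"`.
#' @return numeric vector in the `to` unit.
#' @examples
#' site_density_convert(1.77, "umol_m2", "sites_nm2")   # ~1.07
#' site_density_convert(3.45, "sites_nm2", "umol_m2")   # ~5.73
#' @export
site_density_convert <- function(value,
                                 from = c("umol_m2", "sites_nm2"),
                                 to = c("sites_nm2", "umol_m2")) {
  from <- match.arg(from)
  to <- match.arg(to)
  stopifnot(is.numeric(value), all(value >= 0 | is.na(value)))
  if (from == to) return(value)
  if (from == "umol_m2") value * .const$sites_per_umol
  else value / .const$sites_per_umol
}
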