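#' Population exposure profile
#'
#' Bundles the exposure factors of the dose equations. Each factor is either a
#' point value or a [dist_spec()] (for Monte Carlo propagation). `AT_r` may be
#' `NULL`, in which case the engine applies the averaging-time convention:
#' `ED * 365` days for non-carcinogenic endpoints (which cancels `ED`
#' algebraically) and `70 * 365` days for carcinogenic endpoints.
#'
#' @param IR_w water intake rate (L/day).
#' @param EF_r exposure frequency (days/year).
#' @param ED exposure duration (years).
#' @param BW body weight (kg).
#' @param AT_r averaging time (days), or `NULL` for the endpoint convention.
#' @param SA exposed skin area (cm^2).
#' @param K_p dermal permeability coefficient for water (cm/hour).
#' @param ET water exposure time (hours/day).
#' @param CF volumetric conversion factor (L/cm^3), 0.001 by definition.
#' @param population label, e.g. `"adult"` or `"child"`.
#' @return an object of class `exposure_profile`.
#' @export
exposure_profile <- function(IR_w, EF_r, ED, BW, AT_r = NULL,
                             SA = NA, K_p = NA, ET = NA, CF = 0.001,
                             population = "adult") {
  prof <- list(IR_w = IR_w, EF_r = EF_r, ED = ED, BW = BW, AT_r = AT_r,
               SA = SA, K_p = K_p, ET = ET, CF = CF, population = population)
  for (nm in c("IR_w", "EF_r", "ED", "BW", "AT_r", "SA", "K_p", "ET", "CF")) {
    v <- prof[[nm]]
    if (is.null(v) || is_dist_spec(v)) next
    if (length(v) != 1L || (!is.numeric(v) && !is.na(v)))
      stop(nm, " must be a single number or a dist_spec", call. = FALSE)
    if (is.na(v)) { prof[[nm]] <- NA_real_; next }
    if (v <= 0) stop(nm, " must be strictly positive", call. = FALSE)
  }
  structure(prof, class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat("<exposure_profile:", x$population, ">\n")
  for (nm in c("IR_w", "EF_r", "ED", "BW", "AT_r", "SA", "K_p", "ET", "CF")) {
    v <- x[[nm]]
    lab <- if (is.null(v)) "<endpoint convention>" else if (is_dist_spec(v))
      .spec_serialize(v) else format(v)
    cat(sprintf("  %-5s %s\n", nm, lab))
  }
  invisible(x)
}

## resolve the averaging time for an endpoint; lifetime = 70 years
.resolve_at <- function(profile, endpoint, ED = profile$ED) {
  if (!is.null(profile$AT_r)) return(profile$AT_r)
  if (endpoint == "LTCR") 70 * 365 else ED * 365
}

#' Toxicity reference table
#'
#' Ingestion/dermal reference doses (ug/kg/day) and oral slope factors
#' ((mg/kg/day)^-1) for the screened metals. The dermal RfD defaults to the
#' ingestion value unless a dermal-specific entry is supplied. Two Pb RfD
#' conventions are provided: `"adjusted"` (1.4 ug/kg/day, the value consistent
#' with the study's reported hazard-quotient magnitudes) and `"printed"`
#' (140 ug/kg/day, the value the study's methods section lists); the
#' discrepancy is documented rather than silently resolved.
#'
#' @param pb_rfd `"adjusted"` (default) or `"printed"`.
#' @return data frame with columns `metal`, `rfd_i`, `rfd_d`, `sf`.
#' @export
default_toxicity <- function(pb_rfd = c("adjusted", "printed")) {
  pb_rfd <- match.arg(pb_rfd)
  tox <- data.frame(
    metal = c("Al", "Cr", "Fe", "Mn", "Ni", "Pb"),
    rfd_i = c(1000, 1500, 700, 140, 20, if (pb_rfd == "adjusted") 1.4 else 140),
    sf    = c(NA, 0.5, NA, NA, 1.7, 0.0085))
  tox$rfd_d <- tox$rfd_i
  tox[c("metal", "rfd_i", "rfd_d", "sf")]
}

.tox_lookup <- function(tox, metal, field) {
  i <- match(metal, tox$metal)
  if (is.na(i) || is.na(tox[[field]][i]))
    stop("no ", field, " entry for metal '", metal,
         "' in the toxicity table", call. = FALSE)
  tox[[field]][i]
}

#' Chronic daily intake via the ingestion route
#'
#' `CDI = C * IR_w * EF_r * ED / (BW * AT_r)` in ug/kg/day, with `C` in ug/L.
#' Vectorized over all arguments (recycled), so it is the Monte Carlo kernel.
#'
#' @param C concentration in water (ug/L), `>= 0`.
#' @param profile an [exposure_profile()] with numeric (resolved) factors.
#' @param endpoint used only to resolve the averaging-time convention when
#'   `AT_r` is `NULL`.
#' @return CDI in ug/kg/day.
#' @export
cdi_ingestion <- function(C, profile, endpoint = "HQ") {
  if (any(!is.finite(C)) || any(C < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  AT <- .resolve_at(profile, endpoint)
  C * profile$IR_w * profile$EF_r * profile$ED / (profile$BW * AT)
}

#' Chronic daily intake via the dermal route
#'
#' `CDI = C * SA * K_p * EF_r * ED * ET * CF / (BW * AT_r)` in ug/kg/day.
#'
#' @inheritParams cdi_ingestion
#' @export
cdi_dermal <- function(C, profile, endpoint = "HQ") {
  if (any(!is.finite(C)) || any(C < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  for (nm in c("SA", "K_p", "ET", "CF"))
    if (is.null(profile[[nm]]) || anyNA(profile[[nm]]))
      stop("dermal dose requires ", nm, " in the exposure profile", call. = FALSE)
  AT <- .resolve_at(profile, endpoint)
  C * profile$SA * profile$K_p * profile$EF_r * profile$ED * profile$ET *
    profile$CF / (profile$BW * AT)
}

#' Hazard quotient
#'
#' `HQ = CDI / RfD` with the route-specific reference dose; both in
#' ug/kg/day, so HQ is unitless. `HQ > 1` flags potential non-carcinogenic
#' risk.
#'
#' @param cdi chronic daily intake (ug/kg/day).
#' @param metal metal name matching the toxicity table.
#' @param tox toxicity table, default [default_toxicity()].
#' @param route `"ingestion"` or `"dermal"`.
#' @export
hazard_quotient <- function(cdi, metal, tox = default_toxicity(),
                            route = c("ingestion", "dermal")) {
  route <- match.arg(route)
  rfd <- .tox_lookup(tox, metal, if (route == "ingestion") "rfd_i" else "rfd_d")
  cdi / rfd
}

#' Lifetime cancer risk
#'
#' `LTCR = CDI * SF` with CDI converted from ug/kg/day to mg/kg/day (the
#' single point where that conversion happens) and SF in (mg/kg/day)^-1.
#' Defined for the ingestion route only.
#'
#' @inheritParams hazard_quotient
#' @param route must be `"ingestion"`; a dermal dose is a route error.
#' @export
lifetime_cancer_risk <- function(cdi, metal, tox = default_toxicity(),
                                 route = "ingestion") {
  if (!identical(route, "ingestion"))
    stop("lifetime cancer risk is defined for the ingestion route only",
         call. = FALSE)
  sf <- .tox_lookup(tox, metal, "sf")
  (cdi / 1000) * sf
}

#' Classify lifetime cancer risk against the acceptable band
#'
#' Risks between 1e-6 and 1e-4 are conventionally acceptable; values above
#' 1e-4 indicate an inadmissible cancer risk over a lifetime.
#'
#' @param ltcr numeric vector of lifetime cancer risks.
#' @return `"negligible"`, `"acceptable"` or `"above_limit"` per element.
#' @export
classify_ltcr <- function(ltcr) {
  ifelse(ltcr > 1e-4, "above_limit",
         ifelse(ltcr >= 1e-6, "acceptable", "negligible"))
}
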