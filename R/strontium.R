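# Ocean-sediment strontium cycle and 87Sr/86Sr isotope system with explicit
# 87Rb decay in the crustal end-members and the sedimentary reservoir.

#' Calibrate a Rb/Sr ratio from a present-day 87Sr/86Sr target
#'
#' Inverts the radiogenic growth law so that a reservoir starting at the
#' initial solar-system ratio reaches `present_ratio` exactly after the age
#' of the Earth: Rb/Sr = (present - initial) / (1 - exp(-lambda * age)).
#'
#' @param present_ratio Target present-day 87Sr/86Sr (> initial ratio).
#' @param params A `copse_params` object (uses `lambda_Rb`,
#'   `sr_ratio_initial`, `earth_age_yr`).
#' @return The 87Rb/86Sr ratio (dimensionless, non-negative).
#' @export
rb_sr_calibrate <- function(present_ratio, params) {
  cn <- params$constants
  if (present_ratio < cn$sr_ratio_initial) {
    stop("rb_sr_calibrate: present_ratio below the initial ratio")
  }
  (present_ratio - cn$sr_ratio_initial) /
    (1 - exp(-cn$lambda_Rb * cn$earth_age_yr))
}

#' Radiogenic growth of a 87Sr/86Sr ratio
#'
#' @param rb_sr 87Rb/86Sr ratio of the reservoir.
#' @param t_yr Time since Earth formation, yr.
#' @param params A `copse_params` object.
#' @return The 87Sr/86Sr ratio at `t_yr`.
#' @export
rb_sr_grow <- function(rb_sr, t_yr, params) {
  cn <- params$constants
  cn$sr_ratio_initial + rb_sr * (1 - exp(-cn$lambda_Rb * t_yr))
}

#' Crustal and mantle 87Sr/86Sr end-member ratios
#'
#' Each end-member grows from the initial ratio towards its configured
#' present-day value; the Rb/Sr ratio of each rock type is calibrated so the
#' present value is reached exactly at the age of the Earth.
#'
#' @param t_since_formation_yr Years since Earth formation, in
#'   [0, earth_age_yr].
#' @param params A `copse_params` object.
#' @return Named numeric: `granite`, `basalt`, `mantle`.
#' @export
end_member_ratios <- function(t_since_formation_yr, params) {
  cn <- params$constants
  if (t_since_formation_yr < 0 || t_since_formation_yr > cn$earth_age_yr) {
    stop("end_member_ratios: time outside [0, earth age]")
  }
  targets <- c(granite = cn$sr_present_granite,
               basalt = cn$sr_present_basalt,
               mantle = cn$sr_present_mantle)
  vapply(targets, function(r) {
    rb_sr_grow(rb_sr_calibrate(r, params), t_since_formation_yr, params)
  }, numeric(1))
}

#' Strontium fluxes
#'
#' Each Sr flux tracks its carbon-cycle counterpart: mantle input and
#' metamorphic output scale with degassing, weathering inputs with the
#' corresponding rock weathering fluxes, and removal (carbonate burial and
#' seafloor weathering) with the carbonate burial and seafloor weathering
#' carbon fluxes times the relative ocean Sr inventory.
#'
#' @param state Named vector with `OSr` and `SSr` (mol).
#' @param forcing Forcing snapshot (uses `D`).
#' @param carbon_fluxes Named flux vector with basw, granw, carbw, mccb, sfw.
#' @param params A `copse_params` object.
#' @return Named numeric Sr fluxes (mol yr^-1).
#' @export
sr_fluxes <- function(state, forcing, carbon_fluxes, params) {
  cn <- params$constants
  sp <- params$sr
  f0 <- params$flux0
  f <- as.list(carbon_fluxes)
  osr_rel <- state[["OSr"]] / cn$OSr0
  ssr_rel <- state[["SSr"]] / cn$SSr0
  c(
    Sr_mantle = sp$k_Srmantle * forcing$D,
    Sr_basw = sp$k_Srbasw * f$basw / f0$basw,
    Sr_granw = sp$k_Srgranw * f$granw / f0$granw,
    Sr_sedw = sp$k_Srsedw * (f$carbw / f0$carbw) * ssr_rel,
    Sr_sedb = sp$k_Srsedb * (f$mccb / f0$mccb) * osr_rel,
    Sr_sfw = sp$k_Srsfw * (f$sfw / f0$sfw) * osr_rel,
    Sr_metam = sp$k_Srmetam * forcing$D * ssr_rel
  )
}

#' Strontium isotope moment balance
#'
#' Moment bookkeeping for MOSr = OSr * (87Sr/86Sr)_ocean and
#' MSSr = SSr * (87Sr/86Sr)_sediment. Inputs carry their source ratios
#' (crustal end-members evaluated at the current time since Earth formation),
#' outputs carry the ratio of the reservoir they leave. The sediment ratio
#' used for the sediment-sourced fluxes and diagnostics includes an in-run
#' Rb-decay term with the sediment Rb/Sr calibrated to the average crustal
#' ratio; `run_elapsed_yr = 0` (e.g. during spin-up) disables that term.
#'
#' @param state Named vector with OSr, SSr, MOSr, MSSr.
#' @param srf Named Sr flux vector from [sr_fluxes()].
#' @param members Named end-member ratios from [end_member_ratios()].
#' @param run_elapsed_yr Time since the start of the transient run, yr.
#' @param params A `copse_params` object.
#' @return List with derivatives `dOSr`, `dSSr`, `dMOSr`, `dMSSr` and
#'   diagnostics `sr_ocean`, `sr_sediment`.
#' @export
sr_isotope_balance <- function(state, srf, members, run_elapsed_yr, params) {
  cn <- params$constants
  OSr <- state[["OSr"]]; SSr <- state[["SSr"]]
  if (OSr <= 0 || SSr <= 0) stop("sr_isotope_balance: non-positive reservoir")
  f <- as.list(srf)

  r_ocean <- state[["MOSr"]] / OSr
  rb_sr_sed <- rb_sr_calibrate(cn$sr_crustal_avg, params)
  r_sediment <- state[["MSSr"]] / SSr +
    rb_sr_sed * (1 - exp(-cn$lambda_Rb * run_elapsed_yr))

  dOSr <- f$Sr_granw + f$Sr_basw + f$Sr_sedw + f$Sr_mantle -
    f$Sr_sedb - f$Sr_sfw
  dSSr <- f$Sr_sedb - f$Sr_sedw - f$Sr_metam
  dMOSr <- f$Sr_granw * members[["granite"]] + f$Sr_basw * members[["basalt"]] +
    f$Sr_sedw * r_sediment + f$Sr_mantle * members[["mantle"]] -
    (f$Sr_sedb + f$Sr_sfw) * r_ocean
  dMSSr <- f$Sr_sedb * r_ocean - (f$Sr_sedw + f$Sr_metam) * r_sediment

  list(dOSr = dOSr, dSSr = dSSr, dMOSr = dMOSr, dMSSr = dMSSr,
       sr_ocean = r_ocean, sr_sediment = r_sediment)
}
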