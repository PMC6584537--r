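# Flux laws of the box model: climate, anoxia, marine ecology, weathering,
# burial/degassing, and the mass and isotope balances they drive.
#
# Conventions: reservoir state vectors are named absolute inventories in mol
# (P, N, O, A, S plus isotope moments MA = A * d13C_A and MS = S * d34S).
# Every flux law is written as (present-day flux) x (dimensionless shape
# factor normalised to 1 at the reference point), so the reference point is
# an exact steady state by construction.

#' Relative reservoir values
#' @param state Named numeric with at least P, N, O, A, S (mol).
#' @param params A `copse_params` object.
#' @return Named numeric p, n, o, a, s.
#' @export
relative_reservoirs <- function(state, params) {
  cn <- params$constants
  c(p = unname(state[["P"]]) / cn$P0, n = unname(state[["N"]]) / cn$N0,
    o = unname(state[["O"]]) / cn$O0, a = unname(state[["A"]]) / cn$A0,
    s = unname(state[["S"]]) / cn$S0)
}

#' CO2 and global temperature anomaly
#'
#' Atmospheric CO2 relative to present is the square of the relative
#' atmosphere-ocean carbon reservoir; temperature follows the logarithmic
#' CO2 law with a linear solar-luminosity correction over 570 Myr.
#'
#' @param a_rel Relative atmosphere-ocean carbon reservoir (A/A0), > 0.
#' @param t_Ma Time before present, Myr (>= 0).
#' @param params A `copse_params` object (supplies `k_c` and `k_l`).
#' @return List with `RCO2` and `deltaT` (degC).
#' @export
climate_state <- function(a_rel, t_Ma, params) {
  if (!is.finite(a_rel) || a_rel <= 0) {
    stop("climate_state: a_rel must be positive, got ", a_rel)
  }
  RCO2 <- a_rel^2
  deltaT <- params$k_c * log(RCO2) - params$constants$k_l * t_Ma / 570
  list(RCO2 = RCO2, deltaT = deltaT)
}

#' Ocean anoxic fraction
#'
#' Logistic function of relative new production (pushing anoxia up) and
#' relative O2 (pushing it down); strictly inside (0, 1).
#'
#' @param newp_rel Relative marine new production (newp/newp0), >= 0.
#' @param o_rel Relative O2 reservoir, >= 0.
#' @param params A `copse_params` object (supplies `k_anox`, `k_u`).
#' @return Anoxic fraction in (0, 1).
#' @export
anoxic_fraction <- function(newp_rel, o_rel, params) {
  stopifnot(newp_rel >= 0, o_rel >= 0)
  cn <- params$constants
  1 / (1 + exp(-cn$k_anox * (cn$k_u * newp_rel - o_rel)))
}

#' Marine ecology and nutrient-burial fluxes
#'
#' New production is limited by the scarcer of nitrate and phosphate in
#' Redfield proportion; organic C burial scales with uplift and the square of
#' relative new production, with an optional direct O2 dependence
#' f(O2) = 2.1276 exp(-0.755 o). P is buried organically (C:P 250),
#' as Ca-bound P and as Fe-sorbed P (suppressed under anoxia); the N cycle
#' closes through fixation, denitrification and organic burial.
#'
#' @param state Named numeric reservoir vector (mol).
#' @param anox Ocean anoxic fraction in [0, 1].
#' @param forcing Forcing snapshot list (uses `U`).
#' @param params A `copse_params` object.
#' @return Named numeric fluxes (mol yr^-1): newp (relative units of C),
#'   nfix, denit, monb (mol N yr^-1), mocb, mopb, capb, fepb.
#' @export
ocean_ecology_fluxes <- function(state, anox, forcing, params) {
  cn <- params$constants
  f0 <- params$flux0
  r <- relative_reservoirs(state, params)
  if (any(r[c("p", "n", "o")] < 0)) {
    stop("ocean_ecology_fluxes: negative reservoir")
  }
  newp <- cn$r_CP * min(30.9 * r[["n"]] / cn$r_NP, 2.2 * r[["p"]])
  newp_rel <- newp / params$newp0

  f_o2 <- if (isTRUE(params$options$mocb_o2_dependence)) {
    2.1276 * exp(-0.755 * r[["o"]])
  } else 1
  mocb <- f0$mocb * forcing$U * newp_rel^2 * f_o2
  mopb <- mocb / cn$CP_sea
  monb <- mocb / cn$CN_sea

  f_anox <- if (is.function(params$options$capb_anoxia)) {
    params$options$capb_anoxia(anox)
  } else 1
  capb <- f0$capb * newp_rel^2 * f_anox
  fepb <- f0$fepb * ((1 - anox) / (1 - params$anox0)) * r[["p"]]

  P <- state[["P"]]; N <- state[["N"]]
  nfix <- if (N / cn$r_NP < P) {
    f0$nfix * ((P - N / cn$r_NP) / (cn$P0 - cn$N0 / cn$r_NP))^2
  } else 0
  denit <- f0$denit *
    (1 + anox / (1 - cn$k1_oxfrac)) / (1 + params$anox0 / (1 - cn$k1_oxfrac)) *
    r[["n"]]

  c(newp = newp, newp_rel = newp_rel, nfix = nfix, denit = denit,
    monb = monb, mocb = mocb, mopb = mopb, capb = capb, fepb = fepb)
}

## temperature / runoff / biota shape factors. Temperature and runoff laws
## are 1 at deltaT = 0 (runoff floored at zero for deep glacial anomalies).
## The biota factor is 1 at the vegetated present (V = 1); with vegetation
## off it drops to the abiotic baseline k_preplant * sqrt(RCO2), whose direct
## CO2 dependence partially substitutes for the absent plant pump.
weathering_factors <- function(climate, params, V = 0) {
  tf <- params$tf
  dT <- climate$deltaT
  list(
    f_Tgran = exp(tf$gran * dT),
    f_Tbas = exp(tf$bas * dT),
    f_runoff = max(0, 1 + 0.038 * dT)^0.65,
    g_runoff = max(0, 1 + 0.087 * dT),
    f_biota = V + (1 - V) * params$constants$k_preplant * sqrt(climate$RCO2),
    sfw_T = exp(tf$sfw * dT)
  )
}

#' Continental and seafloor weathering fluxes
#'
#' Granite weathering scales with uplift, palaeogeography, temperature,
#' runoff and the abiotic CO2 factor; basalt weathering is identical but
#' erosion-independent. Carbonate and gypsum weathering share the carbonate
#' runoff law. Oxidative weathering scales with uplift and relative O2 to the
#' sampled power. Seafloor weathering scales with degassing and exponentially
#' with the temperature anomaly. Phosphorus weathering is a weighted blend of
#' the relative silicate, carbonate and oxidative channels (weights 2/12,
#' 5/12, 5/12 as in the parent COPSE Reloaded formulation, configurable).
#'
#' @param state Named reservoir vector (mol).
#' @param forcing Forcing snapshot (uses D, U, PG, a_gran, a_bas).
#' @param climate Output of [climate_state()] for the same state.
#' @param params A `copse_params` object.
#' @return Named numeric fluxes (mol yr^-1): granw, basw, silw, carbw,
#'   oxidw, phosw, pyrw, gypw, sfw.
#' @export
weathering_fluxes <- function(state, forcing, climate, params) {
  if (forcing$D < 0 || forcing$U < 0) {
    stop("weathering_fluxes: negative forcing")
  }
  f0 <- params$flux0
  r <- relative_reservoirs(state, params)
  wf <- weathering_factors(climate, params, V = forcing$V)

  granw <- f0$granw * forcing$U * forcing$PG * forcing$a_gran *
    wf$f_Tgran * wf$f_runoff * wf$f_biota
  basw <- f0$basw * forcing$PG * forcing$a_bas *
    wf$f_Tbas * wf$f_runoff * wf$f_biota
  silw <- granw + basw
  carbw <- f0$carbw * forcing$U * forcing$PG * wf$g_runoff * wf$f_biota
  oxidw <- f0$oxidw * forcing$U * r[["o"]]^params$oxidw_exponent
  sfw <- f0$sfw * forcing$D * wf$sfw_T
  pyrw <- f0$pyrw * forcing$U
  gypw <- f0$gypw * forcing$U * forcing$PG * wf$g_runoff * wf$f_biota
  pw <- params$constants$phosw_weights
  phosw <- f0$phosw * (pw[["silw"]] * silw / f0$silw +
                         pw[["carbw"]] * carbw / f0$carbw +
                         pw[["oxidw"]] * oxidw / f0$oxidw)

  c(granw = granw, basw = basw, silw = silw, carbw = carbw, oxidw = oxidw,
    phosw = phosw, pyrw = pyrw, gypw = gypw, sfw = sfw)
}

#' Burial and degassing fluxes
#'
#' Pyrite burial scales with the sulphate:O2 ratio and relative organic
#' burial; gypsum burial with relative sulphate and the calcium forcing.
#' Carbonate burial balances the alkalinity budget exactly:
#' mccb = silw + carbw + mpsb - pyrw - pyrdeg (clamped at zero with a flag
#' under extreme draws). Degassing fluxes and the reduced gas flux are linear
#' in the degassing forcing. With vegetation off, land organic burial and the
#' land P pathway are identically zero.
#'
#' @param state Named reservoir vector (mol).
#' @param forcing Forcing snapshot (uses D, B, c_cal, V).
#' @param ecology Output of [ocean_ecology_fluxes()].
#' @param weathering Output of [weathering_fluxes()].
#' @param params A `copse_params` object.
#' @return Named numeric fluxes (mol yr^-1) with attribute `mccb_clamped`
#'   (logical).
#' @export
burial_and_degassing_fluxes <- function(state, forcing, ecology, weathering,
                                        params) {
  f0 <- params$flux0
  r <- relative_reservoirs(state, params)
  mocb_rel <- ecology[["mocb"]] / f0$mocb

  mpsb <- f0$mpsb * (r[["s"]] / r[["o"]]) * mocb_rel
  mgsb <- f0$mgsb * r[["s"]] * forcing$c_cal
  ocdeg <- f0$ocdeg * forcing$D
  ccdeg <- f0$ccdeg * forcing$D * forcing$B
  pyrdeg <- f0$pyrdeg * forcing$D
  gypdeg <- f0$gypdeg * forcing$D
  rgf <- f0$rgf * forcing$D

  mccb <- weathering[["silw"]] + weathering[["carbw"]] + mpsb -
    weathering[["pyrw"]] - pyrdeg
  clamped <- mccb < 0
  if (clamped) mccb <- 0

  out <- c(mccb = mccb, mpsb = mpsb, mgsb = mgsb, ocdeg = ocdeg,
           ccdeg = ccdeg, pyrdeg = pyrdeg, gypdeg = gypdeg, rgf = rgf,
           locb = 0, pland = 0)
  attr(out, "mccb_clamped") <- clamped
  out
}

#' Mass balance of the evolving reservoirs
#'
#' @param state Named reservoir vector (mol); unused except for errors, the
#'   derivatives depend on the fluxes only.
#' @param fluxes Named numeric flux vector containing all entries produced by
#'   the ecology, weathering and burial/degassing stages.
#' @param params A `copse_params` object (supplies the O2-equivalence of the
#'   reduced gas flux).
#' @return Named derivatives (mol yr^-1) of P, N, O, A, S.
#' @export
mass_balance <- function(state, fluxes, params) {
  f <- as.list(fluxes)
  rgf_o2 <- params$options$rgf_o2_equiv * f$rgf
  c(
    P = f$psea - f$mopb - f$capb - f$fepb,
    N = f$nfix - f$denit - f$monb,
    O = (f$mocb + f$locb - f$oxidw - f$ocdeg) +
      2 * (f$mpsb - f$pyrw - f$pyrdeg) - rgf_o2,
    A = f$ccdeg + f$ocdeg + f$oxidw + f$carbw + f$rgf -
      f$mocb - f$locb - f$mccb - f$sfw,
    S = f$gypw + f$pyrw + f$gypdeg + f$pyrdeg - f$mgsb - f$mpsb
  )
}

#' Carbon and sulphur isotope moment balance
#'
#' Moment bookkeeping for MA = A * d13C_A and MS = S * d34S: each input flux
#' carries its source delta, carbonate burial and seafloor weathering carry
#' the ocean-atmosphere delta, organic burial is fractionated by Delta_C and
#' pyrite burial by Delta_S.
#'
#' @param state Named vector with A, S, MA, MS (mol and mol permil).
#' @param fluxes Named flux vector (complete set).
#' @param params A `copse_params` object.
#' @return List with moment derivatives `dMA`, `dMS` (mol permil yr^-1) and
#'   diagnostics `d13C_carb`, `d34S_sw`, `f_org`, `f_py`.
#' @export
isotope_balance <- function(state, fluxes, params) {
  cn <- params$constants
  f <- as.list(fluxes)
  A <- state[["A"]]; S <- state[["S"]]
  if (A <= 0 || S <= 0) stop("isotope_balance: non-positive reservoir")
  dA13 <- state[["MA"]] / A
  dS34 <- state[["MS"]] / S

  dMA <- (f$ccdeg + f$carbw) * cn$d13C_carb_rock +
    (f$ocdeg + f$oxidw) * cn$d13C_org_rock +
    f$rgf * cn$d13C_mantle -
    (f$mccb + f$sfw) * dA13 -
    (f$mocb + f$locb) * (dA13 - cn$Delta_C)

  dMS <- (f$pyrw + f$pyrdeg) * cn$d34S_pyr_rock +
    (f$gypw + f$gypdeg) * cn$d34S_gyp_rock -
    f$mgsb * dS34 -
    f$mpsb * (dS34 - cn$Delta_S)

  list(
    dMA = dMA, dMS = dMS,
    d13C_carb = dA13, d34S_sw = dS34,
    f_org = (f$mocb + f$locb) / (f$mocb + f$locb + f$mccb + f$sfw),
    f_py = f$mpsb / (f$mpsb + f$mgsb)
  )
}
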