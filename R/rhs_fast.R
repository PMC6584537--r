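# Fast scalar right-hand side used inside the integrator. Mirrors the
# modular composition in copse_point() exactly (an equivalence test holds the
# two paths together); exists because the solver evaluates the rhs tens of
# thousands of times per ensemble.

## one-time unpack of everything the rhs needs into a flat environment
make_rhs_context <- function(params) {
  cn <- params$constants
  f0 <- params$flux0
  e <- new.env(parent = emptyenv())
  e$P0 <- cn$P0; e$N0 <- cn$N0; e$O0 <- cn$O0; e$A0 <- cn$A0; e$S0 <- cn$S0
  e$OSr0 <- cn$OSr0; e$SSr0 <- cn$SSr0
  e$rNP <- cn$r_NP
  e$newp_den <- min(30.9 / cn$r_NP, 2.2)  # newp0 / r_CP
  e$k_anox <- cn$k_anox; e$k_u <- cn$k_u
  e$anox0 <- params$anox0; e$k1c <- 1 - cn$k1_oxfrac
  e$CP_sea <- cn$CP_sea; e$CN_sea <- cn$CN_sea
  e$mocb0 <- f0$mocb; e$capb0 <- f0$capb; e$fepb0 <- f0$fepb
  e$nfix0 <- f0$nfix; e$denit0 <- f0$denit
  e$nfix_den <- cn$P0 - cn$N0 / cn$r_NP
  e$denit_norm <- 1 + params$anox0 / e$k1c
  e$granw0 <- f0$granw; e$basw0 <- f0$basw; e$silw0 <- f0$silw
  e$carbw0 <- f0$carbw; e$oxidw0 <- f0$oxidw; e$sfw0 <- f0$sfw
  e$pyrw0 <- f0$pyrw; e$gypw0 <- f0$gypw; e$phosw0 <- f0$phosw
  e$mpsb0 <- f0$mpsb; e$mgsb0 <- f0$mgsb
  e$ocdeg0 <- f0$ocdeg; e$ccdeg0 <- f0$ccdeg
  e$pyrdeg0 <- f0$pyrdeg; e$gypdeg0 <- f0$gypdeg; e$rgf0 <- f0$rgf
  e$mccb0 <- f0$mccb
  e$kc <- params$k_c; e$kl <- cn$k_l
  e$cgran <- params$tf$gran; e$cbas <- params$tf$bas; e$csfw <- params$tf$sfw
  e$kpre <- cn$k_preplant
  e$oxexp <- params$oxidw_exponent
  e$pw_sil <- cn$phosw_weights[["silw"]]
  e$pw_carb <- cn$phosw_weights[["carbw"]]
  e$pw_oxid <- cn$phosw_weights[["oxidw"]]
  e$mocb_o2 <- isTRUE(params$options$mocb_o2_dependence)
  e$capb_anox_fun <- params$options$capb_anoxia
  e$rgf_eq <- params$options$rgf_o2_equiv
  e$dCrock <- cn$d13C_carb_rock; e$dGrock <- cn$d13C_org_rock
  e$dMan <- cn$d13C_mantle; e$DC <- cn$Delta_C
  e$dPyr <- cn$d34S_pyr_rock; e$dGyp <- cn$d34S_gyp_rock; e$DS <- cn$Delta_S
  sp <- params$sr
  e$kSrman <- sp$k_Srmantle; e$kSrbas <- sp$k_Srbasw; e$kSrgran <- sp$k_Srgranw
  e$kSrsedw <- sp$k_Srsedw; e$kSrsedb <- sp$k_Srsedb; e$kSrsfw <- sp$k_Srsfw
  e$kSrmetam <- sp$k_Srmetam
  e$lam <- cn$lambda_Rb; e$r0 <- cn$sr_ratio_initial
  e$age <- cn$earth_age_yr
  den <- 1 - exp(-cn$lambda_Rb * cn$earth_age_yr)
  e$rb_gran <- (cn$sr_present_granite - cn$sr_ratio_initial) / den
  e$rb_bas <- (cn$sr_present_basalt - cn$sr_ratio_initial) / den
  e$rb_man <- (cn$sr_present_mantle - cn$sr_ratio_initial) / den
  e$rb_sed <- (cn$sr_crustal_avg - cn$sr_ratio_initial) / den
  e
}

## derivative of the 11-component state; masses/moments are scalars in a
## numeric vector ordered as STATE_NAMES. Returns unnamed derivs.
rhs_fast <- function(st, D, U, PG, a_gran, a_bas, V, B, c_cal,
                     t_solar_Ma, elapsed_yr, e) {
  P <- st[1]; N <- st[2]; O <- st[3]; A <- st[4]; S <- st[5]
  OSr <- st[6]; SSr <- st[7]
  MA <- st[8]; MS <- st[9]; MOSr <- st[10]; MSSr <- st[11]
  p <- P / e$P0; n <- N / e$N0; o <- O / e$O0; a <- A / e$A0; s <- S / e$S0

  RCO2 <- a * a
  dT <- e$kc * log(RCO2) - e$kl * t_solar_Ma / 570

  newp_rel <- min(30.9 * n / e$rNP, 2.2 * p) / e$newp_den
  anox <- 1 / (1 + exp(-e$k_anox * (e$k_u * newp_rel - o)))

  f_o2 <- if (e$mocb_o2) 2.1276 * exp(-0.755 * o) else 1
  mocb <- e$mocb0 * U * newp_rel * newp_rel * f_o2
  mopb <- mocb / e$CP_sea
  monb <- mocb / e$CN_sea
  f_anox <- if (is.function(e$capb_anox_fun)) e$capb_anox_fun(anox) else 1
  capb <- e$capb0 * newp_rel * newp_rel * f_anox
  fepb <- e$fepb0 * ((1 - anox) / (1 - e$anox0)) * p
  nfix <- if (N / e$rNP < P) {
    x <- (P - N / e$rNP) / e$nfix_den
    e$nfix0 * x * x
  } else 0
  denit <- e$denit0 * (1 + anox / e$k1c) / e$denit_norm * n

  f_Tgran <- exp(e$cgran * dT)
  f_Tbas <- exp(e$cbas * dT)
  f_runoff <- max(0, 1 + 0.038 * dT)^0.65
  g_runoff <- max(0, 1 + 0.087 * dT)
  f_biota <- V + (1 - V) * e$kpre * sqrt(RCO2)

  granw <- e$granw0 * U * PG * a_gran * f_Tgran * f_runoff * f_biota
  basw <- e$basw0 * PG * a_bas * f_Tbas * f_runoff * f_biota
  silw <- granw + basw
  carbw <- e$carbw0 * U * PG * g_runoff * f_biota
  oxidw <- e$oxidw0 * U * o^e$oxexp
  sfw <- e$sfw0 * D * exp(e$csfw * dT)
  pyrw <- e$pyrw0 * U
  gypw <- e$gypw0 * U * PG * g_runoff * f_biota
  phosw <- e$phosw0 * (e$pw_sil * silw / e$silw0 +
                         e$pw_carb * carbw / e$carbw0 +
                         e$pw_oxid * oxidw / e$oxidw0)

  mpsb <- e$mpsb0 * (s / o) * (mocb / e$mocb0)
  mgsb <- e$mgsb0 * s * c_cal
  ocdeg <- e$ocdeg0 * D
  ccdeg <- e$ccdeg0 * D * B
  pyrdeg <- e$pyrdeg0 * D
  gypdeg <- e$gypdeg0 * D
  rgf <- e$rgf0 * D
  mccb <- silw + carbw + mpsb - pyrw - pyrdeg
  if (mccb < 0) mccb <- 0

  dP <- phosw - mopb - capb - fepb
  dN <- nfix - denit - monb
  dO <- (mocb - oxidw - ocdeg) + 2 * (mpsb - pyrw - pyrdeg) - e$rgf_eq * rgf
  dA <- ccdeg + ocdeg + oxidw + carbw + rgf - mocb - mccb - sfw
  dS <- gypw + pyrw + gypdeg + pyrdeg - mgsb - mpsb

  dA13 <- MA / A
  dS34 <- MS / S
  dMA <- (ccdeg + carbw) * e$dCrock + (ocdeg + oxidw) * e$dGrock +
    rgf * e$dMan - (mccb + sfw) * dA13 - mocb * (dA13 - e$DC)
  dMS <- (pyrw + pyrdeg) * e$dPyr + (gypw + gypdeg) * e$dGyp -
    mgsb * dS34 - mpsb * (dS34 - e$DS)

  grow <- 1 - exp(-e$lam * (e$age - t_solar_Ma * 1e6))
  r_gran <- e$r0 + e$rb_gran * grow
  r_bas <- e$r0 + e$rb_bas * grow
  r_man <- e$r0 + e$rb_man * grow
  r_oc <- MOSr / OSr
  r_sed <- MSSr / SSr + e$rb_sed * (1 - exp(-e$lam * elapsed_yr))

  Sr_man <- e$kSrman * D
  Sr_bas <- e$kSrbas * basw / e$basw0
  Sr_gran <- e$kSrgran * granw / e$granw0
  Sr_sedw <- e$kSrsedw * (carbw / e$carbw0) * (SSr / e$SSr0)
  Sr_sedb <- e$kSrsedb * (mccb / e$mccb0) * (OSr / e$OSr0)
  Sr_sfw <- e$kSrsfw * (sfw / e$sfw0) * (OSr / e$OSr0)
  Sr_metam <- e$kSrmetam * D * (SSr / e$SSr0)

  dOSr <- Sr_gran + Sr_bas + Sr_sedw + Sr_man - Sr_sedb - Sr_sfw
  dSSr <- Sr_sedb - Sr_sedw - Sr_metam
  dMOSr <- Sr_gran * r_gran + Sr_bas * r_bas + Sr_sedw * r_sed +
    Sr_man * r_man - (Sr_sedb + Sr_sfw) * r_oc
  dMSSr <- Sr_sedb * r_oc - (Sr_sedw + Sr_metam) * r_sed

  c(dP, dN, dO, dA, dS, dOSr, dSSr, dMA, dMS, dMOSr, dMSSr)
}
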