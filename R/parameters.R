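# Model parameters: sampled present-day fluxes, derived (closure-constructed)
# fluxes, and fixed constants adopted from the COPSE Reloaded baseline.

#' Default fixed constants of the box model
#'
#' Constants that are not part of the Monte-Carlo space: present-day reservoir
#' inventories, stoichiometric ratios, the anoxia law, isotope end-members and
#' the seafloor-weathering baseline. All are taken from the COPSE Reloaded
#' baseline (Lenton, Daines & Mills 2018) and are exposed here so that any of
#' them can be overridden.
#'
#' @return Named list of constants. Units: reservoirs mol; fluxes mol yr^-1;
#'   isotope deltas per mil; Sr quantities mol and dimensionless ratios.
#' @export
copse_constants <- function() {
  list(
    ## present-day reservoir inventories (mol)
    P0   = 3.1e15,    # ocean phosphate
    N0   = 4.35e16,   # ocean nitrate
    O0   = 3.7e19,    # atmosphere + ocean O2
    A0   = 3.193e18,  # atmosphere + ocean CO2
    S0   = 4e19,      # ocean sulphate
    ## ecology / stoichiometry
    r_CP     = 117,    # Redfield C:P of new production
    r_NP     = 16,     # Redfield N:P
    CP_sea   = 250,    # C:P of buried marine organic matter
    CN_sea   = 37.5,   # C:N of buried marine organic matter
    ## anoxia law (logistic)
    k_anox   = 12,
    k_u      = 0.5,
    k1_oxfrac = 0.86,  # oxic-fraction constant in the fepb / denit laws
    ## nitrogen cycle present-day denitrification
    denit0   = 4.3e12, # mol N yr^-1
    ## climate
    k_l      = 7.4,    # degC, luminosity term over 570 Myr
    T0_K     = 288,    # reference surface temperature, K
    R_gas    = 8.314,  # J mol^-1 K^-1
    ## seafloor weathering present-day flux (mol C yr^-1)
    sfw0     = 1.75e12,
    ## partition of total outgassing between carbonate and organic C
    ## (present-day proportion of the COPSE baseline: 6.65:1.25)
    ocdeg_frac = 1.25 / 7.9,
    ## split of the non-organic marine P burial residual, capb:fepb
    capb_fepb_ratio = c(capb = 1.5, fepb = 0.6),
    ## reactive-P weathering channel weights (sum to 1)
    phosw_weights = c(silw = 2 / 12, carbw = 5 / 12, oxidw = 5 / 12),
    ## abiotic (pre-vegetation) weathering baseline relative to the
    ## plant-assisted present, before its sqrt(RCO2) CO2 dependence
    k_preplant = 0.15,
    ## carbon isotope end-members (per mil)
    d13C_carb_rock = 0,     # weathered/degassed carbonate
    d13C_org_rock  = -27,   # weathered/degassed organic carbon
    d13C_mantle    = -5,    # ridge CO2
    Delta_C        = 27,    # fractionation of buried organic C
    ## sulphur isotope end-members (per mil)
    d34S_pyr_rock  = -15,   # weathered/degassed pyrite
    d34S_gyp_rock  = 20,    # weathered/degassed gypsum
    Delta_S        = 35,    # fractionation of buried pyrite
    ## ocean sulphate concentration at S = S0 (mM), diagnostic only
    SO4_conc0      = 28,
    ## strontium cycle
    OSr0 = 1.2e17,          # ocean Sr, mol
    SSr0 = 5e18,            # sedimentary-carbonate Sr, mol
    k_Srgranw  = 13e9,      # mol yr^-1
    k_Srbasw   = 13e9,
    k_Srsedw   = 17e9,
    k_Srmantle = 7.3e9,
    lambda_Rb      = 1.42e-11,  # 87Rb decay constant, yr^-1
    sr_ratio_initial = 0.69898, # 87Sr/86Sr at Earth formation (BABI)
    sr_present_granite = 0.715,
    sr_present_basalt  = 0.705,
    sr_present_mantle  = 0.703,
    sr_crustal_avg     = 0.73,  # target average crustal ratio (sediment Rb/Sr)
    earth_age_yr   = 4.5e9
  )
}

#' Construct a closed model parameter set
#'
#' Builds a full parameter set from the sampled (or default, Table-of-ranges
#' midpoint) present-day fluxes, then applies the closure construction so that
#' the present-day reference point (all relative reservoirs and forcings at 1,
#' model time 0) is an exact steady state of every evolving reservoir:
#'
#' 1. total outgassing is split into carbonate and organic degassing in the
#'    baseline present-day proportion;
#' 2. present-day oxidative weathering is set by the O2 balance;
#' 3. present-day silicate weathering is the residual of the carbon balance
#'    (given the seafloor-weathering baseline), split into basalt/granite by
#'    the sampled basaltic fraction;
#' 4. the sulphur balance residual is absorbed into the effective present-day
#'    gypsum burial constant;
#' 5. marine P burial is closed against reactive P weathering, with the
#'    non-organic residual split between Ca-bound and Fe-sorbed burial in the
#'    baseline proportion; the N cycle is closed against denitrification.
#'
#' Draws for which any derived present-day flux is non-positive are rejected
#' with a classed error (`copse_closure_error`), which the Monte-Carlo sampler
#' catches and logs.
#'
#' @param carbw0 Present-day carbonate weathering, mol C yr^-1.
#' @param totdeg0 Present-day total outgassing (carbonate + organic), mol yr^-1.
#' @param mocb0 Present-day total organic carbon burial, mol C yr^-1 (all
#'   marine in this pre-vegetation configuration).
#' @param basfrac Basaltic fraction of present-day silicate weathering.
#' @param pyrdeg0,gypdeg0 Present-day pyrite/gypsum S degassing, mol S yr^-1.
#' @param mpsb0,mgsb0 Present-day marine pyrite/gypsum S burial, mol S yr^-1
#'   (`mgsb0` is replaced by the S-balance residual; the sampled value is kept
#'   for reference as `mgsb0_sampled`).
#' @param pyrw0,gypw0 Present-day pyrite/gypsum S weathering, mol S yr^-1.
#' @param phosw0 Present-day reactive phosphorus weathering, mol P yr^-1.
#' @param E_sfw,E_bas,E_gran Activation energies of seafloor, basalt and
#'   granite weathering, J mol^-1.
#' @param rgf0 Present-day reduced gas (H2) flux, mol yr^-1.
#' @param oxidw_exponent Power-law dependence of oxidative weathering on
#'   relative O2, in [0, 0.5].
#' @param climate_sensitivity Equilibrium warming per CO2 doubling, degC.
#' @param options List of switches: `mocb_o2_dependence` (logical, default
#'   FALSE), `capb_anoxia` (function of anox or NULL for no dependence),
#'   `rgf_o2_equiv` (mol O2 consumed per mol H2, default 1).
#' @param constants Fixed constants, see [copse_constants()].
#'
#' @return An object of class `copse_params`: a list with the sampled values,
#'   every derived present-day flux, and all constants.
#' @export
copse_parameters <- function(carbw0 = 10.5e12,
                             totdeg0 = 10.125e12,
                             mocb0 = 9.5e12,
                             basfrac = 0.26,
                             pyrdeg0 = 0.25e12,
                             gypdeg0 = 0.5e12,
                             mpsb0 = 0.70e12,
                             mgsb0 = 2.5e12,
                             pyrw0 = 0.45e12,
                             gypw0 = 2e12,
                             phosw0 = 4.2e10,
                             E_sfw = 70e3,
                             E_bas = 47.5e3,
                             E_gran = 53.5e3,
                             rgf0 = 1.1e12,
                             oxidw_exponent = 0.25,
                             climate_sensitivity = 3.75,
                             options = list(),
                             constants = copse_constants()) {
  cn <- constants
  opts <- utils::modifyList(
    list(mocb_o2_dependence = FALSE, capb_anoxia = NULL, rgf_o2_equiv = 1),
    options
  )
  stopifnot(carbw0 > 0, totdeg0 > 0, mocb0 > 0, phosw0 > 0,
            basfrac > 0, basfrac < 1, oxidw_exponent >= 0)

  ## (1) outgassing split
  ocdeg0 <- totdeg0 * cn$ocdeg_frac
  ccdeg0 <- totdeg0 - ocdeg0

  ## (2) O2 balance: mocb - oxidw - ocdeg + 2(mpsb - pyrw - pyrdeg) - rgf = 0
  oxidw0 <- mocb0 - ocdeg0 - opts$rgf_o2_equiv * rgf0 +
    2 * (mpsb0 - pyrw0 - pyrdeg0)
  if (oxidw0 <= 0) {
    closure_error("derived present-day oxidative weathering is non-positive",
                  oxidw0 = oxidw0)
  }

  ## (3) A balance residual (using the carbonate-burial identity
  ## mccb = silw + carbw + mpsb - pyrw - pyrdeg):
  ## silw0 = ccdeg0 + mpsb0 - pyrw0 - pyrdeg0 - sfw0
  silw0 <- ccdeg0 + mpsb0 - pyrw0 - pyrdeg0 - cn$sfw0
  if (silw0 <= 0) {
    closure_error("derived present-day silicate weathering is non-positive",
                  silw0 = silw0)
  }
  basw0 <- basfrac * silw0
  granw0 <- (1 - basfrac) * silw0
  mccb0 <- silw0 + carbw0 + mpsb0 - pyrw0 - pyrdeg0

  ## (4) S balance absorbed into effective gypsum burial
  mgsb0_eff <- gypw0 + pyrw0 + gypdeg0 + pyrdeg0 - mpsb0
  if (mgsb0_eff <= 0) {
    closure_error("derived present-day gypsum burial is non-positive",
                  mgsb0_eff = mgsb0_eff)
  }

  ## (5) P and N closure
  mopb0 <- mocb0 / cn$CP_sea
  p_resid <- phosw0 - mopb0
  if (p_resid <= 0) {
    closure_error(
      "organic P burial exceeds reactive P weathering at the reference point",
      mopb0 = mopb0, phosw0 = phosw0
    )
  }
  w <- cn$capb_fepb_ratio / sum(cn$capb_fepb_ratio)
  capb0 <- unname(w["capb"]) * p_resid
  fepb0 <- unname(w["fepb"]) * p_resid
  monb0 <- mocb0 / cn$CN_sea
  nfix0 <- cn$denit0 + monb0

  ## derived ecology/climate constants
  newp0 <- cn$r_CP * min(30.9 / cn$r_NP, 2.2)   # nutrient-limited reference
  anox0 <- 1 / (1 + exp(-cn$k_anox * (cn$k_u - 1)))
  k_c <- climate_sensitivity / log(2)
  arr <- cn$R_gas * cn$T0_K^2                   # linearised Arrhenius scale
  tf <- list(gran = E_gran / arr, bas = E_bas / arr, sfw = E_sfw / arr)

  ## strontium closure: total ocean input split between burial and seafloor
  ## weathering in the mccb0 : sfw0 proportion; metamorphic output balances
  ## the sediment reservoir.
  sr_in0 <- cn$k_Srgranw + cn$k_Srbasw + cn$k_Srsedw + cn$k_Srmantle
  k_Srsedb <- sr_in0 * mccb0 / (mccb0 + cn$sfw0)
  k_Srsfw <- sr_in0 * cn$sfw0 / (mccb0 + cn$sfw0)
  k_Srmetam <- k_Srsedb - cn$k_Srsedw
  if (k_Srmetam <= 0) {
    closure_error("derived present-day Sr metamorphic flux is non-positive",
                  k_Srmetam = k_Srmetam)
  }

  p <- list(
    sampled = list(
      carbw0 = carbw0, totdeg0 = totdeg0, mocb0 = mocb0, basfrac = basfrac,
      pyrdeg0 = pyrdeg0, gypdeg0 = gypdeg0, mpsb0 = mpsb0,
      mgsb0_sampled = mgsb0, pyrw0 = pyrw0, gypw0 = gypw0, phosw0 = phosw0,
      E_sfw = E_sfw, E_bas = E_bas, E_gran = E_gran, rgf0 = rgf0,
      oxidw_exponent = oxidw_exponent,
      climate_sensitivity = climate_sensitivity
    ),
    flux0 = list(
      phosw = phosw0, psea = phosw0, mocb = mocb0, mopb = mopb0,
      capb = capb0, fepb = fepb0, nfix = nfix0, denit = cn$denit0,
      monb = monb0, granw = granw0, basw = basw0, silw = silw0,
      carbw = carbw0, oxidw = oxidw0, mccb = mccb0, sfw = cn$sfw0,
      pyrw = pyrw0, gypw = gypw0, mpsb = mpsb0, mgsb = mgsb0_eff,
      ocdeg = ocdeg0, ccdeg = ccdeg0, pyrdeg = pyrdeg0, gypdeg = gypdeg0,
      rgf = rgf0
    ),
    oxidw_exponent = oxidw_exponent,
    k_c = k_c,
    tf = tf,
    anox0 = anox0,
    newp0 = newp0,
    sr = list(
      k_Srgranw = cn$k_Srgranw, k_Srbasw = cn$k_Srbasw,
      k_Srsedw = cn$k_Srsedw, k_Srmantle = cn$k_Srmantle,
      k_Srsedb = k_Srsedb, k_Srsfw = k_Srsfw, k_Srmetam = k_Srmetam
    ),
    options = opts,
    constants = cn
  )
  class(p) <- "copse_params"
  p
}

closure_error <- function(msg, ...) {
  stop(structure(
    class = c("copse_closure_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = list(...))
  ))
}

#' @export
print.copse_params <- function(x, ...) {
  cat("<copse_params>\n")
  cat("  sampled present-day values:\n")
  s <- unlist(x$sampled)
  for (nm in names(s)) cat(sprintf("    %-20s %g\n", nm, s[[nm]]))
  cat("  derived present-day fluxes (mol yr^-1):\n")
  f <- unlist(x$flux0)
  for (nm in names(f)) cat(sprintf("    %-8s %.4g\n", nm, f[[nm]]))
  invisible(x)
}

#' Monte-Carlo parameter ranges
#'
#' The flat-sampling intervals for the seventeen uncertain quantities:
#' eleven present-day fluxes/fractions, three weathering activation energies,
#' the modern H2 outgassing rate, the oxidative-weathering O2 exponent and
#' the climate sensitivity.
#'
#' @return Data frame with columns `name`, `min`, `max`, `units`.
#' @export
parameter_ranges <- function() {
  data.frame(
    name = c("carbw0", "totdeg0", "mocb0", "basfrac", "pyrdeg0", "gypdeg0",
             "mpsb0", "mgsb0", "pyrw0", "gypw0", "phosw0",
             "E_sfw", "E_bas", "E_gran", "rgf0", "oxidw_exponent",
             "climate_sensitivity"),
    min = c(7e12, 4e12, 5e12, 0.17, 0.12e12, 0.25e12,
            0.53e12, 1e12, 0.37e12, 1e12, 3.7e10,
            40e3, 33e3, 45e3, 0, 0, 1.5),
    max = c(14e12, 16.25e12, 14e12, 0.35, 0.38e12, 0.75e12,
            0.87e12, 4e12, 0.53e12, 3e12, 4.7e10,
            100e3, 62e3, 62e3, 2.2e12, 0.5, 6.0),
    units = c(rep("mol yr-1", 3), "", rep("mol yr-1", 7),
              rep("J mol-1", 3), "mol yr-1", "", "degC"),
    stringsAsFactors = FALSE
  )
}

#' Draw one flat sample of the uncertain quantities
#'
#' Independent uniform draw on each row of [parameter_ranges()]. This is the
#' raw flat-sampling stage; closure construction and rejection live in
#' [sample_parameters()].
#'
#' @param ranges Data frame as returned by [parameter_ranges()].
#' @return Named numeric vector of sampled values.
#' @export
draw_flat_sample <- function(ranges = parameter_ranges()) {
  stopifnot(all(ranges$min <= ranges$max))
  stats::setNames(stats::runif(nrow(ranges), ranges$min, ranges$max),
                  ranges$name)
}

#' Sample a closed parameter set from the Monte-Carlo ranges
#'
#' Draws flat samples and applies the closure construction, redrawing (and
#' logging) any draw whose derived present-day fluxes are infeasible.
#'
#' @param ranges Data frame as returned by [parameter_ranges()].
#' @param options,constants Passed to [copse_parameters()].
#' @param max_rejections Error after this many consecutive rejections.
#' @return A `copse_params` object with attribute `"rejections"`: a character
#'   vector of rejection reasons (empty if the first draw closed).
#' @export
sample_parameters <- function(ranges = parameter_ranges(), options = list(),
                              constants = copse_constants(),
                              max_rejections = 1000) {
  rejections <- character(0)
  repeat {
    d <- draw_flat_sample(ranges)
    res <- tryCatch(
      copse_parameters(
        carbw0 = d[["carbw0"]], totdeg0 = d[["totdeg0"]], mocb0 = d[["mocb0"]],
        basfrac = d[["basfrac"]], pyrdeg0 = d[["pyrdeg0"]],
        gypdeg0 = d[["gypdeg0"]], mpsb0 = d[["mpsb0"]], mgsb0 = d[["mgsb0"]],
        pyrw0 = d[["pyrw0"]], gypw0 = d[["gypw0"]], phosw0 = d[["phosw0"]],
        E_sfw = d[["E_sfw"]], E_bas = d[["E_bas"]], E_gran = d[["E_gran"]],
        rgf0 = d[["rgf0"]], oxidw_exponent = d[["oxidw_exponent"]],
        climate_sensitivity = d[["climate_sensitivity"]],
        options = options, constants = constants
      ),
      copse_closure_error = function(e) e
    )
    if (inherits(res, "copse_params")) {
      attr(res, "rejections") <- rejections
      return(res)
    }
    rejections <- c(rejections, conditionMessage(res))
    if (length(rejections) >= max_rejections) {
      stop("sample_parameters: more than ", max_rejections,
           " consecutive closure rejections; check the configured ranges")
    }
  }
}
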