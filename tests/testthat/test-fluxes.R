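# Flux laws: present-day normalisation, printed functional forms, the
# carbonate-burial identity and the mass/isotope balances.

ref_setup <- function(p = fixture_params()) {
  st <- reference_state(p)
  snap <- forcing_at(copse_forcing(V = 1), 0)
  cl <- climate_state(1, 0, p)
  anox <- anoxic_fraction(1, 1, p)
  eco <- ocean_ecology_fluxes(st, anox, snap, p)
  wea <- weathering_fluxes(st, snap, cl, p)
  bur <- burial_and_degassing_fluxes(st, snap, eco, wea, p)
  list(p = p, st = st, snap = snap, cl = cl, anox = anox,
       eco = eco, wea = wea, bur = bur)
}

test_that("every flux equals its present-day constant at the reference point", {
  s <- ref_setup()
  f0 <- s$p$flux0
  expect_equal(unname(s$eco["mocb"]), f0$mocb)
  expect_equal(unname(s$eco["mopb"]), f0$mopb)
  expect_equal(unname(s$eco["capb"]), f0$capb)
  expect_equal(unname(s$eco["fepb"]), f0$fepb)
  expect_equal(unname(s$eco["nfix"]), f0$nfix)
  expect_equal(unname(s$eco["denit"]), f0$denit)
  expect_equal(unname(s$eco["newp_rel"]), 1)
  for (nm in c("granw", "basw", "silw", "carbw", "oxidw", "sfw", "pyrw",
               "gypw", "phosw")) {
    expect_equal(unname(s$wea[nm]), f0[[nm]], tolerance = 1e-12, label = nm)
  }
  for (nm in c("mccb", "mpsb", "mgsb", "ocdeg", "ccdeg", "pyrdeg",
               "gypdeg", "rgf")) {
    expect_equal(unname(s$bur[nm]), f0[[nm]], tolerance = 1e-12, label = nm)
  }
  # the phosphorus channel weights sum to one
  expect_equal(sum(s$p$constants$phosw_weights), 1)
})

test_that("oxidative weathering follows the sampled power law in O2", {
  p <- copse_parameters(oxidw_exponent = 0.5)
  st <- reference_state(p)
  st[["O"]] <- 4 * p$constants$O0
  snap <- forcing_at(copse_forcing(V = 1), 0)
  w <- weathering_fluxes(st, snap, climate_state(1, 0, p), p)
  expect_equal(unname(w["oxidw"]), 2 * p$flux0$oxidw)
})

test_that("seafloor weathering matches an independent arithmetic evaluation", {
  p <- copse_parameters(E_sfw = 70e3)   # sampling-interval midpoint
  st <- reference_state(p)
  snap <- forcing_at(copse_forcing(D = 1.3, V = 1), 0)
  cl <- list(RCO2 = 1, deltaT = 2)
  w <- weathering_fluxes(st, snap, cl, p)
  k_T <- 70e3 / (8.314 * 288^2)
  expect_equal(unname(w["sfw"]), 1.75e12 * 1.3 * exp(k_T * 2))
})

test_that("optional O2 dependence of organic burial is 1 at present O2", {
  f <- 2.1276 * exp(-0.755 * 1)
  expect_lt(abs(f - 1), 1e-4)
  p <- copse_parameters(options = list(mocb_o2_dependence = TRUE))
  st <- reference_state(p)
  snap <- forcing_at(copse_forcing(V = 1), 0)
  eco <- ocean_ecology_fluxes(st, anoxic_fraction(1, 1, p), snap, p)
  expect_equal(unname(eco["mocb"]), p$flux0$mocb * f)
})

test_that("new production switches to the phosphorus-limited branch", {
  p <- fixture_params()
  cn <- p$constants
  st <- reference_state(p)
  st[["N"]] <- 100 * cn$N0          # nitrogen-replete
  snap <- forcing_at(copse_forcing(V = 1), 0)
  eco <- ocean_ecology_fluxes(st, 0.0025, snap, p)
  expect_equal(unname(eco["newp"]), cn$r_CP * 2.2)
  # nitrogen fixation shuts off when N / r_NP >= P
  expect_equal(unname(eco["nfix"]), 0)
})

test_that("degassing fluxes are linear in D and pyrite burial in s/o", {
  s <- ref_setup()
  snap2 <- forcing_at(copse_forcing(D = 2, V = 1), 0)
  bur2 <- burial_and_degassing_fluxes(s$st, snap2, s$eco, s$wea, s$p)
  for (nm in c("ocdeg", "ccdeg", "pyrdeg", "gypdeg", "rgf")) {
    expect_equal(unname(bur2[nm]), 2 * s$p$flux0[[nm]], label = nm)
  }
  # s/o = 2 at unchanged relative organic burial doubles pyrite burial
  st2 <- s$st
  st2[["S"]] <- 2 * s$p$constants$S0
  bur3 <- burial_and_degassing_fluxes(st2, s$snap, s$eco, s$wea, s$p)
  expect_equal(unname(bur3["mpsb"]), 2 * s$p$flux0$mpsb)
})

test_that("carbonate burial identity holds exactly and clamps at zero", {
  s <- ref_setup()
  expect_identical(
    unname(s$bur["mccb"]),
    unname(s$wea["silw"] + s$wea["carbw"] + s$bur["mpsb"] -
             s$wea["pyrw"] - s$bur["pyrdeg"]))
  expect_false(attr(s$bur, "mccb_clamped"))
  # force a negative identity: no weathering inputs, large pyrite degassing
  wea0 <- s$wea; wea0[c("silw", "carbw")] <- 0; wea0["pyrw"] <- 5e12
  bur <- burial_and_degassing_fluxes(s$st, s$snap, s$eco, wea0, s$p)
  expect_identical(unname(bur["mccb"]), 0)
  expect_true(attr(bur, "mccb_clamped"))
})

test_that("vegetation-off runs carry no land organic burial or land P", {
  p <- fixture_params()
  st <- reference_state(p)
  snap <- forcing_at(copse_forcing(V = 0), 600)
  eco <- ocean_ecology_fluxes(st, 0.5, snap, p)
  wea <- weathering_fluxes(st, snap, climate_state(1.5, 600, p), p)
  bur <- burial_and_degassing_fluxes(st, snap, eco, wea, p)
  expect_identical(unname(bur["locb"]), 0)
  expect_identical(unname(bur["pland"]), 0)
})

test_that("mass balance identities", {
  p <- fixture_params()
  st <- reference_state(p)
  nms <- c("psea", "mopb", "capb", "fepb", "nfix", "denit", "monb",
           "mocb", "locb", "oxidw", "ocdeg", "mpsb", "pyrw", "pyrdeg",
           "rgf", "ccdeg", "carbw", "mccb", "sfw", "gypw", "gypdeg", "mgsb")
  zero <- stats::setNames(rep(0, length(nms)), nms)
  expect_true(all(mass_balance(st, zero, p) == 0))
  # a unit pyrite-burial increase adds twice as much O2
  f1 <- zero; f1["mpsb"] <- 1e12
  expect_equal(unname(mass_balance(st, f1, p)["O"]), 2e12)
  expect_equal(unname(mass_balance(st, f1, p)["S"]), -1e12)
})

test_that("degenerate fractionation reduces moments to delta x mass balance", {
  p0 <- fixture_params()
  cn <- p0$constants
  cn$d13C_carb_rock <- 5; cn$d13C_org_rock <- 5; cn$d13C_mantle <- 5
  cn$Delta_C <- 0
  cn$d34S_pyr_rock <- 7; cn$d34S_gyp_rock <- 7; cn$Delta_S <- 0
  p <- copse_parameters(constants = cn)
  st <- reference_state(p, d13C_A = 5, d34S = 7)
  snap <- forcing_at(copse_forcing(D = 1.4, U = 0.8, V = 0), 600)
  pt <- copse_point(600, st, snap, p)
  expect_equal(pt$derivs[["MA"]], 5 * pt$derivs[["A"]], tolerance = 1e-9)
  expect_equal(pt$derivs[["MS"]], 7 * pt$derivs[["S"]], tolerance = 1e-9)
})

test_that("pyrite fraction of sulphur burial at interval midpoints", {
  # mpsb 0.70e12 against the S-balance gypsum burial at all-midpoint draws
  p <- fixture_params()
  s <- ref_setup(p)
  iso <- isotope_balance(s$st, c(s$eco, s$wea, s$bur,
                                 psea = unname(s$wea["phosw"])), p)
  expect_equal(iso$f_py, 0.70e12 / (0.70e12 + 2.5e12))
  expect_equal(iso$f_py, 0.21875)
  expect_gte(iso$f_org, 0); expect_lte(iso$f_org, 1)
})

test_that("isotope moment change equals a brute-force flux-by-flux sum", {
  p <- fixture_params()
  st <- reference_state(p) * exp(seq(-0.2, 0.2, length.out = 11))
  snap <- forcing_at(copse_forcing(D = 1.2, U = 1.4, V = 0), 580)
  pt <- copse_point(580, st, snap, p)
  f <- as.list(pt$fluxes)
  cn <- p$constants
  dA13 <- st[["MA"]] / st[["A"]]
  influx <- (f$ccdeg + f$carbw) * cn$d13C_carb_rock +
    (f$ocdeg + f$oxidw) * cn$d13C_org_rock + f$rgf * cn$d13C_mantle
  outflux <- (f$mccb + f$sfw) * dA13 + f$mocb * (dA13 - cn$Delta_C)
  expect_equal(pt$derivs[["MA"]], influx - outflux)
})
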