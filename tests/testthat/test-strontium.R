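# Strontium cycle: Rb/Sr calibration, end-member growth, fluxes and the
# isotope moment balance.

test_that("Rb/Sr calibration round-trips exactly", {
  p <- fixture_params()
  cn <- p$constants
  expect_equal(rb_sr_calibrate(cn$sr_ratio_initial, p), 0)
  # crustal average target reproduced after the age of the Earth
  rb <- rb_sr_calibrate(0.73, p)
  expect_identical(rb_sr_grow(rb, cn$earth_age_yr, p), 0.73)
  # round trip for arbitrary admissible ratios
  for (r in c(0.700, 0.7092, 0.715, 0.73, 0.85)) {
    expect_equal(rb_sr_grow(rb_sr_calibrate(r, p), cn$earth_age_yr, p), r)
  }
  expect_error(rb_sr_calibrate(0.69, p), "initial")
})

test_that("end-member ratios grow from the initial value to present targets", {
  p <- fixture_params()
  cn <- p$constants
  em0 <- end_member_ratios(0, p)
  expect_true(all(em0 == cn$sr_ratio_initial))
  em1 <- end_member_ratios(cn$earth_age_yr, p)
  expect_equal(unname(em1["granite"]), cn$sr_present_granite)
  expect_equal(unname(em1["basalt"]), cn$sr_present_basalt)
  expect_equal(unname(em1["mantle"]), cn$sr_present_mantle)
  # independent evaluation of the growth law at half the Earth's age
  t_half <- 2.25e9
  rb_g <- (cn$sr_present_granite - cn$sr_ratio_initial) /
    (1 - exp(-cn$lambda_Rb * cn$earth_age_yr))
  hand <- cn$sr_ratio_initial + rb_g * (1 - exp(-cn$lambda_Rb * t_half))
  expect_equal(unname(end_member_ratios(t_half, p)["granite"]), hand)
  # monotone growth
  ts <- seq(0, cn$earth_age_yr, length.out = 20)
  gr <- vapply(ts, function(t) end_member_ratios(t, p)[["granite"]],
               numeric(1))
  expect_true(all(diff(gr) > 0))
  expect_error(end_member_ratios(-1, p), "outside")
  expect_error(end_member_ratios(5e9, p), "outside")
})

test_that("Sr fluxes track their carbon-cycle counterparts", {
  p <- fixture_params()
  st <- reference_state(p)
  f0 <- p$flux0
  carbon <- c(basw = f0$basw, granw = f0$granw, carbw = f0$carbw,
              mccb = f0$mccb, sfw = f0$sfw)
  snap <- forcing_at(copse_forcing(V = 1), 0)
  srf <- sr_fluxes(st, snap, carbon, p)
  # each flux equals its constant, and ocean inputs equal outputs
  sp <- p$sr
  expect_equal(unname(srf["Sr_mantle"]), sp$k_Srmantle)
  expect_equal(unname(srf["Sr_basw"]), sp$k_Srbasw)
  expect_equal(unname(srf["Sr_granw"]), sp$k_Srgranw)
  expect_equal(unname(srf["Sr_sedw"]), sp$k_Srsedw)
  inputs <- sum(srf[c("Sr_mantle", "Sr_basw", "Sr_granw", "Sr_sedw")])
  outputs <- sum(srf[c("Sr_sedb", "Sr_sfw")])
  expect_equal(inputs, outputs)
  # removal split follows the carbonate-burial : seafloor-weathering ratio
  expect_equal(unname(srf["Sr_sedb"] / srf["Sr_sfw"]), f0$mccb / f0$sfw)
  # linearity in D; proportionality to basalt weathering
  snap2 <- forcing_at(copse_forcing(D = 1.5, V = 1), 0)
  srf2 <- sr_fluxes(st, snap2, carbon, p)
  expect_equal(unname(srf2["Sr_mantle"]), 1.5 * sp$k_Srmantle)
  expect_equal(unname(srf2["Sr_metam"]), 1.5 * sp$k_Srmetam)
  carbon2 <- carbon; carbon2["basw"] <- 2 * carbon["basw"]
  srf3 <- sr_fluxes(st, snap, carbon2, p)
  expect_equal(unname(srf3["Sr_basw"]), 2 * sp$k_Srbasw)
})

test_that("uniform source ratios are a fixed point of the ocean ratio", {
  p <- fixture_params()
  st <- reference_state(p, sr_ocean = 0.71, sr_sediment = 0.71)
  srf <- c(Sr_mantle = 1e10, Sr_basw = 1e10, Sr_granw = 1e10,
           Sr_sedw = 1e10, Sr_sedb = 2.5e10, Sr_sfw = 1.5e10,
           Sr_metam = 0.5e10)
  members <- c(granite = 0.71, basalt = 0.71, mantle = 0.71)
  b <- sr_isotope_balance(st, srf, members, 0, p)
  # d(r_ocean)/dt = (dMOSr - r * dOSr) / OSr = 0
  dr <- (b$dMOSr - b$sr_ocean * b$dOSr) / st[["OSr"]]
  expect_equal(dr, 0)
})

test_that("steady ocean ratio is the flux-weighted mean of its sources", {
  p <- fixture_params()
  # 4-source toy configuration, outputs carry the ocean ratio
  f <- c(Sr_mantle = 2e9, Sr_basw = 3e9, Sr_granw = 4e9, Sr_sedw = 1e9,
         Sr_sedb = 6e9, Sr_sfw = 4e9, Sr_metam = 0)
  members <- c(granite = 0.718, basalt = 0.705, mantle = 0.703)
  r_sed <- 0.709
  target <- (2e9 * 0.703 + 3e9 * 0.705 + 4e9 * 0.718 + 1e9 * r_sed) / 1e10
  # iterate the moment ODE to steady state by brute force
  st <- reference_state(p, sr_ocean = 0.75, sr_sediment = r_sed)
  r <- 0.75
  for (i in 1:4000) {
    st[["MOSr"]] <- st[["OSr"]] * r
    b <- sr_isotope_balance(st, f, members, 0, p)
    r <- r + 1e6 * (b$dMOSr - r * b$dOSr) / st[["OSr"]]
  }
  expect_equal(r, target, tolerance = 1e-10)
})

test_that("the in-run sediment Rb decay term raises the sediment ratio", {
  p <- fixture_params()
  st <- reference_state(p)
  srf <- rep(0, 7)
  names(srf) <- c("Sr_mantle", "Sr_basw", "Sr_granw", "Sr_sedw",
                  "Sr_sedb", "Sr_sfw", "Sr_metam")
  members <- end_member_ratios(4.0e9, p)
  b0 <- sr_isotope_balance(st, srf, members, 0, p)
  b1 <- sr_isotope_balance(st, srf, members, 1e8, p)
  rb_sed <- rb_sr_calibrate(0.73, p)
  expected <- rb_sed * (1 - exp(-p$constants$lambda_Rb * 1e8))
  expect_equal(b1$sr_sediment - b0$sr_sediment, expected)
  expect_gt(expected, 0)
})
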