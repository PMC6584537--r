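# Right-hand side composition and stiff integration.

test_that("rhs is pure: identical inputs give bit-identical outputs", {
  p <- fixture_params()
  st <- reference_state(p) * exp(seq(-0.1, 0.1, length.out = 11))
  frc <- copse_forcing(D = 1.2, U = 0.8, V = 0)
  d1 <- copse_rhs(600, st, frc, p, run_elapsed_yr = 1e7)
  d2 <- copse_rhs(600, st, frc, p, run_elapsed_yr = 1e7)
  expect_identical(d1, d2)
})

test_that("fast solver path reproduces the modular composition exactly", {
  p <- fixture_params()
  ctx <- copsebox:::make_rhs_context(p)
  set.seed(8)
  for (i in 1:20) {
    st <- reference_state(p) * exp(runif(11, -0.5, 0.5))
    D <- runif(1, 0.8, 2); U <- runif(1, 0.5, 2); t <- runif(1, 541, 650)
    el <- runif(1, 0, 1e8)
    snap <- forcing_at(copse_forcing(D = D, U = U, V = 0), t)
    d_mod <- copse_point(t, st, snap, p, run_elapsed_yr = el)$derivs
    d_fast <- copsebox:::rhs_fast(unname(st), D, U, 1, 1, 1, 0, 1, 1,
                                  t_solar_Ma = t, elapsed_yr = el, e = ctx)
    expect_equal(unname(d_mod), d_fast, tolerance = 1e-14)
  }
})

test_that("doubling D at fixed state shifts derivatives by the degassing deltas", {
  p <- fixture_params()
  st <- reference_state(p) * exp(seq(0.1, -0.1, length.out = 11))
  f1 <- copse_forcing(D = 1, U = 1, V = 0)
  f2 <- copse_forcing(D = 2, U = 1, V = 0)
  p1 <- copse_point(600, st, forcing_at(f1, 600), p)
  p2 <- copse_point(600, st, forcing_at(f2, 600), p)
  dfl <- p2$fluxes - p1$fluxes
  f0 <- p$flux0
  expect_equal(unname(dfl["ocdeg"]), f0$ocdeg)
  expect_equal(unname(dfl["ccdeg"]), f0$ccdeg)
  expect_equal(unname(dfl["pyrdeg"]), f0$pyrdeg)
  expect_equal(unname(dfl["gypdeg"]), f0$gypdeg)
  expect_equal(unname(dfl["rgf"]), f0$rgf)
  # O derivative shifts by -(2 pyrdeg + ocdeg + rgf) deltas plus mccb/sfw terms
  dO_expect <- -f0$ocdeg - 2 * f0$pyrdeg - f0$rgf
  sfw_delta <- unname(dfl["sfw"])   # sfw is also linear in D
  expect_equal(p2$derivs[["O"]] - p1$derivs[["O"]], dO_expect)
  expect_equal(p2$derivs[["A"]] - p1$derivs[["A"]],
               f0$ccdeg + f0$ocdeg + f0$rgf -
                 (unname(dfl["mccb"])) - sfw_delta)
})

test_that("integration preserves an exact steady state over 100 Myr", {
  p <- fixture_params()
  ss <- run_to_steady(forcing_at(copse_forcing(D = 1.2, U = 1, V = 0), 650),
                      p, t_ref_Ma = 650)
  expect_true(ss$converged)
  frc <- copse_forcing(D = 1.2, U = 1, V = 0)
  # constant forcing and frozen solar age: the state must not move
  out <- copsebox:::integrate_segment(
    ss$state, c(0, 1e8), function(tau) c(650, 0, 650), frc, p,
    rtol = 1e-6, method = "lsoda", maxsteps = 1e5)
  final <- copsebox:::unpack_state(out[nrow(out), -1])
  expect_equal(unname(final), unname(ss$state), tolerance = 1e-5)
})

test_that("halving solver tolerances changes end-state O2 by < 0.1%", {
  p <- fixture_params()
  frc <- fixture_forcing()
  spin <- fixture_midline_run()$spin
  tr1 <- copse_integrate(spin$state, 650, 630, frc, p, rtol = 1e-6)
  tr2 <- copse_integrate(spin$state, 650, 630, frc, p, rtol = 5e-7)
  o1 <- tr1$final_state[["O"]]; o2 <- tr2$final_state[["O"]]
  expect_lt(abs(o1 / o2 - 1), 1e-3)
})

test_that("a step increase in D relaxes towards the matching steady state", {
  p <- fixture_params()
  lo <- run_to_steady(forcing_at(copse_forcing(D = 1.0, U = 1, V = 0), 600),
                      p, t_ref_Ma = 600)
  hi <- run_to_steady(forcing_at(copse_forcing(D = 1.5, U = 1, V = 0), 600),
                      p, t_ref_Ma = 600)
  # integrate from the low-D steady state under high D with frozen solar age
  frc <- copse_forcing(D = 1.5, U = 1, V = 0)
  time_map <- function(tau) c(600, 0, 600)
  out <- copsebox:::integrate_segment(
    lo$state, seq(0, 4e8, by = 2e7), time_map, frc, p,
    rtol = 1e-6, method = "lsoda", maxsteps = 1e5)
  o_path <- exp(out[, 4])   # column 1 is time; O is the 3rd state
  # monotone rise up to solver noise at the asymptote
  expect_true(all(diff(o_path) > -1e-6 * o_path[-1]))
  expect_gt(o_path[length(o_path)], o_path[1])
  expect_equal(o_path[length(o_path)], hi$state[["O"]], tolerance = 1e-3)
  expect_gt(hi$state[["O"]], lo$state[["O"]])
})

test_that("redox bookkeeping holds at every step of a run without reduced gas", {
  p <- copse_parameters(rgf0 = 1e-9)  # effectively zero reduced-gas flux
  frc <- copse_forcing(D = 1.2, U = 1, V = 0)
  ss <- run_to_steady(forcing_at(frc, 650), p, t_ref_Ma = 650)
  tr <- copse_integrate(ss$state, 650, 600, frc, p)
  tab <- tr$table
  lhs <- (tab$mocb - tab$oxidw - tab$ocdeg) +
    2 * (tab$mpsb - tab$pyrw - tab$pyrdeg)
  # recompute dO independently at each emitted state
  for (i in seq(1, nrow(tab), by = 10)) {
    st <- unlist(tab[i, c("P", "N", "O", "A", "S", "OSr", "SSr",
                          "MA", "MS", "MOSr", "MSSr")])
    d <- copse_rhs(tab$t_Ma[i], st, frc, p)
    expect_equal(d[["O"]], lhs[i], tolerance = 1e-6)
  }
})

test_that("reservoirs stay positive along a strongly forced trajectory", {
  p <- fixture_params()
  run <- fixture_midline_run()
  tab <- run$trajectory$table
  for (v in c("P", "N", "O", "A", "S", "OSr", "SSr")) {
    expect_true(all(tab[[v]] > 0), label = v)
  }
  expect_equal(nrow(tab), 110)
  expect_equal(tab$t_Ma, seq(650, 541))
  expect_lte(run$trajectory$clamped_Myr, 0)
})
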