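# Shared fixtures, memoised so expensive objects are built once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_params <- function() memo("params", copse_parameters())

## midline degassing path + uplift ramp forcing over 650 -> 541 Ma
fixture_forcing <- function() memo("forcing", {
  path <- midline_degassing_path(default_ediacaran_window())
  copse_forcing(D = path,
                U = function(t) uplift_forcing(t, 650, 541, 0.5, 2),
                V = 0, breaks_Ma = path$breaks_Ma)
})

## one spun-up + integrated midline run
fixture_midline_run <- function() memo("midline_run", {
  p <- fixture_params()
  frc <- fixture_forcing()
  spin <- run_to_steady(forcing_at(frc, 650), p, t_ref_Ma = 650)
  list(spin = spin,
       trajectory = copse_integrate(spin$state, 650, 541, frc, p))
})

fixture_small_ensemble <- function() memo("small_ensemble",
                                          run_ensemble(8, master_seed = 7))

## degenerate ranges collapsed onto the default midpoints
degenerate_ranges <- function() {
  r <- parameter_ranges()
  mid <- (r$min + r$max) / 2
  r$min <- mid
  r$max <- mid
  r
}

## a degenerate (zero-width) window at constant D
degenerate_window <- function(d = 1, t_old = 650, t_young = 540) {
  nodes <- seq(t_old, t_young, by = -10)
  degassing_window(nodes, rep(d, length(nodes)), rep(d, length(nodes)))
}
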