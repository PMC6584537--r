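# Long-run equilibration under frozen forcing, and D x U response surfaces.

#' Steady-state residual of a state
#'
#' Maximum instantaneous rate of change over all model variables, measured as
#' relative rate (yr^-1) for mole inventories and absolute rate for the
#' isotopic diagnostics (per mil yr^-1 for d13C/d34S, ratio yr^-1 for Sr).
#'
#' @param state Named state vector.
#' @param snapshot Forcing snapshot.
#' @param params A `copse_params` object.
#' @param t_solar_Ma Time used for the solar term and Sr end-members.
#' @return Scalar residual (yr^-1).
#' @export
steady_residual <- function(state, snapshot, params, t_solar_Ma) {
  pt <- copse_point(t_solar_Ma, state, snapshot, params,
                    run_elapsed_yr = 0, t_solar_Ma = t_solar_Ma)
  d <- pt$derivs
  m <- STATE_MASSES
  rel <- abs(d[m] / state[m])
  ## d(delta)/dt = (dM - delta * dX) / X for each moment/mass pair
  ddel <- c(
    abs((d[["MA"]] - (state[["MA"]] / state[["A"]]) * d[["A"]]) / state[["A"]]),
    abs((d[["MS"]] - (state[["MS"]] / state[["S"]]) * d[["S"]]) / state[["S"]]),
    abs((d[["MOSr"]] - (state[["MOSr"]] / state[["OSr"]]) * d[["OSr"]]) /
          state[["OSr"]]),
    abs((d[["MSSr"]] - (state[["MSSr"]] / state[["SSr"]]) * d[["SSr"]]) /
          state[["SSr"]])
  )
  max(c(rel, ddel))
}

#' Equilibrate the model under constant forcing
#'
#' Integrates with frozen forcing and frozen solar term until the residual
#' drops below `tol` or the horizon is reached (the long horizon is a
#' relaxation device, not a physical history). The sedimentary Rb-decay
#' run-time term is frozen during equilibration.
#'
#' @param snapshot Forcing snapshot (e.g. `forcing_at(copse_forcing(D = 1.2,
#'   U = 0.5), 650)`), or a `copse_forcing` evaluated at `t_ref_Ma`.
#' @param params A `copse_params` object.
#' @param t_ref_Ma Reference time pinning the solar term and Sr end-member
#'   ages, Myr before present.
#' @param state0 Starting state; defaults to the present-day reference state.
#' @param horizon_yr Maximum integrated time (default 10 Gyr).
#' @param tol Convergence threshold on the residual, yr^-1.
#' @param rtol Solver relative tolerance.
#' @return An object of class `steady_state_result`: `state`, `fluxes`,
#'   `diag`, `residual`, `converged`, `t_integrated_yr`, `snapshot`.
#' @export
run_to_steady <- function(snapshot, params, t_ref_Ma = 541, state0 = NULL,
                          horizon_yr = 1e10, tol = 1e-10, rtol = 1e-6) {
  if (inherits(snapshot, "copse_forcing")) {
    snapshot <- forcing_at(snapshot, t_ref_Ma)
  }
  if (is.null(state0)) state0 <- reference_state(params)
  frc <- copse_forcing(D = snapshot$D, U = snapshot$U, PG = snapshot$PG,
                       a_gran = snapshot$a_gran, a_bas = snapshot$a_bas,
                       V = snapshot$V, B = snapshot$B, c_cal = snapshot$c_cal)
  time_map <- function(tau) c(t_ref_Ma, 0, t_ref_Ma)

  state <- state0
  t_done <- 0
  chunks <- c(1e6, 1e7, 1e8, 1e9, rep(2.225e9, 4))
  residual <- steady_residual(state, snapshot, params, t_ref_Ma)
  for (ch in chunks) {
    if (residual < tol || t_done >= horizon_yr) break
    ch <- min(ch, horizon_yr - t_done)
    out <- integrate_segment(state, c(0, ch), time_map, frc, params,
                             rtol = rtol, method = "lsoda", maxsteps = 1e5)
    state <- unpack_state(out[nrow(out), -1])
    t_done <- t_done + ch
    residual <- steady_residual(state, snapshot, params, t_ref_Ma)
  }

  pt <- copse_point(t_ref_Ma, state, snapshot, params, run_elapsed_yr = 0,
                    t_solar_Ma = t_ref_Ma)
  structure(
    list(state = state, fluxes = pt$fluxes, diag = pt$diag,
         residual = residual, converged = residual < tol,
         t_integrated_yr = t_done, snapshot = snapshot,
         t_ref_Ma = t_ref_Ma),
    class = "steady_state_result"
  )
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf(
    "<steady_state_result> D=%.3g U=%.3g %s (residual %.2e /yr after %.3g yr)\n",
    x$snapshot$D, x$snapshot$U,
    if (x$converged) "converged" else "NOT converged",
    x$residual, x$t_integrated_yr))
  cat(sprintf("  O2 = %.3f PAL, d13C = %+.2f, d34S = %.2f, 87Sr/86Sr = %.5f\n",
              x$diag[["O2_PAL"]], x$diag[["d13C_carb"]],
              x$diag[["d34S_sw"]], x$diag[["sr_ocean"]]))
  invisible(x)
}

#' Steady-state response surface over degassing and uplift
#'
#' Full factorial table of equilibrated model states over grids of the
#' degassing (D) and uplift/erosion (U) forcings, all other forcings at 1.
#'
#' @param d_values,u_values Forcing grids.
#' @param params A `copse_params` object.
#' @param t_ref_Ma Reference time for the solar term.
#' @param ... Passed to [run_to_steady()].
#' @return Data frame keyed by (D, U) with mocb, mccb, O2_mol, O2_PAL,
#'   d13C_carb, d34S_sw, sr_ocean, f_org, f_py, mpsb, mgsb, anox, RCO2,
#'   residual and convergence flag.
#' @export
sweep_DU <- function(d_values = seq(0.75, 2, by = 0.25),
                     u_values = seq(0.5, 2, by = 0.5),
                     params = copse_parameters(), t_ref_Ma = 541, ...) {
  stopifnot(length(d_values) > 0, length(u_values) > 0)
  grid <- expand.grid(D = d_values, U = u_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ss <- run_to_steady(forcing_at(copse_forcing(D = grid$D[i], U = grid$U[i]),
                                   t_ref_Ma),
                        params, t_ref_Ma = t_ref_Ma, ...)
    data.frame(
      D = grid$D[i], U = grid$U[i],
      mocb = ss$fluxes[["mocb"]], mccb = ss$fluxes[["mccb"]],
      mpsb = ss$fluxes[["mpsb"]], mgsb = ss$fluxes[["mgsb"]],
      O2_mol = ss$state[["O"]], O2_PAL = ss$diag[["O2_PAL"]],
      RCO2 = ss$diag[["RCO2"]], anox = ss$diag[["anox"]],
      d13C_carb = ss$diag[["d13C_carb"]], d34S_sw = ss$diag[["d34S_sw"]],
      sr_ocean = ss$diag[["sr_ocean"]], f_org = ss$diag[["f_org"]],
      f_py = ss$diag[["f_py"]],
      residual = ss$residual, converged = ss$converged
    )
  })
  do.call(rbind, res)
}
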