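# ODE right-hand side and stiff integration. The evolving state is
#   P, N, O, A, S, OSr, SSr        (mole inventories, integrated in log space)
#   MA = A * d13C_A, MS = S * d34S, MOSr = OSr * rOSr, MSSr = SSr * rSSr
# Crustal reservoirs (carbonate, organic C, pyrite, gypsum) are frozen at
# their relative value 1 throughout.

STATE_MASSES <- c("P", "N", "O", "A", "S", "OSr", "SSr")
STATE_MOMENTS <- c("MA", "MS", "MOSr", "MSSr")
STATE_NAMES <- c(STATE_MASSES, STATE_MOMENTS)

#' Steady isotopic compositions at the present-day reference point
#'
#' With the mole fluxes at their closed present-day values, the isotope
#' moment balances are linear in the reservoir compositions and can be
#' solved directly: the ocean-atmosphere carbon delta balances weathering
#' and degassing inputs against fractionated organic burial; sulphate
#' likewise; the ocean Sr ratio is the flux-weighted mean of its sources
#' (with the sediment ratio equal to the ocean ratio at full steady state).
#'
#' @param params A `copse_params` object.
#' @return Named numeric: `d13C_A`, `d34S`, `sr_ocean`, `sr_sediment`.
#' @export
reference_isotopes <- function(params) {
  cn <- params$constants
  f <- params$flux0
  c_in <- (f$ccdeg + f$carbw) * cn$d13C_carb_rock +
    (f$ocdeg + f$oxidw) * cn$d13C_org_rock + f$rgf * cn$d13C_mantle
  d13C_A <- (c_in + f$mocb * cn$Delta_C) / (f$mccb + f$sfw + f$mocb)
  s_in <- (f$pyrw + f$pyrdeg) * cn$d34S_pyr_rock +
    (f$gypw + f$gypdeg) * cn$d34S_gyp_rock
  d34S <- (s_in + f$mpsb * cn$Delta_S) / (f$mgsb + f$mpsb)
  sp <- params$sr
  em <- end_member_ratios(cn$earth_age_yr, params)
  sr_ocean <- (sp$k_Srgranw * em[["granite"]] + sp$k_Srbasw * em[["basalt"]] +
                 sp$k_Srmantle * em[["mantle"]]) /
    (sp$k_Srsedb + sp$k_Srsfw - sp$k_Srsedw)
  c(d13C_A = d13C_A, d34S = d34S, sr_ocean = sr_ocean,
    sr_sediment = sr_ocean)
}

#' Present-day reference state
#'
#' All mole inventories at their present-day values; the starting isotopic
#' compositions default to the analytic reference steady state of
#' [reference_isotopes()], so the full right-hand side vanishes here.
#'
#' @param params A `copse_params` object.
#' @param d13C_A Initial ocean-atmosphere carbon delta13C, per mil.
#' @param d34S Initial seawater sulphate delta34S, per mil.
#' @param sr_ocean,sr_sediment Initial 87Sr/86Sr ratios.
#' @return Named numeric state vector (mol; moments mol permil / mol ratio).
#' @export
reference_state <- function(params, d13C_A = NULL, d34S = NULL,
                            sr_ocean = NULL, sr_sediment = NULL) {
  cn <- params$constants
  iso <- reference_isotopes(params)
  if (is.null(d13C_A)) d13C_A <- iso[["d13C_A"]]
  if (is.null(d34S)) d34S <- iso[["d34S"]]
  if (is.null(sr_ocean)) sr_ocean <- iso[["sr_ocean"]]
  if (is.null(sr_sediment)) sr_sediment <- iso[["sr_sediment"]]
  c(P = cn$P0, N = cn$N0, O = cn$O0, A = cn$A0, S = cn$S0,
    OSr = cn$OSr0, SSr = cn$SSr0,
    MA = cn$A0 * d13C_A, MS = cn$S0 * d34S,
    MOSr = cn$OSr0 * sr_ocean, MSSr = cn$SSr0 * sr_sediment)
}

newp_relative <- function(state, params) {
  cn <- params$constants
  r <- relative_reservoirs(state, params)
  cn$r_CP * min(30.9 * r[["n"]] / cn$r_NP, 2.2 * r[["p"]]) / params$newp0
}

#' Evaluate all fluxes, derivatives and diagnostics at one point
#'
#' Composes the model stages in order: climate, anoxia, marine ecology,
#' weathering, burial/degassing, mass balance, C/S isotope balance and the
#' strontium system. Pure function of its arguments.
#'
#' @param t_Ma Time before present, Myr (drives the solar term and the Sr
#'   end-member ages unless overridden).
#' @param state Named state vector, see [reference_state()].
#' @param snapshot Forcing snapshot from [forcing_at()].
#' @param params A `copse_params` object.
#' @param run_elapsed_yr Time since the start of the transient run, yr (used
#'   by the in-run sedimentary Rb decay term; 0 freezes it, as during
#'   spin-up).
#' @param t_solar_Ma Time used for the solar-luminosity term and Sr
#'   end-member ages; defaults to `t_Ma`, frozen during equilibration runs.
#' @return List with `fluxes` (named, mol yr^-1), `derivs` (named, all state
#'   variables), `diag` (named diagnostics) and `mccb_clamped`.
#' @export
copse_point <- function(t_Ma, state, snapshot, params, run_elapsed_yr = 0,
                        t_solar_Ma = t_Ma) {
  cn <- params$constants
  r <- relative_reservoirs(state, params)
  climate <- climate_state(r[["a"]], t_solar_Ma, params)
  newp_rel <- newp_relative(state, params)
  anox <- anoxic_fraction(newp_rel, r[["o"]], params)

  eco <- ocean_ecology_fluxes(state, anox, snapshot, params)
  wea <- weathering_fluxes(state, snapshot, climate, params)
  bur <- burial_and_degassing_fluxes(state, snapshot, eco, wea, params)
  clamped <- attr(bur, "mccb_clamped")

  fluxes <- c(eco, wea, bur)
  fluxes[["psea"]] <- fluxes[["phosw"]] - fluxes[["pland"]]

  dm <- mass_balance(state, fluxes, params)
  iso <- isotope_balance(state, fluxes, params)

  members <- end_member_ratios(cn$earth_age_yr - t_solar_Ma * 1e6, params)
  srf <- sr_fluxes(state, snapshot, fluxes, params)
  srb <- sr_isotope_balance(state, srf, members, run_elapsed_yr, params)

  derivs <- c(dm["P"], dm["N"], dm["O"], dm["A"], dm["S"],
              OSr = srb$dOSr, SSr = srb$dSSr,
              MA = iso$dMA, MS = iso$dMS,
              MOSr = srb$dMOSr, MSSr = srb$dMSSr)

  diag <- c(RCO2 = climate$RCO2, deltaT = climate$deltaT, anox = anox,
            O2_PAL = r[["o"]], CO2_PAL = climate$RCO2,
            p_rel = r[["p"]], n_rel = r[["n"]], s_rel = r[["s"]],
            a_rel = r[["a"]], newp_rel = newp_rel,
            d13C_carb = iso$d13C_carb, d34S_sw = iso$d34S_sw,
            f_org = iso$f_org, f_py = iso$f_py,
            sr_ocean = srb$sr_ocean, sr_sediment = srb$sr_sediment,
            SO4_conc = r[["s"]] * cn$SO4_conc0)

  list(fluxes = c(fluxes, srf), derivs = derivs, diag = diag,
       mccb_clamped = clamped)
}

#' ODE right-hand side
#'
#' Derivatives of all state variables at `(t_Ma, state)` under a forcing
#' provider; deterministic and free of side effects.
#'
#' @param t_Ma Time before present, Myr.
#' @param state Named state vector.
#' @param forcing A `copse_forcing` provider.
#' @param params A `copse_params` object.
#' @inheritParams copse_point
#' @return Named derivative vector (per year).
#' @export
copse_rhs <- function(t_Ma, state, forcing, params, run_elapsed_yr = 0,
                      t_solar_Ma = t_Ma) {
  copse_point(t_Ma, state, forcing_at(forcing, t_Ma), params,
              run_elapsed_yr, t_solar_Ma)$derivs
}

pack_state <- function(state) {
  c(log(state[STATE_MASSES]), state[STATE_MOMENTS])
}

unpack_state <- function(y) {
  out <- c(exp(y[seq_len(7)]), y[8:11])
  names(out) <- STATE_NAMES
  out
}

state_atol <- function(params) {
  cn <- params$constants
  c(rep(1e-8, 7),
    1e-6 * cn$A0, 1e-6 * cn$S0 * 20,
    1e-6 * cn$OSr0 * 0.7, 1e-6 * cn$SSr0 * 0.7)
}

solver_error <- function(msg, ...) {
  stop(structure(
    class = c("copse_solver_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = list(...))
  ))
}

## integrate one smooth segment in physical years; `times_yr` must start at 0.
## `time_map` converts solver time to c(t_Ma, run_elapsed_yr, t_solar_Ma).
integrate_segment <- function(state, times_yr, time_map, forcing, params,
                              rtol, method, maxsteps) {
  ctx <- make_rhs_context(params)
  D_fun <- forcing$D; U_fun <- forcing$U
  PG <- forcing$PG; a_gran <- forcing$a_gran; a_bas <- forcing$a_bas
  V <- forcing$V; B <- forcing$B; c_cal <- forcing$c_cal
  fn <- function(tau, y, parms) {
    masses <- exp(y[seq_len(7)])
    tm <- time_map(tau)
    d <- rhs_fast(c(masses, y[8:11]), D_fun(tm[1]), U_fun(tm[1]),
                  PG, a_gran, a_bas, V, B, c_cal,
                  t_solar_Ma = tm[3], elapsed_yr = tm[2], e = ctx)
    list(c(d[seq_len(7)] / masses, d[8:11]))
  }
  ## solver diagnostics on failed steps are captured; failures surface as a
  ## classed condition below instead
  log <- utils::capture.output(
    out <- try(suppressWarnings(deSolve::ode(
      y = pack_state(state), times = times_yr, func = fn, parms = NULL,
      method = method, rtol = rtol, atol = state_atol(params),
      maxsteps = maxsteps
    )), silent = TRUE),
    type = "output"
  )
  if (inherits(out, "try-error") ||
      attr(out, "istate")[1] < 0 ||
      nrow(out) < length(times_yr) ||
      any(!is.finite(out[, -1]))) {
    solver_error("stiff integration failed",
                 t_reached = if (inherits(out, "try-error")) NA else
                   utils::tail(out[, 1], 1))
  }
  out
}

#' Integrate the model through time
#'
#' Adaptive stiff integration (via the deSolve solvers, reservoirs in log
#' space for positivity) from an initial state at `t_start_Ma` down to
#' `t_end_Ma`, splitting the run at forcing discontinuities and reporting on
#' a uniform output grid.
#'
#' @param state0 Named initial state vector.
#' @param t_start_Ma,t_end_Ma Run span, Myr before present
#'   (`t_start_Ma > t_end_Ma`).
#' @param forcing A `copse_forcing`.
#' @param params A `copse_params` object.
#' @param dt_out_Myr Output grid spacing, Myr.
#' @param rtol Relative solver tolerance.
#' @param method deSolve method (default `"lsoda"`).
#' @param maxsteps Maximum internal solver steps per segment.
#' @param sr_run_decay If `TRUE`, the sedimentary Rb-decay term accumulates
#'   from `t_start_Ma`.
#' @return A list of class `copse_trajectory`: `table` (data frame, one row
#'   per grid time with reservoirs, fluxes and diagnostics), `final_state`,
#'   and `clamped_Myr` (cumulative time with the carbonate-burial clamp
#'   active, estimated on the output grid).
#' @export
copse_integrate <- function(state0, t_start_Ma, t_end_Ma, forcing, params,
                            dt_out_Myr = 1, rtol = 1e-6, method = "lsoda",
                            maxsteps = 50000, sr_run_decay = TRUE) {
  stopifnot(t_start_Ma > t_end_Ma, dt_out_Myr > 0)
  grid <- seq(t_start_Ma, t_end_Ma, by = -dt_out_Myr)
  breaks <- forcing$breaks_Ma
  breaks <- sort(breaks[breaks < t_start_Ma & breaks > t_end_Ma],
                 decreasing = TRUE)
  seg_edges <- c(t_start_Ma, breaks, t_end_Ma)

  state <- state0
  rows <- vector("list", length(grid))
  emitted <- rep(FALSE, length(grid))
  emit <- function(t_Ma, st) {
    elapsed <- (t_start_Ma - t_Ma) * 1e6
    pt <- copse_point(t_Ma, st, forcing_at(forcing, t_Ma), params,
                      run_elapsed_yr = if (sr_run_decay) elapsed else 0)
    c(t_Ma = t_Ma, st, pt$fluxes, pt$diag,
      mccb_clamped = as.numeric(pt$mccb_clamped))
  }

  rows[[1]] <- emit(grid[1], state)
  emitted[1] <- TRUE
  for (i in seq_len(length(seg_edges) - 1)) {
    a <- seg_edges[i]; b <- seg_edges[i + 1]
    times_Ma <- sort(unique(c(a, grid[grid < a - 1e-9 & grid > b + 1e-9], b)),
                     decreasing = TRUE)
    times_yr <- (a - times_Ma) * 1e6
    ## solver time tau runs 0 .. (a - b) Myr within the segment; forcing is
    ## evaluated just inside the segment so step edges stay unambiguous
    time_map <- function(tau) {
      t_Ma <- a - tau / 1e6
      c(max(t_Ma, b + 1e-6),
        if (sr_run_decay) (t_start_Ma - t_Ma) * 1e6 else 0,
        t_Ma)
    }
    out <- integrate_segment(state, times_yr, time_map, forcing, params,
                             rtol, method, maxsteps)
    for (j in seq_along(times_Ma)) {
      st <- unpack_state(out[j, -1])
      if (j == length(times_Ma)) state <- st
      idx <- which(abs(grid - times_Ma[j]) < 1e-9)
      if (length(idx) == 1 && !emitted[idx]) {
        rows[[idx]] <- emit(times_Ma[j], st)
        emitted[idx] <- TRUE
      }
    }
  }

  tab <- as.data.frame(do.call(rbind, rows[emitted]))
  clamped_Myr <- sum(tab$mccb_clamped) * dt_out_Myr
  structure(list(table = tab, final_state = state,
                 clamped_Myr = clamped_Myr,
                 t_start_Ma = t_start_Ma, t_end_Ma = t_end_Ma),
            class = "copse_trajectory")
}

#' @export
print.copse_trajectory <- function(x, ...) {
  cat(sprintf("<copse_trajectory> %g -> %g Ma, %d grid points\n",
              x$t_start_Ma, x$t_end_Ma, nrow(x$table)))
  invisible(x)
}
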