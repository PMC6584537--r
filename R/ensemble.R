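# Monte-Carlo uncertainty engine: flat parameter sampling, per-run degassing
# paths, transient ensemble runs with per-run steady-state spin-up, band
# statistics, and the O2-change distribution between two age windows.

ENSEMBLE_VARS <- c("O2_PAL", "RCO2", "mocb", "mccb", "mpsb", "mgsb",
                   "f_org", "f_py", "d13C_carb", "d34S_sw", "sr_ocean",
                   "sr_sediment", "SO4_conc", "anox", "s_rel")

#' Deterministic per-run seed
#'
#' Counter-based substream keyed on (master seed, run index): adding runs to
#' an ensemble never perturbs existing ones, and runs may execute in any
#' order with identical results.
#'
#' @param master_seed Integer master seed.
#' @param run_index Run number (1-based).
#' @return Integer seed < 2^31.
#' @export
run_seed <- function(master_seed, run_index) {
  as.integer((as.numeric(master_seed) * 48271 +
                as.numeric(run_index) * 30269) %% 2147483647)
}

run_one <- function(seed, window, uplift, t_start_Ma, t_end_Ma, ranges,
                    options, constants, rtol, spinup_tol) {
  set.seed(seed)
  params <- sample_parameters(ranges, options = options,
                              constants = constants)
  path <- sample_degassing_path(window)
  frc <- copse_forcing(
    D = path,
    U = function(t_Ma) uplift_forcing(t_Ma, t_start_Ma, t_end_Ma,
                                      uplift[1], uplift[2]),
    V = 0, breaks_Ma = path$breaks_Ma
  )
  spin <- run_to_steady(forcing_at(frc, t_start_Ma), params,
                        t_ref_Ma = t_start_Ma, tol = spinup_tol, rtol = rtol)
  tr <- copse_integrate(spin$state, t_start_Ma, t_end_Ma, frc, params,
                        rtol = rtol)
  list(params = params, path = path, spin = spin, trajectory = tr,
       valid = spin$converged && tr$clamped_Myr <= 1,
       rejections = attr(params, "rejections"))
}

#' Run a Monte-Carlo transient ensemble
#'
#' For each run: draw a flat parameter sample (with closure construction),
#' draw a degassing path from the window, spin the model to steady state
#' under the run's start-of-run forcing, then integrate the transient to
#' `t_end_Ma` on a 1-Myr output grid. Runs are seeded independently from the
#' master seed and are order-independent. Runs with solver failures,
#' unconverged spin-up or a persistent carbonate-burial clamp (> 1 Myr) are
#' flagged invalid and excluded from statistics.
#'
#' @param n_runs Number of runs (the full experiment uses 10,000; a reduced
#'   ensemble of a few hundred reproduces the headline statistics at desk
#'   scale).
#' @param master_seed Integer master seed.
#' @param window A `degassing_window` (default [default_ediacaran_window()]).
#' @param uplift Length-2 numeric `c(u_start, u_end)`; use equal values for
#'   the constant-uplift variant.
#' @param ranges Data frame of sampling intervals, see [parameter_ranges()].
#' @param t_start_Ma,t_end_Ma Transient span, Myr before present.
#' @param options,constants Passed to [copse_parameters()].
#' @param rtol Solver relative tolerance.
#' @param spinup_tol Steady-state residual threshold, yr^-1.
#' @param max_invalid_frac Error if more than this fraction of runs is
#'   invalid.
#' @return Object of class `copse_ensemble`: `t_grid_Ma`, 3-d array `vars`
#'   (time x variable x run), per-run `draws` data frame, `seeds`, `valid`
#'   flags, `failures` diagnostics, and the experiment configuration.
#' @export
run_ensemble <- function(n_runs, master_seed,
                         window = default_ediacaran_window(),
                         uplift = c(0.5, 2.0),
                         ranges = parameter_ranges(),
                         t_start_Ma = 650, t_end_Ma = 541,
                         options = list(), constants = copse_constants(),
                         rtol = 1e-6, spinup_tol = 1e-10,
                         max_invalid_frac = 0.1) {
  stopifnot(n_runs >= 1)
  t_grid <- seq(t_start_Ma, t_end_Ma, by = -1)
  vars <- array(NA_real_,
                dim = c(length(t_grid), length(ENSEMBLE_VARS), n_runs),
                dimnames = list(NULL, ENSEMBLE_VARS, NULL))
  seeds <- vapply(seq_len(n_runs), function(i) run_seed(master_seed, i),
                  integer(1))
  valid <- logical(n_runs)
  draws <- vector("list", n_runs)
  failures <- list()
  n_rejections <- 0L

  for (i in seq_len(n_runs)) {
    res <- tryCatch(
      run_one(seeds[i], window, uplift, t_start_Ma, t_end_Ma, ranges,
              options, constants, rtol, spinup_tol),
      copse_solver_error = function(e) e
    )
    if (inherits(res, "copse_solver_error")) {
      failures[[length(failures) + 1]] <- list(run = i, seed = seeds[i],
                                               message = conditionMessage(res))
      draws[[i]] <- rep(NA_real_, nrow(ranges))
      next
    }
    tab <- res$trajectory$table
    stopifnot(nrow(tab) == length(t_grid))
    vars[, , i] <- as.matrix(tab[, ENSEMBLE_VARS])
    valid[i] <- res$valid
    draws[[i]] <- unlist(res$params$sampled)
    n_rejections <- n_rejections + length(res$rejections)
    if (!res$valid) {
      failures[[length(failures) + 1]] <- list(
        run = i, seed = seeds[i],
        message = if (!res$spin$converged) "spin-up not converged"
        else "persistent mccb clamp")
    }
  }

  if (mean(!valid) > max_invalid_frac) {
    stop(sprintf("run_ensemble: %d/%d runs invalid (limit %.0f%%)",
                 sum(!valid), n_runs, 100 * max_invalid_frac))
  }
  draws <- as.data.frame(do.call(rbind, draws))
  structure(
    list(n_runs = n_runs, master_seed = master_seed, seeds = seeds,
         t_grid_Ma = t_grid, vars = vars, draws = draws, valid = valid,
         failures = failures, n_closure_rejections = n_rejections,
         window = window, uplift = uplift,
         t_start_Ma = t_start_Ma, t_end_Ma = t_end_Ma),
    class = "copse_ensemble"
  )
}

#' @export
print.copse_ensemble <- function(x, ...) {
  cat(sprintf(
    "<copse_ensemble> %d runs (%d valid), seed %d, %g -> %g Ma\n",
    x$n_runs, sum(x$valid), x$master_seed, x$t_start_Ma, x$t_end_Ma))
  cat(sprintf("  closure redraws: %d; failures: %d\n",
              x$n_closure_rejections, length(x$failures)))
  invisible(x)
}

#' Ensemble band statistics for one variable
#'
#' Per-time-point mean and sample standard deviation over valid runs, with
#' the +/- 0.5 sd and +/- 1 sd bands used for ensemble envelope plots.
#'
#' @param ensemble A `copse_ensemble`.
#' @param variable One of the recorded variables (see `dimnames` of
#'   `ensemble$vars`).
#' @return Data frame: t_Ma, mean, sd, lo_half, hi_half, lo_1, hi_1.
#' @export
band_statistics <- function(ensemble, variable) {
  v <- ensemble$vars[, variable, ensemble$valid, drop = FALSE]
  if (dim(v)[3] < 2) stop("band_statistics: need >= 2 valid runs")
  m <- apply(v, 1, mean)
  s <- apply(v, 1, stats::sd)
  data.frame(t_Ma = ensemble$t_grid_Ma, mean = m, sd = s,
             lo_half = m - 0.5 * s, hi_half = m + 0.5 * s,
             lo_1 = m - s, hi_1 = m + s)
}

window_mean <- function(t_grid, values, window_Ma) {
  sel <- t_grid <= max(window_Ma) & t_grid >= min(window_Ma)
  if (!any(sel)) stop("window outside the trajectory span")
  mean(values[sel])
}

#' Distribution of the per-run O2 change between two age windows
#'
#' For each valid run the surface O2 change is the fractional difference of
#' the mean O2 over the late window relative to the mean over the early
#' window, in percent.
#'
#' @param ensemble A `copse_ensemble`.
#' @param early_window,late_window Length-2 age windows, Ma.
#' @param breaks Histogram bin edges (percent change).
#' @return List: `changes_pct` (per valid run), `fraction_positive`,
#'   `fraction_25_75` (runs with a 25-75% increase), and a `histogram` data
#'   frame (bin lo/hi, count).
#' @export
o2_change_distribution <- function(ensemble, early_window = c(640, 620),
                                   late_window = c(560, 540),
                                   breaks = seq(-100, 400, by = 12.5)) {
  t_grid <- ensemble$t_grid_Ma
  for (w in list(early_window, late_window)) {
    if (!any(t_grid <= max(w) & t_grid >= min(w))) {
      stop("o2_change_distribution: window outside the trajectory span")
    }
  }
  o2 <- ensemble$vars[, "O2_PAL", ensemble$valid, drop = FALSE]
  changes <- apply(o2, 3, function(v) {
    100 * (window_mean(t_grid, v, late_window) /
             window_mean(t_grid, v, early_window) - 1)
  })
  h <- graphics::hist(pmin(pmax(changes, min(breaks)), max(breaks)),
                      breaks = breaks, plot = FALSE)
  list(
    changes_pct = changes,
    fraction_positive = mean(changes > 0),
    fraction_25_75 = mean(changes >= 25 & changes <= 75),
    histogram = data.frame(lo = utils::head(h$breaks, -1),
                           hi = utils::tail(h$breaks, -1),
                           count = h$counts)
  )
}
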