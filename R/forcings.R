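# External forcings: the degassing window and its seeded step-function
# sampling, the linear uplift ramp, and the combined forcing provider used
# by the integrator.

#' Construct a degassing uncertainty window
#'
#' A window is a set of time nodes with lower/upper relative degassing
#' bounds; paths are drawn by resampling uniformly inside the envelope on a
#' fixed interval (default every 10 Myr).
#'
#' @param node_times_Ma Strictly ordered (decreasing towards present) node
#'   times, Myr before present.
#' @param d_min,d_max Lower/upper relative degassing at each node (present
#'   day = 1); both positive, `d_min <= d_max` everywhere.
#' @param resample_interval_Myr Width of the constant segments drawn by
#'   [sample_degassing_path()].
#' @return An object of class `degassing_window`.
#' @export
degassing_window <- function(node_times_Ma, d_min, d_max,
                             resample_interval_Myr = 10) {
  stopifnot(length(node_times_Ma) >= 2,
            length(d_min) == length(node_times_Ma),
            length(d_max) == length(node_times_Ma),
            all(diff(node_times_Ma) < 0),
            all(d_min > 0), all(d_max >= d_min),
            resample_interval_Myr > 0)
  structure(
    list(node_times_Ma = node_times_Ma, d_min = d_min, d_max = d_max,
         resample_interval_Myr = resample_interval_Myr),
    class = "degassing_window"
  )
}

window_bounds_at <- function(window, t_Ma) {
  lo <- stats::approx(window$node_times_Ma, window$d_min, xout = t_Ma,
                      rule = 2)$y
  hi <- stats::approx(window$node_times_Ma, window$d_max, xout = t_Ma,
                      rule = 2)$y
  list(lo = lo, hi = hi, mid = (lo + hi) / 2)
}

#' Default late-Neoproterozoic degassing window
#'
#' A synthetic stand-in for reconstructed subduction-zone-length forcing:
#' relative degassing rises monotonically from about 1.0-1.2 at 650 Ma to
#' about 1.4-1.6 at the Precambrian-Cambrian boundary, with an envelope
#' half-width of 0.1 throughout (midline 1.1 -> 1.5). Users with a digitised
#' reconstruction should supply their own node table via
#' [degassing_window()] or [read_window_csv()].
#'
#' @param t_old_Ma,t_young_Ma Span of the window, Myr before present.
#' @return A `degassing_window`.
#' @export
default_ediacaran_window <- function(t_old_Ma = 650, t_young_Ma = 540) {
  nodes <- seq(t_old_Ma, t_young_Ma, by = -10)
  frac <- (t_old_Ma - nodes) / (t_old_Ma - 541)
  mid <- 1.1 + 0.4 * pmin(frac, 1)
  degassing_window(nodes, d_min = mid - 0.1, d_max = mid + 0.1)
}

#' Draw one degassing path from a window
#'
#' One uniform draw inside the envelope per resample segment, held constant
#' within the segment (a step function). Uses the current RNG stream, so the
#' path is reproducible from the seed set by the caller.
#'
#' @param window A `degassing_window`.
#' @param blend If `TRUE`, linearly interpolate between segment draws
#'   instead of holding them constant.
#' @return A list of class `degassing_path` with `fun(t_Ma)`, the segment
#'   start times `breaks_Ma`, and the drawn `values`.
#' @export
sample_degassing_path <- function(window, blend = FALSE) {
  span <- range(window$node_times_Ma)
  starts <- seq(span[1], span[2], by = window$resample_interval_Myr)
  b <- window_bounds_at(window, starts)
  values <- stats::runif(length(starts), b$lo, b$hi)
  fun <- if (blend) {
    stats::approxfun(starts, values, rule = 2)
  } else {
    ## segment [starts[i], starts[i] - interval) takes values[i]
    stats::approxfun(starts, values, method = "constant", rule = 2,
                     f = 1)
  }
  structure(list(fun = fun, breaks_Ma = starts, values = values,
                 window = window),
            class = "degassing_path")
}

#' Midline (degenerate) degassing path of a window
#' @param window A `degassing_window`.
#' @return A `degassing_path` following the envelope midline exactly.
#' @export
midline_degassing_path <- function(window) {
  span <- range(window$node_times_Ma)
  starts <- seq(span[1], span[2], by = window$resample_interval_Myr)
  b <- window_bounds_at(window, starts)
  structure(
    list(fun = stats::approxfun(starts, b$mid, method = "constant",
                                rule = 2, f = 1),
         breaks_Ma = starts, values = b$mid, window = window),
    class = "degassing_path"
  )
}

#' Linear uplift/erosion forcing
#'
#' Linear interpolation from `u_start` at `t_start_Ma` to `u_end` at
#' `t_end_Ma`; the constant-uplift variant is obtained with
#' `u_start == u_end`.
#'
#' @param t_Ma Evaluation time, Myr before present (inside the span).
#' @param t_start_Ma,t_end_Ma Span of the ramp (old to young).
#' @param u_start,u_end Relative uplift at the span ends.
#' @return Relative uplift/erosion rate.
#' @export
uplift_forcing <- function(t_Ma, t_start_Ma = 650, t_end_Ma = 541,
                           u_start = 0.5, u_end = 2.0) {
  if (any(t_Ma > t_start_Ma + 1e-9) || any(t_Ma < t_end_Ma - 1e-9)) {
    stop("uplift_forcing: t outside the forcing span")
  }
  u_start + (u_end - u_start) * (t_start_Ma - t_Ma) / (t_start_Ma - t_end_Ma)
}

#' Combined forcing provider
#'
#' Bundles degassing and uplift functions with the constant forcings
#' (palaeogeography, land-area factors, vegetation switch, carbonate-burial
#' and calcium forcings) into the provider consumed by the integrator.
#'
#' @param D Function of `t_Ma`, or a single number, or a `degassing_path`.
#' @param U Function of `t_Ma` or a single number.
#' @param PG,a_gran,a_bas,B,c_cal Constant forcing factors (default 1).
#' @param V Vegetation forcing; 0 for all pre-plant runs.
#' @param breaks_Ma Times of forcing discontinuities, used to split the
#'   integration into smooth segments.
#' @return An object of class `copse_forcing`.
#' @export
copse_forcing <- function(D = 1, U = 1, PG = 1, a_gran = 1, a_bas = 1,
                          V = 0, B = 1, c_cal = 1, breaks_Ma = numeric(0)) {
  if (inherits(D, "degassing_path")) {
    breaks_Ma <- sort(unique(c(breaks_Ma, D$breaks_Ma)), decreasing = TRUE)
    D <- D$fun
  }
  if (is.numeric(D)) { dval <- D; D <- function(t_Ma) dval }
  if (is.numeric(U)) { uval <- U; U <- function(t_Ma) uval }
  structure(
    list(D = D, U = U, PG = PG, a_gran = a_gran, a_bas = a_bas, V = V,
         B = B, c_cal = c_cal, breaks_Ma = breaks_Ma),
    class = "copse_forcing"
  )
}

#' Evaluate a forcing provider at one time
#' @param forcing A `copse_forcing`.
#' @param t_Ma Time before present, Myr.
#' @return Snapshot list with D, U, PG, a_gran, a_bas, V, B, c_cal.
#' @export
forcing_at <- function(forcing, t_Ma) {
  list(D = forcing$D(t_Ma), U = forcing$U(t_Ma), PG = forcing$PG,
       a_gran = forcing$a_gran, a_bas = forcing$a_bas, V = forcing$V,
       B = forcing$B, c_cal = forcing$c_cal)
}

#' Read / write degassing-window node tables
#'
#' Plain CSV with columns `t_Ma`, `d_min`, `d_max`.
#'
#' @param path File path.
#' @param window A `degassing_window` (for writing).
#' @param resample_interval_Myr Resample interval used when reading.
#' @return `read_window_csv` returns a `degassing_window`.
#' @export
read_window_csv <- function(path, resample_interval_Myr = 10) {
  d <- utils::read.csv(path)
  stopifnot(all(c("t_Ma", "d_min", "d_max") %in% names(d)))
  d <- d[order(d$t_Ma, decreasing = TRUE), ]
  degassing_window(d$t_Ma, d$d_min, d$d_max, resample_interval_Myr)
}

#' @rdname read_window_csv
#' @export
write_window_csv <- function(window, path) {
  utils::write.csv(
    data.frame(t_Ma = window$node_times_Ma, d_min = window$d_min,
               d_max = window$d_max),
    path, row.names = FALSE
  )
  invisible(path)
}
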