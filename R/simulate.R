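# Integration of the ODE system over piecewise-constant glucose protocols.
# Every protocol reduces to constant-glucose pieces (square waves included),
# so the solver is restarted at each discontinuity and never steps across one.

# breakpoints and levels of the piecewise-constant driving function
protocol_pieces <- function(protocol) {
  dur <- protocol_duration(protocol)
  brk <- c(0, switch_times(protocol), dur)
  data.frame(a = brk[-length(brk)], b = brk[-1],
             level = glucose_at(protocol, brk[-length(brk)]))
}

# Workhorse: integrate over the protocol, returning states at `times`.
# `pieces` may be precomputed (hot loops in the likelihood). Two engines
# solve the identical right-hand side: "lsoda" (deSolve, the user-facing
# default) and "dp45", a compiled multi-segment Dormand-Prince 5(4) used in
# likelihood loops where per-call overhead dominates; their equivalence is
# asserted in the test suite.
integrate_pieces <- function(protocol, params, init, times,
                             rtol = 1e-8, atol = 1e-10, pieces = NULL,
                             engine = c("lsoda", "dp45")) {
  engine <- match.arg(engine)
  if (is.null(pieces)) pieces <- protocol_pieces(protocol)
  if (is.unsorted(times)) stop("output times must be non-decreasing")
  dur <- pieces$b[nrow(pieces)]
  if (times[1] < 0 || times[length(times)] > dur)
    stop("output times outside protocol domain [0, ", dur, "]")
  if (engine == "dp45") {
    st <- .Call("rosmm_c_solve", pack_params(params, 0)[1:10],
                as.double(c(pieces$a[1], pieces$b)),
                as.double(pieces$level), as.double(init),
                as.double(times), as.double(rtol), as.double(atol),
                PACKAGE = "rosmm")
    out <- cbind(st, adaptation_effect(pmax(st[, 3], 0), params))
    colnames(out) <- c("ROS", "MM", "AD", "AD_ef")
    return(out)
  }
  state <- init
  out <- matrix(NA_real_, length(times), 4,
                dimnames = list(NULL, c("ROS", "MM", "AD", "AD_ef")))
  for (i in seq_len(nrow(pieces))) {
    a <- pieces$a[i]; b <- pieces$b[i]
    sel <- which(times >= a & (times < b | (b == dur & times <= b)))
    tt <- sort(unique(c(a, times[sel], b)))
    sol <- deSolve::lsoda(y = state, times = tt, func = "rosmm_derivs",
                          parms = pack_params(params, pieces$level[i]),
                          dllname = "rosmm", initfunc = "rosmm_initparms",
                          nout = 1, outnames = "AD_ef",
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failure in segment ", i, " [", a, ", ", b,
           "] h of protocol '", attr(protocol, "name"), "'")
    if (length(sel)) {
      idx <- match(times[sel], sol[, 1])
      out[sel, ] <- sol[idx, c("ROS", "MM", "AD", "AD_ef"), drop = FALSE]
    }
    state <- sol[nrow(sol), c("ROS", "MM", "AD")]
  }
  out
}

#' Simulate the model over a glucose protocol
#'
#' Integrates the ROS / metabolic-memory / adaptation system with
#' `deSolve::lsoda` (compiled right-hand side), restarting at every
#' glucose discontinuity. Default output grid is hourly, fine enough to
#' resolve 24-hour oscillations.
#'
#' @param protocol A [glucose_protocol()].
#' @param params A [ros_params()] object.
#' @param init Initial state, named vector `(ROS, MM, AD)`;
#'   defaults to [healthy_state()].
#' @param times Output grid (hours) within the protocol domain;
#'   default `seq(0, duration, by = 1)`.
#' @param rtol,atol Solver tolerances.
#' @param engine `"lsoda"` (deSolve, default) or `"dp45"`, a compiled
#'   adaptive Dormand-Prince solver of the same system (used internally
#'   by the likelihood; the two agree to solver tolerance).
#' @return A `ros_traj`: data frame with columns `time`, `GLU`, `ROS`,
#'   `MM`, `AD`, `AD_ef`, carrying the protocol and parameters as
#'   attributes.
#' @examples
#' tr <- simulate_protocol(make_cg(20, 336, ng_duration_h = 336))
#' max(tr$ROS)
#' @export
simulate_protocol <- function(protocol, params = ros_params(),
                              init = healthy_state(), times = NULL,
                              rtol = 1e-8, atol = 1e-10,
                              engine = c("lsoda", "dp45")) {
  stopifnot(inherits(protocol, "glucose_protocol"))
  validate_params(params)
  init <- check_init(init)
  if (is.null(times)) times <- seq(0, protocol_duration(protocol), by = 1)
  states <- integrate_pieces(protocol, params, init, times, rtol, atol,
                             engine = match.arg(engine))
  traj <- data.frame(time = times, GLU = glucose_at(protocol, times), states)
  structure(traj, class = c("ros_traj", "data.frame"),
            protocol = protocol, params = params)
}

check_init <- function(init) {
  if (is.null(names(init))) names(init) <- c("ROS", "MM", "AD")
  init <- init[c("ROS", "MM", "AD")]
  if (any(!is.finite(init)) || any(init < 0))
    stop("initial state must be finite and non-negative")
  init
}

#' @export
print.ros_traj <- function(x, ...) {
  if (is.null(x$time) || is.null(x$ROS) || nrow(x) == 0L)
    return(NextMethod())                    # subset without the core columns
  cat("Model trajectory over protocol '", attr(attr(x, "protocol"), "name"),
      "': ", nrow(x), " time points, ", x$time[1], "-", x$time[nrow(x)],
      " h\n", sep = "")
  cat("  terminal state: ROS ", signif(x$ROS[nrow(x)], 5), ", MM ",
      signif(x$MM[nrow(x)], 5), ", AD ", signif(x$AD[nrow(x)], 5), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.ros_traj <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$GLU, type = "s", xlab = "time (h)",
                 ylab = "glucose (mM)", main = "driving function", ...)
  graphics::plot(x$time, x$ROS, type = "l", xlab = "time (h)",
                 ylab = "ROS (fold of control)", main = "ROS", ...)
  graphics::plot(x$time, x$MM, type = "l", xlab = "time (h)",
                 ylab = "MM", main = "metabolic memory", ...)
  graphics::plot(x$time, x$AD, type = "l", xlab = "time (h)",
                 ylab = "AD", main = "adaptation", ...)
  invisible(x)
}

#' Write a trajectory (or sweep) as tidy CSV
#'
#' Long format with columns `protocol`, `time_h`, `variable`, `value`,
#' suitable for external contour plotting.
#'
#' @param x A `ros_traj` or `ros_sweep` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(x, file) {
  vars <- intersect(c("GLU", "ROS", "MM", "AD", "AD_ef"), names(x))
  id <- if (!is.null(attr(x, "protocol")))
    attr(attr(x, "protocol"), "name") else as.character(x$protocol)
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(protocol = id, time_h = x$time, variable = v, value = x[[v]])))
  extra <- intersect(c("level", "amplitude", "duration_h"), names(x))
  for (e in extra) long[[e]] <- rep(x[[e]], times = length(vars))
  write.csv(long, file, row.names = FALSE)
  invisible(file)
}

#' Post-normalization quasi-steady state
#'
#' Runs the protocol, then keeps integrating under its terminal
#' normal-glucose (NG) level until the state stops moving: the criterion
#' is a maximal component-wise change over a trailing 24-h window below
#' `rel_tol`, relative with a unit floor on the denominator
#' (`|x(t) - x(t-24)| / max(|x(t)|, 1)`), so a decaying adaptation level
#' converges once it is numerically gone. A hard cap of one simulated
#' year of extra NG time applies.
#'
#' With `a_rosmm = 1` the post-normalization states form the equilibrium
#' family `(ROS, MM, AD) = (1 + M, M, 0)`, so the returned pair satisfies
#' `ros_ss = 1 + mm_ss`.
#'
#' @inheritParams simulate_protocol
#' @param window_h Trailing-window length (hours).
#' @param rel_tol Convergence threshold on the windowed change.
#' @param max_extra_h Cap on extra NG integration beyond the protocol.
#' @return List with `ros_ss`, `mm_ss`, `ad_ss`, `t_ss` (hours at which
#'   the criterion was met), and `converged` (FALSE when the cap was hit;
#'   reported via warning, distinct from a solver failure, which errors).
#' @export
post_ng_steady_state <- function(protocol, params = ros_params(),
                                 init = healthy_state(), window_h = 24,
                                 rel_tol = 1e-6, max_extra_h = 8760,
                                 rtol = 1e-8, atol = 1e-10) {
  n <- nrow(protocol)
  if (protocol$mode[n] != "constant")
    stop("protocol must end with a constant (NG) segment")
  ng_level <- protocol$level[n]
  dur <- protocol_duration(protocol)
  st <- integrate_pieces(protocol, params, check_init(init),
                         c(dur - window_h, dur), rtol, atol)
  state <- st[2, c("ROS", "MM", "AD")]
  delta <- rel_change(st[2, 1:3], st[1, 1:3])
  t_now <- dur
  chunk <- 240
  while (delta >= rel_tol && t_now < dur + max_extra_h) {
    step <- min(chunk, dur + max_extra_h - t_now)
    seg <- glucose_protocol(list(list(duration_h = step, level = ng_level)),
                            name = "ng-extension")
    st <- integrate_pieces(seg, params, state,
                           c(max(step - window_h, 0), step), rtol, atol)
    state <- st[2, c("ROS", "MM", "AD")]
    delta <- rel_change(st[2, 1:3], st[1, 1:3])
    t_now <- t_now + step
  }
  converged <- delta < rel_tol
  if (!converged)
    warning("no quasi-steady state within ", max_extra_h,
            " h of extra NG integration (last windowed change ",
            signif(delta, 3), ")")
  list(ros_ss = unname(state["ROS"]), mm_ss = unname(state["MM"]),
       ad_ss = unname(state["AD"]), t_ss = t_now, converged = converged)
}

rel_change <- function(now, before) {
  max(abs(now - before) / pmax(abs(now), 1))
}

#' Constant-glucose exposure sweep
#'
#' Simulates constant-glucose protocols across a grid of levels on a
#' shared time grid (the contour-plot raw material for CG exposures).
#'
#' @param levels Glucose levels (mM).
#' @param duration_h Exposure duration (hours); default 21 days.
#' @param params A [ros_params()] object.
#' @param times Output grid; default hourly.
#' @param ... Passed to [simulate_protocol()].
#' @return A `ros_sweep` data frame: `level`, `time`, `ROS`, `MM`, `AD`,
#'   `AD_ef`.
#' @export
sweep_cg <- function(levels = seq(9, 25, by = 1), duration_h = 21 * 24,
                     params = ros_params(), times = NULL, ...) {
  if (!length(levels)) stop("empty level grid")
  if (is.null(times)) times <- seq(0, duration_h, by = 1)
  rows <- lapply(levels, function(lv) {
    tr <- simulate_protocol(make_cg(lv, duration_h), params, times = times, ...)
    cbind(level = lv, as.data.frame(tr)[c("time", "ROS", "MM", "AD", "AD_ef")])
  })
  structure(do.call(rbind, rows), class = c("ros_sweep", "data.frame"),
            mode = "cg", axes = list(level = levels, time = times))
}

#' Exposure level x duration sweep of post-normalization steady states
#'
#' For every (glucose level, exposure duration) cell: constant exposure,
#' then normalization, then the post-NG quasi-steady state.
#'
#' @param levels Glucose levels (mM).
#' @param durations_h Exposure durations (hours).
#' @param ng_level Normalization glucose level (mM).
#' @param params A [ros_params()] object.
#' @param ... Passed to [post_ng_steady_state()].
#' @return A `ros_sweep` data frame: `level`, `duration_h`, `ros_ss`,
#'   `mm_ss`, `converged`.
#' @export
sweep_exposure <- function(levels = seq(9, 25, by = 2),
                           durations_h = c(1, 6, 24, 72, 168, 336),
                           ng_level = 5, params = ros_params(), ...) {
  if (!length(levels) || !length(durations_h)) stop("empty grid")
  grid <- expand.grid(level = levels, duration_h = durations_h)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pr <- make_cg(grid$level[i], grid$duration_h[i], ng_level = ng_level,
                  ng_duration_h = 24)
    ss <- post_ng_steady_state(pr, params, ...)
    data.frame(ros_ss = ss$ros_ss, mm_ss = ss$mm_ss, converged = ss$converged)
  })
  structure(cbind(grid, do.call(rbind, res)),
            class = c("ros_sweep", "data.frame"), mode = "exposure",
            axes = list(level = levels, duration_h = durations_h))
}

#' Oscillation-amplitude sweep (OG exposures)
#'
#' Simulates square-wave protocols across oscillation amplitudes. The
#' published description of this design is ambiguous, so both readings
#' are supported: `"fixed_max"` keeps the wave maximum at `max_level` and
#' lowers the trough as the amplitude grows (amplitude 0 is constant
#' exposure at `max_level`); `"fixed_min"` keeps the trough at
#' `min_level` and raises the peak (amplitude 0 is constant `min_level`).
#'
#' @param amplitudes Peak-to-trough amplitudes (mM).
#' @param encoding `"fixed_max"` or `"fixed_min"` (see above).
#' @param max_level,min_level The fixed end of the wave (mM).
#' @param half_period_h Square-wave half-period (hours).
#' @param duration_h Exposure duration (hours).
#' @param params A [ros_params()] object.
#' @param times Output grid; default hourly.
#' @param ... Passed to [simulate_protocol()].
#' @return A `ros_sweep` data frame: `amplitude`, `time`, `ROS`, `MM`,
#'   `AD`, `AD_ef`.
#' @export
sweep_og <- function(amplitudes = seq(0, 20, by = 2),
                     encoding = c("fixed_max", "fixed_min"),
                     max_level = 25, min_level = 5, half_period_h = 24,
                     duration_h = 21 * 24, params = ros_params(),
                     times = NULL, ...) {
  encoding <- match.arg(encoding)
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  if (is.null(times)) times <- seq(0, duration_h, by = 1)
  rows <- lapply(amplitudes, function(a) {
    pr <- if (encoding == "fixed_max") {
      if (a == 0) make_cg(max_level, duration_h)
      else make_og(max_level - a, max_level, half_period_h, duration_h)
    } else {
      if (a == 0) make_cg(min_level, duration_h)
      else make_og(min_level, min_level + a, half_period_h, duration_h)
    }
    tr <- simulate_protocol(pr, params, times = times, ...)
    cbind(amplitude = a,
          as.data.frame(tr)[c("time", "ROS", "MM", "AD", "AD_ef")])
  })
  structure(do.call(rbind, rows), class = c("ros_sweep", "data.frame"),
            mode = paste0("og-", encoding),
            axes = list(amplitude = amplitudes, time = times))
}

#' @export
print.ros_sweep <- function(x, ...) {
  ax <- attr(x, "axes")
  cat("Simulation sweep (", attr(x, "mode"), "): ",
      paste(vapply(names(ax), function(n) paste0(n, " [", length(ax[[n]]),
            "]"), ""), collapse = " x "), ", ", nrow(x), " rows\n", sep = "")
  invisible(x)
}
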