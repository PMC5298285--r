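#' Glucose exposure protocols
#'
#' A protocol is an ordered, contiguous list of segments, each either
#' `constant` (a fixed glucose level) or `oscillating` (a square wave
#' alternating between `high` and `low` every `half_period` hours,
#' starting in the HIGH phase: cells are moved into high glucose at
#' segment start). Times are hours throughout.
#'
#' @param segments List of segments; each a list with `duration_h` plus
#'   either `level` (constant) or `low`, `high`, `half_period`
#'   (oscillating). A `mode` field is inferred if absent.
#' @param name Protocol label.
#' @return An object of class `glucose_protocol`: a data frame of
#'   segments (`t_start`, `t_end`, `mode`, `level`, `low`, `high`,
#'   `half_period`) with a `name` attribute.
#' @seealso [make_cg()], [make_og()], [make_ng()], [parse_protocol()]
#' @examples
#' glucose_protocol(list(
#'   list(duration_h = 336, low = 5, high = 20, half_period = 24),
#'   list(duration_h = 1680, level = 5)), name = "og-then-ng")
#' @export
glucose_protocol <- function(segments, name = "protocol") {
  if (!length(segments)) stop("protocol needs at least one segment")
  rows <- lapply(segments, function(s) {
    dur <- s$duration_h
    if (is.null(dur) || !is.finite(dur) || dur <= 0)
      stop("every segment needs a positive duration_h")
    mode <- s$mode
    if (is.null(mode)) mode <- if (is.null(s$level)) "oscillating" else "constant"
    if (mode == "constant") {
      if (is.null(s$level) || s$level < 0) stop("constant segment needs level >= 0")
      data.frame(dur = dur, mode = "constant", level = s$level,
                 low = NA_real_, high = NA_real_, half_period = NA_real_)
    } else if (mode == "oscillating") {
      if (is.null(s$low) || is.null(s$high) || is.null(s$half_period))
        stop("oscillating segment needs low, high, half_period")
      if (s$low < 0 || s$high <= s$low) stop("need high > low >= 0")
      if (s$half_period <= 0) stop("half_period must be > 0")
      data.frame(dur = dur, mode = "oscillating", level = NA_real_,
                 low = s$low, high = s$high, half_period = s$half_period)
    } else stop("unknown segment mode: ", mode)
  })
  seg <- do.call(rbind, rows)
  seg$t_end <- cumsum(seg$dur)
  seg$t_start <- seg$t_end - seg$dur
  seg <- seg[c("t_start", "t_end", "mode", "level", "low", "high", "half_period")]
  structure(seg, class = c("glucose_protocol", "data.frame"), name = name)
}

#' @export
print.glucose_protocol <- function(x, ...) {
  cat("Glucose protocol '", attr(x, "name"), "' (", protocol_duration(x),
      " h)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    if (x$mode[i] == "constant") {
      cat(sprintf("  %6g-%6g h  constant %g mM\n", x$t_start[i], x$t_end[i],
                  x$level[i]))
    } else {
      cat(sprintf("  %6g-%6g h  oscillating %g<->%g mM, half-period %g h\n",
                  x$t_start[i], x$t_end[i], x$low[i], x$high[i],
                  x$half_period[i]))
    }
  }
  invisible(x)
}

#' Total protocol duration in hours
#' @param protocol A [glucose_protocol()].
#' @return Duration (hours).
#' @export
protocol_duration <- function(protocol) protocol$t_end[nrow(protocol)]

#' Glucose level at given times
#'
#' Evaluates the piecewise-constant driving function. Right-continuous at
#' every switch: at an oscillation flip or segment boundary the new level
#' applies. Square waves start in the HIGH phase at segment start.
#'
#' @param protocol A [glucose_protocol()].
#' @param t Times (hours), within `[0, protocol_duration(protocol)]`.
#' @return Glucose concentrations (mM), same length as `t`.
#' @export
glucose_at <- function(protocol, t) {
  dur <- protocol_duration(protocol)
  if (any(!is.finite(t)) || any(t < 0) || any(t > dur))
    stop("t outside protocol domain [0, ", dur, "]")
  idx <- findInterval(t, protocol$t_start)   # right-continuous segment lookup
  idx[t >= dur] <- nrow(protocol)
  out <- numeric(length(t))
  for (k in unique(idx)) {
    sel <- idx == k
    if (protocol$mode[k] == "constant") {
      out[sel] <- protocol$level[k]
    } else {
      phase <- floor((t[sel] - protocol$t_start[k]) / protocol$half_period[k])
      out[sel] <- ifelse(phase %% 2 == 0, protocol$high[k], protocol$low[k])
    }
  }
  out
}

#' Constant-high-glucose (CG) protocol, optionally followed by NG
#'
#' @param level Exposure glucose level (mM).
#' @param duration_h Exposure duration (hours).
#' @param ng_level Normal-glucose level of the tail segment (mM).
#' @param ng_duration_h Tail duration (hours); 0 omits the tail.
#' @return A [glucose_protocol()].
#' @examples
#' make_cg(20, 14 * 24, ng_duration_h = 70 * 24)
#' @export
make_cg <- function(level, duration_h, ng_level = 5, ng_duration_h = 0) {
  segs <- list(list(duration_h = duration_h, level = level))
  if (ng_duration_h > 0)
    segs <- c(segs, list(list(duration_h = ng_duration_h, level = ng_level)))
  glucose_protocol(segs, name = sprintf("cg-%g", level))
}

#' Oscillating-glucose (OG) protocol, optionally followed by NG
#'
#' @param low,high Square-wave glucose levels (mM), `high > low`.
#' @param half_period_h Half-period of the square wave (hours); the wave
#'   starts HIGH.
#' @param duration_h Oscillation duration (hours).
#' @inheritParams make_cg
#' @return A [glucose_protocol()].
#' @examples
#' make_og(5, 20, 24, 14 * 24, ng_duration_h = 70 * 24)
#' @export
make_og <- function(low, high, half_period_h, duration_h, ng_level = 5,
                    ng_duration_h = 0) {
  segs <- list(list(duration_h = duration_h, low = low, high = high,
                    half_period = half_period_h))
  if (ng_duration_h > 0)
    segs <- c(segs, list(list(duration_h = ng_duration_h, level = ng_level)))
  glucose_protocol(segs, name = sprintf("og-%g-%g", low, high))
}

#' Normal-glucose (NG) only protocol
#' @inheritParams make_cg
#' @export
make_ng <- function(level = 5, duration_h) {
  glucose_protocol(list(list(duration_h = duration_h, level = level)),
                   name = sprintf("ng-%g", level))
}

#' Discontinuity times of a protocol
#'
#' All interior times where the driving function may jump: segment
#' boundaries and square-wave flips. The ODE solver restarts at each so a
#' discontinuity is never stepped across.
#'
#' @param protocol A [glucose_protocol()].
#' @return Strictly increasing vector of hours in `(0, duration)`.
#' @export
switch_times <- function(protocol) {
  dur <- protocol_duration(protocol)
  ts <- numeric(0)
  for (i in seq_len(nrow(protocol))) {
    if (i > 1) ts <- c(ts, protocol$t_start[i])
    if (protocol$mode[i] == "oscillating" &&
        protocol$t_start[i] + protocol$half_period[i] <= protocol$t_end[i]) {
      flips <- seq(protocol$t_start[i] + protocol$half_period[i],
                   protocol$t_end[i], by = protocol$half_period[i])
      ts <- c(ts, flips)
    }
  }
  ts <- sort(unique(ts))
  ts[ts > 0 & ts < dur]
}

#' Parse a shorthand protocol string
#'
#' Accepts compact strings like `"cg:20mM:14d+ng:5mM:70d"` or
#' `"og:5-20mM:24h:14d+ng:5mM:70d"`: phases are joined with `+`; times
#' take `h` (hours) or `d` (days, converted to hours); `cg`/`ng` phases
#' give `level:duration`, `og` gives `low-high:half_period:duration`.
#'
#' @param spec Shorthand string.
#' @return A [glucose_protocol()].
#' @examples
#' parse_protocol("og:5-20mM:24h:14d+ng:5mM:70d")
#' @export
parse_protocol <- function(spec) {
  num_h <- function(s) {
    m <- regmatches(s, regexec("^([0-9.]+)(h|d)$", s))[[1]]
    if (length(m) != 3) stop("cannot parse time '", s, "' (want e.g. 24h, 14d)")
    as.numeric(m[2]) * if (m[3] == "d") 24 else 1
  }
  num_mm <- function(s) as.numeric(sub("mM$", "", s))
  segs <- lapply(strsplit(spec, "+", fixed = TRUE)[[1]], function(ph) {
    f <- strsplit(ph, ":", fixed = TRUE)[[1]]
    kind <- tolower(f[1])
    if (kind %in% c("cg", "ng")) {
      if (length(f) != 3) stop("phase '", ph, "' wants <cg|ng>:<level>mM:<dur>")
      list(duration_h = num_h(f[3]), level = num_mm(f[2]))
    } else if (kind == "og") {
      if (length(f) != 4) stop("phase '", ph, "' wants og:<lo>-<hi>mM:<half>:<dur>")
      lh <- as.numeric(strsplit(sub("mM$", "", f[2]), "-", fixed = TRUE)[[1]])
      list(duration_h = num_h(f[4]), low = lh[1], high = lh[2],
           half_period = num_h(f[3]))
    } else stop("unknown phase kind '", f[1], "'")
  })
  glucose_protocol(segs, name = spec)
}

#' Read a protocol (or a named protocol library) from a config file
#'
#' A protocol file (YAML or JSON) holds either a single protocol —
#' a `segments` list, each with `duration_h` or `duration_d` plus level
#' fields — or a top-level `protocols` mapping of names to such entries
#' (or shorthand strings, see [parse_protocol()]).
#'
#' @param file Path to `.yaml`/`.yml`/`.json`.
#' @return A `glucose_protocol`, or a named list of them.
#' @export
read_protocol <- function(file) {
  cfg <- read_config(file)
  if (!is.null(cfg$protocols)) {
    out <- lapply(cfg$protocols, protocol_from_entry)
    for (nm in names(out)) attr(out[[nm]], "name") <- nm
    return(out)
  }
  protocol_from_entry(cfg)
}

protocol_from_entry <- function(entry) {
  if (is.character(entry)) return(parse_protocol(entry))
  segs <- lapply(entry$segments, function(s) {
    if (!is.null(s$duration_d)) {
      s$duration_h <- 24 * s$duration_d
      s$duration_d <- NULL
    }
    s
  })
  glucose_protocol(segs, name = if (is.null(entry$name)) "protocol" else entry$name)
}
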