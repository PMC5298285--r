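# Local one-at-a-time sensitivity analysis: perturb each structural
# parameter within +/-50%, re-simulate a reference exposure protocol, and
# compare predicted ROS at three characteristic time points (early response,
# end of exposure, long after normalization).

perturbable_default <- function() {
  c("GLU_basal", "ktu_MM", "ktu_AD", "ktu_ROS", "a_rosmm", "a_gluros",
    "Fmax_ad", "EC50_ad", "Nh_ad")
}

#' Multiplicatively perturb one structural parameter
#'
#' Returns a copy of `params` with `name` scaled by `1 + fraction`. The
#' result is re-validated; where a perturbation would leave the
#' admissible region the value is clamped with a warning (`Fmax_ad` to a
#' ceiling of 0.999, `Nh_ad` to its floor of 1).
#'
#' @param params A [ros_params()] object.
#' @param name Parameter name (any structural parameter).
#' @param fraction Signed relative change, `|fraction| <= 0.5`.
#' @return A perturbed `ros_params` object.
#' @examples
#' perturb_parameter(ros_params(), "a_gluros", 0.5)$a_gluros  # 0.546
#' @export
perturb_parameter <- function(params, name, fraction) {
  stopifnot(inherits(params, "ros_params"))
  if (!name %in% names(params)) stop("unknown parameter name: ", name)
  if (!is.finite(fraction) || abs(fraction) > 0.5)
    stop("|fraction| must be <= 0.5")
  p <- unclass(params)
  p[[name]] <- p[[name]] * (1 + fraction)
  if (name == "Fmax_ad" && p[[name]] >= 1) {
    warning("Fmax_ad perturbed to ", p[[name]],
            " >= 1; clamped to ceiling 0.999")
    p[[name]] <- 0.999
  }
  if (name == "Nh_ad" && p[[name]] < 1) {
    warning("Nh_ad perturbed below 1; clamped to 1")
    p[[name]] <- 1
  }
  validate_params(p)
  structure(p, class = "ros_params")
}

#' Tornado (local sensitivity) analysis
#'
#' For each perturbable parameter and each step of the perturbation grid,
#' simulates the reference exposure protocol and records predicted ROS at
#' the characteristic time points, as absolute and relative deltas
#' against the unperturbed reference. The tornado ranking per time point
#' uses the larger absolute relative delta of the two +/-50% endpoints
#' (tornado-plot convention). Deterministic.
#'
#' Sensitivity is computed on single (fixed-effects) predictions; random
#' effects play no role here.
#'
#' @param params Reference parameters, a [ros_params()] object.
#' @param protocol `"cg"` (constant 20 mM for 2 weeks) or `"og"`
#'   (5<->20 mM square wave, 24-h half-period, 2 weeks), each followed by
#'   normal glucose through the last time point; or a custom
#'   [glucose_protocol()] covering all `timepoints_h`.
#' @param timepoints_h Characteristic time points (hours); defaults to
#'   24 h (early response), 2 weeks (end of exposure) and 12 weeks
#'   (10 weeks after normalization).
#' @param steps Positive perturbation fractions per side; the signed grid
#'   is `c(-rev(steps), steps)`. Default five uniform steps to 50%.
#' @param perturb Names of parameters to perturb. The default is every
#'   structural parameter except `ROS_basal`, which defines the
#'   observation scale.
#' @param ng_level Normalization glucose level (mM) for the built-in
#'   protocols.
#' @param ... Passed to [simulate_protocol()].
#' @return An object of class `ros_tornado`: list with `table`
#'   (parameter, fraction, direction, timepoint_h, ros, delta,
#'   rel_delta), `ranking` (per time point, parameters ordered by the
#'   endpoint metric) and `reference` (unperturbed ROS per time point).
#' @examples
#' \donttest{
#' tor <- tornado(protocol = "cg")
#' subset(tor$ranking, timepoint_h == 24)[1:2, ]
#' }
#' @export
tornado <- function(params = ros_params(), protocol = c("cg", "og"),
                    timepoints_h = c(24, 336, 2016),
                    steps = seq(0.1, 0.5, by = 0.1),
                    perturb = perturbable_default(), ng_level = 5, ...) {
  if (is.character(protocol)) {
    protocol <- match.arg(protocol)
    ng_dur <- max(timepoints_h) - 336
    protocol <- if (protocol == "cg") {
      make_cg(20, 336, ng_level = ng_level, ng_duration_h = max(ng_dur, 24))
    } else {
      make_og(5, 20, 24, 336, ng_level = ng_level,
              ng_duration_h = max(ng_dur, 24))
    }
  }
  stopifnot(inherits(protocol, "glucose_protocol"))
  if (max(timepoints_h) > protocol_duration(protocol))
    stop("protocol must extend through the last time point")
  if (any(steps < 0) || any(steps > 0.5)) stop("steps must lie in [0, 0.5]")
  unknown <- setdiff(perturb, names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))

  ros_at <- function(p) simulate_protocol(protocol, p,
                                          times = timepoints_h, ...)$ROS
  ref <- ros_at(params)
  fractions <- unique(c(-rev(steps), steps))
  rows <- list()
  for (nm in perturb) {
    for (fr in fractions) {
      p <- if (fr == 0) params else
        withCallingHandlers(perturb_parameter(params, nm, fr),
                            warning = function(w) invokeRestart("muffleWarning"))
      ros <- tryCatch(ros_at(p), error = function(e)
        stop("simulation failed for ", nm, " at ", fr * 100, "%: ",
             conditionMessage(e)))
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = nm, fraction = fr,
                   direction = if (fr >= 0) "+" else "-",
                   timepoint_h = timepoints_h, ros = ros,
                   delta = ros - ref, rel_delta = (ros - ref) / ref)
    }
  }
  tab <- do.call(rbind, rows)

  ends <- tab[abs(tab$fraction) == max(abs(fractions)) | max(abs(fractions)) == 0, ]
  agg <- aggregate(abs(ends$rel_delta),
                   by = list(parameter = ends$parameter,
                             timepoint_h = ends$timepoint_h), FUN = max)
  names(agg)[3] <- "metric"
  agg <- agg[order(agg$timepoint_h, -agg$metric), ]
  agg$rank <- unlist(lapply(split(agg$metric, agg$timepoint_h),
                            function(v) seq_along(v)), use.names = FALSE)
  agg <- do.call(rbind, lapply(split(agg, agg$timepoint_h), function(d) {
    d$rank <- seq_len(nrow(d)); d
  }))
  rownames(agg) <- NULL

  structure(list(table = tab, ranking = agg,
                 reference = data.frame(timepoint_h = timepoints_h,
                                        ros = ref),
                 protocol = protocol),
            class = "ros_tornado")
}

#' @export
print.ros_tornado <- function(x, n = 3, ...) {
  cat("Local sensitivity (tornado) over protocol '",
      attr(x$protocol, "name"), "'\n", sep = "")
  for (tp in unique(x$ranking$timepoint_h)) {
    d <- x$ranking[x$ranking$timepoint_h == tp, ][seq_len(n), ]
    cat(sprintf("  t = %5g h: %s\n", tp,
                paste(sprintf("%s (%.3f)", d$parameter, d$metric),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write a tornado result as tidy CSV
#'
#' @param x A [tornado()] result.
#' @param file Output path for the long table; the ranking is written
#'   alongside with suffix `_ranking.csv`.
#' @return `file`, invisibly.
#' @export
write_tornado <- function(x, file) {
  stopifnot(inherits(x, "ros_tornado"))
  write.csv(x$table, file, row.names = FALSE)
  write.csv(x$ranking, sub("\\.csv$", "_ranking.csv", file),
            row.names = FALSE)
  invisible(file)
}
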