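# Synthetic pooled-dataset generator: emulates the statistical structure of
# the multi-study in vitro calibration setting (mixed CG/OG/post-NG designs,
# lognormal inter-study random effects, proportional residual error) so the
# estimation layer can be exercised and validated without any external data.

#' Default study designs (synthetic calibration fixture)
#'
#' Nine invented study designs totalling 43 observation slots, frozen in
#' `extdata/calibration_designs_synthetic.json`. They span the ranges of
#' the pooled in vitro setting they stand in for: constant high glucose
#' at 15-25 mM (hours to 14 days), square-wave oscillating glucose with a
#' 24-hour half-period, and post-normalization sampling at least 7 days
#' after return to normal glucose. The real per-study designs were never
#' published; this fixture is a documented synthetic stand-in.
#'
#' @return List of designs; each has `study_id`, `protocol_id`,
#'   `protocol` (a [glucose_protocol()]), `sampling_times` (hours) and
#'   `n_replicates`.
#' @examples
#' sum(lengths(lapply(default_designs(), `[[`, "sampling_times")))  # 43
#' @export
default_designs <- function() {
  file <- system.file("extdata", "calibration_designs_synthetic.json",
                      package = "rosmm", mustWork = TRUE)
  cfg <- jsonlite::read_json(file, simplifyVector = FALSE)
  lapply(cfg$designs, function(d) {
    pr <- parse_protocol(d$protocol)
    times <- unlist(d$times_h)
    if (any(times > protocol_duration(pr)))
      stop("design ", d$id, ": sampling times outside protocol")
    list(study_id = d$id, protocol_id = d$protocol, protocol = pr,
         sampling_times = times, n_replicates = d$n_replicates)
  })
}

#' Recycle designs to a target number of studies
#'
#' Repeats a design list cyclically, assigning fresh study ids, e.g. to
#' build a 50-study parameter-recovery set from the 9 default designs.
#'
#' @param designs A list of designs as from [default_designs()].
#' @param n Target number of studies.
#' @return A list of `n` designs with ids `study01 ... studyNN`.
#' @export
replicate_designs <- function(designs, n) {
  stopifnot(n >= 1, length(designs) >= 1)
  out <- designs[rep(seq_along(designs), length.out = n)]
  for (i in seq_len(n)) out[[i]]$study_id <- sprintf("study%02d", i)
  out
}

#' Generate a synthetic pooled observation dataset
#'
#' For each study: draws study-level parameters from the population model
#' ([sample_study_parameters()]), integrates its protocol, evaluates the
#' predictions at the sampling times and applies proportional residual
#' error ([apply_residual_error()]). Deterministic under `seed`. The true
#' per-study parameters are returned separately (`truth`) so recovery
#' experiments never leak them through the fitting interface.
#'
#' @param pop A [population_model()]; defaults to the calibrated
#'   population values.
#' @param designs Study designs, see [default_designs()].
#' @param seed Integer seed.
#' @param n_studies Optionally recycle `designs` to this many studies.
#' @param rtol,atol Solver tolerances.
#' @param engine Solver engine (compiled fast path by default), see
#'   [simulate_protocol()].
#' @return An object of class `ros_synth`: list with `observations`
#'   (data frame `study_id`, `protocol_id`, `time_h`, `ros_norm`),
#'   `truth` (per-study parameters and log-deviations), `protocols`
#'   (named list resolving every `protocol_id`), `pop` and `seed`.
#' @examples
#' d <- generate_studies(seed = 1)
#' head(d$observations)
#' @export
generate_studies <- function(pop = population_model(),
                             designs = default_designs(), seed = NULL,
                             n_studies = NULL, rtol = 1e-8, atol = 1e-10,
                             engine = c("dp45", "lsoda")) {
  engine <- match.arg(engine)
  stopifnot(inherits(pop, "ros_pop"))
  if (!is.null(n_studies)) designs <- replicate_designs(designs, n_studies)
  if (!is.null(seed)) set.seed(seed)
  obs <- list(); truth <- list()
  for (d in designs) {
    p <- sample_study_parameters(pop)
    eta <- attr(p, "eta")
    times <- rep(d$sampling_times, each = d$n_replicates)
    f <- predict_observations(p, d$protocol, times, rtol, atol, engine)
    y <- apply_residual_error(f, pop$b)
    obs[[d$study_id]] <- data.frame(study_id = d$study_id,
                                    protocol_id = d$protocol_id,
                                    time_h = times, ros_norm = y)
    truth[[d$study_id]] <- data.frame(study_id = d$study_id,
                                      ktu_ROS = p$ktu_ROS,
                                      a_gluros = p$a_gluros,
                                      eta_ktu_ROS = eta[["ktu_ROS"]],
                                      eta_a_gluros = eta[["a_gluros"]])
  }
  protocols <- list()
  for (d in designs) protocols[[d$protocol_id]] <- d$protocol
  structure(list(observations = do.call(rbind, c(obs, make.row.names = FALSE)),
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 protocols = protocols, pop = pop, seed = seed),
            class = "ros_synth")
}

#' @export
print.ros_synth <- function(x, ...) {
  cat("Synthetic pooled dataset:", length(unique(x$observations$study_id)),
      "studies,", nrow(x$observations), "observations",
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `observations.csv`, `truth.csv` (kept separate so fitting code
#' cannot see the generating parameters) and `protocols.json` (shorthand
#' protocol library resolving each `protocol_id`).
#'
#' @param x A [generate_studies()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(x, dir) {
  stopifnot(inherits(x, "ros_synth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$observations, file.path(dir, "observations.csv"),
            row.names = FALSE)
  write.csv(x$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(list(protocols = as.list(names(x$protocols))),
                       file.path(dir, "protocols.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Normalize raw ROS measurements by their normoglycemic control
#'
#' The model works on the control-normalized scale; this helper ingests
#' externally supplied raw measurements.
#'
#' @param raw Raw measurement(s).
#' @param control Control (normoglycemia) value, `> 0`.
#' @return `raw / control`, preserving length and order.
#' @export
normalize_to_control <- function(raw, control) {
  if (length(control) != 1L || !is.finite(control) || control <= 0)
    stop("control must be a single positive value")
  raw / control
}
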