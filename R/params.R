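#' Structural model parameters
#'
#' Constructs the parameter set of the glucose / ROS / metabolic-memory /
#' adaptation system. Defaults are the calibrated population values for
#' pooled HUVEC (human umbilical vein endothelial cell) in vitro data.
#'
#' The model tracks three coupled quantities: `ROS`, a normalized ROS
#' production potential (fold of normoglycemic control); `MM`, metabolic
#' memory, the persistent ROS-driven cell alteration; and `AD`, a lumped
#' cellular adaptation variable triggered by glucose excess that inhibits
#' ROS synthesis through a Hill function.
#'
#' @param GLU_basal Highest glucose level (mM) that does not drive the
#'   system: glucose excess is `max(GLU - GLU_basal, 0)`.
#' @param ROS_basal Basal normalized ROS level; ROS excess is
#'   `max(ROS - ROS_basal, 0)`.
#' @param ktu_MM Metabolic-memory turnover constant (1/hour). The default
#'   derives from a 4-day mitochondrial protein half-life,
#'   `log(2)/96`, reported rounded to 0.007.
#' @param ktu_AD Adaptation turnover constant (1/hour).
#' @param ktu_ROS ROS turnover constant (1/hour). Also known under the
#'   alias `kel_ROS` (elimination-rate notation); the two names denote the
#'   same parameter and `kel_ROS` is accepted by [read_params()].
#' @param a_rosmm Gain of ROS excess on metabolic-memory synthesis
#'   (dimensionless). `a_rosmm = 1` holds post-normalization ROS at a
#'   quasi-steady state; `a_rosmm < 1` lets the system decay back to
#'   baseline; `a_rosmm > 1` amplifies.
#' @param a_gluros Gain of glucose excess on ROS synthesis (1/mM).
#' @param Fmax_ad Maximal fractional inhibition of ROS synthesis by
#'   adaptation, in `[0, 1)`.
#' @param EC50_ad Adaptation level giving half-maximal inhibition
#'   (in AD units, i.e. mM of glucose excess at equilibrium).
#' @param Nh_ad Hill coefficient of the adaptation effect (>= 1).
#'
#' @return An object of class `ros_params`: a validated named list.
#' @examples
#' p <- ros_params()
#' p$ktu_ROS
#' adaptation_effect(c(0, p$EC50_ad, 11), p)
#' @export
ros_params <- function(GLU_basal = 9, ROS_basal = 1, ktu_MM = 0.007,
                       ktu_AD = 0.00714, ktu_ROS = 0.0316, a_rosmm = 1,
                       a_gluros = 0.364, Fmax_ad = 0.8, EC50_ad = 6.142,
                       Nh_ad = 5) {
  p <- list(GLU_basal = GLU_basal, ROS_basal = ROS_basal, ktu_MM = ktu_MM,
            ktu_AD = ktu_AD, ktu_ROS = ktu_ROS, a_rosmm = a_rosmm,
            a_gluros = a_gluros, Fmax_ad = Fmax_ad, EC50_ad = EC50_ad,
            Nh_ad = Nh_ad)
  validate_params(p)
  structure(p, class = "ros_params")
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p))
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar")
  if (p$ktu_MM <= 0 || p$ktu_AD <= 0 || p$ktu_ROS <= 0 || p$EC50_ad <= 0)
    stop("turnover constants and EC50_ad must be strictly positive")
  if (p$Fmax_ad < 0 || p$Fmax_ad >= 1)
    stop("Fmax_ad must lie in [0, 1)")
  if (p$Nh_ad < 1) stop("Nh_ad must be >= 1")
  if (p$a_gluros < 0 || p$a_rosmm < 0)
    stop("gains a_gluros and a_rosmm must be non-negative")
  if (p$GLU_basal < 0 || p$ROS_basal < 0)
    stop("basal levels must be non-negative")
  invisible(p)
}

#' @export
print.ros_params <- function(x, ...) {
  cat("Structural parameters (glucose/ROS/metabolic-memory model)\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 10), " ", format(v)), sep = "\n")
  invisible(x)
}

# deSolve parameter vector for one constant-glucose segment
pack_params <- function(p, glu) {
  c(p$GLU_basal, p$ROS_basal, p$ktu_MM, p$ktu_AD, p$ktu_ROS,
    p$a_rosmm, p$a_gluros, p$Fmax_ad, p$EC50_ad, p$Nh_ad, glu)
}

#' Healthy initial state
#'
#' The reference initial condition: normalized ROS at its control value of
#' 1, with no accumulated metabolic memory and no adaptation (the healthy
#' state neither stimulates metabolic memory nor adaptive processes).
#'
#' @return Named numeric vector `c(ROS = 1, MM = 0, AD = 0)`.
#' @export
healthy_state <- function() c(ROS = 1, MM = 0, AD = 0)

#' Positive-part glucose excess
#'
#' @param GLU Glucose concentration (mM), vectorized.
#' @param params A [ros_params()] object.
#' @return `max(GLU - GLU_basal, 0)` elementwise (mM).
#' @export
glucose_excess <- function(GLU, params = ros_params()) {
  if (any(!is.finite(GLU)) || any(GLU < 0))
    stop("GLU must be finite and non-negative")
  pmax(GLU - params$GLU_basal, 0)
}

#' Positive-part ROS excess
#'
#' @param ROS Normalized ROS level, vectorized.
#' @inheritParams glucose_excess
#' @return `max(ROS - ROS_basal, 0)` elementwise.
#' @export
ros_excess <- function(ROS, params = ros_params()) {
  if (any(!is.finite(ROS)) || any(ROS < 0))
    stop("ROS must be finite and non-negative")
  pmax(ROS - params$ROS_basal, 0)
}

#' Effective adaptation inhibition of ROS synthesis
#'
#' Hill-type negative feedback: `AD_ef = 1 - Fmax_ad * AD^Nh /
#' (AD^Nh + EC50_ad^Nh)`. Equals 1 with no adaptation and saturates at
#' `1 - Fmax_ad`; `AD^Nh` at `AD = 0` is taken as 0 (`Nh >= 1`).
#'
#' @param AD Adaptation level (>= 0), vectorized.
#' @inheritParams glucose_excess
#' @return `AD_ef` values in `[1 - Fmax_ad, 1]`.
#' @export
adaptation_effect <- function(AD, params = ros_params()) {
  if (any(!is.finite(AD)) || any(AD < 0)) stop("AD must be finite and >= 0")
  hill <- ifelse(AD > 0, AD^params$Nh_ad, 0)
  1 - params$Fmax_ad * hill / (hill + params$EC50_ad^params$Nh_ad)
}

#' Model right-hand side (reference R implementation)
#'
#' Time derivatives of `(ROS, MM, AD)` at a given state and glucose level:
#' \deqn{dMM/dt = ktu_{MM} (a_{rosmm} ROS_{excess} - MM)}
#' \deqn{dAD/dt = ktu_{AD} (GLU_{excess} - AD)}
#' \deqn{dROS/dt = ktu_{ROS} ((1 + (a_{gluros} GLU_{excess} + MM) AD_{ef}) - ROS)}
#' The solver uses an equivalent compiled version of this function; this
#' one is exported as the readable reference and for spot checks.
#'
#' @param state Named numeric vector with components `ROS`, `MM`, `AD`.
#' @param GLU Glucose concentration (mM).
#' @inheritParams glucose_excess
#' @return Named vector of derivatives `(dROS, dMM, dAD)` per hour.
#' @examples
#' ros_rhs(healthy_state(), GLU = 5)   # normoglycemic fixed point: all zero
#' @export
ros_rhs <- function(state, GLU, params = ros_params()) {
  if (any(!is.finite(state))) stop("state components must be finite")
  ROS <- state[["ROS"]]; MM <- state[["MM"]]; AD <- state[["AD"]]
  if (MM < 0 || AD < 0 || ROS < 0) stop("state components must be non-negative")
  ge <- glucose_excess(GLU, params)
  re <- ros_excess(ROS, params)
  ad_ef <- adaptation_effect(AD, params)
  c(dROS = params$ktu_ROS * ((1 + (ge * params$a_gluros + MM) * ad_ef) - ROS),
    dMM = params$ktu_MM * (re * params$a_rosmm - MM),
    dAD = params$ktu_AD * (ge - AD))
}

#' Closed-form adaptation relaxation on a constant-glucose segment
#'
#' The AD equation is linear when glucose (hence glucose excess `GE`) is
#' constant, with exact solution `GE + (AD0 - GE) * exp(-ktu_AD * t)`.
#' Used as an integration oracle for the numeric solver.
#'
#' @param t Time since segment start (hours, >= 0), vectorized.
#' @param GE Glucose excess of the segment (mM).
#' @param AD0 Adaptation level at segment start.
#' @inheritParams glucose_excess
#' @return AD level at time `t`.
#' @export
ad_relax <- function(t, GE, AD0 = 0, params = ros_params()) {
  if (any(t < 0)) stop("t must be >= 0")
  GE + (AD0 - GE) * exp(-params$ktu_AD * t)
}

#' Memory gain consistent with a target post-normalization steady state
#'
#' The gain `a_rosmm` controls what happens after glucose normalization.
#' For the post-normalization ROS level to settle at `ROS_ss`, the gain
#' must equal `(ROS_ss - 1) / (ROS_ss - ROS_basal)`; with the basal level
#' fixed at 1 this is 1 for every admissible target, which is why the
#' calibrated model uses `a_rosmm = 1` (metabolic memory held constant).
#'
#' @param ROS_ss Target steady-state ROS after normalization; must exceed
#'   both 1 and `ROS_basal`.
#' @inheritParams glucose_excess
#' @return The implied `a_rosmm` value.
#' @export
a_rosmm_from_target <- function(ROS_ss, params = ros_params()) {
  if (any(ROS_ss <= params$ROS_basal) || any(ROS_ss <= 1))
    stop("ROS_ss must exceed max(1, ROS_basal)")
  (ROS_ss - 1) / (ROS_ss - params$ROS_basal)
}

#' Read / write structural parameters as flat key-value config
#'
#' Serializes a [ros_params()] object to YAML or JSON (chosen by file
#' extension) with keys named exactly as the parameter symbols
#' (`ktu_MM`, `a_gluros`, `EC50_ad`, ...). On read, the alias `kel_ROS`
#' is accepted for `ktu_ROS`; missing keys fall back to defaults.
#'
#' @param file Path ending in `.yaml`/`.yml` or `.json`.
#' @param params A `ros_params` object.
#' @return `read_params()` returns a `ros_params` object;
#'   `write_params()` returns `file` invisibly.
#' @export
read_params <- function(file) {
  vals <- read_config(file)
  if (!is.null(vals$kel_ROS) && is.null(vals$ktu_ROS)) {
    vals$ktu_ROS <- vals$kel_ROS
  }
  vals$kel_ROS <- NULL
  known <- names(formals(ros_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  do.call(ros_params, vals)
}

#' @rdname read_params
#' @export
write_params <- function(params, file) {
  stopifnot(inherits(params, "ros_params"))
  write_config(unclass(params), file)
  invisible(file)
}

read_config <- function(file) {
  if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    yaml::read_yaml(file)
  } else if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else stop("config file must be .yaml/.yml or .json: ", file)
}

write_config <- function(x, file) {
  if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    yaml::write_yaml(x, file)
  } else if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else stop("config file must be .yaml/.yml or .json: ", file)
}
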