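# Nonlinear mixed-effects layer: lognormal inter-study random effects on
# ktu_ROS and a_gluros, proportional residual error, marginal likelihood by
# Laplace approximation or adaptive Gauss-Hermite quadrature centred at the
# per-study posterior mode.

#' Population (mixed-effects) model
#'
#' Fixed-effect structural parameters plus inter-study variability:
#' per-study parameters are `ktu_ROS * exp(eta1)` and
#' `a_gluros * exp(eta2)` with independent `eta_i ~ N(0, omega_i^2)`
#' (lognormal random effects, the convention of standard NLME estimation
#' software), and observations carry proportional residual error
#' `y = f * (1 + b * e)`, `e ~ N(0, 1)`.
#'
#' The published inter-study variability values are interpreted as
#' standard deviations of the log-scale random effects (their printed
#' rate/gain units are a table artifact); set `omega_scale = "var"` to
#' supply variances instead.
#'
#' @param params Fixed effects, a [ros_params()] object.
#' @param omega_ktu_ROS,omega_a_gluros Random-effect scales (log-scale
#'   SDs by default), `>= 0`; 0 switches a random effect off.
#' @param b Proportional residual error coefficient, in `(0, 1)`.
#' @param omega_scale `"sd"` (default) or `"var"`: how the omega
#'   arguments are to be read.
#' @return An object of class `ros_pop`.
#' @examples
#' population_model()          # the calibrated population parameter set
#' @export
population_model <- function(params = ros_params(), omega_ktu_ROS = 1.145,
                             omega_a_gluros = 0.936, b = 0.09932,
                             omega_scale = c("sd", "var")) {
  omega_scale <- match.arg(omega_scale)
  validate_params(params)
  if (omega_ktu_ROS < 0 || omega_a_gluros < 0) stop("omegas must be >= 0")
  if (b <= 0 || b >= 1) stop("b must lie in (0, 1)")
  if (omega_scale == "var") {
    omega_ktu_ROS <- sqrt(omega_ktu_ROS)
    omega_a_gluros <- sqrt(omega_a_gluros)
  }
  structure(list(params = params, omega_ktu_ROS = omega_ktu_ROS,
                 omega_a_gluros = omega_a_gluros, b = b),
            class = "ros_pop")
}

#' @export
print.ros_pop <- function(x, ...) {
  cat("Population model\n  fixed effects:\n")
  v <- unlist(x$params)
  cat(paste0("    ", format(names(v), width = 10), " ", format(v)), sep = "\n")
  cat(sprintf("  omega(ktu_ROS) %g, omega(a_gluros) %g  (log-scale SD)\n",
              x$omega_ktu_ROS, x$omega_a_gluros))
  cat(sprintf("  proportional error b = %g\n", x$b))
  invisible(x)
}

#' Draw study-level parameters from the population model
#'
#' Multiplies `ktu_ROS` and `a_gluros` of the fixed effects by
#' independent lognormal factors `exp(eta)`, `eta ~ N(0, omega^2)`. All
#' other parameters are shared across studies.
#'
#' @param pop A [population_model()].
#' @param n Number of studies to draw.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return For `n = 1` a [ros_params()] object with an `"eta"` attribute
#'   (the drawn log-scale deviations); for `n > 1` a list of such.
#' @export
sample_study_parameters <- function(pop, n = 1, seed = NULL) {
  stopifnot(inherits(pop, "ros_pop"))
  if (!is.null(seed)) set.seed(seed)
  draws <- lapply(seq_len(n), function(i) {
    eta <- c(ktu_ROS = rnorm(1, 0, pop$omega_ktu_ROS),
             a_gluros = rnorm(1, 0, pop$omega_a_gluros))
    p <- study_params(pop$params, eta)
    attr(p, "eta") <- eta
    p
  })
  if (n == 1) draws[[1]] else draws
}

study_params <- function(theta, eta) {
  p <- unclass(theta)
  p$ktu_ROS <- p$ktu_ROS * exp(eta[[1]])
  p$a_gluros <- p$a_gluros * exp(eta[[2]])
  structure(p, class = "ros_params")
}

#' Model-predicted observations
#'
#' The ROS component of the trajectory at the requested sampling times:
#' the structural prediction `f` entering the observation model.
#'
#' @param params A [ros_params()] object (study-level or population).
#' @param protocol A [glucose_protocol()].
#' @param times Sampling times (hours) within the protocol domain.
#' @param rtol,atol Solver tolerances.
#' @param engine Solver engine, see [simulate_protocol()].
#' @return Numeric vector of predicted normalized ROS, one per time.
#' @export
predict_observations <- function(params, protocol, times,
                                 rtol = 1e-8, atol = 1e-10,
                                 engine = c("lsoda", "dp45")) {
  ord <- order(times)
  tt <- times[ord]
  st <- integrate_pieces(protocol, params, healthy_state(), tt, rtol, atol,
                         engine = match.arg(engine))
  out <- numeric(length(times))
  out[ord] <- st[, "ROS"]
  out
}

#' Apply proportional residual error
#'
#' `y = f * (1 + b * e)` with `e ~ N(0, 1)`. Non-positive draws (vanishing
#' probability at `b` near 0.1) are resampled so measurements stay
#' positive.
#'
#' @param f Positive predictions.
#' @param b Proportional error coefficient (`b = 0` returns `f` exactly).
#' @param seed Optional seed.
#' @return Noisy observations, same length as `f`.
#' @export
apply_residual_error <- function(f, b, seed = NULL) {
  if (any(f <= 0)) stop("predictions must be positive")
  if (b < 0) stop("b must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  y <- f * (1 + b * rnorm(length(f)))
  while (any(bad <- y <= 0))
    y[bad] <- f[bad] * (1 + b * rnorm(sum(bad)))
  y
}

# ---- marginal likelihood ---------------------------------------------------

check_observation_table <- function(data, protocols) {
  need <- c("study_id", "protocol_id", "time_h", "ros_norm")
  if (!all(need %in% names(data)))
    stop("observation table needs columns: ", paste(need, collapse = ", "))
  if (any(data$ros_norm <= 0)) stop("ros_norm must be positive")
  miss <- setdiff(unique(data$protocol_id), names(protocols))
  if (length(miss))
    stop("unresolvable protocol_id(s): ", paste(miss, collapse = ", "))
  for (sid in unique(data$study_id)) {
    rows <- data[data$study_id == sid, ]
    pr <- protocols[[as.character(rows$protocol_id[1])]]
    if (length(unique(rows$protocol_id)) != 1L)
      stop("study ", sid, " refers to more than one protocol")
    if (any(rows$time_h < 0) || any(rows$time_h > protocol_duration(pr)))
      stop("study ", sid, ": times outside protocol domain")
  }
  invisible(data)
}

# per-study bookkeeping reused across likelihood evaluations
study_blocks <- function(data, protocols) {
  ids <- unique(data$study_id)
  lapply(ids, function(sid) {
    rows <- data[data$study_id == sid, , drop = FALSE]
    pr <- protocols[[as.character(rows$protocol_id[1])]]
    ord <- order(rows$time_h)
    list(study_id = sid, protocol = pr, pieces = protocol_pieces(pr),
         times = rows$time_h[ord], y = rows$ros_norm[ord])
  })
}

# negative joint log density of (y, eta) for one study; eta over active dims
study_joint_nll <- function(eta_active, active, theta, blk, b, omegas,
                            rtol, atol, engine = "dp45") {
  eta <- c(0, 0)
  eta[active] <- eta_active
  p <- study_params(theta, eta)
  f <- integrate_pieces(blk$protocol, p, healthy_state(), blk$times,
                        rtol, atol, pieces = blk$pieces,
                        engine = engine)[, "ROS"]
  ll <- sum(dnorm(blk$y, mean = f, sd = b * f, log = TRUE))
  if (length(active))
    ll <- ll + sum(dnorm(eta[active], 0, omegas[active], log = TRUE))
  -ll
}

# log marginal likelihood of one study: Laplace (nodes = 1) or adaptive
# Gauss-Hermite on a tensor grid centred at the posterior mode of eta
study_log_marginal <- function(theta, blk, b, omegas, nodes, rtol, atol,
                               start = NULL, engine = "dp45") {
  active <- which(omegas > 0)
  d <- length(active)
  # far-tail eta (e.g. +6 SD on a log-scale omega above 1) can make the
  # system too stiff to integrate; such points carry no likelihood mass,
  # so a solver failure maps to a huge joint nll (zero contribution)
  fn <- function(e) tryCatch(
    study_joint_nll(e, active, theta, blk, b, omegas, rtol, atol, engine),
    error = function(err) 1e10)
  if (d == 0L)
    return(list(logL = -fn(numeric(0)), mode = c(0, 0)))
  if (is.null(start)) start <- rep(0, d)
  opt <- nlminb(start, fn, control = list(rel.tol = 1e-9))
  mode <- opt$par
  # FD step wide enough that solver-level noise (~1e-9) cannot dominate
  # the curvature estimate
  H <- optimHess(mode, fn, control = list(ndeps = rep(5e-3, d)))
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) H <- diag(1 / omegas[active]^2, d)  # prior curvature fallback
  if (nodes <= 1L) {
    logL <- -opt$objective + (d / 2) * log(2 * pi) -
      0.5 * determinant(H, logarithm = TRUE)$modulus
  } else {
    gh <- pracma::gaussHermite(nodes)
    R <- chol(H)
    Cinv <- backsolve(R, diag(d))          # Cinv %*% t(Cinv) = H^{-1}
    grid <- as.matrix(expand.grid(rep(list(seq_len(nodes)), d)))
    terms <- apply(grid, 1, function(idx) {
      z <- gh$x[idx]
      e <- mode + sqrt(2) * drop(Cinv %*% z)
      sum(log(gh$w[idx])) + sum(z^2) - fn(e)
    })
    m <- max(terms)
    logL <- (d / 2) * log(2) -
      0.5 * determinant(H, logarithm = TRUE)$modulus +
      m + log(sum(exp(terms - m)))
  }
  eta_mode <- c(0, 0)
  eta_mode[active] <- mode
  list(logL = as.numeric(logL), mode = eta_mode)
}

#' Marginal log-likelihood of a population model
#'
#' Integrates the per-study random effects out of the joint density by
#' Laplace approximation (`nodes = 1`, the default) or adaptive
#' Gauss-Hermite quadrature (`nodes > 1`, a tensor grid centred and
#' scaled at the per-study posterior mode). With both omegas zero the
#' result collapses exactly to the fixed-effects likelihood (the product
#' of proportional-error normal densities). Deterministic given the
#' configuration.
#'
#' @param pop A [population_model()].
#' @param data Observation table: data frame with columns `study_id`,
#'   `protocol_id`, `time_h`, `ros_norm`.
#' @param protocols Named list of [glucose_protocol()] objects resolving
#'   every `protocol_id`.
#' @param nodes Gauss-Hermite nodes per random-effect dimension
#'   (1 = Laplace).
#' @param rtol,atol Solver tolerances.
#' @param engine Solver engine; the compiled `"dp45"` fast path is the
#'   default here (see [simulate_protocol()]).
#' @return Scalar log-likelihood with attribute `"modes"` (per-study
#'   empirical-Bayes eta modes).
#' @export
loglik_population <- function(pop, data, protocols, nodes = 1,
                              rtol = 1e-8, atol = 1e-10,
                              engine = c("dp45", "lsoda")) {
  engine <- match.arg(engine)
  stopifnot(inherits(pop, "ros_pop"))
  check_observation_table(data, protocols)
  blocks <- study_blocks(data, protocols)
  omegas <- c(pop$omega_ktu_ROS, pop$omega_a_gluros)
  total <- 0
  modes <- matrix(0, length(blocks), 2,
                  dimnames = list(vapply(blocks, `[[`, "", "study_id"),
                                  c("eta_ktu_ROS", "eta_a_gluros")))
  for (i in seq_along(blocks)) {
    res <- study_log_marginal(pop$params, blocks[[i]], pop$b, omegas,
                              nodes, rtol, atol, engine = engine)
    total <- total + res$logL
    modes[i, ] <- res$mode
  }
  structure(total, modes = modes)
}

# ---- fitting ---------------------------------------------------------------

#' Fit the population model to pooled multi-study ROS data
#'
#' Maximizes the marginal likelihood over the free fixed effects
#' (`ktu_ROS`, `ktu_AD`, `a_gluros`, `EC50_ad` by default, matching the
#' calibration layout: `GLU_basal`, `ROS_basal`, `ktu_MM`, `a_rosmm`,
#' `Fmax_ad` and `Nh_ad` stay fixed), the two random-effect scales and
#' the residual coefficient `b`. All free parameters are optimized on
#' the log scale with box constraints; per-study posterior modes are
#' warm-started across objective evaluations.
#'
#' Relative standard errors come from the observed information
#' (finite-difference Hessian of the marginal log-likelihood at the
#' optimum, on the log scale, so `RSE% ~ 100 * SE(log parameter)`); see
#' [rse_bootstrap()] for a seeded nonparametric bootstrap alternative
#' when the Hessian is ill-conditioned.
#'
#' @inheritParams loglik_population
#' @param start A [population_model()] supplying initial values (and the
#'   values of the non-estimated parameters).
#' @param estimate Names of the free fixed effects.
#' @param nodes Gauss-Hermite nodes per dimension for the likelihood
#'   (1 = Laplace, the default).
#' @param control Passed to [stats::nlminb()] (merged over sensible
#'   defaults).
#' @param engine Solver engine (compiled fast path by default), see
#'   [simulate_protocol()].
#' @param restarts Number of additional seeded random initial points
#'   (log-scale Gaussian jitter, SD 0.5, around `start`); the best
#'   optimum is kept. 0 fits once from `start`.
#' @param restart_seed Seed for the restart jitter.
#' @param polish Follow the first-stage optimizer with a quasi-Newton
#'   polish using wide-step central-difference gradients (recommended;
#'   see Details).
#' @param compute_rse Set `FALSE` to skip the Hessian (faster).
#' @return An object of class `ros_fit` with methods `print`, `summary`,
#'   `coef`, `logLik`, `vcov`, `predict`, `residuals`, `simulate` and
#'   `plot`. Fields include the fitted [population_model()] (`pop`),
#'   `rse` (%), `loglik`, `aic`, `convergence` and per-study
#'   empirical-Bayes modes (`eb`).
#' @export
ros_fit <- function(data, protocols, start = population_model(),
                    estimate = c("ktu_ROS", "ktu_AD", "a_gluros", "EC50_ad"),
                    nodes = 1, control = list(), rtol = 1e-8, atol = 1e-10,
                    engine = c("dp45", "lsoda"), restarts = 0,
                    restart_seed = 1, polish = TRUE, compute_rse = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(start, "ros_pop"))
  check_observation_table(data, protocols)
  if (length(unique(data$study_id)) < 2L)
    stop("need at least 2 studies to separate inter-study variability")
  bad <- setdiff(estimate, c("ktu_ROS", "ktu_AD", "ktu_MM", "a_gluros",
                             "a_rosmm", "EC50_ad", "Fmax_ad", "Nh_ad"))
  if (length(bad)) stop("cannot estimate: ", paste(bad, collapse = ", "))
  blocks <- study_blocks(data, protocols)
  nstud <- length(blocks)

  par0 <- c(log(unlist(start$params[estimate])),
            log(pmax(c(start$omega_ktu_ROS, start$omega_a_gluros), 1e-3)),
            log(start$b))
  names(par0) <- c(estimate, "omega_ktu_ROS", "omega_a_gluros", "b")
  k <- length(par0)
  lower <- rep(-12, k); upper <- rep(12, k)
  upper[k] <- log(0.9)                       # b < 1
  lower[(k - 2):(k - 1)] <- log(1e-4)        # omega boundary

  unpack <- function(par) {
    th <- start$params
    for (nm in estimate) th[[nm]] <- exp(par[[nm]])
    list(theta = th,
         omegas = exp(c(par[["omega_ktu_ROS"]], par[["omega_a_gluros"]])),
         b = exp(par[["b"]]))
  }
  # deterministic objective: the inner (eta) optimization always starts at 0,
  # so finite-difference gradients of the outer optimizer stay consistent
  eval_marginal <- function(par) {
    pp <- unpack(par)
    total <- 0
    modes <- matrix(0, nstud, 2)
    for (i in seq_len(nstud)) {
      res <- try(study_log_marginal(pp$theta, blocks[[i]], pp$b, pp$omegas,
                                    nodes, rtol, atol, engine = engine),
                 silent = TRUE)
      if (inherits(res, "try-error"))
        return(list(nll = 1e10, modes = modes))
      modes[i, ] <- res$mode
      total <- total + res$logL
    }
    list(nll = -total, modes = modes)
  }
  nll <- function(par) eval_marginal(par)$nll

  ctl <- modifyList(list(rel.tol = 1e-8, iter.max = 300, eval.max = 600),
                    control)
  run_one <- function(p0) nlminb(p0, nll, lower = lower, upper = upper,
                                 control = ctl)
  opt <- run_one(par0)
  if (restarts > 0) {                        # seeded random multistart
    set.seed(restart_seed)
    for (r in seq_len(restarts)) {
      p0 <- par0 + rnorm(k, 0, 0.5)
      p0 <- pmin(pmax(p0, lower), upper)
      cand <- try(run_one(p0), silent = TRUE)
      if (!inherits(cand, "try-error") && cand$objective < opt$objective)
        opt <- cand
    }
  }
  if (polish) {
    # derivative-free polish: the Laplace objective carries small-scale
    # jaggedness (inner eta modes switching basins) that can stall
    # gradient-based search short of the optimum; a Nelder-Mead stage
    # walks through it reliably
    pol <- try(optim(opt$par, nll, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-9)),
               silent = TRUE)
    if (!inherits(pol, "try-error") && pol$value < opt$objective) {
      pp <- pmin(pmax(pol$par, lower), upper)
      opt <- list(par = setNames(pp, names(par0)), objective = pol$value,
                  convergence = 0, message = "polished (Nelder-Mead)",
                  iterations = opt$iterations, evaluations = opt$evaluations)
    }
  }
  final <- eval_marginal(opt$par)
  warm <- final$modes
  loglik <- -opt$objective
  aic <- 2 * k - 2 * loglik

  est <- exp(opt$par)
  boundary <- est[c("omega_ktu_ROS", "omega_a_gluros")] < 2e-4
  if (any(boundary))
    warning("omega estimate(s) at the boundary (inter-study variability ",
            "indistinguishable from 0): ",
            paste(names(boundary)[boundary], collapse = ", "))
  if (opt$convergence != 0)
    warning("optimizer did not report clean convergence: ", opt$message)

  rse <- setNames(rep(NA_real_, k), names(par0))
  vc <- NULL
  if (compute_rse) {
    # wide FD step: the marginal objective carries ~1e-3 numerical noise
    # from its nested optimizations, which a small step would amplify
    H <- try(optimHess(opt$par, nll, control = list(ndeps = rep(2e-2, k))),
             silent = TRUE)
    if (!inherits(H, "try-error")) {
      H <- (H + t(H)) / 2
      vc <- try(solve(H), silent = TRUE)
      if (!inherits(vc, "try-error") && all(diag(vc) > 0)) {
        rse <- 100 * sqrt(diag(vc))          # SE of log-parameter = CV
        names(rse) <- names(par0)
      } else {
        vc <- NULL
        warning("observed information ill-conditioned; RSEs unavailable ",
                "(consider rse_bootstrap())")
      }
    }
  }

  pp <- unpack(opt$par)
  pop_hat <- population_model(pp$theta, pp$omegas[1], pp$omegas[2], pp$b)
  eb <- data.frame(study_id = vapply(blocks, `[[`, "", "study_id"),
                   eta_ktu_ROS = warm[, 1], eta_a_gluros = warm[, 2])
  eb$ktu_ROS <- pp$theta$ktu_ROS * exp(eb$eta_ktu_ROS)
  eb$a_gluros <- pp$theta$a_gluros * exp(eb$eta_a_gluros)

  structure(list(pop = pop_hat, estimate = estimate, rse = rse,
                 loglik = loglik, aic = aic, vcov = vc,
                 convergence = list(code = opt$convergence,
                                    message = opt$message,
                                    iterations = opt$iterations,
                                    evaluations = opt$evaluations,
                                    boundary = boundary),
                 eb = eb, data = data, protocols = protocols,
                 settings = list(nodes = nodes, rtol = rtol, atol = atol,
                                 engine = engine, start = start,
                                 control = ctl, restarts = restarts,
                                 restart_seed = restart_seed),
                 par = opt$par, call = match.call()),
            class = "ros_fit")
}

#' @export
print.ros_fit <- function(x, ...) {
  cat("Population fit:", length(unique(x$data$study_id)), "studies,",
      nrow(x$data), "observations\n")
  print(signif(coef(x), 5))
  cat(sprintf("logLik %.3f, AIC %.3f\n", x$loglik, x$aic))
  invisible(x)
}

#' @export
coef.ros_fit <- function(object, ...) {
  p <- object$pop
  c(unlist(p$params[object$estimate]),
    omega_ktu_ROS = p$omega_ktu_ROS, omega_a_gluros = p$omega_a_gluros,
    b = p$b)
}

#' @export
logLik.ros_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par), nobs = nrow(object$data),
            class = "logLik")
}

#' @export
vcov.ros_fit <- function(object, ...) object$vcov

#' @export
summary.ros_fit <- function(object, ...) {
  tab <- data.frame(estimate = coef(object), rse_pct = object$rse)
  structure(list(table = tab, loglik = object$loglik, aic = object$aic,
                 convergence = object$convergence,
                 n_studies = length(unique(object$data$study_id)),
                 n_obs = nrow(object$data)),
            class = "summary.ros_fit")
}

#' @export
print.summary.ros_fit <- function(x, ...) {
  cat("Population model fit (", x$n_studies, " studies, ", x$n_obs,
      " observations)\n", sep = "")
  print(signif(as.matrix(x$table), 5))
  cat(sprintf("logLik %.3f   AIC %.3f   convergence code %d (%s)\n",
              x$loglik, x$aic, x$convergence$code, x$convergence$message))
  invisible(x)
}

#' @export
predict.ros_fit <- function(object, newdata = NULL,
                            type = c("population", "individual"), ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  check_observation_table(data, object$protocols)
  eb <- object$eb
  out <- numeric(nrow(data))
  for (sid in unique(data$study_id)) {
    sel <- data$study_id == sid
    pr <- object$protocols[[as.character(data$protocol_id[sel][1])]]
    p <- object$pop$params
    if (type == "individual") {
      row <- match(as.character(sid), as.character(eb$study_id))
      if (!is.na(row))
        p <- study_params(p, c(eb$eta_ktu_ROS[row], eb$eta_a_gluros[row]))
    }
    out[sel] <- predict_observations(p, pr, data$time_h[sel],
                                     object$settings$rtol,
                                     object$settings$atol)
  }
  out
}

#' @export
residuals.ros_fit <- function(object, type = c("individual", "population"),
                              ...) {
  type <- match.arg(type)
  f <- predict(object, type = type)
  (object$data$ros_norm - f) / (object$pop$b * f)   # weighted residuals
}

#' @export
simulate.ros_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    out <- object$data
    for (sid in unique(out$study_id)) {
      sel <- out$study_id == sid
      pr <- object$protocols[[as.character(out$protocol_id[sel][1])]]
      p <- sample_study_parameters(object$pop)
      f <- predict_observations(p, pr, out$time_h[sel],
                                object$settings$rtol, object$settings$atol)
      out$ros_norm[sel] <- apply_residual_error(f, object$pop$b)
    }
    out
  })
}

#' @export
plot.ros_fit <- function(x, type = c("individual", "population"), ...) {
  type <- match.arg(type)
  f <- predict(x, type = type)
  graphics::plot(f, x$data$ros_norm, xlab = paste(type, "prediction"),
                 ylab = "observed ROS (fold of control)",
                 main = "observed vs predicted", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Seeded nonparametric bootstrap RSEs
#'
#' Resamples studies with replacement, refits, and reports the
#' percent coefficient of variation of the bootstrap estimates —
#' the fallback precision measure when the observed-information Hessian
#' is ill-conditioned.
#'
#' @param fit A [ros_fit()] result.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Seed for the resampling.
#' @return Named vector of bootstrap RSEs (%).
#' @export
rse_bootstrap <- function(fit, n_boot = 50, seed = 1) {
  set.seed(seed)
  ids <- unique(fit$data$study_id)
  ests <- matrix(NA_real_, n_boot, length(coef(fit)),
                 dimnames = list(NULL, names(coef(fit))))
  for (r in seq_len(n_boot)) {
    take <- sample(ids, replace = TRUE)
    dat <- do.call(rbind, lapply(seq_along(take), function(i) {
      d <- fit$data[fit$data$study_id == take[i], , drop = FALSE]
      d$study_id <- paste0("boot", i)
      d
    }))
    bf <- try(ros_fit(dat, fit$protocols, start = fit$pop,
                      estimate = fit$estimate, nodes = fit$settings$nodes,
                      rtol = fit$settings$rtol, atol = fit$settings$atol,
                      engine = fit$settings$engine, compute_rse = FALSE),
              silent = TRUE)
    if (!inherits(bf, "try-error")) ests[r, ] <- coef(bf)
  }
  100 * apply(ests, 2, sd, na.rm = TRUE) / colMeans(ests, na.rm = TRUE)
}

#' Visual predictive check percentile bands
#'
#' Simulates study-level observations (random effects plus residual
#' error) under a design and summarizes them as per-time percentiles.
#' With both omegas and `b` at zero all bands collapse onto the
#' deterministic prediction.
#'
#' @param pop A [population_model()] or a [ros_fit()] (its fitted
#'   population model is used).
#' @param protocol A [glucose_protocol()] defining the design.
#' @param times Sampling times (hours).
#' @param n_sim Number of simulated studies (>= 100 recommended).
#' @param probs Percentile levels.
#' @param seed Seed for reproducibility.
#' @param include_residual Include the residual-error layer (TRUE, as in
#'   an observation-level VPC) or only parameter variability.
#' @param rtol,atol Solver tolerances.
#' @param engine Solver engine (compiled fast path by default).
#' @return Data frame: `time_h`, one column per percentile (`p5`, ...),
#'   and the deterministic fixed-effects prediction `f_pop`.
#' @export
vpc <- function(pop, protocol, times, n_sim = 500,
                probs = c(0.05, 0.25, 0.5, 0.75, 0.95), seed = NULL,
                include_residual = TRUE, rtol = 1e-8, atol = 1e-10,
                engine = c("dp45", "lsoda")) {
  engine <- match.arg(engine)
  if (inherits(pop, "ros_fit")) pop <- pop$pop
  stopifnot(inherits(pop, "ros_pop"))
  if (n_sim < 2) stop("n_sim must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  sims <- matrix(NA_real_, n_sim, length(times))
  for (i in seq_len(n_sim)) {
    p <- sample_study_parameters(pop)
    f <- predict_observations(p, protocol, times, rtol, atol, engine)
    sims[i, ] <- if (include_residual) apply_residual_error(f, pop$b) else f
  }
  qs <- t(apply(sims, 2, quantile, probs = probs))
  colnames(qs) <- paste0("p", probs * 100)
  f_pop <- predict_observations(pop$params, protocol, times, rtol, atol,
                                engine)
  cbind(data.frame(time_h = times), as.data.frame(qs), f_pop = f_pop)
}

#' Serialize a fit result to JSON
#'
#' Writes estimates, RSEs, log-likelihood, AIC, convergence diagnostics,
#' empirical-Bayes modes and settings.
#'
#' @param fit A [ros_fit()] result.
#' @param file Output path (`.json`).
#' @return `file`, invisibly.
#' @export
write_fit <- function(fit, file) {
  out <- list(estimates = as.list(coef(fit)), rse_pct = as.list(fit$rse),
              loglik = fit$loglik, aic = fit$aic,
              convergence = fit$convergence, eb = fit$eb,
              fixed = unclass(fit$pop$params),
              settings = list(nodes = fit$settings$nodes,
                              rtol = fit$settings$rtol,
                              atol = fit$settings$atol))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
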