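#' Annealing schedules for the inverse temperature
#'
#' Differentiation in the model is driven by annealing: \eqn{\beta} is
#' transiently decreased ("heating", which destabilizes terminal identities
#' and moves the cell to a multipotent averaged state) and then increased
#' again ("cooling"), so that the cell passes through progenitor states of
#' progressively restricted potency. A schedule maps time to \eqn{\beta(t)}.
#'
#' Two shapes are supported. `"linear"` ramps from `beta_start` to
#' `beta_end` over `duration`, optionally after an initial hold of
#' `hold_start` time units at `beta_start` (time spent at low \eqn{\beta}
#' erases the memory of the starting identity). `"piecewise"` interpolates
#' linearly through `(times, betas)` breakpoints, which permits staged
#' anneals that pause inside a progenitor's stability window, as in staged
#' simulated-annealing practice.
#'
#' @param beta_start,beta_end endpoints of the ramp.
#' @param duration ramp duration in time units (> 0).
#' @param hold_start optional hold at `beta_start` before ramping.
#' @param times,betas breakpoints for the piecewise shape; `times` must be
#'   strictly increasing and start at 0, `betas` nonnegative.
#' @param shape `"linear"` or `"piecewise"` (implied by supplying `times`).
#' @return An `anneal_schedule` object: a list with `beta_at(t)`, `duration`
#'   (total time covered) and `beta_end`.
#' @examples
#' sch <- anneal_schedule(0, 50, duration = 50)
#' sch$beta_at(c(0, 25, 50))
#' @export
anneal_schedule <- function(beta_start = 0, beta_end = 50, duration = 50,
                            hold_start = 0, times = NULL, betas = NULL,
                            shape = if (is.null(times)) "linear" else "piecewise") {
  shape <- match.arg(shape, c("linear", "piecewise"))
  if (shape == "linear") {
    stopifnot_scalar(duration, "duration", lower = 0, strict = TRUE)
    if (beta_start < 0 || beta_end < 0) stop("beta values must be >= 0")
    times <- c(0, hold_start, hold_start + duration)
    betas <- c(beta_start, beta_start, beta_end)
    if (hold_start == 0) { times <- times[-1]; betas <- betas[-1] }
  } else {
    if (is.null(times) || is.null(betas) || length(times) != length(betas)) {
      stop("piecewise schedule needs matching 'times' and 'betas'")
    }
    if (any(diff(times) <= 0) || times[1] != 0) {
      stop("'times' must be strictly increasing and start at 0")
    }
    if (any(betas < 0)) stop("beta values must be >= 0")
  }
  total <- max(times)
  bfun <- stats::approxfun(times, betas, rule = 2)
  structure(list(shape = shape, times = times, betas = betas,
                 beta_at = bfun, duration = total,
                 beta_end = betas[length(betas)]),
            class = "anneal_schedule")
}

#' @export
print.anneal_schedule <- function(x, ...) {
  cat(sprintf("%s annealing schedule over %g time units: beta %s\n", x$shape,
              x$duration, paste(signif(x$betas, 4), collapse = " -> ")))
  invisible(x)
}

#' Additive white-noise specification
#'
#' @param sigma noise amplitude (expression units per sqrt(time)), >= 0.
#' @param seed integer seed; required for reproducible stochastic paths.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sigma = 0.01, seed = NULL) {
  stopifnot_scalar(sigma, "sigma", lower = 0)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(sigma = sigma, seed = seed), class = "noise_spec")
}

#' Simulate expression dynamics
#'
#' Integrates \eqn{\tau\,dx/dt = Q^\top p(x) - x + \delta} from `x0` over
#' `tspan`. Deterministic paths use the adaptive `lsoda` integrator
#' (relative tolerance 1e-8, absolute 1e-10); stochastic paths use
#' fixed-step Euler-Maruyama with step `dt` and per-component additive noise
#' \eqn{\sigma\,dW}, clipping the state at zero after each step (expression
#' cannot be negative; the deterministic flow preserves nonnegativity on its
#' own since \eqn{dx/dt \ge -x/\tau}).
#'
#' @param object a [fatenet] object.
#' @param nsim,seed number of replicate paths and RNG seed (the seed in a
#'   supplied `noise` spec takes precedence). With `nsim > 1` a list of
#'   trajectories is returned.
#' @param x0 initial state (nonnegative, length T).
#' @param tspan `c(t0, t1)`.
#' @param beta_schedule optional [anneal_schedule()]; otherwise \eqn{\beta}
#'   is held at `object$beta`. Schedule time is measured from `tspan[1]`.
#' @param noise optional [noise_spec()]; `sigma > 0` requires a seed here or
#'   via `seed`.
#' @param forcing optional length-T constitutive production vector
#'   \eqn{\delta} (see [apply_recipe()]).
#' @param dt Euler-Maruyama step for stochastic paths (default
#'   \eqn{0.01\tau}).
#' @param save_every save interval for the returned time grid (default: a
#'   grid of about 400 points).
#' @param method `"auto"` (adaptive when deterministic, Euler-Maruyama when
#'   stochastic) or `"euler"` to force the fixed-step scheme, e.g. for
#'   integrator cross-validation.
#' @param ... unused.
#' @return A `fatenet_trajectory`: list with `times`, `beta` (per sample),
#'   `states` (samples x T), `activities` (samples x E) and bookkeeping
#'   fields. With `nsim > 1`, a list of such objects.
#' @examples
#' net <- fatenet(diag(2), beta = 8)
#' tr <- simulate(net, x0 = c(0.9, 0.2), tspan = c(0, 20))
#' tail(tr$states, 1)
#' @export
simulate.fatenet <- function(object, nsim = 1, seed = NULL, x0,
                             tspan = c(0, 100), beta_schedule = NULL,
                             noise = NULL, forcing = NULL, dt = NULL,
                             save_every = NULL, method = c("auto", "euler"),
                             ...) {
  net <- object
  method <- match.arg(method)
  x0 <- .check_state(net, x0)
  if (any(x0 < 0)) stop("x0 must be nonnegative")
  if (length(tspan) != 2L || !all(is.finite(tspan)) || diff(tspan) <= 0) {
    stop("tspan must be a finite increasing pair")
  }
  if (!is.null(forcing)) forcing <- .check_state(net, forcing)
  sigma <- if (is.null(noise)) 0 else noise$sigma
  if (sigma > 0) {
    seed <- noise$seed %||% seed
    if (is.null(seed)) stop("stochastic simulation (sigma > 0) requires a seed")
  }
  bfun <- if (is.null(beta_schedule)) {
    function(t) rep(net$beta, length(t))
  } else {
    function(t) beta_schedule$beta_at(t - tspan[1])
  }
  if (nsim > 1) {
    if (is.null(seed)) stop("nsim > 1 requires a seed")
    return(lapply(seq_len(nsim), function(k) {
      ns <- if (sigma > 0) noise_spec(sigma, seed + k - 1L) else NULL
      simulate.fatenet(object, nsim = 1, seed = seed + k - 1L, x0 = x0,
                       tspan = tspan, beta_schedule = beta_schedule,
                       noise = ns, forcing = forcing, dt = dt,
                       save_every = save_every, method = method)
    }))
  }

  span <- diff(tspan)
  save_every <- save_every %||% (span / 400)
  times <- seq(tspan[1], tspan[2], by = save_every)
  if (times[length(times)] < tspan[2]) times <- c(times, tspan[2])

  if (sigma == 0 && method == "auto") {
    rhs <- function(t, y, parms) {
      list(drift(net, y, beta = bfun(t), forcing = forcing))
    }
    sol <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    X <- unname(sol[, -1, drop = FALSE])
    if (any(!is.finite(X))) {
      bad <- which(!stats::complete.cases(X))[1]
      stop(sprintf("integration produced a non-finite state at t = %g",
                   times[bad]))
    }
    X[X < 0 & X > -1e-12] <- 0  # integrator round-off at the boundary
  } else {
    dt <- dt %||% (0.01 * net$tau)
    X <- with_seed(seed, {
      .euler_maruyama(net, x0, tspan, bfun, forcing, sigma, dt, times)
    })
  }
  .new_trajectory(net, times, bfun(times), X, seed = seed, sigma = sigma)
}

.euler_maruyama <- function(net, x0, tspan, bfun, forcing, sigma, dt, save_times) {
  n_steps <- ceiling(diff(tspan) / dt)
  x <- x0
  T_ <- length(x0)
  out <- matrix(NA_real_, length(save_times), T_)
  out[1, ] <- x0
  nxt <- 2L
  sq <- sigma * sqrt(dt)
  t <- tspan[1]
  for (i in seq_len(n_steps)) {
    h <- min(dt, tspan[2] - t)
    x <- x + h * drift(net, x, beta = bfun(t), forcing = forcing) +
      sq * stats::rnorm(T_)
    x[x < 0] <- 0
    if (any(!is.finite(x))) {
      stop(sprintf("integration produced a non-finite state at t = %g", t + h))
    }
    t <- t + h
    while (nxt <= length(save_times) && save_times[nxt] <= t + 1e-12) {
      out[nxt, ] <- x
      nxt <- nxt + 1L
    }
  }
  if (nxt <= length(save_times)) out[nxt:length(save_times), ] <- rep(x, each = length(save_times) - nxt + 1L)
  out
}

.new_trajectory <- function(net, times, beta, X, seed = NULL, sigma = 0) {
  # activities recomputed per sample at the sample's own beta
  P <- matrix(NA_real_, nrow(X), nrow(net$binding))
  for (i in seq_len(nrow(X))) {
    P[i, ] <- enhancer_activities(net, X[i, ], beta = beta[i])
  }
  colnames(X) <- net$tf_names
  colnames(P) <- net$enhancer_names
  structure(list(times = times, beta = beta, states = X, activities = P,
                 net = net, seed = seed, sigma = sigma),
            class = "fatenet_trajectory")
}

#' @export
print.fatenet_trajectory <- function(x, ...) {
  n <- length(x$times)
  fin <- assign_identity(x$net, x$states[n, ])
  cat(sprintf(
    "Trajectory: %d samples over t = [%g, %g], beta %g -> %g%s\n",
    n, x$times[1], x$times[n], x$beta[1], x$beta[n],
    if (x$sigma > 0) sprintf(", sigma = %g (seed %d)", x$sigma, x$seed) else ""))
  cat(sprintf("  final state nearest '%s' (cosine distance %.3g)\n",
              fin$label, fin$distance))
  invisible(x)
}

# Instantaneous speed ||dx/dt|| at each sample of a trajectory.
.trajectory_speeds <- function(traj, weights = NULL) {
  vapply(seq_along(traj$times), function(i) {
    vec_norm(drift(traj$net, traj$states[i, ], beta = traj$beta[i],
                   weights = weights))
  }, numeric(1))
}
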