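#' Enhancer scores, activities, drift, potential and Jacobian
#'
#' `enhancer_scores()` returns the log-propensity of each enhancer,
#' \eqn{s_i = \beta \zeta_i (\xi_i \cdot x) + w_i}; the baseline weights enter
#' unscaled by \eqn{\beta}, so signalling biases persist at small \eqn{\beta}.
#' `enhancer_activities()` maps scores through a numerically stabilized
#' softmax to the Boltzmann transcription-initiation probabilities \eqn{p},
#' which always sum to one. `drift()` is the right-hand side of the
#' expression dynamics \eqn{dx/dt = (Q^\top p(x) - x)/\tau}.
#'
#' @param net a [fatenet] object.
#' @param x nonnegative expression state (length T).
#' @param beta,weights optional overrides of the network's values (used by
#'   annealing schedules and signalling feedback).
#' @param forcing optional length-T vector \eqn{\delta} of constitutive
#'   production rates (TF overexpression); adds \eqn{\delta/\tau} to the
#'   drift.
#' @return `enhancer_scores` and `enhancer_activities` a length-E vector;
#'   `drift` a length-T vector.
#' @examples
#' net <- fatenet(diag(2), beta = 5)
#' enhancer_activities(net, c(1, 0))
#' @export
enhancer_scores <- function(net, x, beta = NULL, weights = NULL) {
  x <- .check_state(net, x)
  beta <- beta %||% net$beta
  weights <- weights %||% net$weights
  drop(beta * (.binding_eff(net) %*% x)) + weights
}

.check_state <- function(net, x) {
  x <- as.numeric(x)
  if (length(x) != ncol(net$binding)) {
    stop(sprintf("state has length %d but the network has %d TFs (axis T)",
                 length(x), ncol(net$binding)))
  }
  x
}

#' @rdname enhancer_scores
#' @export
enhancer_activities <- function(net, x, beta = NULL, weights = NULL) {
  softmax(enhancer_scores(net, x, beta, weights))
}

#' @rdname enhancer_scores
#' @export
drift <- function(net, x, beta = NULL, weights = NULL, forcing = NULL) {
  p <- enhancer_activities(net, x, beta, weights)
  d <- unname(drop(crossprod(net$coupling, p))) - x
  if (!is.null(forcing)) d <- d + forcing
  d / net$tau
}

# Batched drift for an n x T matrix of states (one row per state); used by
# attractor searches. Returns an n x T matrix.
.drift_matrix <- function(net, X, beta = NULL, weights = NULL) {
  beta <- beta %||% net$beta
  weights <- weights %||% net$weights
  S <- beta * tcrossprod(X, .binding_eff(net))
  S <- sweep(S, 2L, weights, `+`)
  S <- S - apply(S, 1L, max)
  P <- exp(S)
  P <- P / rowSums(P)
  (P %*% net$coupling - X) / net$tau
}

#' Scalar potential of the symmetric dynamics
#'
#' For autoregulatory networks (\eqn{Q = \nu \Xi}, constant gain) the
#' expression dynamics are a gradient flow, \eqn{\tau\,dx/dt = -\nabla V(x)},
#' with
#' \deqn{V(x) = \tfrac12 \lVert x \rVert^2 -
#'   \frac{\nu}{\beta} \log \sum_i e^{\beta \xi_i \cdot x + w_i}.}
#' \eqn{V} decreases along every deterministic trajectory; its local minima
#' are the stable cell identities. At \eqn{\beta = 0} the log-sum-exp term
#' degenerates and the analytic limit
#' \eqn{V = \tfrac12\lVert x\rVert^2 - \nu\, p_0^\top \Xi x} is used, where
#' \eqn{p_0 = \mathrm{softmax}(w)} (the x-independent divergent constant is
#' dropped; the \eqn{\beta = 0} gradient is exact).
#'
#' @inheritParams enhancer_scores
#' @return Scalar potential value.
#' @export
potential <- function(net, x, beta = NULL, weights = NULL) {
  if (!net$symmetric) {
    stop("potential undefined for asymmetric networks (requires Q = nu * Xi)")
  }
  if (diff(range(net$gain)) > 1e-12) {
    stop("potential requires a constant enhancer gain vector")
  }
  x <- .check_state(net, x)
  beta <- beta %||% net$beta
  weights <- weights %||% net$weights
  zeta <- net$gain[1]
  if (beta * zeta == 0) {
    p0 <- softmax(weights)
    return(0.5 * sum(x^2) - net$nu * sum(p0 * drop(net$binding %*% x)))
  }
  s <- beta * zeta * drop(net$binding %*% x) + weights
  0.5 * sum(x^2) - net$nu / (beta * zeta) * logsumexp(s)
}

#' Jacobian of the expression dynamics
#'
#' Analytic derivative of [drift()] with respect to the state:
#' \deqn{J = \frac{1}{\tau}\left(\beta Q^\top \mathrm{diag}(p)\, \Xi_\zeta
#'   - \beta (Q^\top p)(p^\top \Xi_\zeta) - I\right),}
#' where \eqn{\Xi_\zeta} has rows \eqn{\zeta_i \xi_i}. Used for stability
#' classification and Newton refinement of fixed points. For symmetric
#' networks the Jacobian is a symmetric matrix: reciprocal TF interactions
#' are equivalent to autoregulation.
#'
#' @inheritParams enhancer_scores
#' @return T x T matrix.
#' @export
jacobian <- function(net, x, beta = NULL, weights = NULL) {
  x <- .check_state(net, x)
  beta <- beta %||% net$beta
  p <- enhancer_activities(net, x, beta, weights)
  xe <- .binding_eff(net)
  qp <- crossprod(net$coupling, p)            # T x 1
  J <- beta * (crossprod(net$coupling, p * xe) - tcrossprod(qp, crossprod(xe, p)))
  unname((J - diag(ncol(xe))) / net$tau)
}

#' Probe whether TF interactions are reciprocal
#'
#' Samples random expression states and measures the asymmetry of the
#' Jacobian at each. Reciprocity (the effect of TF j on the production of TF
#' k equals the effect of k on j, for every pair) holds exactly when the
#' coupling matrix is proportional to the binding matrix, i.e. when TFs
#' autoregulate through their own enhancers; the fitted proportionality
#' constant \eqn{\nu} is reported.
#'
#' @param net a [fatenet] object.
#' @param n_probe_points number of random states to probe.
#' @param seed RNG seed for the probe states.
#' @return List with `is_reciprocal`, `max_asymmetry` (largest absolute
#'   difference \eqn{|J_{jk} - J_{kj}|} over all probes) and `nu`.
#' @export
check_reciprocity <- function(net, n_probe_points = 20, seed = 1) {
  T_ <- ncol(net$binding)
  scale <- max(net$coupling, 1e-3)
  worst <- 0
  with_seed(seed, {
    for (i in seq_len(n_probe_points)) {
      x <- stats::runif(T_, 0, scale)
      J <- jacobian(net, x)
      worst <- max(worst, max(abs(J - t(J))))
    }
  })
  list(is_reciprocal = worst < 1e-6, max_asymmetry = worst, nu = net$nu)
}

#' Collapse duplicated enhancers into enhancer types
#'
#' Physical enhancers with identical (gain-scaled) binding rows are
#' indistinguishable to the softmax competition, so each duplicate group can
#' be replaced by one combined "enhancer type" without changing the dynamics:
#' the merged weight is \eqn{w_* = \log \sum_g e^{w_g}} and the merged
#' coupling row is the \eqn{e^{w_g}}-weighted mean of the group's coupling
#' rows. The reduction is exact (trajectory-equivalent) and idempotent.
#'
#' @param net a [fatenet] object.
#' @param tol rows are considered identical when the largest elementwise
#'   difference of their gain-scaled binding vectors is below `tol`.
#' @return A [fatenet] with one enhancer per distinct binding profile.
#' @export
reduce_to_types <- function(net, tol = 1e-9) {
  xe <- .binding_eff(net)
  E <- nrow(xe)
  group <- integer(E)
  reps <- integer(0)
  for (i in seq_len(E)) {
    hit <- 0L
    for (r in seq_along(reps)) {
      if (max(abs(xe[i, ] - xe[reps[r], ])) <= tol) { hit <- r; break }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
    group[i] <- hit
  }
  if (length(reps) == E) return(net)
  G <- length(reps)
  binding <- xe[reps, , drop = FALSE]
  coupling <- matrix(0, G, ncol(xe))
  weights <- numeric(G)
  nms <- character(G)
  for (g in seq_len(G)) {
    idx <- which(group == g)
    wg <- net$weights[idx]
    weights[g] <- logsumexp(wg)
    a <- exp(wg - max(wg)); a <- a / sum(a)
    coupling[g, ] <- colSums(a * net$coupling[idx, , drop = FALSE])
    nms[g] <- paste(net$enhancer_names[idx], collapse = "+")
  }
  fatenet(binding, coupling, weights, beta = net$beta, tau = net$tau,
          tf_names = net$tf_names, enhancer_names = nms)
}
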