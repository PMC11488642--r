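#' Chromatin barrier parameters
#'
#' Extends the model with a slow repressive chromatin modification
#' \eqn{u_i} per enhancer that raises the enhancer's activation energy
#' (subtracting \eqn{\lambda u_i} from its weight). The modification is
#' autocatalytic with a steep Hill nonlinearity and inhibited by enhancer
#' activity:
#' \deqn{du_i/dt = f(p_i)\,\frac{u_i^n}{\rho^n + u_i^n} + f(p_i)\,
#'   \varepsilon - \gamma u_i,}
#' with \eqn{f} a decreasing function of the activity \eqn{p_i} crossing
#' its bistability range at `p_crit`. While an enhancer stays active
#' (\eqn{p_i > p_{crit}}) the low branch \eqn{u_i \approx 0} is stable;
#' when activity drops below `p_crit` the low branch disappears and
#' \eqn{u_i} jumps to a high branch, locking the enhancer out and creating
#' a barrier against reprogramming into the corresponding cell type.
#' Depending on \eqn{\rho} the switch is bistable (hysteretic) or
#' reversible.
#'
#' The exact closure is a modelling choice; only the qualitative contract
#' (stable low branch above `p_crit`, jump and hysteresis below) is load
#' bearing, and the defaults were chosen by a numerical root scan of the
#' production-degradation balance.
#'
#' @param lambda energy penalty per unit of u on the enhancer weight.
#' @param rho Hill midpoint of the autocatalytic term.
#' @param hill_n Hill exponent (integer >= 2; steep, default 8).
#' @param p_crit activity threshold in (0, 1).
#' @param f_shape decreasing function of activity returning the production
#'   drive; the default interpolates between `f_hi` (silent enhancer) and
#'   `f_lo` (active enhancer) with a steep Hill centred at `p_crit`.
#' @param f_lo,f_hi drive bounds used by the default `f_shape`.
#' @param baseline basal production fraction \eqn{\varepsilon}.
#' @param degradation linear degradation rate \eqn{\gamma}.
#' @param u initial modification levels (length-E when used with a
#'   network; scalar default 0).
#' @return A `barrier_params` object.
#' @export
barrier_params <- function(lambda = 2, rho = 0.5, hill_n = 8, p_crit = 0.1,
                           f_shape = NULL, f_lo = 0.5, f_hi = 5,
                           baseline = 0.12, degradation = 1, u = 0) {
  if (hill_n < 2) stop("hill_n must be >= 2")
  if (p_crit <= 0 || p_crit >= 1) stop("p_crit must be in (0, 1)")
  if (any(u < 0)) stop("u must be nonnegative")
  f <- f_shape %||% function(p) {
    f_lo + (f_hi - f_lo) * p_crit^4 / (p_crit^4 + p^4)
  }
  pr <- seq(0.001, 0.999, length.out = 64)
  if (any(diff(f(pr)) > 1e-12)) stop("f_shape must be decreasing in p")
  structure(list(lambda = lambda, rho = rho, hill_n = hill_n,
                 p_crit = p_crit, f_shape = f, baseline = baseline,
                 degradation = degradation, u = u),
            class = "barrier_params")
}

#' Advance the chromatin barrier by one step
#'
#' Low-level update of the modification levels for given enhancer
#' activities (sub-stepped explicit Euler), plus the network-coupled
#' wrapper that computes activities from the current state under the
#' barrier-penalized weights and returns the updated effective weights.
#'
#' @param barrier a [barrier_params()] object.
#' @param p enhancer activity vector.
#' @param dt time step (> 0).
#' @return `barrier_update`: the updated `barrier_params` (field `u`).
#' @export
barrier_update <- function(barrier, p, dt) {
  stopifnot_scalar(dt, "dt", lower = 0, strict = TRUE)
  u <- rep_len(barrier$u, length(p))
  f <- barrier$f_shape(p)
  n <- barrier$hill_n
  sub <- max(1L, ceiling(dt / 0.05))
  h <- dt / sub
  for (s in seq_len(sub)) {
    hill <- u^n / (barrier$rho^n + u^n)
    du <- f * hill + f * barrier$baseline - barrier$degradation * u
    u <- pmax(u + h * du, 0)
  }
  barrier$u <- u
  barrier
}

#' @rdname barrier_update
#' @param net a [fatenet] object.
#' @param x current expression state.
#' @return `chromatin_barrier_step`: list with the updated `barrier`, the
#'   `weights_effective` vector \eqn{w - \lambda u} and the `activities`
#'   used for the update.
#' @export
chromatin_barrier_step <- function(net, barrier, x, dt) {
  w_eff <- net$weights - barrier$lambda * rep_len(barrier$u,
                                                  nrow(net$binding))
  p <- enhancer_activities(net, x, weights = w_eff)
  barrier <- barrier_update(barrier, p, dt)
  list(barrier = barrier,
       weights_effective = net$weights - barrier$lambda * barrier$u,
       activities = p)
}

#' Sweep enhancer activity and record the barrier response
#'
#' Drives a single enhancer's activity along `p_path`, integrating the
#' modification dynamics for `t_per_step` time units at each value, and
#' records the settled \eqn{u}. Comparing a down-sweep with the subsequent
#' up-sweep exposes the hysteresis of the switch.
#'
#' @param barrier a [barrier_params()].
#' @param p_path activity values, visited in order.
#' @param t_per_step dwell time per activity value.
#' @return Data frame with `p` and the settled `u` at each step.
#' @export
barrier_sweep <- function(barrier, p_path, t_per_step = 40) {
  out <- numeric(length(p_path))
  for (i in seq_along(p_path)) {
    barrier <- barrier_update(barrier, p_path[i], t_per_step)
    out[i] <- barrier$u
  }
  data.frame(p = p_path, u = out)
}
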