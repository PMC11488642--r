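#' Refine and classify a fixed point of the dynamics
#'
#' Polishes a candidate state with a damped Newton iteration on the drift
#' (using the analytic [jacobian()]), projecting onto the nonnegative
#' orthant, and classifies local stability from the Jacobian spectrum at the
#' refined point. States whose leading eigenvalue real part lies within
#' 1e-8 of zero are reported as `"marginal"` rather than silently stable.
#'
#' @param net a [fatenet] object.
#' @param x0 nonnegative starting state.
#' @param beta,weights optional overrides of the network parameters.
#' @param tol residual norm target (default 1e-10).
#' @param max_iter Newton iteration cap; non-convergence is flagged in the
#'   result, never silent.
#' @param pre_relax time units of integration applied before Newton when the
#'   starting residual is large.
#' @param label attach the nearest-identity label (costs a candidate-subset
#'   search; disable in tight loops).
#' @return A `fatenet_fixed_point`: list with `x`, `residual`, `converged`,
#'   `stable`, `marginal`, `leading_eigenvalue` (largest real part, units
#'   1/time) and `label` (nearest identity per [label_state()]).
#' @export
refine_fixed_point <- function(net, x0, beta = NULL, weights = NULL,
                               tol = 1e-10, max_iter = 200, pre_relax = 20,
                               label = TRUE) {
  x <- .check_state(net, x0)
  if (any(x < 0)) stop("x0 must be nonnegative")
  beta <- beta %||% net$beta
  weights <- weights %||% net$weights

  res <- vec_norm(drift(net, x, beta, weights))
  if (res > 0.05 && pre_relax > 0) {
    x <- .relax_states(net, matrix(x, 1L), beta, weights, t_end = pre_relax)[1, ]
    res <- vec_norm(drift(net, x, beta, weights))
  }
  for (it in seq_len(max_iter)) {
    if (res < tol) break
    d <- drift(net, x, beta, weights)
    J <- jacobian(net, x, beta, weights)
    step <- tryCatch(solve(J, -d), error = function(e) d * net$tau)
    lam <- 1
    repeat {
      xn <- pmax(x + lam * step, 0)
      rn <- vec_norm(drift(net, xn, beta, weights))
      if (rn < res || lam < 1e-6) break
      lam <- lam / 2
    }
    if (rn >= res && lam < 1e-6) break  # stalled
    x <- xn; res <- rn
  }
  ev <- eigen(jacobian(net, x, beta, weights), only.values = TRUE)$values
  lead <- max(Re(ev))
  structure(list(
    x = stats::setNames(x, net$tf_names), residual = res,
    converged = res < 1e-8, stable = lead < -1e-8,
    marginal = abs(lead) <= 1e-8, leading_eigenvalue = lead,
    label = if (label) label_state(net, x)$label else NA_character_),
    class = "fatenet_fixed_point")
}

#' @export
print.fatenet_fixed_point <- function(x, ...) {
  cat(sprintf("Fixed point near '%s': residual %.2g, %s (leading Re = %.3g)\n",
              x$label, x$residual,
              if (!x$converged) "NOT CONVERGED"
              else if (x$marginal) "marginal"
              else if (x$stable) "stable" else "unstable",
              x$leading_eigenvalue))
  invisible(x)
}

# Fixed-step batched relaxation of an n x T matrix of states; the step is
# shrunk with beta to respect the stiffness of the softmax competition.
.relax_states <- function(net, X, beta = NULL, weights = NULL, t_end = 60) {
  beta <- beta %||% net$beta
  # explicit midpoint step; |lambda| grows ~ beta/4, keep h * lambda < 1.5
  h <- min(0.2, 6 / (1 + beta)) * net$tau
  n <- ceiling(t_end / h)
  for (i in seq_len(n)) {
    k1 <- .drift_matrix(net, X, beta, weights)
    k2 <- .drift_matrix(net, X + 0.5 * h * k1, beta, weights)
    X <- X + h * k2
    X[X < 0] <- 0
  }
  X
}

#' Label a state by its nearest identity template
#'
#' Compares a state against the pattern rows of the coupling matrix and
#' against candidate subset averages (by default: all pairs plus the global
#' average, extended with the nested subsets obtained by cutting the
#' cosine-similarity dendrogram of the patterns). Distances are cosine
#' distances, so labels are scale-free.
#'
#' @param net a [fatenet] object.
#' @param x state to label.
#' @param tol cosine distance below which a state is identified with a
#'   template; otherwise the label is `"other"`.
#' @param subsets optional list of integer index vectors naming the subset
#'   averages to consider (in addition to the patterns).
#' @return List with `label` (`"pattern:<name>"`, `"average:<names>"` or
#'   `"other"`), `distance` and `template` (the matched state, or NULL).
#' @export
label_state <- function(net, x, tol = 1e-3, subsets = NULL) {
  cands <- .identity_candidates(net, subsets)
  d <- vapply(cands$states, function(s) cosine_distance(x, s), numeric(1))
  i <- which.min(d)
  if (d[i] <= tol) {
    list(label = cands$labels[i], distance = d[i], template = cands$states[[i]])
  } else {
    list(label = "other", distance = d[i], template = NULL)
  }
}

.identity_candidates <- function(net, subsets = NULL) {
  pats <- .patterns(net)
  E <- nrow(pats)
  states <- lapply(seq_len(E), function(i) pats[i, ])
  labels <- paste0("pattern:", net$enhancer_names)
  if (is.null(subsets)) subsets <- .default_subsets(net)
  for (ss in subsets) {
    ss <- sort(unique(ss))
    if (length(ss) < 2) next
    states[[length(states) + 1L]] <- colMeans(pats[ss, , drop = FALSE])
    labels <- c(labels,
                paste0("average:", paste(net$enhancer_names[ss], collapse = ",")))
  }
  list(states = states, labels = labels)
}

# Candidate progenitor subsets: all pairs, the global average, and the
# nested clusters of the pattern dendrogram (progenitors are predicted only
# for subsets of high internal similarity, so the dendrogram cuts are the
# natural candidates; enumerating all 2^E subsets is not).
.default_subsets <- function(net) {
  E <- nrow(net$binding)
  out <- list()
  if (E >= 2) {
    cmb <- utils::combn(E, 2)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
    if (E > 2) out <- c(out, list(seq_len(E)))
    if (E > 3) {
      pats <- .patterns(net)
      nrm <- sqrt(rowSums(pats^2))
      ok <- nrm > 0
      if (sum(ok) > 3) {
        u <- pats[ok, , drop = FALSE] / nrm[ok]
        hc <- stats::hclust(stats::as.dist(pmax(1 - tcrossprod(u), 0)),
                            method = "average")
        idx <- which(ok)
        for (k in 2:(sum(ok) - 1)) {
          for (grp in split(idx, stats::cutree(hc, k))) {
            if (length(grp) > 2) out <- c(out, list(unname(grp)))
          }
        }
      }
    }
  }
  unique(lapply(out, sort))
}

#' Enumerate attractors of the network
#'
#' Seeds fixed-point searches from (a) every pattern row, (b) patterns under
#' multiplicative perturbation of relative scale `perturbation_scale`, and
#' (c) uniform random states; integrates each seed to convergence, polishes
#' with [refine_fixed_point()], deduplicates by Euclidean distance and labels
#' each attractor by its nearest pattern or subset average.
#'
#' @param net a [fatenet] object.
#' @param n_random_restarts number of uniform random seeds.
#' @param perturbation_scale relative scale of the multiplicative pattern
#'   perturbations (default 0.25).
#' @param seed RNG seed.
#' @param beta optional override of the network inverse temperature.
#' @param n_noisy perturbed seeds per pattern.
#' @param dedup_tol Euclidean deduplication distance.
#' @param keep_unstable also report converged saddle points (default FALSE:
#'   an attractor set holds attractors).
#' @return A `fatenet_attractors` object: data frame `summary` (label,
#'   stable, marginal, residual, leading eigenvalue) plus `states` matrix,
#'   `beta` and `dedup_tol`.
#' @export
enumerate_attractors <- function(net, n_random_restarts = 50,
                                 perturbation_scale = 0.25, seed = 1,
                                 beta = NULL, n_noisy = 3, dedup_tol = 1e-3,
                                 keep_unstable = FALSE) {
  beta <- beta %||% net$beta
  pats <- .patterns(net)
  T_ <- ncol(pats)
  hi <- max(pats) * 1.2
  seeds <- pats
  with_seed(seed, {
    for (k in seq_len(nrow(pats))) {
      for (j in seq_len(n_noisy)) {
        seeds <- rbind(seeds, pmax(pats[k, ] *
          (1 + perturbation_scale * stats::rnorm(T_)), 0))
      }
    }
    if (n_random_restarts > 0) {
      seeds <- rbind(seeds, matrix(stats::runif(n_random_restarts * T_, 0, hi),
                                   n_random_restarts, T_))
    }
  })
  X <- .relax_states(net, seeds, beta, t_end = 80)
  found <- list()
  for (i in seq_len(nrow(X))) {
    fp <- refine_fixed_point(net, X[i, ], beta = beta, pre_relax = 0)
    if (!fp$converged) next
    if (!fp$stable && !keep_unstable) next
    dup <- FALSE
    for (g in found) {
      if (vec_norm(g$x - fp$x) < dedup_tol) { dup <- TRUE; break }
    }
    if (!dup) found[[length(found) + 1L]] <- fp
  }
  .new_attractor_set(net, found, beta, dedup_tol)
}

.new_attractor_set <- function(net, fps, beta, dedup_tol) {
  if (length(fps)) {
    states <- do.call(rbind, lapply(fps, function(f) unname(f$x)))
    colnames(states) <- net$tf_names
    summary <- data.frame(
      label = vapply(fps, function(f) f$label, character(1)),
      stable = vapply(fps, function(f) f$stable, logical(1)),
      marginal = vapply(fps, function(f) f$marginal, logical(1)),
      residual = vapply(fps, function(f) f$residual, numeric(1)),
      leading_eigenvalue = vapply(fps, function(f) f$leading_eigenvalue,
                                  numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    states <- matrix(numeric(0), 0, ncol(net$binding))
    summary <- data.frame(label = character(0), stable = logical(0),
                          marginal = logical(0), residual = numeric(0),
                          leading_eigenvalue = numeric(0))
  }
  structure(list(summary = summary, states = states, beta = beta,
                 dedup_tol = dedup_tol, net = net),
            class = "fatenet_attractors")
}

#' @export
print.fatenet_attractors <- function(x, ...) {
  cat(sprintf("%d fixed point(s) at beta = %g (%d stable):\n",
              nrow(x$summary), x$beta, sum(x$summary$stable)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Per-pattern fixed-point and stability report
#'
#' For each pattern (row of the coupling matrix), refines a fixed point from
#' the pattern, reports whether a fixed point exists near it (relative
#' Euclidean distance below `match_tol`), whether it is stable, and whether
#' the pattern passes the binding-alignment condition: among all enhancers,
#' the pattern's own enhancer must attain the highest (gain-scaled) binding
#' score at the pattern. A pattern whose overall binding affinity is
#' dominated by a similar competitor fails the condition and is inaccessible
#' at any inverse temperature.
#'
#' @param net a [fatenet] object.
#' @param beta optional override.
#' @param match_tol relative distance for identifying the refined point with
#'   the pattern.
#' @return Data frame with one row per pattern: `pattern`, `is_fixed_point`,
#'   `is_stable`, `cosine_condition_ok`, `residual`, `distance`.
#' @export
pattern_stability_report <- function(net, beta = NULL, match_tol = 0.05) {
  beta <- beta %||% net$beta
  pats <- .patterns(net)
  xe <- .binding_eff(net)
  out <- lapply(seq_len(nrow(pats)), function(k) {
    pk <- pats[k, ]
    scores <- drop(xe %*% pk)
    cond <- which.max(scores) == k &&
      (nrow(pats) < 2 || scores[k] > max(scores[-k]) + 1e-12)
    fp <- refine_fixed_point(net, pk, beta = beta, label = FALSE)
    rel <- vec_norm(unname(fp$x) - pk) / max(vec_norm(pk), 1e-12)
    data.frame(pattern = net$enhancer_names[k],
               is_fixed_point = fp$converged && rel <= match_tol,
               is_stable = fp$converged && rel <= match_tol && fp$stable,
               cosine_condition_ok = cond,
               residual = fp$residual, distance = rel,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Test a subset average as a progenitor fixed point
#'
#' The average of a subset of pattern rows is a candidate progenitor state:
#' it is a (meta)stable fixed point at intermediate inverse temperature when
#' the subset's members are similar to each other and distinct from the
#' remaining patterns. The candidate is refined and classified at the given
#' \eqn{\beta}.
#'
#' @param net a [fatenet] object.
#' @param subset integer (or enhancer-name) vector of pattern indices.
#' @param beta inverse temperature at which to test.
#' @param match_tol cosine distance within which the refined point still
#'   counts as the subset average.
#' @return List with `is_fixed_point`, `is_stable`, `fixed_point` (the
#'   refined `fatenet_fixed_point`) and `candidate` (the exact average).
#' @export
subset_average_stability <- function(net, subset, beta = NULL,
                                     match_tol = 0.05) {
  beta <- beta %||% net$beta
  if (is.character(subset)) subset <- match(subset, net$enhancer_names)
  subset <- sort(unique(as.integer(subset)))
  if (!length(subset) || anyNA(subset) ||
      any(subset < 1 | subset > nrow(net$binding))) {
    stop("subset must be a non-empty set of valid enhancer indices")
  }
  cand <- colMeans(.patterns(net)[subset, , drop = FALSE])
  fp <- refine_fixed_point(net, cand, beta = beta, pre_relax = 0)
  near <- cosine_distance(unname(fp$x), cand) <= match_tol
  list(is_fixed_point = fp$converged && near,
       is_stable = fp$converged && near && fp$stable,
       fixed_point = fp, candidate = cand)
}

#' Scan candidate states for their intervals of stability in beta
#'
#' For each candidate state (by default: every pattern, every pair average
#' and the global average) the scan determines on a grid, refined by
#' bisection, the interval of \eqn{\beta} over which the candidate is a
#' stable fixed point that retains its identity (the refined point stays
#' within `match_tol` cosine distance of the candidate). The global average
#' is stable from \eqn{\beta = 0}; each pattern is stable above a finite
#' threshold; pair averages of similar patterns occupy an intermediate
#' window -- the bifurcation structure behind hierarchical differentiation.
#'
#' @param net a [fatenet] object.
#' @param beta_grid increasing vector of inverse temperatures.
#' @param candidates optional named list of candidate states; the default is
#'   built from the patterns and their subset averages.
#' @param match_tol identity-retention cosine tolerance.
#' @param rel_precision relative precision of the bisection for interval
#'   endpoints.
#' @return Data frame with `label`, `beta_lo`, `beta_hi` for each maximal
#'   stability run found on the grid (rows with none are omitted), plus the
#'   attribute `"grid"` with the per-grid-point logical matrix.
#' @export
bifurcation_scan_beta <- function(net, beta_grid, candidates = NULL,
                                  match_tol = 0.05, rel_precision = 1e-3) {
  if (any(diff(beta_grid) <= 0)) stop("beta_grid must be increasing")
  if (is.null(candidates)) {
    E <- nrow(net$binding)
    cands <- .identity_candidates(net,
      subsets = c(if (E >= 2) lapply(seq_len(ncol(utils::combn(E, 2))),
                                     function(j) utils::combn(E, 2)[, j]),
                  if (E > 2) list(seq_len(E))))
    candidates <- stats::setNames(cands$states, cands$labels)
  }
  stable_at <- function(cand, beta) {
    fp <- refine_fixed_point(net, cand, beta = beta, pre_relax = 0,
                             label = FALSE)
    fp$converged && fp$stable &&
      cosine_distance(unname(fp$x), cand) <= match_tol
  }
  grid_ok <- matrix(FALSE, length(candidates), length(beta_grid),
                    dimnames = list(names(candidates), NULL))
  rows <- list()
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    ok <- vapply(beta_grid, function(b) stable_at(cand, b), logical(1))
    grid_ok[ci, ] <- ok
    r <- rle(ok); ends <- cumsum(r$lengths)
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      i0 <- if (j == 1) 1L else ends[j - 1] + 1L
      i1 <- ends[j]
      lo <- beta_grid[i0]
      if (i0 > 1) {
        lo <- .bisect_edge(function(b) stable_at(cand, b),
                           beta_grid[i0 - 1], beta_grid[i0], rel_precision,
                           rising = TRUE)
      }
      hi <- beta_grid[i1]
      if (i1 < length(beta_grid)) {
        hi <- .bisect_edge(function(b) stable_at(cand, b),
                           beta_grid[i1], beta_grid[i1 + 1], rel_precision,
                           rising = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        label = names(candidates)[ci], beta_lo = lo, beta_hi = hi,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), beta_lo = numeric(0),
               beta_hi = numeric(0))
  attr(out, "grid") <- grid_ok
  attr(out, "beta_grid") <- beta_grid
  out
}

# Bisect the predicate edge in (a, b); rising = TRUE means f is FALSE at a
# and TRUE at b and the returned value is the onset, else the offset.
.bisect_edge <- function(f, a, b, rel = 1e-3, rising = TRUE) {
  while ((b - a) > rel * max(abs(b), 1e-8)) {
    m <- (a + b) / 2
    if (f(m) == rising) b <- m else a <- m
  }
  if (rising) b else a
}
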