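#' Define a TF-overexpression reprogramming recipe
#'
#' A recipe is a set of transcription factors to overexpress transiently,
#' with per-factor activation degrees \eqn{\delta_j \ge 0}. During forcing,
#' the production term \eqn{\delta_j/\tau} is added to each targeted TF's
#' dynamics (constitutive expression without feedback), which deepens the
#' basins of cell types whose enhancers bind the overexpressed factors; the
#' forcing is then withdrawn and the state relaxes in the unperturbed
#' landscape. Defaults: \eqn{\delta = 1} per factor, 20 time units of
#' forcing, 20 of relaxation.
#'
#' @param factors character vector of TF names (or integer indices).
#' @param delta activation degree(s), recycled over `factors`; at least one
#'   must be positive.
#' @param duration forcing time (> 0).
#' @param relax relaxation time after withdrawal.
#' @return A `fatenet_recipe` object.
#' @export
recipe <- function(factors, delta = 1, duration = 20, relax = 20) {
  if (!length(factors)) stop("a recipe needs at least one factor")
  delta <- rep_len(delta, length(factors))
  if (any(delta < 0)) stop("delta must be nonnegative")
  if (all(delta == 0)) stop("at least one delta must be positive")
  stopifnot_scalar(duration, "duration", lower = 0, strict = TRUE)
  stopifnot_scalar(relax, "relax", lower = 0)
  structure(list(factors = factors, delta = delta, duration = duration,
                 relax = relax), class = "fatenet_recipe")
}

#' @export
print.fatenet_recipe <- function(x, ...) {
  cat(sprintf("Reprogramming recipe: %s (forcing %g, relaxation %g)\n",
              paste(sprintf("%s (delta=%g)", x$factors, x$delta),
                    collapse = ", "),
              x$duration, x$relax))
  invisible(x)
}

.recipe_delta <- function(net, rec) {
  d <- numeric(ncol(net$binding))
  idx <- if (is.character(rec$factors)) {
    match(rec$factors, net$tf_names)
  } else as.integer(rec$factors)
  if (anyNA(idx) || any(idx < 1 | idx > length(d))) {
    stop("recipe names TFs absent from the network: ",
         paste(rec$factors[is.na(idx) | idx < 1 | idx > length(d)],
               collapse = ", "))
  }
  d[idx] <- rec$delta
  d
}

#' Apply a reprogramming recipe by simulation
#'
#' Simulates transient overexpression: forcing for `recipe$duration`, then
#' free relaxation for `recipe$relax`. Success means the final identity
#' differs from the source identity and the final state is committed
#' (cosine distance below `commit_tol`).
#'
#' @param net a [fatenet] object.
#' @param x0 starting state, normally at (or near) an attractor.
#' @param recipe a [recipe()].
#' @param noise optional [noise_spec()]; `seed` as in [simulate.fatenet()].
#' @param commit_tol commitment threshold on the final cosine distance.
#' @param seed RNG seed for stochastic runs.
#' @return List with `trajectory` (forcing and relaxation concatenated),
#'   `source`, `final` (identity labels), `distance` and `success`.
#' @export
apply_recipe <- function(net, x0, recipe, noise = NULL, seed = NULL,
                         commit_tol = 0.05) {
  delta <- .recipe_delta(net, recipe)
  src <- assign_identity(net, x0)
  tr1 <- simulate.fatenet(net, x0 = x0, tspan = c(0, recipe$duration),
                          forcing = delta, noise = noise, seed = seed)
  x1 <- tr1$states[nrow(tr1$states), ]
  ns2 <- if (!is.null(noise) && noise$sigma > 0) {
    noise_spec(noise$sigma, (noise$seed %||% seed) + 1L)
  } else NULL
  tr2 <- simulate.fatenet(net, x0 = x1,
                          tspan = c(recipe$duration,
                                    recipe$duration + max(recipe$relax, 1e-6)),
                          noise = ns2, seed = if (is.null(ns2)) NULL else seed)
  xf <- tr2$states[nrow(tr2$states), ]
  fin <- assign_identity(net, xf)
  traj <- .new_trajectory(net, c(tr1$times, tr2$times[-1]),
                          c(tr1$beta, tr2$beta[-1]),
                          rbind(tr1$states, tr2$states[-1, , drop = FALSE]),
                          seed = seed,
                          sigma = if (is.null(noise)) 0 else noise$sigma)
  list(trajectory = traj, source = src$label, final = fin$label,
       distance = fin$distance,
       success = fin$label != src$label && fin$distance < commit_tol)
}

#' Score a recipe against every cell type
#'
#' First-order landscape perturbation: overexpressing TFs with degrees
#' \eqn{\delta} deepens the potential well of pattern \eqn{i} by
#' \eqn{\sum_j \delta_j \xi_{i,j}} (the binding of the overexpressed factors
#' to the pattern's enhancer). A recipe steers the dynamics toward target
#' \eqn{k} when its score for \eqn{k} clearly exceeds the score of every
#' other pattern; the `margin` reports that gap. The ideal reprogramming
#' factor binds strongly and exclusively to the target's enhancer, i.e. is
#' highly and uniquely expressed in the target cell type.
#'
#' @param net a [fatenet] object.
#' @param target pattern index or enhancer name.
#' @param recipe a [recipe()].
#' @return List with `target_score`, `scores` (named, per pattern) and
#'   `margin` (target score minus best non-target score).
#' @export
recipe_score <- function(net, target, recipe) {
  if (is.character(target)) target <- match(target, net$enhancer_names)
  if (is.na(target) || target < 1 || target > nrow(net$binding)) {
    stop("invalid target pattern")
  }
  delta <- .recipe_delta(net, recipe)
  scores <- drop(.binding_eff(net) %*% delta)
  names(scores) <- net$enhancer_names
  margin <- if (length(scores) > 1) {
    scores[target] - max(scores[-target])
  } else scores[target]
  list(target_score = unname(scores[target]), scores = scores,
       margin = unname(margin))
}

#' Rank candidate reprogramming factors for a target cell type
#'
#' Greedy forward selection: factors are added one at a time, each time
#' choosing the TF that maximizes the resulting score margin for the
#' target; ties break alphabetically by TF name. Selection stops early if no
#' remaining factor improves the margin, so the margin is non-decreasing in
#' recipe size.
#'
#' @param net a [fatenet] object.
#' @param target pattern index or enhancer name.
#' @param max_factors maximum recipe size (>= 1).
#' @param delta activation degree used for every candidate factor.
#' @param duration,relax forwarded to [recipe()].
#' @return Data frame ranked by recipe size with columns `factors`
#'   (comma-separated), `margin`; attribute `"recipes"` holds the
#'   [recipe()] objects.
#' @export
rank_candidate_factors <- function(net, target, max_factors = 3, delta = 1,
                                   duration = 20, relax = 20) {
  if (max_factors < 1) stop("max_factors must be >= 1")
  chosen <- character(0)
  rows <- list(); recs <- list()
  best_prev <- -Inf
  pool <- sort(net$tf_names)
  for (size in seq_len(max_factors)) {
    cand <- setdiff(pool, chosen)
    if (!length(cand)) break
    margins <- vapply(cand, function(f) {
      recipe_score(net, target,
                   recipe(c(chosen, f), delta, duration, relax))$margin
    }, numeric(1))
    best <- max(margins)
    if (best <= best_prev) break
    pick <- cand[which(margins == best)[1]]  # pool is sorted: ties by name
    chosen <- c(chosen, pick)
    rec <- recipe(chosen, delta, duration, relax)
    rows[[size]] <- data.frame(factors = paste(chosen, collapse = ","),
                               margin = best, stringsAsFactors = FALSE)
    recs[[size]] <- rec
    best_prev <- best
  }
  out <- do.call(rbind, rows)
  attr(out, "recipes") <- recs
  out
}

#' Verify a recipe by replicate simulation
#'
#' Runs [apply_recipe()] once deterministically and `n_noise_replicates`
#' times with additive noise, counting the fraction of runs whose final
#' identity is the target.
#'
#' @param net a [fatenet] object.
#' @param source starting state, or a pattern index/name (the pattern row is
#'   used as the state).
#' @param target pattern index or enhancer name that counts as success.
#' @param recipe a [recipe()].
#' @param n_noise_replicates number of noisy replicates.
#' @param sigma noise amplitude for the replicates.
#' @param seed base RNG seed.
#' @param commit_tol commitment threshold.
#' @return List with `success_rate`, `n_runs` and the per-run `finals`.
#' @export
verify_recipe <- function(net, source, target, recipe,
                          n_noise_replicates = 10, sigma = 0.01, seed = 1,
                          commit_tol = 0.05) {
  if (is.character(target)) target <- match(target, net$enhancer_names)
  x0 <- if (length(source) == 1) {
    if (is.character(source)) source <- match(source, net$enhancer_names)
    .patterns(net)[source, ]
  } else .check_state(net, source)
  target_label <- net$enhancer_names[target]
  runs <- vector("list", n_noise_replicates + 1L)
  runs[[1]] <- apply_recipe(net, x0, recipe, commit_tol = commit_tol)
  for (r in seq_len(n_noise_replicates)) {
    runs[[r + 1L]] <- apply_recipe(net, x0, recipe,
                                   noise = noise_spec(sigma, seed + 2L * r),
                                   commit_tol = commit_tol)
  }
  finals <- vapply(runs, function(z) z$final, character(1))
  hits <- vapply(runs, function(z) {
    z$final == target_label && z$distance < commit_tol
  }, logical(1))
  list(success_rate = mean(hits), n_runs = length(runs), finals = finals)
}
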