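#' Differentiate by annealing the inverse temperature
#'
#' Runs [simulate.fatenet()] under a time-varying \eqn{\beta(t)} given by an
#' [anneal_schedule()], then relaxes for `terminal_relax` time units at the
#' terminal \eqn{\beta} so that the endpoint is a fixed point of the frozen
#' dynamics. A warning is raised if the terminal residual exceeds 1e-6.
#'
#' @param net a [fatenet] object.
#' @param x0 initial state; defaults to the mean of the pattern rows (the
#'   multipotent average).
#' @param schedule an [anneal_schedule()].
#' @param noise optional [noise_spec()].
#' @param seed RNG seed (used when `noise` carries none).
#' @param terminal_relax relaxation time appended at the terminal beta.
#' @param save_every sampling interval of the returned trajectory.
#' @return A `fatenet_trajectory`.
#' @examples
#' fx <- fixture_progenitor_toy()
#' tr <- anneal(fx$net, fx$x0, fx$schedule)
#' detect_plateaus(tr, fx$net)
#' @export
anneal <- function(net, x0 = NULL, schedule = anneal_schedule(),
                   noise = NULL, seed = NULL, terminal_relax = 20,
                   save_every = 0.25) {
  x0 <- x0 %||% colMeans(.patterns(net))
  total <- schedule$duration + terminal_relax
  traj <- simulate.fatenet(net, x0 = x0, tspan = c(0, total),
                           beta_schedule = schedule, noise = noise,
                           seed = seed, save_every = save_every)
  n <- length(traj$times)
  res <- vec_norm(drift(net, traj$states[n, ], beta = schedule$beta_end))
  if (res > 1e-6 && (is.null(noise) || noise$sigma == 0)) {
    warning(sprintf("terminal state is not settled (residual %.2g)", res))
  }
  traj
}

#' Detect progenitor plateaus along a trajectory
#'
#' Identifies maximal time intervals during which the instantaneous speed
#' \eqn{\lVert dx/dt \rVert} stays below `speed_threshold` for at least
#' `min_dwell` time units, excluding the terminal interval (the committed
#' endpoint is not a progenitor). Each plateau's representative state (the
#' interval midpoint) is matched to the nearest pattern or subset average by
#' cosine distance.
#'
#' The defaults follow the scale of the problem: the threshold is
#' \eqn{10^{-3}} of the typical pattern norm per \eqn{\tau}, and the
#' minimum dwell is \eqn{2\tau}.
#'
#' @param traj a `fatenet_trajectory`.
#' @param net the network that produced it (defaults to `traj$net`).
#' @param min_dwell minimum plateau duration.
#' @param speed_threshold speed below which the state counts as resting.
#' @param subsets optional candidate subsets forwarded to [label_state()].
#' @return Data frame of class `fatenet_plateaus` with `t_start`, `t_end`,
#'   `label`, `distance` and the matrix of representative states as
#'   attribute `"states"`. Zero rows when no plateau qualifies.
#' @export
detect_plateaus <- function(traj, net = traj$net, min_dwell = 2 * net$tau,
                            speed_threshold = NULL, subsets = NULL) {
  if (!length(traj$times)) stop("empty trajectory")
  speed_threshold <- speed_threshold %||%
    (1e-3 * stats::median(sqrt(rowSums(.patterns(net)^2))) / net$tau)
  sp <- .trajectory_speeds(traj)
  slow <- sp < speed_threshold
  r <- rle(slow); ends <- cumsum(r$lengths)
  rows <- list(); reps <- list()
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    i0 <- if (j == 1) 1L else ends[j - 1] + 1L
    i1 <- ends[j]
    if (i1 == length(slow)) next  # terminal interval
    if (traj$times[i1] - traj$times[i0] < min_dwell) next
    mid <- traj$states[round((i0 + i1) / 2), ]
    lab <- label_state(net, mid, tol = Inf, subsets = subsets)
    rows[[length(rows) + 1L]] <- data.frame(
      t_start = traj$times[i0], t_end = traj$times[i1],
      label = lab$label, distance = lab$distance, stringsAsFactors = FALSE)
    reps[[length(reps) + 1L]] <- mid
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t_start = numeric(0), t_end = numeric(0),
               label = character(0), distance = numeric(0))
  attr(out, "states") <- if (length(reps)) do.call(rbind, reps) else
    matrix(numeric(0), 0, ncol(net$binding))
  attr(out, "speed_threshold") <- speed_threshold
  class(out) <- c("fatenet_plateaus", class(out))
  out
}

#' Assign a cell identity to a state
#'
#' Nearest pattern row by cosine distance; exact ties are broken toward the
#' lowest row index and flagged.
#'
#' @param net a [fatenet] object.
#' @param x expression state.
#' @return List with `label` (enhancer name), `distance` and `tie`.
#' @export
assign_identity <- function(net, x) {
  x <- .check_state(net, x)
  pats <- .patterns(net)
  d <- vapply(seq_len(nrow(pats)), function(i) cosine_distance(x, pats[i, ]),
              numeric(1))
  i <- which.min(d)
  list(label = net$enhancer_names[i], distance = d[i],
       tie = sum(d - d[i] < 1e-9) > 1L)
}

#' Balanced differentiation with signalling feedback
#'
#' Repeats annealed differentiation from the multipotent average and applies
#' negative feedback on the signalling weights: after each run committing to
#' lineage \eqn{i}, \eqn{w_i} is decremented by \eqn{0.5\,(1 - k/k_{max})}
#' (runs indexed \eqn{k = 0, \dots, k_{max}-1}) and \eqn{w} is re-centred to
#' mean zero. The feedback mimics population-level inhibition of each cell
#' type's own production and balances the lineage output without touching
#' the binding or coupling matrices -- signalling controls production, not
#' identity. Noise is required for the runs to explore different lineages.
#'
#' @param net a [fatenet] object; its weights are used as the starting
#'   signalling state after being reset to zero.
#' @param k_max number of differentiation runs (>= 1).
#' @param schedule annealing schedule (default: linear 0 to 50 over 50 time
#'   units).
#' @param sigma additive noise amplitude.
#' @param seed RNG seed (one stream drives all runs).
#' @param commit_tol runs whose terminal state is farther than this cosine
#'   distance from every pattern are counted as `"uncommitted"`.
#' @param keep_trajectories store the per-run trajectories (memory-heavy for
#'   large `k_max`).
#' @return List with `counts` (named lineage counts, including
#'   `uncommitted`), `weights` (final w), `labels` (per-run outcomes),
#'   `final_states` and optionally `trajectories`.
#' @export
balanced_differentiation <- function(net, k_max = 100,
                                     schedule = anneal_schedule(0, 50, 50),
                                     sigma = 0.01, seed = 1,
                                     commit_tol = 0.1,
                                     keep_trajectories = FALSE) {
  if (k_max < 1) stop("k_max must be >= 1")
  E <- nrow(net$binding)
  w <- numeric(E)
  x0 <- colMeans(.patterns(net))
  labels <- character(k_max)
  finals <- matrix(NA_real_, k_max, ncol(net$binding))
  trajs <- if (keep_trajectories) vector("list", k_max) else NULL
  counts <- stats::setNames(numeric(E), net$enhancer_names)
  uncommitted <- 0
  for (k in seq_len(k_max) - 1L) {
    run_net <- .update_net(net, weights = w)
    ns <- if (sigma > 0) noise_spec(sigma, seed = seed + k) else NULL
    traj <- simulate.fatenet(run_net, x0 = x0,
                             tspan = c(0, schedule$duration + 20),
                             beta_schedule = schedule, noise = ns,
                             save_every = schedule$duration / 50)
    xT <- traj$states[nrow(traj$states), ]
    id <- assign_identity(net, xT)
    finals[k + 1L, ] <- xT
    if (id$distance <= commit_tol) {
      labels[k + 1L] <- id$label
      counts[id$label] <- counts[id$label] + 1
      i <- match(id$label, net$enhancer_names)
      w[i] <- w[i] - 0.5 * (1 - k / k_max)
      w <- w - mean(w)
    } else {
      labels[k + 1L] <- "uncommitted"
      uncommitted <- uncommitted + 1
    }
    if (keep_trajectories) trajs[[k + 1L]] <- traj
  }
  out <- list(counts = c(counts, uncommitted = uncommitted), weights = w,
              labels = labels, final_states = finals)
  if (keep_trajectories) out$trajectories <- trajs
  out
}

#' Hierarchical lineage tree from terminal expression profiles
#'
#' Agglomerative clustering of terminal cell-type profiles by pairwise
#' cosine distance. The resulting dendrogram is the model's estimate of the
#' differentiation hierarchy: progenitors appear between profiles of high
#' cosine similarity, so nested clusters correspond to nested progenitor
#' potency. Average linkage is the default; complete linkage is available.
#'
#' @param profiles matrix with one row per terminal cell type (rownames are
#'   labels) or a named list of vectors.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return A `fatenet_lineage_tree`: list with the `hclust` object, `labels`
#'   and the cosine-distance matrix. Profiles are sorted by label first so
#'   the result is independent of input order.
#' @export
lineage_tree <- function(profiles, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (is.list(profiles) && !is.data.frame(profiles)) {
    profiles <- do.call(rbind, profiles)
  }
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 profiles")
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("type", seq_len(nrow(profiles)))
  }
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  nrm <- sqrt(rowSums(profiles^2))
  if (any(nrm == 0)) {
    stop(sprintf("zero-norm profile: %s",
                 paste(rownames(profiles)[nrm == 0], collapse = ", ")))
  }
  u <- profiles / nrm
  D <- pmax(1 - tcrossprod(u), 0)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  structure(list(hclust = hc, labels = rownames(profiles), distances = D),
            class = "fatenet_lineage_tree")
}

#' @export
print.fatenet_lineage_tree <- function(x, ...) {
  cat(sprintf("Lineage tree over %d terminal types (%s linkage):\n",
              length(x$labels), x$hclust$method))
  cat(tree_to_newick(x), "\n")
  invisible(x)
}

#' Serialize a lineage tree to Newick text
#'
#' Branch lengths are differences of merge heights (cosine distances), so
#' leaf-to-root distance equals the root merge height. The output parses
#' with standard Newick readers.
#'
#' @param tree a `fatenet_lineage_tree` or `hclust` object.
#' @param digits significant digits for branch lengths.
#' @return A single Newick string, terminated by ";".
#' @export
tree_to_newick <- function(tree, digits = 10) {
  hc <- if (inherits(tree, "fatenet_lineage_tree")) tree$hclust else tree
  lab <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1))
  node_txt <- function(i, parent_h) {
    if (i < 0) {  # leaf
      sprintf("%s:%s", lab[-i], format(parent_h, digits = digits))
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%s",
              node_txt(hc$merge[i, 1], h), node_txt(hc$merge[i, 2], h),
              format(parent_h - h, digits = digits))
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  sprintf("(%s,%s);", node_txt(hc$merge[root, 1], h),
          node_txt(hc$merge[root, 2], h))
}
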