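#' Ensembles of closely related cell-type patterns
#'
#' Parameterizes a family of binary expression codes: K related cell types
#' share `N_prime` always-active TFs and differ over `N` variable TFs, of
#' which a fraction `eta` is active in each type (drawn at random);
#' `N_doubleprime` TFs are inactive throughout, and `K_prime` unrelated
#' types draw their active set uniformly over all TFs. All patterns have
#' unit Euclidean norm, so the active level is
#' \eqn{a = (\eta N + N')^{-1/2}}. The number of active variable TFs is the
#' rounded count `round(eta * N)`.
#'
#' @param K number of related patterns (>= 1).
#' @param N number of variable TF positions.
#' @param eta active fraction among the variable positions, in (0, 1].
#' @param K_prime number of unrelated patterns.
#' @param N_prime number of always-active positions.
#' @param N_doubleprime number of always-inactive positions.
#' @param seed RNG seed used by [sample_pattern_family()].
#' @return A `pattern_family` parameter object.
#' @examples
#' fam <- pattern_family(K = 10, N = 30, eta = 0.2, seed = 1)
#' Xi <- sample_pattern_family(fam)$binding
#' dim(Xi)
#' @export
pattern_family <- function(K, N, eta, K_prime = 0, N_prime = 0,
                           N_doubleprime = 0, seed = 1) {
  if (K < 1 || N < 0 || K_prime < 0 || N_prime < 0 || N_doubleprime < 0) {
    stop("counts must be nonnegative and K >= 1")
  }
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]")
  n_var <- round(eta * N)
  if (K >= 2 && n_var < 1) {
    stop("eta * N must be >= 1 when K >= 2, otherwise related patterns are identical")
  }
  if (n_var + N_prime < 1) stop("patterns would have no active TFs")
  structure(list(K = K, K_prime = K_prime, N = N, N_prime = N_prime,
                 N_doubleprime = N_doubleprime, eta = eta, n_var = n_var,
                 a = 1 / sqrt(n_var + N_prime), seed = seed),
            class = "pattern_family")
}

#' @export
print.pattern_family <- function(x, ...) {
  cat(sprintf(
    "Pattern family: K = %d related (+%d unrelated), N = %d variable TFs,\n",
    x$K, x$K_prime, x$N))
  cat(sprintf(
    "  eta = %g (%d active variable TFs), N' = %d, N'' = %d, a = %.4g\n",
    x$eta, x$n_var, x$N_prime, x$N_doubleprime, x$a))
  invisible(x)
}

#' Sample a binding matrix from a pattern-family ensemble
#'
#' Related rows share the always-active block and draw their active variable
#' positions uniformly without replacement; unrelated rows draw the same
#' number of active positions uniformly over all TFs. Duplicate rows are
#' rejected and redrawn (bounded retries); an error is raised when the
#' ensemble cannot hold K distinct patterns.
#'
#' @param params a [pattern_family()].
#' @param seed optional override of the family's seed.
#' @return List with `binding` (rows = patterns, unit norm), `family`
#'   (factor: `"related"` / `"unrelated"`) and `params`.
#' @export
sample_pattern_family <- function(params, seed = NULL) {
  p <- params
  seed <- seed %||% p$seed
  T_ <- p$N + p$N_prime + p$N_doubleprime
  n_act <- p$n_var + p$N_prime
  if (p$K >= 2 && lchoose(p$N, p$n_var) < log(p$K)) {
    stop(sprintf(
      "cannot draw %d distinct related patterns: only choose(%d, %d) distinct codes exist",
      p$K, p$N, p$n_var))
  }
  var_cols <- seq_len(p$N)
  act_cols <- if (p$N_prime > 0) p$N + seq_len(p$N_prime) else integer(0)
  Xi <- matrix(0, p$K + p$K_prime, T_)
  with_seed(seed, {
    seen <- new.env(hash = TRUE)
    draw_unique <- function(make_row) {
      for (try in 1:1000) {
        r <- make_row()
        key <- paste(r, collapse = ",")
        if (is.null(seen[[key]])) { seen[[key]] <- TRUE; return(r) }
      }
      stop("could not draw a distinct pattern after 1000 retries")
    }
    for (k in seq_len(p$K)) {
      cols <- draw_unique(function() {
        sort(c(sample(var_cols, p$n_var), act_cols))
      })
      Xi[k, cols] <- p$a
    }
    for (k in seq_len(p$K_prime)) {
      cols <- draw_unique(function() sort(sample(T_, n_act)))
      Xi[p$K + k, cols] <- p$a
    }
  })
  rownames(Xi) <- c(paste0("rel", seq_len(p$K)),
                    if (p$K_prime > 0) paste0("unr", seq_len(p$K_prime)))
  colnames(Xi) <- paste0("TF", seq_len(T_))
  list(binding = Xi,
       family = factor(rep(c("related", "unrelated"), c(p$K, p$K_prime)),
                       levels = c("related", "unrelated")),
       params = p)
}

#' Analytic similarity statistics of a pattern family
#'
#' Closed forms under the ensemble construction:
#' within-family mean inner product
#' \eqn{A = (\eta^2 N + N') / (\eta N + N')}, cross-family mean inner
#' product \eqn{B = (\eta N + N') / (N + N' + N'')}, and the inner product
#' of a pattern with its two-bit variant \eqn{C = 1 - 1/(\eta N + N')}.
#' With `discrete = TRUE` (default) the rounded active count
#' `round(eta * N)` replaces \eqn{\eta N}, matching the sampled matrices;
#' the continuous forms use \eqn{\eta} exactly.
#'
#' @param params a [pattern_family()].
#' @param discrete use the rounded active-variable count.
#' @return List with `A`, `B`, `C`.
#' @export
similarity_stats <- function(params, discrete = TRUE) {
  p <- params
  nv <- if (discrete) p$n_var else p$eta * p$N
  n_act <- nv + p$N_prime
  A <- if (p$N > 0) (nv^2 / p$N + p$N_prime) / n_act else 1
  B <- n_act / (p$N + p$N_prime + p$N_doubleprime)
  C <- 1 - 1 / n_act
  list(A = A, B = B, C = C)
}

#' Measured similarity statistics of a sampled family
#'
#' @param binding pattern matrix (rows = patterns).
#' @param family factor/vector marking `"related"` vs `"unrelated"` rows;
#'   default treats all rows as related.
#' @return List with `A` (mean within-related inner product) and `B` (mean
#'   related-vs-unrelated inner product, `NA` if no unrelated rows).
#' @export
empirical_similarity_stats <- function(binding, family = NULL) {
  G <- tcrossprod(binding)
  rel <- if (is.null(family)) rep(TRUE, nrow(binding)) else family == "related"
  gr <- G[rel, rel, drop = FALSE]
  A <- mean(gr[upper.tri(gr)])
  B <- if (any(!rel)) mean(G[rel, !rel]) else NA_real_
  list(A = A, B = B)
}

#' Energy of an averaged pattern under the two-level similarity model
#'
#' Potential of the average of `subset_size` unit-norm patterns whose
#' internal mean inner product is `A`, amid `K` patterns overall whose
#' similarity to (and within) the rest is `B`, at inverse temperature
#' `beta` (equal weights):
#' \deqn{V = \tfrac{M}{2} - \tfrac{1}{\beta}\log\left(n e^{\beta M} +
#'   (K - n) e^{\beta B}\right), \quad M = \frac{1 + (n-1)A}{n}.}
#' The energy depends only on the subset's cosine similarity to all
#' patterns and its internal cosine similarity. At large \eqn{\beta} the
#' subset-size term is negligible and single patterns (\eqn{A = 1}) are the
#' minima; at intermediate \eqn{\beta} larger, internally similar subsets
#' can have lower energy -- the progenitor regime.
#'
#' @param A internal mean inner product of the subset, |A| <= 1.
#' @param B background inner product, |B| <= 1.
#' @param subset_size number of patterns averaged (>= 1).
#' @param beta inverse temperature (> 0).
#' @param K total number of patterns (>= subset_size).
#' @return Scalar energy.
#' @export
averaged_pattern_energy <- function(A, B, subset_size, beta, K) {
  if (subset_size < 1 || K < subset_size) stop("need 1 <= subset_size <= K")
  if (abs(A) > 1 || abs(B) > 1) stop("|A| and |B| must be <= 1")
  stopifnot_scalar(beta, "beta", lower = 0, strict = TRUE)
  n <- subset_size
  M <- (1 + (n - 1) * A) / n
  terms <- c(log(n) + beta * M,
             if (K > n) log(K - n) + beta * B)
  M / 2 - logsumexp(terms) / beta
}

#' Critical inverse temperature for bipotent commitment
#'
#' For a bipotent progenitor (the average of two unit-norm patterns with
#' cosine similarity `A`, well separated from the rest), two analytic
#' thresholds are provided. `"commitment"` (default) is the
#' energy-crossing temperature at which the individual patterns drop below
#' the pair average in potential, \eqn{\beta_c = 4\ln 2/(1-A)}; this is the
#' form the specification-gain ratio builds on. `"destabilization"` is the
#' local pitchfork at which the pair average loses linear stability,
#' \eqn{\beta_c = 2/(1-A)}; this matches the endpoint of the numerical
#' stability interval of [bifurcation_scan_beta()]. Both diverge as
#' \eqn{A \to 1}: progenitors of similar fates persist over a wider range
#' of \eqn{\beta}.
#'
#' @param A cosine similarity of the pair, < 1.
#' @param type `"commitment"` or `"destabilization"`.
#' @return Critical beta (Inf when A = 1).
#' @export
critical_beta_bipotent <- function(A, type = c("commitment",
                                               "destabilization")) {
  type <- match.arg(type)
  if (any(A > 1)) stop("A must be <= 1")
  k <- if (type == "commitment") 4 * log(2) else 2
  ifelse(A == 1, Inf, k / (1 - A))
}

#' Critical inverse temperature for leaving the global average
#'
#' Energy-crossing temperature at which individual patterns drop below the
#' global average of K related patterns (mean internal inner product A):
#' \deqn{\beta_1 = \frac{2 \ln K}{(1 - A)(1 - 1/K)}.}
#' For K >> 1 this is \eqn{2\ln K/(1-A)}.
#'
#' @param A mean internal inner product, < 1.
#' @param K number of related patterns (>= 2).
#' @return Critical beta.
#' @export
critical_beta_global <- function(A, K) {
  if (K < 2) stop("K must be >= 2")
  if (any(A >= 1)) return(Inf)
  2 * log(K) / ((1 - A) * (1 - 1 / K))
}

#' Specification gain for evolving a new cell type
#'
#' Ratio \eqn{\chi} of the inverse temperature needed to individuate a
#' two-bit variant pair of cell types, \eqn{4\ln 2/(1 - C)}, to the inverse
#' temperature at which the multipotent average of the K-member family
#' first yields to individual patterns, \eqn{2\ln K/(1 - A)}:
#' \deqn{\chi = \frac{2 \ln 2 \; \eta (1 - \eta) N}{\ln K}.}
#' The gain depends only on the variable TFs and scales with the variance
#' \eqn{\eta(1-\eta)} of the active code among them; it is invariant to the
#' number of always-active TFs. \eqn{\chi > 1} means newly evolved sister
#' cell types demand a sharper enhancer competition than the ancestral
#' repertoire did.
#'
#' @param K number of related cell types, or a [pattern_family()].
#' @param N number of variable TFs (ignored when `K` is a family).
#' @param eta active fraction among variable TFs.
#' @return The gain \eqn{\chi}.
#' @examples
#' specification_gain_chi(K = 118, N = 68, eta = 0.1)  # ~1.78
#' @export
specification_gain_chi <- function(K, N = NULL, eta = NULL) {
  if (inherits(K, "pattern_family")) {
    N <- K$N; eta <- K$eta; K <- K$K
  }
  if (K < 2) stop("K must be >= 2")
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]")
  2 * log(2) * eta * (1 - eta) * N / log(K)
}

#' Two-threshold scan of a pattern family
#'
#' Measures by direct fixed-point analysis the two operational temperatures
#' of a sampled family: `beta_destabilize`, the smallest \eqn{\beta} at
#' which the global family average is no longer a stable fixed point
#' (refining from the average fails to converge, loses stability, or drifts
#' beyond `match_tol` cosine distance of the average), and
#' `beta_full_specification`, the smallest \eqn{\beta} at which every
#' family pattern is a distinct stable fixed point, each attracting a
#' 1\%-perturbed restart. With `scope = "variant_pair"` a two-bit variant
#' of the first pattern is appended and must individuate as well.
#'
#' Both thresholds are located by bisection between grid points. Note that
#' patterns and the multipotent average typically coexist as attractors
#' over a wide range of \eqn{\beta}, so the two operational thresholds need
#' not be ordered; see the package vignette for how they relate to the
#' analytic energy-crossing temperatures.
#'
#' @param binding pattern matrix (rows = unit-norm patterns), e.g. from
#'   [sample_pattern_family()].
#' @param beta_grid increasing grid bracketing both thresholds.
#' @param scope `"classes"` (the K sampled patterns) or `"variant_pair"`.
#' @param match_tol identity-retention cosine tolerance.
#' @param seed seed for the perturbed restarts.
#' @param rel_precision bisection precision.
#' @return List with `beta_destabilize`, `beta_full_specification`, `ratio`
#'   (full / destabilize) and `scope`.
#' @export
two_threshold_scan <- function(binding, beta_grid = 2^seq(0, 7, by = 0.5),
                               scope = c("classes", "variant_pair"),
                               match_tol = 0.05, seed = 1,
                               rel_precision = 1e-3) {
  scope <- match.arg(scope)
  Xi <- as.matrix(binding)
  if (scope == "variant_pair") Xi <- rbind(Xi, .two_bit_variant(Xi[1, ]))
  net <- fatenet(Xi, beta = 1)
  xbar <- colMeans(Xi)

  avg_ok <- function(beta) {
    fp <- refine_fixed_point(net, xbar, beta = beta, pre_relax = 0,
                             label = FALSE)
    fp$converged && fp$stable &&
      cosine_distance(unname(fp$x), xbar) <= match_tol
  }
  full_ok <- function(beta) .family_specified(net, Xi, beta, match_tol, seed)

  bd <- .first_edge(avg_ok, beta_grid, rel_precision, want = FALSE)
  bf <- .first_edge(full_ok, beta_grid, rel_precision, want = TRUE)
  list(beta_destabilize = bd, beta_full_specification = bf,
       ratio = bf / bd, scope = scope)
}

# Smallest beta on/within the grid where pred == want (assumes a single
# crossing; bisects the bracketing interval).
.first_edge <- function(pred, grid, rel, want) {
  vals <- logical(length(grid))
  hit <- NA_integer_
  for (i in seq_along(grid)) {
    vals[i] <- pred(grid[i])
    if (vals[i] == want) { hit <- i; break }
  }
  if (is.na(hit)) return(NA_real_)
  if (hit == 1L) return(grid[1])
  .bisect_edge(function(b) pred(b) == want, grid[hit - 1L], grid[hit], rel,
               rising = TRUE)
}

.two_bit_variant <- function(x) {
  act <- which(x > 0); inact <- which(x == 0)
  if (!length(act) || !length(inact)) {
    stop("pattern has no room for a two-bit variant")
  }
  v <- x
  v[act[1]] <- 0
  v[inact[1]] <- x[act[1]]
  v
}

# Every row of Xi is a distinct stable fixed point at beta, attracting a
# 1%-perturbed restart. Batched for speed; early exit on first failure.
.family_specified <- function(net, Xi, beta, match_tol, seed) {
  K <- nrow(Xi)
  pts <- matrix(NA_real_, K, ncol(Xi))
  for (k in seq_len(K)) {
    fp <- refine_fixed_point(net, Xi[k, ], beta = beta, pre_relax = 0,
                             max_iter = 60, label = FALSE)
    if (!fp$converged || !fp$stable) return(FALSE)
    if (cosine_distance(unname(fp$x), Xi[k, ]) > match_tol) return(FALSE)
    pts[k, ] <- unname(fp$x)
  }
  if (min(stats::dist(pts)) <= 1e-3) return(FALSE)
  pert <- with_seed(seed, {
    pts * (1 + 0.01 * matrix(stats::rnorm(length(pts)), nrow(pts)))
  })
  pert[pert < 0] <- 0
  X <- .relax_states(net, pert, beta = beta, t_end = 40)
  all(sqrt(rowSums((X - pts)^2)) < 1e-3)
}

#' Preset family for sparse neuronal identity codes
#'
#' Parameter preset emulating the combinatorial homeobox code of the
#' C. elegans nervous system: 118 neuron classes over 68 variably expressed
#' TFs with a sparse active fraction of 0.1.
#'
#' @param seed RNG seed carried by the returned [pattern_family()].
#' @param N_prime optional always-active block size.
#' @return A [pattern_family()] with K = 118, N = 68, eta = 0.1.
#' @export
fixture_celegans_family <- function(seed = 1, N_prime = 0) {
  pattern_family(K = 118, N = 68, eta = 0.1, K_prime = 0, N_prime = N_prime,
                 N_doubleprime = 0, seed = seed)
}
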