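#' Construct a TF-enhancer regulatory network model
#'
#' A `fatenet` object holds the parameterization of an enhancer-competition
#' model of cell identity. Each of the E enhancer types is characterized by a
#' row of the binding matrix \eqn{\Xi} (affinity of the enhancer for each of
#' the T identity transcription factors) and a row of the coupling matrix
#' \eqn{Q} (the rate at which transcription initiated at the enhancer produces
#' each TF). Enhancers compete for transcriptional machinery: at expression
#' state \eqn{x}, enhancer \eqn{i} initiates transcription with probability
#' \eqn{p_i \propto \exp(\beta \zeta_i \xi_i \cdot x + w_i)}, a Boltzmann
#' (softmax) competition whose sharpness is set by the effective inverse
#' temperature \eqn{\beta}. TF expression then relaxes as
#' \deqn{\tau \, dx/dt = Q^\top p(x) - x.}
#'
#' When \eqn{Q = \nu \Xi} for a positive scalar \eqn{\nu} (TFs bind the
#' enhancers that drive their own expression -- autoregulation), the dynamics
#' are a gradient flow of the potential returned by [potential()], and the
#' rows of \eqn{Q} are the attractor cell types at large \eqn{\beta}. The
#' `symmetric` flag is always recomputed from the matrices, never asserted by
#' the caller.
#'
#' @param binding E x T matrix of nonnegative binding affinities; rows are
#'   enhancer types, columns are TFs.
#' @param coupling E x T matrix of nonnegative transcription-coupling rates.
#'   Defaults to `binding` (the autoregulatory, symmetric case).
#' @param weights length-E vector of baseline log-activities (signalling
#'   input); default all zero.
#' @param beta effective inverse temperature, \eqn{\beta \ge 0}.
#' @param tau expression turnover timescale, \eqn{\tau > 0}; default 1.
#' @param gain optional length-E vector of enhancer-level (pioneer-factor)
#'   gains \eqn{\zeta_i \ge 0}; default all 1.
#' @param tf_names,enhancer_names optional identifier vectors; taken from
#'   `dimnames(binding)` when present.
#'
#' @return An object of class `fatenet` with components `binding`, `coupling`,
#'   `weights`, `gain`, `beta`, `tau`, `tf_names`, `enhancer_names`,
#'   `symmetric` (logical) and `nu` (the fitted proportionality constant when
#'   symmetric, `NA` otherwise).
#'
#' @examples
#' xi <- rbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1)) / sqrt(2)
#' net <- fatenet(xi, beta = 20)
#' net
#' drift(net, c(1, 0, 0, 0) / sqrt(2))
#' @seealso [network_from_profiles()] to fit a network from expression data,
#'   [simulate.fatenet()], [enumerate_attractors()], [potential()].
#' @export
fatenet <- function(binding, coupling = binding, weights = NULL, beta = 10,
                    tau = 1, gain = NULL, tf_names = NULL,
                    enhancer_names = NULL) {
  binding <- as.matrix(binding)
  coupling <- as.matrix(coupling)
  if (!all(dim(binding) == dim(coupling))) {
    stop(sprintf(
      "binding is %d x %d but coupling is %d x %d; shapes must agree",
      nrow(binding), ncol(binding), nrow(coupling), ncol(coupling)))
  }
  E <- nrow(binding); T_ <- ncol(binding)
  if (E < 1L || T_ < 1L) stop("need at least one enhancer and one TF")
  weights <- weights %||% numeric(E)
  gain <- gain %||% rep(1, E)
  if (length(weights) != E) {
    stop(sprintf("weights has length %d, expected E = %d", length(weights), E))
  }
  if (length(gain) != E) {
    stop(sprintf("gain has length %d, expected E = %d", length(gain), E))
  }
  if (any(binding < 0)) stop("binding affinities must be nonnegative")
  if (any(coupling < 0)) stop("coupling rates must be nonnegative")
  if (any(gain < 0)) stop("gain must be nonnegative")
  stopifnot_scalar(beta, "beta", lower = 0)
  stopifnot_scalar(tau, "tau", lower = 0, strict = TRUE)

  tf_names <- tf_names %||% colnames(binding) %||% paste0("TF", seq_len(T_))
  enhancer_names <- enhancer_names %||% rownames(binding) %||%
    paste0("EN", seq_len(E))
  if (anyDuplicated(tf_names)) stop("TF names must be unique")
  if (anyDuplicated(enhancer_names)) stop("enhancer names must be unique")
  dimnames(binding) <- dimnames(coupling) <- list(enhancer_names, tf_names)

  sym <- .fit_symmetry(binding, coupling)
  structure(
    list(binding = binding, coupling = coupling, weights = unname(weights),
         gain = unname(gain), beta = beta, tau = tau, tf_names = tf_names,
         enhancer_names = enhancer_names, symmetric = sym$symmetric,
         nu = sym$nu),
    class = "fatenet")
}

# Least-squares fit of coupling = nu * binding; symmetric iff the residual
# is below 1e-9 elementwise.
.fit_symmetry <- function(binding, coupling) {
  ss <- sum(binding^2)
  if (ss == 0) return(list(symmetric = FALSE, nu = NA_real_))
  nu <- sum(binding * coupling) / ss
  if (nu > 0 && max(abs(coupling - nu * binding)) <= 1e-9) {
    list(symmetric = TRUE, nu = nu)
  } else {
    list(symmetric = FALSE, nu = NA_real_)
  }
}

# Gain-scaled binding matrix (rows zeta_i * xi_i); the form entering scores.
.binding_eff <- function(net) net$gain * net$binding

# Identity templates: the attractor cell types are the rows of Q.
.patterns <- function(net) net$coupling

#' @export
print.fatenet <- function(x, ...) {
  cat(sprintf("TF-enhancer attractor network (%d enhancer types, %d TFs)\n",
              nrow(x$binding), ncol(x$binding)))
  cat(sprintf("  beta = %g, tau = %g, %s (nu = %s)\n", x$beta, x$tau,
              if (x$symmetric) "symmetric: Q = nu * Xi" else "asymmetric",
              if (x$symmetric) format(x$nu) else "-"))
  if (any(x$weights != 0)) {
    cat("  weights:", paste(format(signif(x$weights, 3)), collapse = " "), "\n")
  }
  if (any(x$gain != 1)) {
    cat("  gain:", paste(format(signif(x$gain, 3)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Summarize a regulatory network model
#'
#' Reports dimensions, symmetry, the pairwise cosine-similarity range of the
#' identity patterns (rows of the coupling matrix) and, for each pattern,
#' whether it is a stable fixed point at the network's inverse temperature.
#'
#' @param object a [fatenet] object.
#' @param ... unused.
#' @return A list of class `summary.fatenet`.
#' @export
summary.fatenet <- function(object, ...) {
  pats <- .patterns(object)
  nrm <- sqrt(rowSums(pats^2))
  cs <- NULL
  if (nrow(pats) >= 2) {
    u <- pats / pmax(nrm, .Machine$double.eps)
    g <- tcrossprod(u)
    cs <- range(g[upper.tri(g)])
  }
  rep_ <- pattern_stability_report(object)
  out <- list(n_enhancers = nrow(pats), n_tfs = ncol(pats),
              beta = object$beta, tau = object$tau,
              symmetric = object$symmetric, nu = object$nu,
              pattern_norm_range = range(nrm), cosine_range = cs,
              stability = rep_)
  class(out) <- "summary.fatenet"
  out
}

#' @export
print.summary.fatenet <- function(x, ...) {
  cat(sprintf("Network: %d enhancer types, %d TFs, beta = %g, %s\n",
              x$n_enhancers, x$n_tfs, x$beta,
              if (x$symmetric) "symmetric" else "asymmetric"))
  cat(sprintf("Pattern norms in [%.3g, %.3g]\n",
              x$pattern_norm_range[1], x$pattern_norm_range[2]))
  if (!is.null(x$cosine_range)) {
    cat(sprintf("Pairwise pattern cosine similarity in [%.3g, %.3g]\n",
                x$cosine_range[1], x$cosine_range[2]))
  }
  ns <- sum(x$stability$is_stable)
  cat(sprintf("%d / %d patterns are stable fixed points at beta = %g\n",
              ns, nrow(x$stability), x$beta))
  invisible(x)
}

#' Extract model parameters
#'
#' @param object a [fatenet] object.
#' @param ... unused.
#' @return Named list with `binding`, `coupling`, `weights`, `gain`, `beta`,
#'   `tau`.
#' @export
coef.fatenet <- function(object, ...) {
  object[c("binding", "coupling", "weights", "gain", "beta", "tau")]
}

# Replace fields and recompute derived state (symmetry).
.update_net <- function(net, ...) {
  args <- list(...)
  for (nm in names(args)) net[[nm]] <- args[[nm]]
  fatenet(net$binding, net$coupling, net$weights, net$beta, net$tau, net$gain,
          net$tf_names, net$enhancer_names)
}
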