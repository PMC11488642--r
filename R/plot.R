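#' Plot a simulated trajectory
#'
#' Base-graphics view of a trajectory: TF expression (or enhancer
#' activities) against time, with the annealing profile \eqn{\beta(t)}
#' overlaid on a secondary axis when it varies.
#'
#' @param x a `fatenet_trajectory`.
#' @param what `"expression"` or `"activities"`.
#' @param ... forwarded to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.fatenet_trajectory <- function(x, what = c("expression", "activities"),
                                    ...) {
  what <- match.arg(what)
  Y <- if (what == "expression") x$states else x$activities
  graphics::matplot(x$times, Y, type = "l", lty = 1, xlab = "time",
                    ylab = what, ...)
  graphics::legend("topright", legend = colnames(Y), col = seq_len(ncol(Y)),
                   lty = 1, cex = 0.7, bty = "n")
  if (diff(range(x$beta)) > 0) {
    usr <- graphics::par("usr")
    b <- x$beta / max(x$beta) * usr[4]
    graphics::lines(x$times, b, col = "grey40", lty = 2)
    graphics::axis(4, at = pretty(c(0, usr[4])),
                   labels = signif(pretty(c(0, usr[4])) / usr[4] *
                                     max(x$beta), 2))
    graphics::mtext("beta", side = 4, line = 2, col = "grey40")
  }
  invisible(x)
}

#' Plot the binding structure of a network
#'
#' Heat image of the (gain-scaled) binding matrix, enhancers by TFs.
#'
#' @param x a [fatenet] object.
#' @param ... forwarded to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.fatenet <- function(x, ...) {
  M <- .binding_eff(x)
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)), t(M[rev(seq_len(nrow(M))), , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  xlab = "TF", ylab = "enhancer type", axes = FALSE, ...)
  graphics::axis(1, seq_len(ncol(M)), x$tf_names, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(M)), rev(x$enhancer_names), las = 1,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Plot a lineage tree
#'
#' @param x a `fatenet_lineage_tree`.
#' @param ... forwarded to the dendrogram plot.
#' @return `x`, invisibly.
#' @export
plot.fatenet_lineage_tree <- function(x, ...) {
  plot(stats::as.dendrogram(x$hclust), ylab = "cosine distance", ...)
  invisible(x)
}
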