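#' Read a cell-type expression matrix from CSV/TSV
#'
#' Expects a header row of cell-type names and a first column of gene
#' names. The delimiter is inferred from the file extension and content
#' unless forced. Duplicated gene or cell-type names, missing values and
#' negative entries are rejected with explicit errors.
#'
#' @param path file path.
#' @param sep optional delimiter ("," or "\\t"); inferred when NULL.
#' @return Numeric matrix, genes x cell types, with dimnames.
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t"
           else if (grepl(",", first)) ","
           else stop("could not infer the delimiter; pass 'sep'")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicated gene name(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicated cell-type name(s): ",
         paste(unique(names(df)[-1][duplicated(names(df)[-1])]),
               collapse = ", "))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values")
  if (anyNA(mat)) stop("missing values in the expression matrix")
  if (any(mat < 0)) stop("negative expression values")
  rownames(mat) <- genes
  mat
}

#' Write an expression matrix to CSV/TSV
#'
#' @param mat genes x cell types matrix with dimnames.
#' @param path output path; extension `.tsv` selects tab delimiting unless
#'   `sep` is given.
#' @param sep optional delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Preprocess an expression matrix for network construction
#'
#' Applies the log(1 + x) transform elementwise and keeps genes whose
#' row mean and row standard deviation (population, i.e. divisor n) both
#' strictly exceed their thresholds, log(4) by default. The log transform
#' reduces the variance of binding rows and hence the sensitivity of the
#' network to TF choice; the filter keeps TFs that are both expressed and
#' variable across cell types.
#'
#' @param mat genes x cell types matrix of nonnegative counts.
#' @param mean_threshold,std_threshold filter thresholds (>= 0), applied to
#'   the log-transformed values.
#' @param sd_type `"population"` (divisor n, default) or `"sample"`
#'   (divisor n - 1).
#' @return Filtered, log-transformed matrix in the original gene order.
#' @export
preprocess_expression <- function(mat, mean_threshold = log(4),
                                  std_threshold = log(4),
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (any(mat < 0)) stop("expression values must be nonnegative")
  lg <- log1p(mat)
  mu <- rowMeans(lg)
  n <- ncol(lg)
  v <- rowSums((lg - mu)^2) / if (sd_type == "population") n else (n - 1)
  keep <- mu > mean_threshold & sqrt(v) > std_threshold
  if (!any(keep)) stop("no genes survive filtering")
  lg[keep, , drop = FALSE]
}

#' Build a network from terminal cell-type expression profiles
#'
#' Parameterizes the model directly from data: each cell type's TF profile
#' becomes one enhancer-type row, normalized to unit Euclidean norm, with
#' coupling equal to binding (the autoregulatory case) and zero weights
#' unless supplied. When `beta` is omitted it is calibrated with
#' [calibrate_beta()] so that every observed cell type is a stable
#' attractor. Apart from \eqn{\beta} and the signalling weights the model
#' has no free parameters.
#'
#' @param mat genes (TFs) x cell types matrix, e.g. the output of
#'   [preprocess_expression()].
#' @param beta optional inverse temperature.
#' @param weights optional per-cell-type signalling weights.
#' @param beta_grid calibration grid when `beta` is missing.
#' @return A [fatenet] object with one enhancer type per cell type.
#' @export
network_from_profiles <- function(mat, beta = NULL, weights = NULL,
                                  beta_grid = c(1, 2, 5, 10, 20, 50, 100,
                                                200, 500)) {
  Xi <- t(as.matrix(mat))
  nrm <- sqrt(rowSums(Xi^2))
  if (any(nrm == 0)) {
    stop(sprintf("zero-norm expression profile for cell type: %s",
                 paste(rownames(Xi)[nrm == 0], collapse = ", ")))
  }
  Xi <- Xi / nrm
  dup <- duplicated(round(Xi, 9))
  if (any(dup)) {
    warning(sprintf(
      "duplicate expression profile(s): %s; consider reduce_to_types()",
      paste(rownames(Xi)[dup], collapse = ", ")))
  }
  net <- fatenet(Xi, weights = weights, beta = beta %||% 1)
  if (is.null(beta)) net <- .update_net(net, beta = calibrate_beta(net, beta_grid))
  net
}

#' Calibrate the inverse temperature so all patterns are stable
#'
#' Returns the smallest grid value of \eqn{\beta} at which every pattern of
#' the network is a stable fixed point per [pattern_stability_report()].
#'
#' @param net a [fatenet] object.
#' @param beta_grid increasing candidate values.
#' @return The calibrated beta.
#' @export
calibrate_beta <- function(net, beta_grid = c(1, 2, 5, 10, 20, 50, 100, 200,
                                              500)) {
  for (b in beta_grid) {
    rep_ <- pattern_stability_report(net, beta = b)
    if (all(rep_$is_stable)) return(b)
  }
  stop("no beta on the grid stabilizes all patterns")
}

#' Write a trajectory or an attractor set to CSV
#'
#' Columns are `t`, `beta`, the expression coordinates `x:<TF>` and the
#' enhancer activities `p:<enhancer>`. Values are written with 17
#' significant digits so that reading the file back reproduces the numbers
#' exactly.
#'
#' @param traj a `fatenet_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$times, beta = traj$beta,
                   traj$states, traj$activities, check.names = FALSE)
  names(df) <- c("t", "beta",
                 paste0("x:", colnames(traj$states)),
                 paste0("p:", colnames(traj$activities)))
  .write_full_precision(df, path)
}

#' @rdname write_trajectory
#' @param aset a `fatenet_attractors` object.
#' @export
write_attractors <- function(aset, path) {
  df <- data.frame(label = aset$summary$label, stable = aset$summary$stable,
                   residual = aset$summary$residual, aset$states,
                   check.names = FALSE)
  names(df) <- c("label", "stable", "residual",
                 paste0("x:", colnames(aset$states)))
  .write_full_precision(df, path)
}

.write_full_precision <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a trajectory written by [write_trajectory()]
#'
#' @param path CSV path.
#' @param net the network the trajectory belongs to (restores classed
#'   structure); when NULL a bare list is returned.
#' @return A `fatenet_trajectory` (or bare list of the same fields).
#' @export
read_trajectory <- function(path, net = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  xc <- grep("^x:", names(df)); pc <- grep("^p:", names(df))
  out <- list(times = df$t, beta = df$beta,
              states = as.matrix(df[, xc, drop = FALSE]),
              activities = as.matrix(df[, pc, drop = FALSE]))
  colnames(out$states) <- sub("^x:", "", names(df)[xc])
  colnames(out$activities) <- sub("^p:", "", names(df)[pc])
  if (!is.null(net)) {
    out$net <- net
    out$sigma <- 0
    class(out) <- "fatenet_trajectory"
  }
  out
}
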