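#' Toy network of overlapping enhancer pairs (hierarchical differentiation)
#'
#' Nine TFs and six enhancer types; each enhancer binds exactly two TFs and
#' the enhancer pairs (1,2), (3,4), (5,6) overlap by a single shared TF
#' (layout EN1 = {TF1, TF2}, EN2 = {TF2, TF3}, EN3 = {TF4, TF5},
#' EN4 = {TF5, TF6}, EN5 = {TF7, TF8}, EN6 = {TF8, TF9}), so each pair has
#' cosine similarity 1/2 and the pairs are mutually orthogonal. Binding
#' rows are unit-normalized, the network is symmetric, and EN5 carries a
#' slight positive signalling weight \eqn{w_5 = 0.05} -- the induced fate.
#'
#' The bundled annealing schedule is staged: a hold at \eqn{\beta = 0}
#' (which erases the starting identity and parks the cell at the
#' multipotent average), a ramp, a pause inside the stability window of the
#' restricted progenitor (the average of EN5 and EN6, selected by the
#' signalling bias), and a final ramp to the terminal \eqn{\beta}. Annealed
#' from the EN1 pattern, the trajectory passes exactly two progenitors --
#' the global average and the {EN5, EN6} average -- before committing to
#' the induced pattern EN5.
#'
#' @param beta terminal inverse temperature of the network.
#' @return List of class `fatenet_fixture` with `net`, `x0` (the EN1
#'   pattern), `schedule`, `progenitors` (the expected plateau subsets) and
#'   `layout`.
#' @export
fixture_progenitor_toy <- function(beta = 20) {
  layout <- list(EN1 = c(1, 2), EN2 = c(2, 3), EN3 = c(4, 5),
                 EN4 = c(5, 6), EN5 = c(7, 8), EN6 = c(8, 9))
  Xi <- matrix(0, 6, 9,
               dimnames = list(names(layout), paste0("TF", 1:9)))
  for (i in seq_along(layout)) Xi[i, layout[[i]]] <- 1 / sqrt(2)
  w <- c(0, 0, 0, 0, 0.05, 0)
  net <- fatenet(Xi, weights = w, beta = beta)
  # staged anneal: hold 0, ramp at 0.2/time, pause at beta = 4.3 inside the
  # {EN5,EN6} progenitor window, ramp to the terminal beta
  b_mid <- 4.3; rate <- 0.2; hold0 <- 40; hold_mid <- 150
  t1 <- hold0; t2 <- t1 + b_mid / rate; t3 <- t2 + hold_mid
  t4 <- t3 + (beta - b_mid) / rate
  schedule <- anneal_schedule(times = c(0, t1, t2, t3, t4),
                              betas = c(0, 0, b_mid, b_mid, beta))
  structure(list(net = net, x0 = Xi[1, ], schedule = schedule,
                 progenitors = list(global = 1:6, pair = c(5, 6)),
                 induced = "EN5", layout = layout),
            class = "fatenet_fixture")
}

#' @export
print.fatenet_fixture <- function(x, ...) {
  print(x$net)
  if (!is.null(x$schedule)) print(x$schedule)
  invisible(x)
}

#' Physical-enhancer network for the evolution of sister cell types
#'
#' Builds the shadow-enhancer scenario for genetic individuation: an
#' ancestral cell type expresses TF1-TF4 through enhancer copies placed
#' adjacent to each of the four TFs (each copy drives only its adjacent
#' gene) plus two shadow copies near TF1 and two near TF2. Because coupling
#' is per-adjacent-gene while binding is shared, the network has
#' \eqn{Q \neq \Xi} and the full physical-enhancer dynamics are exercised.
#'
#' Two variant binding profiles can arise by enhancer mutation:
#' EN1' binds TF1, TF2, TF3 (it lost the TF4 site) and EN1'' binds TF1,
#' TF2, TF4. A mutated copy binds its distinguishing TF at full site
#' affinity and retains a weaker (half) affinity for the shared TFs; rows
#' are unit-normalized. This concentration is what lets a sister type win
#' the enhancer competition decisively at its own state while remaining
#' uncompetitive at the ancestral state, so that ancestral and sister
#' attractors coexist.
#'
#' Stages:
#' \describe{
#'   \item{`"ancestral"`}{every copy binds TF1-TF4: a single family
#'     attractor (the ancestral type).}
#'   \item{`"mutated"`}{the TF3- and TF4-adjacent enhancers specialize to
#'     EN1'/EN1'' and the shadow copies near TF1 and TF2 diversify, one to
#'     each variant, while the TF1- and TF2-adjacent enhancers keep the
#'     ancestral binding: three stable family states coexist -- the
#'     ancestral type (TF1-4 active, TF3/TF4 reduced) and the two sister
#'     types (TF1, TF2 and either TF3 or TF4).}
#'   \item{`"destabilized"`}{the TF1/TF2-adjacent enhancers also lose
#'     their opposite-TF sites (no copy binds all four): the ancestral
#'     state survives only as a symmetry-protected saddle and any
#'     perturbation commits it to a sister; two family attractors remain.}
#' }
#' An optional background block adds two disjoint cell types on TF5-TF6 and
#' TF7-TF8 that stay stable attractors throughout -- evolution of the new
#' types does not interfere with the rest of the repertoire.
#'
#' The default inverse temperature sits mid-window: the three-attractor
#' coexistence of the mutated stage holds from roughly a quarter of the
#' default to far above it, so the stage properties are robust to at least
#' a +/-50\% uniform rescaling of all binding and coupling magnitudes at
#' fixed `beta` (a uniform magnitude factor s acts on the dynamics exactly
#' like replacing beta by s^2 beta).
#'
#' @param stage `"ancestral"`, `"mutated"` or `"destabilized"`.
#' @param include_background add the two background cell types.
#' @param scale uniform magnitude factor on binding and coupling.
#' @param beta inverse temperature (default 250).
#' @param shared_affinity residual site affinity of a variant copy for the
#'   shared TFs, relative to its distinguishing TF (default 0.5).
#' @return List of class `fatenet_fixture` with `net`, `stage`,
#'   `family_states` (ancestral and sister templates) and
#'   `background_states`.
#' @export
fixture_sister_evolution <- function(stage = c("ancestral", "mutated", "destabilized"),
                         include_background = TRUE, scale = 1, beta = 250,
                         shared_affinity = 0.5) {
  stage <- match.arg(stage)
  stopifnot_scalar(scale, "scale", lower = 0, strict = TRUE)
  u <- shared_affinity
  b4 <- c(1, 1, 1, 1); bA <- c(u, u, 1, 0); bB <- c(u, u, 0, 1)
  cp <- function(b, d, nm) list(b = b, d = d, nm = nm)
  copies <- switch(stage,
    ancestral = list(
      cp(b4, 1, "EN1.t1"), cp(b4, 2, "EN1.t2"),
      cp(b4, 3, "EN1.t3"), cp(b4, 4, "EN1.t4"),
      cp(b4, 1, "EN1.s1a"), cp(b4, 1, "EN1.s1b"),
      cp(b4, 2, "EN1.s2a"), cp(b4, 2, "EN1.s2b")),
    mutated = list(
      cp(b4, 1, "EN1.t1"), cp(b4, 2, "EN1.t2"),
      cp(bA, 3, "EN1p.t3"), cp(bB, 4, "EN1pp.t4"),
      cp(bA, 1, "EN1p.s1a"), cp(bB, 1, "EN1pp.s1b"),
      cp(bA, 2, "EN1p.s2a"), cp(bB, 2, "EN1pp.s2b")),
    destabilized = list(
      cp(bA, 1, "EN1p.t1"), cp(bB, 2, "EN1pp.t2"),
      cp(bA, 3, "EN1p.t3"), cp(bB, 4, "EN1pp.t4"),
      cp(bA, 1, "EN1p.s1a"), cp(bB, 1, "EN1pp.s1b"),
      cp(bA, 2, "EN1p.s2a"), cp(bB, 2, "EN1pp.s2b")))
  T_ <- if (include_background) 8 else 4
  if (include_background) {
    bg1 <- c(0, 0, 0, 0, 1, 1, 0, 0)[seq_len(T_)]
    bg2 <- c(0, 0, 0, 0, 0, 0, 1, 1)[seq_len(T_)]
    for (d in 5:6) copies <- c(copies, list(cp(bg1, d, paste0("BG1.t", d))))
    for (d in 7:8) copies <- c(copies, list(cp(bg2, d, paste0("BG2.t", d))))
  }
  E <- length(copies)
  Xi <- matrix(0, E, T_)
  Q <- matrix(0, E, T_)
  for (i in seq_len(E)) {
    b <- copies[[i]]$b
    b <- c(b, numeric(T_ - length(b)))
    Xi[i, ] <- scale * b / sqrt(sum(b^2))
    Q[i, copies[[i]]$d] <- scale
  }
  rownames(Xi) <- rownames(Q) <- vapply(copies, `[[`, character(1), "nm")
  colnames(Xi) <- colnames(Q) <- paste0("TF", seq_len(T_))
  net <- fatenet(Xi, Q, beta = beta)
  fam <- function(v) { x <- numeric(T_); x[v] <- scale; x }
  structure(list(
    net = net, stage = stage,
    family_states = list(ancestral = fam(1:4), sisterA = fam(c(1, 2, 3)),
                         sisterB = fam(c(1, 2, 4))),
    background_states = if (include_background) {
      list(bg1 = fam(5:6), bg2 = fam(7:8))
    } else list(),
    scale = scale), class = "fatenet_fixture")
}

#' Count the distinct stable family attractors of an evolution-stage fixture
#'
#' Relaxes the fixture's family template states (ancestral and both
#' sisters, plus slightly desymmetrized copies so that unstable symmetric
#' saddles are not mistaken for attractors), refines the endpoints and
#' counts distinct stable fixed points supported on the family TFs
#' (TF1-TF4). Background templates are counted separately.
#'
#' @param fx a [fixture_sister_evolution()] result.
#' @param dedup_tol Euclidean deduplication tolerance.
#' @return List with `n_family`, `n_background` and the stacked `states`.
#' @export
count_family_attractors <- function(fx, dedup_tol = 1e-3) {
  net <- fx$net
  starts <- fx$family_states
  # deterministic symmetry-breaking nudges (TF3 vs TF4)
  nudge <- function(x, eps) { x[3] <- x[3] * (1 + eps); pmax(x, 0) }
  starts <- c(starts, lapply(fx$family_states, nudge, eps = 0.02),
              lapply(fx$family_states, nudge, eps = -0.02))
  fam_pts <- list()
  for (x0 in starts) {
    X <- .relax_states(net, matrix(x0, 1L), t_end = 200)
    fp <- refine_fixed_point(net, X[1, ], pre_relax = 0, label = FALSE)
    if (!fp$converged || !fp$stable) next
    x <- unname(fp$x)
    if (sum(x[1:4]) < 1e-3) next  # escaped the family block
    dup <- any(vapply(fam_pts, function(g) vec_norm(g - x) < dedup_tol,
                      logical(1)))
    if (!dup) fam_pts[[length(fam_pts) + 1L]] <- x
  }
  bg_pts <- list()
  for (x0 in fx$background_states) {
    fp <- refine_fixed_point(net, x0, label = FALSE)
    if (!fp$converged || !fp$stable) next
    x <- unname(fp$x)
    dup <- any(vapply(bg_pts, function(g) vec_norm(g - x) < dedup_tol,
                      logical(1)))
    if (!dup) bg_pts[[length(bg_pts) + 1L]] <- x
  }
  list(n_family = length(fam_pts), n_background = length(bg_pts),
       states = do.call(rbind, c(fam_pts, bg_pts)))
}

#' Synthetic cell-type-by-TF expression matrix
#'
#' Emulates an averaged single-cell atlas: each cell type expresses a
#' sparse private block of identity TFs at high counts, optional shared
#' housekeeping-like TFs are expressed everywhere, and multiplicative
#' lognormal noise roughens the counts. Genes are rows, cell types are
#' columns, counts are nonnegative.
#'
#' @param n_types number of cell types.
#' @param tfs_per_type private identity TFs per type.
#' @param n_housekeeping TFs expressed across all types.
#' @param base_count expression of an identity TF in its own cell type.
#' @param background low off-target expression of identity TFs (keeps the
#'   row mean above the expressed-gene filter while preserving high
#'   between-type variability).
#' @param noise_sd lognormal sdlog of the multiplicative noise.
#' @param seed RNG seed.
#' @return Numeric matrix with gene rownames and cell-type colnames.
#' @export
synthetic_expression_matrix <- function(n_types = 6, tfs_per_type = 4,
                                        n_housekeeping = 5, base_count = 500,
                                        background = 2, noise_sd = 0.2,
                                        seed = 1) {
  G <- n_types * tfs_per_type + n_housekeeping
  mat <- matrix(background, G, n_types)
  for (ct in seq_len(n_types)) {
    rows <- (ct - 1) * tfs_per_type + seq_len(tfs_per_type)
    mat[rows, ct] <- base_count
  }
  if (n_housekeeping > 0) {
    hk <- n_types * tfs_per_type + seq_len(n_housekeeping)
    mat[hk, ] <- base_count * 40  # high and flat: removed by the std filter
  }
  with_seed(seed, {
    mat <- mat * matrix(stats::rlnorm(G * n_types, 0, noise_sd), G, n_types)
  })
  rownames(mat) <- c(paste0("Tf", seq_len(n_types * tfs_per_type)),
                     if (n_housekeeping > 0) paste0("Hk", seq_len(n_housekeeping)))
  colnames(mat) <- paste0("type", seq_len(n_types))
  round(mat, 3)
}

#' Synthetic nested-lineage expression profiles
#'
#' Builds terminal expression profiles for eight blood-like lineages whose
#' similarity structure encodes a known binary hierarchy: TFs are assigned
#' to the nodes of the tree and each lineage expresses the TF blocks of all
#' nodes on its root-to-leaf path, with weights increasing toward the leaf.
#' Pairwise cosine similarity is then monotone in the depth of the last
#' common ancestor, so average-linkage clustering on cosine distance
#' recovers the generating topology exactly; small multiplicative noise is
#' added to avoid exact ties.
#'
#' @param seed RNG seed.
#' @param block TFs per tree node.
#' @param noise_sd multiplicative lognormal noise.
#' @return List with `profiles` (8 x T matrix, rownames are lineage names)
#'   and `newick` (the generating topology, without branch lengths).
#' @export
synthetic_hematopoiesis_profiles <- function(seed = 1, block = 3,
                                             noise_sd = 0.05) {
  leaves <- c("Ery", "Mk", "Neu", "Mono", "B", "DC", "T", "NK")
  # path node ids per leaf: root(1); L(2)/R(3); 4..7; leaf nodes 8..15
  paths <- list(Ery = c(1, 2, 4, 8), Mk = c(1, 2, 4, 9),
                Neu = c(1, 2, 5, 10), Mono = c(1, 2, 5, 11),
                B = c(1, 3, 6, 12), DC = c(1, 3, 6, 13),
                T = c(1, 3, 7, 14), NK = c(1, 3, 7, 15))
  n_nodes <- 15
  T_ <- n_nodes * block
  depth_w <- c(1, 2, 4, 8)  # weight per depth: leaf-specific TFs dominate
  prof <- matrix(0, length(leaves), T_,
                 dimnames = list(leaves, paste0("TF", seq_len(T_))))
  for (i in seq_along(leaves)) {
    for (d in seq_along(paths[[i]])) {
      node <- paths[[i]][d]
      cols <- (node - 1) * block + seq_len(block)
      prof[i, cols] <- depth_w[d]
    }
  }
  with_seed(seed, {
    prof <- prof * matrix(stats::rlnorm(length(prof), 0, noise_sd),
                          nrow(prof))
  })
  newick <- "(((Ery,Mk),(Neu,Mono)),((B,DC),(T,NK)));"
  list(profiles = prof, newick = newick)
}
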