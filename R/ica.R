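#' MDL model-order selection from an eigenvalue spectrum
#'
#' Chooses the number of sources by minimizing the minimum-description-
#' length criterion computed from the eigenvalues of the frame-by-frame
#' data covariance: for each candidate order `k`, the log-likelihood term
#' compares the geometric and arithmetic means of the trailing
#' eigenvalues and the penalty is `0.5 k (2 p - k) log N` (`p` channels,
#' `N` effective samples).
#'
#' @param data numeric matrix frames x voxels (frames are the channels,
#'   voxels the samples), or `NULL` if `eigenvalues` is given.
#' @param eigenvalues optionally, the covariance eigenvalues directly.
#' @param n_samples effective sample count (defaults to the voxel count).
#' @return integer model order (the argmin over `k = 1 .. p - 1`).
#' @export
mdl_order <- function(data = NULL, eigenvalues = NULL, n_samples = NULL) {
  if (is.null(eigenvalues)) {
    stopifnot(is.matrix(data), nrow(data) >= 2L)
    x <- data - rowMeans(data)
    n_samples <- n_samples %||% ncol(data)
    eigenvalues <- eigen(tcrossprod(x) / ncol(x), symmetric = TRUE,
                         only.values = TRUE)$values
  }
  ev <- pmax(eigenvalues, .Machine$double.eps)
  p <- length(ev)
  N <- n_samples %||% p
  if (p < 2L) stop("degenerate spectrum")
  crit <- vapply(1:(p - 1L), function(k) {
    tail_ev <- ev[(k + 1L):p]
    g <- mean(log(tail_ev))
    a <- log(mean(tail_ev))
    -N * (p - k) * (g - a) + 0.5 * k * (2 * p - k) * log(N)
  }, 1)
  which.min(crit)
}

#' Subject-wise PCA reduction and temporal concatenation
#'
#' Reduces every subject's frames x voxels matrix to its leading temporal
#' principal components, stacks the reduced matrices, and applies a
#' second group-level PCA, recording the retained variance of both
#' stages and the projection matrices needed for back-reconstruction.
#'
#' @param runs list of frames x voxels matrices (one per subject, same
#'   voxel set).
#' @param n_pc_subject components kept per subject.
#' @param n_pc_group components kept at the group level.
#' @return list with `group` (reduced matrix, n_pc_group x voxels),
#'   `subject_proj` (list of n_pc_subject x frames projections),
#'   `group_proj` (n_pc_group x (S * n_pc_subject)), `var_subject`,
#'   `var_group`, `row_block` (index of each subject's block rows).
#' @export
reduce_and_concatenate <- function(runs, n_pc_subject, n_pc_group) {
  stopifnot(length(runs) >= 1L)
  V <- ncol(runs[[1]])
  subject_proj <- list(); reduced <- list(); var_subject <- numeric(0)
  for (i in seq_along(runs)) {
    X <- runs[[i]] - rowMeans(runs[[i]])
    if (n_pc_subject > nrow(X)) stop("requested PCs exceed frame count")
    e <- eigen(tcrossprod(X) / ncol(X), symmetric = TRUE)
    if (n_pc_subject > sum(e$values > 1e-12 * e$values[1]))
      stop("requested PCs exceed data rank")
    P <- t(e$vectors[, seq_len(n_pc_subject), drop = FALSE])
    subject_proj[[i]] <- P
    reduced[[i]] <- P %*% X
    var_subject[i] <- sum(e$values[seq_len(n_pc_subject)]) / sum(pmax(e$values, 0))
  }
  G <- do.call(rbind, reduced)
  if (n_pc_group > nrow(G)) stop("group PCs exceed stacked rows")
  Gc <- G - rowMeans(G)
  e <- eigen(tcrossprod(Gc) / ncol(Gc), symmetric = TRUE)
  if (n_pc_group > sum(e$values > 1e-12 * e$values[1]))
    stop("group PCs exceed stacked rank")
  R <- t(e$vectors[, seq_len(n_pc_group), drop = FALSE])
  nb <- nrow(reduced[[1]])
  list(group = R %*% Gc,
       subject_proj = subject_proj, group_proj = R,
       var_subject = var_subject,
       var_group = sum(e$values[seq_len(n_pc_group)]) / sum(pmax(e$values, 0)),
       row_block = lapply(seq_along(runs),
                          function(i) (i - 1L) * nb + seq_len(nb)))
}

#' Infomax independent component analysis
#'
#' Natural-gradient infomax with the logistic nonlinearity on whitened
#' data: `W <- W + lr * (I + (1 - 2 g(Y)) Y') W` over voxel minibatches,
#' with a fixed annealing schedule.  Converged when the maximum absolute
#' weight change drops below `tol`; otherwise the best iterate is
#' returned with a warning.
#'
#' @param X numeric matrix channels x samples (channels = model order;
#'   reduce first with [reduce_and_concatenate()]).
#' @param seed RNG seed (sample order and initial weights).
#' @param lr initial learning rate.
#' @param max_iter maximum sweeps through the data.
#' @param tol convergence tolerance on the weight update.
#' @param block minibatch size.
#' @return list with `S` (sources, channels x samples, unit variance),
#'   `W` (unmixing applied to the whitened data), `whitener`,
#'   `unwhitener`, `converged`, `iterations`.
#' @export
group_infomax <- function(X, seed = 1L, lr = 0.01 / log(nrow(X) + 1),
                          max_iter = 512L, tol = 1e-6, block = NULL) {
  k <- nrow(X); n <- ncol(X)
  if (k > n) stop("more channels than samples")
  set.seed(seed)
  X <- X - rowMeans(X)
  e <- eigen(tcrossprod(X) / n, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values))
    stop("input not full rank; reduce the order")
  wh <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
  unwh <- e$vectors %*% diag(sqrt(e$values))
  Z <- wh %*% X
  W <- diag(k) + 0.05 * matrix(rnorm(k * k), k)
  block <- block %||% max(64L, floor(sqrt(n / 3)))
  I_k <- diag(k)
  converged <- FALSE; it <- 0L
  anneal <- 0.97
  for (it in seq_len(max_iter)) {
    perm <- sample.int(n)
    W_old <- W
    for (start in seq(1L, n, by = block)) {
      idx <- perm[start:min(start + block - 1L, n)]
      Y <- W %*% Z[, idx, drop = FALSE]
      g <- 1 / (1 + exp(-Y))
      W <- W + lr * (I_k + (1 - 2 * g) %*% t(Y) / length(idx)) %*% W
      if (!all(is.finite(W))) stop("infomax diverged; lower the learning rate")
    }
    delta <- max(abs(W - W_old))
    if (delta < tol) { converged <- TRUE; break }
    if (delta > 1) lr <- lr * 0.5 else lr <- lr * anneal
  }
  if (!converged)
    warning("infomax did not fully converge after ", it, " sweeps")
  S <- W %*% Z
  sc <- apply(S, 1L, sd)
  S <- S / sc
  W <- W / sc
  list(S = S, W = W, whitener = wh, unwhitener = unwh,
       converged = converged, iterations = it)
}

#' Template-matching component selection
#'
#' Goodness of fit of each component map to a binary template: mean
#' z-score inside the template minus mean outside.  The best-matching
#' component is selected and sign-flipped so its inside-mean is positive.
#'
#' @param maps components x voxels matrix of z-scored spatial maps.
#' @param template logical/index vector marking template voxels within
#'   the map columns.
#' @return list of class `template_match` with `component`, `gof` (all
#'   scores, sign-corrected), `sign`, `map` (the selected, flipped map).
#' @export
template_match <- function(maps, template) {
  maps <- as.matrix(maps)
  if (is.logical(template)) template <- which(template)
  if (!length(template) || max(template) > ncol(maps))
    stop("empty or out-of-range template")
  inside <- rowMeans(maps[, template, drop = FALSE])
  outside <- rowMeans(maps[, -template, drop = FALSE])
  gof <- inside - outside
  comp <- which.max(abs(gof))
  sgn <- sign(gof[comp])
  if (sgn == 0) sgn <- 1
  structure(list(component = comp, gof = gof,
                 score = abs(gof[comp]), sign = sgn,
                 map = sgn * maps[comp, ]),
            class = "template_match")
}

#' GICA back-reconstruction of subject maps and time courses
#'
#' Projects one subject's data through the composed reduction and
#' unmixing transform: with subject reduction `P_i`, group-PCA block
#' `R_i` and unmixing `W` (on whitened group data), the subject map is
#' `pinv(W_w R_i) ' -> S_i = pinv(A_i) P_i X_i` where `A_i = pinv(W_w R_i)`
#' and `W_w` is the unmixing composed with the whitener.  The mean of the
#' subject maps approximates the group maps.
#'
#' @param run_data the subject's frames x voxels matrix (as entered into
#'   the concatenation).
#' @param reduction the [reduce_and_concatenate()] result.
#' @param ica the [group_infomax()] result on `reduction$group`.
#' @param subject index of the subject within the reduction.
#' @return list with `maps` (components x voxels) and `timecourses`
#'   (frames x components).
#' @export
back_reconstruct <- function(run_data, reduction, ica, subject) {
  n <- length(reduction$subject_proj)
  if (subject < 1L || subject > n)
    stop("subject not part of the decomposition")
  P <- reduction$subject_proj[[subject]]
  Rb <- reduction$group_proj[, reduction$row_block[[subject]], drop = FALSE]
  Ww <- ica$W %*% ica$whitener          # components x group-PC rows
  Mi <- Ww %*% Rb                       # components x subject-PC rows
  X <- run_data - rowMeans(run_data)
  Y <- P %*% X
  ## partitioned GICA back-projection: the group sources are the sum of
  ## the subject contributions, so scaling by n makes their mean the
  ## group map
  maps <- n * (Mi %*% Y)
  tc <- t(P) %*% MASS_pinv(Mi)          # frames x components
  list(maps = maps, timecourses = tc)
}

## Moore-Penrose pseudo-inverse via SVD (input n x k, returns k x n).
MASS_pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Spatial correlation between two maps
#'
#' @param map_a,map_b numeric vectors over the same voxel set.
#' @param mask optional logical/index subset.
#' @return Pearson r.
#' @export
map_spatial_correlation <- function(map_a, map_b, mask = NULL) {
  if (!is.null(mask)) { map_a <- map_a[mask]; map_b <- map_b[mask] }
  if (sd(map_a) == 0 || sd(map_b) == 0) stop("constant map")
  cor(map_a, map_b)
}

#' Group spatial ICA of one state with DMN component selection
#'
#' Runs the full ICA arm for one state: subject-wise PCA reduction,
#' temporal concatenation, group PCA, infomax, z-scoring of the
#' component maps, template matching, and back-reconstruction of every
#' subject's selected-component map.
#'
#' @param runs list of frames x voxels matrices (brain-masked), one per
#'   subject.
#' @param template template voxels (columns) marking the expected DMN.
#' @param order model order; `"auto"` selects by [mdl_order()] on the
#'   concatenated data.
#' @param n_pc_subject per-subject PCA order (default: `order + 5`,
#'   capped by frames).
#' @param seed RNG seed.
#' @return list of class `ica_decomposition` with the group `maps`
#'   (z-scored), the selected `match`, per-subject `subject_maps` of the
#'   selected component, `order`, `reduction`, `ica`.
#' @export
run_group_ica <- function(runs, template, order = "auto",
                          n_pc_subject = NULL, seed = 1L) {
  T <- nrow(runs[[1]])
  if (identical(order, "auto")) {
    ## order selected per subject, aggregated by the median
    orders <- vapply(runs, mdl_order, 1L)
    order <- as.integer(round(stats::median(orders)))
    order <- max(2L, min(order, T - 5L))
  }
  n_pc_subject <- min(n_pc_subject %||% (order + 5L), T - 1L)
  n_pc_subject <- max(n_pc_subject, order)
  red <- reduce_and_concatenate(runs, n_pc_subject, order)
  ica <- group_infomax(red$group, seed = seed)
  maps <- row_standardize(ica$S)
  match <- template_match(maps, template)
  subject_maps <- lapply(seq_along(runs), function(i) {
    br <- back_reconstruct(runs[[i]], red, ica, i)
    match$sign * as.numeric(row_standardize(
      br$maps[match$component, , drop = FALSE]))
  })
  structure(list(maps = maps, match = match, subject_maps = subject_maps,
                 order = order, reduction = red, ica = ica),
            class = "ica_decomposition")
}

#' ICA-arm state statistics
#'
#' Feeds back-reconstructed subject DMN maps (one per subject per state)
#' through the identical group-statistics chain as the seed arm: group
#' significance per state, union mask, repeated-measures ANOVA, cluster
#' filtering, retrospective classification, region assembly.
#'
#' @param subject_maps_by_state named list (per state) of voxels x
#'   subjects matrices of back-reconstructed component maps.
#' @param mask voxel indices of the map rows.
#' @param grid the `dmn_grid`.
#' @param seed a [seed_spec()] for stable-region tagging.
#' @param q FDR level.
#' @param method FDR variant.
#' @param min_cluster cluster-extent threshold (exclusive).
#' @param connectivity cluster adjacency.
#' @return list like the seed arm's region stage: `maps`, `union`,
#'   `anova`, `clusters`, `labels`, `region_set`.
#' @export
ica_state_statistics <- function(subject_maps_by_state, mask, grid,
                                 seed = seed_spec(), q = 0.05, method = "BY",
                                 min_cluster = 5L, connectivity = 26L) {
  stopifnot(setequal(names(subject_maps_by_state), dmn_states()))
  maps <- lapply(dmn_states(), function(st)
    group_significance(subject_maps_by_state[[st]], mask, st, q, method))
  names(maps) <- dmn_states()
  un <- union_mask(maps)
  rows <- match(un$voxels, mask)
  z_by_state <- lapply(subject_maps_by_state[dmn_states()],
                       function(m) m[rows, , drop = FALSE])
  anova <- voxelwise_rm_anova(z_by_state, un$voxels, q = q, method = method)
  clusters <- cluster_filter(anova$significant, grid, min_cluster,
                             connectivity)
  labels <- classify_voxels(z_by_state, un$voxels, clusters)
  rs <- define_regions(labels, un, anova$significant, grid, seed,
                       connectivity)
  list(maps = maps, union = un, anova = anova, clusters = clusters,
       labels = labels, region_set = rs)
}
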