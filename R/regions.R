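#' Union of the four states' significant connectivity maps
#'
#' Voxels significant (positive-t) in at least one state's group map,
#' with the per-state membership recorded.
#'
#' @param maps named list of four [group_significance()] results, one per
#'   state in [dmn_states()].
#' @return list of class `union_mask` with `voxels` (sorted indices) and
#'   `membership` (voxels x 4 logical matrix).
#' @export
union_mask <- function(maps) {
  if (!setequal(names(maps), dmn_states()))
    stop("need the four state maps ", paste(dmn_states(), collapse = ", "))
  maps <- maps[dmn_states()]
  vox <- sort(unique(unlist(lapply(maps, `[[`, "significant"))))
  membership <- vapply(maps, function(m) vox %in% m$significant,
                       logical(length(vox)))
  if (length(vox) == 1L) membership <- matrix(membership, 1L)
  dimnames(membership) <- list(NULL, dmn_states())
  structure(list(voxels = vox, membership = membership), class = "union_mask")
}

#' @export
print.union_mask <- function(x, ...) {
  cat(sprintf("<union_mask: %d voxels (%s)>\n", length(x$voxels),
              paste(dmn_states(), colSums(x$membership), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Voxelwise one-way repeated-measures ANOVA across states
#'
#' For every voxel of the mask, a one-way RM-ANOVA of the subjects'
#' Fisher-Z connectivity over the four states with subject as the
#' blocking factor: `F = MS_state / MS_error` on `(k - 1, (k - 1)(n - 1))`
#' degrees of freedom.  Multiple testing is handled by FDR across the
#' mask voxels.  An optional Greenhouse-Geisser correction rescales the
#' degrees of freedom by the sphericity estimate.
#'
#' @param z_by_state named list (one per state) of matrices, mask voxels
#'   x subjects, of Fisher-Z values; only subjects with all four states.
#' @param voxels the voxel indices the rows refer to.
#' @param q FDR level.
#' @param method FDR variant.
#' @param gg apply the Greenhouse-Geisser sphericity correction?
#' @return list with `F`, `p`, `significant` (voxel indices), `df`,
#'   `voxels`, and `epsilon` when `gg = TRUE`.
#' @export
voxelwise_rm_anova <- function(z_by_state, voxels, q = 0.05, method = "BY",
                               gg = FALSE) {
  stopifnot(setequal(names(z_by_state), dmn_states()))
  z_by_state <- lapply(z_by_state[dmn_states()], as.matrix)
  n <- ncol(z_by_state[[1]])
  k <- length(z_by_state)
  if (n < 2L) stop("need at least 2 subjects")
  if (!all(vapply(z_by_state, ncol, 1L) == n)) stop("missing subject cells")
  if (!all(vapply(z_by_state, nrow, 1L) == length(voxels)))
    stop("rows must align with `voxels`")

  sm <- lapply(z_by_state, rowMeans)              # state means per voxel
  SM <- Reduce(`+`, z_by_state) / k               # subject means (V x n)
  grand <- rowMeans(SM)
  ss_state <- n * Reduce(`+`, lapply(sm, function(m) (m - grand)^2))
  ss_subj <- k * rowSums((SM - grand)^2)
  ss_tot <- Reduce(`+`, lapply(z_by_state, function(z) rowSums((z - grand)^2)))
  ss_err <- pmax(ss_tot - ss_state - ss_subj, 0)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fv <- (ss_state / df1) / (ss_err / df2)
  Fv[ss_err == 0 & ss_state == 0] <- 0
  Fv[ss_err == 0 & ss_state > 0] <- Inf

  eps <- NULL
  if (gg) {
    ## Greenhouse-Geisser epsilon from the double-centred state covariance
    cent <- lapply(seq_len(k), function(j) z_by_state[[j]] - sm[[j]])
    Sjk <- array(0, c(length(voxels), k, k))
    for (j in seq_len(k)) for (l in j:k) {
      v <- rowSums(cent[[j]] * cent[[l]]) / (n - 1)
      Sjk[, j, l] <- v; Sjk[, l, j] <- v
    }
    eps <- vapply(seq_len(length(voxels)), function(v) {
      S <- Sjk[v, , ]
      C <- S - outer(rowMeans(S), rep(1, k)) -
        outer(rep(1, k), colMeans(S)) + mean(S)
      tr <- sum(diag(C))
      if (tr <= 0) return(1)
      min(1, max(1 / (k - 1), tr^2 / ((k - 1) * sum(C^2))))
    }, 1)
  }
  p <- if (gg) pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
       else pf(Fv, df1, df2, lower.tail = FALSE)
  p[!is.finite(Fv)] <- ifelse(is.infinite(Fv[!is.finite(Fv)]), 0, 1)
  p[Fv == 0] <- 1
  rej <- fdr_correct(p, q = q, method = method)
  list(F = Fv, p = p, significant = voxels[rej], df = c(df1, df2),
       voxels = voxels, epsilon = eps)
}

#' Connected-component cluster filtering
#'
#' Splits a voxel set into connected components under the configured 3D
#' adjacency and retains components strictly larger than `min_size`.
#'
#' @param sig_voxels integer voxel indices.
#' @param grid the `dmn_grid` the indices refer to.
#' @param min_size exclusive size threshold (default 5: clusters of 6 or
#'   more voxels survive).
#' @param connectivity 26 (default) or 6.
#' @return list of integer vectors, one per surviving cluster, largest
#'   first.
#' @export
cluster_filter <- function(sig_voxels, grid, min_size = 5L,
                           connectivity = 26L) {
  sig_voxels <- sort(unique(as.integer(sig_voxels)))
  if (!length(sig_voxels)) return(list())
  comps <- connected_components(sig_voxels, grid, connectivity)
  keep <- comps[lengths(comps) > min_size]
  keep[order(-lengths(keep))]
}

## Connected components of a voxel set via igraph.
connected_components <- function(voxels, grid, connectivity = 26L) {
  off <- neighbour_offsets(connectivity)
  off <- off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
               (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), ,
             drop = FALSE]  # half-space: each pair once
  ijk <- index_to_ijk(grid, voxels)
  d <- grid$dims
  edges <- NULL
  for (o in seq_len(nrow(off))) {
    nb <- sweep(ijk, 2L, off[o, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_idx <- ijk_to_index(grid, nb[ok, , drop = FALSE])
    j <- match(nb_idx, voxels)
    hit <- !is.na(j)
    if (any(hit)) edges <- rbind(edges, cbind(which(ok)[hit], j[hit]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(voxels), seq_along(voxels))),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  unname(split(voxels, memb))
}

#' Classify state-dependent voxels by a retrospective paired t-test
#'
#' For each ANOVA-detected voxel, a paired t-test across subjects of the
#' mean task connectivity (T1, T2) against the mean resting connectivity
#' (R1, R2), on the Fisher-Z scale.  Voxels with a significant negative
#' difference are `decreasing`, significant positive `increasing`; a
#' non-significant paired test leaves the voxel `unclassified` with a
#' warning.
#'
#' @param z_by_state named list of mask-voxels x subjects Fisher-Z
#'   matrices.
#' @param voxels mask voxel indices (rows of the matrices).
#' @param clusters list of voxel clusters from [cluster_filter()].
#' @param alpha significance level of the retrospective test.
#' @param method multiple-testing handling across the tested voxels:
#'   `"BY"` (FDR, default, matching the map-level correction) or
#'   `"none"` for the raw per-voxel level.
#' @return data.frame with `voxel`, `t`, `p`, `label`.
#' @export
classify_voxels <- function(z_by_state, voxels, clusters, alpha = 0.05,
                            method = c("BY", "BH", "none")) {
  method <- match.arg(method)
  cl_vox <- sort(unique(unlist(clusters)))
  if (!length(cl_vox))
    return(data.frame(voxel = integer(0), t = numeric(0), p = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  rows <- match(cl_vox, voxels)
  if (anyNA(rows)) stop("clusters contain voxels outside the tested mask")
  task <- (z_by_state$T1[rows, , drop = FALSE] +
             z_by_state$T2[rows, , drop = FALSE]) / 2
  rest <- (z_by_state$R1[rows, , drop = FALSE] +
             z_by_state$R2[rows, , drop = FALSE]) / 2
  d <- task - rest
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  degenerate <- s == 0
  s[degenerate] <- 1
  tt <- m / (s / sqrt(n))
  p <- 2 * pt(abs(tt), df = n - 1, lower.tail = FALSE)
  p[degenerate] <- ifelse(m[degenerate] == 0, 1, 0)
  sig <- if (method == "none") p < alpha
         else fdr_correct(p, q = alpha, method = method)
  label <- ifelse(sig & m < 0, "decreasing",
                  ifelse(sig & m > 0, "increasing", "unclassified"))
  if (any(label == "unclassified"))
    warning(sum(label == "unclassified"),
            " ANOVA-significant voxel(s) left unclassified by the paired test")
  data.frame(voxel = cl_vox, t = tt, p = p, label = label,
             stringsAsFactors = FALSE)
}

#' Assemble the region set
#'
#' Decreasing/increasing regions are the connected components of the
#' classified cluster voxels sharing a label; stable voxels are those
#' present in all four state maps and NOT significant in the ANOVA,
#' split into connected components.  Regions are named by class and the
#' world coordinate of their centroid; the stable region containing the
#' seed sphere is tagged.
#'
#' @param labels data.frame from [classify_voxels()].
#' @param union a [union_mask()].
#' @param anova_sig voxel indices significant in the RM-ANOVA.
#' @param grid the `dmn_grid`.
#' @param seed a [seed_spec()] used to tag the seed-bearing region.
#' @param connectivity 26 or 6.
#' @param min_stable_size exclusive size threshold for stable components
#'   (the cluster-extent rule applied to the stable system, so degenerate
#'   one-voxel "regions" never enter the system-level averages).
#' @return an object of class `region_set`: list of regions (`name`,
#'   `class`, `voxels`, `seed_region`), plus `grid`.
#' @export
define_regions <- function(labels, union, anova_sig, grid,
                           seed = seed_spec(), connectivity = 26L,
                           min_size = 5L, min_stable_size = 5L) {
  regions <- list()
  add_regions <- function(vox, class, regions, min_size = 0L) {
    if (!length(vox)) return(regions)
    for (comp in connected_components(sort(vox), grid, connectivity)) {
      if (length(comp) <= min_size) next
      ctr <- round(colMeans(voxel_to_mm(grid, index_to_ijk(grid, comp))))
      nm <- sprintf("%s_%+d%+d%+d", class, ctr[1], ctr[2], ctr[3])
      regions[[nm]] <- list(name = nm, class = class, voxels = comp,
                            seed_region = FALSE)
    }
    regions
  }
  ## the > 5 voxel extent rule also applies per classified region, so a
  ## clump of same-label voxels split off a cluster cannot form a
  ## degenerate region
  regions <- add_regions(labels$voxel[labels$label == "decreasing"],
                         "decreasing", regions, min_size = min_size)
  regions <- add_regions(labels$voxel[labels$label == "increasing"],
                         "increasing", regions, min_size = min_size)
  in_all <- union$voxels[rowSums(union$membership) == 4L]
  stable_vox <- setdiff(in_all, anova_sig)
  if (!length(stable_vox))
    message("no stable voxels found")
  regions <- add_regions(stable_vox, "stable", regions,
                         min_size = min_stable_size)
  sphere <- sphere_voxels(grid, seed$center_mm, seed$radius_mm)
  for (nm in names(regions)) {
    if (regions[[nm]]$class == "stable" &&
        length(intersect(regions[[nm]]$voxels, sphere)))
      regions[[nm]]$seed_region <- TRUE
  }
  structure(list(regions = regions, grid = grid), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cls <- vapply(x$regions, `[[`, "", "class")
  cat(sprintf("<region_set: %d stable, %d decreasing, %d increasing>\n",
              sum(cls == "stable"), sum(cls == "decreasing"),
              sum(cls == "increasing")))
  invisible(x)
}

#' Regions of a region set by class
#' @param rs a `region_set`.
#' @param class one of `"stable"`, `"decreasing"`, `"increasing"`.
#' @return list of regions.
#' @export
regions_of <- function(rs, class) {
  Filter(function(r) r$class == class, rs$regions)
}
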