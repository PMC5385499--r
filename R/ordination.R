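#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues, axes ordered by eigenvalue. For reproducible orientation the
#' first nonzero loading of each axis is made positive.
#'
#' @param d symmetric nonnegative distance matrix with zero diagonal
#'   (typically pairwise differentiation between sites).
#' @return A list: `coords` (sites x axes), `eig` (positive eigenvalues),
#'   `frac` (fraction of positive-eigenvalue variance per axis).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  cm <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = max(1L, nrow(d) - 1L), eig = TRUE))
  eig <- cm$eig
  pos <- which(eig > 1e-12 * max(abs(eig), 1))
  coords <- cm$points[, seq_along(pos), drop = FALSE]
  # deterministic sign: first loading of each axis with |.| > tol positive
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  list(coords = coords, eig = eig[pos], frac = eig[pos] / sum(eig[pos]))
}

#' Mantel test of isolation by distance
#'
#' Great-circle distances between site coordinates (haversine, Earth radius
#' 6371 km) against a pairwise differentiation matrix; the Mantel statistic
#' is the Pearson correlation of the off-diagonal vectors, the p-value is by
#' joint row/column permutation of one matrix (one-tailed, positive
#' association), as conventional for testing isolation by distance.
#'
#' @param fst symmetric pairwise differentiation matrix (site x site, named).
#' @param metadata a [site_metadata()] table covering those sites.
#' @param n_perm permutations (default 9999).
#' @param linearize if `TRUE`, uses `fst / (1 - fst)` (Rousset's
#'   linearization) instead of the raw values.
#' @param seed integer seed.
#' @return A list of class `ibd_result`: `r`, `r2`, `p`, `dist_km`,
#'   `n_perm`.
#' @export
mantel_ibd <- function(fst, metadata, n_perm = 9999L, linearize = FALSE,
                       seed = 1L) {
  sites <- rownames(fst)
  if (nrow(fst) < 4L) stop("need >= 4 sites for a Mantel test")
  idx <- match(sites, metadata$site_id)
  if (anyNA(idx))
    stop("missing coordinates for sites: ",
         paste(sites[is.na(idx)], collapse = ", "))
  ll <- cbind(metadata$lon[idx], metadata$lat[idx])
  dkm <- matrix(0, length(sites), length(sites),
                dimnames = list(sites, sites))
  for (i in seq_along(sites)) {
    dkm[i, ] <- geosphere::distHaversine(ll[i, ], ll, r = 6371000) / 1000
  }
  g <- fst
  if (linearize) g <- g / (1 - g)
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(dkm), stats::as.dist(g),
                      method = "pearson", permutations = n_perm)
  structure(list(r = unname(mt$statistic), r2 = unname(mt$statistic)^2,
                 p = mt$signif, dist_km = dkm, n_perm = n_perm,
                 linearized = linearize),
            class = "ibd_result")
}
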