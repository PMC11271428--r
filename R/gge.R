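#' GGE decomposition (environment-centered SVD)
#'
#' Centers the cell-means matrix by environment (column) means, so the
#' decomposed variation is genotype main effect plus genotype-by-environment
#' interaction, and applies an unscaled singular value decomposition.
#' Singular values are allocated to the scores according to `svp`:
#' `"genotype"` (row-metric preserving), `"environment"` (column-metric
#' preserving, the default, appropriate for environment evaluation), or
#' `"symmetric"` (square root to both sides).
#'
#' @param cells a `cell_means` object with g, e >= 3.
#' @param svp singular-value partitioning, see above.
#' @return a list of class `gge` with `centered`, `singular_values`,
#'   `genotype_scores`, `environment_scores`, `svp`, and `pc_share`
#'   (fraction of the G + GxE sum of squares per axis).
#' @export
gge_decompose <- function(cells, svp = c("environment", "genotype",
                                         "symmetric")) {
  stopifnot(inherits(cells, "cell_means"))
  svp <- match.arg(svp)
  m <- cells$means
  g <- nrow(m); e <- ncol(m)
  if (g < 3L || e < 3L) stop("need >= 3 genotypes and >= 3 environments")
  centered <- sweep(m, 2L, colMeans(m))
  k <- min(g, e)
  sv <- svd(centered, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  u <- sv$u; v <- sv$v
  for (j in seq_len(k)) {
    piv <- which.max(abs(u[, j]))
    if (u[piv, j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  alloc <- switch(svp,
    genotype = list(gp = 1, ep = 0),
    environment = list(gp = 0, ep = 1),
    symmetric = list(gp = 0.5, ep = 0.5))
  gscore <- u %*% diag(d^alloc$gp, k)
  escore <- v %*% diag(d^alloc$ep, k)
  dimnames(gscore) <- list(cells$genotypes, paste0("PC", seq_len(k)))
  dimnames(escore) <- list(cells$environments, paste0("PC", seq_len(k)))
  tot <- sum(d^2)
  structure(list(centered = centered, singular_values = d,
                 genotype_scores = gscore, environment_scores = escore,
                 svp = svp,
                 pc_share = if (tot > 0) d^2 / tot else rep(0, k)),
            class = "gge")
}

#' Which-won-where partition of the GGE biplot
#'
#' Builds the convex hull of the genotype markers in the PC1-PC2 plane; rays
#' from the origin perpendicular to the hull edges divide the plane into
#' sectors, each headed by the hull-vertex genotype that wins (has the
#' highest rank-2 predicted value) in every environment falling inside it.
#' Environment markers are assigned to the sector of the vertex genotype
#' maximizing the inner product of the paired 2-PC scores, which is the
#' rank-2 winner and is equivalent to the geometric sector construction.
#'
#' @param gge a [gge_decompose()] result.
#' @return a list of class `which_won_where` with `hull_vertices` (genotype
#'   labels, counter-clockwise), `winner_per_environment` (named character
#'   vector), `sectors` (list: vertex genotype -> environments), and
#'   `mega_environments` (the sectors holding >= 1 environment).
#' @export
which_won_where <- function(gge) {
  stopifnot(inherits(gge, "gge"))
  gm <- gge$genotype_scores[, 1:2, drop = FALSE]
  em <- gge$environment_scores[, 1:2, drop = FALSE]
  ctr <- sweep(gm, 2L, colMeans(gm))
  if (qr(ctr)$rank < 2L) stop("genotype markers are collinear; no polygon exists")
  hull <- grDevices::chull(gm[, 1L], gm[, 2L])
  hull_genotypes <- rownames(gm)[hull]
  # inner product of paired scores is svp-invariant up to a positive
  # per-axis factor only when svp is symmetric; rebuild the true rank-2
  # product from the singular values so the winner is scaling-independent
  d2 <- gge$singular_values[1:2]
  uu <- sweep(gm, 2L, switch(gge$svp,
                             genotype = d2, environment = rep(1, 2),
                             symmetric = sqrt(d2)), "/")
  vv <- sweep(em, 2L, switch(gge$svp,
                             genotype = rep(1, 2), environment = d2,
                             symmetric = sqrt(d2)), "/")
  pred <- sweep(uu, 2L, d2, "*") %*% t(vv)  # rank-2 reconstruction, g x e
  winners <- vapply(seq_len(ncol(pred)), function(j) {
    cand <- pred[hull, j]
    hull_genotypes[which.max(cand)]
  }, character(1L))
  names(winners) <- rownames(em)
  sectors <- split(names(winners), factor(winners, levels = hull_genotypes))
  sectors <- sectors[vapply(sectors, length, 0L) >= 0L]
  structure(list(hull_vertices = hull_genotypes,
                 winner_per_environment = winners,
                 sectors = sectors,
                 mega_environments = sectors[vapply(sectors, length, 0L) > 0L]),
            class = "which_won_where")
}

#' Environment discrimination and representativeness
#'
#' In the PC1-PC2 plane, the length of an environment vector measures its
#' capacity to discriminate genotypes, and the cosine of the angle between
#' the environment vector and the average-environment coordinate (AEC, the
#' mean of all environment markers) measures how representative it is of the
#' target region.
#'
#' @param gge a [gge_decompose()] result.
#' @param ortho_band half-width, in degrees, of the band around 90 degrees
#'   classified as "orthogonal" when labeling angles.
#' @return a data frame with columns `environment`, `vector_length`,
#'   `representativeness` (cosine with the AEC), `angle_deg`, and
#'   `angle_class` (acute / orthogonal / obtuse), plus attribute `aec`
#'   (the AEC coordinates).
#' @export
environment_metrics <- function(gge, ortho_band = 5) {
  stopifnot(inherits(gge, "gge"))
  em <- gge$environment_scores[, 1:2, drop = FALSE]
  aec <- colMeans(em)
  if (sqrt(sum(aec^2)) == 0) stop("average-environment vector is zero")
  len <- sqrt(rowSums(em^2))
  cosine <- as.vector(em %*% aec) / (len * sqrt(sum(aec^2)))
  cosine[len == 0] <- NA_real_
  ang <- acos(pmin(pmax(cosine, -1), 1)) * 180 / pi
  cls <- ifelse(abs(ang - 90) <= ortho_band, "orthogonal",
                ifelse(ang < 90, "acute", "obtuse"))
  out <- data.frame(environment = rownames(em), vector_length = unname(len),
                    representativeness = unname(cosine),
                    angle_deg = unname(ang), angle_class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "aec") <- aec
  out
}
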