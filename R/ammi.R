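#' AMMI decomposition of a cell-means matrix
#'
#' Removes the additive genotype and environment main effects from the
#' genotype x environment table of means and decomposes the doubly centered
#' interaction residual `Z_ij = Ybar_ij - Ybar_i. - Ybar_.j + Ybar_..` by
#' singular value decomposition. Scores are scaled symmetrically
#' (`u_ik * sqrt(lambda_k)` for genotypes, `v_jk * sqrt(lambda_k)` for
#' environments), so the inner product of paired scores reconstructs `Z`.
#' The sign of each axis is fixed by forcing the largest-magnitude genotype
#' loading positive.
#'
#' @param cells a `cell_means` object with at least 3 genotypes and 3
#'   environments.
#' @return a list of class `ammi` with `grand_mean`, `genotype_effects`,
#'   `environment_effects`, `singular_values` (length `min(g, e) - 1`),
#'   `genotype_scores`, `environment_scores`, and `ss_share` (fraction of the
#'   interaction sum of squares per axis; zero vector when the interaction is
#'   null).
#' @export
ammi_decompose <- function(cells) {
  stopifnot(inherits(cells, "cell_means"))
  m <- cells$means
  g <- nrow(m); e <- ncol(m)
  if (g < 3L || e < 3L) stop("need >= 3 genotypes and >= 3 environments")
  mu <- mean(m)
  gen_eff <- rowMeans(m) - mu
  env_eff <- colMeans(m) - mu
  z <- m - outer(rowMeans(m), rep(1, e)) -
    outer(rep(1, g), colMeans(m)) + mu
  k <- min(g, e) - 1L
  sv <- svd(z, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  u <- sv$u; v <- sv$v
  # deterministic sign: largest-|.| genotype loading positive per axis
  for (j in seq_len(k)) {
    piv <- which.max(abs(u[, j]))
    if (u[piv, j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  gscore <- u %*% diag(sqrt(d), k)
  escore <- v %*% diag(sqrt(d), k)
  dimnames(gscore) <- list(cells$genotypes, paste0("IPCA", seq_len(k)))
  dimnames(escore) <- list(cells$environments, paste0("IPCA", seq_len(k)))
  tot <- sum(d^2)
  structure(list(grand_mean = mu,
                 genotype_effects = stats::setNames(gen_eff, cells$genotypes),
                 environment_effects = stats::setNames(env_eff,
                                                       cells$environments),
                 singular_values = d,
                 genotype_scores = gscore,
                 environment_scores = escore,
                 ss_share = if (tot > 0) d^2 / tot else rep(0, k)),
            class = "ammi")
}

#' AMMI stability value (ASV)
#'
#' Weighted distance of each genotype from the origin of the IPCA1-IPCA2
#' plane:
#' `ASV_i = sqrt(((SS_IPCA1 / SS_IPCA2) * IPCA1_i)^2 + IPCA2_i^2)`,
#' where `SS_IPCAk = lambda_k^2`. Smaller values indicate more stable
#' genotypes; ranks are assigned ascending in ASV (average ranks on ties).
#'
#' @param ammi an [ammi_decompose()] result with at least two non-null axes.
#' @return a data frame with columns `genotype`, `asv`, `rank`.
#' @export
asv <- function(ammi) {
  stopifnot(inherits(ammi, "ammi"))
  if (length(ammi$singular_values) < 2L || ammi$singular_values[2L] <= 0) {
    stop("ASV needs two interaction axes with positive singular values")
  }
  w <- ammi$singular_values[1L]^2 / ammi$singular_values[2L]^2
  s1 <- ammi$genotype_scores[, 1L]
  s2 <- ammi$genotype_scores[, 2L]
  val <- sqrt((w * s1)^2 + s2^2)
  data.frame(genotype = rownames(ammi$genotype_scores), asv = unname(val),
             rank = rank(val, ties.method = "average"),
             stringsAsFactors = FALSE)
}
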