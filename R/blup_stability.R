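#' BLUPs of genotype and interaction effects for a balanced MET
#'
#' Fits the mixed model `y = mu + environment (fixed) + block-within-
#' environment (fixed) + genotype (random) + genotype x environment (random)
#' + error` by plugging the expected-mean-square variance components into
#' the balanced-case closed-form shrinkage solutions:
#' `g_i = c_g (Ybar_i. - Ybar_..)` with
#' `c_g = var_g / (var_g + var_ge / e + var_e / (e r))`, and
#' `(ge)_ij = c_ge (Ybar_ij - Ybar_i. - Ybar_.j + Ybar_..) +
#' c_a (Ybar_i. - Ybar_..)` with `c_ge = var_ge / (var_ge + var_e / r)` and
#' `c_a = (var_ge / e) / (var_g + var_ge / e + var_e / (e r))`. The second
#' term is the share of the genotype-mean deviation that the mixed model
#' attributes to the interaction means (the genotype mean carries
#' `g_i + mean_j(ge_ij)`, and both random terms claim part of it). For
#' balanced complete data these closed forms coincide with the REML
#' mixed-model solutions.
#'
#' @param met a balanced `met_table` with >= 2 blocks.
#' @param trait trait label.
#' @return a list of class `blup_result` with `grand_mean`,
#'   `genotype_blups`, `ge_blups` (g x e), `genotypic_values`
#'   (`mu + g_i + (ge)_ij`), `shrinkage` (named vector `c_g`, `c_ge`), and
#'   `variance_components`.
#' @export
fit_blups <- function(met, trait) {
  ja <- joint_anova(met, trait, include_ipca = FALSE)
  reps <- attr(ja, "reps")
  if (reps < 2L) stop("need >= 2 blocks")
  n_env <- attr(ja, "n_env")
  vc <- variance_components(ja, reps = reps, n_env = n_env)
  cm <- cell_means(met, trait)
  m <- cm$means
  mu <- mean(m)
  if (vc$var_g + vc$var_ge + vc$var_e <= 0) stop("total variance is zero")
  denom_mean <- vc$var_g + vc$var_ge / n_env + vc$var_e / (n_env * reps)
  c_g <- vc$var_g / denom_mean
  c_a <- (vc$var_ge / n_env) / denom_mean
  c_ge <- if (vc$var_ge + vc$var_e / reps > 0) {
    vc$var_ge / (vc$var_ge + vc$var_e / reps)
  } else 0
  a <- rowMeans(m) - mu
  g_hat <- c_g * a
  z <- m - outer(rowMeans(m), rep(1, ncol(m))) -
    outer(rep(1, nrow(m)), colMeans(m)) + mu
  ge_hat <- c_ge * z + outer(c_a * a, rep(1, ncol(m)))
  gv <- mu + outer(g_hat, rep(1, ncol(m))) + ge_hat
  dimnames(ge_hat) <- dimnames(gv) <- list(cm$genotypes, cm$environments)
  structure(list(grand_mean = mu,
                 genotype_blups = stats::setNames(g_hat, cm$genotypes),
                 ge_blups = ge_hat, genotypic_values = gv,
                 shrinkage = c(c_g = c_g, c_ge = c_ge, c_a = c_a),
                 variance_components = vc),
            class = "blup_result")
}

#' Harmonic mean of genotypic values (HMGV)
#'
#' `HMGV_i = e / sum_j (1 / GV_ij)` over the predicted genotypic values
#' `GV_ij = mu + g_i + (ge)_ij`. Because the harmonic mean is at most the
#' arithmetic mean, unstable genotypes (large interaction swings) are
#' penalized relative to their plain mean. Rank 1 is the largest HMGV.
#'
#' @param blup a [fit_blups()] result with all genotypic values positive.
#' @return a data frame with columns `genotype`, `hmgv`, `rank`.
#' @export
hmgv <- function(blup) {
  stopifnot(inherits(blup, "blup_result"))
  gv <- blup$genotypic_values
  if (any(gv <= 0)) {
    bad <- which(gv <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive genotypic value at ", rownames(gv)[bad[1L]], "/",
         colnames(gv)[bad[2L]], "; the harmonic mean requires positive values")
  }
  h <- ncol(gv) / rowSums(1 / gv)
  data.frame(genotype = rownames(gv), hmgv = unname(h),
             rank = rank(-h, ties.method = "average"),
             stringsAsFactors = FALSE)
}

#' Weighted average of absolute BLUP interaction scores (WAASB)
#'
#' Singular value decomposition of the genotype x environment matrix of
#' interaction BLUPs (doubly centered first, so only the pure interaction
#' pattern — not the share of genotype means carried by the interaction
#' BLUPs — enters the axes); for each genotype the absolute scores on all
#' `min(g, e) - 1` axes are averaged with weights equal to the proportion of
#' interaction variation explained by each axis:
#' `WAASB_i = sum_k |IPCA_ik| EP_k / sum_k EP_k`. Rank 1 is the smallest
#' (most stable) value.
#'
#' @param blup a [fit_blups()] result.
#' @return a data frame with columns `genotype`, `waasb`, `rank`.
#' @export
waasb <- function(blup) {
  stopifnot(inherits(blup, "blup_result"))
  z <- blup$ge_blups
  z <- z - rowMeans(z) - rep(colMeans(z), each = nrow(z)) + mean(z)
  z <- zapsmall(z, digits = 12)
  k <- min(dim(z)) - 1L
  if (all(z == 0)) {
    warning("interaction BLUPs are all zero; WAASB is 0 for every genotype")
    w <- rep(0, nrow(z))
  } else {
    sv <- svd(z, nu = k, nv = k)
    d <- sv$d[seq_len(k)]
    scores <- abs(sv$u %*% diag(sqrt(d), k))
    ep <- d^2 / sum(d^2)
    w <- as.vector(scores %*% ep) / sum(ep)
  }
  data.frame(genotype = rownames(z), waasb = unname(w),
             rank = rank(w, ties.method = "average"),
             stringsAsFactors = FALSE)
}

#' Joint performance-stability rank (equal weights)
#'
#' Composite score giving half weight to mean performance and half to WAASB
#' stability: both criteria are converted to ranks (mean descending, WAASB
#' ascending) and averaged.
#'
#' @param waasb_table output of [waasb()].
#' @param means named numeric vector of genotype means.
#' @return a data frame with columns `genotype`, `composite`, `rank`.
#' @export
performance_stability_score <- function(waasb_table, means) {
  means <- means[waasb_table$genotype]
  rp <- rank(-means, ties.method = "average")
  rs <- rank(waasb_table$waasb, ties.method = "average")
  comp <- (rp + rs) / 2
  data.frame(genotype = waasb_table$genotype, composite = unname(comp),
             rank = rank(comp, ties.method = "average"),
             stringsAsFactors = FALSE)
}

#' Performance x stability quadrants
#'
#' Classifies genotypes into the four quadrants of the mean-vs-WAASB plane:
#' Group 1 = below-average mean and high WAASB (unproductive, unstable),
#' Group 2 = above-average mean and high WAASB (productive, unstable),
#' Group 3 = below-average mean and low WAASB, Group 4 = above-average mean
#' and low WAASB (broadly adapted). The WAASB pivot defaults to its median.
#'
#' @param waasb_table output of [waasb()].
#' @param means named numeric vector of genotype means.
#' @param mean_pivot pivot on the performance axis (default: mean of
#'   `means`).
#' @param waasb_pivot pivot on the stability axis (default: median WAASB).
#' @return a data frame with columns `genotype`, `group` (integer 1-4).
#' @export
performance_stability_quadrants <- function(waasb_table, means,
                                            mean_pivot = NULL,
                                            waasb_pivot = NULL) {
  means <- means[waasb_table$genotype]
  if (is.null(mean_pivot)) mean_pivot <- mean(means)
  if (is.null(waasb_pivot)) waasb_pivot <- stats::median(waasb_table$waasb)
  high_mean <- means > mean_pivot
  low_waasb <- waasb_table$waasb <= waasb_pivot
  group <- ifelse(high_mean & !low_waasb, 2L,
           ifelse(high_mean & low_waasb, 4L,
           ifelse(!high_mean & low_waasb, 3L, 1L)))
  data.frame(genotype = waasb_table$genotype, group = group,
             stringsAsFactors = FALSE)
}
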