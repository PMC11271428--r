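#' Environmental index and favorability
#'
#' The environmental index is the environment mean deviation from the grand
#' mean, `I_j = Ybar_.j - Ybar_..`; an environment is favorable when its
#' index is positive.
#'
#' @param cells a `cell_means` object.
#' @return a data frame with columns `environment`, `index`, `favorable`.
#' @export
environmental_index <- function(cells) {
  stopifnot(inherits(cells, "cell_means"))
  idx <- colMeans(cells$means) - mean(cells$means)
  data.frame(environment = cells$environments, index = unname(idx),
             favorable = unname(idx > 0), stringsAsFactors = FALSE)
}

#' Eberhart-Russell joint regression statistics
#'
#' Regresses each genotype's environment means on the environmental index.
#' Returns the slope `bi`, the deviation variance
#' `S2di = sum(delta^2) / (e - 2) - ms_error / reps` (reported as computed,
#' possibly negative), the root mean square deviation
#' `RMSE = sqrt(sum(delta^2) / e)`, and the coefficient of determination
#' `R2` (regression SS over total SS).
#'
#' @param cells a `cell_means` object with >= 3 environments.
#' @param ms_error pooled residual mean square (used only in `S2di`).
#' @param reps number of blocks behind each cell mean.
#' @return a data frame with columns `genotype`, `bi`, `s2di`, `rmse`, `r2`.
#' @export
eberhart_russell <- function(cells, ms_error = 0, reps = 1L) {
  stopifnot(inherits(cells, "cell_means"))
  m <- cells$means
  e <- ncol(m)
  if (e < 3L) stop("need >= 3 environments for the joint regression")
  idx <- colMeans(m) - mean(m)
  sxx <- sum(idx^2)
  out <- t(apply(m, 1L, function(y) {
    yc <- y - mean(y)
    bi <- if (sxx > 0) sum(yc * idx) / sxx else 0
    delta <- yc - bi * idx
    ssd <- sum(delta^2)
    sst <- sum(yc^2)
    c(bi = bi,
      s2di = ssd / (e - 2) - ms_error / reps,
      rmse = sqrt(ssd / e),
      r2 = if (sst > 0) 1 - ssd / sst else NA_real_)
  }))
  data.frame(genotype = cells$genotypes, out, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Perkins-Jinks regression on interaction residuals
#'
#' Regresses the interaction term `Ybar_ij - Ybar_i. - Ybar_.j + Ybar_..` of
#' each genotype on the environmental index; the slope `Bi` equals the
#' Eberhart-Russell slope minus one, and `Di` is the deviation mean square
#' with an `e - 2` denominator.
#'
#' @param cells a `cell_means` object with >= 3 environments.
#' @return a data frame with columns `genotype`, `bi_pj`, `di`.
#' @export
perkins_jinks <- function(cells) {
  stopifnot(inherits(cells, "cell_means"))
  m <- cells$means
  e <- ncol(m)
  if (e < 3L) stop("need >= 3 environments for the joint regression")
  mu <- mean(m)
  z <- m - outer(rowMeans(m), rep(1, e)) - outer(rep(1, nrow(m)), colMeans(m)) + mu
  idx <- colMeans(m) - mu
  sxx <- sum(idx^2)
  out <- t(apply(z, 1L, function(zi) {
    bi <- if (sxx > 0) sum(zi * idx) / sxx else 0
    delta <- zi - bi * idx
    c(bi_pj = bi, di = sum(delta^2) / (e - 2))
  }))
  data.frame(genotype = cells$genotypes, out, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Wricke's ecovalence
#'
#' Each genotype's share of the interaction sum of squares of the cell-means
#' matrix: `Wi = sum_j (Ybar_ij - Ybar_i. - Ybar_.j + Ybar_..)^2`.
#'
#' @param cells a `cell_means` object.
#' @return a data frame with columns `genotype`, `wi`.
#' @export
wricke_ecovalence <- function(cells) {
  stopifnot(inherits(cells, "cell_means"))
  m <- cells$means
  mu <- mean(m)
  z <- m - outer(rowMeans(m), rep(1, ncol(m))) -
    outer(rep(1, nrow(m)), colMeans(m)) + mu
  data.frame(genotype = cells$genotypes, wi = unname(rowSums(z^2)),
             stringsAsFactors = FALSE)
}

#' Lin-Binns superiority index
#'
#' Mean squared distance of each genotype from the best genotype in each
#' environment: `Pi = sum_j (Ybar_ij - M_j)^2 / (2 e)` where `M_j` is the
#' environment maximum. Smaller is better.
#'
#' @param cells a `cell_means` object.
#' @return a data frame with columns `genotype`, `pi`.
#' @export
lin_binns <- function(cells) {
  stopifnot(inherits(cells, "cell_means"))
  m <- cells$means
  mx <- apply(m, 2L, max)
  p <- rowSums(sweep(m, 2L, mx)^2) / (2 * ncol(m))
  data.frame(genotype = cells$genotypes, pi = unname(p),
             stringsAsFactors = FALSE)
}

#' Annicchiarico confidence indices
#'
#' Works on the percentage scale `p_ij = 100 * Ybar_ij / Ybar_.j`. For the
#' general set of environments, and separately for the favorable
#' (environmental index > 0) and unfavorable subsets, the index is
#' `li = mean(p_ij) - Z_(1 - alpha) * sd(p_ij)` with a one-sided normal
#' quantile (sample standard deviation). A genotype exceeding 100 is
#' expected, with the stated confidence, to beat the environment mean.
#' When one of the subsets is empty its index is `NA` with a warning.
#'
#' @param cells a `cell_means` object.
#' @param alpha one-sided risk level; the default 0.25 gives Z = 0.6745.
#' @return a data frame with columns `genotype`, `li_general`,
#'   `li_favorable`, `li_unfavorable`.
#' @export
annicchiarico <- function(cells, alpha = 0.25) {
  stopifnot(inherits(cells, "cell_means"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  m <- cells$means
  pct <- sweep(m, 2L, colMeans(m), "/") * 100
  z <- stats::qnorm(1 - alpha)
  idx <- colMeans(m) - mean(m)
  li_of <- function(columns) {
    if (length(columns) == 0L) return(rep(NA_real_, nrow(m)))
    sub <- pct[, columns, drop = FALSE]
    apply(sub, 1L, function(p) {
      mean(p) - z * (if (length(p) > 1L) stats::sd(p) else 0)
    })
  }
  fav <- which(idx > 0)
  unf <- which(idx <= 0)
  if (length(fav) == 0L || length(unf) == 0L) {
    warning("empty favorable or unfavorable environment class; index reported as NA")
  }
  data.frame(genotype = cells$genotypes,
             li_general = unname(li_of(seq_len(ncol(m)))),
             li_favorable = unname(li_of(fav)),
             li_unfavorable = unname(li_of(unf)),
             stringsAsFactors = FALSE)
}

#' Plot-level standard deviation and environmental variance
#'
#' Two dispersion measures per genotype: `dp`, the population standard
#' deviation (n denominator) of all plot-level observations of the genotype
#' across environments and blocks, and `s2x`, the variance (e - 1
#' denominator) of the genotype's environment means.
#'
#' @param met a `met_table` (source of the plot-level values).
#' @param cells the matching `cell_means` object.
#' @param trait trait label.
#' @return a data frame with columns `genotype`, `dp`, `s2x`.
#' @export
dispersion_measures <- function(met, cells, trait) {
  stopifnot(inherits(met, "met_table"), inherits(cells, "cell_means"))
  sub <- met[met$trait == trait, , drop = FALSE]
  dp <- vapply(cells$genotypes, function(g) {
    x <- sub$value[sub$genotype == g]
    sqrt(sum((x - mean(x))^2) / length(x))
  }, 0)
  s2x <- apply(cells$means, 1L, stats::var)
  data.frame(genotype = cells$genotypes, dp = unname(dp),
             s2x = unname(s2x), stringsAsFactors = FALSE)
}

#' Nassar-Huehn nonparametric rank stability statistics
#'
#' Genotypes are ranked within each environment (mid-ranks on ties); by
#' default the ranking is applied to the corrected values
#' `Ybar_ij - Ybar_i. + Ybar_..`, which removes genotype main effects so
#' that only interaction drives rank changes. `Si1` is the mean absolute
#' rank difference over all environment pairs,
#' `2 * sum_{j < j'} |r_ij - r_ij'| / (e (e - 1))`, and `Si6` is
#' `sum_j |r_ij - rbar_i.| / rbar_i.`.
#'
#' @param cells a `cell_means` object with >= 2 environments.
#' @param corrected rank corrected values (default) or raw cell means.
#' @return a data frame with columns `genotype`, `si1`, `si6`.
#' @export
nassar_huehn <- function(cells, corrected = TRUE) {
  stopifnot(inherits(cells, "cell_means"))
  m <- cells$means
  e <- ncol(m)
  if (e < 2L) stop("need >= 2 environments")
  x <- if (corrected) m - rowMeans(m) + mean(m) else m
  r <- apply(x, 2L, rank, ties.method = "average")
  si1 <- apply(r, 1L, function(ri) {
    if (e < 2L) return(0)
    s <- 0
    for (j in seq_len(e - 1L)) {
      s <- s + sum(abs(ri[j] - ri[(j + 1L):e]))
    }
    2 * s / (e * (e - 1L))
  })
  si6 <- apply(r, 1L, function(ri) sum(abs(ri - mean(ri))) / mean(ri))
  data.frame(genotype = cells$genotypes, si1 = unname(si1),
             si6 = unname(si6), stringsAsFactors = FALSE)
}

#' All univariate stability indices for one trait
#'
#' Convenience wrapper assembling the full per-genotype index table
#' (dispersion, ecovalence, superiority, joint-regression, Annicchiarico and
#' Nassar-Huehn statistics) from plot-level data. The pooled residual mean
#' square feeding `S2di` is taken from the joint analysis of variance.
#'
#' @param met a balanced `met_table`.
#' @param trait trait label.
#' @param alpha Annicchiarico risk level.
#' @return a data frame, one row per genotype, with a `mean` column and all
#'   index columns; the per-environment index table is attached as attribute
#'   `environmental_index`.
#' @export
stability_indices <- function(met, trait, alpha = 0.25) {
  cm <- cell_means(met, trait)
  ja <- joint_anova(met, trait, include_ipca = FALSE)
  ms_error <- ja[ja$source == "residual", "ms"]
  reps <- attr(ja, "reps")
  er <- eberhart_russell(cm, ms_error = ms_error, reps = reps)
  pj <- perkins_jinks(cm)
  out <- data.frame(genotype = cm$genotypes,
                    mean = unname(rowMeans(cm$means)),
                    stringsAsFactors = FALSE)
  out <- merge(out, dispersion_measures(met, cm, trait), by = "genotype",
               sort = FALSE)
  out <- merge(out, wricke_ecovalence(cm), by = "genotype", sort = FALSE)
  out <- merge(out, lin_binns(cm), by = "genotype", sort = FALSE)
  out <- merge(out, er, by = "genotype", sort = FALSE)
  out <- merge(out, pj, by = "genotype", sort = FALSE)
  out <- merge(out, annicchiarico(cm, alpha = alpha), by = "genotype",
               sort = FALSE)
  out <- merge(out, nassar_huehn(cm), by = "genotype", sort = FALSE)
  out <- out[match(cm$genotypes, out$genotype), ]
  rownames(out) <- NULL
  attr(out, "environmental_index") <- environmental_index(cm)
  out
}
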