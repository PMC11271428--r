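#' Rank genotypes under a direction rule
#'
#' Converts an index column into genotype ranks. Rules: `"asc"` (smaller is
#' better: variance-type statistics), `"desc"` (larger is better: means,
#' confidence indices, HMGV, R2), `"target"` (closest to `target` is better:
#' regression slopes judged against 1 or 0). Ties receive the average rank;
#' the display rank rounds that average half-up, which is how tied ranks are
#' conventionally printed in trial reports.
#'
#' @param values named numeric vector (names = genotypes).
#' @param direction `"asc"`, `"desc"`, or `"target"`.
#' @param target target value for `direction = "target"`.
#' @return a list with `exact` (average ranks, used for statistics) and
#'   `display` (integer half-up rounded ranks).
#' @export
rank_genotypes <- function(values, direction = c("asc", "desc", "target"),
                           target = 1) {
  direction <- match.arg(direction)
  if (any(!is.finite(values))) stop("values must be finite")
  key <- switch(direction,
                asc = values,
                desc = -values,
                target = abs(values - target))
  exact <- rank(key, ties.method = "average")
  display <- as.integer(floor(exact + 0.5))  # half-up, not banker's rounding
  names(display) <- names(exact) <- names(values)
  list(exact = exact, display = display)
}

#' Assemble a genotype x method rank matrix
#'
#' @param values a data frame or matrix of index values: one row per
#'   genotype (rownames or a `genotype` column), one column per method.
#' @param directions named list or vector registering the rule per method:
#'   `"asc"`, `"desc"`, or a number (rank by closeness to that target).
#'   Every method column must be covered.
#' @return a list of class `rank_matrix` with `exact` and `display` g x m
#'   rank matrices and `directions`.
#' @export
rank_matrix <- function(values, directions) {
  if (is.data.frame(values) && "genotype" %in% names(values)) {
    rn <- values$genotype
    values <- values[setdiff(names(values), "genotype")]
    rownames(values) <- rn
  }
  values <- as.matrix(values)
  missing_dir <- setdiff(colnames(values), names(directions))
  if (length(missing_dir)) {
    stop("no direction registered for method(s): ",
         paste(missing_dir, collapse = ", "))
  }
  exact <- display <- matrix(NA_real_, nrow(values), ncol(values),
                             dimnames = dimnames(values))
  for (mth in colnames(values)) {
    d <- directions[[mth]]
    r <- if (is.numeric(d)) {
      rank_genotypes(values[, mth], "target", target = d)
    } else {
      rank_genotypes(values[, mth], d)
    }
    exact[, mth] <- r$exact
    display[, mth] <- r$display
  }
  structure(list(exact = exact, display = display, directions = directions),
            class = "rank_matrix")
}

#' Spearman concordance between stability methods
#'
#' Pairwise Spearman correlations between the rank columns, with two-sided
#' p-values and significance stars (0.05 / 0.01 / 0.001). Exact
#' (tie-averaged) ranks are used. A constant column yields `NA` correlations
#' with a warning.
#'
#' @param ranks a `rank_matrix`, or a plain numeric matrix of ranks.
#' @return a list of class `spearman_matrix` with `rho`, `p`, and `stars`
#'   (m x m character matrix).
#' @export
spearman_matrix <- function(ranks) {
  m <- if (inherits(ranks, "rank_matrix")) ranks$exact else as.matrix(ranks)
  if (nrow(m) < 3L) stop("need >= 3 genotypes")
  if (any(apply(m, 2L, stats::sd) == 0)) {
    warning("constant rank column(s); correlations reported as NA")
  }
  k <- ncol(m)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { p[i, j] <- 0; next }
      if (is.na(rho[i, j])) next
      p[i, j] <- suppressWarnings(
        stats::cor.test(m[, i], m[, j], method = "spearman",
                        exact = FALSE)$p.value)
    }
  }
  stars <- ifelse(is.na(p), "", ifelse(p < 0.001, "***",
           ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
  diag(stars) <- ""
  structure(list(rho = rho, p = p, stars = stars),
            class = "spearman_matrix")
}

#' PCA grouping of stability methods
#'
#' Eigen-decomposes the method correlation matrix, takes loadings on the
#' first two components (eigenvectors scaled by the square root of their
#' eigenvalues), and clusters the methods on those 2-D loadings with Ward
#' hierarchical clustering cut at `n_groups`.
#'
#' @param spearman a `spearman_matrix` or a plain m x m correlation matrix.
#' @param n_groups number of method groups (>= 2).
#' @return a list of class `method_groups` with `loadings` (m x 2),
#'   `explained` (percent of total variance on the first two components),
#'   `eigenvalues`, and `groups` (named integer vector).
#' @export
pca_group_methods <- function(spearman, n_groups = 4L) {
  rho <- if (inherits(spearman, "spearman_matrix")) spearman$rho
         else as.matrix(spearman)
  if (n_groups < 2L) stop("n_groups must be >= 2")
  if (nrow(rho) < n_groups) stop("fewer methods than groups")
  if (anyNA(rho)) stop("correlation matrix contains NA")
  eg <- eigen((rho + t(rho)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  loadings <- eg$vectors[, 1:2] %*% diag(sqrt(ev[1:2]))
  rownames(loadings) <- rownames(rho)
  colnames(loadings) <- c("PC1", "PC2")
  grp <- stats::cutree(
    stats::hclust(stats::dist(loadings), method = "ward.D2"),
    k = n_groups)
  structure(list(loadings = loadings,
                 explained = 100 * ev[1:2] / sum(ev),
                 eigenvalues = ev,
                 groups = grp),
            class = "method_groups")
}

#' Label method groups by stability concept
#'
#' A group of methods whose rankings track the trait-mean ranking captures
#' dynamic (agronomic) stability; a group essentially uncorrelated with the
#' trait captures static (biological) stability; intermediate groups are
#' labeled weak.
#'
#' @param groups a `method_groups` object (or named integer vector).
#' @param trait_corr named numeric vector: each method's correlation with
#'   the trait-mean ranking.
#' @param dynamic_threshold group mean absolute correlation at or above
#'   which a group is dynamic (default 0.6).
#' @param static_threshold group mean absolute correlation below which a
#'   group is static (default 0.3).
#' @return a data frame with columns `method`, `group`, `concept`.
#' @export
stability_concept_classification <- function(groups, trait_corr,
                                             dynamic_threshold = 0.6,
                                             static_threshold = 0.3) {
  grp <- if (inherits(groups, "method_groups")) groups$groups else groups
  grp <- grp[names(grp) %in% names(trait_corr)]
  mean_abs <- tapply(abs(trait_corr[names(grp)]), grp, mean)
  concept_of <- function(a) {
    if (a >= dynamic_threshold) "dynamic"
    else if (a < static_threshold) "static"
    else "weak"
  }
  concepts <- vapply(mean_abs, concept_of, character(1L))
  data.frame(method = names(grp), group = unname(grp),
             concept = unname(concepts[as.character(grp)]),
             stringsAsFactors = FALSE)
}
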