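#' Individual (per-environment) RCBD analysis of variance
#'
#' Fits `y_ij = mu + g_i + b_j + e_ij` for one environment and returns the
#' genotype / block / residual partition.
#'
#' @param met a `met_table`.
#' @param trait trait label.
#' @param environment environment label.
#' @return a data frame of class `anova_table` with columns
#'   `source`, `df`, `ss`, `ms`, `f`, `p`.
#' @export
individual_anova <- function(met, trait, environment) {
  stopifnot(inherits(met, "met_table"))
  sub <- met[met$trait == trait & met$environment == environment, ,
             drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for trait/environment")
  if (length(unique(sub$block)) < 2L) stop("need >= 2 blocks for an RCBD analysis")
  fit <- stats::aov(value ~ genotype + block, data = sub)
  tab <- summary(fit)[[1L]]
  src <- trimws(rownames(tab))
  src[src == "genotype"] <- "genotypes"
  src[src == "block"] <- "blocks"
  src[src == "Residuals"] <- "residual"
  out <- data.frame(source = src, df = tab$Df, ss = tab$`Sum Sq`,
                    ms = tab$`Mean Sq`, f = tab$`F value`,
                    p = tab$`Pr(>F)`, stringsAsFactors = FALSE)
  structure(out, class = c("anova_table", "data.frame"),
            environment = environment, trait = trait)
}

#' Homogeneity of residual variances across environments
#'
#' Applies Bartlett's test to the per-environment residual mean squares and
#' reports the max/min residual mean-square ratio together with the
#' conventional screening rule that a joint analysis is admissible when that
#' ratio is below 7.
#'
#' @param individual_tables a list of `anova_table` objects from
#'   [individual_anova()].
#' @return a list with `bartlett_stat`, `df`, `p`, `ms_ratio`, and
#'   `pass_ratio_rule`.
#' @export
homogeneity_check <- function(individual_tables) {
  if (length(individual_tables) < 2L) stop("need >= 2 environments")
  res <- lapply(individual_tables, function(t) {
    row <- t[t$source == "residual", , drop = FALSE]
    if (nrow(row) != 1L || row$df <= 0) stop("each table needs a residual row with df > 0")
    c(ms = row$ms, df = row$df)
  })
  ms <- vapply(res, `[[`, 0, "ms")
  df <- vapply(res, `[[`, 0, "df")
  # Bartlett statistic from summary variances (the raw plots are not needed)
  n <- sum(df)
  sp2 <- sum(df * ms) / n
  k <- length(ms)
  num <- n * log(sp2) - sum(df * log(ms))
  corr <- 1 + (sum(1 / df) - 1 / n) / (3 * (k - 1))
  stat <- num / corr
  list(bartlett_stat = stat, df = k - 1L,
       p = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
       ms_ratio = max(ms) / min(ms),
       pass_ratio_rule = (max(ms) / min(ms)) < 7)
}

#' Joint analysis of variance for a balanced MET
#'
#' Partitions the total sum of squares into genotypes, environments, blocks
#' within environments, genotype-by-environment interaction, and residual,
#' optionally appending interaction principal-component (IPCA) rows obtained
#' from the AMMI decomposition of the cell-means matrix. Percentage shares of
#' the treatment sum of squares (G, E and G x E relative to their sum) and of
#' the interaction sum of squares per IPCA axis are attached as attributes.
#'
#' @param met a balanced `met_table`.
#' @param trait trait label.
#' @param include_ipca append IPCA rows (default `TRUE`).
#' @return an `anova_table` with attributes `pct_ss` (named G/E/GxE percent
#'   shares), `ipca_pct` (percent of interaction SS per axis), `grand_mean`,
#'   `reps`, `n_env`, `n_gen`.
#' @export
joint_anova <- function(met, trait, include_ipca = TRUE) {
  stopifnot(inherits(met, "met_table"))
  bal <- validate_balance(met, trait)
  if (!bal$is_balanced) {
    stop("design is unbalanced; analyse a balanced subset (no imputation is performed)")
  }
  sub <- met[met$trait == trait, , drop = FALSE]
  sub$genotype <- factor(sub$genotype, levels = unique(sub$genotype))
  sub$environment <- factor(sub$environment, levels = unique(sub$environment))
  sub$block <- factor(sub$block, levels = unique(sub$block))
  fit <- stats::aov(value ~ genotype * environment + environment:block,
                    data = sub)
  tab <- summary(fit)[[1L]]
  src <- trimws(rownames(tab))
  map <- c(genotype = "genotypes", environment = "environments",
           `environment:block` = "blocks_within_env",
           `genotype:environment` = "gxe", Residuals = "residual")
  src <- unname(map[src])
  out <- data.frame(source = src, df = tab$Df, ss = tab$`Sum Sq`,
                    ms = tab$`Mean Sq`, f = tab$`F value`, p = tab$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  canon <- c("genotypes", "environments", "blocks_within_env", "gxe",
             "residual")
  out <- out[match(canon, out$source), ]
  rownames(out) <- NULL
  ss <- stats::setNames(out$ss, out$source)
  trt <- ss[["genotypes"]] + ss[["environments"]] + ss[["gxe"]]
  pct <- 100 * c(G = ss[["genotypes"]], E = ss[["environments"]],
                 GxE = ss[["gxe"]]) / trt
  ipca_pct <- NULL
  if (include_ipca) {
    am <- ammi_decompose(cell_means(met, trait))
    r <- bal$reps_per_cell
    g <- nlevels(sub$genotype); e <- nlevels(sub$environment)
    n_axes <- length(am$singular_values)
    ipca_ss <- r * am$singular_values^2
    ipca_df <- g + e - 1 - 2 * seq_len(n_axes)  # Gollob axis df
    ipca <- data.frame(source = paste0("IPCA", seq_len(n_axes)),
                       df = ipca_df, ss = ipca_ss, ms = ipca_ss / ipca_df,
                       f = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    res_row <- which(out$source == "residual")
    out <- rbind(out[seq_len(res_row - 1L), ], ipca, out[res_row, ])
    rownames(out) <- NULL
    ipca_pct <- 100 * am$ss_share
  }
  structure(out, class = c("anova_table", "data.frame"),
            pct_ss = pct, ipca_pct = ipca_pct,
            grand_mean = mean(sub$value),
            reps = bal$reps_per_cell,
            n_env = nlevels(sub$environment),
            n_gen = nlevels(sub$genotype), trait = trait)
}

#' Build an `anova_table` from known sums of squares
#'
#' Convenience constructor for feeding published or externally computed
#' ANOVA summaries into the variance-component and accuracy chain.
#'
#' @param source character vector of source labels (must include
#'   `"genotypes"`, `"gxe"`, `"residual"` for downstream use).
#' @param df,ss integer degrees of freedom and sums of squares.
#' @return an `anova_table` with `ms = ss/df`.
#' @export
anova_table <- function(source, df, ss) {
  stopifnot(length(source) == length(df), length(df) == length(ss))
  out <- data.frame(source = as.character(source), df = df, ss = ss,
                    ms = ss / df, f = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  structure(out, class = c("anova_table", "data.frame"))
}

#' Percentage sum-of-squares partitions of a joint ANOVA table
#'
#' Shares of the treatment variation (genotypes, environments and G x E
#' relative to their summed SS) and, when IPCA rows are present, the share
#' of the interaction SS carried by each axis.
#'
#' @param anova an `anova_table` with `genotypes`, `environments` and `gxe`
#'   rows; `IPCA*` rows are used when present.
#' @return a list with `main` (named percent vector `G`, `E`, `GxE`) and
#'   `ipca` (percent of interaction SS per axis, or `NULL`).
#' @export
ss_shares <- function(anova) {
  ss_g <- .anova_row(anova, "genotypes")$ss
  ss_e <- .anova_row(anova, "environments")$ss
  ss_ge <- .anova_row(anova, "gxe")$ss
  tot <- ss_g + ss_e + ss_ge
  ipca_rows <- anova[grepl("^IPCA", anova$source), , drop = FALSE]
  ipca <- if (nrow(ipca_rows)) {
    stats::setNames(100 * ipca_rows$ss / ss_ge, ipca_rows$source)
  }
  list(main = 100 * c(G = ss_g, E = ss_e, GxE = ss_ge) / tot, ipca = ipca)
}

.anova_row <- function(anova, source) {
  row <- anova[anova$source == source, , drop = FALSE]
  if (nrow(row) != 1L) stop("ANOVA table needs a single '", source, "' row")
  row
}

#' Selective accuracy of genotype discrimination
#'
#' Computes `sqrt(1 - 1/F)` where `F` is the ratio of the genotype mean
#' square to the genotype-by-environment mean square. Values near 1 indicate
#' that observed genotype differences are reliable. When `F < 1` the
#' statistic is undefined on the real line and 0 is returned with a warning.
#'
#' @param anova an `anova_table` containing `genotypes` and `gxe` rows.
#' @return a number in `[0, 1]`.
#' @export
selective_accuracy <- function(anova) {
  ms_g <- .anova_row(anova, "genotypes")$ms
  ms_ge <- .anova_row(anova, "gxe")$ms
  if (ms_ge <= 0) stop("G x E mean square must be positive")
  f <- ms_g / ms_ge
  if (f < 1) {
    warning("F < 1: selective accuracy truncated to 0")
    return(0)
  }
  sqrt(1 - 1 / f)
}

#' Variance components from expected mean squares
#'
#' Solves the balanced-design method-of-moments equations
#' `sigma_e^2 = MS_res`, `sigma_ge^2 = (MS_GxE - MS_res) / r`,
#' `sigma_g^2 = (MS_G - MS_GxE) / (r e)`. Negative solutions are truncated at
#' zero and flagged. The phenotypic variance is either the plain sum of the
#' three components (`mode = "component_sum"`) or the genotype-mean basis
#' `sigma_g^2 + sigma_ge^2/E + sigma_e^2/(E R)` (`mode = "mean_basis"`).
#'
#' @param anova an `anova_table` with `genotypes`, `gxe` and `residual` rows.
#' @param reps number of blocks per environment (R).
#' @param n_env number of environments (E).
#' @param mode `"component_sum"` (default) or `"mean_basis"`.
#' @return a list of class `variance_components` with `var_g`, `var_ge`,
#'   `var_e`, `var_p`, `mode`, and `truncated` (logical flag).
#' @export
variance_components <- function(anova, reps, n_env,
                                mode = c("component_sum", "mean_basis")) {
  mode <- match.arg(mode)
  if (reps < 2L || n_env < 2L) stop("reps and n_env must be >= 2")
  ms_g <- .anova_row(anova, "genotypes")$ms
  ms_ge <- .anova_row(anova, "gxe")$ms
  ms_e <- .anova_row(anova, "residual")$ms
  raw <- c(var_g = (ms_g - ms_ge) / (reps * n_env),
           var_ge = (ms_ge - ms_e) / reps,
           var_e = ms_e)
  truncated <- any(raw < 0)
  if (truncated) warning("negative variance-component solution truncated to 0")
  comp <- pmax(raw, 0)
  var_p <- if (mode == "component_sum") {
    sum(comp)
  } else {
    comp[["var_g"]] + comp[["var_ge"]] / n_env + comp[["var_e"]] / (n_env * reps)
  }
  structure(list(var_g = comp[["var_g"]], var_ge = comp[["var_ge"]],
                 var_e = comp[["var_e"]], var_p = var_p, mode = mode,
                 truncated = truncated),
            class = "variance_components")
}

#' Genetic parameters from variance components
#'
#' Computes broad-sense heritability `h2 = var_g / var_p`, the genotypic,
#' phenotypic and residual coefficients of variation
#' (`100 * sqrt(component) / mu`), their ratio `CVg/CVr`, the difference
#' `CVp - CVg`, the expected genetic advance `GA = k * sqrt(var_p) * h2`, and
#' the advance as a percentage of the mean `GAM = 100 * GA / mu`.
#'
#' @param vc a [variance_components()] object.
#' @param grand_mean trait grand mean (> 0).
#' @param k_intensity standardized selection differential; the default 1.554
#'   corresponds to truncation selection of the best 15 percent under
#'   normality.
#' @param ga optional externally estimated genetic advance; when supplied it
#'   replaces the internally computed `GA` (and drives `GAM`).
#' @return a list of class `genetic_parameters`.
#' @export
genetic_parameters <- function(vc, grand_mean, k_intensity = 1.554,
                               ga = NULL) {
  stopifnot(inherits(vc, "variance_components"))
  if (grand_mean <= 0) stop("grand_mean must be positive")
  cv_g <- 100 * sqrt(vc$var_g) / grand_mean
  cv_p <- 100 * sqrt(vc$var_p) / grand_mean
  cv_r <- 100 * sqrt(vc$var_e) / grand_mean
  h2 <- if (vc$var_p > 0) vc$var_g / vc$var_p else 0
  if (is.null(ga)) ga <- k_intensity * sqrt(vc$var_p) * h2
  structure(list(h2 = h2, cv_g = cv_g, cv_p = cv_p, cv_r = cv_r,
                 cv_ratio = if (cv_r > 0) cv_g / cv_r else NA_real_,
                 p_minus_g = cv_p - cv_g, ga = ga,
                 gam = 100 * ga / grand_mean,
                 k_intensity = k_intensity, grand_mean = grand_mean),
            class = "genetic_parameters")
}

#' Scott-Knott clustering of genotype means
#'
#' Recursive binary partitioning of the mean-sorted genotypes: at each step
#' the contiguous split maximizing the between-group sum of squares `B0` is
#' accepted when `lambda = pi / (2 (pi - 2)) * B0 / sigma0^2` exceeds the
#' chi-square critical value at `g / (pi - 2)` degrees of freedom, where
#' `sigma0^2 = (sum((m_i - m)^2) + nu * s2y) / (g + nu)`, `s2y` is the
#' variance of a treatment mean (`ms_error / reps`) and `nu` its error
#' degrees of freedom.
#'
#' @param means named numeric vector of genotype means.
#' @param ms_error residual mean square from the ANOVA (> 0).
#' @param df_error residual degrees of freedom.
#' @param reps_per_mean number of observations behind each mean.
#' @param alpha significance level in (0, 1).
#' @return a list of class `scott_knott` with `groups` (list of label
#'   vectors, ordered by descending group mean), `letters` (named character
#'   vector), and `alpha`.
#' @export
scott_knott <- function(means, ms_error, df_error, reps_per_mean,
                        alpha = 0.05) {
  if (length(means) < 2L) stop("need >= 2 means")
  if (ms_error <= 0) stop("ms_error must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(names(means))) names(means) <- paste0("G", seq_along(means))
  ord <- order(means, decreasing = TRUE)
  sorted <- means[ord]
  s2y <- ms_error / reps_per_mean
  nu <- df_error

  split_stat <- function(m) {
    g <- length(m)
    best <- list(b0 = -Inf, cut = NA_integer_)
    tot <- sum(m)
    for (cut in seq_len(g - 1L)) {
      n1 <- cut; n2 <- g - cut
      t1 <- sum(m[seq_len(cut)]); t2 <- tot - t1
      b0 <- t1^2 / n1 + t2^2 / n2 - tot^2 / g
      if (b0 > best$b0) best <- list(b0 = b0, cut = cut)
    }
    best
  }

  test_split <- function(m) {
    g <- length(m)
    if (g < 2L) return(NULL)
    best <- split_stat(m)
    sigma0 <- (sum((m - mean(m))^2) + nu * s2y) / (g + nu)
    lambda <- pi / (2 * (pi - 2)) * best$b0 / sigma0
    crit <- stats::qchisq(1 - alpha, df = g / (pi - 2))
    if (lambda > crit) best$cut else NULL
  }

  partition <- function(m) {
    cut <- test_split(m)
    if (is.null(cut)) return(list(names(m)))
    c(partition(m[seq_len(cut)]), partition(m[-seq_len(cut)]))
  }

  groups <- partition(sorted)
  letters_vec <- character(length(means))
  names(letters_vec) <- names(sorted)
  for (i in seq_along(groups)) {
    letters_vec[groups[[i]]] <- letters[i]
  }
  structure(list(groups = groups, letters = letters_vec[names(means)],
                 alpha = alpha),
            class = "scott_knott")
}
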