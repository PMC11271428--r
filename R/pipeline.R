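#' Run the full MET stability pipeline
#'
#' Orchestrates the complete analysis for one or more traits of a balanced
#' MET table — joint ANOVA with IPCA axes, variance components and genetic
#' parameters, Scott-Knott mean grouping, AMMI (with ASV), GGE (biplot
#' coordinates, which-won-where, environment metrics), the univariate
#' stability-index battery, BLUP-based HMGV/WAASB, and the cross-method rank
#' concordance — and writes a structured CSV/JSON bundle plus a manifest.
#'
#' @param met a balanced `met_table`, or a [synthetic_config()] from which
#'   one is generated.
#' @param out_dir output directory (created if absent).
#' @param traits traits to analyse; default: all traits in the table.
#' @param alpha Annicchiarico risk level.
#' @param sk_alpha Scott-Knott significance level.
#' @param k_intensity selection intensity for the genetic advance.
#' @param svp singular-value partitioning for the GGE decomposition.
#' @param vc_mode phenotypic-variance mode for [variance_components()].
#' @param n_groups number of method groups in the concordance PCA.
#' @return (invisibly) a named list of per-trait result bundles; side
#'   effect: files under `out_dir/<trait>/` and `out_dir/manifest.json`.
#' @export
run_pipeline <- function(met, out_dir, traits = NULL, alpha = 0.25,
                         sk_alpha = 0.05, k_intensity = 1.554,
                         svp = "environment", vc_mode = "component_sum",
                         n_groups = 4L) {
  if (inherits(met, "synthetic_config")) met <- generate_met(met)
  stopifnot(inherits(met, "met_table"))
  if (is.null(traits)) traits <- unique(met$trait)
  if (length(traits) == 0L) stop("no traits to analyse")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  settings <- list(alpha = alpha, sk_alpha = sk_alpha,
                   k_intensity = k_intensity, svp = svp, vc_mode = vc_mode,
                   n_groups = n_groups)
  results <- lapply(traits, function(tr) {
    .run_trait(met, tr, out_dir, settings)
  })
  names(results) <- traits

  cfg_json <- jsonlite::toJSON(c(settings, list(traits = traits,
                                                n_records = nrow(met))),
                               auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "metstab",
    version = as.character(utils::packageVersion("metstab")),
    traits = traits,
    settings = settings,
    config_hash = .stable_hash(as.character(cfg_json)),
    data_hash = .stable_hash(paste(met$genotype, met$environment, met$block,
                                   met$trait, format(met$value, digits = 15),
                                   collapse = ";"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

# small deterministic FNV-1a string hash (hex); enough to fingerprint runs
.stable_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.run_trait <- function(met, trait, out_dir, s) {
  dir_t <- file.path(out_dir, trait)
  dir.create(dir_t, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir_t, paste0(name, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }

  ja <- joint_anova(met, trait)
  wr(as.data.frame(ja), "anova_joint")
  reps <- attr(ja, "reps"); n_env <- attr(ja, "n_env")
  vc <- variance_components(ja, reps = reps, n_env = n_env,
                            mode = s$vc_mode)
  gp <- genetic_parameters(vc, grand_mean = attr(ja, "grand_mean"),
                           k_intensity = s$k_intensity)
  wr(data.frame(parameter = c("var_g", "var_ge", "var_e", "var_p", "h2",
                              "cv_g", "cv_p", "cv_r", "cv_ratio",
                              "p_minus_g", "ga", "gam"),
                value = c(vc$var_g, vc$var_ge, vc$var_e, vc$var_p, gp$h2,
                          gp$cv_g, gp$cv_p, gp$cv_r, gp$cv_ratio,
                          gp$p_minus_g, gp$ga, gp$gam)),
     "genetic_parameters")

  cm <- cell_means(met, trait)
  means <- rowMeans(cm$means)
  ms_error <- ja[ja$source == "residual", "ms"]
  df_error <- ja[ja$source == "residual", "df"]
  sk <- scott_knott(means, ms_error = ms_error, df_error = df_error,
                    reps_per_mean = reps * n_env, alpha = s$sk_alpha)
  wr(data.frame(genotype = names(means), mean = unname(means),
                group = unname(sk$letters[names(means)])),
     "means_scott_knott")

  am <- ammi_decompose(cm)
  wr(data.frame(genotype = rownames(am$genotype_scores),
                am$genotype_scores), "ammi_genotype_scores")
  wr(data.frame(environment = rownames(am$environment_scores),
                am$environment_scores), "ammi_environment_scores")
  asv_tab <- asv(am)
  wr(asv_tab, "ammi_asv")

  gg <- gge_decompose(cm, svp = s$svp)
  wr(data.frame(genotype = rownames(gg$genotype_scores),
                gg$genotype_scores[, 1:2]), "gge_genotype_scores")
  wr(data.frame(environment = rownames(gg$environment_scores),
                gg$environment_scores[, 1:2]), "gge_environment_scores")
  www <- which_won_where(gg)
  wr(data.frame(environment = names(www$winner_per_environment),
                winner = unname(www$winner_per_environment)),
     "gge_which_won_where")
  wr(environment_metrics(gg), "gge_environment_metrics")

  st <- stability_indices(met, trait, alpha = s$alpha)
  wr(st, "stability_indices")
  wr(attr(st, "environmental_index"), "environmental_index")

  bl <- fit_blups(met, trait)
  hm <- hmgv(bl)
  wb <- waasb(bl)
  wr(hm, "blup_hmgv")
  wr(wb, "blup_waasb")
  wr(performance_stability_quadrants(wb, means), "blup_quadrants")

  idx <- st[, c("genotype", "mean", "dp", "wi", "pi", "bi", "s2di", "rmse",
                "r2", "bi_pj", "di", "li_general", "li_favorable",
                "li_unfavorable", "s2x", "si1", "si6")]
  idx$asv <- asv_tab$asv[match(idx$genotype, asv_tab$genotype)]
  idx$waasb <- wb$waasb[match(idx$genotype, wb$genotype)]
  idx$hmgv <- hm$hmgv[match(idx$genotype, hm$genotype)]
  dirs <- list(mean = "desc", dp = "asc", wi = "asc", pi = "asc", bi = 1,
               s2di = "asc", rmse = "asc", r2 = 1, bi_pj = 1, di = "asc",
               li_general = "desc", li_favorable = "desc",
               li_unfavorable = "desc", s2x = "asc", si1 = "asc",
               si6 = "asc", asv = "asc", waasb = "asc", hmgv = "desc")
  rm_ <- rank_matrix(idx, dirs)
  wr(data.frame(genotype = rownames(rm_$display), rm_$display),
     "rank_matrix")
  sp <- spearman_matrix(rm_)
  wr(data.frame(method = rownames(sp$rho), round(sp$rho, 4)),
     "spearman_matrix")
  grp <- pca_group_methods(sp, n_groups = s$n_groups)
  trait_corr <- sp$rho["mean", setdiff(colnames(sp$rho), "mean")]
  cls <- stability_concept_classification(grp, trait_corr)
  wr(merge(data.frame(method = names(grp$groups),
                      group = unname(grp$groups), stringsAsFactors = FALSE),
           cls[, c("method", "concept")], by = "method", all.x = TRUE),
     "method_groups")

  list(anova = ja, variance_components = vc, genetic_parameters = gp,
       scott_knott = sk, ammi = am, asv = asv_tab, gge = gg,
       which_won_where = www, stability = st, blup = bl, hmgv = hm,
       waasb = wb, ranks = rm_, spearman = sp, groups = grp)
}
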