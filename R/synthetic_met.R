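#' Configuration for the synthetic MET generator
#'
#' Defaults emulate a final-stage cassava variety trial series: 12 genotypes
#' evaluated in 12 environments with 3 complete blocks per environment, a
#' grand mean of 26.14 t/ha of fresh root yield, and variance components
#' sigma_g^2 = 20.16, sigma_gxe^2 = 17.87, sigma_e^2 = 6.54 (squared trait
#' units). Environment and block effect spreads default to magnitudes that
#' give the environment and block strata mean squares the same order as the
#' genotype stratum in such trials.
#'
#' @param n_genotypes,n_environments,n_blocks design counts (all >= 2).
#' @param grand_mean trait grand mean, in trait units.
#' @param var_g genetic variance sigma_g^2 (>= 0).
#' @param var_ge genotype-by-environment interaction variance (>= 0).
#' @param var_error plot-level residual variance (>= 0).
#' @param env_effect_sd standard deviation of environment main effects.
#'   Environments are drawn once, then treated as fixed by the analysis.
#' @param block_effect_sd standard deviation of block-within-environment
#'   effects.
#' @param seed integer seed controlling all random draws.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genotypes = 12L, n_environments = 12L,
                             n_blocks = 3L, grand_mean = 26.14,
                             var_g = 20.16, var_ge = 17.87,
                             var_error = 6.54, env_effect_sd = 4.7,
                             block_effect_sd = 0.9, seed = 1L) {
  counts <- c(n_genotypes = n_genotypes, n_environments = n_environments,
              n_blocks = n_blocks)
  if (any(counts < 2L)) stop("all design counts must be >= 2")
  vars <- c(var_g = var_g, var_ge = var_ge, var_error = var_error)
  if (any(vars < 0) || env_effect_sd < 0 || block_effect_sd < 0) {
    stop("variances and effect standard deviations must be >= 0")
  }
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_environments = as.integer(n_environments),
                 n_blocks = as.integer(n_blocks),
                 grand_mean = grand_mean, var_g = var_g, var_ge = var_ge,
                 var_error = var_error, env_effect_sd = env_effect_sd,
                 block_effect_sd = block_effect_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic per-effect sub-seed so each random term has its own stream
.effect_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483587)
}

#' Generate a balanced synthetic MET dataset
#'
#' Simulates `y_ijk = mu + g_i + tau_j + (ge)_ij + b_k(j) + eps_ijk` with all
#' random terms independent, normal and zero-mean at the configured
#' variances: genotype effects at `var_g`, environment effects at
#' `env_effect_sd^2`, interaction at `var_ge`, blocks within environments at
#' `block_effect_sd^2`, and plot error at `var_error`. The same seed always
#' yields the same table.
#'
#' @param config a [synthetic_config()].
#' @param trait trait label to attach.
#' @return a balanced `met_table` with
#'   `n_genotypes * n_environments * n_blocks` records.
#' @export
generate_met <- function(config, trait = "trait") {
  stopifnot(inherits(config, "synthetic_config"))
  g <- config$n_genotypes; e <- config$n_environments; r <- config$n_blocks
  draw <- function(k, n, sd) {
    if (sd == 0) return(rep(0, n))
    set.seed(.effect_seed(config$seed, k))
    stats::rnorm(n, 0, sd)
  }
  gen_eff <- draw(1L, g, sqrt(config$var_g))
  env_eff <- draw(2L, e, config$env_effect_sd)
  ge_eff <- matrix(draw(3L, g * e, sqrt(config$var_ge)), nrow = g)
  blk_eff <- matrix(draw(4L, e * r, config$block_effect_sd), nrow = e)
  err <- array(draw(5L, g * e * r, sqrt(config$var_error)), dim = c(g, e, r))

  idx <- expand.grid(gi = seq_len(g), ej = seq_len(e), bk = seq_len(r))
  value <- config$grand_mean + gen_eff[idx$gi] + env_eff[idx$ej] +
    ge_eff[cbind(idx$gi, idx$ej)] + blk_eff[cbind(idx$ej, idx$bk)] +
    err[cbind(idx$gi, idx$ej, idx$bk)]
  as_met_table(data.frame(
    genotype = sprintf("G%02d", idx$gi),
    environment = sprintf("E%02d", idx$ej),
    block = sprintf("B%d", idx$bk),
    trait = trait,
    value = value,
    stringsAsFactors = FALSE
  ))
}

#' Handcrafted toy fixtures with known analytic structure
#'
#' Small deterministic MET tables used throughout the test-suite and the
#' documentation:
#' \describe{
#'   \item{`"additive_no_ge"`}{4 genotypes x 4 environments x 2 blocks with
#'     purely additive genotype and environment effects: every interaction
#'     residual, and hence every interaction-based stability statistic, is
#'     exactly zero.}
#'   \item{`"rank1_interaction"`}{additive structure plus a rank-one
#'     interaction term `u_i v_j`, so the first interaction axis carries 100
#'     percent of the interaction sum of squares.}
#'   \item{`"crossover"`}{two genotype groups winning in two disjoint
#'     environment groups, producing at least two occupied sectors in a
#'     which-won-where partition.}
#' }
#'
#' @param name one of the fixture names above.
#' @return a `met_table`.
#' @export
toy_fixture <- function(name = c("additive_no_ge", "rank1_interaction",
                                 "crossover")) {
  name <- match.arg(name)
  g <- 4L; e <- 4L; r <- 2L
  gen_eff <- c(-3, -1, 1, 3)
  env_eff <- c(-4, -2, 2, 4)
  inter <- matrix(0, g, e)
  if (name == "rank1_interaction") {
    inter <- outer(c(-1.5, -0.5, 0.5, 1.5), c(2, 1, -1, -2))
  } else if (name == "crossover") {
    # genotypes 1-2 win in environments 1-2, genotypes 3-4 in environments 3-4
    inter <- 6 * outer(c(1, 1, -1, -1), c(1, 1, -1, -1)) +
      2 * outer(c(1, -1, 1, -1), c(1, -1, -1, 1))
  }
  idx <- expand.grid(gi = seq_len(g), ej = seq_len(e), bk = seq_len(r))
  value <- 20 + gen_eff[idx$gi] + env_eff[idx$ej] +
    inter[cbind(idx$gi, idx$ej)]
  as_met_table(data.frame(
    genotype = paste0("G", idx$gi),
    environment = paste0("E", idx$ej),
    block = paste0("B", idx$bk),
    trait = "trait",
    value = value,
    stringsAsFactors = FALSE
  ))
}
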