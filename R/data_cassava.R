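#' Published-style cassava VCU trial summary tables
#'
#' Summary statistics from a series of final-stage cassava
#' value-for-cultivation-and-use (VCU) trials in the Brazilian humid
#' tropics: 12 genotypes evaluated in 12 environments (4 locations x 3
#' seasons) in randomized complete blocks with 3 replicates, for fresh root
#' yield (FRY, t/ha) and root dry matter content (DMC, %). The raw
#' plot-level data are not distributed; what is included is the reported
#' joint ANOVA (sums of squares and degrees of freedom), the genetic
#' parameter estimates, and the per-genotype stability-index values with
#' their published parenthetical ranks. These tables exercise every derived
#' chain of the package: expected-mean-square variance components, genetic
#' parameters, percentage sum-of-squares partitions, rank construction, and
#' rank concordance.
#'
#' @return a list with components:
#' \describe{
#'   \item{`anova`}{named list (`FRY`, `DMC`) of `anova_table` objects with
#'     sources `genotypes`, `environments`, `blocks_within_env`, `gxe`,
#'     `IPCA1`, `IPCA2`, `residual`.}
#'   \item{`design`}{list with `n_gen`, `n_env`, `reps`.}
#'   \item{`genetic_parameters`}{data frame of the reported Table of
#'     variance components and genetic parameters per trait.}
#'   \item{`indices`}{named list (`FRY`, `DMC`) of per-genotype index-value
#'     data frames (column `mean` plus one column per stability method).}
#'   \item{`ranks`}{named list (`FRY`, `DMC`) of the corresponding reported
#'     integer ranks.}
#'   \item{`directions`}{the direction registry for [rank_matrix()]:
#'     `"asc"`, `"desc"`, or a numeric target.}
#' }
#' @export
cassava_vcu <- function() {
  anova <- list(
    FRY = anova_table(
      source = c("genotypes", "environments", "blocks_within_env", "gxe",
                 "IPCA1", "IPCA2", "residual"),
      df = c(11, 11, 24, 121, 21, 19, 264),
      ss = c(8645.52, 8780.89, 371.10, 7279.50, 2390.07, 1506.66, 1726.49)),
    DMC = anova_table(
      source = c("genotypes", "environments", "blocks_within_env", "gxe",
                 "IPCA1", "IPCA2", "residual"),
      df = c(11, 11, 24, 121, 21, 19, 264),
      ss = c(1400.56, 479.66, 24.45, 301.72, 115.66, 63.00, 112.63))
  )

  genetic_parameters <- data.frame(
    parameter = c("var_g", "var_ge", "var_e", "var_p", "h2", "cv_g", "cv_p",
                  "cv_r", "cv_ratio", "p_minus_g", "ga", "gam",
                  "grand_mean"),
    FRY = c(20.16, 17.87, 6.54, 44.57, 0.45, 17.18, 25.53, 9.78, 1.75,
            8.35, 6.38, 24.40, 26.14),
    DMC = c(3.46, 0.68, 0.42, 4.56, 0.75, 5.14, 5.84, 1.80, 2.85, 0.70,
            3.13, 8.64, 36.22),
    stringsAsFactors = FALSE
  )

  gen_fry <- c("BR11-24-156", "Cigana Preta", "Corrente", "IAC-90",
               "BR11-34-41", "BR11-34-45", "BR11-34-64", "BR11-34-69",
               "BR12-107-002", "BRS Formosa", "BRS Mulatinha",
               "BRS Novo Horizonte")
  idx_fry <- data.frame(
    genotype = gen_fry,
    mean = c(24.64, 22.14, 24.71, 16.03, 33.57, 28.66, 26.53, 31.49,
             22.50, 29.67, 26.33, 27.40),
    dp = c(5.41, 7.10, 5.51, 6.37, 7.85, 7.63, 6.43, 6.98, 5.13, 5.89,
           5.49, 5.93),
    waasb = c(0.50, 1.17, 1.08, 0.73, 1.04, 0.75, 1.07, 1.55, 0.86, 0.80,
              0.81, 1.04),
    asv = c(0.89, 1.57, 2.01, 2.61, 2.69, 3.65, 1.97, 3.03, 0.76, 3.25,
            5.72, 1.27),
    gge = c(0.32, -0.29, 4.46, -5.76, -2.83, -9.35, -5.10, -3.80, -2.85,
            6.44, 17.03, 1.73),
    wi = c(64.67, 235.16, 123.01, 200.80, 205.39, 213.30, 115.14, 227.14,
           161.39, 280.66, 450.70, 149.16),
    pi = c(76.62, 111.58, 79.97, 224.17, 11.58, 38.21, 60.88, 19.36,
           113.67, 31.90, 77.02, 45.98),
    si1 = c(0.06, 0.11, 0.06, 0.03, 0.06, 0.03, 0.03, 0.08, 0.09, 0.05,
            0.02, 0.03),
    si6 = c(4.12, 6.97, 4.28, 7.27, 1.12, 3.77, 3.08, 2.69, 5.18, 3.33,
            3.69, 3.93),
    hmgv = c(23.4, 20.2, 23.6, 14.0, 32.1, 27.2, 25.1, 30.2, 21.6, 28.6,
             25.4, 26.3),
    s2di = c(4.27, 20.76, 10.01, 17.90, 12.98, 15.72, 8.39, 20.11, 12.57,
             23.79, 29.35, 12.73),
    rmse = c(2.31, 4.37, 3.18, 4.09, 3.55, 3.86, 2.96, 4.30, 3.50, 4.65,
             5.12, 3.52),
    r2 = c(0.80, 0.59, 0.63, 0.55, 0.78, 0.72, 0.77, 0.58, 0.49, 0.32,
           0.05, 0.61),
    bi_pj = c(0.03, 0.15, -0.07, 0.00, 0.47, 0.38, 0.20, 0.13, -0.24,
              -0.29, -0.75, -0.01),
    di = c(6.45, 22.94, 12.19, 20.08, 15.16, 17.9, 10.57, 22.29, 14.75,
           25.97, 31.53, 14.91),
    li_general = c(86.9, 70.9, 85.9, 48.0, 118.0, 99.0, 91.9, 109.0, 76.7,
                   101.0, 88.6, 95.1),
    li_favorable = c(89.0, 78.9, 84.9, 58.2, 124.0, 99.7, 101.0, 105.0,
                     73.3, 99.1, 75.5, 92.7),
    li_unfavorable = c(85.4, 65.3, 86.0, 42.7, 114.0, 98.0, 86.7, 110.0,
                       78.5, 107.0, 99.6, 96.4),
    s2x = c(6.0, 8.11, 5.48, 4.0, 1.48, 7.75, 6.39, 8.45, 5.73, 8.09, 9.2,
            8.82),
    stringsAsFactors = FALSE
  )
  rk_fry <- data.frame(
    genotype = gen_fry,
    dp = c(2, 10, 4, 7, 12, 11, 8, 9, 1, 5, 3, 6),
    waasb = c(1, 11, 10, 2, 8, 3, 9, 12, 6, 4, 5, 7),
    asv = c(2, 4, 6, 7, 8, 11, 5, 9, 1, 10, 12, 3),
    gge = c(2, 1, 7, 9, 4, 11, 8, 6, 5, 10, 12, 3),
    wi = c(1, 10, 3, 6, 7, 8, 2, 9, 5, 11, 12, 4),
    pi = c(7, 10, 9, 12, 1, 4, 6, 2, 11, 3, 8, 5),
    si1 = c(8, 12, 8, 4, 8, 4, 4, 10, 11, 6, 1, 4),
    si6 = c(8, 11, 9, 12, 1, 6, 3, 2, 10, 4, 5, 7),
    hmgv = c(9, 11, 8, 12, 1, 4, 7, 2, 10, 3, 6, 5),
    s2di = c(1, 10, 3, 8, 6, 7, 2, 9, 4, 11, 12, 5),
    rmse = c(1, 10, 3, 8, 6, 7, 2, 9, 4, 11, 12, 5),
    r2 = c(1, 7, 5, 9, 2, 4, 3, 8, 10, 11, 12, 6),
    bi_pj = c(6, 4, 9, 7, 1, 2, 3, 5, 10, 11, 12, 8),
    di = c(1, 10, 3, 8, 6, 7, 2, 9, 4, 11, 12, 5),
    li_general = c(8, 11, 9, 12, 1, 4, 6, 2, 10, 3, 7, 5),
    li_favorable = c(7, 9, 8, 12, 1, 4, 3, 2, 11, 5, 10, 6),
    li_unfavorable = c(9, 11, 8, 12, 1, 5, 7, 2, 10, 3, 4, 6),
    s2x = c(5, 9, 3, 2, 1, 7, 6, 10, 4, 8, 12, 11),
    stringsAsFactors = FALSE
  )

  gen_dmc <- c("BR11-34-45", "Cigana Preta", "BR11-34-64", "BR12-107-002",
               "Corrente", "BRS Novo Horizonte", "BR11-34-41", "BR11-34-69",
               "BRS Formosa", "BR11-24-156", "BRS Mulatinha", "IAC-90")
  idx_dmc <- data.frame(
    genotype = gen_dmc,
    mean = c(36.69, 36.80, 34.14, 37.46, 37.90, 39.33, 33.45, 33.68,
             36.23, 37.13, 37.46, 34.35),
    dp = c(1.77, 1.77, 1.49, 1.56, 1.43, 1.25, 1.50, 1.21, 1.23, 1.10,
           1.09, 1.22),
    waasb = c(0.59, 0.56, 0.25, 0.49, 0.36, 0.18, 0.57, 0.23, 0.41, 0.35,
              0.55, 0.77),
    asv = c(1.49, 1.96, 0.52, 1.54, 1.17, 0.27, 1.78, 0.32, 1.03, 1.11,
            1.60, 2.66),
    gge = c(-1.08, -1.84, -0.98, -1.29, -0.72, 0.67, 0.66, -1.06, 0.65,
            1.39, 1.79, 1.81),
    wi = c(14.10, 31.60, 30.35, 15.71, 10.01, 25.26, 22.20, 41.27, 6.59,
           30.95, 18.52, 55.14),
    pi = c(3.84, 3.83, 13.93, 2.25, 1.34, 0.01, 18.10, 16.55, 5.41, 2.78,
           2.33, 13.65),
    si1 = c(0.02, 0.06, 0.05, 0.03, 0.06, 0.09, 0.11, 0.02, 0.08, 0.00,
            0.06, 0.08),
    si6 = c(2.56, 2.79, 4.35, 1.84, 1.16, 0.28, 4.92, 4.89, 3.05, 1.75,
            3.21, 4.80),
    hmgv = c(36.6, 36.7, 34.1, 37.4, 37.9, 39.3, 33.4, 33.6, 36.2, 37.1,
             37.4, 34.3),
    s2di = c(0.63, 0.66, 0.31, 0.65, 0.45, 0.07, 0.91, 0.19, 0.56, 0.28,
             0.86, 1.25),
    rmse = c(0.80, 0.82, 0.61, 0.81, 0.70, 0.42, 0.93, 0.52, 0.76, 0.59,
             0.91, 1.08),
    r2 = c(0.77, 0.76, 0.81, 0.70, 0.73, 0.87, 0.57, 0.79, 0.57, 0.67,
           0.22, 0.14),
    bi_pj = c(0.42, 0.41, 0.22, 0.19, 0.11, 0.06, 0.03, -0.02, -0.15,
              -0.17, -0.53, -0.57),
    di = c(0.78, 0.81, 0.46, 0.79, 0.60, 0.21, 1.05, 0.33, 0.71, 0.43,
           1.01, 1.40),
    li_general = c(96.97, 97.12, 90.98, 99.45, 101.28, 106.57, 87.85,
                   90.42, 96.26, 99.47, 98.27, 89.08),
    li_favorable = c(99.11, 98.31, 91.76, 101.42, 100.83, 107.32, 88.27,
                     91.28, 96.99, 99.36, 97.98, 87.47),
    li_unfavorable = c(96.58, 95.38, 89.81, 97.31, 102.24, 105.78, 86.83,
                       89.56, 96.35, 99.33, 98.85, 92.70),
    s2x = c(3.45, 5.27, 1.45, 3.36, 2.27, 0.18, 1.45, 1.18, 4.36, 2.55,
            6.45, 3.09),
    stringsAsFactors = FALSE
  )
  rk_dmc <- data.frame(
    genotype = gen_dmc,
    dp = c(11, 12, 8, 10, 7, 6, 9, 3, 5, 2, 1, 4),
    waasb = c(11, 9, 3, 7, 5, 1, 10, 2, 6, 4, 8, 12),
    asv = c(7, 11, 3, 8, 6, 1, 10, 2, 4, 5, 9, 12),
    gge = c(7, 12, 5, 8, 4, 3, 2, 6, 1, 9, 10, 11),
    wi = c(3, 10, 8, 4, 2, 7, 6, 11, 1, 9, 5, 12),
    pi = c(7, 6, 10, 3, 2, 1, 12, 11, 8, 5, 4, 9),
    si1 = c(2, 7, 5, 4, 7, 11, 12, 2, 9, 1, 7, 9),
    si6 = c(5, 6, 9, 4, 2, 1, 12, 11, 7, 3, 8, 10),
    hmgv = c(7, 6, 10, 4, 2, 1, 12, 11, 8, 5, 3, 9),
    s2di = c(7, 9, 4, 8, 5, 1, 11, 2, 6, 3, 10, 12),
    rmse = c(7, 9, 4, 8, 5, 1, 11, 2, 6, 3, 10, 12),
    r2 = c(4, 5, 2, 7, 6, 1, 9, 3, 10, 8, 11, 12),
    bi_pj = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    di = c(7, 9, 4, 8, 5, 1, 11, 2, 6, 3, 10, 12),
    li_general = c(7, 6, 9, 4, 2, 1, 12, 10, 8, 3, 5, 11),
    li_favorable = c(5, 6, 9, 2, 3, 1, 11, 10, 8, 4, 7, 12),
    li_unfavorable = c(6, 8, 10, 5, 2, 1, 12, 11, 7, 3, 4, 9),
    s2x = c(9, 11, 4, 8, 5, 1, 3, 2, 10, 6, 12, 7),
    stringsAsFactors = FALSE
  )

  directions <- list(
    mean = "desc", dp = "asc", waasb = "asc", asv = "asc", gge = 0,
    wi = "asc", pi = "asc", si1 = "asc", si6 = "asc", hmgv = "desc",
    s2di = "asc", rmse = "asc", r2 = 1, bi_pj = 1, di = "asc",
    li_general = "desc", li_favorable = "desc", li_unfavorable = "desc",
    s2x = "asc"
  )

  list(anova = anova,
       design = list(n_gen = 12L, n_env = 12L, reps = 3L),
       genetic_parameters = genetic_parameters,
       indices = list(FRY = idx_fry, DMC = idx_dmc),
       ranks = list(FRY = rk_fry, DMC = rk_dmc),
       directions = directions)
}
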