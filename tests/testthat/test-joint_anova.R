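test_that("individual RCBD ANOVA matches the mean-decomposition oracle", {
  # handmade 3 genotypes x 2 blocks
  d <- data.frame(genotype = rep(c("G1", "G2", "G3"), each = 2L),
                  environment = "E1",
                  block = rep(c("B1", "B2"), 3L),
                  trait = "t",
                  value = c(10, 12, 15, 13, 20, 24))
  met <- as_met_table(d)
  tab <- individual_anova(met, "t", "E1")
  gm <- mean(d$value)
  gmeans <- tapply(d$value, d$genotype, mean)
  bmeans <- tapply(d$value, d$block, mean)
  ss_g <- 2 * sum((gmeans - gm)^2)
  ss_b <- 3 * sum((bmeans - gm)^2)
  ss_tot <- sum((d$value - gm)^2)
  expect_equal(tab[tab$source == "genotypes", "ss"], ss_g)
  expect_equal(tab[tab$source == "blocks", "ss"], ss_b)
  expect_equal(tab[tab$source == "residual", "ss"], ss_tot - ss_g - ss_b)
  expect_equal(tab$df, c(2L, 1L, 2L))
  expect_equal(tab$ms, tab$ss / tab$df)

  # constant data: every SS is zero
  dc <- d; dc$value <- 7
  tabc <- individual_anova(as_met_table(dc), "t", "E1")
  expect_equal(tabc$ss, rep(0, 3), tolerance = 1e-12)

  expect_error(individual_anova(as_met_table(d[d$block == "B1", ]),
                                "t", "E1"), ">= 2 blocks")
})

test_that("joint ANOVA reproduces oracle sums of squares and df layout", {
  met <- rand_met(g = 4L, e = 3L, r = 2L, seed = 21L)
  ja <- joint_anova(met, "trait", include_ipca = FALSE)
  oracle <- joint_ss_oracle(met, "trait")
  for (src in c("genotypes", "environments", "blocks_within_env", "gxe",
                "residual")) {
    expect_equal(ja[ja$source == src, "ss"], unname(oracle[src]),
                 tolerance = 1e-8, label = src)
  }
  expect_equal(sum(ja$ss), unname(oracle["total"]), tolerance = 1e-8)
  expect_equal(ja$df, c(3L, 2L, 3L, 6L, 9L))

  # the published-design df layout: 12 genotypes x 12 environments x 3 blocks
  met12 <- generate_met(synthetic_config(seed = 2L))
  ja12 <- joint_anova(met12, "trait", include_ipca = FALSE)
  expect_equal(ja12$df[match(c("genotypes", "environments",
                               "blocks_within_env", "gxe", "residual"),
                             ja12$source)],
               c(11L, 11L, 24L, 121L, 264L))
})

test_that("IPCA rows carry the interaction SS and Gollob df", {
  met <- rand_met(g = 5L, e = 4L, r = 3L, seed = 8L)
  ja <- joint_anova(met, "trait", include_ipca = TRUE)
  ipca <- ja[grepl("^IPCA", ja$source), ]
  expect_equal(sum(ipca$ss), ja[ja$source == "gxe", "ss"],
               tolerance = 1e-8)
  expect_equal(ipca$df, c(5L + 4L - 1L - 2L, 5L + 4L - 1L - 4L,
                          5L + 4L - 1L - 6L))
  expect_equal(sum(attr(ja, "ipca_pct")), 100, tolerance = 1e-8)
})

test_that("unbalanced data are refused with a useful message", {
  met <- rand_met(g = 4L, e = 3L, r = 2L, seed = 33L)
  cut <- as_met_table(as.data.frame(met)[-1L, ])
  expect_error(joint_anova(cut, "trait"), "unbalanced")
})

test_that("Bartlett homogeneity check matches stats::bartlett.test", {
  set.seed(42)
  groups <- list(rnorm(9, sd = 1), rnorm(9, sd = 1.4), rnorm(9, sd = 0.8))
  tables <- lapply(groups, function(x) {
    anova_table(source = c("genotypes", "residual"),
                df = c(1L, length(x) - 1L),
                ss = c(1, stats::var(x) * (length(x) - 1L)))
  })
  hc <- homogeneity_check(tables)
  bt <- stats::bartlett.test(groups)
  expect_equal(hc$bartlett_stat, unname(bt$statistic), tolerance = 1e-10)
  expect_equal(hc$p, bt$p.value, tolerance = 1e-10)

  # identical variances: statistic 0, ratio 1, rule passes
  same <- replicate(3, anova_table(c("genotypes", "residual"), c(1L, 8L),
                                   c(1, 16)), simplify = FALSE)
  hc0 <- homogeneity_check(same)
  expect_equal(hc0$bartlett_stat, 0, tolerance = 1e-12)
  expect_equal(hc0$ms_ratio, 1)
  expect_true(hc0$pass_ratio_rule)

  # the <7 screening rule is strict
  unequal <- list(anova_table(c("genotypes", "residual"), c(1L, 8L), c(1, 8)),
                  anova_table(c("genotypes", "residual"), c(1L, 8L),
                              c(1, 8 * 7.5)))
  expect_false(homogeneity_check(unequal)$pass_ratio_rule)
})

test_that("selective accuracy has the stated boundary and monotone behavior", {
  tab <- function(f) anova_table(c("genotypes", "gxe"), c(10L, 50L),
                                 c(10 * f, 50))
  expect_equal(selective_accuracy(tab(1)), 0)
  expect_warning(out <- selective_accuracy(tab(0.5)), "F < 1")
  expect_equal(out, 0)
  acc <- vapply(c(1.5, 3, 10, 100, 1e6), function(f)
    selective_accuracy(tab(f)), 0)
  expect_true(all(diff(acc) > 0))
  expect_equal(acc[5L], 1, tolerance = 1e-3)
})

test_that("variance components solve the EMS equations with truncation", {
  # all mean squares equal: only residual variance remains
  flat <- anova_table(c("genotypes", "gxe", "residual"),
                      c(11L, 121L, 264L), c(11 * 5, 121 * 5, 264 * 5))
  vc <- variance_components(flat, reps = 3L, n_env = 12L)
  expect_equal(c(vc$var_g, vc$var_ge, vc$var_e), c(0, 0, 5))
  expect_false(vc$truncated)

  # genotype MS below interaction MS: negative solution truncated + flagged
  neg <- anova_table(c("genotypes", "gxe", "residual"),
                     c(11L, 121L, 264L), c(11 * 2, 121 * 5, 264 * 1))
  expect_warning(vcn <- variance_components(neg, reps = 3L, n_env = 12L),
                 "truncated")
  expect_equal(vcn$var_g, 0)
  expect_true(vcn$truncated)

  # mean-basis phenotypic variance
  tab <- anova_table(c("genotypes", "gxe", "residual"),
                     c(11L, 121L, 264L),
                     c(8645.52, 7279.50, 1726.49))
  vm <- variance_components(tab, reps = 3L, n_env = 12L,
                            mode = "mean_basis")
  expect_equal(vm$var_p,
               vm$var_g + vm$var_ge / 12 + vm$var_e / 36,
               tolerance = 1e-12)
})

test_that("genetic parameters satisfy their defining identities", {
  tab <- anova_table(c("genotypes", "gxe", "residual"),
                     c(11L, 121L, 264L), c(8645.52, 7279.50, 1726.49))
  vc <- variance_components(tab, reps = 3L, n_env = 12L)
  gp <- genetic_parameters(vc, grand_mean = 26.14)
  expect_equal(gp$cv_ratio, gp$cv_g / gp$cv_r)
  expect_equal(gp$p_minus_g, gp$cv_p - gp$cv_g)
  expect_equal(gp$gam, 100 * gp$ga / 26.14)
  expect_equal(gp$ga, 1.554 * sqrt(vc$var_p) * gp$h2)

  # no genetic variance: h2, CVg, GA, GAM all zero
  vc0 <- vc; vc0$var_g <- 0
  gp0 <- genetic_parameters(vc0, grand_mean = 26.14)
  expect_equal(c(gp0$h2, gp0$cv_g, gp0$ga, gp0$gam), rep(0, 4))

  expect_error(genetic_parameters(vc, grand_mean = 0), "positive")
})

test_that("Scott-Knott matches the exhaustive oracle and is order invariant", {
  # two well-separated clusters whose within-cluster gaps sit far below
  # the error scale: exactly two groups
  m <- c(A = 10, B = 10.05, C = 30, D = 30.05)
  sk <- scott_knott(m, ms_error = 0.5, df_error = 20L,
                    reps_per_mean = 3L, alpha = 0.05)
  expect_length(sk$groups, 2L)
  expect_setequal(sk$groups[[1L]], c("C", "D"))
  expect_equal(unname(sk$letters[c("C", "D")]), c("a", "a"))
  expect_equal(unname(sk$letters[c("A", "B")]), c("b", "b"))

  # against the independently coded recursive oracle on <= 8 means
  set.seed(7)
  for (rep_i in 1:5) {
    m8 <- stats::setNames(rnorm(8, 20, 4), paste0("G", 1:8))
    sk8 <- scott_knott(m8, ms_error = 2, df_error = 30L,
                       reps_per_mean = 3L, alpha = 0.05)
    expect_identical(sk8$groups,
                     scott_knott_oracle(m8, 2, 30L, 3L, 0.05))
  }

  # permutation of the input leaves the partition unchanged
  perm <- sample(names(m))
  sk_p <- scott_knott(m[perm], ms_error = 0.5, df_error = 20L,
                      reps_per_mean = 3L, alpha = 0.05)
  expect_identical(sk$groups, sk_p$groups)
  expect_identical(sk$letters[names(m)], sk_p$letters[names(m)])

  # identical means never separate
  same <- c(A = 5, B = 5, C = 5)
  expect_length(scott_knott(same, 1, 10L, 2L)$groups, 1L)

  # null case: one normal population with large error -> a single group
  set.seed(123)
  null_means <- stats::setNames(rnorm(12, 25, 0.5), paste0("G", 1:12))
  sk_null <- scott_knott(null_means, ms_error = 30, df_error = 264L,
                         reps_per_mean = 36L, alpha = 0.05)
  expect_length(sk_null$groups, 1L)
})
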