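test_that("environmental index centers to zero and flags favorability", {
  m <- matrix(c(18, 22, 18, 22, 28, 32), 3, 2, byrow = TRUE)
  # column means 20 and 30, grand mean 25
  m <- rbind(c(18, 28), c(20, 30), c(22, 32))
  ei <- environmental_index(as_cell_means(m))
  expect_equal(ei$index, c(-5, 5))
  expect_equal(ei$favorable, c(FALSE, TRUE))

  set.seed(4)
  rnd <- environmental_index(as_cell_means(matrix(rnorm(24, 20), 4, 6)))
  expect_equal(sum(rnd$index), 0, tolerance = 1e-12)

  flat <- environmental_index(as_cell_means(matrix(7, 3, 3)))
  expect_equal(flat$index, rep(0, 3))
  expect_false(any(flat$favorable))
})

test_that("joint regression statistics match the normal-equations oracle", {
  set.seed(19)
  m <- matrix(rnorm(24, 25, 4), 4, 6)
  cm <- as_cell_means(m, reps_per_cell = 3L)
  er <- eberhart_russell(cm, ms_error = 1.8, reps = 3L)
  idx <- colMeans(m) - mean(m)
  for (i in 1:4) {
    fit <- stats::lm(m[i, ] ~ idx)
    expect_equal(er$bi[i], unname(coef(fit)[2]), tolerance = 1e-10)
    delta <- stats::residuals(fit)
    expect_equal(er$s2di[i], sum(delta^2) / 4 - 1.8 / 3, tolerance = 1e-10)
    expect_equal(er$rmse[i], sqrt(sum(delta^2) / 6), tolerance = 1e-10)
    expect_equal(er$r2[i], summary(fit)$r.squared, tolerance = 1e-10)
  }
  # slopes average to one on any complete matrix
  expect_equal(mean(er$bi), 1, tolerance = 1e-10)

  # genotype tracking the environmental index exactly: bi = 1, perfect fit
  track <- outer(c(10, 20, 30), rep(1, 6)) +
    outer(rep(1, 3), seq(-5, 5, length.out = 6))
  ert <- eberhart_russell(as_cell_means(track))
  expect_equal(ert$bi, rep(1, 3), tolerance = 1e-10)
  expect_equal(ert$rmse, rep(0, 3), tolerance = 1e-10)
  expect_equal(ert$r2, rep(1, 3), tolerance = 1e-10)

  # constant genotype: zero slope
  const <- rbind(rep(15, 5), seq(10, 30, 5), seq(30, 10, -5))
  expect_equal(eberhart_russell(as_cell_means(const))$bi[1], 0,
               tolerance = 1e-10)
})

test_that("Perkins-Jinks slope is the Eberhart-Russell slope minus one", {
  set.seed(23)
  m <- matrix(rnorm(30, 22, 3), 5, 6)
  cm <- as_cell_means(m)
  er <- eberhart_russell(cm)
  pj <- perkins_jinks(cm)
  expect_equal(pj$bi_pj, er$bi - 1, tolerance = 1e-10)
  expect_equal(mean(pj$bi_pj), 0, tolerance = 1e-10)
  # Di differs from S2di (at ms_error = 0) by nothing: same deviations
  er0 <- eberhart_russell(cm, ms_error = 0, reps = 1L)
  expect_equal(pj$di, er0$s2di, tolerance = 1e-10)

  add <- cell_means(toy_fixture("additive_no_ge"), "trait")
  pj0 <- perkins_jinks(add)
  expect_equal(pj0$bi_pj, rep(0, 4), tolerance = 1e-10)
  expect_equal(pj0$di, rep(0, 4), tolerance = 1e-10)
})

test_that("ecovalence partitions the interaction SS of the cell means", {
  set.seed(29)
  m <- matrix(rnorm(28, 20, 5), 4, 7)
  cm <- as_cell_means(m)
  wi <- wricke_ecovalence(cm)$wi
  z <- m - rowMeans(m) - rep(colMeans(m), each = 4) + mean(m)
  expect_equal(sum(wi), sum(z^2), tolerance = 1e-8 * sum(z^2))
  # hand oracle on a 2x2-style contrast embedded in a 3x3 matrix
  h <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 9))
  wh <- wricke_ecovalence(as_cell_means(h))$wi
  zh <- h - rowMeans(h) - rep(colMeans(h), each = 3) + mean(h)
  expect_equal(wh, rowSums(zh^2), tolerance = 1e-12)
})

test_that("Lin-Binns superiority is zero only at the per-environment maximum", {
  m <- rbind(c(3, 5), c(1, 1))
  cm <- as_cell_means(m)
  pi_ <- lin_binns(cm)$pi
  expect_equal(pi_[1], 0)
  expect_equal(pi_[2], (4 + 16) / 4)

  met <- rand_met(g = 5L, e = 4L, r = 2L, seed = 61L)
  cmr <- cell_means(met, "trait")
  pir <- lin_binns(cmr)$pi
  best <- apply(cmr$means, 2L, max)
  oracle <- rowSums((cmr$means - rep(best, each = 5))^2) / (2 * 4)
  expect_equal(pir, unname(oracle), tolerance = 1e-12)
})

test_that("Annicchiarico indices behave on the percentage scale", {
  # a genotype exactly at every environment mean: p = 100, sd = 0
  m <- rbind(c(20, 30, 40), c(10, 20, 30), c(30, 40, 50))
  # row 1 equals the column means by construction
  expect_equal(colMeans(m), m[1, ])
  ann <- annicchiarico(as_cell_means(m), alpha = 0.25)
  expect_equal(ann$li_general[1], 100, tolerance = 1e-10)

  # two-environment hand evaluation
  m2 <- rbind(c(22, 18), c(18, 22))
  m2 <- rbind(m2, colMeans(m2))  # keep 3 genotypes
  cm2 <- as_cell_means(m2)
  ann2 <- suppressWarnings(annicchiarico(cm2, alpha = 0.25))
  p1 <- 100 * m2[1, ] / colMeans(m2)
  expect_equal(ann2$li_general[1],
               mean(p1) - stats::qnorm(0.75) * stats::sd(p1),
               tolerance = 1e-10)

  # a genotype above average everywhere with zero spread exceeds 100
  m3 <- rbind(c(24, 36), c(16, 24), c(20, 30))
  ann3 <- suppressWarnings(annicchiarico(as_cell_means(m3)))
  expect_gt(ann3$li_general[1], 100)

  # smaller alpha (larger Z) can only lower the index
  set.seed(3)
  m4 <- matrix(rnorm(20, 25, 3), 4, 5)
  a25 <- annicchiarico(as_cell_means(m4), alpha = 0.25)$li_general
  a05 <- annicchiarico(as_cell_means(m4), alpha = 0.05)$li_general
  expect_true(all(a05 <= a25))

  # favorable/unfavorable split covers all environments
  cm4 <- as_cell_means(m4)
  ei <- environmental_index(cm4)
  expect_equal(sum(ei$favorable) + sum(!ei$favorable), 5L)
})

test_that("dispersion measures use plot-level and mean-level denominators", {
  met <- rand_met(g = 4L, e = 3L, r = 3L, seed = 71L)
  cm <- cell_means(met, "trait")
  dm <- dispersion_measures(met, cm, "trait")
  d <- as.data.frame(met)
  for (i in seq_along(cm$genotypes)) {
    x <- d$value[d$genotype == cm$genotypes[i]]
    expect_equal(dm$dp[i], sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
    expect_equal(dm$s2x[i], stats::var(cm$means[i, ]), tolerance = 1e-12)
  }
  # an exactly constant genotype has zero dispersion on both scales
  dflat <- as.data.frame(met)
  dflat$value[dflat$genotype == "G01"] <- 9
  metf <- as_met_table(dflat)
  dmf <- dispersion_measures(metf, cell_means(metf, "trait"), "trait")
  expect_equal(dmf$dp[1], 0)
  expect_equal(dmf$s2x[1], 0)
  # env means (10, 14) -> s2x = 8
  expect_equal(unname(stats::var(c(10, 14))), 8)
})

test_that("Nassar-Huehn statistics match the pairwise brute-force oracle", {
  set.seed(37)
  m <- matrix(rnorm(9, 20, 4), 3, 3)
  cm <- as_cell_means(m)
  nh <- nassar_huehn(cm)
  corrected <- m - rowMeans(m) + mean(m)
  r <- apply(corrected, 2L, rank)
  pairs <- utils::combn(3, 2)
  for (i in 1:3) {
    expect_equal(nh$si1[i], 2 * sum(abs(r[i, pairs[1, ]] -
                                          r[i, pairs[2, ]])) / (3 * 2),
                 tolerance = 1e-12)
    expect_equal(nh$si6[i], sum(abs(r[i, ] - mean(r[i, ]))) / mean(r[i, ]),
                 tolerance = 1e-12)
  }

  # constant-rank genotype scores zero on both statistics
  mc <- rbind(c(30, 40, 50), c(20, 30, 40), c(10, 20, 30))
  nhc <- nassar_huehn(as_cell_means(mc), corrected = FALSE)
  expect_equal(nhc$si1, rep(0, 3))
  expect_equal(nhc$si6, rep(0, 3))

  # alternating extremes maximize Si1 among the tested genotypes
  ma <- rbind(c(10, 30, 10, 30), c(30, 10, 30, 10),
              c(20, 20.5, 20, 20.5), c(21, 19.5, 21, 19.5))
  nha <- nassar_huehn(as_cell_means(ma), corrected = FALSE)
  expect_true(all(nha$si1[1:2] >= nha$si1[3:4]))
  expect_equal(max(nha$si1), max(nha$si1[1:2]))
})

test_that("the additive fixture zeroes every interaction-driven index", {
  met <- toy_fixture("additive_no_ge")
  st <- stability_indices(met, "trait")
  expect_equal(st$wi, rep(0, 4), tolerance = 1e-10)
  expect_equal(st$rmse, rep(0, 4), tolerance = 1e-10)
  expect_equal(st$si1, rep(0, 4), tolerance = 1e-10)
  expect_equal(st$si6, rep(0, 4), tolerance = 1e-10)
  expect_equal(st$s2x, rep(stats::var(c(-4, -2, 2, 4)), 4),
               tolerance = 1e-10)
  # Pi is zero only for the uniformly best genotype
  expect_equal(st$pi[4], 0, tolerance = 1e-10)
  expect_true(all(st$pi[1:3] > 0))
})
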