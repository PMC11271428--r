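# Independent oracles and small fixtures shared across the test files.

# a modest random balanced MET for property checks
rand_met <- function(g = 5L, e = 4L, r = 3L, seed = 1L, mu = 25,
                     var_g = 9, var_ge = 4, var_error = 2.25) {
  generate_met(synthetic_config(
    n_genotypes = g, n_environments = e, n_blocks = r, grand_mean = mu,
    var_g = var_g, var_ge = var_ge, var_error = var_error,
    env_effect_sd = 3, block_effect_sd = 1, seed = seed))
}

# explicit mean-decomposition ANOVA for the joint RCBD-within-environment
# layout: computed from raw sums, no model-fitting code involved
joint_ss_oracle <- function(met, trait) {
  d <- as.data.frame(met)
  d <- d[d$trait == trait, ]
  gm <- mean(d$value)
  gi <- tapply(d$value, d$genotype, mean)
  ej <- tapply(d$value, d$environment, mean)
  cellm <- tapply(d$value, list(d$genotype, d$environment), mean)
  blkm <- tapply(d$value, list(d$environment, d$block), mean)
  g <- length(gi); e <- length(ej)
  r <- nrow(d) / (g * e)
  ss_g <- e * r * sum((gi - gm)^2)
  ss_e <- g * r * sum((ej - gm)^2)
  ss_b <- g * sum((blkm - rowMeans(blkm)[row(blkm)])^2)
  z <- sweep(sweep(cellm, 1L, gi), 2L, ej) + gm
  ss_ge <- r * sum(z^2)
  ss_tot <- sum((d$value - gm)^2)
  c(genotypes = ss_g, environments = ss_e, blocks_within_env = ss_b,
    gxe = ss_ge, residual = ss_tot - ss_g - ss_e - ss_b - ss_ge,
    total = ss_tot)
}

# EM-REML for y = X beta + Zg g + Zge ge + eps on balanced data, iterated to
# a tight fixed point; returns variance components and BLUPs. This solves the
# mixed-model equations numerically and never uses the package's closed forms.
em_reml_blup <- function(met, trait, tol = 1e-12, maxit = 50000L) {
  d <- as.data.frame(met)
  d <- d[d$trait == trait, ]
  for (f in c("genotype", "environment", "block")) {
    d[[f]] <- factor(d[[f]], levels = unique(d[[f]]))
  }
  y <- d$value
  X <- stats::model.matrix(~ environment + environment:block, data = d)
  qx <- qr(X)
  X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  Zg <- stats::model.matrix(~ genotype - 1, data = d)
  Zge <- stats::model.matrix(~ genotype:environment - 1, data = d)
  Z <- cbind(Zg, Zge)
  p <- ncol(X); qg <- ncol(Zg); qge <- ncol(Zge)
  W <- cbind(X, Z)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  n <- length(y)
  ig <- p + seq_len(qg)
  ige <- p + qg + seq_len(qge)
  s <- c(g = stats::var(y) / 3, ge = stats::var(y) / 3, e = stats::var(y) / 3)
  for (it in seq_len(maxit)) {
    C <- WtW
    diag(C)[ig] <- diag(WtW)[ig] + s["e"] / s["g"]
    diag(C)[ige] <- diag(WtW)[ige] + s["e"] / s["ge"]
    Cinv <- solve(C)
    sol <- Cinv %*% Wty
    ug <- sol[ig]; uge <- sol[ige]
    new <- c(
      g = (sum(ug^2) + s[["e"]] * sum(diag(Cinv)[ig])) / qg,
      ge = (sum(uge^2) + s[["e"]] * sum(diag(Cinv)[ige])) / qge,
      e = (sum(y^2) - sum(sol * Wty)) / (n - p)
    )
    if (max(abs(new - s) / pmax(abs(s), 1e-8)) < tol) {
      s <- new
      break
    }
    s <- new
  }
  C <- WtW
  diag(C)[ig] <- diag(WtW)[ig] + s["e"] / s["g"]
  diag(C)[ige] <- diag(WtW)[ige] + s["e"] / s["ge"]
  sol <- solve(C, Wty)
  g_hat <- stats::setNames(as.vector(sol[ig]),
                           sub("^genotype", "", colnames(Zg)))
  ge_hat <- as.vector(sol[ige])
  nm <- sub("^genotype", "", colnames(Zge))
  parts <- do.call(rbind, strsplit(nm, ":environment"))
  gens <- levels(d$genotype); envs <- levels(d$environment)
  m <- matrix(NA_real_, length(gens), length(envs),
              dimnames = list(gens, envs))
  m[cbind(parts[, 1L], parts[, 2L])] <- ge_hat
  list(var = s, g = g_hat, ge = m)
}

# recursive Scott-Knott oracle coded independently: enumerate every
# contiguous cut, score it by explicit group sums, apply the likelihood test
scott_knott_oracle <- function(means, ms_error, df_error, reps, alpha) {
  s2y <- ms_error / reps
  recurse <- function(m) {
    g <- length(m)
    if (g < 2L) return(list(names(m)))
    b0 <- vapply(seq_len(g - 1L), function(cut) {
      g1 <- m[seq_len(cut)]; g2 <- m[-seq_len(cut)]
      length(g1) * (mean(g1) - mean(m))^2 +
        length(g2) * (mean(g2) - mean(m))^2
    }, 0)
    cut <- which.max(b0)
    sigma0 <- (sum((m - mean(m))^2) + df_error * s2y) / (g + df_error)
    lambda <- pi / (2 * (pi - 2)) * max(b0) / sigma0
    if (lambda <= stats::qchisq(1 - alpha, g / (pi - 2))) {
      return(list(names(m)))
    }
    c(recurse(m[seq_len(cut)]), recurse(m[-seq_len(cut)]))
  }
  recurse(sort(means, decreasing = TRUE))
}
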