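# EM machinery for the 16-component mixture.

test_that("log_likelihood matches a direct-summation oracle", {
  set.seed(11)
  inst <- random_instance(25)
  u <- rnorm(16); s2 <- 1.7
  expect_equal(log_likelihood(inst$omega, u, s2, inst$y),
               oracle_loglik(inst$omega, u, s2, inst$y), tolerance = 1e-12)
  # degenerate omega on one component at the sample mean: plain normal fit
  omega1 <- matrix(0, 25, 16); omega1[, 5] <- 1
  ybar <- mean(inst$y)
  expect_equal(log_likelihood(omega1, rep(ybar, 16), s2, inst$y),
               sum(dnorm(inst$y, ybar, sqrt(s2), log = TRUE)))
  # equal means: likelihood independent of omega
  expect_equal(log_likelihood(inst$omega, rep(1.3, 16), s2, inst$y),
               log_likelihood(omega1, rep(1.3, 16), s2, inst$y))
  expect_error(log_likelihood(inst$omega, u, -1, inst$y), "positive")
})

test_that("e_step handles uniform, degenerate and extreme inputs", {
  set.seed(12)
  n <- 30
  omega <- matrix(1 / 16, n, 16)
  y <- rnorm(n)
  P <- e_step(omega, rep(0, 16), 1, y)
  expect_equal(P, matrix(1 / 16, n, 16), tolerance = 1e-12)

  omega_deg <- matrix(0, n, 16); omega_deg[, 7] <- 1
  P <- e_step(omega_deg, rnorm(16), 1, y)
  expect_equal(P[, 7], rep(1, n))

  # huge |y - u|: no overflow/underflow, rows still normalised
  y_big <- c(1e6, -1e6, rnorm(n - 2))
  P <- e_step(matrix(rexp(n * 16), n, 16), rnorm(16), 0.5, y_big)
  expect_true(all(is.finite(P)))
  expect_equal(rowSums(P), rep(1, n), tolerance = 1e-12)
})

test_that("m_step reduces to class means and increases the Q-function", {
  set.seed(13)
  n <- 64
  cls <- sample.int(16, n, replace = TRUE)
  y <- rnorm(n, mean = cls)
  hard <- matrix(0, n, 16); hard[cbind(1:n, cls)] <- 1
  res <- m_step(hard, y)
  for (g in unique(cls))
    expect_equal(res$u[g], mean(y[cls == g]))
  expect_equal(res$sigma2,
               sum((y - res$u[cls])^2) / n)

  # uniform posteriors: all means collapse to the sample mean
  res_u <- m_step(matrix(1 / 16, n, 16), y)
  expect_equal(res_u$u, rep(mean(y), 16))

  # Q-function increase over the previous parameter value
  inst <- random_instance(50)
  u_old <- rnorm(16); s2_old <- 2
  P <- e_step(inst$omega, u_old, s2_old, inst$y)
  res <- m_step(P, inst$y)
  expect_gt(oracle_Q(P, inst$omega, res$u, res$sigma2, inst$y),
            oracle_Q(P, inst$omega, u_old, s2_old, inst$y) - 1e-10)
})

test_that("constrained_m_step enforces its constraint exactly", {
  set.seed(14)
  n <- 80
  inst <- random_instance(n)
  P <- e_step(inst$omega, rnorm(16), 2, inst$y)
  for (eff in c("alpha1", "J_bg", "L_gg")) {
    cvec <- effect_contrast(eff)$coefficient
    res <- constrained_m_step(P, inst$y, eff)
    expect_lt(abs(sum(cvec * res$u)), 1e-10)
    # the constrained solution cannot beat the unconstrained Q-value
    free <- m_step(P, inst$y)
    expect_lte(oracle_Q(P, inst$omega, res$u, res$sigma2, inst$y),
               oracle_Q(P, inst$omega, free$u, free$sigma2, inst$y) + 1e-10)
  }
  # unconstrained means already satisfying the constraint are unchanged
  Pu <- matrix(1 / 16, n, 16)
  res <- constrained_m_step(Pu, inst$y, "alpha1")
  expect_equal(res$u, rep(mean(inst$y), 16))
  # equal class masses: closed form ybar - c * mean(c * ybar) * 16/16
  hard <- matrix(0, 32, 16); hard[cbind(1:32, rep(1:16, 2))] <- 1
  yh <- rnorm(32)
  ybar <- vapply(1:16, function(g) mean(yh[rep(1:16, 2) == g]), 0)
  cvec <- effect_contrast("I_bb")$coefficient
  res <- constrained_m_step(hard, yh, "I_bb")
  expect_equal(res$u, ybar - cvec * sum(cvec * ybar) / 16, tolerance = 1e-12)
})

test_that("EM log-likelihood is non-decreasing on random instances", {
  set.seed(15)
  for (k in 1:50) {
    inst <- random_instance(40)
    fit <- fit_qtl_mixture(inst$omega, inst$y, tol = 1e-8, max_iter = 300,
                           keep_posteriors = FALSE)
    expect_gt(min(diff(fit$loglik_trace)), -1e-8)
  }
})

test_that("the compiled EM reproduces the R step functions", {
  set.seed(16)
  inst <- random_instance(60)
  # hand-rolled EM from the same deterministic initialisation; the
  # log-likelihood trace entry k belongs to the parameters after k - 1
  # M-steps
  u <- unname(drop(crossprod(inst$omega, inst$y))) / unname(colSums(inst$omega))
  s2 <- mean((inst$y - mean(inst$y))^2)
  lls <- numeric(25)
  for (it in 1:25) {
    lls[it] <- log_likelihood(inst$omega, u, s2, inst$y)
    P <- e_step(inst$omega, u, s2, inst$y)
    res <- m_step(P, inst$y, prev_u = u)
    u <- res$u; s2 <- res$sigma2
  }
  fit <- fit_qtl_mixture(inst$omega, inst$y, tol = 0, max_iter = 25)
  expect_equal(fit$loglik_trace, lls, tolerance = 1e-9)
  expect_equal(unname(fit$genotype_values), unname(u), tolerance = 1e-9)
  expect_equal(fit$sigma2, s2, tolerance = 1e-9)
  # with a constraint as well
  fitc <- fit_qtl_mixture(inst$omega, inst$y, constraint = "gamma2",
                          tol = 0, max_iter = 25)
  uc <- unname(drop(crossprod(inst$omega, inst$y))) / unname(colSums(inst$omega))
  s2c <- mean((inst$y - mean(inst$y))^2)
  for (it in 1:25) {
    P <- e_step(inst$omega, uc, s2c, inst$y)
    res <- constrained_m_step(P, inst$y, "gamma2", prev_u = uc)
    uc <- res$u; s2c <- res$sigma2
  }
  expect_equal(unname(fitc$genotype_values), unname(uc), tolerance = 1e-9)
})

test_that("constrained fits satisfy the constraint and never beat the full fit", {
  set.seed(18)
  fam <- simulate_family(sim_preset(n = 150, h2 = 0.4))
  omega <- omega_table(fam, "G1", 30, "G1", 70)
  y <- fam$pheno$value
  full <- fit_qtl_mixture(omega, y, keep_posteriors = FALSE)
  for (eff in c("alpha1", "gamma1", "I_ab", "K_gb", "L_gg")) {
    con <- fit_qtl_mixture(omega, y, constraint = eff,
                           keep_posteriors = FALSE)
    cvec <- effect_contrast(eff)$coefficient
    scale <- max(abs(con$genotype_values))
    expect_lt(abs(sum(cvec * con$genotype_values)), 1e-8 * scale)
    expect_lte(con$loglik, full$loglik + 1e-8)
    expect_equal(con$constraint, eff)
  }
})

test_that("hard assignments with tiny noise are recovered immediately", {
  set.seed(19)
  n <- 160
  cls <- rep(1:16, 10)
  u_true <- seq(10, 40, length.out = 16)
  y <- u_true[cls] + rnorm(n, sd = 1e-8)
  omega <- matrix(0, n, 16); omega[cbind(1:n, cls)] <- 1
  fit <- fit_qtl_mixture(omega, y, keep_posteriors = FALSE)
  class_means <- vapply(1:16, function(g) mean(y[cls == g]), 0)
  expect_equal(unname(fit$genotype_values), class_means, tolerance = 1e-10)
})

test_that("the EM optimum survives a multi-restart optimiser challenge", {
  set.seed(20)
  fam <- simulate_family(sim_preset(n = 48, h2 = 0.4))
  inst <- list(omega = omega_table(fam, "G1", 32, "G1", 68),
               y = fam$pheno$value)
  fit1 <- fit_qtl_mixture(inst$omega, inst$y, keep_posteriors = FALSE)
  fit <- fit_qtl_mixture(inst$omega, inst$y, n_start = 25,
                         keep_posteriors = FALSE)
  # extra starts can only improve on the deterministic start
  expect_gte(fit$loglik, fit1$loglik - 1e-8)
  negll <- function(par) {
    s2 <- exp(par[17])
    if (!is.finite(s2) || s2 <= 0) return(1e10)
    -log_likelihood(inst$omega, par[1:16], s2, inst$y)
  }
  best <- -Inf
  ybar <- mean(inst$y)
  for (k in 1:100) {
    par0 <- c(rnorm(16, ybar, sd = 2), log(runif(1, 0.5, 6)))
    opt <- suppressWarnings(
      optim(par0, negll, method = "BFGS", control = list(maxit = 300)))
    best <- max(best, -opt$value)
  }
  expect_gte(fit$loglik, best - 1e-6)
})

test_that("null single-mean model matches its closed form", {
  expect_equal(fit_null_single_mean(c(0, 2)),
               list(mu = 1, sigma2 = 1,
                    loglik = -1 * (log(2 * pi * 1) + 1)))
  set.seed(21)
  y <- rnorm(40, 5, 2)
  nullfit <- fit_null_single_mean(y)
  omega <- matrix(1 / 16, 40, 16)
  expect_equal(nullfit$loglik,
               log_likelihood(omega, rep(nullfit$mu, 16), nullfit$sigma2, y),
               tolerance = 1e-10)
  expect_error(fit_null_single_mean(rep(3, 10)), "constant")
})

test_that("effects are recovered at the true positions (large n)", {
  set.seed(22)
  res <- replicate_study(n = 2000, h2 = 0.4, n_rep = 60, scan = FALSE)
  truth <- reference_effects()
  # per-replicate sampling s.d. of each effect estimate at n = 2000 is
  # roughly 0.5-0.75 trait units for this design; the mean absolute error
  # must stay within three times that scale
  se <- c(mu = 0.51, alpha1 = 0.55, beta1 = 0.54, gamma1 = 0.58,
          alpha2 = 0.53, beta2 = 0.53, gamma2 = 0.60,
          I_aa = 0.61, I_ab = 0.59, I_ba = 0.61, I_bb = 0.60,
          J_ag = 0.67, J_bg = 0.65, K_ga = 0.67, K_gb = 0.64, L_gg = 0.73)
  for (eff in effect_names()) {
    mae <- mean(abs(res[[eff]] - truth[[eff]]))
    expect_lt(mae, 3 * se[[eff]])
  }
  expect_lt(abs(mean(res$sigma2) - 222.375) / 222.375, 0.05)
})
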