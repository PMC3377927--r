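# Independent oracles used across the test files: straightforward, slow
# reimplementations that do not share code with the package internals.

# mixture log-likelihood by plain double loop
oracle_loglik <- function(omega, u, sigma2, y) {
  tot <- 0
  for (i in seq_along(y)) {
    s <- 0
    for (g in seq_len(ncol(omega)))
      s <- s + omega[i, g] * dnorm(y[i], u[g], sqrt(sigma2))
    tot <- tot + log(s)
  }
  unname(tot)
}

# EM Q-function: expected complete-data log-likelihood under posteriors P
oracle_Q <- function(P, omega, u, sigma2, y) {
  q <- 0
  for (i in seq_along(y)) for (g in seq_len(ncol(P))) {
    if (P[i, g] > 0)
      q <- q + P[i, g] *
        (log(omega[i, g]) + dnorm(y[i], u[g], sqrt(sigma2), log = TRUE))
  }
  unname(q)
}

# joint origin probabilities of two QTL between two flanking markers by
# exhaustive enumeration of the 16 origin configurations of
# (left marker, qtl1, qtl2, right marker) under the Haldane Markov chain
oracle_same_interval <- function(oL, oR, d_left, d_mid, d_right) {
  stay <- function(d) 1 - epiqtl::haldane_r(d)
  move <- function(a, b, d) if (a == b) stay(d) else epiqtl::haldane_r(d)
  joint <- matrix(0, 2, 2, dimnames = list(o1 = 0:1, o2 = 0:1))
  for (o1 in 0:1) for (o2 in 0:1)
    joint[o1 + 1, o2 + 1] <-
      0.5 * move(oL, o1, d_left) * move(o1, o2, d_mid) * move(o2, oR, d_right)
  # condition on the observed flanks
  joint / sum(joint)
}

# a small two-group map for fast scans
tiny_map <- function() {
  tibble::tibble(
    group = rep(c("G1", "G2"), each = 3),
    marker = paste0("M", 1:6),
    position = rep(c(0, 20, 40), 2)
  )
}

# family with pure-noise phenotypes (no QTL anywhere)
null_family <- function(n, map = tiny_map()) {
  cfg <- epiqtl::sim_config(
    map,
    qtl1 = list(group = "G1", pos = 10), qtl2 = list(group = "G2", pos = 30),
    effects = epiqtl::reference_effects(), h2 = 0.4, n = n)
  fam <- epiqtl::simulate_family(cfg)
  fam$pheno$value <- rnorm(n)
  fam$truth <- NULL
  fam
}

# random mixture instance for EM property tests
random_instance <- function(n, seed_shift = 0) {
  omega <- matrix(rexp(n * 16), n, 16)
  omega <- omega / rowSums(omega)
  colnames(omega) <- epiqtl::two_locus_genotype_labels()
  u <- rnorm(16, sd = 3)
  y <- u[sample.int(16, n, replace = TRUE)] + rnorm(n, sd = 2)
  list(omega = omega, y = y)
}
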