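# Two-dimensional genome scan for a pair of interacting QTL: grid search
# over position pairs, likelihood-ratio statistic against the single-mean
# (no-QTL) null, permutation thresholds, and constrained-EM tests for each
# of the 15 genetic effects at fixed positions.

#' Likelihood-ratio statistic between nested fits
#'
#' `LR = 2 * (loglik_full - loglik_null)`.  Tiny negative values (within
#' 1e-6 of zero, numerical noise) are clipped to 0.
#'
#' @param full An `em_fit` object (the full 16-mean model).
#' @param null_loglik The null log-likelihood: a number or the list
#'   returned by [fit_null_single_mean()].
#' @return The LR statistic (non-negative up to numerical slack).
#' @export
lr_statistic <- function(full, null_loglik) {
  if (is.list(null_loglik)) null_loglik <- null_loglik$loglik
  stopifnot(inherits(full, "em_fit"), is.numeric(null_loglik))
  lr <- 2 * (full$loglik - null_loglik)
  if (lr < 0 && lr > -1e-6) lr <- 0
  lr
}

# grid of candidate positions along a group's marker span
.position_grid <- function(map, group, step) {
  mpos <- sort(map$position[map$group == group])
  if (length(mpos) < 2)
    stop("linkage group '", group, "' not found or has fewer than 2 markers",
         call. = FALSE)
  sort(unique(c(seq(mpos[1], mpos[length(mpos)], by = step),
                mpos[length(mpos)])))
}

# n x 2 single-position origin conditionals for every grid position,
# per parent; used to assemble omega tables cheaply across the grid
.grid_singles <- function(family, group, grid) {
  om <- .origin_matrices(family, group)
  lapply(c(p1 = "p1", p2 = "p2"), function(par)
    lapply(grid, function(p) .gamete_one_qtl(om[[par]], om$pos, p)))
}

# omega for a pair of positions in distinct intervals (factorised form)
.omega_from_singles <- function(s1_p1, s1_p2, s2_p1, s2_p2) {
  n <- nrow(s1_p1)
  omega <- matrix(0, n, 16)
  g <- 0L
  for (u1 in 1:2) for (v1 in 1:2) for (u2 in 1:2) for (v2 in 1:2) {
    g <- g + 1L
    omega[, g] <- s1_p1[, u1] * s2_p1[, u2] * s1_p2[, v1] * s2_p2[, v2]
  }
  colnames(omega) <- two_locus_genotype_labels()
  omega
}

#' Two-dimensional likelihood-ratio scan for an interacting QTL pair
#'
#' Evaluates the EM fit of the two-QTL mixture at every pair of grid
#' positions (one on each group; on a single group, only pairs lying in
#' distinct marker intervals with `pos1 < pos2`) and reports
#' `LR = 2 (loglik_pair - loglik_single_mean)` against the no-QTL null.
#' The best pair is the LR maximum, ties broken towards the
#' lexicographically smallest positions; the fit at the best pair is
#' refitted and returned with its genetic-effect estimates.
#'
#' @inheritParams omega_table
#' @param step Grid step in cM (default 2).
#' @param em_tol,em_max_iter,min_class_mass EM controls, see
#'   [fit_qtl_mixture()].
#' @return An object of class `fs_scan`: list with `surface` (a tibble
#'   with one row per evaluated pair: `group1, pos1, group2, pos2, lr,
#'   loglik, n_iter, converged`), `best` (one-row tibble), `best_fit`
#'   (the refitted `em_fit`), `null` (single-mean fit), `step` and
#'   `n_nonconverged`.
#' @examples
#' \donttest{
#' fam <- simulate_family(sim_preset(n = 400, h2 = 0.4, seed = 11))
#' sc <- scan_qtl_pair(fam, "G1", step = 10)
#' glance(sc)
#' }
#' @export
scan_qtl_pair <- function(family, group1, group2 = group1, step = 2,
                          em_tol = 1e-8, em_max_iter = 2000,
                          min_class_mass = 1e-10) {
  y <- family$pheno$value
  null <- fit_null_single_mean(y)
  map <- family$map
  grid1 <- .position_grid(map, group1, step)
  grid2 <- .position_grid(map, group2, step)
  same <- identical(group1, group2)

  if (same) {
    mpos <- sort(map$position[map$group == group1])
    iv1 <- vapply(grid1, .interval_index, 1L, mpos = mpos)
    pairs <- tidyr::expand_grid(i = seq_along(grid1), j = seq_along(grid2))
    pairs <- pairs[iv1[pairs$i] < iv1[pairs$j] & grid1[pairs$i] < grid2[pairs$j], ]
  } else {
    pairs <- tidyr::expand_grid(i = seq_along(grid1), j = seq_along(grid2))
  }
  if (nrow(pairs) == 0) stop("empty scan grid", call. = FALSE)

  s1 <- .grid_singles(family, group1, grid1)
  s2 <- if (same) s1 else .grid_singles(family, group2, grid2)

  m <- nrow(pairs)
  lr <- loglik <- numeric(m)
  n_iter <- integer(m)
  conv <- logical(m)
  for (k in seq_len(m)) {
    i <- pairs$i[k]; j <- pairs$j[k]
    omega <- .omega_from_singles(s1$p1[[i]], s1$p2[[i]],
                                 s2$p1[[j]], s2$p2[[j]])
    fit <- fit_qtl_mixture(omega, y, tol = em_tol, max_iter = em_max_iter,
                           min_class_mass = min_class_mass,
                           keep_posteriors = FALSE)
    loglik[k] <- fit$loglik
    lr[k] <- lr_statistic(fit, null)
    n_iter[k] <- fit$n_iter
    conv[k] <- fit$converged
  }

  surface <- tibble::tibble(
    group1 = group1, pos1 = grid1[pairs$i],
    group2 = group2, pos2 = grid2[pairs$j],
    lr = lr, loglik = loglik, n_iter = n_iter, converged = conv
  )
  ord <- order(-surface$lr, surface$pos1, surface$pos2)
  best <- surface[ord[1], ]
  best_fit <- fit_qtl_pair(family, group1, best$pos1, group2, best$pos2,
                           tol = em_tol, max_iter = em_max_iter,
                           min_class_mass = min_class_mass,
                           keep_posteriors = FALSE)

  structure(
    list(surface = surface, best = best, best_fit = best_fit, null = null,
         step = step, n_nonconverged = sum(!conv)),
    class = "fs_scan"
  )
}

#' @export
print.fs_scan <- function(x, ...) {
  cat("<fs_scan> ", nrow(x$surface), " position pairs (step ", x$step,
      " cM)\n  max LR = ", format(x$best$lr, digits = 6), " at ",
      x$best$group1, ":", x$best$pos1, " x ", x$best$group2, ":",
      x$best$pos2, " cM\n", sep = "")
  if (x$n_nonconverged > 0)
    cat("  warning: ", x$n_nonconverged, " grid fits did not converge\n",
        sep = "")
  invisible(x)
}

#' @rdname tidy.em_fit
#' @export
tidy.fs_scan <- function(x, ...) x$surface

#' @rdname tidy.em_fit
#' @export
glance.fs_scan <- function(x, ...) {
  tibble::tibble(
    group1 = x$best$group1, pos1 = x$best$pos1,
    group2 = x$best$group2, pos2 = x$best$pos2,
    lr = x$best$lr, sigma2 = x$best_fit$sigma2,
    n_pairs = nrow(x$surface), n_nonconverged = x$n_nonconverged
  )
}

#' Plot a two-dimensional LR surface
#'
#' Heat map of the likelihood-ratio surface over the scanned position
#' pairs, with the maximum marked.
#'
#' @param object An `fs_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_scan <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = .data$pos1, y = .data$pos2,
                               fill = .data$lr)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, shape = 4, size = 3,
                        colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "LR") +
    ggplot2::labs(
      x = paste0("QTL 1 position on ", object$best$group1, " (cM)"),
      y = paste0("QTL 2 position on ", object$best$group2, " (cM)")
    ) +
    ggplot2::theme_minimal()
}

#' Permutation threshold for the pairwise scan
#'
#' Permutes the phenotypes against the fixed marker genotypes, rescans the
#' group pair for each permutation, and returns the empirical
#' `(1 - alpha)` quantile (order statistic `ceiling((1 - alpha) * n_perm)`)
#' of the per-permutation maximum LR — the group-pair-wide critical value
#' for declaring a pair of interacting QTL.
#'
#' @inheritParams scan_qtl_pair
#' @param n_perm Number of permutations (1000 for production use; smaller
#'   values are useful for checks).
#' @param alpha Significance level in (0, 1).
#' @param seed Optional seed for the permutation stream.
#' @return An object of class `fs_perm`: list with `threshold`,
#'   `max_lr_draws`, `n_perm`, `alpha`.
#' @export
permutation_threshold <- function(family, group1, group2 = group1,
                                  n_perm = 1000, alpha = 0.05, step = 2,
                                  seed = NULL, em_tol = 1e-8,
                                  em_max_iter = 2000) {
  stopifnot(n_perm >= 1, alpha > 0, alpha < 1)
  if (!is.null(seed)) set.seed(seed)
  if (n_perm * alpha < 1)
    warning("n_perm * alpha < 1: threshold is the largest permutation draw",
            call. = FALSE)
  perm_family <- family
  draws <- vapply(seq_len(n_perm), function(b) {
    perm_family$pheno$value <- sample(family$pheno$value)
    sc <- scan_qtl_pair(perm_family, group1, group2, step = step,
                        em_tol = em_tol, em_max_iter = em_max_iter)
    sc$best$lr
  }, numeric(1))
  k <- min(max(ceiling((1 - alpha) * n_perm), 1L), n_perm)
  structure(
    list(threshold = sort(draws)[k], max_lr_draws = draws,
         n_perm = n_perm, alpha = alpha),
    class = "fs_perm"
  )
}

#' @export
print.fs_perm <- function(x, ...) {
  cat("<fs_perm> ", x$n_perm, " permutations, alpha = ", x$alpha,
      ", threshold = ", format(x$threshold, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio tests of the 15 individual genetic effects
#'
#' At fixed QTL positions (typically the scan maximum), refits the mixture
#' under each single-effect null constraint (the effect's +/-1 contrast on
#' the genotypic values set to zero) and reports
#' `LR = 2 (loglik_full - loglik_constrained)` per effect.
#'
#' @inheritParams fit_qtl_pair
#' @param full Optional pre-computed unconstrained `em_fit` at the same
#'   positions (saves one fit).
#' @param threshold Optional critical value; adds a `significant` column.
#' @param ... EM controls passed to the fits.
#' @return A tibble with one row per effect: `effect`, `estimate` (from
#'   the full fit), `loglik_constrained`, `lr` and optionally
#'   `significant`.  The full fit is attached as attribute `"full_fit"`.
#' @examples
#' \donttest{
#' fam <- simulate_family(sim_preset(n = 400, h2 = 0.4, seed = 3))
#' effect_tests(fam, "G1", 30, "G1", 70)
#' }
#' @export
effect_tests <- function(family, group1, pos1, group2, pos2, full = NULL,
                         threshold = NULL, ...) {
  omega <- omega_table(family, group1, pos1, group2, pos2)
  y <- family$pheno$value
  if (is.null(full))
    full <- fit_qtl_mixture(omega, y, keep_posteriors = FALSE, ...)
  stopifnot(inherits(full, "em_fit"))
  est <- tidy(full)
  out <- purrr::map_dfr(setdiff(effect_names(), "mu"), function(eff) {
    con <- fit_qtl_mixture(omega, y, constraint = eff,
                           keep_posteriors = FALSE, ...)
    lr <- 2 * (full$loglik - con$loglik)
    if (lr < 0 && lr > -1e-6) lr <- 0
    tibble::tibble(effect = eff,
                   estimate = est$value[est$effect == eff],
                   loglik_constrained = con$loglik, lr = lr)
  })
  if (!is.null(threshold)) out$significant <- out$lr > threshold
  attr(out, "full_fit") <- full
  out
}

#' Simulated critical values for a single-effect test
#'
#' Parametric bootstrap under the null of one effect being zero: fits the
#' constrained model at the given positions, simulates phenotypes from that
#' constrained MLE (genotypes drawn from each offspring's conditional
#' probabilities), re-runs the effect's LR test on each simulated dataset,
#' and returns the empirical `(1 - alpha)` quantile of the null LR draws.
#'
#' @inheritParams effect_tests
#' @param effect The effect to calibrate (one of the 15 non-intercept
#'   names).
#' @param n_sim Number of simulated null datasets.
#' @param alpha Significance level.
#' @param seed Optional seed.
#' @return A list with `threshold`, `draws`, `n_sim`, `alpha`.
#' @export
effect_test_threshold <- function(family, group1, pos1, group2, pos2,
                                  effect, n_sim = 200, alpha = 0.05,
                                  seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  omega <- omega_table(family, group1, pos1, group2, pos2)
  y <- family$pheno$value
  n <- length(y)
  con0 <- fit_qtl_mixture(omega, y, constraint = effect,
                          keep_posteriors = FALSE, ...)
  u0 <- con0$genotype_values
  s0 <- sqrt(con0$sigma2)
  draws <- vapply(seq_len(n_sim), function(b) {
    g <- vapply(seq_len(n),
                function(i) sample.int(16L, 1L, prob = omega[i, ]), 1L)
    yb <- u0[g] + rnorm(n, 0, s0)
    fullb <- fit_qtl_mixture(omega, yb, keep_posteriors = FALSE, ...)
    conb <- fit_qtl_mixture(omega, yb, constraint = effect,
                            keep_posteriors = FALSE, ...)
    max(2 * (fullb$loglik - conb$loglik), 0)
  }, numeric(1))
  k <- min(max(ceiling((1 - alpha) * n_sim), 1L), n_sim)
  list(threshold = sort(draws)[k], draws = draws, n_sim = n_sim,
       alpha = alpha)
}
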