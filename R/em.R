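# EM fitting of the 16-component normal mixture at fixed QTL positions.
# The mixture weights (omega) carry the QTL-position information; the
# component means are the 16 genotypic values, sharing one residual
# variance.  The E and M steps have closed forms; a single linear
# constraint on the means (one effect set to zero) is handled exactly in
# the M step by a Lagrange multiplier.

#' Mixture log-likelihood of the two-QTL model
#'
#' `sum_i log sum_g omega[i, g] * dnorm(y[i], u[g], sqrt(sigma2))` —
#' the observed-data log-likelihood at fixed QTL positions.
#'
#' @param omega An n x 16 matrix of conditional QTL-genotype probabilities
#'   (rows sum to 1), as from [omega_table()].
#' @param u The 16 genotypic values (numeric vector, canonical order).
#' @param sigma2 Residual variance, > 0.
#' @param y Phenotypes (length n).
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(omega, u, sigma2, y) {
  stopifnot(is.matrix(omega), length(y) == nrow(omega),
            length(u) == ncol(omega))
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 <= 0)
    stop("sigma2 must be a single positive number", call. = FALSE)
  ld <- -0.5 * log(2 * pi * sigma2) -
    outer(y, as.numeric(u), `-`)^2 / (2 * sigma2)
  lw <- log(omega) + ld           # -Inf where omega == 0
  m <- apply(lw, 1, max)
  sum(m + log(rowSums(exp(lw - m))))
}

#' E step: posterior QTL-genotype probabilities
#'
#' `P[i, g]` proportional to `omega[i, g] * dnorm(y[i], u[g], sqrt(sigma2))`,
#' normalised per row; computed via log densities with per-row max
#' subtraction so extreme phenotypes do not underflow.
#'
#' @inheritParams log_likelihood
#' @return An n x 16 matrix of posterior probabilities, rows summing to 1.
#' @export
e_step <- function(omega, u, sigma2, y) {
  stopifnot(is.matrix(omega), length(y) == nrow(omega),
            length(u) == ncol(omega), sigma2 > 0)
  ld <- -outer(y, as.numeric(u), `-`)^2 / (2 * sigma2)
  lw <- log(omega) + ld
  m <- apply(lw, 1, max)
  if (any(!is.finite(m)))
    stop("a row of omega is entirely zero", call. = FALSE)
  w <- exp(lw - m)
  w / rowSums(w)
}

#' M step: closed-form updates of genotypic values and residual variance
#'
#' `u[g] = sum_i P[i, g] y[i] / sum_i P[i, g]` and
#' `sigma2 = (1/n) sum_i sum_g P[i, g] (y[i] - u[g])^2` (maximum-likelihood
#' divisor).  `constrained_m_step()` maximises the same criterion subject
#' to `sum_g c[g] u[g] = 0` for a single +/-1 effect contrast, via the
#' exact Lagrange solution `u[g] = ybar[g] - lambda c[g] / n[g]` with
#' `lambda = sum(c * ybar) / sum(c^2 / n)`.  Classes with posterior mass
#' below `min_mass` keep their previous mean (`prev_u`).
#'
#' @param posteriors An n x 16 posterior matrix from [e_step()].
#' @param y Phenotypes.
#' @param contrast An [effect_contrast()] tibble, an effect name, or a
#'   length-16 coefficient vector.
#' @param prev_u Previous genotypic values, used for empty classes.
#' @param min_mass Mass threshold below which a class is frozen.
#' @return A list with `u` (length 16) and `sigma2`.
#' @export
m_step <- function(posteriors, y, prev_u = NULL, min_mass = 1e-10) {
  stopifnot(is.matrix(posteriors), length(y) == nrow(posteriors))
  ng <- colSums(posteriors)
  u <- drop(crossprod(posteriors, y)) / ng
  if (any(empty <- ng <= min_mass)) {
    if (is.null(prev_u)) prev_u <- rep(mean(y), ncol(posteriors))
    u[empty] <- prev_u[empty]
  }
  resid2 <- outer(y, u, `-`)^2
  list(u = u, sigma2 = sum(posteriors * resid2) / length(y))
}

#' @rdname m_step
#' @export
constrained_m_step <- function(posteriors, y, contrast, prev_u = NULL,
                               min_mass = 1e-10) {
  cvec <- .as_contrast_vector(contrast)
  ng <- colSums(posteriors)
  active <- ng > min_mass
  ybar <- drop(crossprod(posteriors, y))
  ybar[active] <- ybar[active] / ng[active]
  if (is.null(prev_u)) prev_u <- rep(mean(y), ncol(posteriors))
  ybar[!active] <- prev_u[!active]
  off <- sum(cvec[!active] * prev_u[!active])
  lambda <- (sum(cvec[active] * ybar[active]) + off) /
    sum(cvec[active]^2 / ng[active])
  u <- ybar
  u[active] <- ybar[active] - lambda * cvec[active] / ng[active]
  resid2 <- outer(y, u, `-`)^2
  list(u = u, sigma2 = sum(posteriors * resid2) / length(y))
}

.as_contrast_vector <- function(contrast) {
  if (is.character(contrast)) contrast <- effect_contrast(contrast)
  if (is.data.frame(contrast)) contrast <- contrast$coefficient
  stopifnot(is.numeric(contrast), length(contrast) == 16)
  as.numeric(contrast)
}

.contrast_label <- function(contrast) {
  if (is.character(contrast)) return(contrast)
  cvec <- .as_contrast_vector(contrast)
  D <- two_locus_design_matrix()
  hit <- which(colSums(D != matrix(cvec, 16, 16)) == 0)
  if (length(hit)) colnames(D)[hit[1]] else "custom"
}

#' Fit the two-QTL normal mixture by EM
#'
#' Iterates [e_step()] and [m_step()] (or [constrained_m_step()]) until the
#' log-likelihood is stable.  Initialisation is deterministic: the
#' genotypic values start at the omega-weighted class means of `y` and the
#' residual variance at the total phenotypic variance (1/n divisor).  The
#' log-likelihood trace is recorded and is non-decreasing.
#'
#' @inheritParams log_likelihood
#' @param constraint Optional: an effect name (see [effect_names()]), an
#'   [effect_contrast()] tibble, or a length-16 coefficient vector; the fit
#'   then maximises the likelihood subject to that effect being zero.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param min_class_mass Posterior mass below which a class's mean is
#'   frozen for that iteration.
#' @param n_start Number of EM starts.  The first start is always the
#'   deterministic initialisation; additional starts perturb it with
#'   normal noise (using the current RNG stream) and the best final
#'   log-likelihood wins.  The default is a single deterministic start.
#' @param keep_posteriors Return the n x 16 posterior matrix.
#' @return An object of class `em_fit` with elements `genotype_values`
#'   (named length-16 vector), `sigma2`, `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`, `constraint`, `posteriors` (optional) and `n`.
#' @seealso [fit_qtl_pair()] for the position-based interface,
#'   [tidy.em_fit()] and [glance.em_fit()].
#' @export
fit_qtl_mixture <- function(omega, y, constraint = NULL, tol = 1e-8,
                            max_iter = 2000, min_class_mass = 1e-10,
                            n_start = 1, keep_posteriors = TRUE) {
  stopifnot(is.matrix(omega), ncol(omega) == 16, nrow(omega) == length(y))
  if (any(!is.finite(y))) stop("non-finite phenotype", call. = FALSE)
  if (any(rowSums(omega) <= 0))
    stop("a row of omega is entirely zero", call. = FALSE)
  mass <- colSums(omega)
  u0 <- drop(crossprod(omega, y))
  u0 <- ifelse(mass > min_class_mass, u0 / pmax(mass, min_class_mass), mean(y))
  s2_0 <- mean((y - mean(y))^2)
  if (s2_0 <= 0) stop("phenotype is constant; the mixture is degenerate",
                      call. = FALSE)
  cvec <- if (is.null(constraint)) numeric(16) else
    .as_contrast_vector(constraint)
  res <- em_fit_cpp(omega, y, u0, s2_0, tol, as.integer(max_iter), cvec,
                    !is.null(constraint), min_class_mass, keep_posteriors)
  for (k in seq_len(max(n_start, 1) - 1)) {
    u0_k <- u0 + rnorm(16, sd = sqrt(s2_0))
    s2_k <- s2_0 * exp(runif(1, log(0.05), log(1.5)))
    res_k <- em_fit_cpp(omega, y, u0_k, s2_k, tol, as.integer(max_iter),
                        cvec, !is.null(constraint), min_class_mass,
                        keep_posteriors)
    if (res_k$loglik > res$loglik) res <- res_k
  }
  structure(
    list(
      genotype_values = setNames(drop(res$u), two_locus_genotype_labels()),
      sigma2 = res$sigma2,
      loglik = res$loglik,
      loglik_trace = res$loglik_trace,
      n_iter = res$n_iter,
      converged = res$converged,
      constraint = if (is.null(constraint)) NULL else
        .contrast_label(constraint),
      posteriors = res$posteriors,
      n = length(y)
    ),
    class = "em_fit"
  )
}

#' Fit the two-QTL model at fixed map positions
#'
#' Convenience wrapper: builds the conditional-probability table with
#' [omega_table()] and fits the mixture with [fit_qtl_mixture()].
#'
#' @inheritParams omega_table
#' @inheritParams fit_qtl_mixture
#' @param ... Passed to [fit_qtl_mixture()].
#' @return An `em_fit` object with a `positions` element.
#' @examples
#' fam <- simulate_family(sim_preset(n = 200, h2 = 0.4, seed = 7))
#' fit <- fit_qtl_pair(fam, "G1", 30, "G1", 70)
#' glance(fit)
#' tidy(fit)
#' @export
fit_qtl_pair <- function(family, group1, pos1, group2, pos2,
                         constraint = NULL, ...) {
  omega <- omega_table(family, group1, pos1, group2, pos2)
  fit <- fit_qtl_mixture(omega, family$pheno$value, constraint = constraint,
                         ...)
  fit$positions <- tibble::tibble(
    qtl = c(1L, 2L), group = c(group1, group2), position = c(pos1, pos2))
  fit
}

#' Single-normal null model (no QTL)
#'
#' The reduced model in which all sixteen genotypic values coincide:
#' `mu = mean(y)`, `sigma2 = (1/n) sum (y - mu)^2`, and the corresponding
#' normal log-likelihood.  This is the null of the QTL existence test.
#'
#' @param y Phenotypes, length >= 2, not all equal.
#' @return A list with `mu`, `sigma2` and `loglik`.
#' @export
fit_null_single_mean <- function(y) {
  stopifnot(length(y) >= 2, all(is.finite(y)))
  mu <- mean(y)
  sigma2 <- mean((y - mu)^2)
  if (sigma2 <= 0)
    stop("phenotype is constant; the normal log-likelihood is degenerate",
         call. = FALSE)
  n <- length(y)
  list(mu = mu, sigma2 = sigma2,
       loglik = -n / 2 * (log(2 * pi * sigma2) + 1))
}

#' @export
print.em_fit <- function(x, ...) {
  cat("<em_fit> 16-component normal mixture",
      if (!is.null(x$constraint)) paste0(" [", x$constraint, " = 0]"),
      "\n  n = ", x$n, ", loglik = ", format(x$loglik, digits = 8),
      ", sigma2 = ", signif(x$sigma2, 6),
      ", ", x$n_iter, " iterations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted two-QTL mixture
#'
#' `tidy()` returns the sixteen genetic effects recovered from the fitted
#' genotypic values (via the orthogonal design matrix); `glance()` returns
#' a one-row model summary.
#'
#' @param x An `em_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.em_fit <- function(x, ...) {
  genotype_values_to_effects(x$genotype_values)
}

#' @rdname tidy.em_fit
#' @export
glance.em_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, sigma2 = x$sigma2, n = x$n,
    n_iter = x$n_iter, converged = x$converged,
    constraint = x$constraint %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
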