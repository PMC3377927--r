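# Quantitative genetic model for two interacting multiallelic QTL in a
# full-sib family of two outbred parents.  Each locus segregates four
# genotypes: the offspring inherits allele u (1 or 2) from parent P1 and
# allele v (3 or 4) from parent P2.  Genotypic values and genetic effects
# are linked by an orthogonal +/-1 design matrix.

#' Canonical genotype and effect labels
#'
#' A single QTL in a full-sib outbred cross segregates four genotypes,
#' written `13, 14, 23, 24` (P1 allele then P2 allele).  Two QTL jointly
#' segregate sixteen genotypes labelled `q1/q2`, ordered with the first
#' locus varying slowest.  The sixteen genetic effects are the overall mean
#' `mu`; per-locus additive effects `alpha` (substitution 1 to 2, parent P1)
#' and `beta` (substitution 3 to 4, parent P2); per-locus dominance `gamma`;
#' additive x additive epistasis `I_aa, I_ab, I_ba, I_bb`; additive x
#' dominance `J_ag, J_bg`; dominance x additive `K_ga, K_gb`; and dominance
#' x dominance `L_gg`.
#'
#' @return A character vector of labels.
#' @examples
#' genotype_labels()
#' two_locus_genotype_labels()
#' effect_names()
#' @export
genotype_labels <- function() c("13", "14", "23", "24")

#' @rdname genotype_labels
#' @export
two_locus_genotype_labels <- function() {
  g <- genotype_labels()
  as.vector(t(outer(g, g, paste, sep = "/")))
}

#' @rdname genotype_labels
#' @export
effect_names <- function() {
  c("mu", "alpha1", "beta1", "gamma1", "alpha2", "beta2", "gamma2",
    "I_aa", "I_ab", "I_ba", "I_bb", "J_ag", "J_bg", "K_ga", "K_gb", "L_gg")
}

# per-locus contrast columns over genotypes (13, 14, 23, 24):
# A codes the P1 allele, B the P2 allele, G = A*B the intra-locus interaction
.locus_contrasts <- function() {
  A <- c(1, 1, -1, -1)
  B <- c(1, -1, 1, -1)
  list(one = c(1, 1, 1, 1), A = A, B = B, G = A * B)
}

#' Orthogonal design matrices linking genotypic values and genetic effects
#'
#' `single_locus_design_matrix()` returns the 4 x 4 matrix `D` with
#' `u = D a` for one QTL, where `u` holds the four genotypic values in
#' canonical order and `a = (mu, alpha, beta, gamma)`.
#' `two_locus_design_matrix()` returns the 16 x 16 analogue whose columns
#' are all Kronecker products of the per-locus contrast columns, ordered as
#' [effect_names()].  Both matrices have entries in \{+1, -1\} and mutually
#' orthogonal columns, so `D^-1 = t(D)/nrow(D)`.
#'
#' @return A numeric matrix with genotype row names and effect column names.
#' @examples
#' D <- single_locus_design_matrix()
#' crossprod(D)  # 4 * diag(4)
#' @export
single_locus_design_matrix <- function() {
  k <- .locus_contrasts()
  D <- cbind(mu = k$one, alpha = k$A, beta = k$B, gamma = k$G)
  rownames(D) <- genotype_labels()
  D
}

#' @rdname single_locus_design_matrix
#' @export
two_locus_design_matrix <- function() {
  k <- .locus_contrasts()
  # columns: first factor acts on locus 1 (slowest), second on locus 2
  cols <- list(
    mu     = c(k$one, k$one),
    alpha1 = c(k$A,   k$one),
    beta1  = c(k$B,   k$one),
    gamma1 = c(k$G,   k$one),
    alpha2 = c(k$one, k$A),
    beta2  = c(k$one, k$B),
    gamma2 = c(k$one, k$G),
    I_aa   = c(k$A,   k$A),
    I_ab   = c(k$A,   k$B),
    I_ba   = c(k$B,   k$A),
    I_bb   = c(k$B,   k$B),
    J_ag   = c(k$A,   k$G),
    J_bg   = c(k$B,   k$G),
    K_ga   = c(k$G,   k$A),
    K_gb   = c(k$G,   k$B),
    L_gg   = c(k$G,   k$G)
  )
  D <- vapply(cols, function(x) kronecker(x[1:4], x[5:8]), numeric(16))
  rownames(D) <- two_locus_genotype_labels()
  D
}

.as_effect_vector <- function(a) {
  nm <- effect_names()
  if (is.data.frame(a)) {
    stopifnot(all(c("effect", "value") %in% names(a)))
    a <- setNames(a$value, a$effect)
  }
  if (!is.null(names(a))) {
    missing <- setdiff(nm, names(a))
    if (length(missing))
      stop("missing effects: ", paste(missing, collapse = ", "), call. = FALSE)
    a <- a[nm]
  } else if (length(a) != 16) {
    stop("an effect vector has exactly 16 components", call. = FALSE)
  }
  stopifnot(is.numeric(a), length(a) == 16, all(is.finite(a)))
  setNames(as.numeric(a), nm)
}

.as_value_vector <- function(u) {
  lab <- two_locus_genotype_labels()
  if (is.data.frame(u)) {
    stopifnot(all(c("genotype", "value") %in% names(u)))
    u <- setNames(u$value, u$genotype)
  }
  if (!is.null(names(u))) u <- u[lab]
  stopifnot(is.numeric(u), length(u) == 16, all(is.finite(u)))
  setNames(as.numeric(u), lab)
}

#' Convert between genetic effects and two-locus genotypic values
#'
#' The sixteen genotypic values `u` and the sixteen genetic effects `a`
#' are linked by the orthogonal design matrix `D`: `u = D a` and
#' `a = t(D) u / 16`.  The map is an exact bijection.
#'
#' @param a Genetic effects: a named numeric vector (names as
#'   [effect_names()]), an unnamed length-16 vector in that order, or a
#'   data frame with columns `effect` and `value`.
#' @param u Genotypic values: a named numeric vector (names as
#'   [two_locus_genotype_labels()]), an unnamed length-16 vector in that
#'   order, or a data frame with columns `genotype` and `value`.
#' @return A tibble with columns `genotype` and `value`
#'   (for `effects_to_genotype_values()`) or `effect` and `value`
#'   (for `genotype_values_to_effects()`).
#' @examples
#' a <- c(mu = 50, setNames(rep(0, 15), effect_names()[-1]))
#' effects_to_genotype_values(a)
#' @export
effects_to_genotype_values <- function(a) {
  a <- .as_effect_vector(a)
  u <- drop(two_locus_design_matrix() %*% a)
  tibble::tibble(genotype = two_locus_genotype_labels(), value = unname(u))
}

#' @rdname effects_to_genotype_values
#' @export
genotype_values_to_effects <- function(u) {
  u <- .as_value_vector(u)
  a <- drop(crossprod(two_locus_design_matrix(), u)) / 16
  tibble::tibble(effect = effect_names(), value = unname(a))
}

#' Contrast defining the null hypothesis for one genetic effect
#'
#' Each of the fifteen non-intercept effects is a balanced +/-1 contrast on
#' the sixteen genotypic values (a column of the two-locus design matrix):
#' the null hypothesis "effect = 0" is `sum(coefficients * u) = 0`, i.e. the
#' eight genotypes carrying +1 have the same total value as the eight
#' carrying -1.
#'
#' @param effect_name One of `effect_names()` except `"mu"`.
#' @return A tibble with columns `genotype` and `coefficient` (+1/-1).
#' @examples
#' effect_contrast("alpha1")
#' @export
effect_contrast <- function(effect_name) {
  valid <- setdiff(effect_names(), "mu")
  if (!is.character(effect_name) || length(effect_name) != 1 ||
      !effect_name %in% valid)
    stop("unknown effect name: ", paste(effect_name, collapse = ","),
         " (expected one of ", paste(valid, collapse = ", "), ")",
         call. = FALSE)
  D <- two_locus_design_matrix()
  tibble::tibble(
    genotype = rownames(D),
    coefficient = unname(D[, effect_name])
  )
}

#' Genetic variance of an effect vector
#'
#' Variance of the sixteen genotypic values under equal (1/16) genotype
#' frequencies.  By orthogonality of the design matrix this is the sum of
#' squares of the fifteen non-intercept effects.  It treats the two loci as
#' if unlinked; the simulator's heritability scaling is defined in these
#' terms.
#'
#' @inheritParams effects_to_genotype_values
#' @return A single non-negative number (squared trait units).
#' @examples
#' genetic_variance(reference_effects())
#' @export
genetic_variance <- function(a) {
  a <- .as_effect_vector(a)
  sum(a[-1]^2)
}

#' Reference effect set used in the package's simulation studies
#'
#' A fixed vector of true genetic effects featuring all fifteen effect
#' types, including strong additive x dominance and dominance x dominance
#' epistasis.  Its genetic variance is 148.25 squared trait units, so
#' residual variances of 1334.25 and 222.375 give heritabilities 0.1
#' and 0.4.
#'
#' @return A named numeric vector of length 16 (see [effect_names()]).
#' @export
reference_effects <- function() {
  c(mu = 50, alpha1 = 2, beta1 = 3, gamma1 = 4,
    alpha2 = -3, beta2 = 1, gamma2 = -2.5,
    I_aa = -2, I_ab = 2.5, I_ba = -3, I_bb = 3.5,
    J_ag = -4, J_bg = -4.5, K_ga = -2, K_gb = 2.5, L_gg = -5)
}
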