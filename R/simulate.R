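# Full-sib family simulator: two outbred parents, fully informative markers
# (every offspring genotype reveals which allele came from each parent),
# two linked epistatic QTL, phenotype = genotypic value + normal error.

#' Residual variance implied by a heritability
#'
#' The simulator scales the residual error so that the two QTL explain a
#' chosen fraction `h2` of the phenotypic variance:
#' `sigma2 = genetic_variance(effects) * (1 - h2) / h2`, with the genetic
#' variance taken under equal two-locus genotype frequencies.
#'
#' @inheritParams effects_to_genotype_values
#' @param h2 Heritability, strictly between 0 and 1.
#' @return Residual variance in squared trait units.
#' @examples
#' residual_variance_for_h2(reference_effects(), 0.4)
#' @export
residual_variance_for_h2 <- function(a, h2) {
  if (!is.numeric(h2) || length(h2) != 1 || h2 <= 0 || h2 >= 1)
    stop("h2 must lie strictly between 0 and 1", call. = FALSE)
  genetic_variance(a) * (1 - h2) / h2
}

#' Simulate parental gametes along one linkage group
#'
#' Each gamete is a sequence of grandparental origins (0/1) over the given
#' loci: the first origin is a fair coin and each successive origin flips
#' with probability equal to the Haldane recombination fraction of the
#' inter-locus distance.  Uses the current RNG state.
#'
#' @param positions Sorted locus positions in cM.
#' @param n Number of gametes.
#' @return An `n x length(positions)` 0/1 integer matrix.
#' @examples
#' set.seed(1)
#' simulate_gamete(c(0, 20, 40), n = 5)
#' @export
simulate_gamete <- function(positions, n = 1) {
  stopifnot(length(positions) >= 1, !is.unsorted(positions))
  L <- length(positions)
  out <- matrix(0L, n, L)
  out[, 1] <- rbinom(n, 1L, 0.5)
  if (L > 1) {
    r <- haldane_r(diff(positions))
    for (j in 2:L) {
      flip <- rbinom(n, 1L, r[j - 1])
      out[, j] <- bitwXor(out[, j - 1], flip)
    }
  }
  out
}

#' Simulation configuration
#'
#' Bundles everything [simulate_family()] needs: a linkage map, the two QTL
#' positions, the true genetic effects, a heritability and a family size.
#' `sim_preset()` returns the design used throughout the package's
#' simulation studies: one 100 cM group with six equidistant markers
#' (0, 20, ..., 100 cM), QTL at 30 and 70 cM, and [reference_effects()].
#'
#' @param map A tibble with columns `group`, `marker`, `position` (cM),
#'   positions strictly increasing within a group.
#' @param qtl1,qtl2 Lists `list(group =, pos =)` giving each QTL's linkage
#'   group and position in cM.
#' @param effects True genetic effects (see [effects_to_genotype_values()]).
#' @param h2 Heritability in (0, 1) used to scale the residual variance.
#' @param n Family size (number of offspring).
#' @param seed Optional integer seed; recorded in the dataset metadata.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_preset(n = 100, h2 = 0.4, seed = 42)
#' fam <- simulate_family(cfg)
#' fam
#' @export
sim_config <- function(map, qtl1, qtl2, effects, h2, n, seed = NULL) {
  map <- tibble::as_tibble(map)
  stopifnot(all(c("group", "marker", "position") %in% names(map)),
            n >= 1, h2 > 0, h2 < 1)
  bad <- map |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(ok = !is.unsorted(.data$position, strictly = TRUE))
  if (!all(bad$ok))
    stop("marker positions must be strictly increasing within each group",
         call. = FALSE)
  structure(
    list(map = map, qtl1 = qtl1, qtl2 = qtl2,
         effects = .as_effect_vector(effects), h2 = h2,
         n = as.integer(n), seed = seed),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
sim_preset <- function(n = 400, h2 = 0.4, seed = NULL) {
  map <- tibble::tibble(
    group = "G1",
    marker = paste0("M", 1:6),
    position = seq(0, 100, by = 20)
  )
  sim_config(map,
             qtl1 = list(group = "G1", pos = 30),
             qtl2 = list(group = "G1", pos = 70),
             effects = reference_effects(), h2 = h2, n = n, seed = seed)
}

#' Simulate a full-sib family with two epistatic QTL
#'
#' Draws one P1 gamete (alleles 1/2) and one P2 gamete (alleles 3/4) per
#' offspring over the markers and the two QTL, records the transmitted
#' marker alleles as genotype codes `13/14/23/24`, and simulates the
#' phenotype as the true two-locus genotypic value plus
#' `Normal(0, sigma2)` noise with `sigma2` from
#' [residual_variance_for_h2()].  Parental QTL alleles are in coupling
#' phase with the markers (origin 0 carries allele 1 resp. 3).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `fs_family`: a list with tibbles `map`,
#'   `geno` (column `id` plus one column per marker), `pheno` (`id`,
#'   `value`) and a `truth` list holding the simulated QTL genotypes, the
#'   true effects, `sigma2`, `h2` and the seed.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  map <- dplyr::arrange(config$map, .data$group, .data$position)
  qtls <- list(config$qtl1, config$qtl2)

  groups <- unique(map$group)
  p1_origin <- p2_origin <- list()
  for (g in groups) {
    gm <- map[map$group == g, ]
    qtl_here <- which(vapply(qtls, function(q) identical(q$group, g), TRUE))
    loci <- c(gm$position, vapply(qtls[qtl_here], `[[`, numeric(1), "pos"))
    labels <- c(gm$marker, paste0(".qtl", qtl_here))
    ord <- order(loci)
    o1 <- simulate_gamete(loci[ord], n)
    o2 <- simulate_gamete(loci[ord], n)
    colnames(o1) <- colnames(o2) <- labels[ord]
    p1_origin[[g]] <- o1
    p2_origin[[g]] <- o2
  }
  geno_cols <- lapply(map$marker, function(m) {
    g <- map$group[map$marker == m]
    paste0(p1_origin[[g]][, m] + 1L, p2_origin[[g]][, m] + 3L)
  })
  names(geno_cols) <- map$marker
  geno <- tibble::as_tibble(c(list(id = paste0("ind", seq_len(n))), geno_cols))

  qtl_origin <- function(parent, k) {
    g <- qtls[[k]]$group
    (if (parent == 1) p1_origin else p2_origin)[[g]][, paste0(".qtl", k)]
  }
  u1 <- qtl_origin(1, 1); v1 <- qtl_origin(2, 1)
  u2 <- qtl_origin(1, 2); v2 <- qtl_origin(2, 2)
  gidx <- 8L * u1 + 4L * v1 + 2L * u2 + v2 + 1L
  uvals <- effects_to_genotype_values(config$effects)$value
  sigma2 <- residual_variance_for_h2(config$effects, config$h2)
  y <- uvals[gidx] + rnorm(n, 0, sqrt(sigma2))

  structure(
    list(
      map = map,
      geno = geno,
      pheno = tibble::tibble(id = geno$id, value = y),
      truth = list(
        qtl1 = config$qtl1, qtl2 = config$qtl2,
        genotype = two_locus_genotype_labels()[gidx],
        effects = config$effects, sigma2 = sigma2, h2 = config$h2,
        seed = config$seed
      )
    ),
    class = "fs_family"
  )
}

#' @export
print.fs_family <- function(x, ...) {
  cat("<fs_family> ", nrow(x$pheno), " offspring, ",
      nrow(x$map), " markers in ", length(unique(x$map$group)),
      " linkage group(s)\n", sep = "")
  if (!is.null(x$truth))
    cat("  simulated: QTL at ", x$truth$qtl1$group, ":", x$truth$qtl1$pos,
        " and ", x$truth$qtl2$group, ":", x$truth$qtl2$pos,
        " cM, h2 = ", x$truth$h2, ", sigma2 = ",
        signif(x$truth$sigma2, 6), "\n", sep = "")
  invisible(x)
}
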