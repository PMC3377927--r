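# Conditional probabilities of two-QTL genotypes given flanking-marker
# genotypes.  Each parental gamete is a Markov chain of grandparental
# origins (0/1) along the linkage group, with transition probability equal
# to the Haldane recombination fraction of the inter-locus distance.  With
# complete marker data the flanking markers are sufficient for a QTL's
# origin, and QTL in distinct intervals are conditionally independent.

.ONMARKER_TOL <- 1e-9

#' Haldane map function
#'
#' Converts a map distance in centiMorgans to a recombination fraction
#' assuming no crossover interference: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d Map distance in cM (vectorised, must be non-negative).
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 20, 1e6))
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative", call. = FALSE)
  (1 - exp(-2 * d / 100)) / 2
}

# transition probability of the origin chain: stay with 1-r, flip with r
.trans <- function(a, b, r) ifelse(a == b, 1 - r, r)

#' Conditional origin probabilities for a QTL inside a marker interval
#'
#' For one parental gamete, the probability that a QTL between two markers
#' carries grandparental origin 0 or 1, given the origins observed at the
#' flanking markers, under the no-interference two-point model:
#' `P(o | oL, oR) = t(oL, o; r1) t(o, oR; r2) / t(oL, oR; r12)` with
#' `t(a, b; r) = 1 - r` if `a == b` and `r` otherwise.
#'
#' @param left_origin,right_origin Origins (0/1) at the flanking markers;
#'   vectorised.
#' @param r1 Recombination fraction between the left marker and the QTL.
#' @param r2 Recombination fraction between the QTL and the right marker.
#' @param r12 Recombination fraction between the two markers.
#' @return A matrix with one row per input and columns `o0`, `o1` summing
#'   to 1.
#' @examples
#' r <- haldane_r(10)
#' interval_qtl_prob(0, 0, r, r, haldane_r(20))
#' @export
interval_qtl_prob <- function(left_origin, right_origin, r1, r2, r12) {
  stopifnot(all(left_origin %in% 0:1), all(right_origin %in% 0:1))
  denom <- .trans(left_origin, right_origin, r12)
  if (any(denom <= 0))
    stop("impossible flank configuration: recombinant flanks at zero distance",
         call. = FALSE)
  p0 <- .trans(left_origin, 0, r1) * .trans(0, right_origin, r2) / denom
  p1 <- .trans(left_origin, 1, r1) * .trans(1, right_origin, r2) / denom
  out <- cbind(o0 = p0, o1 = p1)
  out / rowSums(out)
}

# interval index of a position within sorted marker positions:
# interval k = [m_k, m_{k+1}), last interval closed on the right
.interval_index <- function(pos, mpos) {
  if (pos < mpos[1] - .ONMARKER_TOL || pos > mpos[length(mpos)] + .ONMARKER_TOL)
    stop("position ", pos, " outside the marker span [", mpos[1], ", ",
         mpos[length(mpos)], "]", call. = FALSE)
  min(max(findInterval(pos, mpos), 1L), length(mpos) - 1L)
}

# index of a marker coinciding with pos, or 0L
.on_marker <- function(pos, mpos) {
  j <- which(abs(mpos - pos) < .ONMARKER_TOL)
  if (length(j)) j[1] else 0L
}

# P(origin at qtl position | gamete's marker origins), one group
# origins: n x m matrix of 0/1; returns n x 2 matrix
.gamete_one_qtl <- function(origins, mpos, pos) {
  j <- .on_marker(pos, mpos)
  if (j > 0L) {
    o <- origins[, j]
    return(cbind(o0 = 1 - o, o1 = o))
  }
  k <- .interval_index(pos, mpos)
  interval_qtl_prob(
    origins[, k], origins[, k + 1L],
    r1 = haldane_r(pos - mpos[k]),
    r2 = haldane_r(mpos[k + 1L] - pos),
    r12 = haldane_r(mpos[k + 1L] - mpos[k])
  )
}

#' Joint origin probabilities of two QTL on one parental gamete
#'
#' Computes `P(o1, o2 | marker origins)` for two QTL positions on the same
#' linkage group, for each gamete (row of `origins`).  When the QTL fall in
#' distinct marker intervals (or coincide with markers) the joint
#' distribution factorises into the two single-interval conditionals by the
#' Markov property; when both fall strictly inside the same interval the
#' closed form over the three sub-segments is used.
#'
#' @param origins An n x m 0/1 matrix of grandparental origins at the
#'   group's markers (one row per gamete), or a single vector.
#' @param marker_pos Strictly increasing marker positions in cM.
#' @param pos1,pos2 QTL positions in cM within the marker span,
#'   `pos1 < pos2`.
#' @return An n x 4 matrix with columns `o00, o01, o10, o11` (origin of
#'   QTL 1 varying slowest); rows sum to 1.
#' @examples
#' gamete_two_qtl_probs(c(0, 1, 1), c(0, 20, 40), 10, 30)
#' @export
gamete_two_qtl_probs <- function(origins, marker_pos, pos1, pos2) {
  if (is.null(dim(origins))) origins <- matrix(origins, nrow = 1)
  stopifnot(ncol(origins) == length(marker_pos), pos1 < pos2)
  j1 <- .on_marker(pos1, marker_pos)
  j2 <- .on_marker(pos2, marker_pos)
  same_interval <- j1 == 0L && j2 == 0L &&
    .interval_index(pos1, marker_pos) == .interval_index(pos2, marker_pos)
  if (same_interval) {
    k <- .interval_index(pos1, marker_pos)
    mL <- marker_pos[k]; mR <- marker_pos[k + 1L]
    ra <- haldane_r(pos1 - mL)
    rb <- haldane_r(pos2 - pos1)
    rc <- haldane_r(mR - pos2)
    rLR <- haldane_r(mR - mL)
    oL <- origins[, k]; oR <- origins[, k + 1L]
    denom <- .trans(oL, oR, rLR)
    cells <- lapply(0:3, function(code) {
      o1 <- code %/% 2L; o2 <- code %% 2L
      .trans(oL, o1, ra) * .trans(o1, o2, rb) * .trans(o2, oR, rc) / denom
    })
    out <- do.call(cbind, cells)
  } else {
    p1 <- .gamete_one_qtl(origins, marker_pos, pos1)
    p2 <- .gamete_one_qtl(origins, marker_pos, pos2)
    out <- cbind(p1[, 1] * p2[, 1], p1[, 1] * p2[, 2],
                 p1[, 2] * p2[, 1], p1[, 2] * p2[, 2])
  }
  colnames(out) <- c("o00", "o01", "o10", "o11")
  out / rowSums(out)
}

# marker origin matrices (0/1) for one group, one per parent
.origin_matrices <- function(family, group) {
  map <- dplyr::filter(family$map, .data$group == !!group)
  if (nrow(map) < 2)
    stop("linkage group '", group, "' not found or has fewer than 2 markers",
         call. = FALSE)
  map <- dplyr::arrange(map, .data$position)
  codes <- as.matrix(family$geno[, map$marker, drop = FALSE])
  if (any(is.na(codes)) || !all(codes %in% genotype_labels()))
    stop("invalid or missing genotype code; expected one of 13/14/23/24",
         call. = FALSE)
  p1 <- matrix(as.integer(substr(codes, 1, 1)) - 1L, nrow = nrow(codes))
  p2 <- matrix(as.integer(substr(codes, 2, 2)) - 3L, nrow = nrow(codes))
  list(p1 = p1, p2 = p2, pos = map$position)
}

# joint (o at qtl1, o at qtl2) for one parent's gametes, possibly across groups
.parent_joint <- function(family, parent, group1, pos1, group2, pos2) {
  if (identical(group1, group2)) {
    om <- .origin_matrices(family, group1)
    gamete_two_qtl_probs(om[[parent]], om$pos, pos1, pos2)
  } else {
    om1 <- .origin_matrices(family, group1)
    om2 <- .origin_matrices(family, group2)
    s1 <- .gamete_one_qtl(om1[[parent]], om1$pos, pos1)
    s2 <- .gamete_one_qtl(om2[[parent]], om2$pos, pos2)
    cbind(s1[, 1] * s2[, 1], s1[, 1] * s2[, 2],
          s1[, 2] * s2[, 1], s1[, 2] * s2[, 2])
  }
}

#' Conditional probabilities of the 16 two-QTL genotypes
#'
#' For each offspring, the probability of each of the sixteen two-locus QTL
#' genotypes given its marker genotypes — the mixture weights of the
#' QTL-mapping likelihood.  The P1 gamete determines the first allele of
#' both QTL genotypes and the P2 gamete the second, so each row is the
#' product of the two parental joint origin distributions, with origin 0
#' mapped to alleles 1 (P1) and 3 (P2).
#'
#' @param family A full-sib family object (see [read_family()] or
#'   [simulate_family()]).
#' @param group1,group2 Linkage-group identifiers for the two QTL.
#' @param pos1,pos2 QTL positions in cM; if the groups are equal,
#'   `pos1 < pos2` is required.
#' @return An n x 16 matrix, columns named by
#'   [two_locus_genotype_labels()]; each row sums to 1.
#' @examples
#' fam <- simulate_family(sim_preset(n = 20, h2 = 0.4, seed = 1))
#' w <- omega_table(fam, "G1", 30, "G1", 70)
#' range(rowSums(w))
#' @export
omega_table <- function(family, group1, pos1, group2, pos2) {
  if (identical(group1, group2) && !(pos1 < pos2))
    stop("pos1 < pos2 is required for two QTL on the same group",
         call. = FALSE)
  w1 <- .parent_joint(family, "p1", group1, pos1, group2, pos2)
  w2 <- .parent_joint(family, "p2", group1, pos1, group2, pos2)
  omega <- matrix(0, nrow(w1), 16)
  g <- 0L
  for (u1 in 0:1) for (v1 in 0:1) for (u2 in 0:1) for (v2 in 0:1) {
    g <- g + 1L
    omega[, g] <- w1[, 2L * u1 + u2 + 1L] * w2[, 2L * v1 + v2 + 1L]
  }
  colnames(omega) <- two_locus_genotype_labels()
  omega / rowSums(omega)
}
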