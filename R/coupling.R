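#' Coupling-step parameters
#'
#' Rate constants of the second (coupling) stage, in which the
#' linker-bearing intermediate reacts with the unreacted substrate.
#' `induction_ratio = k2_hetero / k2_homo`; 1 is the statistical
#' (no-asymmetric-induction) case in which the stereochemical outcome is
#' set purely by the pool compositions.
#'
#' @param k2_hetero,k2_homo Positive rate constants
#'   (concentration^-1 time^-1) for heterochiral and homochiral pairings.
#' @return Object of class `coupling_parameters`.
#' @export
coupling_parameters <- function(k2_hetero, k2_homo = k2_hetero) {
  check_number(k2_hetero, "k2_hetero", lower = 0, strict_lower = TRUE)
  check_number(k2_homo, "k2_homo", lower = 0, strict_lower = TRUE)
  structure(list(k2_hetero = as.numeric(k2_hetero),
                 k2_homo = as.numeric(k2_homo),
                 induction_ratio = as.numeric(k2_hetero / k2_homo)),
            class = "coupling_parameters")
}

#' @export
print.coupling_parameters <- function(x, ...) {
  cat(sprintf("<coupling_parameters> k2_hetero = %g, k2_homo = %g (induction ratio %g)\n",
              x$k2_hetero, x$k2_homo, x$induction_ratio))
  invisible(x)
}

#' Statistical coupling of two enantiomer pools
#'
#' Random (no-induction) pairing of one unit from each pool through an
#' unsymmetrical linker. By convention `pool1` is the linker-bearing
#' intermediate and `pool2` the unreacted substrate; a heterochiral product
#' joins units of opposite configuration. With equal rate constants each
#' pool's composition is invariant during the coupling, so the outcome is
#' exactly time-independent: the stereoisomer fractions are the products of
#' the configuration fractions, scaled to `min(total1, total2)` pairs (the
#' limiting pool).
#'
#' Writing a for the signed e.e. of `pool1` and b for the R-excess of
#' `pool2` (the orientation produced by a kinetic resolution: the
#' intermediate is S-enriched, the recovered substrate R-enriched), the
#' closed forms are
#' heterochiral e.e. = (a + b) / (1 + a b) and d.r. = (1 + a b) / (1 - a b):
#' Horeau's statistical amplification.
#'
#' @param pool1,pool2 [enantiomer_pool()] objects with positive totals.
#' @return A [product_distribution()] over the four pairings.
#' @examples
#' a <- pool_from_ee(0.96, 1, "intermediate")
#' b <- pool_from_ee(-0.99, 1, "substrate")   # R-enriched
#' d <- statistical_coupling(a, b)
#' hetero_ee(d)  # 0.9998
#' dr_of(d)      # 39.3
#' @export
statistical_coupling <- function(pool1, pool2) {
  t1 <- pool_total(pool1); t2 <- pool_total(pool2)
  if (t1 <= 0 || t2 <= 0)
    stop_undefined("statistical coupling undefined for an empty pool")
  n <- min(t1, t2)
  f1S <- pool1$amount_S / t1; f1R <- pool1$amount_R / t1
  f2S <- pool2$amount_S / t2; f2R <- pool2$amount_R / t2
  product_distribution(hetero_SR = n * f1S * f2R,
                       hetero_RS = n * f1R * f2S,
                       homo_SS   = n * f1S * f2S,
                       homo_RR   = n * f1R * f2R)
}

#' Closed-form heterochiral e.e. and d.r. of a statistical coupling
#'
#' Convenience scalar forms taking the two pool e.e. magnitudes directly
#' (a = e.e. of the intermediate, b = e.e. of the recovered substrate, both
#' as major-enantiomer excesses).
#'
#' @param a,b e.e. magnitudes in \[0, 1\].
#' @return `coupled_ee`: (a + b)/(1 + a b); `coupled_dr`:
#'   (1 + a b)/(1 - a b), `Inf` when a b = 1.
#' @export
coupled_ee <- function(a, b) (a + b) / (1 + a * b)

#' @rdname coupled_ee
#' @export
coupled_dr <- function(a, b) ifelse(a * b >= 1, Inf, (1 + a * b) / (1 - a * b))

#' Horeau homocoupling through a symmetrical linker
#'
#' Random pairing of a single enantioenriched pool with itself. The
#' homochiral dimers (SS, RR) are chiral and come out in amplified e.e.
#' `2a / (1 + a^2)`; the heterochiral SR pairing is the achiral meso dimer,
#' formed as a fraction `(1 - a^2)/2` of all dimers. In the returned
#' distribution the meso amount is split evenly between `hetero_SR` and
#' `hetero_RS` (they are the same compound).
#'
#' @param pool An [enantiomer_pool()] with positive total.
#' @return A [product_distribution()] scaled so the dimer total equals
#'   `pool_total(pool) / 2` (two units per dimer).
#' @examples
#' d <- horeau_homocoupling(pool_from_ee(0.62, 1))
#' homochiral_ee(d)   # 0.8957
#' meso_fraction(d)   # 0.3078
#' @export
horeau_homocoupling <- function(pool) {
  tot <- pool_total(pool)
  if (tot <= 0)
    stop_undefined("homocoupling undefined for an empty pool")
  n <- tot / 2                       # dimers formed
  p <- pool$amount_S / tot; q <- pool$amount_R / tot
  product_distribution(hetero_SR = n * p * q, hetero_RS = n * p * q,
                       homo_SS = n * p * p, homo_RR = n * q * q)
}

#' Summaries of a homocoupling distribution
#'
#' `homochiral_ee` is the e.e. over the chiral SS/RR dimers,
#' (SS - RR)/(SS + RR); `meso_fraction` is the meso (heterochiral) share of
#' all dimers.
#'
#' @param dist A [product_distribution()] from [horeau_homocoupling()].
#' @export
homochiral_ee <- function(dist) {
  hom <- dist$homo_SS + dist$homo_RR
  if (hom <= 0)
    stop_undefined("homochiral e.e. undefined: no homochiral dimer")
  (dist$homo_SS - dist$homo_RR) / hom
}

#' @rdname homochiral_ee
#' @export
meso_fraction <- function(dist) {
  tot <- dist$hetero_SR + dist$hetero_RS + dist$homo_SS + dist$homo_RR
  if (tot <= 0)
    stop_undefined("meso fraction undefined for an all-zero distribution")
  (dist$hetero_SR + dist$hetero_RS) / tot
}

#' Infer pool e.e.s from an observed d.r. and d.e. — feasibility diagnostic
#'
#' Inverts the statistical-coupling closed forms: an observed
#' heterochiral:homochiral ratio R (as "R:1") fixes the product of the two
#' pool e.e.s, `a b = (R - 1)/(R + 1)`, and the observed heterochiral
#' d.e. fixes their sum, `a + b = de (1 + a b)`. The pair (a, b) is then a
#' root pair of `x^2 - (a+b) x + a b`. If the discriminant is negative, or a
#' root falls outside \[0, 1\], no statistical (no-induction) coupling of
#' any two pools can produce the observation — evidence of asymmetric
#' induction or more complex kinetics in the coupling step.
#'
#' The assignment of the recovered pair to intermediate vs substrate is the
#' caller's: d.r. and d.e. cannot distinguish them, so the pair is returned
#' in decreasing order. With a chiral (enantiopure) linker the observed
#' stereoisomers are diastereomers throughout; the d.e. is read as the
#' major:minor excess over the heterochiral pair.
#'
#' @param dr_observed Observed ratio R >= 1 (the X of "X:1").
#' @param de_observed Observed heterochiral diastereomeric (or
#'   enantiomeric) excess in \[0, 1\].
#' @return A list of class `pool_inference`: `feasible` (logical); when
#'   feasible, `a` and `b` (e.e. magnitudes, a >= b); otherwise `reason`.
#' @examples
#' infer_pool_ees(39.3, 0.9998)  # recovers approx (0.99, 0.96)
#' infer_pool_ees(3.2, 0.93)     # infeasible: induction required
#' @export
infer_pool_ees <- function(dr_observed, de_observed) {
  check_number(dr_observed, "dr_observed", lower = 1)
  check_number(de_observed, "de_observed", lower = 0, upper = 1)
  ab <- (dr_observed - 1) / (dr_observed + 1)
  s2 <- de_observed * (1 + ab)      # a + b
  disc <- s2^2 - 4 * ab
  out <- list(dr = dr_observed, de = de_observed, sum = s2, product = ab)
  if (disc < 0) {
    out$feasible <- FALSE
    out$reason <- sprintf(paste0(
      "no statistical (no-induction) coupling of any two pools can give ",
      "d.r. %s with %s d.e.: the implied e.e. sum %.4f and product %.4f ",
      "admit no real pair (discriminant %.4g < 0)"),
      format_dr(dr_observed), ee_percent(de_observed), s2, ab, disc)
  } else {
    a <- (s2 + sqrt(disc)) / 2
    b <- (s2 - sqrt(disc)) / 2
    if (a > 1 + 1e-12 || b < -1e-12) {
      out$feasible <- FALSE
      out$reason <- sprintf(
        "implied pool e.e. pair (%.4f, %.4f) falls outside [0, 1]", a, b)
    } else {
      out$feasible <- TRUE
      out$a <- min(a, 1)
      out$b <- max(b, 0)
    }
  }
  structure(out, class = "pool_inference")
}

#' @export
print.pool_inference <- function(x, ...) {
  cat(sprintf("<pool_inference> observed d.r. %s, d.e. %s\n",
              format_dr(x$dr), ee_percent(x$de)))
  if (x$feasible) {
    cat(sprintf("  feasible under statistical coupling: pool e.e.s %s and %s\n",
                ee_percent(x$a), ee_percent(x$b)))
  } else {
    cat("  INFEASIBLE under statistical coupling\n")
    cat(sprintf("  %s\n", x$reason))
  }
  invisible(x)
}
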