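#' Kinetic-resolution parameters
#'
#' The selectivity factor s = k1_S / k1_R of a kinetic resolution obeying
#' simple second-order competing kinetics (one rate-determining encounter of
#' each substrate enantiomer with the resolving reagent). s is stored as
#' given; the rate constants default to k1_R = 1, k1_S = s in normalized
#' concentration^-1 time^-1 units — every closed-form relation below is
#' invariant to that one free scale. s in biocatalysis is usually written E.
#'
#' @param s Selectivity factor, >= 1. Inputs with s < 1 are rejected rather
#'   than silently mirrored; mirror the pool labels explicitly with
#'   [mirror_pool()] instead.
#' @param k1_R Rate constant of the slow (R) enantiomer; k1_S is s * k1_R.
#' @return Object of class `kr_parameters` with fields `s`, `k1_S`, `k1_R`.
#' @export
kr_parameters <- function(s, k1_R = 1) {
  check_number(s, "s", lower = 1)
  check_number(k1_R, "k1_R", lower = 0, strict_lower = TRUE)
  structure(list(s = as.numeric(s), k1_S = as.numeric(s * k1_R),
                 k1_R = as.numeric(k1_R)),
            class = "kr_parameters")
}

#' @export
print.kr_parameters <- function(x, ...) {
  cat(sprintf("<kr_parameters> s = %g (k1_S = %g, k1_R = %g)\n",
              x$s, x$k1_S, x$k1_R))
  invisible(x)
}

# The two Kagan relations link conversion C of the racemic substrate to the
# e.e. of the product pool (ee_p) and of the unreacted substrate pool (ee_s):
#   s = ln[1 - C(1 + ee_p)] / ln[1 - C(1 - ee_p)]   (product)
#   s = ln[(1 - C)(1 - ee_s)] / ln[(1 - C)(1 + ee_s)] (substrate)
# Both follow from integrating the competing second-order rate laws, under
# which d ln[A_S] / d ln[A_R] = s independently of the co-reactant profile.

kagan_product_objective <- function(ee, s, C) {
  log1p(-C * (1 + ee)) - s * log1p(-C * (1 - ee))
}

kagan_substrate_objective <- function(ee, s, C) {
  log((1 - C) * (1 - ee)) - s * log((1 - C) * (1 + ee))
}

#' Product e.e. of a kinetic resolution at a given conversion
#'
#' Solves the product-side Kagan relation for the e.e. of the material
#' consumed by the resolution (the linker-bearing intermediate of the
#' multicomponent process) when a fraction `C` of the racemic substrate has
#' reacted. The root is located by bracketed search (`uniroot`) on
#' \[0, min(1, 1/C - 1) - delta\]; the objective is strictly monotone in ee,
#' so the root is unique.
#'
#' @param s Selectivity factor >= 1.
#' @param C Conversion of the racemic substrate, strictly in (0, 1).
#' @param tol Root tolerance (absolute, in e.e. units).
#' @return e.e. fraction in \[0, 1).
#' @examples
#' ee_product_at_conversion(8, 0.5)   # 0.6233 -> "62% e.e."
#' ee_product_at_conversion(28, 0.5)  # 0.8310 -> "83% e.e."
#' @export
ee_product_at_conversion <- function(s, C, tol = 1e-10) {
  check_number(s, "s", lower = 1)
  check_number(C, "C", lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  if (s == 1) return(0)
  delta <- 1e-12
  upper <- min(1, 1 / C - 1) - delta
  # objective is positive at 0 and negative near the feasibility edge; at
  # extreme s the root sits closer to the edge than machine precision and
  # the perfect-resolution limit is the answer
  if (kagan_product_objective(upper, s, C) >= 0) return(upper)
  stats::uniroot(kagan_product_objective, c(0, upper), s = s, C = C,
                 tol = tol)$root
}

#' Substrate e.e. of a kinetic resolution at a given conversion
#'
#' Solves the substrate-side Kagan relation for the e.e. of the unreacted
#' substrate pool. Satisfies the mass balance
#' `ee_s * (1 - C) == ee_p * C` with [ee_product_at_conversion()].
#' Note the unreacted pool is enriched in the slow (R) enantiomer; the value
#' returned is the unsigned magnitude, i.e. the R-excess of that pool.
#'
#' @inheritParams ee_product_at_conversion
#' @return e.e. fraction in \[0, 1).
#' @export
ee_substrate_at_conversion <- function(s, C, tol = 1e-10) {
  check_number(s, "s", lower = 1)
  check_number(C, "C", lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  if (s == 1) return(0)
  delta <- 1e-12
  if (kagan_substrate_objective(1 - delta, s, C) >= 0) return(1 - delta)
  stats::uniroot(kagan_substrate_objective, c(0, 1 - delta), s = s, C = C,
                 tol = tol)$root
}

#' Selectivity factor from one (conversion, e.e.) observation
#'
#' Direct inversion of the Kagan relations:
#' `s = ln[1 - C(1 + ee)] / ln[1 - C(1 - ee)]` for a product observation,
#' `s = ln[(1-C)(1-ee)] / ln[(1-C)(1+ee)]` for a substrate observation.
#' Round-trips with the forward relations to better than 1e-6 relative.
#'
#' @param C Conversion in (0, 1).
#' @param ee Observed e.e. magnitude in \[0, 1).
#' @param which `"product"` or `"substrate"`.
#' @return s >= 1.
#' @export
s_from_observation <- function(C, ee, which = c("product", "substrate")) {
  which <- match.arg(which)
  check_number(C, "C", lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(ee, "ee", lower = 0, upper = 1, strict_upper = TRUE)
  if (which == "product") {
    num_arg <- 1 - C * (1 + ee)
    if (num_arg <= 0)
      stop_infeasible(sprintf(
        "product observation infeasible: C*(1+ee) = %g must be < 1 (a pool of e.e. %g cannot amount to conversion %g)",
        C * (1 + ee), ee, C))
    s <- log(num_arg) / log(1 - C * (1 - ee))
  } else {
    # (1-C)(1±ee) are positive whenever C < 1 and ee < 1, but the
    # observation is infeasible if it implies more fast enantiomer consumed
    # than was present: (1-C)(1+ee) must be <= 1.
    if ((1 - C) * (1 + ee) > 1)
      stop_infeasible(sprintf(
        "substrate observation infeasible: (1-C)(1+ee) = %g must be <= 1",
        (1 - C) * (1 + ee)))
    s <- log((1 - C) * (1 - ee)) / log((1 - C) * (1 + ee))
  }
  if (is.nan(s)) 1 else s
}

#' Conversion from the two pool e.e.s
#'
#' Mass balance of the resolution stage: the S-excess carried by the
#' consumed pool must equal the R-excess left behind, so
#' `C = ee_s / (ee_s + ee_p)` where `ee_s` and `ee_p` are the substrate and
#' product e.e. magnitudes.
#'
#' @param ee_s,ee_p e.e. magnitudes in \[0, 1\] of the unreacted-substrate
#'   and product pools.
#' @return Conversion fraction in \[0, 1\].
#' @examples
#' conversion_from_ees(0.99, 0.96)  # 0.5077, the lipase resolution
#' @export
conversion_from_ees <- function(ee_s, ee_p) {
  check_number(ee_s, "ee_s", lower = 0, upper = 1)
  check_number(ee_p, "ee_p", lower = 0, upper = 1)
  if (ee_s + ee_p <= 0)
    stop_undefined("conversion undefined when both pool e.e.s are zero")
  ee_s / (ee_s + ee_p)
}
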