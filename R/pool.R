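#' Enantiomer pool
#'
#' A chemically uniform pool of one compound held as the amounts of its two
#' configurations. The S/R labels are bookkeeping labels for the two
#' enantiomers; by package convention positive enantiomeric excess (e.e.)
#' means S-enrichment, and the fast-reacting enantiomer of a kinetic
#' resolution is S (so the selectivity factor s = k1_S / k1_R is >= 1).
#'
#' @param amount_S,amount_R Nonnegative amounts (mol or normalized units) of
#'   the S- and R-configured molecules.
#' @param label Identifier of the chemical pool, e.g. `"substrate"`,
#'   `"intermediate"`, `"product"`.
#' @return An object of class `enantiomer_pool` with fields `amount_S`,
#'   `amount_R`, `label`.
#' @examples
#' p <- enantiomer_pool(0.98, 0.02, "chloroacetamide")
#' ee_of(p)  # 0.96
#' @export
enantiomer_pool <- function(amount_S, amount_R, label = "pool") {
  check_number(amount_S, "amount_S", lower = 0)
  check_number(amount_R, "amount_R", lower = 0)
  structure(
    list(amount_S = as.numeric(amount_S), amount_R = as.numeric(amount_R),
         label = as.character(label)[1L]),
    class = "enantiomer_pool"
  )
}

#' @export
print.enantiomer_pool <- function(x, ...) {
  tot <- pool_total(x)
  cat(sprintf("<enantiomer_pool '%s'> S = %g, R = %g, total = %g", x$label,
              x$amount_S, x$amount_R, tot))
  if (tot > 0) cat(sprintf(", e.e. = %s", ee_percent(ee_of(x))))
  cat("\n")
  invisible(x)
}

#' @rdname enantiomer_pool
#' @param pool An `enantiomer_pool`.
#' @export
pool_total <- function(pool) pool$amount_S + pool$amount_R

#' Enantiomeric excess of a pool
#'
#' Signed e.e. = (S - R) / (S + R), in \[-1, 1\]; positive means S-enriched.
#'
#' @param pool An [enantiomer_pool()].
#' @return Signed fraction in \[-1, 1\].
#' @export
ee_of <- function(pool) {
  tot <- pool_total(pool)
  if (tot <= 0)
    stop_undefined(sprintf("e.e. undefined for empty pool '%s' (total = 0)", pool$label))
  (pool$amount_S - pool$amount_R) / tot
}

#' Build a pool from an e.e. and a total amount
#'
#' Inverse of [ee_of()]: `ee_of(pool_from_ee(e, t))` equals `e` to machine
#' precision.
#'
#' @param ee Signed e.e. fraction in \[-1, 1\] (positive = S-enriched).
#' @param total Positive total amount.
#' @inheritParams enantiomer_pool
#' @export
pool_from_ee <- function(ee, total, label = "pool") {
  check_number(ee, "ee", lower = -1, upper = 1)
  check_number(total, "total", lower = 0, strict_lower = TRUE)
  enantiomer_pool(total * (1 + ee) / 2, total * (1 - ee) / 2, label)
}

#' Mirror a pool (swap the S and R amounts)
#'
#' Relabelling S <-> R negates the e.e. exactly; used to orient inputs so
#' that s >= 1 rather than silently mirroring inside the kinetics.
#'
#' @inheritParams ee_of
#' @export
mirror_pool <- function(pool) {
  enantiomer_pool(pool$amount_R, pool$amount_S, pool$label)
}

#' Format an e.e. fraction as a percentage
#'
#' @param ee Signed e.e. fraction(s).
#' @param digits Decimal places (default 2: coupling of highly enriched pools
#'   produces e.e. values whose comparison is destroyed by 1-decimal
#'   rounding, e.g. 99.98 vs 99.99).
#' @return Character vector like `"96.00%"`. Rounding is round-half-even
#'   (base R), the assumption made for all printed comparisons.
#' @export
ee_percent <- function(ee, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"), round(100 * ee, digits))
}
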