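#' Stereoisomer distribution of a two-unit coupling product
#'
#' Amounts of the four configuration pairings of a dimeric product: the two
#' heterochiral stereoisomers (units of opposite configuration joined) and
#' the two homochiral ones. For an unsymmetrical linker the heterochiral
#' pair is chiral and `hetero_SR` / `hetero_RS` are enantiomers; for a
#' symmetrical linker they are the same meso compound and the amounts are
#' split evenly between the two fields.
#'
#' @param hetero_SR Amount with pool-1 unit S, pool-2 unit R.
#' @param hetero_RS Amount with pool-1 unit R, pool-2 unit S.
#' @param homo_SS,homo_RR Amounts of the homochiral pairings.
#' @return An object of class `product_distribution`.
#' @export
product_distribution <- function(hetero_SR, hetero_RS, homo_SS, homo_RR) {
  for (nm in c("hetero_SR", "hetero_RS", "homo_SS", "homo_RR"))
    check_number(get(nm), nm, lower = 0)
  structure(
    list(hetero_SR = as.numeric(hetero_SR), hetero_RS = as.numeric(hetero_RS),
         homo_SS = as.numeric(homo_SS), homo_RR = as.numeric(homo_RR)),
    class = "product_distribution"
  )
}

#' @export
print.product_distribution <- function(x, ...) {
  cat(sprintf(paste0(
    "<product_distribution> hetero SR = %g, RS = %g | homo SS = %g, RR = %g\n"),
    x$hetero_SR, x$hetero_RS, x$homo_SS, x$homo_RR))
  het <- x$hetero_SR + x$hetero_RS
  hom <- x$homo_SS + x$homo_RR
  if (het > 0)
    cat(sprintf("  heterochiral e.e. %s", ee_percent(hetero_ee(x))))
  if (het + hom > 0)
    cat(sprintf("  d.r. %s\n", format_dr(dr_of(x))))
  invisible(x)
}

#' Heterochiral enantiomeric excess
#'
#' Signed e.e. over the two heterochiral stereoisomers,
#' (SR - RS)/(SR + RS).
#'
#' @param dist A [product_distribution()].
#' @export
hetero_ee <- function(dist) {
  het <- dist$hetero_SR + dist$hetero_RS
  if (het <= 0)
    stop_undefined("heterochiral e.e. undefined: no heterochiral product")
  (dist$hetero_SR - dist$hetero_RS) / het
}

#' Diastereomeric ratio (heterochiral : homochiral)
#'
#' Reported as X in "X:1". A distribution with no homochiral product returns
#' `Inf` (the "all heterochiral" sentinel); an all-zero distribution is an
#' error.
#'
#' @param dist A [product_distribution()].
#' @export
dr_of <- function(dist) {
  het <- dist$hetero_SR + dist$hetero_RS
  hom <- dist$homo_SS + dist$homo_RR
  if (het + hom <= 0)
    stop_undefined("d.r. undefined for an all-zero distribution")
  if (hom == 0) return(Inf)
  het / hom
}

#' Format a d.r. as "X:1"
#'
#' @param dr Nonnegative ratio or `Inf`.
#' @param digits Decimal places for X (default 1).
#' @export
format_dr <- function(dr, digits = 1) {
  ifelse(is.infinite(dr), "Inf:1",
         paste0(formatC(round(dr, digits), format = "f", digits = digits), ":1"))
}

#' Mirror a distribution (swap S and R labels everywhere)
#'
#' Negates the heterochiral e.e. exactly and leaves the d.r. unchanged.
#'
#' @param dist A [product_distribution()].
#' @export
mirror_distribution <- function(dist) {
  product_distribution(hetero_SR = dist$hetero_RS, hetero_RS = dist$hetero_SR,
                       homo_SS = dist$homo_RR, homo_RR = dist$homo_SS)
}
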