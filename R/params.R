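#' Parameter set for the two-location diversity-dependent model
#'
#' Bundles all rate constants of the spatial model: intrinsic sympatric
#' speciation rates for each location, the allopatric speciation rate at unit
#' dispersal, the (constant) local extinction rate, the intrinsic dispersal
#' rate, the two ecological limits, and the crown age over which the clade is
#' simulated.
#'
#' @param lam1_0,lam2_0 Intrinsic sympatric speciation rates of locations 1
#'   and 2 (events per lineage per time unit; the rates at zero diversity).
#' @param lam12_0 Allopatric speciation rate of a widespread species when the
#'   intrinsic dispersal rate equals 1 (events per widespread lineage per
#'   time unit).
#' @param mu Local extinction rate (per lineage-location per time unit),
#'   identical for both locations and diversity-independent.
#' @param M0 Intrinsic dispersal rate (per endemic lineage per time unit; the
#'   rate at zero diversity in the receiving location).
#' @param kprime1,kprime2 Ecological limits \eqn{K'_1}, \eqn{K'_2}: the local
#'   richness at which the linear diversity-dependent rates reach zero. Need
#'   not be integers.
#' @param crown_age Total simulated time span (time units since the crown
#'   split).
#' @return An object of class `spatial_params`.
#' @seealso [nonspatial_params()], [simulate_spatial()]
#' @export
spatial_params <- function(lam1_0 = 0.8, lam2_0 = 0.8, lam12_0 = 0.2,
                           mu = 0, M0 = 0.5, kprime1 = 20, kprime2 = 20,
                           crown_age = 15) {
  stopifnot(lam1_0 >= 0, lam2_0 >= 0, lam12_0 >= 0, mu >= 0, M0 >= 0)
  if (kprime1 <= 0 || kprime2 <= 0)
    stop("ecological limits kprime1 and kprime2 must be positive")
  if (crown_age <= 0) stop("crown_age must be positive")
  structure(list(lam1_0 = lam1_0, lam2_0 = lam2_0, lam12_0 = lam12_0,
                 mu = mu, M0 = M0, kprime1 = kprime1, kprime2 = kprime2,
                 crown_age = crown_age),
            class = "spatial_params")
}

#' Parameter set for the nonspatial diversity-dependent model
#'
#' @param lam0 Intrinsic speciation rate (per lineage per time unit).
#' @param mu Extinction rate (per lineage per time unit).
#' @param kprime Ecological limit \eqn{K'} (need not be an integer; `Inf`
#'   recovers the constant-rates model).
#' @param crown_age Total simulated time span.
#' @return An object of class `nonspatial_params`.
#' @export
nonspatial_params <- function(lam0 = 0.8, mu = 0, kprime = 20,
                              crown_age = 15) {
  stopifnot(lam0 >= 0, mu >= 0)
  if (!(kprime > 0)) stop("ecological limit kprime must be positive")
  if (crown_age <= 0) stop("crown_age must be positive")
  structure(list(lam0 = lam0, mu = mu, kprime = kprime,
                 crown_age = crown_age),
            class = "nonspatial_params")
}

#' Community state of the two-location model
#'
#' The community is summarised by `(a, b, c)`: `a` species endemic to
#' location 1, `b` endemic to location 2 and `c` widespread (present on
#' both).  Local richnesses are `n1 = a + c` and `n2 = b + c`.
#'
#' @param a,b,c Non-negative integer counts of location-1 endemics,
#'   location-2 endemics and widespread species.
#' @return An object of class `community_state` with fields `a`, `b`, `c`,
#'   `n1`, `n2`.
#' @export
community_state <- function(a, b, c) {
  stopifnot(length(a) == 1, length(b) == 1, length(c) == 1)
  if (a < 0 || b < 0 || c < 0 || a != round(a) || b != round(b) ||
      c != round(c))
    stop("a, b, c must be non-negative integers")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 n1 = as.integer(a + c), n2 = as.integer(b + c)),
            class = "community_state")
}

#' @export
print.spatial_params <- function(x, ...) {
  cat("Two-location diversity-dependent model parameters\n")
  cat(sprintf("  sympatric speciation : lam1_0 = %g, lam2_0 = %g\n",
              x$lam1_0, x$lam2_0))
  cat(sprintf("  allopatric speciation: lam12_0 = %g\n", x$lam12_0))
  cat(sprintf("  extinction           : mu = %g\n", x$mu))
  cat(sprintf("  dispersal            : M0 = %g\n", x$M0))
  cat(sprintf("  ecological limits    : K'1 = %g, K'2 = %g\n",
              x$kprime1, x$kprime2))
  cat(sprintf("  crown age            : %g\n", x$crown_age))
  invisible(x)
}

#' @export
print.nonspatial_params <- function(x, ...) {
  cat(sprintf(
    "Nonspatial DD model: lam0 = %g, mu = %g, K' = %g, crown age = %g\n",
    x$lam0, x$mu, x$kprime, x$crown_age))
  invisible(x)
}
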