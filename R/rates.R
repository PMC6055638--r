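#' Diversity-dependent sympatric speciation rate
#'
#' Per-lineage speciation rate at a location holding `n` species:
#' \deqn{\lambda(n) = \max(0,\; \lambda_0 (1 - n/K')).}
#' Equivalently, in the carrying-capacity parameterization,
#' \eqn{\max(0, \lambda_0 - (\lambda_0-\mu) n / K)} with
#' \eqn{K' = \lambda_0 K / (\lambda_0 - \mu)} (see [kprime_from_k()]).
#'
#' @param n Species count at the location (non-negative).
#' @param lam0 Intrinsic speciation rate (rate at zero diversity).
#' @param kprime Ecological limit \eqn{K'} (> 0, possibly non-integer).
#' @param mu Extinction rate; unused in this parameterization, accepted so
#'   callers holding the \eqn{(\lambda_0,\mu,K)} form can pass it through.
#' @return Per-lineage rate, never negative.
#' @export
sympatric_rate <- function(n, lam0, kprime, mu = 0) {
  if (any(kprime <= 0)) stop("ecological limit kprime must be positive")
  if (any(n < 0) || any(lam0 < 0)) stop("n and lam0 must be non-negative")
  pmax(0, lam0 * (1 - n / kprime))
}

#' Diversity-dependent dispersal rate
#'
#' Per-endemic-lineage rate of dispersal into the other location, declining
#' with the receiving location's richness:
#' \deqn{M(n_{dest}) = \max(0,\; M_0 (1 - n_{dest}/K'_{dest})).}
#'
#' @param n_dest Species count at the destination location.
#' @param M0 Intrinsic dispersal rate (rate at zero destination diversity).
#' @param kprime_dest Ecological limit of the destination (> 0).
#' @return Per-endemic-lineage rate, never negative.
#' @export
dispersal_rate <- function(n_dest, M0, kprime_dest) {
  if (any(kprime_dest <= 0))
    stop("ecological limit kprime_dest must be positive")
  if (any(n_dest < 0) || any(M0 < 0))
    stop("n_dest and M0 must be non-negative")
  pmax(0, M0 * (1 - n_dest / kprime_dest))
}

#' Allopatric speciation rate
#'
#' Rate at which a widespread species splits into two endemics, one per
#' location.  The rate is inversely proportional to the intrinsic dispersal
#' rate, \eqn{\lambda_{12} = \lambda_{12,0} / M_0}: gene flow between the
#' locations opposes divergence, so the more freely species disperse, the
#' less likely a widespread species is to split.  \eqn{\lambda_{12,0}} is the
#' allopatric rate when the dispersal rate equals unity.
#'
#' @param M0 Intrinsic dispersal rate (> 0; with `M0 = 0` no widespread
#'   species can exist, so the rate is undefined and requesting it is an
#'   error).
#' @param lam12_0 Allopatric speciation rate at unit dispersal.
#' @return Per-widespread-lineage rate, strictly decreasing in `M0`.
#' @export
allopatric_rate <- function(M0, lam12_0) {
  if (any(M0 <= 0))
    stop("allopatric rate undefined at M0 = 0 (no widespread species exist)")
  if (any(lam12_0 < 0)) stop("lam12_0 must be non-negative")
  lam12_0 / M0
}

#' Ecological limit from carrying capacity
#'
#' Converts the carrying capacity \eqn{K} of the linear diversity-dependence
#' written as \eqn{\max(0, \lambda_0 - (\lambda_0 - \mu) n / K)} into the
#' ecological limit \eqn{K' = \lambda_0 K / (\lambda_0 - \mu)} at which the
#' speciation rate itself reaches zero.  Requires \eqn{\lambda_0 > \mu}.
#'
#' @param lam0 Intrinsic speciation rate.
#' @param mu Extinction rate (`lam0 > mu` required).
#' @param K Carrying capacity (> 0).
#' @return The ecological limit \eqn{K' \ge K}.
#' @export
kprime_from_k <- function(lam0, mu, K) {
  if (any(mu < 0) || any(K <= 0)) stop("need mu >= 0 and K > 0")
  if (any(lam0 <= mu))
    stop("ecological limit undefined unless lam0 > mu")
  lam0 * K / (lam0 - mu)
}

#' Event classes of the spatial model, in fixed order
#'
#' The order matches the rate vector of [total_event_rates()].
#' @format A character vector of length 9.
#' @export
EVENT_CLASSES <- c("sympatric-1", "sympatric-2", "allopatric",
                   "extinction-endemic-1", "extinction-endemic-2",
                   "contraction-lose-1", "contraction-lose-2",
                   "dispersal-1to2", "dispersal-2to1")

#' Total event-class rates of the spatial model
#'
#' Given a community state `(a, b, c)` and the model parameters, returns the
#' total rate of each of the nine event classes, in the fixed order
#' sympatric speciation at location 1 and 2, allopatric speciation, local
#' extinction of a location-1 and of a location-2 endemic, range contraction
#' of a widespread species losing location 1 or location 2, and dispersal
#' from 1 to 2 and from 2 to 1.  Widespread species contribute to both
#' locations' sympatric pools; only endemics disperse; contraction and
#' endemic extinction each proceed at the constant rate `mu` per
#' lineage-location.
#'
#' @param state A [community_state()].
#' @param params A [spatial_params()].
#' @return Named numeric vector of nine non-negative total rates.
#' @export
total_event_rates <- function(state, params) {
  stopifnot(inherits(state, "community_state"),
            inherits(params, "spatial_params"))
  a <- state$a; b <- state$b; c <- state$c
  n1 <- state$n1; n2 <- state$n2
  lam12 <- if (c > 0) allopatric_rate(params$M0, params$lam12_0) else 0
  r <- c(n1 * sympatric_rate(n1, params$lam1_0, params$kprime1),
         n2 * sympatric_rate(n2, params$lam2_0, params$kprime2),
         c * lam12,
         a * params$mu,
         b * params$mu,
         c * params$mu,
         c * params$mu,
         a * dispersal_rate(n2, params$M0, params$kprime2),
         b * dispersal_rate(n1, params$M0, params$kprime1))
  names(r) <- EVENT_CLASSES
  r
}
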