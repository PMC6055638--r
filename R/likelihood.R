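# Constant-rates birth-death building blocks, on the "time remaining to the
# present" axis s.  With r = lam - mu and den(s) = lam - mu*exp(-r*s):
#   E(s)  = extinction probability of a single lineage within time s
#   p1(s) = probability a lineage leaves exactly one lineage in the
#           reconstructed tree:  r^2 exp(-r s) / den(s)^2
# The critical case lam == mu uses the limits 1/(1+lam*s) and 1/(1+lam*s)^2.
log_1mE_cr <- function(s, lam, mu) {
  r <- lam - mu
  if (abs(r) * s < 1e-10) return(-log1p(lam * s))
  log(abs(r)) - log(abs(lam - mu * exp(-r * s)))
}

log_p1_cr <- function(s, lam, mu) {
  r <- lam - mu
  if (abs(r) * s < 1e-10) return(-2 * log1p(lam * s))
  2 * log(abs(r)) - r * s - 2 * log(abs(lam - mu * exp(-r * s)))
}

# coerce phylo / numeric-with-crown-age / branching_times inputs
as_bt <- function(bt, crown_age = NULL) {
  if (inherits(bt, "branching_times")) return(bt)
  if (inherits(bt, "phylo")) return(branching_times(bt, crown_age))
  if (is.numeric(bt)) {
    if (is.null(crown_age)) stop("crown_age required with numeric input")
    return(as_branching_times(bt, crown_age))
  }
  stop("cannot interpret branching-times input")
}

#' Constant-rates birth-death log-likelihood of branching times
#'
#' Log-density of the ordered branching times of a reconstructed tree under
#' the constant-rates birth-death process, conditioned on the crown age and
#' on both crown lineages surviving to the present:
#' \deqn{\log L = \sum_{i=3}^{N}\left[\log((i-1)\lambda) +
#'   \log p_1(T - t_i)\right] + 2\log p_1(T) - 2\log(1 - E(T)),}
#' where \eqn{p_1} and \eqn{E} are the classical reconstructed-process
#' one-descendant and extinction probabilities.  The \eqn{(i-1)} factors make
#' \eqn{e^{\log L}} a proper density: summed over tip counts and integrated
#' over the branching-time simplex it equals 1.  The diversity-dependent
#' likelihood [dd_loglik()] uses the same convention and reduces to this one
#' as \eqn{K' \to \infty}.
#'
#' @param bt A `branching_times` object, an ultrametric [ape::phylo], or a
#'   numeric vector of times (then `crown_age` is required).
#' @param lam Speciation rate (> 0).
#' @param mu Extinction rate (>= 0).
#' @param crown_age Crown age when `bt` is a bare numeric vector.
#' @return The log-likelihood (a finite number for valid inputs).
#' @export
cr_loglik <- function(bt, lam, mu, crown_age = NULL) {
  if (lam <= 0) stop("lam must be positive")
  if (mu < 0) stop("mu must be non-negative")
  bt <- as_bt(bt, crown_age)
  N <- bt$n_tips; T <- bt$crown_age
  ll <- 2 * log_p1_cr(T, lam, mu) - 2 * log_1mE_cr(T, lam, mu)
  if (N > 2) {
    ts <- bt$times[-1]
    ll <- ll + sum(log(seq(2, N - 1)) + log(lam) +
                     vapply(T - ts, log_p1_cr, 0, lam = lam, mu = mu))
  }
  ll
}

# per-lineage DD speciation rate at total diversity Ntot
lam_dd <- function(Ntot, lam0, kprime) {
  if (!is.finite(kprime)) return(rep(lam0, length(Ntot)))
  pmax(0, lam0 * (1 - Ntot / kprime))
}

#' Crown-survival probability under the nonspatial DD model
#'
#' Probability that both crown lineages of the diversity-dependent
#' birth-death process still have living descendants at the present.  The
#' pair of descendant counts \eqn{(m_1, m_2)} follows a master equation with
#' per-lineage speciation \eqn{\lambda(m_1 + m_2)} and extinction \eqn{\mu};
#' a count that hits zero can never recover, so the computation lumps all
#' failed states into one absorbing state and integrates the equation over
#' the crown age.
#'
#' For a finite ecological limit the state space is closed at
#' \eqn{\lfloor K' \rfloor + 1} total species and the computation is exact.
#' For very large or infinite \eqn{K'} the space is truncated adaptively: the
#' cap is doubled until the probability mass near the cap is below `1e-8`
#' (mass escaping the cap is counted as surviving, so the returned value is
#' accurate to that tolerance); failure to satisfy the tolerance at the
#' largest cap is an error.
#'
#' @param params A [nonspatial_params()].
#' @param n_max Optional explicit cap on total species; overrides the rules
#'   above.
#' @return A probability in `(0, 1]`; exactly 1 when `mu == 0`.
#' @export
crown_conditioning_dd <- function(params, n_max = NULL) {
  stopifnot(inherits(params, "nonspatial_params"))
  lam0 <- params$lam0; mu <- params$mu
  kp <- params$kprime; T <- params$crown_age
  if (mu <= 0) return(1)
  closed_cap <- if (is.finite(kp)) floor(kp) + 1 else Inf
  if (!is.null(n_max)) {
    res <- pair_survival_cpp(lam0, mu, kp, T, as.integer(n_max))
    if (n_max < closed_cap && res$top_mass > 1e-8)
      stop("truncation failure: tail mass ", format(res$top_mass),
           " above tolerance at cap ", n_max)
    return(res$p_survive)
  }
  if (closed_cap <= 1000) {
    res <- pair_survival_cpp(lam0, mu, kp, T, as.integer(closed_cap))
    return(res$p_survive)
  }
  for (cap in c(200L, 400L, 800L, 1600L)) {
    res <- pair_survival_cpp(lam0, mu, kp, T, cap)
    if (res$top_mass < 1e-8) return(res$p_survive)
  }
  stop("truncation failure: tail mass above tolerance at cap 1600; ",
       "the process is too supercritical for the ecological limit given")
}

# Conditioning used inside likelihood evaluation and fitting.  Exact pair
# master equation for moderate ecological limits; for K' far above any
# reachable diversity the DD adjustment to crown survival is far below 1e-6
# and the constant-rates closed form (1 - E)^2 is used.
cond_logprob <- function(lam0, mu, kprime, T) {
  if (mu <= 1e-10) return(0)
  if (is.finite(kprime) && floor(kprime) + 1 <= 200) {
    p <- pair_survival_cpp(lam0, mu, kprime, T,
                           as.integer(floor(kprime) + 1))$p_survive
    return(log(p))
  }
  2 * log_1mE_cr(T, lam0, mu)
}

#' Diversity-dependent birth-death log-likelihood of branching times
#'
#' Likelihood of the branching times of a complete extant-species tree under
#' the nonspatial diversity-dependent model, computed with the hidden-state
#' master equation.  Between consecutive branching times, while `k` lineages
#' of the reconstructed tree are observed, the probability vector
#' \eqn{Q_n} over the number `n` of co-existing species *not* among those
#' `k` evolves as
#' \deqn{\frac{dQ_n}{dt} = (n-1+2k)\,\lambda(n-1+k)\,Q_{n-1}
#'   + \mu\,(n+1)\,Q_{n+1} - (n+k)\,(\lambda(n+k)+\mu)\,Q_n,}
#' with \eqn{\lambda(N) = \max(0, \lambda_0 (1 - N/K'))}.  The \eqn{2k} in
#' the gain term reflects that when a species carrying an observed branch
#' buds an (eventually extinct) side lineage, either child may carry the
#' branch onward; this multiplicity is what makes the recursion reduce
#' exactly to the classical constant-rates reconstructed-process density
#' when \eqn{K' \to \infty}.  At each branching
#' time \eqn{Q_n} is multiplied by \eqn{k\,\lambda(n+k)} (any of the `k`
#' observed lineages may be the one that splits) and `k` increments.  The
#' computation starts at the crown (`k = 2`, \eqn{Q_0 = 1}); with complete
#' sampling the likelihood is \eqn{Q_0} at the present, divided by the
#' crown-survival probability (see [crown_conditioning_dd()]).  The vector is
#' renormalized after every interval and the log-scale accumulated, so no
#' underflow occurs.
#'
#' The hidden dimension is truncated: with a finite ecological limit no more
#' than \eqn{\lfloor K' \rfloor + 1} species can ever coexist, which closes
#' the state space exactly; otherwise the cap is doubled until the mass near
#' the cap is below `1e-8`.
#'
#' @inheritParams cr_loglik
#' @param params A [nonspatial_params()] (its `crown_age` must match the
#'   data's).
#' @param n_max Optional explicit hidden-state cap (number of unobserved
#'   species allowed at the crown); overrides the adaptive rule.
#' @param conditioning `"crown"` (default) divides by the crown-survival
#'   probability; `"none"` returns the unconditioned log-density.
#' @return The log-likelihood; `-Inf` when the tip count exceeds
#'   \eqn{\lfloor K' \rfloor + 1}.
#' @export
dd_loglik <- function(bt, params, n_max = NULL,
                      conditioning = c("crown", "none")) {
  stopifnot(inherits(params, "nonspatial_params"))
  conditioning <- match.arg(conditioning)
  bt <- as_bt(bt, params$crown_age)
  if (abs(bt$crown_age - params$crown_age) > 1e-9)
    stop("crown_age of data and parameters disagree")
  lam0 <- params$lam0; mu <- params$mu; kp <- params$kprime
  N <- bt$n_tips; T <- bt$crown_age
  closed_cap <- if (is.finite(kp)) floor(kp) + 1 else Inf
  if (N > closed_cap) return(-Inf)

  if (!is.null(n_max)) {
    cap <- min(N + n_max, closed_cap)
    out <- dd_loglik_pass(bt, lam0, mu, kp, cap)
  } else {
    # A-priori estimate of the hidden occupancy, used to start the cap
    # ladder at a realistic rung and to refuse hopeless parameter regions
    # at once; the top-mass check below remains the actual arbiter of
    # truncation quality.  Hidden lineages are side branches doomed to die
    # before the present, so they behave like the extinction-conditioned
    # process (rates swapped): they immigrate from the <= N observed
    # lineages at rate <= 2*N*lambda*E with E = min(1, mu/lambda) the
    # eventual-extinction probability, and each decays at net rate
    # |lambda - mu|, giving a stationary occupancy iota / |lambda - mu|
    # (or iota * T near criticality).
    if (!is.finite(closed_cap) || closed_cap > N + 2048) {
      r <- lam0 - mu
      Einf <- if (lam0 > 0) min(1, mu / lam0) else 1
      iota <- 2 * N * lam0 * Einf
      m_est <- if (abs(r) > 1e-8) min(iota / abs(r), iota * T)
               else iota * T
      need <- m_est + 10 * sqrt(m_est + 4)
      if (need > 2048)
        stop("numerical error: hidden-state truncation tolerance not ",
             "reachable at any affordable cap")
    } else {
      need <- 0
    }
    out <- NULL
    for (headroom in c(32L, 64L, 128L, 256L, 512L, 1024L, 2048L)) {
      if (headroom < need && N + headroom < closed_cap) next
      cap <- min(N + headroom, closed_cap)
      # uniformization work scales as (lam0 + mu) * T * cap^2; abandoning a
      # rung whose cost estimate is absurd keeps optimizer excursions into
      # extreme rate regions (where the likelihood is negligible anyway)
      # from stalling the fit
      if (cap < closed_cap && (lam0 + mu) * T * cap^2 > 5e7)
        stop("numerical error: hidden-state truncation budget exceeded")
      out <- dd_loglik_pass(bt, lam0, mu, kp, cap)
      if (cap == closed_cap || out$top_mass < 1e-8) break
      out <- NULL
    }
    if (is.null(out))
      stop("numerical error: hidden-state truncation tolerance not reached")
  }
  if (!is.finite(out$loglik) && !identical(out$loglik, -Inf))
    stop("numerical error: non-finite likelihood intermediate")
  if (conditioning == "none") return(out$loglik)
  out$loglik - cond_logprob(lam0, mu, kp, T)
}

# One pass of the master-equation recursion with total-diversity cap `cap`;
# the C++ kernel does the work, the pure-R twin below is kept as a
# cross-checking reference implementation.
dd_loglik_pass <- function(bt, lam0, mu, kp, cap) {
  dd_pass_cpp(bt$times, bt$crown_age, lam0, mu, kp, as.integer(cap))
}

dd_loglik_pass_ref <- function(bt, lam0, mu, kp, cap) {
  N <- bt$n_tips; T <- bt$crown_age
  t_pts <- c(bt$times, T)
  k <- 2L
  nm <- max(0L, cap - k)                 # hidden states n = 0..nm
  Q <- c(1, numeric(nm))
  logS <- 0
  top_mass <- 0
  for (j in seq_len(N - 1L)) {
    k <- j + 1L
    dt <- t_pts[j + 1L] - t_pts[j]
    nm <- length(Q) - 1L
    n <- 0:nm
    lamv <- lam_dd(n + k, lam0, kp)
    dg <- -(n + k) * (lamv + mu)
    dn <- ((n + 2 * k) * lamv)[seq_len(nm)]  # flow n -> n+1
    up <- mu * seq_len(nm)               # flow n+1 -> n
    Q <- expm_tridiag_cpp(dt, dg, up, dn, Q)
    s <- sum(Q)
    if (s <= 0) return(list(loglik = -Inf, top_mass = top_mass))
    if (nm >= 3)
      top_mass <- max(top_mass, sum(Q[(nm - 1):(nm + 1)]) / s)
    Q <- Q / s
    logS <- logS + log(s)
    if (j < N - 1L) {                    # branching time: k -> k + 1
      Q <- Q * (k * lamv)
      s <- sum(Q)
      if (s <= 0) return(list(loglik = -Inf, top_mass = top_mass))
      Q <- Q / s
      logS <- logS + log(s)
      if (length(Q) > 1L) Q <- Q[-length(Q)]   # hidden cap shrinks with k
    }
  }
  if (Q[1] <= 0) return(list(loglik = -Inf, top_mass = top_mass))
  list(loglik = log(Q[1]) + logS, top_mass = top_mass)
}
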