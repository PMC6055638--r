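# Independently coded reference quantities used as test oracles.

# Crown-conditioned pure-birth (Yule) log-likelihood of ordered branching
# times: with no extinction every lineage survives, so the classical
# reconstructed-process density reduces to
#   sum_{i=3}^{N} [ log(i-1) + log(lam) - lam (T - t_i) ] - 2 lam T.
yule_loglik <- function(times, lam, T) {
  N <- length(times) + 1
  ll <- -2 * lam * T
  if (N > 2) {
    ts <- times[-1]
    ll <- ll + sum(log(seq(2, N - 1)) + log(lam) - lam * (T - ts))
  }
  ll
}

# Constant-rates extinction probability E(t) and the closed-form crown
# survival (1 - E)^2, coded directly from the birth-death formulas.
cr_extinction_prob <- function(t, lam, mu) {
  if (abs(lam - mu) < 1e-12) return(lam * t / (1 + lam * t))
  r <- lam - mu
  mu * (exp(r * t) - 1) / (lam * exp(r * t) - mu)
}

# Gauss-Legendre nodes/weights on (-1, 1) via the Golub-Welsch eigenvalue
# construction (symmetric tridiagonal Jacobi matrix).
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

# Species registry -> event_log wrapper for hand-built fixtures (only the
# fields the tree machinery consumes need to be populated).
manual_log <- function(species, events, crown_age, model = "dd") {
  structure(list(model = model, params = NULL, seed = NA_integer_,
                 events = events, species = species, ranges = NULL,
                 n_rejected = 0L, crown_age = crown_age),
            class = "event_log")
}

# Extant species ids of an event log.
extant_ids <- function(log) {
  log$species$species_id[is.na(log$species$death_time)]
}
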