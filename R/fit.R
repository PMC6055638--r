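new_dd_fit <- function(model, estimates, loglik, converged, n_starts_used,
                       trace, bt, flags = character(0)) {
  structure(list(model = model, estimates = estimates, loglik = loglik,
                 converged = converged, n_starts_used = n_starts_used,
                 trace = trace, bt = bt, n_tips = bt$n_tips,
                 crown_age = bt$crown_age, flags = flags),
            class = "dd_fit")
}

run_starts <- function(starts, nll, reltol, maxit) {
  trace <- data.frame(start = seq_along(starts), loglik = NA_real_,
                      evals = NA_integer_, convergence = NA_integer_)
  best <- NULL
  for (i in seq_along(starts)) {
    res <- tryCatch(
      stats::optim(starts[[i]], nll, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res)) next
    trace$loglik[i] <- -res$value
    trace$evals[i] <- res$counts[1]
    trace$convergence[i] <- res$convergence
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("fit failure: no optimization start converged")
  list(best = best, trace = trace)
}

#' Fit the constant-rates birth-death model by maximum likelihood
#'
#' Maximizes [cr_loglik()] over the speciation and extinction rates with a
#' multi-start Nelder-Mead simplex on log-transformed coordinates.
#'
#' @param bt A `branching_times` object, an ultrametric [ape::phylo], or a
#'   numeric vector of branching times (then `crown_age` is required).
#' @param crown_age Crown age when `bt` is a bare numeric vector.
#' @return A `dd_fit` with `model = "CR"` and estimates `lam0`, `mu`.
#' @export
fit_cr <- function(bt, crown_age = NULL) {
  bt <- as_bt(bt, crown_age)
  N <- bt$n_tips; T <- bt$crown_age
  eps <- 1e-10
  nll <- function(th) {
    lam <- exp(th[1]); mu <- max(0, exp(th[2]) - eps)
    if (!is.finite(lam) || lam <= 0) return(1e10)
    v <- tryCatch(cr_loglik(bt, lam, mu), error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  lam_y <- max((log(N) - log(2)) / T, 0.01)      # Yule-flavored initial rate
  starts <- list(c(log(lam_y), log(0.05 + eps)),
                 c(log(0.8), log(0.1 + eps)),
                 c(log(lam_y) + 0.3, log(0.05 + eps) - 0.5))
  out <- run_starts(starts, nll, reltol = 1e-8, maxit = 500)
  th <- out$best$par
  est <- c(lam0 = exp(th[1]), mu = max(0, exp(th[2]) - eps))
  new_dd_fit("CR", est, -out$best$value,
             converged = any(out$trace$convergence == 0, na.rm = TRUE),
             n_starts_used = length(starts), trace = out$trace, bt = bt)
}

#' Fit the diversity-dependent birth-death model by maximum likelihood
#'
#' Maximizes [dd_loglik()] over \eqn{(\lambda_0, \mu, K')} under the
#' constraints \eqn{\lambda_0 > 0}, \eqn{\mu \ge 0} and
#' \eqn{K' > N_{tips} - 1}, with a multi-start Nelder-Mead simplex on the
#' transformed coordinates \eqn{(\log\lambda_0, \log(\mu + 10^{-10}),
#' \log(K' - (N_{tips}-1)))}.  One start is seeded at the constant-rates
#' optimum with a very large ecological limit: the CR model is the boundary
#' limit of the DD model, so the returned DD log-likelihood never falls
#' below the CR one by more than numerical tolerance, and the likelihood
#' ratio statistic is guaranteed non-negative.  If, despite the seed, the DD
#' optimum ends below the CR one, the fit carries the flag
#' `"below_cr_optimum"` and [lr_statistic()] reports 0.
#'
#' Trees with very few tips cannot identify three parameters; fits on fewer
#' than 4 tips carry the flag `"weakly_identified"`.
#'
#' @inheritParams fit_cr
#' @param cr_fit Optional `dd_fit` of the CR model on the same data (fitted
#'   internally when missing); used to seed the boundary start.
#' @return A `dd_fit` with `model = "DD"` and estimates `lam0`, `mu`,
#'   `kprime`.
#' @export
fit_dd <- function(bt, crown_age = NULL, cr_fit = NULL) {
  bt <- as_bt(bt, crown_age)
  N <- bt$n_tips; T <- bt$crown_age
  if (is.null(cr_fit)) cr_fit <- fit_cr(bt)
  eps <- 1e-10
  kp_floor <- N - 1
  nll <- function(th) {
    # search bounds: per-lineage rates beyond 20 are absurd on any usable
    # tree (hundreds of expected events per lineage over the crown age) and
    # make the hidden-state computation arbitrarily expensive; the gentle
    # slope steers the simplex back
    if (th[1] > log(20) || th[2] > log(20))
      return(1e10 + max(th[1], th[2]))
    lam0 <- exp(th[1]); mu <- max(0, exp(th[2]) - eps)
    kp <- kp_floor + exp(th[3])
    if (!is.finite(lam0) || lam0 <= 0 || !is.finite(kp)) return(1e10)
    p <- nonspatial_params(lam0 = lam0, mu = mu, kprime = kp, crown_age = T)
    v <- tryCatch(dd_loglik(bt, p), error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  lam_y <- max((log(N) - log(2)) / T, 0.01)
  cr_est <- cr_fit$estimates
  starts <- list(
    c(log(lam_y), log(0.05 + eps), log(2 * N - kp_floor)),
    c(log(0.8), log(0.1 + eps), log(N + 10 - kp_floor)),
    c(log(max(cr_est[["lam0"]], 1e-4)), log(cr_est[["mu"]] + eps),
      log(1e6 - kp_floor)))
  out <- run_starts(starts, nll, reltol = 1e-6, maxit = 120)
  th <- out$best$par
  est <- c(lam0 = exp(th[1]), mu = max(0, exp(th[2]) - eps),
           kprime = kp_floor + exp(th[3]))
  loglik <- -out$best$value
  flags <- character(0)
  if (N < 4) flags <- c(flags, "weakly_identified")
  if (est[["kprime"]] - kp_floor < 1e-4) flags <- c(flags, "kprime_boundary")
  if (est[["kprime"]] > 1e5) flags <- c(flags, "effectively_cr")
  if (loglik < cr_fit$loglik - 1e-6) flags <- c(flags, "below_cr_optimum")
  new_dd_fit("DD", est, loglik,
             converged = any(out$trace$convergence == 0, na.rm = TRUE),
             n_starts_used = length(starts), trace = out$trace, bt = bt,
             flags = flags)
}

#' @export
print.dd_fit <- function(x, ...) {
  cat(sprintf("%s birth-death fit (%d tips, crown age %g)\n", x$model,
              x$n_tips, x$crown_age))
  cat("  estimates:",
      paste(sprintf("%s = %.4g", names(x$estimates), x$estimates),
            collapse = ", "), "\n")
  cat(sprintf("  log-likelihood: %.6g   converged: %s\n", x$loglik,
              x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dd_fit <- function(object, ...) {
  print(object)
  cat("  optimization starts:\n")
  print(object$trace, row.names = FALSE)
  invisible(object)
}

#' @export
coef.dd_fit <- function(object, ...) object$estimates

#' @export
logLik.dd_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates),
            nobs = object$n_tips - 1L, class = "logLik")
}

#' Simulate new trees from a fitted model
#'
#' Draws crown-conditioned event histories at the fitted parameters: the CR
#' model via [simulate_cr()], the DD model via [simulate_nonspatial_dd()].
#'
#' @param object A `dd_fit`.
#' @param nsim Number of replicate histories.
#' @param seed Master seed; replicate `r` uses `derive_seed(seed, r)`.
#' @param ... Unused.
#' @return A list of `event_log` objects (length `nsim`).
#' @export
simulate.dd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  est <- object$estimates
  T <- object$crown_age
  lapply(seq_len(nsim), function(r) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, r)
    if (object$model == "CR")
      simulate_cr(max(est[["lam0"]], 1e-12), est[["mu"]], T, seed = s)
    else
      simulate_nonspatial_dd(
        nonspatial_params(lam0 = max(est[["lam0"]], 1e-12), mu = est[["mu"]],
                          kprime = est[["kprime"]], crown_age = T),
        seed = s)
  })
}
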