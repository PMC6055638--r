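#' Configuration of the bootstrap likelihood-ratio test
#'
#' @param X_CR Number of bootstrap datasets simulated under the fitted CR
#'   model (the null distribution; >= 1).
#' @param X_DD Number of bootstrap datasets simulated under the fitted DD
#'   model (the power estimate; >= 0, 0 skips the power phase).
#' @param alpha Significance level in (0, 1).
#' @param seed Master seed; every bootstrap replicate derives its own seed
#'   deterministically, so the result is independent of execution order.
#' @return An object of class `test_config`.
#' @export
test_config <- function(X_CR = 100L, X_DD = 100L, alpha = 0.05, seed = 1L) {
  stopifnot(X_CR >= 1, X_DD >= 0, alpha > 0, alpha < 1)
  structure(list(X_CR = as.integer(X_CR), X_DD = as.integer(X_DD),
                 alpha = alpha, seed = as.integer(seed)),
            class = "test_config")
}

#' Likelihood-ratio statistic of DD versus CR
#'
#' Twice the log-likelihood difference between the diversity-dependent and
#' the constant-rates fit of the same branching times.  Because CR is the
#' boundary limit of DD and [fit_dd()] seeds one start at the CR optimum,
#' the statistic is non-negative; a finite-precision negative difference is
#' reported as 0 (with attribute `flagged = TRUE`).
#'
#' @param fit_cr A `dd_fit` with `model = "CR"`.
#' @param fit_dd A `dd_fit` with `model = "DD"` on the same branching times.
#' @return The LR statistic (>= 0).
#' @export
lr_statistic <- function(fit_cr, fit_dd) {
  stopifnot(inherits(fit_cr, "dd_fit"), inherits(fit_dd, "dd_fit"))
  if (fit_cr$model != "CR" || fit_dd$model != "DD")
    stop("expected a CR fit and a DD fit, in that order")
  if (fit_cr$n_tips != fit_dd$n_tips ||
      abs(fit_cr$crown_age - fit_dd$crown_age) > 1e-9 ||
      max(abs(fit_cr$bt$times - fit_dd$bt$times)) > 1e-9)
    stop("mismatched inputs: the two fits are not on the same data")
  lr <- 2 * (fit_dd$loglik - fit_cr$loglik)
  if (lr < 0) return(structure(0, flagged = TRUE))
  lr
}

# p-value, critical value and power from raw LR collections; the formulas
# are the test's definitions: p = (R_CR + 1)/(X_CR + 1) with R_CR the count
# of null LRs strictly larger than LR0 (ties are non-exceedances), LR_alpha
# the ceiling((1 - alpha)(X_CR + 1))-th order statistic (clipped to X_CR),
# and power = R_DD/(X_DD + 1).
summarize_lrt <- function(LR0, LR_null, LR_alt, alpha) {
  X_CR <- length(LR_null)
  R_CR <- sum(LR_null > LR0)
  p_value <- (R_CR + 1) / (X_CR + 1)
  idx <- min(X_CR, ceiling((1 - alpha) * (X_CR + 1)))
  LR_alpha <- sort(LR_null)[idx]
  if (length(LR_alt) > 0) {
    R_DD <- sum(LR_alt > LR_alpha)
    power <- R_DD / (length(LR_alt) + 1)
  } else {
    R_DD <- NA_integer_
    power <- NA_real_
  }
  list(R_CR = R_CR, p_value = p_value, LR_alpha = LR_alpha, R_DD = R_DD,
       power = power)
}

# simulate one bootstrap tree at a fitted model, refit both models, return
# the LR; failures are conservative: unsatisfiable conditioning retries with
# the next derived seed, an irrecoverable fit failure records LR = 0.
boot_replicate <- function(fit, seed) {
  for (j in 1:5) {
    log <- tryCatch(simulate(fit, nsim = 1, seed = derive_seed(seed, j))[[1]],
                    error = function(e) NULL)
    if (!is.null(log)) break
  }
  if (is.null(log)) return(list(LR = 0, failed = TRUE, n_tips = NA_integer_))
  out <- tryCatch({
    bt <- branching_times(build_extant_tree(log))
    fc <- fit_cr(bt)
    fd <- fit_dd(bt, cr_fit = fc)
    list(LR = as.numeric(lr_statistic(fc, fd)), failed = FALSE,
         n_tips = bt$n_tips)
  }, error = function(e) list(LR = 0, failed = TRUE, n_tips = NA_integer_))
  out
}

#' Bootstrap likelihood-ratio test for diversity-dependence
#'
#' The parametric bootstrap procedure for comparing the diversity-dependent
#' model against the constant-rates null on one set of branching times:
#' \enumerate{
#'   \item Fit CR and DD to the data; the observed statistic is
#'     \eqn{LR_0 = 2(\ell_{DD} - \ell_{CR})}.
#'   \item Simulate `X_CR` crown-conditioned trees under the CR model at its
#'     ML estimates (same crown age), refit both models to each, and collect
#'     the null statistics \eqn{LR_i}.
#'   \item The p-value is \eqn{(R_{CR}+1)/(X_{CR}+1)}, with \eqn{R_{CR}} the
#'     number of null statistics exceeding \eqn{LR_0}.
#'   \item The critical value \eqn{LR_\alpha} is the
#'     \eqn{\lceil(1-\alpha)(X_{CR}+1)\rceil}-th order statistic of the null
#'     statistics.
#'   \item Simulate `X_DD` trees under the DD model at its ML estimates,
#'     refit both models, and estimate the power as
#'     \eqn{R_{DD}/(X_{DD}+1)}, with \eqn{R_{DD}} the number of these
#'     statistics exceeding \eqn{LR_\alpha}.
#' }
#' Every bootstrap replicate derives its seed from `cfg$seed`, so the result
#' is reproducible and independent of execution order.  A replicate whose
#' fit fails irrecoverably enters with LR = 0 (conservative both against
#' rejection and against power) and is flagged, never dropped, keeping the
#' denominators as defined.
#'
#' @param bt A `branching_times` object, ultrametric [ape::phylo], or
#'   numeric vector (with `crown_age`).
#' @param cfg A [test_config()].
#' @param crown_age Crown age when `bt` is a bare numeric vector.
#' @return An object of class `dd_lrt` with the observed statistic, the two
#'   bootstrap LR collections, `p_value`, `LR_alpha`, `power`, the fits of
#'   the observed data, and per-replicate failure flags.
#' @export
bootstrap_lrt <- function(bt, cfg = test_config(), crown_age = NULL) {
  stopifnot(inherits(cfg, "test_config"))
  bt <- as_bt(bt, crown_age)
  fc <- fit_cr(bt)
  fd <- fit_dd(bt, cr_fit = fc)
  LR0 <- as.numeric(lr_statistic(fc, fd))

  null_reps <- lapply(seq_len(cfg$X_CR), function(i)
    boot_replicate(fc, derive_seed(cfg$seed, i)))
  alt_reps <- lapply(seq_len(cfg$X_DD), function(i)
    boot_replicate(fd, derive_seed(cfg$seed, cfg$X_CR + i)))

  LR_null <- vapply(null_reps, `[[`, 0, "LR")
  LR_alt <- vapply(alt_reps, `[[`, 0, "LR")
  s <- summarize_lrt(LR0, LR_null, LR_alt, cfg$alpha)

  structure(list(LR0 = LR0, LR_null = LR_null, LR_alt = LR_alt,
                 R_CR = s$R_CR, p_value = s$p_value, LR_alpha = s$LR_alpha,
                 R_DD = s$R_DD, power = s$power, alpha = cfg$alpha,
                 X_CR = cfg$X_CR, X_DD = cfg$X_DD, seed = cfg$seed,
                 fit_cr = fc, fit_dd = fd,
                 n_failed_null = sum(vapply(null_reps, `[[`, TRUE, "failed")),
                 n_failed_alt = sum(vapply(alt_reps, `[[`, TRUE, "failed"))),
            class = "dd_lrt")
}

#' Accept or reject the constant-rates model
#'
#' Rejects the CR null when the bootstrap p-value is at most `alpha`
#' (boundary inclusive).
#'
#' @param result A `dd_lrt`.
#' @param alpha Significance level; defaults to the one the test was run
#'   with.
#' @return `"reject CR"` or `"retain CR"`.
#' @export
decision <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "dd_lrt"))
  if (result$p_value <= alpha) "reject CR" else "retain CR"
}

#' @export
print.dd_lrt <- function(x, ...) {
  cat("Bootstrap likelihood-ratio test of diversity-dependence\n")
  cat(sprintf("  observed LR0 = %.4g\n", x$LR0))
  cat(sprintf("  p-value = %.4g  (R_CR = %d of X_CR = %d null LRs > LR0)\n",
              x$p_value, x$R_CR, x$X_CR))
  cat(sprintf("  critical value LR_alpha = %.4g at alpha = %g -> %s\n",
              x$LR_alpha, x$alpha, decision(x)))
  if (!is.na(x$power))
    cat(sprintf("  power = %.4g  (R_DD = %d of X_DD = %d alt LRs > LR_alpha)\n",
                x$power, x$R_DD, x$X_DD))
  if (x$n_failed_null + x$n_failed_alt > 0)
    cat(sprintf("  flagged replicates entered with LR = 0: %d null, %d alt\n",
                x$n_failed_null, x$n_failed_alt))
  invisible(x)
}

#' One-row summary of a bootstrap test, for CSV output
#'
#' @param x A `dd_lrt`.
#' @return A one-row `data.frame` (LR0, p, LR_alpha, power, X_CR, X_DD,
#'   alpha, seed).
#' @export
lrt_summary_row <- function(x) {
  stopifnot(inherits(x, "dd_lrt"))
  data.frame(LR0 = x$LR0, p_value = x$p_value, LR_alpha = x$LR_alpha,
             power = x$power, X_CR = x$X_CR, X_DD = x$X_DD,
             alpha = x$alpha, seed = x$seed)
}
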