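#' Scenario definition for the simulation study
#'
#' Five canonical scenarios: three spatial (Scenario 1: \eqn{K' = 20} on
#' both locations; Scenario 2: 40/40; Scenario 3: 20/40) and two nonspatial
#' (Scenario 4: \eqn{K' = 20}; Scenario 5: \eqn{K' = 40}).  All share the
#' intrinsic rates \eqn{\lambda_{1,0} = \lambda_{2,0} = 0.8},
#' \eqn{\lambda_{12,0} = 0.2} and a crown age of 15 time units.  Spatial
#' scenarios cross an extinction grid with a dispersal grid; nonspatial ones
#' use the extinction grid alone (their intrinsic rate is taken equal to the
#' spatial locations', 0.8).
#'
#' @param scenario_id Integer in 1..5.
#' @param reps Trees per parameter set (100 at published scale).
#' @param mu_grid Extinction rates explored.
#' @param m0_grid Intrinsic dispersal rates explored (spatial scenarios).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id, reps = 100L,
                          mu_grid = c(0, 0.1, 0.2, 0.4),
                          m0_grid = c(0, 0.05, 0.1, 0.15, 0.3, 0.5, 1, 5,
                                      1000)) {
  if (!scenario_id %in% 1:5) stop("unknown scenario_id: ", scenario_id)
  spatial <- scenario_id <= 3
  kp <- switch(scenario_id, c(20, 20), c(40, 40), c(20, 40), 20, 40)
  structure(list(scenario_id = as.integer(scenario_id), spatial = spatial,
                 kprime1 = if (spatial) kp[1] else NA_real_,
                 kprime2 = if (spatial) kp[2] else NA_real_,
                 kprime = if (spatial) NA_real_ else kp,
                 lam1_0 = 0.8, lam2_0 = 0.8, lam12_0 = 0.2, lam0 = 0.8,
                 crown_age = 15, mu_grid = mu_grid,
                 m0_grid = if (spatial) m0_grid else numeric(0),
                 reps = as.integer(reps)),
            class = "scenario_spec")
}

#' Parameter sets of a scenario
#'
#' Spatial scenarios cross the extinction grid with the dispersal grid (4 x
#' 9 = 36 sets with the default grids); nonspatial scenarios enumerate the
#' extinction grid alone.
#'
#' @param spec A [scenario_spec()].
#' @return A `data.frame`, one row per parameter set.
#' @export
scenario_grid <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$spatial) {
    g <- expand.grid(mu = spec$mu_grid, M0 = spec$m0_grid,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[order(g$mu, g$M0), , drop = FALSE]
    rownames(g) <- NULL
    data.frame(scenario = spec$scenario_id, mu = g$mu, M0 = g$M0,
               lam1_0 = spec$lam1_0, lam2_0 = spec$lam2_0,
               lam12_0 = spec$lam12_0, kprime1 = spec$kprime1,
               kprime2 = spec$kprime2, crown_age = spec$crown_age)
  } else {
    data.frame(scenario = spec$scenario_id, mu = sort(spec$mu_grid),
               M0 = NA_real_, lam0 = spec$lam0, kprime = spec$kprime,
               crown_age = spec$crown_age)
  }
}

#' Planned full-scale workload of a scenario
#'
#' Number of simulations-plus-estimations the published-scale study design
#' implies: parameter sets x trees per set x bootstrap samples per tree
#' (36 x 100 x 2000 = 7.2 million for a spatial scenario).
#'
#' @param spec A [scenario_spec()].
#' @param trees Trees per parameter set (published scale: 100).
#' @param bootstraps Bootstrap samples per tree (published scale: 2000).
#' @return A number.
#' @export
planned_workload <- function(spec, trees = 100, bootstraps = 2000) {
  nrow(scenario_grid(spec)) * trees * bootstraps
}

sim_for_row <- function(row, spatial, seed) {
  if (spatial) {
    p <- spatial_params(lam1_0 = row$lam1_0, lam2_0 = row$lam2_0,
                        lam12_0 = row$lam12_0, mu = row$mu, M0 = row$M0,
                        kprime1 = row$kprime1, kprime2 = row$kprime2,
                        crown_age = row$crown_age)
    simulate_spatial(p, seed = seed)
  } else {
    p <- nonspatial_params(lam0 = row$lam0, mu = row$mu,
                           kprime = row$kprime, crown_age = row$crown_age)
    simulate_nonspatial_dd(p, seed = seed)
  }
}

#' Run the power / type-I-error / bias study over a scenario grid
#'
#' For every parameter set of the scenario, simulates `reps` crown-conditioned
#' trees, applies the bootstrap likelihood-ratio test to each, and aggregates
#' rejection fractions, power and quantiles of the DD parameter estimates.
#' Fully seeded: replicate `r` of set `s` derives its seed from
#' `(seed, s, r)`, so reruns are bitwise identical regardless of worker
#' count.  With `out_dir` given, per-set CSV checkpoints are written and
#' re-used, so interrupted runs resume.
#'
#' @param spec A [scenario_spec()].
#' @param reps Trees per parameter set (defaults to `spec$reps`).
#' @param cfg A [test_config()]; its seed is overridden per replicate.
#' @param seed Master seed of the whole run.
#' @param out_dir Optional checkpoint/output directory.
#' @param workers Number of worker processes (forked; 1 = serial).
#' @return An object of class `grid_result`: list with `grid` (the parameter
#'   sets), `trees` (one row per simulated tree: set index, tip count, LR0,
#'   p-value, power, rejection at `alpha`, and the CR and DD estimates) and
#'   `summary` (one row per set).
#' @export
run_grid <- function(spec, reps = spec$reps, cfg = test_config(),
                     seed = 1L, out_dir = NULL, workers = 1L) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(cfg, "test_config"))
  grid <- scenario_grid(spec)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  run_set <- function(s) {
    row <- grid[s, , drop = FALSE]
    ckpt <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("set%d_mu%g_M0%s.csv", spec$scenario_id,
                                 row$mu, ifelse(spec$spatial, row$M0, "NA")))
    if (!is.null(out_dir) && file.exists(ckpt))
      return(utils::read.csv(ckpt))
    set_seed <- derive_seed(seed, s)
    rows <- lapply(seq_len(reps), function(r) {
      rs <- derive_seed(set_seed, r)
      log <- sim_for_row(row, spec$spatial, rs)
      bt <- branching_times(build_extant_tree(log))
      res <- bootstrap_lrt(bt, test_config(cfg$X_CR, cfg$X_DD, cfg$alpha,
                                           derive_seed(rs, 7L)))
      data.frame(set = s, rep = r, n_tips = bt$n_tips, LR0 = res$LR0,
                 p_value = res$p_value, power = res$power,
                 reject = res$p_value <= cfg$alpha,
                 cr_lam = res$fit_cr$estimates[["lam0"]],
                 cr_mu = res$fit_cr$estimates[["mu"]],
                 dd_lam0 = res$fit_dd$estimates[["lam0"]],
                 dd_mu = res$fit_dd$estimates[["mu"]],
                 dd_kprime = res$fit_dd$estimates[["kprime"]])
    })
    out <- do.call(rbind, rows)
    if (!is.null(out_dir) && !is.null(out) && nrow(out) > 0)
      utils::write.csv(out, ckpt, row.names = FALSE)
    out
  }

  sets <- seq_len(nrow(grid))
  per_set <- if (workers > 1L && requireNamespace("parallel", quietly = TRUE))
    parallel::mclapply(sets, run_set, mc.cores = workers)
  else
    lapply(sets, run_set)
  trees <- do.call(rbind, per_set)

  summary <- if (is.null(trees) || nrow(trees) == 0) {
    cbind(grid, n_trees = 0L)
  } else {
    agg <- lapply(sets, function(s) {
      d <- trees[trees$set == s, , drop = FALSE]
      if (nrow(d) == 0) return(NULL)
      data.frame(set = s, n_trees = nrow(d),
                 reject_frac = mean(d$reject), mean_power = mean(d$power),
                 median_p = stats::median(d$p_value),
                 lam0_q25 = stats::quantile(d$dd_lam0, 0.25, names = FALSE),
                 lam0_med = stats::median(d$dd_lam0),
                 lam0_q75 = stats::quantile(d$dd_lam0, 0.75, names = FALSE),
                 mu_q25 = stats::quantile(d$dd_mu, 0.25, names = FALSE),
                 mu_med = stats::median(d$dd_mu),
                 mu_q75 = stats::quantile(d$dd_mu, 0.75, names = FALSE),
                 kprime_q25 = stats::quantile(d$dd_kprime, 0.25,
                                              names = FALSE),
                 kprime_med = stats::median(d$dd_kprime),
                 kprime_q75 = stats::quantile(d$dd_kprime, 0.75,
                                              names = FALSE))
    })
    cbind(grid[vapply(agg, Negate(is.null), TRUE), , drop = FALSE],
          do.call(rbind, agg))
  }
  structure(list(grid = grid, trees = trees, summary = summary,
                 spec = spec, cfg = cfg, seed = seed),
            class = "grid_result")
}

#' Parameter-estimate bias table of a grid run
#'
#' Per parameter set, the median and quartiles of the DD maximum-likelihood
#' estimates next to the generating values — the tabular counterpart of the
#' estimate-accuracy figures of this kind of study (for spatial scenarios
#' the natural reference for the fitted ecological limit is the sum of the
#' two local limits).
#'
#' @param gr A `grid_result`.
#' @return A `data.frame`, one row per parameter set with trees.
#' @export
estimate_bias_tables <- function(gr) {
  stopifnot(inherits(gr, "grid_result"))
  s <- gr$summary
  if (is.null(s$n_trees) || all(s$n_trees == 0)) return(s)
  spatial <- gr$spec$spatial
  s$true_lam0 <- if (spatial) gr$spec$lam1_0 else gr$spec$lam0
  s$true_mu <- s$mu
  s$true_kprime_ref <- if (spatial) gr$spec$kprime1 + gr$spec$kprime2
                       else gr$spec$kprime
  s
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("Grid result: scenario %d, %d parameter sets, %d trees\n",
              x$spec$scenario_id, nrow(x$grid),
              if (is.null(x$trees)) 0L else nrow(x$trees)))
  invisible(x)
}
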