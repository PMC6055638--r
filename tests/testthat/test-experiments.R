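test_that("scenario definitions expose the study design", {
  expect_error(scenario_spec(6), "unknown scenario")
  s1 <- scenario_spec(1)
  expect_true(s1$spatial)
  expect_equal(c(s1$kprime1, s1$kprime2), c(20, 20))
  s3 <- scenario_spec(3)
  expect_equal(c(s3$kprime1, s3$kprime2), c(20, 40))
  s5 <- scenario_spec(5)
  expect_false(s5$spatial)
  expect_equal(s5$kprime, 40)
})

test_that("the parameter grid crosses extinction with dispersal", {
  g <- scenario_grid(scenario_spec(1))
  expect_equal(nrow(g), 36)                     # 4 mu x 9 M0
  expect_equal(sort(unique(g$mu)), c(0, 0.1, 0.2, 0.4))
  expect_equal(sort(unique(g$M0)),
               c(0, 0.05, 0.1, 0.15, 0.3, 0.5, 1, 5, 1000))
  expect_false(is.unsorted(g$mu))               # ordered by mu, then M0
  expect_false(is.unsorted(g$M0[g$mu == 0]))
  expect_true(all(g$crown_age == 15))

  g4 <- scenario_grid(scenario_spec(4))
  expect_equal(nrow(g4), 4)
  expect_true(all(is.na(g4$M0)))
  expect_equal(g4$kprime, rep(20, 4))
})

test_that("the planned full-scale workload is 7.2 million per spatial scenario", {
  expect_equal(planned_workload(scenario_spec(1)), 7.2e6)
  expect_equal(planned_workload(scenario_spec(2)), 36 * 100 * 2000)
  expect_equal(planned_workload(scenario_spec(4)), 4 * 100 * 2000)
  expect_equal(planned_workload(scenario_spec(1), trees = 10,
                                bootstraps = 50), 36 * 10 * 50)
})

test_that("a desk-scale grid run produces tables and resumes from checkpoints", {
  spec <- scenario_spec(4, reps = 1L, mu_grid = 0)
  cfg <- test_config(X_CR = 2L, X_DD = 1L, alpha = 0.05, seed = 1L)
  out_dir <- file.path(tempdir(), "gridrun")
  unlink(out_dir, recursive = TRUE)

  gr <- run_grid(spec, cfg = cfg, seed = 99L, out_dir = out_dir)
  expect_s3_class(gr, "grid_result")
  expect_equal(nrow(gr$grid), 1)
  expect_equal(nrow(gr$trees), 1)
  expect_true(all(c("n_tips", "LR0", "p_value", "reject", "dd_kprime") %in%
                    names(gr$trees)))
  expect_equal(nrow(gr$summary), 1)
  expect_true(all(c("reject_frac", "kprime_med") %in% names(gr$summary)))
  expect_length(list.files(out_dir, pattern = "\\.csv$"), 1)

  # a second run finds the checkpoint and reproduces the tables exactly
  gr2 <- run_grid(spec, cfg = cfg, seed = 99L, out_dir = out_dir)
  expect_equal(gr2$trees$LR0, gr$trees$LR0)
  expect_equal(gr2$summary$reject_frac, gr$summary$reject_frac)

  bias <- estimate_bias_tables(gr)
  expect_equal(bias$true_lam0, 0.8)
  expect_equal(bias$true_mu, 0)
  expect_equal(bias$true_kprime_ref, 20)

  expect_output(print(gr), "scenario 4")
  unlink(out_dir, recursive = TRUE)
})
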