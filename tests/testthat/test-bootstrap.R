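test_that("test configuration validates its arguments", {
  cfg <- test_config(19L, 0L, alpha = 0.05, seed = 3L)
  expect_identical(cfg$X_CR, 19L)
  expect_identical(cfg$X_DD, 0L)
  expect_error(test_config(0L, 10L))
  expect_error(test_config(10L, -1L))
  expect_error(test_config(10L, 10L, alpha = 0))
  expect_error(test_config(10L, 10L, alpha = 1))
})

test_that("p-value, critical value and power follow their definitions", {
  s <- ddlocal:::summarize_lrt(LR0 = 5.5, LR_null = as.numeric(1:19),
                               LR_alt = c(10, 19, 19.5, 25), alpha = 0.05)
  expect_equal(s$R_CR, 14)                      # 6..19 exceed 5.5
  expect_equal(s$p_value, 15 / 20)
  expect_equal(s$LR_alpha, 19)                  # ceiling(0.95 * 20) = 19th
  expect_equal(s$R_DD, 2)                       # 19.5 and 25 exceed 19
  expect_equal(s$power, 2 / 5)

  # ties with LR0 are non-exceedances
  tied <- ddlocal:::summarize_lrt(5, as.numeric(1:19), numeric(0), 0.05)
  expect_equal(tied$R_CR, 14)
  expect_true(is.na(tied$power))

  # LR0 above every null statistic: the p-value floors at 1/(X_CR + 1)
  top <- ddlocal:::summarize_lrt(100, as.numeric(1:19), numeric(0), 0.05)
  expect_equal(top$p_value, 1 / 20)

  # order-statistic index is clipped to the sample size
  clip <- ddlocal:::summarize_lrt(1, c(2, 3), numeric(0), alpha = 0.01)
  expect_equal(clip$LR_alpha, 3)

  # ties with LR_alpha are non-exceedances in the power count too
  pow <- ddlocal:::summarize_lrt(0, as.numeric(1:19), c(19, 19, 20), 0.05)
  expect_equal(pow$R_DD, 1)
  expect_equal(pow$power, 1 / 4)
})

test_that("the LR statistic is non-negative and validates its inputs", {
  log <- simulate_cr(0.3, 0.05, 10, seed = 80L)
  bt <- branching_times(build_extant_tree(log))
  fc <- fit_cr(bt)
  fd <- fit_dd(bt, cr_fit = fc)
  lr <- lr_statistic(fc, fd)
  expect_gte(as.numeric(lr), 0)
  expect_error(lr_statistic(fd, fc), "CR fit and a DD fit")

  other <- branching_times(build_extant_tree(simulate_cr(0.3, 0.05, 10,
                                                         seed = 81L)))
  fd2 <- fit_dd(other)
  expect_error(lr_statistic(fc, fd2), "same data")

  # a finite-precision negative difference collapses to a flagged zero
  fake_cr <- ddlocal:::new_dd_fit("CR", c(lam0 = 1, mu = 0), -10, TRUE, 1L,
                                  NULL, bt)
  fake_dd <- ddlocal:::new_dd_fit("DD", c(lam0 = 1, mu = 0, kprime = 50),
                                  -10.000001, TRUE, 1L, NULL, bt)
  lr0 <- lr_statistic(fake_cr, fake_dd)
  expect_identical(as.numeric(lr0), 0)
  expect_true(attr(lr0, "flagged"))
})

test_that("the decision rule rejects on the boundary", {
  mk <- function(p) structure(list(p_value = p, alpha = 0.05),
                              class = "dd_lrt")
  expect_identical(decision(mk(0.049)), "reject CR")
  expect_identical(decision(mk(0.05)), "reject CR")
  expect_identical(decision(mk(0.051)), "retain CR")
  expect_identical(decision(mk(0.2), alpha = 0.25), "reject CR")
})

test_that("the bootstrap test is reproducible and keeps its denominators", {
  log <- simulate_cr(0.25, 0, 10, seed = 82L)
  bt <- branching_times(build_extant_tree(log))
  cfg <- test_config(X_CR = 3L, X_DD = 2L, alpha = 0.05, seed = 17L)
  r1 <- bootstrap_lrt(bt, cfg)
  r2 <- bootstrap_lrt(bt, cfg)
  expect_identical(r1$LR_null, r2$LR_null)
  expect_identical(r1$LR_alt, r2$LR_alt)
  expect_identical(r1$p_value, r2$p_value)

  expect_length(r1$LR_null, 3)
  expect_length(r1$LR_alt, 2)
  expect_true(all(r1$LR_null >= 0))
  expect_equal(r1$p_value, (sum(r1$LR_null > r1$LR0) + 1) / 4)
  expect_true(r1$power %in% ((0:2) / 3))
  expect_s3_class(r1$fit_cr, "dd_fit")
  expect_output(print(r1), "p-value")

  row <- lrt_summary_row(r1)
  expect_equal(nrow(row), 1)
  expect_equal(row$LR0, r1$LR0)
  expect_equal(row$p_value, r1$p_value)

  # X_DD = 0 skips the power phase
  r0 <- bootstrap_lrt(bt, test_config(X_CR = 2L, X_DD = 0L, seed = 18L))
  expect_length(r0$LR_alt, 0)
  expect_true(is.na(r0$power))
})
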