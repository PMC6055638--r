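test_that("the constant-rates likelihood matches the pure-birth closed form", {
  for (lam in c(0.2, 0.45)) {
    for (s in 1:3) {
      log <- simulate_cr(lam, 0, 10, seed = 300L + s)
      bt <- branching_times(build_extant_tree(log))
      expect_lt(abs(cr_loglik(bt, lam, 0) -
                      yule_loglik(bt$times, lam, bt$crown_age)), 1e-8)
    }
  }
})

test_that("the constant-rates likelihood is continuous at the critical case", {
  bt <- as_branching_times(c(0, 1.2, 3.7, 6.1), 10)
  ll_crit <- cr_loglik(bt, 0.3, 0.3)
  expect_true(is.finite(ll_crit))
  expect_lt(abs(ll_crit - cr_loglik(bt, 0.3, 0.3 - 1e-9)), 1e-5)
  expect_error(cr_loglik(bt, 0, 0.1), "lam")
  expect_error(cr_loglik(bt, 0.3, -0.1), "mu")
})

test_that("more tips than the ecological limit allows is impossible", {
  bt <- as_branching_times(seq(0, 12, length.out = 24), 15)  # 25 tips
  p <- nonspatial_params(lam0 = 0.8, mu = 0.1, kprime = 20, crown_age = 15)
  expect_identical(dd_loglik(bt, p), -Inf)
  # 21 tips at K' = 20.5 is the boundary case that is still possible
  bt21 <- as_branching_times(seq(0, 12, length.out = 20), 15)
  p2 <- nonspatial_params(lam0 = 0.8, mu = 0.1, kprime = 20.5,
                          crown_age = 15)
  expect_true(is.finite(dd_loglik(bt21, p2)))
})

test_that("the DD likelihood nests the CR likelihood at a huge ecological limit", {
  for (s in 1:2) {
    log <- simulate_cr(0.25, 0.1, 10, seed = 400L + s)
    bt <- branching_times(build_extant_tree(log))
    p <- nonspatial_params(lam0 = 0.25, mu = 0.1, kprime = 1e6,
                           crown_age = 10)
    expect_lt(abs(dd_loglik(bt, p) - cr_loglik(bt, 0.25, 0.1)), 1e-4)
  }
})

test_that("the C++ master-equation kernel agrees with the reference recursion", {
  log <- simulate_nonspatial_dd(
    nonspatial_params(lam0 = 0.7, mu = 0.25, kprime = 30, crown_age = 10),
    seed = 55L)
  bt <- branching_times(build_extant_tree(log))
  for (par in list(c(0.7, 0.25, 30), c(0.5, 0.05, 40), c(0.9, 0.4, 25))) {
    cap <- floor(par[3]) + 1
    a <- ddlocal:::dd_loglik_pass(bt, par[1], par[2], par[3], cap)
    b <- ddlocal:::dd_loglik_pass_ref(bt, par[1], par[2], par[3], cap)
    expect_lt(abs(a$loglik - b$loglik), 1e-10)
    expect_lt(abs(a$top_mass - b$top_mass), 1e-12)
  }
})

test_that("likelihood input validation catches mismatched crown ages", {
  bt <- as_branching_times(c(0, 2), 10)
  p <- nonspatial_params(lam0 = 0.5, mu = 0.1, kprime = 20, crown_age = 15)
  expect_error(dd_loglik(bt, p), "crown_age")
})

test_that("crown conditioning behaves as probability theory requires", {
  # no extinction: survival is certain
  expect_identical(
    crown_conditioning_dd(nonspatial_params(0.8, 0, 20, 15)), 1)
  # probabilities in (0, 1], decreasing in the extinction rate
  ps <- vapply(c(0.1, 0.3, 0.5), function(mu)
    crown_conditioning_dd(nonspatial_params(0.8, mu, 20, 15)), 0)
  expect_true(all(ps > 0 & ps <= 1))
  expect_true(all(diff(ps) < 0))
  # at an ecological limit far beyond any reachable diversity the
  # constant-rates closed form (1 - E)^2 is recovered; rates are chosen so
  # the residual finite-limit effect is orders of magnitude below the
  # tolerance
  p <- crown_conditioning_dd(nonspatial_params(0.15, 0.05, 1e6, 10))
  expect_lt(abs(p - (1 - cr_extinction_prob(10, 0.15, 0.05))^2), 1e-6)
})

test_that("conditioning divides the joint density as documented", {
  log <- simulate_nonspatial_dd(
    nonspatial_params(lam0 = 0.7, mu = 0.2, kprime = 25, crown_age = 10),
    seed = 66L)
  bt <- branching_times(build_extant_tree(log))
  p <- nonspatial_params(lam0 = 0.7, mu = 0.2, kprime = 25, crown_age = 10)
  ll_none <- dd_loglik(bt, p, conditioning = "none")
  ll_crown <- dd_loglik(bt, p)
  expect_equal(ll_crown,
               ll_none - ddlocal:::cond_logprob(0.7, 0.2, 25, 10),
               tolerance = 1e-12)
  expect_gt(ll_crown, ll_none)    # dividing by a probability < 1
})

test_that("integrating the likelihood over the simplex recovers tip-count probabilities", {
  # With no extinction the conditioned density of the ordered branching
  # times integrates, over 0 < t3 < t4 < T, to the probability of observing
  # exactly 4 tips.  Compare that quadrature against the simulated
  # tip-count frequency for two parameter sets.
  gl <- gauss_legendre(24)
  quad_p4 <- function(p) {
    T <- p$crown_age
    t4 <- T / 2 * (gl$x + 1)            # outer node times on (0, T)
    total <- 0
    for (j in seq_along(t4)) {
      t3 <- t4[j] / 2 * (gl$x + 1)      # inner times on (0, t4)
      f <- vapply(t3, function(t) {
        exp(dd_loglik(as_branching_times(c(0, t, t4[j]), T), p))
      }, 0)
      total <- total + gl$w[j] * (T / 2) * sum(gl$w * (t4[j] / 2) * f)
    }
    total
  }
  nsim <- 3000L
  for (p in list(nonspatial_params(0.5, 0, 8, crown_age = 6),
                 nonspatial_params(0.3, 0, 40, crown_age = 6))) {
    tips <- vapply(seq_len(nsim), function(i) {
      length(extant_ids(simulate_nonspatial_dd(p, seed = derive_seed(7L, i))))
    }, 0L)
    phat <- mean(tips == 4L)
    pq <- quad_p4(p)
    se <- sqrt(phat * (1 - phat) / nsim)
    expect_lt(abs(phat - pq), 3 * se)
  }
})
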