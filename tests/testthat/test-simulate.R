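test_that("derive_seed is deterministic, in range and well spread", {
  expect_identical(derive_seed(42L, 7L), derive_seed(42L, 7L))
  s <- vapply(1:1000, function(r) derive_seed(123456L, r), integer(1))
  expect_true(all(s >= 0))
  expect_true(all(s < 2^31))
  expect_length(unique(s), 1000L)
  expect_false(derive_seed(1L, 1L) == derive_seed(2L, 1L))
})

test_that("with_seed restores the caller's random-number state", {
  set.seed(99)
  u1 <- runif(1)
  set.seed(99)
  invisible(ddlocal:::with_seed(7L, function() runif(10)))
  expect_identical(runif(1), u1)
})

test_that("next_event draws waiting times and classes from total rates", {
  expect_null(next_event(c(0, 0, 0)))
  set.seed(1)
  ev <- next_event(c(1, 2, 3))
  expect_true(ev$dt > 0)
  expect_true(ev$class %in% 1:3)
  set.seed(1)
  expect_identical(next_event(c(1, 2, 3)), ev)
})

test_that("spatial simulation is reproducible and respects the model's bounds", {
  p <- spatial_params(lam1_0 = 0.8, lam2_0 = 0.8, lam12_0 = 0.2, mu = 0.1,
                      M0 = 0.5, kprime1 = 5, kprime2 = 5, crown_age = 8)
  log1 <- simulate_spatial(p, seed = 42L)
  log2 <- simulate_spatial(p, seed = 42L)
  expect_identical(log1$events, log2$events)
  expect_identical(log1$species, log2$species)

  expect_s3_class(log1, "event_log")
  expect_true(all(log1$events$event_class %in% EVENT_CLASSES))
  expect_true(all(diff(log1$events$time) >= 0))
  expect_true(all(log1$events$time < p$crown_age))

  # with integer K' = 5 the local speciation and immigration rates both
  # vanish at richness 5, so neither location can ever exceed it
  for (s in 1:20) {
    log <- simulate_spatial(p, seed = 1000L + s)
    expect_lte(max(stt(log, "local-1")$count), 5)
    expect_lte(max(stt(log, "local-2")$count), 5)
  }
})

test_that("returned histories satisfy crown-survival conditioning", {
  p <- spatial_params(mu = 0.4, M0 = 0.5, kprime1 = 10, kprime2 = 10,
                      crown_age = 6)
  for (s in 1:10) {
    log <- simulate_spatial(p, seed = s)
    roots <- ddlocal:::root_ancestor(log$species)
    surviving_roots <- unique(roots[extant_ids(log)])
    expect_setequal(surviving_roots,
                    log$species$species_id[log$species$parent_id == 0L])
  }
  # nonspatial engines count their rejected attempts
  log <- simulate_nonspatial_dd(
    nonspatial_params(lam0 = 0.5, mu = 0.45, kprime = 10, crown_age = 10),
    seed = 3L)
  expect_gte(log$n_rejected, 0L)
  expect_gte(length(extant_ids(log)), 2L)
})

test_that("nonspatial and constant-rates simulators are reproducible", {
  p <- nonspatial_params(lam0 = 0.6, mu = 0.2, kprime = 15, crown_age = 10)
  a <- simulate_nonspatial_dd(p, seed = 11L)
  b <- simulate_nonspatial_dd(p, seed = 11L)
  expect_identical(a$events, b$events)
  expect_true(all(a$events$event_class %in% c("speciation", "extinction")))

  x <- simulate_cr(0.3, 0.1, 10, seed = 5L)
  y <- simulate_cr(0.3, 0.1, 10, seed = 5L)
  expect_identical(x$species, y$species)
  expect_identical(x$model, "cr")
})

test_that("replaying the event stream reproduces the species registry", {
  p <- spatial_params(mu = 0.2, M0 = 1, kprime1 = 10, kprime2 = 10,
                      crown_age = 8)
  log <- simulate_spatial(p, seed = 77L)
  rep <- replay_event_log(log)
  expect_true(isTRUE(all.equal(rep, log$species[names(rep)],
                               check.attributes = FALSE)))

  log2 <- simulate_nonspatial_dd(
    nonspatial_params(lam0 = 0.6, mu = 0.2, kprime = 15, crown_age = 10),
    seed = 8L)
  rep2 <- replay_event_log(log2)
  expect_true(isTRUE(all.equal(rep2, log2$species[names(rep2)],
                               check.attributes = FALSE)))
})

test_that("event logs round-trip through CSV", {
  log <- simulate_nonspatial_dd(
    nonspatial_params(lam0 = 0.6, mu = 0.1, kprime = 10, crown_age = 8),
    seed = 2L)
  prefix <- file.path(tempdir(), "evlog")
  files <- write_event_log(log, prefix)
  expect_true(all(file.exists(files)))
  ev <- read.csv(files[1])
  sp <- read.csv(files[2])
  expect_equal(ev$time, log$events$time)
  expect_equal(ev$event_class, log$events$event_class)
  expect_equal(sp$birth_time, log$species$birth_time)
  unlink(files)
})
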