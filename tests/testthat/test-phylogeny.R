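make_fixture_log <- function() {
  species <- data.frame(
    species_id = 1:4,
    parent_id = c(0L, 0L, 1L, 2L),
    birth_time = c(0, 0, 3, 5),
    death_time = c(NA, NA, 9, NA),
    origin = c("crown", "crown", "speciation", "speciation"),
    stringsAsFactors = FALSE)
  events <- data.frame(
    time = c(3, 5, 9),
    event_class = c("speciation", "speciation", "extinction"),
    actor_id = c(1L, 2L, 3L),
    new_id = c(3L, 4L, NA_integer_),
    stringsAsFactors = FALSE)
  manual_log(species, events, crown_age = 10)
}

test_that("extant-tree reconstruction prunes extinct lineages correctly", {
  log <- make_fixture_log()
  tree <- build_extant_tree(log)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, c("s1", "s2", "s4"))
  bt <- branching_times(tree)
  expect_equal(bt$n_tips, 3L)
  expect_equal(bt$crown_age, 10)
  expect_equal(bt$times, c(0, 5), tolerance = 1e-12)
  # budding convention: s4 branches off s2's lineage, not s1's
  pair <- ape::extract.clade(
    tree, ape::getMRCA(tree, c("s2", "s4")))$tip.label
  expect_setequal(pair, c("s2", "s4"))
})

test_that("a history whose crown lineage died violates conditioning", {
  species <- data.frame(
    species_id = 1:2, parent_id = c(0L, 0L), birth_time = c(0, 0),
    death_time = c(4, NA), origin = c("crown", "crown"),
    stringsAsFactors = FALSE)
  events <- data.frame(time = 4, event_class = "extinction",
                       actor_id = 1L, new_id = NA_integer_,
                       stringsAsFactors = FALSE)
  expect_error(build_extant_tree(manual_log(species, events, 10)),
               "conditioning")
})

test_that("branching-time extraction validates its input", {
  expect_error(branching_times(ape::read.tree(text = "(a:1,b:2);")),
               "ultrametric")
  expect_error(as_branching_times(c(0, 2, 2), 10), "increasing")
  expect_error(as_branching_times(c(0, 11), 10), "crown_age")
  expect_error(as_branching_times(c(1, 2), 10), "crown")
  bt <- as_branching_times(c(0, 1.5, 4), 10)
  expect_equal(bt$n_tips, 4L)
})

test_that("Newick output round-trips through text and file", {
  log <- simulate_nonspatial_dd(
    nonspatial_params(lam0 = 0.6, mu = 0.2, kprime = 15, crown_age = 10),
    seed = 21L)
  tree <- build_extant_tree(log)
  bt <- branching_times(tree)

  txt <- write_newick(tree)
  bt2 <- branching_times(read_newick(text = txt), crown_age = 10)
  expect_equal(bt2$times, bt$times, tolerance = 1e-8)

  f <- file.path(tempdir(), "tree.nwk")
  write_newick(tree, f)
  bt3 <- branching_times(read_newick(file = f), crown_age = 10)
  expect_equal(bt3$times, bt$times, tolerance = 1e-8)
  # a file path in the first argument is recognized as such
  bt4 <- branching_times(read_newick(f), crown_age = 10)
  expect_equal(bt4$times, bt$times, tolerance = 1e-8)
  unlink(f)
})

test_that("species-through-time curves count the fixture history correctly", {
  log <- make_fixture_log()
  s <- stt(log, "global")
  expect_s3_class(s, "step_series")
  expect_equal(s$time, c(0, 3, 5, 9))
  expect_equal(s$count, c(2, 3, 4, 3))
  expect_equal(eval_step(s, 10), 3)
  expect_error(stt(log, "local-1"), "flavor")
})

test_that("spatial richness curves satisfy the (a, b, c) bookkeeping identities", {
  p <- spatial_params(mu = 0.2, M0 = 1, kprime1 = 10, kprime2 = 10,
                      crown_age = 8)
  log <- simulate_spatial(p, seed = 31L)
  s1 <- stt(log, "local-1")
  s2 <- stt(log, "local-2")
  sg <- stt(log, "global")
  expect_equal(s1$count[1], 1)        # one crown endemic per location
  expect_equal(s2$count[1], 1)
  expect_equal(sg$count[1], 2)
  # n1 + n2 - widespread = global, so n1 + n2 >= global everywhere
  expect_true(all(s1$count + s2$count >= sg$count))
  expect_true(all(s1$count + s2$count - sg$count >= 0))
  # present-day global richness equals the extant-species count
  expect_equal(eval_step(sg, p$crown_age), length(extant_ids(log)))
})

test_that("step evaluation is right-continuous", {
  s <- structure(list(time = c(0, 1, 2), count = c(2, 3, 2),
                      flavor = "global", crown_age = 3),
                 class = "step_series")
  expect_equal(eval_step(s, c(0, 0.5, 1, 1.5, 2, 3)), c(2, 2, 3, 3, 2, 2))
  expect_equal(eval_step(s, -1), 2)    # before the first breakpoint
})

test_that("lineage-through-time curves climb from 2 to the tip count", {
  log <- make_fixture_log()
  tree <- build_extant_tree(log)
  l <- ltt(tree)
  expect_equal(l$time, c(0, 5))
  expect_equal(l$count, c(2L, 3L))
  expect_equal(eval_step(l, 10), 3L)
})

test_that("quantile envelopes are ordered and on the requested grid", {
  p <- nonspatial_params(lam0 = 0.6, mu = 0.1, kprime = 10, crown_age = 8)
  series <- lapply(1:25, function(i)
    stt(simulate_nonspatial_dd(p, seed = 100L + i), "global"))
  env <- quantile_envelope(series)
  expect_equal(nrow(env), 201L)
  expect_named(env, c("time", "min", "q025", "q25", "q50", "q75", "q975",
                      "max"))
  qcols <- as.matrix(env[, -1])
  expect_true(all(diff(t(qcols)) >= 0))  # min <= q025 <= ... <= max rowwise
  env2 <- quantile_envelope(series, grid = c(0, 4, 8))
  expect_equal(env2$time, c(0, 4, 8))
  expect_equal(env2$min[1], 2)           # every history starts with 2
  expect_error(quantile_envelope(list()), "non-empty")
})
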