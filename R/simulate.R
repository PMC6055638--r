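#' Deterministic child seed for replicate r of a batch
#'
#' Batches (bootstrap samples, scenario grids) give replicate `r` the seed
#' `derive_seed(master, r)`, so results are independent of execution order
#' and worker count.  A simple 32-bit linear congruential mix keeps the
#' result a valid R integer seed.
#'
#' @param master Master seed (integer).
#' @param r Replicate index (integer >= 0).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, r) {
  m <- 2147483629
  as.integer((as.numeric(master) %% m * 48271 + as.numeric(r) * 16807 +
                r + 1) %% m)
}

# Run fn() with the RNG seeded from `seed` (when non-NULL), restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Draw the next Gillespie event
#'
#' One step of the stochastic simulation algorithm: the waiting time is
#' exponential with the sum of all class rates as parameter, and the event
#' class is chosen by a single uniform draw against the cumulative rate
#' vector (in the fixed order of the `rates` argument).  This is the exact
#' step function used inside the simulators; it is exported so that the
#' event-frequency and waiting-time distributions can be examined directly
#' for a frozen community state.
#'
#' @param rates Numeric vector of non-negative total class rates.
#' @return A list with `dt` (waiting time) and `class` (index into `rates`),
#'   or `NULL` if all rates are zero (frozen state).
#' @export
next_event <- function(rates) {
  tot <- sum(rates)
  if (tot <= 0) return(NULL)
  dt <- stats::rexp(1, tot)
  u <- stats::runif(1) * tot
  cls <- findInterval(u, cumsum(rates), left.open = TRUE) + 1L
  if (cls > length(rates)) cls <- length(rates)  # u == tot edge
  list(dt = dt, class = cls)
}

# uniform draw over a sorted eligible id vector (second uniform of the step)
draw_actor <- function(pool) {
  n <- length(pool)
  if (n == 1L) return(pool[1L])
  pool[min(n, 1L + floor(stats::runif(1) * n))]
}

new_event_log <- function(model, params, seed, events, species, ranges,
                          n_rejected, crown_age) {
  structure(list(model = model, params = params, seed = seed,
                 events = events, species = species, ranges = ranges,
                 n_rejected = n_rejected, crown_age = crown_age),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  extant <- sum(is.na(x$species$death_time))
  cat(sprintf(
    "Event log (%s model): %d species ever (%d extant), %d events, crown age %g\n",
    x$model, nrow(x$species), extant, nrow(x$events), x$crown_age))
  if (x$n_rejected > 0)
    cat(sprintf("  %d histories rejected by crown-survival conditioning\n",
                x$n_rejected))
  invisible(x)
}

#' Simulate the two-location diversity-dependent model
#'
#' Gillespie simulation of the spatial model: two crown ancestors, one
#' endemic to each location, diversify for `crown_age` time units under
#' diversity-dependent sympatric speciation and dispersal, allopatric
#' speciation of widespread species, constant local extinction and range
#' contraction.  Whole histories are rejected and restarted (continuing the
#' random-number stream) until both crown lineages have extant descendants
#' at the present.
#'
#' Daughters of sympatric speciation are endemic to the location where the
#' event happened; at allopatric speciation the parent persists as the
#' location-1 endemic and the daughter is the location-2 endemic (a labelling
#' convention; topology and branching times are unaffected).
#'
#' @param params A [spatial_params()].
#' @param seed Integer seed (optional; when given the result is a pure
#'   function of `(params, seed)` and the caller's RNG state is untouched).
#' @param max_retries Retry budget for the crown-survival conditioning;
#'   exceeding it signals near-certain clade extinction and is an error.
#' @return An object of class `event_log` holding the species registry, the
#'   timestamped event history, the range history and the rejection count.
#' @export
simulate_spatial <- function(params, seed = NULL, max_retries = 100000L) {
  stopifnot(inherits(params, "spatial_params"))
  with_seed(seed, function() {
    n_rejected <- 0L
    repeat {
      log <- sim_spatial_once(params)
      if (!is.null(log)) {
        log$n_rejected <- n_rejected
        log$seed <- seed
        return(log)
      }
      n_rejected <- n_rejected + 1L
      if (n_rejected >= max_retries)
        stop("simulation-infeasible: crown-survival retry budget exhausted")
    }
  })
}

# One attempted spatial history; NULL if crown-survival conditioning fails.
# Species ranges: 1 = endemic location 1, 2 = endemic location 2,
# 3 = widespread, 0 = dead.
sim_spatial_once <- function(params) {
  T <- params$crown_age
  parent <- c(0L, 0L); birth <- c(0, 0); death <- c(NA_real_, NA_real_)
  origin <- c("crown", "crown"); state <- c(1L, 2L); root <- c(1L, 2L)
  ev_time <- numeric(0); ev_class <- character(0)
  ev_actor <- integer(0); ev_new <- integer(0)
  rg_id <- c(1L, 2L); rg_time <- c(0, 0); rg_range <- c(1L, 2L)
  t <- 0

  add_range <- function(id, tm, rng) {
    rg_id[length(rg_id) + 1L] <<- id
    rg_time[length(rg_time) + 1L] <<- tm
    rg_range[length(rg_range) + 1L] <<- rng
  }

  repeat {
    a <- sum(state == 1L); b <- sum(state == 2L); c <- sum(state == 3L)
    rates <- total_event_rates(community_state(a, b, c), params)
    step <- next_event(rates)
    if (is.null(step)) break                       # frozen, run out the clock
    if (t + step$dt > T) break
    t <- t + step$dt
    cls <- step$class
    pool <- switch(cls,
                   which(state == 1L | state == 3L),  # sympatric-1
                   which(state == 2L | state == 3L),  # sympatric-2
                   which(state == 3L),                # allopatric
                   which(state == 1L),                # extinction endemic 1
                   which(state == 2L),                # extinction endemic 2
                   which(state == 3L),                # contraction lose 1
                   which(state == 3L),                # contraction lose 2
                   which(state == 1L),                # dispersal 1 -> 2
                   which(state == 2L))                # dispersal 2 -> 1
    actor <- draw_actor(pool)
    new_id <- NA_integer_
    if (cls <= 3L) {                                 # speciation: new species
      new_id <- length(parent) + 1L
      parent[new_id] <- actor; birth[new_id] <- t
      death[new_id] <- NA_real_; root[new_id] <- root[actor]
      if (cls == 1L) {
        state[new_id] <- 1L; origin[new_id] <- "sympatric-1"
        add_range(new_id, t, 1L)
      } else if (cls == 2L) {
        state[new_id] <- 2L; origin[new_id] <- "sympatric-2"
        add_range(new_id, t, 2L)
      } else {
        state[new_id] <- 2L; origin[new_id] <- "allopatric"
        add_range(new_id, t, 2L)
        state[actor] <- 1L; add_range(actor, t, 1L)  # parent keeps location 1
      }
    } else if (cls <= 5L) {                          # endemic local extinction
      state[actor] <- 0L; death[actor] <- t
    } else if (cls == 6L) {                          # widespread loses loc 1
      state[actor] <- 2L; add_range(actor, t, 2L)
    } else if (cls == 7L) {                          # widespread loses loc 2
      state[actor] <- 1L; add_range(actor, t, 1L)
    } else {                                         # dispersal
      state[actor] <- 3L; add_range(actor, t, 3L)
    }
    ev_time[length(ev_time) + 1L] <- t
    ev_class[length(ev_class) + 1L] <- EVENT_CLASSES[cls]
    ev_actor[length(ev_actor) + 1L] <- actor
    ev_new[length(ev_new) + 1L] <- new_id
  }

  extant <- state != 0L
  if (!any(extant & root == 1L) || !any(extant & root == 2L)) return(NULL)
  species <- data.frame(species_id = seq_along(parent), parent_id = parent,
                        birth_time = birth, death_time = death,
                        origin = origin, stringsAsFactors = FALSE)
  events <- data.frame(time = ev_time, event_class = ev_class,
                       actor_id = ev_actor, new_id = ev_new,
                       stringsAsFactors = FALSE)
  ranges <- data.frame(species_id = rg_id, time = rg_time,
                       range = c("loc1", "loc2", "widespread")[rg_range],
                       stringsAsFactors = FALSE)
  new_event_log("spatial", params, NULL, events, species, ranges, 0L, T)
}

#' Simulate the nonspatial diversity-dependent model
#'
#' Single-community diversity-dependent birth-death process: per-lineage
#' speciation \eqn{\max(0, \lambda_0(1 - n/K'))}, constant per-lineage
#' extinction \eqn{\mu}, two crown lineages at time 0, conditioned on both
#' leaving extant descendants (whole-history rejection).
#'
#' @param params A [nonspatial_params()].
#' @inheritParams simulate_spatial
#' @return An `event_log`.
#' @export
simulate_nonspatial_dd <- function(params, seed = NULL,
                                   max_retries = 100000L) {
  stopifnot(inherits(params, "nonspatial_params"))
  with_seed(seed, function() {
    sim_single_conditioned(params$lam0, params$mu, params$kprime,
                           params$crown_age, n0 = 2L,
                           max_retries = max_retries,
                           model = "dd", params = params)
  })
}

#' Simulate the constant-rates birth-death model
#'
#' Constant per-lineage speciation and extinction rates, two crown lineages,
#' crown-survival conditioning by rejection.
#'
#' @param lam Speciation rate (per lineage per time unit).
#' @param mu Extinction rate.
#' @param crown_age Simulated time span.
#' @inheritParams simulate_spatial
#' @return An `event_log`.
#' @export
simulate_cr <- function(lam, mu, crown_age, seed = NULL,
                        max_retries = 100000L) {
  stopifnot(lam >= 0, mu >= 0, crown_age > 0)
  p <- structure(list(lam0 = lam, mu = mu, kprime = Inf,
                      crown_age = crown_age), class = "nonspatial_params")
  with_seed(seed, function() {
    sim_single_conditioned(lam, mu, Inf, crown_age, n0 = 2L,
                           max_retries = max_retries,
                           model = "cr", params = p)
  })
}

# Single-location engine with crown-survival conditioning.  n0 = 1 runs a
# single founding lineage conditioned on its own survival (used for
# comparisons with one location of the spatial model at M0 = 0).
sim_single_conditioned <- function(lam0, mu, kprime, T, n0, max_retries,
                                   model, params) {
  n_rejected <- 0L
  repeat {
    log <- sim_single_once(lam0, mu, kprime, T, n0, model, params)
    if (!is.null(log)) {
      log$n_rejected <- n_rejected
      return(log)
    }
    n_rejected <- n_rejected + 1L
    if (n_rejected >= max_retries)
      stop("simulation-infeasible: crown-survival retry budget exhausted")
  }
}

sim_single_once <- function(lam0, mu, kprime, T, n0, model, params) {
  parent <- integer(n0); birth <- numeric(n0); death <- rep(NA_real_, n0)
  origin <- rep("crown", n0); alive <- rep(TRUE, n0); root <- seq_len(n0)
  ev_time <- numeric(0); ev_class <- character(0)
  ev_actor <- integer(0); ev_new <- integer(0)
  t <- 0
  repeat {
    n <- sum(alive)
    lam_n <- if (is.finite(kprime)) max(0, lam0 * (1 - n / kprime)) else lam0
    rates <- c(speciation = n * lam_n, extinction = n * mu)
    step <- next_event(rates)
    if (is.null(step)) break
    if (t + step$dt > T) break
    t <- t + step$dt
    actor <- draw_actor(which(alive))
    new_id <- NA_integer_
    if (step$class == 1L) {
      new_id <- length(parent) + 1L
      parent[new_id] <- actor; birth[new_id] <- t
      death[new_id] <- NA_real_; origin[new_id] <- "speciation"
      alive[new_id] <- TRUE; root[new_id] <- root[actor]
    } else {
      alive[actor] <- FALSE; death[actor] <- t
    }
    ev_time[length(ev_time) + 1L] <- t
    ev_class[length(ev_class) + 1L] <-
      c("speciation", "extinction")[step$class]
    ev_actor[length(ev_actor) + 1L] <- actor
    ev_new[length(ev_new) + 1L] <- new_id
  }
  for (rt in seq_len(n0)) if (!any(alive & root == rt)) return(NULL)
  species <- data.frame(species_id = seq_along(parent), parent_id = parent,
                        birth_time = birth, death_time = death,
                        origin = origin, stringsAsFactors = FALSE)
  events <- data.frame(time = ev_time, event_class = ev_class,
                       actor_id = ev_actor, new_id = ev_new,
                       stringsAsFactors = FALSE)
  new_event_log(model, params, NULL, events, species, NULL, 0L, T)
}

#' Replay an event log from its initial state
#'
#' Re-applies the recorded events to the initial community and rebuilds the
#' species registry.  Used to verify that an `event_log` is internally
#' consistent: the replayed registry must reproduce the stored one exactly.
#'
#' @param log An `event_log`.
#' @return A `data.frame` in the same layout as `log$species`.
#' @export
replay_event_log <- function(log) {
  stopifnot(inherits(log, "event_log"))
  spatial <- identical(log$model, "spatial")
  n0 <- if (spatial) 2L else sum(log$species$parent_id == 0L)
  parent <- integer(n0); birth <- numeric(n0)
  death <- rep(NA_real_, n0); origin <- rep("crown", n0)
  ev <- log$events
  for (i in seq_len(nrow(ev))) {
    cls <- ev$event_class[i]
    if (cls %in% c("sympatric-1", "sympatric-2", "allopatric", "speciation")) {
      id <- ev$new_id[i]
      parent[id] <- ev$actor_id[i]; birth[id] <- ev$time[i]
      death[id] <- NA_real_
      origin[id] <- if (cls == "speciation") "speciation" else cls
    } else if (cls %in% c("extinction-endemic-1", "extinction-endemic-2",
                          "extinction")) {
      death[ev$actor_id[i]] <- ev$time[i]
    }
    # dispersal / contraction alter ranges only, not the registry
  }
  data.frame(species_id = seq_along(parent), parent_id = parent,
             birth_time = birth, death_time = death, origin = origin,
             stringsAsFactors = FALSE)
}

#' Write an event log to CSV files
#'
#' Writes `<prefix>.events.csv` (time, event_class, actor_id, new_id) and
#' `<prefix>.species.csv` (species_id, parent_id, birth_time, death_time,
#' origin).
#'
#' @param log An `event_log`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_event_log <- function(log, prefix) {
  stopifnot(inherits(log, "event_log"))
  fe <- paste0(prefix, ".events.csv")
  fs <- paste0(prefix, ".species.csv")
  utils::write.csv(log$events, fe, row.names = FALSE)
  utils::write.csv(log$species, fs, row.names = FALSE)
  invisible(c(fe, fs))
}
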