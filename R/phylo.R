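#' Reconstruct the extant-species phylogeny from an event history
#'
#' Builds the complete (budding) tree implied by the species registry —
#' every daughter attaches to its parent's lineage at its birth time — and
#' prunes all lineages without extant descendants, suppressing the resulting
#' unary nodes.  The result is the rooted, binary, ultrametric tree of the
#' extant species, with the crown node at time 0 and all tips at
#' `crown_age`.
#'
#' @param log An `event_log` satisfying crown-survival conditioning.
#' @return An [ape::phylo] object with tip labels `s<id>` and an attribute
#'   `crown_age`.
#' @export
build_extant_tree <- function(log) {
  stopifnot(inherits(log, "event_log"))
  sp <- log$species
  T <- log$crown_age
  extant_ids <- sp$species_id[is.na(sp$death_time)]
  crown <- sp$species_id[sp$parent_id == 0L]
  desc_root <- root_ancestor(sp)
  if (!all(crown %in% desc_root[extant_ids]))
    stop("invalid input: event log violates crown-survival conditioning")

  txt <- full_newick(sp, T)
  tree <- ape::read.tree(text = txt)
  extinct_tips <- paste0("s", sp$species_id[!is.na(sp$death_time)])
  extinct_tips <- intersect(extinct_tips, tree$tip.label)
  if (length(extinct_tips) > 0)
    tree <- ape::drop.tip(tree, extinct_tips)
  attr(tree, "crown_age") <- T
  tree
}

# root ancestor (crown species id) of every species
root_ancestor <- function(sp) {
  root <- integer(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    p <- sp$parent_id[i]
    root[i] <- if (p == 0L) sp$species_id[i] else root[p]
  }
  root
}

# Newick of the complete tree (extinct species as tips ending at their death
# time).  Budding convention: species i's lineage spans [birth_i, end_i] and
# is subdivided at its daughters' birth times.
full_newick <- function(sp, T) {
  end_time <- ifelse(is.na(sp$death_time), T, sp$death_time)
  kids <- split(sp$species_id[sp$parent_id > 0L],
                factor(sp$parent_id[sp$parent_id > 0L],
                       levels = sp$species_id))
  births <- sp$birth_time
  rec <- function(i, t0) {
    d <- kids[[i]]
    d <- d[births[d] > t0]
    if (length(d) == 0L)
      return(sprintf("s%d:%.17g", i, end_time[i] - t0))
    j <- d[which.min(births[d])]
    t1 <- births[j]
    sprintf("(%s,%s):%.17g", rec(i, t1), rec(j, t1), t1 - t0)
  }
  crown <- sp$species_id[sp$parent_id == 0L]
  if (length(crown) != 2L)
    stop("expected exactly two crown lineages")
  # crown node at time 0; rec() already appends the (zero) root edge length
  paste0("(", rec(crown[1], 0), ",", rec(crown[2], 0), ");")
}

#' Ordered branching times of an ultrametric tree
#'
#' Extracts the internal-node times of an ultrametric phylogeny on the
#' crown-origin axis (crown node at time 0, present at `crown_age`), sorted
#' ascending.  These are the data to which the constant-rates and
#' diversity-dependent likelihoods apply.
#'
#' @param tree An ultrametric [ape::phylo] (tolerance `1e-6`), or an object
#'   already of class `branching_times` (returned unchanged).
#' @param crown_age Present-day age of the crown; defaults to the tree's
#'   `crown_age` attribute, or to the maximum node depth.
#' @return An object of class `branching_times`: list with `times`
#'   (ascending, `times[1] == 0`), `n_tips` and `crown_age`.
#' @export
branching_times <- function(tree, crown_age = NULL) {
  if (inherits(tree, "branching_times")) return(tree)
  stopifnot(inherits(tree, "phylo"))
  tip_depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (diff(range(tip_depths)) > 1e-6)
    stop("invalid input: tree is not ultrametric (tolerance 1e-6)")
  depth <- max(ape::node.depth.edgelength(tree))
  bt <- ape::branching.times(tree)      # time before present, per node
  if (is.null(crown_age)) {
    crown_age <- attr(tree, "crown_age")
    if (is.null(crown_age)) crown_age <- depth
  }
  times <- sort(crown_age - as.numeric(bt))
  times[which.min(abs(times))] <- 0     # crown node exactly at 0
  if (any(diff(times) <= 0))
    stop("invalid input: tied branching times")
  if (times[1] != 0 || any(times < 0) || any(times >= crown_age))
    stop("invalid input: branching times outside (0, crown_age)")
  as_branching_times(times, crown_age)
}

#' Construct a branching-times object from a numeric vector
#'
#' @param times Ascending internal-node times on the crown-origin axis,
#'   including 0 for the crown node (length = number of tips - 1).
#' @param crown_age Present-day age (> all times).
#' @return A `branching_times` object.
#' @export
as_branching_times <- function(times, crown_age) {
  times <- as.numeric(times)
  stopifnot(length(times) >= 1, crown_age > 0)
  if (times[1] != 0) stop("times must include 0 for the crown node")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times >= crown_age)) stop("times must be < crown_age")
  structure(list(times = times, n_tips = length(times) + 1L,
                 crown_age = crown_age),
            class = "branching_times")
}

#' @export
print.branching_times <- function(x, ...) {
  cat(sprintf("Branching times: %d tips, crown age %g\n", x$n_tips,
              x$crown_age))
  cat(" ", paste(signif(x$times, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Write a phylogeny as a Newick string
#'
#' Standard Newick with decimal branch lengths in crown-time units (12
#' significant digits), semicolon-terminated.
#'
#' @param tree An [ape::phylo].
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 12)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read a phylogeny from a Newick string or file
#'
#' @param text Newick string (semicolon-terminated), or the path of a file
#'   holding one (a string without parentheses that names an existing file
#'   is read as a file).
#' @param crown_age Optional crown age to attach; defaults to the tree's
#'   maximum root-to-tip depth.
#' @param file Optional path to read instead of `text`.
#' @return An [ape::phylo] with a `crown_age` attribute.
#' @export
read_newick <- function(text = NULL, crown_age = NULL, file = NULL) {
  if (is.null(file) && length(text) == 1 && is.character(text) &&
      !grepl("(", text, fixed = TRUE) && file.exists(text)) {
    file <- text
    text <- NULL
  }
  tree <- tryCatch({
    if (!is.null(file)) ape::read.tree(file = file)
    else ape::read.tree(text = text)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo") || is.null(tree$edge.length))
    stop("parse error: malformed Newick input")
  attr(tree, "crown_age") <-
    if (is.null(crown_age)) max(ape::node.depth.edgelength(tree))
    else crown_age
  tree
}

#' Species-through-time curve of an event history
#'
#' Counts the species present (per location or in the whole system) at every
#' moment of the simulated history, including species that later went
#' extinct.  The curve is a right-continuous step function with breakpoints
#' at the event times.
#'
#' @param log An `event_log`.
#' @param flavor One of `"local-1"`, `"local-2"` (spatial logs only) or
#'   `"global"`.
#' @return A `step_series`: list with `time`, `count`, `flavor`,
#'   `crown_age`.
#' @export
stt <- function(log, flavor = c("global", "local-1", "local-2")) {
  stopifnot(inherits(log, "event_log"))
  flavor <- match.arg(flavor)
  spatial <- identical(log$model, "spatial")
  if (!spatial && flavor != "global")
    stop("unknown flavor for a single-location log; use \"global\"")
  abc <- abc_trajectory(log)
  count <- switch(flavor,
                  "local-1" = abc$a + abc$c,
                  "local-2" = abc$b + abc$c,
                  "global"  = abc$a + abc$b + abc$c)
  structure(list(time = abc$time, count = count, flavor = flavor,
                 crown_age = log$crown_age),
            class = "step_series")
}

# (a, b, c) after every event; for single-location logs b = c = 0.
abc_trajectory <- function(log) {
  ev <- log$events
  n <- nrow(ev)
  spatial <- identical(log$model, "spatial")
  a <- numeric(n + 1); b <- numeric(n + 1); c <- numeric(n + 1)
  tm <- c(0, ev$time)
  a[1] <- if (spatial) 1 else sum(log$species$parent_id == 0L)
  b[1] <- if (spatial) 1 else 0
  c[1] <- 0
  if (n > 0) for (i in seq_len(n)) {
    a[i + 1] <- a[i]; b[i + 1] <- b[i]; c[i + 1] <- c[i]
    switch(ev$event_class[i],
           "sympatric-1" = { a[i + 1] <- a[i] + 1 },
           "sympatric-2" = { b[i + 1] <- b[i] + 1 },
           "allopatric" = { a[i + 1] <- a[i] + 1; b[i + 1] <- b[i] + 1
                            c[i + 1] <- c[i] - 1 },
           "extinction-endemic-1" = { a[i + 1] <- a[i] - 1 },
           "extinction-endemic-2" = { b[i + 1] <- b[i] - 1 },
           "contraction-lose-1" = { c[i + 1] <- c[i] - 1
                                    b[i + 1] <- b[i] + 1 },
           "contraction-lose-2" = { c[i + 1] <- c[i] - 1
                                    a[i + 1] <- a[i] + 1 },
           "dispersal-1to2" = { a[i + 1] <- a[i] - 1; c[i + 1] <- c[i] + 1 },
           "dispersal-2to1" = { b[i + 1] <- b[i] - 1; c[i + 1] <- c[i] + 1 },
           "speciation" = { a[i + 1] <- a[i] + 1 },
           "extinction" = { a[i + 1] <- a[i] - 1 },
           stop("unknown event class in log"))
  }
  list(time = tm, a = a, b = b, c = c)
}

#' Lineages-through-time curve of a reconstructed tree
#'
#' Counts the lineages of the extant-species tree through time: starts at 2
#' at the crown and increases by 1 at every branching time, ending at the
#' number of tips.
#'
#' @param tree An ultrametric [ape::phylo] or a `branching_times` object.
#' @return A `step_series` with flavor `"ltt"`.
#' @export
ltt <- function(tree) {
  bt <- branching_times(tree)
  structure(list(time = bt$times, count = seq(2L, bt$n_tips),
                 flavor = "ltt", crown_age = bt$crown_age),
            class = "step_series")
}

#' Evaluate a step series at given times
#'
#' Right-continuous evaluation: the value at `t` is the count after the last
#' breakpoint at or before `t`.
#'
#' @param series A `step_series`.
#' @param t Numeric times.
#' @return Numeric counts.
#' @export
eval_step <- function(series, t) {
  stopifnot(inherits(series, "step_series"))
  idx <- findInterval(t, series$time)
  idx[idx < 1L] <- 1L
  series$count[idx]
}

#' @export
print.step_series <- function(x, ...) {
  cat(sprintf("Step series (%s): %d breakpoints on [0, %g], final count %g\n",
              x$flavor, length(x$time), x$crown_age,
              x$count[length(x$count)]))
  invisible(x)
}

#' Quantile envelope of replicate step series
#'
#' Evaluates each replicate series on a common time grid and returns, per
#' grid point, the minimum, 2.5th, 25th, 50th, 75th and 97.5th percentiles
#' and the maximum across replicates.  Quantiles use linear interpolation of
#' order statistics (R's default type 7).
#'
#' @param series A non-empty list of `step_series` objects.
#' @param grid Time grid; defaults to 201 equally spaced points on
#'   `[0, crown_age]`.
#' @return A `data.frame` with columns `time`, `min`, `q025`, `q25`, `q50`,
#'   `q75`, `q975`, `max`.
#' @export
quantile_envelope <- function(series, grid = NULL) {
  if (!is.list(series) || length(series) == 0)
    stop("need a non-empty list of step series")
  if (is.null(grid))
    grid <- seq(0, series[[1]]$crown_age, length.out = 201)
  vals <- vapply(series, eval_step, numeric(length(grid)), t = grid)
  vals <- matrix(vals, nrow = length(grid))
  qs <- t(apply(vals, 1, stats::quantile,
                probs = c(0, 0.025, 0.25, 0.5, 0.75, 0.975, 1),
                type = 7, names = FALSE))
  out <- data.frame(time = grid, qs)
  names(out) <- c("time", "min", "q025", "q25", "q50", "q75", "q975", "max")
  out
}
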