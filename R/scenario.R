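#' Scenario configuration
#'
#' Bundles everything a simulation run needs: the species table, the unit
#' system and arena geometry, initial populations (counts or mM
#' concentrations, never both for one species), the behavioural rulebook
#' (cofactor binding, reactions, membrane actions, influx schedules),
#' crowding obstacles, and the default horizon.
#'
#' The arena is a rectangle with the membrane as its boundary; obstacles are
#' immobile agents of radius equal to the distance unit (configurable),
#' placed uniformly at random without initial overlap.
#'
#' @param species an [species_table()] (plain data frames are accepted and
#'   validated).
#' @param units an [unit_system()].
#' @param initial_counts named integer vector of initial agent counts.
#' @param initial_concentrations named numeric vector of initial
#'   concentrations in mM, converted to counts through `units`.
#' @param binding list of [binding_rule()]s.
#' @param reactions list of [reaction_rule()]s.
#' @param membrane list of [membrane_rule()]s (species without a rule
#'   reflect).
#' @param influx list of [influx_schedule()]s.
#' @param obstacle_count number of crowding obstacles (>= 0).
#' @param obstacle_radius obstacle radius in um; default: the distance unit.
#' @param jitter half-width (radians) of the uniform angular jitter added on
#'   reorientation; default 0.2.
#' @param max_steps default simulation horizon in ticks.
#' @param name scenario label.
#' @return an object of class `enzsim_scenario`.
#' @export
scenario <- function(species, units = unit_system(),
                     initial_counts = integer(),
                     initial_concentrations = numeric(),
                     binding = list(), reactions = list(),
                     membrane = list(), influx = list(),
                     obstacle_count = 0L, obstacle_radius = NULL,
                     jitter = 0.2, max_steps = 1000L,
                     name = "scenario") {
  if (!inherits(species, "enzsim_species")) species <- species_table(species)
  stopifnot(inherits(units, "enzsim_units"))
  if (inherits(binding, "enzsim_binding")) binding <- list(binding)
  if (inherits(reactions, "enzsim_reaction")) reactions <- list(reactions)
  if (inherits(membrane, "enzsim_membrane")) membrane <- list(membrane)
  if (inherits(influx, "enzsim_influx")) influx <- list(influx)

  known <- function(nm, where) {
    bad <- setdiff(nm, species$name)
    if (length(bad))
      stop("unknown species in ", where, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  both <- intersect(names(initial_counts), names(initial_concentrations))
  if (length(both))
    stop("species given both a count and a concentration: ",
         paste(both, collapse = ", "), call. = FALSE)
  known(names(initial_counts), "initial_counts")
  known(names(initial_concentrations), "initial_concentrations")
  if (length(initial_counts) && any(initial_counts < 0))
    stop("initial counts must be non-negative", call. = FALSE)
  if (length(initial_concentrations) && any(initial_concentrations < 0))
    stop("initial concentrations must be non-negative", call. = FALSE)
  for (b in binding) {
    stopifnot(inherits(b, "enzsim_binding"))
    known(c(b$enzyme, b$cofactor, b$holoenzyme), "binding rule")
  }
  for (r in reactions) {
    stopifnot(inherits(r, "enzsim_reaction"))
    known(c(r$catalyst, r$substrate, names(r$products)), paste0("reaction '", r$name, "'"))
  }
  rule_sp <- vapply(membrane, function(m) m$species, "")
  if (anyDuplicated(rule_sp))
    stop("species with more than one membrane rule: ",
         rule_sp[duplicated(rule_sp)][1], call. = FALSE)
  for (m in membrane) {
    stopifnot(inherits(m, "enzsim_membrane"))
    known(c(m$species, m$to), "membrane rule")
  }
  for (f in influx) {
    stopifnot(inherits(f, "enzsim_influx"))
    known(f$species, "influx schedule")
  }
  if (obstacle_count > 0 && !"obstacle" %in% species$role) {
    species <- rbind(species,
                     data.frame(name = "obstacle", molecular_weight = NA_real_,
                                role = "obstacle",
                                particle_radius = if (is.null(obstacle_radius))
                                  distance_unit(species) else obstacle_radius,
                                diffusion_rate = 0,
                                display_tag = "obstacle",
                                stringsAsFactors = FALSE))
    class(species) <- c("enzsim_species", "data.frame")
  }

  units$distance_unit <- distance_unit(species)
  side <- sqrt(units$arena_area)
  obj <- structure(list(
    name = name,
    schema = "enzsim/1",
    species = species,
    units = units,
    arena = list(width = side, height = side),
    initial_counts = initial_counts,
    initial_concentrations = initial_concentrations,
    binding = binding, reactions = reactions,
    membrane = membrane, influx = influx,
    obstacle_count = as.integer(obstacle_count),
    jitter = jitter,
    max_steps = as.integer(max_steps)), class = "enzsim_scenario")
  obj
}

#' Resolved initial counts of a scenario
#'
#' Concentrations are converted to counts through the scenario's unit
#' system; obstacles are appended under the name `"obstacle"`.
#'
#' @param sc an `enzsim_scenario`.
#' @return named integer vector over all species with non-zero presence.
#' @export
initial_counts <- function(sc) {
  stopifnot(inherits(sc, "enzsim_scenario"))
  cnt <- c(as.integer(sc$initial_counts) |>
             stats::setNames(names(sc$initial_counts)),
           stats::setNames(
             as.integer(concentration_to_count(unname(sc$initial_concentrations),
                                               sc$units)),
             names(sc$initial_concentrations)))
  if (sc$obstacle_count > 0)
    cnt <- c(cnt, obstacle = sc$obstacle_count)
  cnt[cnt > 0]
}

# internal: species-name -> index
sp_index <- function(sc, nm) {
  i <- match(nm, sc$species$name)
  if (anyNA(i)) stop("unknown species: ", nm[is.na(i)][1], call. = FALSE)
  i
}

# internal: flatten the scenario into the list the C++ engine consumes
world_tables <- function(sc) {
  sp <- sc$species
  S <- nrow(sp)
  memact <- rep(0L, S)
  reconv <- rep(0L, S)
  for (m in sc$membrane) {
    i <- sp_index(sc, m$species)
    memact[i] <- switch(m$action, reflect = 0L, reconvert = 1L, excrete = 2L)
    if (m$action == "reconvert") reconv[i] <- sp_index(sc, m$to)
  }
  binding <- matrix(0L, nrow = length(sc$binding), ncol = 3)
  for (k in seq_along(sc$binding)) {
    b <- sc$binding[[k]]
    binding[k, ] <- c(sp_index(sc, b$enzyme), sp_index(sc, b$cofactor),
                      sp_index(sc, b$holoenzyme))
  }
  prod_sp <- integer()
  prod_start <- integer(length(sc$reactions))
  prod_len <- integer(length(sc$reactions))
  for (k in seq_along(sc$reactions)) {
    r <- sc$reactions[[k]]
    expanded <- rep(sp_index(sc, names(r$products)), times = r$products)
    prod_start[k] <- length(prod_sp)          # 0-based offset
    prod_len[k] <- length(expanded)
    prod_sp <- c(prod_sp, expanded)
  }
  list(
    species = list(
      radius = sp$particle_radius,
      step_length = unname(step_lengths(sp)),
      mobile = as.integer(sp$role != "obstacle"),
      membrane_action = memact,
      reconvert_to = reconv),
    binding = binding,
    reactions = list(
      catalyst = vapply(sc$reactions, function(r) sp_index(sc, r$catalyst), 1L),
      substrate = vapply(sc$reactions, function(r) sp_index(sc, r$substrate), 1L),
      p_react = vapply(sc$reactions, function(r) r$p_react, 1.0),
      tau = vapply(sc$reactions, function(r) r$duration_steps, 1L),
      prod_start = prod_start, prod_len = prod_len, prod_sp = prod_sp),
    arena = list(width = sc$arena$width, height = sc$arena$height,
                 jitter = sc$jitter))
}

# internal: influx events as an (step, species, count) matrix sorted by step
influx_events <- function(sc) {
  ev <- lapply(sc$influx, function(f) {
    b <- influx_batches(f)
    cbind(step = b$step, species = sp_index(sc, f$species), count = b$count)
  })
  ev <- if (length(ev)) do.call(rbind, ev) else
    matrix(integer(), ncol = 3, dimnames = list(NULL, c("step", "species", "count")))
  storage.mode(ev) <- "integer"
  ev[order(ev[, "step"]), , drop = FALSE]
}

#' Initialise a world from a scenario
#'
#' Places all initial agents (mobile species first, then obstacles) with
#' rejection-sampled non-overlapping positions and random headings, and
#' records the tick-0 state. The returned world carries its own RNG state,
#' so stepping it is reproducible regardless of other random draws in the
#' session.
#'
#' @param sc an `enzsim_scenario`.
#' @param seed integer RNG seed.
#' @return an object of class `enzsim_world`.
#' @export
world_init <- function(sc, seed = 1L) {
  stopifnot(inherits(sc, "enzsim_scenario"))
  set.seed(seed)
  cnt <- initial_counts(sc)
  idx <- sp_index(sc, names(cnt))
  mobile_first <- order(sc$species$role[idx] == "obstacle")
  sp_vec <- rep(idx[mobile_first], times = cnt[mobile_first])
  pos <- .cpp_place(sp_vec, sc$species$particle_radius,
                    sc$arena$width, sc$arena$height, 100L)
  n <- length(sp_vec)
  agents <- list(agent_id = seq_len(n), x = pos[, 1], y = pos[, 2],
                 heading = stats::runif(n, 0, 2 * pi),
                 species = sp_vec, busy_until = integer(n),
                 pending_rule = integer(n))
  w <- structure(list(
    scenario = sc,
    seed = seed,
    tables = world_tables(sc),
    influx = influx_events(sc),
    agents = agents,
    bind_count = integer(length(sc$binding)),
    reaction_count = integer(length(sc$reactions)),
    excreted_count = integer(nrow(sc$species)),
    step = 0L,
    next_id = n + 1L,
    influx_so_far = 0L,
    series = NULL), class = "enzsim_world")
  w$series <- rbind(series_row0(w))
  w$rng <- get(".Random.seed", envir = globalenv())
  w
}

# internal: column names of the time series
series_names <- function(sc) {
  c("tick",
    paste0("n_", sc$species$name),
    if (length(sc$binding))
      paste0("bind_", vapply(sc$binding, function(b) b$holoenzyme, "")),
    if (length(sc$reactions))
      paste0("rx_", vapply(sc$reactions, function(r) r$name, "")),
    paste0("ex_", sc$species$name))
}

# internal: the tick-0 row (initial conditions)
series_row0 <- function(w) {
  sc <- w$scenario
  counts <- tabulate(w$agents$species, nbins = nrow(sc$species))
  row <- c(w$step, counts, w$bind_count, w$reaction_count, w$excreted_count)
  names(row) <- series_names(sc)
  row
}

#' Advance a world by n ticks
#'
#' Each tick applies, in order: influx, movement of all mobile agents in
#' seeded-shuffled order with membrane actions at the boundary, collision
#' detection, rule resolution over colliding pairs in seeded-shuffled order,
#' completion of reactions whose duration ends this tick, and recording of
#' per-species counts and cumulative event counters.
#'
#' @param w an `enzsim_world` from [world_init()].
#' @param n number of ticks (>= 1).
#' @param record append per-tick rows to the world's time series.
#' @return the advanced `enzsim_world`.
#' @export
world_step <- function(w, n = 1L, record = TRUE) {
  stopifnot(inherits(w, "enzsim_world"), n >= 1)
  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", w$rng, envir = globalenv())
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  })
  st <- list(species = w$tables$species, binding = w$tables$binding,
             reactions = w$tables$reactions, arena = w$tables$arena,
             agents = w$agents,
             bind_count = w$bind_count, reaction_count = w$reaction_count,
             excreted_count = w$excreted_count,
             step = w$step, next_id = w$next_id,
             influx_so_far = w$influx_so_far)
  out <- .cpp_run(st, w$influx, as.integer(n), isTRUE(record))
  w$agents <- out$agents
  w$bind_count <- out$bind_count
  w$reaction_count <- out$reaction_count
  w$excreted_count <- out$excreted_count
  w$step <- out$step
  w$next_id <- out$next_id
  w$influx_so_far <- out$influx_so_far
  if (isTRUE(record)) {
    m <- out$series
    colnames(m) <- series_names(w$scenario)
    w$series <- rbind(w$series, m)
  }
  w$rng <- get(".Random.seed", envir = globalenv())
  w
}

#' Run a scenario
#'
#' Convenience wrapper: [world_init()] followed by [world_step()].
#' Identical scenario and seed give bit-identical results.
#'
#' @param sc an `enzsim_scenario`.
#' @param steps horizon in ticks (default: the scenario's `max_steps`).
#' @param seed integer RNG seed.
#' @return an object of class `enzsim_sim` with elements `series` (one data
#'   frame row per tick, first row = initial conditions), `agents` (final
#'   agent table), `reactions`, `bindings` and `excreted` (cumulative event
#'   counts), `seed` and `digest` (scenario digest).
#' @export
simulate_scenario <- function(sc, steps = NULL, seed = 1L) {
  if (is.null(steps)) steps <- sc$max_steps
  w <- world_init(sc, seed)
  if (steps > 0) w <- world_step(w, steps)
  sim_result(w)
}

# internal: package a world into an enzsim_sim result
sim_result <- function(w) {
  sc <- w$scenario
  series <- as.data.frame(w$series, row.names = NULL)
  ag <- as.data.frame(w$agents)
  ag$species <- sc$species$name[ag$species]
  structure(list(
    series = series,
    agents = ag,
    bindings = stats::setNames(w$bind_count,
                               vapply(sc$binding, function(b) b$holoenzyme, "")),
    reactions = stats::setNames(w$reaction_count,
                                vapply(sc$reactions, function(r) r$name, "")),
    excreted = stats::setNames(w$excreted_count, sc$species$name),
    influx_so_far = w$influx_so_far,
    seed = w$seed,
    steps = w$step,
    digest = scenario_digest(sc)), class = "enzsim_sim")
}

#' @export
print.enzsim_sim <- function(x, ...) {
  cat("enzsim simulation:", x$steps, "ticks, seed", x$seed, "\n")
  last <- x$series[nrow(x$series), ]
  n <- last[grep("^n_", names(last))]
  cat("final counts:", paste(sub("^n_", "", names(n)), unlist(n), collapse = ", "),
      "\n")
  if (length(x$reactions))
    cat("reactions completed:",
        paste(names(x$reactions), x$reactions, collapse = ", "), "\n")
  invisible(x)
}

#' Detect colliding agent pairs
#'
#' Two circular agents collide when the Euclidean distance between their
#' centres is strictly less than the sum of their radii. The grid method
#' uses a uniform spatial hash with cell size at least twice the largest
#' radius and returns exactly the same set as the quadratic all-pairs scan.
#'
#' @param x,y agent centre coordinates (um).
#' @param radius agent radii (um), recycled.
#' @param width,height arena extent (um); defaults to the bounding box.
#' @param method `"grid"` (spatial hash, C++) or `"brute"` (vectorised
#'   all-pairs in R, kept as an independent cross-check).
#' @return integer matrix with columns `i`, `j` (`i < j`), ordered by row.
#' @export
detect_collisions <- function(x, y, radius, width = NULL, height = NULL,
                              method = c("grid", "brute")) {
  method <- match.arg(method)
  n <- length(x)
  radius <- rep_len(radius, n)
  if (is.null(width)) width <- max(x + radius)
  if (is.null(height)) height <- max(y + radius)
  if (method == "grid") {
    m <- .cpp_detect_grid(x, y, radius, width, height)
  } else {
    if (n < 2) {
      m <- matrix(integer(), ncol = 2)
    } else {
      dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
      rr <- outer(radius, radius, "+")
      hit <- (dx * dx + dy * dy < rr * rr) & upper.tri(rr)
      idx <- which(hit, arr.ind = TRUE)
      m <- cbind(idx[, 1], idx[, 2])
      m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    }
  }
  colnames(m) <- c("i", "j")
  m
}

#' Mirror-law reorientation
#'
#' Specular reflection of a heading about a contact normal, plus an optional
#' uniform angular jitter: the direction component along the normal is
#' flipped, `d' = d - 2 (d . n) n`.
#'
#' @param heading incoming heading in radians.
#' @param normal length-2 unit vector (contact normal).
#' @param jitter half-width of the uniform jitter in radians (default 0).
#' @return outgoing heading in `[0, 2*pi)`.
#' @examples
#' reflect_heading(0, c(-1, 0))        # head-on wall hit: pi
#' reflect_heading(pi / 4, c(0, 1))    # mirrored off the floor: -pi/4 mod 2pi
#' @export
reflect_heading <- function(heading, normal, jitter = 0) {
  stopifnot(length(normal) == 2)
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("normal must be non-zero", call. = FALSE)
  normal <- normal / nrm
  d <- c(cos(heading), sin(heading))
  d <- d - 2 * sum(d * normal) * normal
  a <- atan2(d[2], d[1])
  if (jitter > 0) a <- a + stats::runif(1, -jitter, jitter)
  a %% (2 * pi)
}
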