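# Scenario configuration files (YAML), time-series files (TSV) and species
# tables (TSV).

# internal: scenario -> plain nested list, stable field order
scenario_to_list <- function(sc) {
  sp <- sc$species
  list(
    schema = sc$schema,
    name = sc$name,
    units = list(arena_area_um2 = sc$units$arena_area,
                 assumed_height_um = sc$units$assumed_height,
                 seconds_per_step = sc$units$seconds_per_step),
    species = lapply(seq_len(nrow(sp)), function(i) list(
      name = sp$name[i],
      molecular_weight = sp$molecular_weight[i],
      particle_radius_um = sp$particle_radius[i],
      diffusion_rate_um2_s = sp$diffusion_rate[i],
      role = sp$role[i],
      display_tag = sp$display_tag[i])),
    initial_counts = as.list(sc$initial_counts),
    initial_concentrations_mM = as.list(sc$initial_concentrations),
    binding = lapply(sc$binding, function(b)
      list(enzyme = b$enzyme, cofactor = b$cofactor, holoenzyme = b$holoenzyme)),
    reactions = lapply(sc$reactions, function(r) list(
      name = r$name, catalyst = r$catalyst, substrate = r$substrate,
      products = as.list(r$products),
      percent_reactive = 100 * r$p_react,
      duration_steps = r$duration_steps)),
    membrane = lapply(sc$membrane, function(m)
      c(list(species = m$species, action = m$action),
        if (!is.null(m$to)) list(to = m$to))),
    influx = lapply(sc$influx, function(f) list(
      species = f$species, total_count = f$total_count,
      fraction_per_batch = f$fraction_per_batch,
      interval_steps = f$interval_steps, start_step = f$start_step)),
    obstacle_count = sc$obstacle_count,
    jitter_rad = sc$jitter,
    max_steps = sc$max_steps,
    assay = sc$assay)
}

# internal: plain list -> scenario (full validation via the constructor)
scenario_from_list <- function(x, path = "<config>") {
  need <- function(field, where = "") {
    if (is.null(x[[field]]))
      stop(path, ": missing required key '", field, "'", call. = FALSE)
    x[[field]]
  }
  spl <- need("species")
  sp <- data.frame(
    name = vapply(spl, function(s) as.character(s$name), ""),
    molecular_weight = vapply(spl, function(s)
      if (is.null(s$molecular_weight)) NA_real_ else as.numeric(s$molecular_weight), 1.0),
    particle_radius = vapply(spl, function(s)
      if (is.null(s$particle_radius_um)) NA_real_ else as.numeric(s$particle_radius_um), 1.0),
    diffusion_rate = vapply(spl, function(s)
      if (is.null(s$diffusion_rate_um2_s)) NA_real_ else as.numeric(s$diffusion_rate_um2_s), 1.0),
    role = vapply(spl, function(s) as.character(s$role), ""),
    display_tag = vapply(spl, function(s)
      if (is.null(s$display_tag)) as.character(s$name) else as.character(s$display_tag), ""),
    stringsAsFactors = FALSE)
  u <- need("units")
  unl <- function(v) stats::setNames(as.numeric(unlist(v)), names(v))
  sc <- scenario(
    species = species_table(sp),
    units = unit_system(arena_area = as.numeric(u$arena_area_um2),
                        assumed_height = as.numeric(u$assumed_height_um),
                        seconds_per_step = as.numeric(u$seconds_per_step)),
    initial_counts = unl(x$initial_counts),
    initial_concentrations = unl(x$initial_concentrations_mM),
    binding = lapply(x$binding, function(b)
      binding_rule(b$enzyme, b$cofactor, b$holoenzyme)),
    reactions = lapply(x$reactions, function(r)
      reaction_rule(r$catalyst, r$substrate,
                    stats::setNames(as.integer(unlist(r$products)),
                                    names(r$products)),
                    p_react = as.numeric(r$percent_reactive) / 100,
                    duration_steps = as.integer(r$duration_steps),
                    name = r$name)),
    membrane = lapply(x$membrane, function(m)
      membrane_rule(m$species, m$action, to = m$to)),
    influx = lapply(x$influx, function(f)
      influx_schedule(f$species, f$total_count, f$fraction_per_batch,
                      f$interval_steps, f$start_step)),
    obstacle_count = as.integer(if (is.null(x$obstacle_count)) 0 else x$obstacle_count),
    jitter = as.numeric(if (is.null(x$jitter_rad)) 0.2 else x$jitter_rad),
    max_steps = as.integer(need("max_steps")),
    name = as.character(need("name")))
  if (!is.null(x$assay)) sc$assay <- x$assay
  sc
}

#' Save a scenario configuration
#'
#' Writes the scenario as a human-readable YAML file with explicit units in
#' the key names (`arena_area_um2`, `particle_radius_um`, ...). Saving and
#' re-loading a scenario yields an identical configuration digest.
#'
#' @param sc an `enzsim_scenario`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "enzsim_scenario"))
  writeLines(yaml::as.yaml(scenario_to_list(sc), precision = 15), path)
  invisible(path)
}

#' Load a scenario configuration
#'
#' Reads a YAML scenario file and fully validates it: every rule must
#' reference a declared species, counts and concentrations must be
#' non-negative and never both given for one species, and required keys
#' must be present. Errors name the offending key or species.
#'
#' @param path scenario file written by [save_scenario()] (or by hand).
#' @return an `enzsim_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  scenario_from_list(yaml::read_yaml(path), path = path)
}

#' Configuration digest
#'
#' MD5 digest of the canonicalised YAML form of a scenario; used to stamp
#' time-series outputs so results can be traced back to their exact
#' configuration.
#'
#' @param sc an `enzsim_scenario`.
#' @return hex digest string.
#' @export
scenario_digest <- function(sc) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  save_scenario(sc, tf)
  unname(tools::md5sum(tf))
}

#' Write a simulated time series
#'
#' One row per tick, one column per tracked quantity (species counts,
#' cumulative binding/reaction events, cumulative excretions), as
#' tab-separated text. The run's seed and configuration digest are stored
#' in comment lines so the file is self-describing.
#'
#' @param sim an `enzsim_sim` from [simulate_scenario()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(sim, path) {
  stopifnot(inherits(sim, "enzsim_sim"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# seed: ", sim$seed),
               paste0("# config: ", sim$digest)), con)
  utils::write.table(sim$series, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a time series written by [write_time_series()]
#'
#' @param path input file.
#' @return data frame with attributes `seed` and `config`.
#' @export
read_time_series <- function(path) {
  hdr <- readLines(path, n = 2)
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(x, "seed") <- as.integer(sub("^# seed: *", "", hdr[1]))
  attr(x, "config") <- sub("^# config: *", "", hdr[2])
  x
}

#' Read a species table from delimited text
#'
#' Expected columns: `name`, `molecular_weight`, `role`, and optionally
#' `particle_radius`, `diffusion_rate`, `display_tag`. Missing radii and
#' diffusion rates are derived from molecular mass by the scaling laws.
#'
#' @param path tab-separated file.
#' @inheritParams species_table
#' @return an `enzsim_species` table.
#' @export
read_species_table <- function(path, ref = NULL, alpha = NULL) {
  species_table(utils::read.delim(path, stringsAsFactors = FALSE),
                ref = ref, alpha = alpha)
}

#' Export per-tick agent snapshots
#'
#' Runs a scenario one tick at a time and appends every agent's position to
#' a tab-separated file (`tick`, `agent_id`, `species`, `x`, `y`,
#' `heading`) for visualisation by external tools.
#'
#' @param sc an `enzsim_scenario`.
#' @param steps number of ticks.
#' @param seed RNG seed.
#' @param path output file.
#' @param every snapshot interval in ticks (default 1).
#' @return the final `enzsim_sim`, invisibly.
#' @export
export_snapshots <- function(sc, steps, seed, path, every = 1L) {
  w <- world_init(sc, seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("tick\tagent_id\tspecies\tx\ty\theading", con)
  dump <- function(w) {
    a <- w$agents
    utils::write.table(
      data.frame(tick = w$step, agent_id = a$agent_id,
                 species = sc$species$name[a$species],
                 x = a$x, y = a$y, heading = a$heading),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  dump(w)
  for (k in seq_len(steps)) {
    w <- world_step(w, 1L)
    if (k %% every == 0 || k == steps) dump(w)
  }
  invisible(sim_result(w))
}
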