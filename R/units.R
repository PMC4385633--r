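#' Avogadro constant (1/mol)
#' @keywords internal
AVOGADRO <- 6.02214076e23

#' Round half away from zero
#'
#' Molecule counts are rounded to the nearest integer with halves going away
#' from zero, so that e.g. a computed 1499.5 molecules becomes 1500.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Unit system of a simulation
#'
#' Couples the laboratory units (mM, seconds) to the simulation units (agent
#' counts, ticks). The simulated arena is a two-dimensional slab of area
#' `arena_area` (um^2) and assumed height `assumed_height` (um, default
#' 0.005 um, a typical enzyme height), so that molar concentrations can be
#' converted to particle counts through the Avogadro constant. One
#' simulation tick corresponds to `seconds_per_step` seconds.
#'
#' @param arena_area arena area in um^2 (> 0).
#' @param assumed_height slab height in um (> 0, default 0.005).
#' @param seconds_per_step real-time seconds represented by one tick (> 0).
#' @param distance_unit optional distance unit in um (radius of the smallest
#'   mobile species); filled in automatically when a scenario is built.
#' @return an object of class `enzsim_units`.
#' @examples
#' u <- unit_system(arena_area = 1, seconds_per_step = 10)
#' concentration_to_count(4.98e-1, u)  # 1500 molecules
#' @export
unit_system <- function(arena_area = 1, assumed_height = 0.005,
                        seconds_per_step = 10, distance_unit = NULL) {
  stopifnot(is.numeric(arena_area), length(arena_area) == 1L, arena_area > 0,
            is.numeric(assumed_height), length(assumed_height) == 1L,
            assumed_height > 0,
            is.numeric(seconds_per_step), length(seconds_per_step) == 1L,
            seconds_per_step > 0)
  structure(list(arena_area = arena_area,
                 assumed_height = assumed_height,
                 seconds_per_step = seconds_per_step,
                 distance_unit = distance_unit,
                 avogadro = AVOGADRO),
            class = "enzsim_units")
}

#' Convert a molar concentration to an agent count
#'
#' A concentration in mM is converted to molecules per litre via the
#' Avogadro constant and then to a particle count by multiplying with the
#' slab volume `arena_area * assumed_height` (um^3, i.e. 1e-15 L). The
#' result is rounded half away from zero to the nearest integer.
#'
#' @param conc concentration in mM (>= 0), vectorised.
#' @param units an [unit_system()] object.
#' @return integer-valued numeric vector of agent counts.
#' @examples
#' u <- unit_system(arena_area = 1, seconds_per_step = 10)
#' concentration_to_count(1.66, u)     # 4998, approx 5e3
#' concentration_to_count(6.64e-2, u)  # 200
#' @export
concentration_to_count <- function(conc, units) {
  stopifnot(inherits(units, "enzsim_units"))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentration must be finite and non-negative", call. = FALSE)
  round_half_away(conc * 1e-3 * units$avogadro * 1e-15 *
                    units$arena_area * units$assumed_height)
}

#' Convert an agent count to a molar concentration
#'
#' Exact algebraic inverse of the (unrounded) concentration-to-count
#' conversion.
#'
#' @param n agent count (>= 0), vectorised.
#' @param units an [unit_system()] object.
#' @return concentration in mM.
#' @export
count_to_concentration <- function(n, units) {
  stopifnot(inherits(units, "enzsim_units"))
  if (any(!is.finite(n)) || any(n < 0))
    stop("count must be finite and non-negative", call. = FALSE)
  n / (1e-3 * units$avogadro * 1e-15 * units$arena_area * units$assumed_height)
}

#' Convert ticks to seconds
#'
#' @param n_steps number of ticks (>= 0).
#' @param units an [unit_system()] object.
#' @return elapsed real time in seconds.
#' @export
steps_to_seconds <- function(n_steps, units) {
  stopifnot(inherits(units, "enzsim_units"))
  n_steps * units$seconds_per_step
}

#' Fit the particle-radius vs molecular-mass power law
#'
#' Particle radii are assumed to scale with molecular mass as a power law
#' `r = r_ref * (M / M_ref)^alpha`. The exponent is estimated as the
#' least-squares slope of log(radius) on log(mass); with exactly two rows
#' this reduces to `log(r2/r1) / log(M2/M1)`.
#'
#' @param molecular_weight masses in g/mol (>= 2 distinct values).
#' @param particle_radius radii in um, same length.
#' @return the dimensionless exponent alpha.
#' @examples
#' # anchored on benzyl alcohol and NAD+:
#' fit_mass_scaling_exponent(c(108.14, 661.41), c(0.323e-3, 0.657e-3))
#' @export
fit_mass_scaling_exponent <- function(molecular_weight, particle_radius) {
  stopifnot(length(molecular_weight) == length(particle_radius))
  ok <- is.finite(molecular_weight) & is.finite(particle_radius) &
    molecular_weight > 0 & particle_radius > 0
  mw <- molecular_weight[ok]; r <- particle_radius[ok]
  if (length(unique(mw)) < 2L)
    stop("need at least two rows with distinct molecular weights", call. = FALSE)
  lx <- log(mw); ly <- log(r)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Predict a particle radius from molecular mass
#'
#' @param mw molecular weight in g/mol (> 0).
#' @param ref reference species: a list or one-row data frame with fields
#'   `molecular_weight` and `particle_radius`.
#' @param alpha scaling exponent, e.g. from [fit_mass_scaling_exponent()].
#' @return predicted radius in um.
#' @export
radius_from_mass <- function(mw, ref, alpha) {
  if (any(!is.finite(mw)) || any(mw <= 0))
    stop("molecular weight must be positive", call. = FALSE)
  ref <- as.list(ref)
  ref$particle_radius * (mw / ref$molecular_weight)^alpha
}

#' Predict a diffusion rate from particle radius
#'
#' Stokes-like inverse-radius scaling: `D = D_ref * (r_ref / r)`, so the
#' smaller the molecule the faster it moves.
#'
#' @param r particle radius in um (> 0).
#' @param ref reference species: a list or one-row data frame with fields
#'   `particle_radius` and `diffusion_rate`.
#' @return predicted diffusion rate in um^2/s.
#' @export
diffusion_from_radius <- function(r, ref) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("radius must be positive", call. = FALSE)
  ref <- as.list(ref)
  ref$diffusion_rate * (ref$particle_radius / r)
}

#' Species roles understood by the simulator
#' @keywords internal
SPECIES_ROLES <- c("enzyme", "metabolite", "cofactor", "holoenzyme",
                   "complex", "obstacle")

#' Build and validate a species table
#'
#' A species table holds the physical identity of every molecular species in
#' a scenario: name, molecular weight (g/mol), particle radius (um),
#' diffusion rate (um^2/s) and role. Missing radii are derived from
#' molecular mass by the fitted power law anchored at `ref`; missing
#' diffusion rates by inverse-radius scaling from the same anchor.
#' Obstacles are immobile (`diffusion_rate = 0`).
#'
#' @param df data frame with columns `name`, `molecular_weight`, `role`, and
#'   optionally `particle_radius`, `diffusion_rate`, `display_tag`.
#' @param ref reference species used for the scaling laws (default: the
#'   benzyl alcohol row of the bundled pathway table).
#' @param alpha power-law exponent; default refits from the rows of `df`
#'   that carry an explicit radius, falling back to the bundled anchor fit.
#' @return a validated `data.frame` of class `enzsim_species`.
#' @export
species_table <- function(df, ref = NULL, alpha = NULL) {
  stopifnot(is.data.frame(df), all(c("name", "molecular_weight", "role") %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicated species name: ", df$name[duplicated(df$name)][1], call. = FALSE)
  if (!all(df$role %in% SPECIES_ROLES))
    stop("unknown role: ", setdiff(df$role, SPECIES_ROLES)[1], call. = FALSE)
  if (is.null(df$particle_radius)) df$particle_radius <- NA_real_
  if (is.null(df$diffusion_rate)) df$diffusion_rate <- NA_real_
  if (is.null(df$display_tag)) df$display_tag <- df$name

  anchor <- reference_anchor_rows()
  if (is.null(ref)) ref <- as.list(anchor[1, ])
  if (is.null(alpha)) {
    have <- !is.na(df$particle_radius) & is.finite(df$molecular_weight)
    alpha <- if (sum(have) >= 2 && length(unique(df$molecular_weight[have])) >= 2)
      fit_mass_scaling_exponent(df$molecular_weight[have], df$particle_radius[have])
    else
      fit_mass_scaling_exponent(anchor$molecular_weight, anchor$particle_radius)
  }
  need_r <- is.na(df$particle_radius)
  df$particle_radius[need_r] <- radius_from_mass(df$molecular_weight[need_r], ref, alpha)
  need_d <- is.na(df$diffusion_rate) & df$role != "obstacle"
  df$diffusion_rate[need_d] <- diffusion_from_radius(df$particle_radius[need_d], ref)
  df$diffusion_rate[df$role == "obstacle"] <- 0

  if (any(df$particle_radius <= 0))
    stop("particle radii must be positive", call. = FALSE)
  if (any(df$diffusion_rate < 0))
    stop("diffusion rates must be non-negative", call. = FALSE)
  if (any(df$diffusion_rate == 0 & df$role != "obstacle"))
    stop("only obstacles may have zero diffusion rate", call. = FALSE)
  class(df) <- c("enzsim_species", "data.frame")
  df
}

#' Anchor rows for the mass-scaling laws
#'
#' The two species (benzyl alcohol and NAD+) whose printed radius and
#' diffusion values anchor the package's power-law radius and inverse-radius
#' diffusion scaling.
#'
#' @return a two-row data frame.
#' @export
reference_anchor_rows <- function() {
  data.frame(name = c("benzyl_alcohol", "NAD"),
             molecular_weight = c(108.14, 661.41),
             particle_radius = c(0.323e-3, 0.657e-3),
             diffusion_rate = c(4.018e-14, 1.975e-14),
             stringsAsFactors = FALSE)
}

#' Distance unit of a species set
#'
#' The simulator's distance unit is the radius of the smallest mobile
#' species; it is also the per-tick displacement of the fastest species.
#'
#' @param species an `enzsim_species` table.
#' @return distance unit in um.
#' @export
distance_unit <- function(species) {
  mobile <- species$role != "obstacle"
  if (!any(mobile)) stop("no mobile species in table", call. = FALSE)
  min(species$particle_radius[mobile])
}

#' Per-tick step length of each species
#'
#' Step lengths are proportional to the diffusion rate, capped so that the
#' fastest mobile species advances exactly one distance unit per tick:
#' `s = distance_unit * D / max(D)`. Obstacles have step length zero.
#'
#' @param species an `enzsim_species` table.
#' @return named numeric vector of step lengths in um.
#' @export
step_lengths <- function(species) {
  mobile <- species$role != "obstacle"
  dmax <- max(species$diffusion_rate[mobile])
  s <- distance_unit(species) * species$diffusion_rate / dmax
  names(s) <- species$name
  s
}
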