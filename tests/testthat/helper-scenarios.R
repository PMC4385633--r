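# shared builders for test scenarios

# bare-enzyme catalysis scenario: E + S -> E + P in a 1 um^2 arena
single_reaction_scenario <- function(n_enzyme = 150, n_substrate = 1000,
                                     p_react = 1, tau = 0L,
                                     obstacle_count = 0L, jitter = 0.2,
                                     arena_area = 1) {
  sp <- species_table(data.frame(
    name = c("enzyme", "substrate", "product"),
    molecular_weight = c(4e4, 108.14, 106.121),
    particle_radius = c(NA, 0.323e-3, 0.321e-3),
    diffusion_rate = c(NA, 4.018e-14, 4.047e-14),
    role = c("enzyme", "metabolite", "metabolite"),
    stringsAsFactors = FALSE))
  scenario(sp, unit_system(arena_area = arena_area, seconds_per_step = 10),
           initial_counts = c(enzyme = n_enzyme, substrate = n_substrate),
           reactions = reaction_rule("enzyme", "substrate",
                                     c(enzyme = 1, product = 1),
                                     p_react = p_react, duration_steps = tau,
                                     name = "catalysis"),
           obstacle_count = obstacle_count, jitter = jitter)
}

# world with agent positions/headings pinned for deterministic rule tests
pinned_world <- function(sc, x, y, heading = NULL, seed = 1) {
  w <- world_init(sc, seed = seed)
  stopifnot(length(x) == length(w$agents$x))
  w$agents$x <- x
  w$agents$y <- y
  if (!is.null(heading)) w$agents$heading <- heading
  w
}

# count column of a species in a series
nn <- function(series, species) series[[paste0("n_", species)]]
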