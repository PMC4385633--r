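#' Species table of the benzyl-alcohol oxidation pathway
#'
#' The molecular species of the two-step aromatic-aldehyde pathway
#' (benzyl alcohol -> benzaldehyde -> benzoate, NAD+/NADH as cofactor) with
#' molecular weights, particle radii (um) and diffusion rates (um^2/s).
#' The two dehydrogenases (aryl-alcohol dehydrogenase, EC 1.1.1.90, and
#' benzaldehyde dehydrogenase, EC 1.2.1.28) are assigned a typical 4e4
#' g/mol subunit mass with geometry derived from the mass-scaling laws;
#' their holoenzymes inherit the enzyme geometry.
#'
#' @return an `enzsim_species` table.
#' @export
benzyl_pathway_species <- function() {
  species_table(data.frame(
    name = c("benzyl_alcohol", "NAD", "NADH", "benzaldehyde", "benzoate",
             "aadh", "badh", "holo1", "holo2"),
    molecular_weight = c(108.14, 661.41, 663.43, 106.121, 121.12,
                         4e4, 4e4, 4e4, 4e4),
    particle_radius = c(0.323e-3, 0.657e-3, 0.658e-3, 0.321e-3, 0.338e-3,
                        NA, NA, NA, NA),
    diffusion_rate = c(4.018e-14, 1.975e-14, 1.973e-14, 4.047e-14, 3.843e-14,
                       NA, NA, NA, NA),
    role = c("metabolite", "cofactor", "cofactor", "metabolite", "metabolite",
             "enzyme", "enzyme", "holoenzyme", "holoenzyme"),
    display_tag = c("benzyl alcohol", "NAD+", "NADH", "benzaldehyde",
                    "benzoate", "aryl-alcohol dehydrogenase",
                    "benzaldehyde dehydrogenase",
                    "aadh:NAD+ holoenzyme", "badh:NAD+ holoenzyme"),
    stringsAsFactors = FALSE))
}

#' Bundled scenarios
#'
#' Builds one of the two bundled scenarios at a given scale:
#'
#' * `"single_reaction_assay"`: one bare enzyme catalysing substrate to
#'   product in a 1 um^2 arena; enzyme at 4.98e-2 mM (150 agents at scale
#'   1) with substrate levels spanning 6.64e-2 to 6.64e-1 mM (200 to 2000
#'   agents). The returned scenario is initialised at the highest substrate
#'   level; the full level series is attached as `$assay`.
#' * `"two_step_pathway"`: the benzyl-alcohol pathway. At scale 1 the 1
#'   um^2 arena holds 1.66 mM (~5e3 agents) of each dehydrogenase, 1e5
#'   crowding obstacles, 33.2 mM NAD+ (~1e5) and 3.32 mM NADH (~1e4);
#'   4.98e-1 mM benzyl alcohol (1500 agents) flows in gradually, 10% every
#'   10 ticks. NADH recycles to NAD+ at the membrane and benzoate is
#'   excreted. Reactions run at p_react 0.75 with a 25-tick duration.
#'
#' Scaling multiplies all counts (and the obstacle count) by `scale` and
#' shrinks the arena area by the same factor, preserving every
#' concentration.
#'
#' @param name which scenario.
#' @param scale fraction in (0, 1].
#' @return an `enzsim_scenario`.
#' @export
generate_fixture <- function(name = c("single_reaction_assay", "two_step_pathway"),
                             scale = 1) {
  name <- match.arg(name)
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale > 1)
    stop("scale must lie in (0, 1]", call. = FALSE)
  if (name == "single_reaction_assay") {
    design <- assay_design(p_react = 0.5, duration_steps = 0L)
    units <- unit_system(arena_area = 1 * scale, assumed_height = 0.005,
                         seconds_per_step = design$seconds_per_step)
    sc <- assay_scenario(design,
                         substrate_concentration = max(design$substrate_concentrations))
    sc$units$arena_area <- 1 * scale
    sc$arena <- list(width = sqrt(scale), height = sqrt(scale))
    sc$assay <- list(
      substrate_concentrations = design$substrate_concentrations,
      substrate_counts = as.integer(concentration_to_count(
        design$substrate_concentrations, units)),
      enzyme_count = as.integer(concentration_to_count(
        design$enzyme_concentration, units)),
      replicates = design$replicates,
      measurement_window = design$measurement_window)
    sc$name <- "single_reaction_assay"
    return(sc)
  }

  units <- unit_system(arena_area = 1 * scale, assumed_height = 0.005,
                       seconds_per_step = 10)
  influx_total <- concentration_to_count(4.98e-1, units)
  scenario(
    species = benzyl_pathway_species(),
    units = units,
    initial_concentrations = c(aadh = 1.66, badh = 1.66,
                               NAD = 33.2, NADH = 3.32),
    binding = list(binding_rule("aadh", "NAD", "holo1"),
                   binding_rule("badh", "NAD", "holo2")),
    reactions = list(
      reaction_rule("holo1", "benzyl_alcohol",
                    c(aadh = 1, NADH = 1, benzaldehyde = 1),
                    p_react = 0.75, duration_steps = 25L, name = "oxidation1"),
      reaction_rule("holo2", "benzaldehyde",
                    c(badh = 1, NADH = 1, benzoate = 1),
                    p_react = 0.75, duration_steps = 25L, name = "oxidation2")),
    membrane = list(membrane_rule("NADH", "reconvert", to = "NAD"),
                    membrane_rule("benzoate", "excrete")),
    influx = list(influx_schedule("benzyl_alcohol", influx_total,
                                  fraction_per_batch = 0.1,
                                  interval_steps = 10L, start_step = 0L)),
    obstacle_count = as.integer(round_half_away(1e5 * scale)),
    max_steps = 15000L,
    name = "two_step_pathway")
}
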