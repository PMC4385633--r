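#' Cofactor binding rule
#'
#' When an enzyme agent collides with its required cofactor, both agents are
#' replaced by a single holoenzyme agent at the enzyme's position with the
#' enzyme's heading. The holoenzyme inherits the enzyme's radius and
#' diffusion rate unless its species row overrides them.
#'
#' @param enzyme,cofactor,holoenzyme species names.
#' @return an object of class `enzsim_binding`.
#' @export
binding_rule <- function(enzyme, cofactor, holoenzyme) {
  stopifnot(is.character(enzyme), is.character(cofactor), is.character(holoenzyme))
  structure(list(enzyme = enzyme, cofactor = cofactor, holoenzyme = holoenzyme),
            class = "enzsim_binding")
}

#' Enzymatic reaction rule
#'
#' A catalyst (holoenzyme or bare enzyme) colliding with its substrate
#' reacts with probability `p_react` per collision. On a reactive collision
#' the substrate agent is removed and the catalyst becomes busy for
#' `duration_steps` ticks; on completion the catalyst agent is removed and
#' one agent per product entry (regenerated enzyme, converted cofactor,
#' products) is created at its position with a random heading. With
#' `duration_steps = 0` the reaction completes within the same tick.
#'
#' @param catalyst,substrate species names.
#' @param products named integer vector: product species and their counts
#'   (include the regenerated enzyme and any converted cofactor).
#' @param p_react reaction probability per collision in `[0, 1]`.
#' @param duration_steps reaction duration tau in ticks (>= 0).
#' @param name optional rule label used in time-series column names.
#' @return an object of class `enzsim_reaction`.
#' @export
reaction_rule <- function(catalyst, substrate, products, p_react,
                          duration_steps = 0L, name = NULL) {
  stopifnot(is.character(catalyst), is.character(substrate))
  if (length(products) == 0) stop("products must be non-empty", call. = FALSE)
  if (is.null(names(products)) || any(!nzchar(names(products))))
    stop("products must be a named vector of species counts", call. = FALSE)
  if (any(products < 1)) stop("product counts must be >= 1", call. = FALSE)
  if (!is.numeric(p_react) || p_react < 0 || p_react > 1)
    stop("p_react must lie in [0, 1]", call. = FALSE)
  if (duration_steps < 0 || duration_steps != round(duration_steps))
    stop("duration_steps must be a non-negative integer", call. = FALSE)
  structure(list(catalyst = catalyst, substrate = substrate,
                 products = as.integer(products) |> stats::setNames(names(products)),
                 p_react = as.numeric(p_react),
                 duration_steps = as.integer(duration_steps),
                 name = if (is.null(name)) paste0(catalyst, "_", substrate) else name),
            class = "enzsim_reaction")
}

#' Membrane rule
#'
#' What happens when an agent of the given species would cross the arena
#' boundary (the cell membrane): `reflect` (default for every species),
#' `reconvert` (the agent is replaced in place by species `to`, e.g. NADH
#' recycling to NAD+), or `excrete` (the agent leaves the cell and the
#' excreted counter of its species is incremented).
#'
#' @param species species name.
#' @param action one of `"reflect"`, `"reconvert"`, `"excrete"`.
#' @param to replacement species (required for `"reconvert"`).
#' @return an object of class `enzsim_membrane`.
#' @export
membrane_rule <- function(species, action = c("reflect", "reconvert", "excrete"),
                          to = NULL) {
  action <- match.arg(action)
  if (action == "reconvert" && is.null(to))
    stop("reconvert requires a target species", call. = FALSE)
  structure(list(species = species, action = action, to = to),
            class = "enzsim_membrane")
}

#' Influx schedule
#'
#' Gradual introduction of `total_count` agents of a species: a fraction
#' `fraction_per_batch` of the total enters every `interval_steps` ticks,
#' starting at `start_step`. Batch sizes follow cumulative rounding so that
#' the batches sum exactly to `total_count`.
#'
#' @param species species name.
#' @param total_count total number of agents to introduce (>= 0).
#' @param fraction_per_batch fraction in (0, 1] per batch.
#' @param interval_steps ticks between batches (>= 1).
#' @param start_step tick of the first batch (>= 0; the batch enters during
#'   tick `start_step + 1`, i.e. a `start_step` of 0 means agents are
#'   present from the first recorded tick onwards).
#' @return an object of class `enzsim_influx`.
#' @export
influx_schedule <- function(species, total_count, fraction_per_batch = 1,
                            interval_steps = 1L, start_step = 0L) {
  stopifnot(is.character(species), total_count >= 0,
            fraction_per_batch > 0, fraction_per_batch <= 1,
            interval_steps >= 1, start_step >= 0)
  structure(list(species = species, total_count = as.integer(total_count),
                 fraction_per_batch = as.numeric(fraction_per_batch),
                 interval_steps = as.integer(interval_steps),
                 start_step = as.integer(start_step)),
            class = "enzsim_influx")
}

#' Batch sizes of an influx schedule
#'
#' Cumulative rounding (half away from zero) guarantees the batches sum
#' exactly to the total: batch k has size
#' `round(k f N) - round((k-1) f N)`.
#'
#' @param schedule an [influx_schedule()].
#' @return data frame with columns `step` (absolute tick of entry) and
#'   `count`.
#' @export
influx_batches <- function(schedule) {
  stopifnot(inherits(schedule, "enzsim_influx"))
  n <- schedule$total_count
  if (n == 0) return(data.frame(step = integer(), count = integer()))
  f <- schedule$fraction_per_batch
  k <- ceiling(1 / f)
  cum <- round_half_away(pmin(seq_len(k) * f, 1) * n)
  counts <- as.integer(diff(c(0, cum)))
  steps <- schedule$start_step + (seq_len(k) - 1L) * schedule$interval_steps + 1L
  keep <- counts > 0
  data.frame(step = steps[keep], count = counts[keep])
}
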