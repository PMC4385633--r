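two_step_micro <- function(counts, x, y, heading = NULL, p_react = 1,
                           tau = c(0L, 0L), seed = 1) {
  sc <- scenario(
    benzyl_pathway_species(),
    unit_system(arena_area = 1, seconds_per_step = 10),
    initial_counts = counts,
    binding = list(binding_rule("aadh", "NAD", "holo1"),
                   binding_rule("badh", "NAD", "holo2")),
    reactions = list(
      reaction_rule("holo1", "benzyl_alcohol",
                    c(aadh = 1, NADH = 1, benzaldehyde = 1),
                    p_react = p_react, duration_steps = tau[1], name = "ox1"),
      reaction_rule("holo2", "benzaldehyde",
                    c(badh = 1, NADH = 1, benzoate = 1),
                    p_react = p_react, duration_steps = tau[2], name = "ox2")),
    membrane = list(membrane_rule("NADH", "reconvert", to = "NAD"),
                    membrane_rule("benzoate", "excrete")),
    jitter = 0)
  pinned_world(sc, x, y, heading, seed = seed)
}

test_that("enzyme-cofactor collision creates one holoenzyme and conserves the enzyme", {
  w <- two_step_micro(c(aadh = 1, NAD = 1), x = c(0.5, 0.5), y = c(0.5, 0.5005))
  w <- world_step(w, 1)
  sp <- w$scenario$species$name[w$agents$species]
  expect_identical(sort(sp), "holo1")
  # holoenzyme sits at the enzyme's position
  expect_equal(w$agents$y, 0.5, tolerance = 1e-3)
  s <- as.data.frame(w$series)
  expect_true(all(s$n_aadh + s$n_holo1 == 1))
})

test_that("an enzyme and an unrelated metabolite fall through to reorientation", {
  w <- two_step_micro(c(aadh = 1, benzoate = 1), x = c(0.5, 0.5),
                      y = c(0.5, 0.5005))
  w <- world_step(w, 1)
  sp <- sort(w$scenario$species$name[w$agents$species])
  expect_identical(sp, c("aadh", "benzoate"))
  # the pair was pushed apart to at least tangency
  d <- sqrt(diff(w$agents$x)^2 + diff(w$agents$y)^2)
  rr <- sum(w$scenario$species$particle_radius[
    match(c("aadh", "benzoate"), w$scenario$species$name)])
  expect_gte(d, rr * (1 - 1e-9))
})

test_that("holoenzyme catalysis emits the full product side", {
  w <- two_step_micro(c(holo1 = 1, benzyl_alcohol = 1),
                      x = c(0.5, 0.5), y = c(0.5, 0.5005))
  w <- world_step(w, 1)
  sp <- w$scenario$species$name[w$agents$species]
  expect_setequal(sp, c("aadh", "NADH", "benzaldehyde"))
  w2 <- two_step_micro(c(holo2 = 1, benzaldehyde = 1),
                       x = c(0.5, 0.5), y = c(0.5, 0.5005))
  w2 <- world_step(w2, 1)
  sp2 <- w2$scenario$species$name[w2$agents$species]
  expect_setequal(sp2, c("badh", "NADH", "benzoate"))
})

test_that("a timed reaction completes exactly after its duration", {
  w <- two_step_micro(c(holo1 = 1, benzyl_alcohol = 1),
                      x = c(0.5, 0.5), y = c(0.5, 0.5005), tau = c(5L, 0L))
  w <- world_step(w, 6)
  s <- as.data.frame(w$series)
  expect_equal(nn(s, "benzaldehyde"), c(0, 0, 0, 0, 0, 0, 1))
  expect_equal(nn(s, "holo1"), c(1, 1, 1, 1, 1, 1, 0))
  # substrate disappears at initiation, products only at completion
  expect_equal(nn(s, "benzyl_alcohol"), c(1, 0, 0, 0, 0, 0, 0))
})

test_that("zero reaction probability never reacts", {
  w <- two_step_micro(c(holo1 = 1, benzyl_alcohol = 1),
                      x = c(0.5, 0.5), y = c(0.5, 0.5005), p_react = 0)
  w <- world_step(w, 100)
  s <- as.data.frame(w$series)
  expect_true(all(nn(s, "benzaldehyde") == 0))
  expect_true(all(nn(s, "benzyl_alcohol") == 1))
})

test_that("reactive collisions follow the binomial law", {
  # 10^4 isolated enzyme-substrate pairs on a lattice, one tick, p = 0.25
  n <- 1e4
  sc <- single_reaction_scenario(n_enzyme = n, n_substrate = n,
                                 p_react = 0.25, jitter = 0)
  gx <- rep(seq(0.005, 0.995, length.out = 100), each = 100)
  gy <- rep(seq(0.005, 0.995, length.out = 100), times = 100)
  w <- pinned_world(sc, x = c(gx, gx), y = c(gy, gy))
  w <- world_step(w, 1)
  s <- as.data.frame(w$series)
  hits <- nn(s, "product")[2]
  se <- sqrt(n * 0.25 * 0.75)
  expect_lt(abs(hits - n * 0.25), 3 * se)
})

test_that("enzyme and cofactor pools are conserved through binding and catalysis", {
  sc <- generate_fixture("two_step_pathway", scale = 0.01)
  s <- simulate_scenario(sc, steps = 500, seed = 17)$series
  expect_true(all(s$n_aadh + s$n_holo1 == s$n_aadh[1] + s$n_holo1[1]))
  expect_true(all(s$n_badh + s$n_holo2 == s$n_badh[1] + s$n_holo2[1]))
  expect_true(all(s$n_NAD + s$n_NADH + s$n_holo1 + s$n_holo2 ==
                    s$n_NAD[1] + s$n_NADH[1]))
})

test_that("membrane rules reconvert, excrete or reflect by species", {
  # NADH heading into the wall reconverts to NAD+ in place
  w <- two_step_micro(c(NADH = 1, badh = 1), x = c(0.0008, 0.5),
                      y = c(0.5, 0.5), heading = c(pi, 0))
  x0 <- w$agents$x[1]
  for (k in 1:10) w <- world_step(w, 1)
  s <- as.data.frame(w$series)
  expect_equal(nn(s, "NAD")[11], 1)
  expect_equal(nn(s, "NADH")[11], 0)
  i <- which(w$scenario$species$name[w$agents$species] == "NAD")
  expect_equal(w$agents$x[i], x0, tolerance = 2e-3)

  # benzoate is excreted and counted
  w <- two_step_micro(c(benzoate = 1, badh = 1), x = c(0.0008, 0.5),
                      y = c(0.5, 0.5), heading = c(pi, 0))
  w <- world_step(w, 10)
  s <- as.data.frame(w$series)
  expect_equal(nn(s, "benzoate")[11], 0)
  expect_equal(s$ex_benzoate[11], 1)

  # benzaldehyde reflects and stays inside
  w <- two_step_micro(c(benzaldehyde = 1, badh = 1), x = c(0.0008, 0.5),
                      y = c(0.5, 0.5), heading = c(pi, 0))
  w <- world_step(w, 10)
  s <- as.data.frame(w$series)
  expect_equal(nn(s, "benzaldehyde")[11], 1)
  expect_true(all(w$agents$x >= 0))
})

test_that("influx batches sum exactly to the scheduled total", {
  b <- influx_batches(influx_schedule("x", 1500, 0.1, 10L))
  expect_equal(b$count, rep(150L, 10))
  expect_equal(b$step, seq(1, 91, by = 10))
  b <- influx_batches(influx_schedule("x", 1005, 0.1, 10L))
  expect_true(all(b$count %in% c(100L, 101L)))
  expect_equal(sum(b$count), 1005L)
  b <- influx_batches(influx_schedule("x", 42, 1, 1L, start_step = 7L))
  expect_equal(b, data.frame(step = 8L, count = 42L))
  for (k in 1:20) {
    tot <- sample.int(2000, 1)
    f <- runif(1, 0.05, 1)
    expect_equal(sum(influx_batches(influx_schedule("x", tot, f, 3L))$count), tot)
  }
})

test_that("influx agents enter the world on schedule", {
  sc <- generate_fixture("two_step_pathway", scale = 0.01)
  sim <- simulate_scenario(sc, steps = 95, seed = 2)
  total <- concentration_to_count(4.98e-1, sc$units)
  expect_identical(sim$influx_so_far, as.integer(total))
  s <- sim$series
  # all batches delivered by tick 91; counts present net of consumption
  expect_lte(max(nn(s, "benzyl_alcohol")), total)
  expect_gt(nn(s, "benzyl_alcohol")[50], 0)
})

test_that("rule constructors validate their inputs", {
  expect_error(reaction_rule("a", "b", c(x = 1), p_react = 1.2), "p_react")
  expect_error(reaction_rule("a", "b", integer(), p_react = 0.5), "non-empty")
  expect_error(reaction_rule("a", "b", c(x = 1), p_react = 0.5,
                             duration_steps = -1), "non-negative")
  expect_error(membrane_rule("a", "reconvert"), "target species")
  expect_error(influx_schedule("a", 10, fraction_per_batch = 0), "fraction")
})
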