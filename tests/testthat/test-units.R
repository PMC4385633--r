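u1 <- unit_system(arena_area = 1, assumed_height = 0.005, seconds_per_step = 10)

test_that("concentration/count conversion reproduces the published pairs", {
  expect_equal(concentration_to_count(4.98e-1, u1), 1500)
  expect_equal(concentration_to_count(4.98e-2, u1), 150)
  expect_equal(concentration_to_count(6.64e-2, u1), 200)
  expect_equal(signif(concentration_to_count(1.66, u1), 2), 5e3)
  expect_equal(signif(concentration_to_count(33.2, u1), 2), 1e5)
  expect_equal(signif(concentration_to_count(3.32, u1), 2), 1e4)
  expect_equal(concentration_to_count(0, u1), 0)
  expect_equal(signif(count_to_concentration(150, u1), 3), 4.98e-2)
  expect_equal(count_to_concentration(0, u1), 0)
  expect_error(concentration_to_count(-1, u1), "non-negative")
  expect_error(count_to_concentration(-1, u1), "non-negative")
})

test_that("count -> concentration -> count round-trips exactly", {
  n <- c(1, 2, 17, 150, 1500, 4998, 99968, 1e6,
         sample.int(1e6, 200))
  expect_equal(concentration_to_count(count_to_concentration(n, u1), u1), n)
  # a fractional-count concentration deviates by less than one molecule
  conc <- 4.98e-1
  back <- count_to_concentration(concentration_to_count(conc, u1), u1)
  expect_lt(abs(back - conc), count_to_concentration(1, u1))
})

test_that("conversion is monotone in concentration, area and height", {
  conc <- sort(runif(50, 0, 50))
  expect_true(all(diff(concentration_to_count(conc, u1)) >= 0))
  areas <- sort(runif(20, 0.01, 5))
  cnts <- vapply(areas, function(a)
    concentration_to_count(1.66, unit_system(arena_area = a)), 1.0)
  expect_true(all(diff(cnts) >= 0))
  hts <- sort(runif(20, 0.001, 0.05))
  cnts <- vapply(hts, function(h)
    concentration_to_count(1.66, unit_system(assumed_height = h)), 1.0)
  expect_true(all(diff(cnts) >= 0))
})

test_that("mass-scaling exponent fit matches the two-point formula and self-consistency", {
  anchor <- reference_anchor_rows()
  a <- fit_mass_scaling_exponent(anchor$molecular_weight, anchor$particle_radius)
  expect_equal(a, log(0.657e-3 / 0.323e-3) / log(661.41 / 108.14), tolerance = 1e-12)
  expect_equal(round(a, 3), 0.392)
  # flat radii -> zero exponent
  expect_equal(fit_mass_scaling_exponent(c(100, 400), c(2e-3, 2e-3)), 0)
  # exact power law recovered to machine precision from > 2 rows
  mw <- c(50, 120, 300, 700, 1500)
  expect_equal(fit_mass_scaling_exponent(mw, 2e-4 * mw^(1 / 3)), 1 / 3,
               tolerance = 1e-12)
  expect_error(fit_mass_scaling_exponent(c(100, 100), c(1, 2)), "distinct")
})

test_that("radius and diffusion predictions reproduce the published species table", {
  anchor <- reference_anchor_rows()
  ref <- as.list(anchor[1, ])
  a <- fit_mass_scaling_exponent(anchor$molecular_weight, anchor$particle_radius)
  expect_equal(signif(radius_from_mass(121.12, ref, a), 3), 0.338e-3)   # benzoate
  expect_equal(signif(radius_from_mass(106.121, ref, a), 3), 0.321e-3)  # benzaldehyde
  expect_equal(signif(radius_from_mass(663.43, ref, a), 3), 0.658e-3)   # NADH
  expect_identical(radius_from_mass(ref$molecular_weight, ref, a), ref$particle_radius)
  expect_equal(signif(diffusion_from_radius(radius_from_mass(663.43, ref, a), ref), 4),
               1.973e-14)                                               # NADH
  expect_equal(signif(diffusion_from_radius(radius_from_mass(121.12, ref, a), ref), 4),
               3.843e-14)                                               # benzoate
  # benzaldehyde diffusion agrees within one unit in the last printed digit
  d_bald <- signif(diffusion_from_radius(radius_from_mass(106.121, ref, a), ref), 4)
  expect_lte(abs(d_bald - 4.047e-14), 1.0001e-17)
  expect_identical(diffusion_from_radius(ref$particle_radius, ref), ref$diffusion_rate)
  expect_error(radius_from_mass(-1, ref, a), "positive")
  expect_error(diffusion_from_radius(0, ref), "positive")
})

test_that("tick-to-seconds mapping is linear", {
  expect_equal(steps_to_seconds(1, u1), 10)
  expect_equal(steps_to_seconds(0, u1), 0)
  expect_equal(steps_to_seconds(2000, u1), 20000)
})

test_that("species table derives geometry and enforces role invariants", {
  sp <- benzyl_pathway_species()
  # radius increases and diffusion decreases with mass among derived values
  derived <- sp[sp$role %in% c("enzyme", "holoenzyme"), ]
  small <- sp[sp$name == "benzyl_alcohol", ]
  expect_true(all(derived$particle_radius > small$particle_radius))
  expect_true(all(derived$diffusion_rate < small$diffusion_rate))
  expect_true(all(sp$particle_radius > 0))
  expect_true(all(sp$diffusion_rate > 0))
  expect_error(species_table(data.frame(name = "x", molecular_weight = 1,
                                        role = "wizard")), "unknown role")
  expect_error(species_table(data.frame(name = c("a", "a"),
                                        molecular_weight = c(1, 2),
                                        role = "metabolite")), "duplicated")
  # only obstacles may be immobile
  tab <- data.frame(name = "slow", molecular_weight = 10,
                    particle_radius = 1e-3, diffusion_rate = 0,
                    role = "metabolite")
  expect_error(species_table(tab), "obstacle")
})

test_that("step lengths cap the fastest species at one distance unit", {
  sp <- species_table(data.frame(
    name = c("fast", "half", "rock"),
    molecular_weight = c(100, 200, NA),
    particle_radius = c(2e-3, 3e-3, 1e-3),
    diffusion_rate = c(4e-14, 2e-14, 0),
    role = c("metabolite", "metabolite", "obstacle")))
  expect_equal(distance_unit(sp), 2e-3)
  s <- step_lengths(sp)
  expect_equal(unname(s["fast"]), 2e-3)        # fastest: one distance unit
  expect_equal(unname(s["half"]), 1e-3)        # D/2 -> half a unit
  expect_equal(unname(s["rock"]), 0)           # obstacles do not move
})
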