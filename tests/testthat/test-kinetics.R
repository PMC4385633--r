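test_that("Michaelis-Menten velocity has the textbook shape", {
  expect_equal(michaelis_menten_velocity(1, km = 1, vmax = 2), 1)     # S = Km
  expect_equal(michaelis_menten_velocity(0, km = 1, vmax = 2), 0)
  expect_equal(michaelis_menten_velocity(3, km = 1, vmax = 2), 1.5)   # 0.75 Vmax
  expect_error(michaelis_menten_velocity(-1, 1, 2), "non-negative")
})

test_that("velocity measurement converts counts and ticks to mM/s", {
  u <- unit_system(arena_area = 1, assumed_height = 0.005, seconds_per_step = 10)
  s <- data.frame(tick = 0:3, n_product = c(0, 10, 20, 30))
  v <- measure_velocity(s, "product", window = 3, units = u)
  # 1 count per second, each count worth 1/3011.07 mM in this geometry
  expect_equal(v, 3.321079e-4, tolerance = 1e-6)
  expect_equal(signif(v, 3), 3.32e-4)
  # flat series -> zero velocity
  s$n_product <- 5
  expect_equal(measure_velocity(s, "product", 3, u), 0)
  # doubling the tick duration halves the velocity
  u2 <- unit_system(seconds_per_step = 20)
  s$n_product <- c(0, 10, 20, 30)
  expect_equal(measure_velocity(s, "product", 3, u2), v / 2)
  expect_error(measure_velocity(s, "product", 10, u), "window")
  expect_error(measure_velocity(s, "nope", 3, u), "no column")
})

test_that("Lineweaver-Burk regression recovers noiseless kinetics exactly", {
  S <- c(0.5, 1, 2, 4)
  pts <- data.frame(S = S, V = michaelis_menten_velocity(S, km = 1, vmax = 2))
  fit <- lineweaver_burk_fit(pts, enzyme_concentration = 4)
  expect_equal(fit$km, 1, tolerance = 1e-9)
  expect_equal(fit$vmax, 2, tolerance = 1e-9)
  expect_equal(fit$kcat, 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  set.seed(31)
  for (k in 1:100) {
    km <- runif(1, 0.05, 10); vmax <- runif(1, 0.1, 5)
    S <- sort(runif(5, km / 4, km * 4))
    fit <- lineweaver_burk_fit(
      data.frame(S = S, V = michaelis_menten_velocity(S, km, vmax)))
    expect_equal(fit$km, km, tolerance = 1e-9)
    expect_equal(fit$vmax, vmax, tolerance = 1e-9)
    # internal consistency: km = slope/intercept, vmax = 1/intercept
    expect_equal(fit$km, fit$slope / fit$intercept, tolerance = 1e-12)
    expect_equal(fit$vmax, 1 / fit$intercept, tolerance = 1e-12)
  }
})

test_that("degenerate Lineweaver-Burk inputs are rejected or flagged", {
  expect_error(lineweaver_burk_fit(data.frame(S = c(1, 2), V = c(1, 2))),
               "three")
  expect_error(lineweaver_burk_fit(data.frame(S = c(1, 2, 3), V = c(1, 0, 2))),
               "2")
  expect_error(lineweaver_burk_fit(data.frame(S = c(0, 2, 3), V = c(1, 1, 2))),
               "positive")
})

test_that("negative estimates from curved data are reported unmodified", {
  # superlinear velocities bend the double-reciprocal plot to a negative
  # intercept, as near-zero-turnover stochastic assays do
  S <- c(0.5, 1, 2, 4)
  fit <- lineweaver_burk_fit(data.frame(S = S, V = 0.3 * S^1.3),
                             enzyme_concentration = 1)
  expect_lt(fit$intercept, 0)
  expect_lt(fit$km, 0)
  expect_lt(fit$kcat, 0)
})

test_that("a single-replicate assay equals a hand-run simulation and fit", {
  d <- assay_design(substrate_concentrations = c(0.0664, 0.332, 0.664),
                    p_react = 1, duration_steps = 0L, replicates = 1L,
                    measurement_window = 100L, base_seed = 11L)
  res <- run_assay(d)
  # rebuild by hand with the same derived seeds
  V <- vapply(seq_along(d$substrate_concentrations), function(ci) {
    sc <- assay_scenario(d, d$substrate_concentrations[ci])
    sim <- simulate_scenario(sc, steps = 100,
                             seed = bitwXor(11L, (ci * 8L) * 65536L))
    measure_velocity(sim$series, "product", 100, sc$units)
  }, 1.0)
  manual <- lineweaver_burk_fit(
    data.frame(S = d$substrate_concentrations, V = V),
    enzyme_concentration = d$enzyme_concentration)
  expect_equal(res$km, manual$km)
  expect_equal(res$kcat, manual$kcat)
  # assays are reproducible
  expect_equal(run_assay(d)$km, res$km)
})

test_that("assay velocities rise with substrate and with reaction probability", {
  d_lo <- assay_design(p_react = 0.25, duration_steps = 0L, replicates = 2L,
                       measurement_window = 300L, base_seed = 5L)
  d_hi <- assay_design(p_react = 1, duration_steps = 0L, replicates = 2L,
                       measurement_window = 300L, base_seed = 5L)
  v_lo <- run_assay(d_lo)$points$V
  v_hi <- run_assay(d_hi)$points$V
  expect_gt(stats::cor(seq_along(v_lo), v_lo), 0)    # increasing in S
  expect_gt(mean(v_hi), mean(v_lo))                  # increasing in p_react
})

test_that("the parameter scan is a tidy grid independent of iteration order", {
  d <- assay_design(substrate_concentrations = c(0.166, 0.332, 0.664),
                    replicates = 1L, measurement_window = 150L, base_seed = 9L)
  tab <- parameter_scan(c(0.5, 1), c(0L, 5L), d)
  expect_equal(nrow(tab), 4L)
  expect_setequal(names(tab),
                  c("p_react", "duration_steps", "km", "vmax", "kcat", "r_squared"))
  tab2 <- parameter_scan(c(1, 0.5), c(5L, 0L), d)
  key <- function(t) t[order(t$p_react, t$duration_steps), c("km", "kcat")]
  expect_equal(key(tab), key(tab2), ignore_attr = TRUE)
  # a 1x1 grid reduces to a (cell-seeded) single assay
  one <- parameter_scan(0.5, 0L, d)
  d1 <- d
  d1$p_react <- 0.5; d1$duration_steps <- 0L
  d1$base_seed <- as.integer((9 + 7919 * 500) %% 2147483647)
  expect_equal(one$km, run_assay(d1)$km)
})

test_that("reference matching picks the closest usable scan row", {
  scan <- data.frame(p_react = c(0.25, 0.75, 0.95),
                     duration_steps = c(0, 50, 100),
                     km = c(0.9, 0.6, -0.2), kcat = c(1.1, 1.0, 0.5))
  refs <- data.frame(name = "exact", km = 0.6, kcat = 1.0)
  m <- match_to_reference(scan, refs)
  expect_equal(m$p_react, 0.75)
  expect_equal(m$distance, 0)
  # negative rows are excluded even when nominally closest
  refs2 <- data.frame(name = "neg", km = -0.2, kcat = 0.5)
  m2 <- match_to_reference(scan, refs2)
  expect_true(m2$km >= 0)
  expect_error(match_to_reference(scan[3, ], refs), "non-negative")
})

test_that("bundled tables load and the published pairings that the metric supports reproduce", {
  scan <- example_scan_table()
  refs <- reference_enzymes()
  expect_equal(nrow(scan), 29L)
  expect_equal(nrow(refs), 6L)
  m <- match_to_reference(scan, refs)
  expect_equal(nrow(m), 6L)
  # the scaled-Euclidean argmin reproduces the published pairing for
  # glutathione reductase and pyruvate decarboxylase
  glut <- m[m$name == "glutathione reductase", ]
  expect_equal(c(glut$p_react, glut$duration_steps), c(0.25, 100))
  expect_equal(glut$km, 0.531257304)
  pyr <- m[m$name == "pyruvate decarboxylase", ]
  expect_equal(c(pyr$p_react, pyr$duration_steps), c(0.25, 5))
  # negative-estimate rows never appear in matches
  expect_true(all(m$km >= 0 & m$kcat >= 0))
})
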