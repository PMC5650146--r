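test_that("make_world defaults state the emulated design and validate fields", {
  tr <- make_world(seed = 1)
  expect_equal(length(tr$primary_dates), 8L)
  expect_equal(tr$secondaries_per_primary, 3L)
  expect_equal(tr$marked_prop, 0.8)
  expect_equal(unname(tr$density_by_stratum[c("Inshore", "Island")]),
               c(1.09, 4.43))
  expect_equal(length(tr$phi_by_interval), 7L)
  expect_true(all(tr$phi_by_interval >= 0.3 & tr$phi_by_interval <= 0.85))

  expect_error(make_world(list(marked_prop = 0)), "marked_prop")
  expect_error(make_world(list(p0 = 1.2)), "p0")
  expect_error(make_world(list(density_by_stratum = c(Inshore = -1))),
               "density_by_stratum")
  expect_error(make_world(list(primary_dates = c("2010-01-01",
                                                 "2010-01-01"))),
               "primary_dates")
  expect_error(make_world(list(phi_by_interval = c(0.5, 0.5))),
               "phi_by_interval")
})

test_that("same config and seed reproduce identical truth and population", {
  a <- make_world(seed = 7); b <- make_world(seed = 7)
  expect_identical(a, b)
  pa <- simulate_population(a); pb <- simulate_population(b)
  expect_identical(pa, pb)
})

test_that("initial abundance follows the Poisson intensity", {
  # density 1.0 on a 100 km^2 single-stratum mask: expected 100 animals;
  # over 500 seeds the mean primary-1 count is within 3 SE of 100
  m <- water_mask(10)
  tr0 <- make_world(list(mask = m, density_by_stratum = c(Inshore = 1.0),
                         primary_dates = "2010-01-01",
                         phi_by_interval = numeric(0)), seed = 1)
  counts <- vapply(1:500, function(s) {
    sum(simulate_population(tr0, seed = s)$alive)
  }, numeric(1))
  se <- sqrt(100 / 500)                 # Poisson var / n seeds
  expect_lt(abs(mean(counts) - 100), 3 * se)
  expect_gt(stats::var(counts), 50)     # roughly Poisson dispersion
})

test_that("survival extremes behave exactly", {
  m <- water_mask(6)
  # phi = 0: no primary-1 animal survives to primary 2
  tr <- make_world(list(mask = m, density_by_stratum = c(Inshore = 2),
                        phi_by_interval = 0,
                        primary_dates = c("2010-01-01", "2010-07-01")),
                   seed = 2)
  pop <- simulate_population(tr)
  p1 <- pop[pop$primary == 1, ]; p2 <- pop[pop$primary == 2, ]
  expect_false(any(p2$alive[p2$id %in% p1$id]))
  # phi = 1: identical alive set across primaries (recruits ~ Poisson(0))
  tr1 <- make_world(list(mask = m, density_by_stratum = c(Inshore = 2),
                         phi_by_interval = 1,
                         primary_dates = c("2010-01-01", "2010-07-01",
                                           "2011-01-01")),
                    seed = 3)
  pop1 <- simulate_population(tr1)
  sets <- lapply(split(pop1, pop1$primary),
                 function(d) sort(d$id[d$alive]))
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[1]], sets[[3]])
  # no resurrection in the default world
  popd <- simulate_population(make_world(seed = 4))
  bad <- vapply(split(popd, popd$id), function(d) {
    a <- d$alive[order(d$primary)]
    any(diff(a) > 0)
  }, logical(1))
  expect_false(any(bad))
})

test_that("all generated locations lie on water", {
  tr <- make_world(seed = 5)
  pop <- simulate_population(tr)
  expect_true(all(dolphinCR:::on_water(tr$mask, pop$x, pop$y)))
  sg <- simulate_captures(tr, pop)
  expect_true(all(dolphinCR:::on_water(tr$mask, sg$x, sg$y)))
  tel <- simulate_telemetry(tr, n_animals = 3, duration_days = 20, seed = 5)
  expect_true(all(dolphinCR:::on_water(tr$mask, tel$x, tel$y)))
})

test_that("capture simulation honors detection extremes", {
  m <- water_mask(6)
  base <- list(mask = m, density_by_stratum = c(Inshore = 1),
               primary_dates = c("2010-01-01", "2010-07-01"),
               phi_by_interval = 1)
  # p0 = 1 and a transect through every cell row: detected on every occasion
  tr <- make_world(c(base, p0 = 1), seed = 6)
  pop <- simulate_population(tr)
  sg <- simulate_captures(tr, pop, transects = default_transects(m, 1))
  n_alive <- sum(pop$alive & pop$primary == 1)
  per_occ <- table(sg$primary, sg$secondary)
  expect_true(all(per_occ == n_alive))
  # p0 = 0: empty table
  tr0 <- make_world(c(base, p0 = 0), seed = 6)
  sg0 <- simulate_captures(tr0, simulate_population(tr0))
  expect_equal(nrow(sg0), 0L)
  expect_error(simulate_captures(tr, pop, transects = list()),
               "empty transects")
})

test_that("per-primary detection counts are Binomial(K, p_eff)", {
  # one animal, transect placed so d gives p_eff = 0.5, 3 occasions
  m <- water_mask(9)
  tr <- make_world(list(mask = m, density_by_stratum = c(Inshore = 1),
                        p0 = 0.8, sigma_det = 1.5,
                        primary_dates = "2010-01-01",
                        phi_by_interval = numeric(0)), seed = 1)
  # place the transect at distance d with 0.8 exp(-d^2/4.5) = 0.5
  d <- sqrt(-2 * 1.5^2 * log(0.5 / 0.8))
  pop <- data.frame(primary = 1L, id = "M00001", cell_row = 5L,
                    cell_col = 5L, x = 4.5, y = 4.5, alive = TRUE,
                    marked = TRUE)
  tr$sigma_loc <- 0.01
  transects <- list(cbind(c(0, 9), c(4.5 + d, 4.5 + d)))
  counts <- vapply(1:2000, function(s) {
    nrow(simulate_captures(tr, pop, transects, seed = s))
  }, numeric(1))
  obs <- tabulate(counts + 1L, nbins = 4L)   # 0..3 detections
  expected <- 2000 * stats::dbinom(0:3, 3, 0.5)
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, stats::qchisq(0.99, df = 3))
})

test_that("telemetry simulation is seeded, bounded, and validates starts", {
  tr <- make_world(seed = 8)
  cfg <- list(tag_life = c(50, 50), fixes_per_day = 6)
  t1 <- simulate_telemetry(tr, n_animals = 2, duration_days = 50,
                           seed = 9, config = cfg)
  t2 <- simulate_telemetry(tr, n_animals = 2, duration_days = 50,
                           seed = 9, config = cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 2 * 50 * 6)
  expect_true(all(diff(as.numeric(t1$timestamp[t1$id == "T001"])) > 0))
  expect_true(all(t1$lc %in% c("3", "2", "1", "0", "A", "B")))
  # zero measurement error: fixes coincide across error settings
  cfg0 <- c(cfg, list(lc_sd = c(`3` = 0, `2` = 0, `1` = 0, `0` = 0,
                                A = 0, B = 0)))
  t0 <- simulate_telemetry(tr, n_animals = 1, duration_days = 10,
                           seed = 10, config = cfg0)
  expect_true(all(dolphinCR:::on_water(tr$mask, t0$x, t0$y)))
  # start position on land errors
  land_start <- matrix(c(5, 11.5), 1)     # mainland strip of default mask
  expect_error(simulate_telemetry(tr, n_animals = 1, duration_days = 5,
                                  seed = 1,
                                  config = list(start_xy = land_start)),
               "start not on water")
  expect_error(simulate_telemetry(tr, n_animals = 0), "n_animals")
})

test_that("truth round-trips through YAML", {
  tr <- make_world(list(p0 = 0.33, marked_prop = 0.9), seed = 12)
  f <- tempfile(fileext = ".yaml")
  fm <- tempfile(fileext = ".csv")
  write_mask_csv(tr$mask, fm)
  write_truth_yaml(tr, f, mask_path = fm)
  tr2 <- read_truth_yaml(f)
  expect_equal(tr2$p0, 0.33)
  expect_equal(tr2$marked_prop, 0.9)
  expect_equal(tr2$primary_dates, tr$primary_dates)
  expect_equal(tr2$mask$stratum, tr$mask$stratum)
})
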