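test_that("credible_interval implements the tail-discarding contract", {
  expect_equal(credible_interval(1:1000, 0.95), c(26, 975))
  expect_equal(credible_interval(rep(3.3, 100), 0.95), c(3.3, 3.3))
  set.seed(51)
  u <- runif(1e5)
  ci <- credible_interval(u, 0.95)
  expect_equal(ci[1], 0.025, tolerance = 0.005 / 0.025)
  expect_equal(ci[2], 0.975, tolerance = 0.005 / 0.975)
  expect_error(credible_interval(1:39, 0.95), "too few")
  expect_silent(credible_interval(1:40, 0.95))
})

test_that("survival annualization follows the 365.25-day exponent", {
  draws <- matrix(0.9, 100, 1)
  a <- annualize_survival(draws, delta_days = 365.25 / 2)
  expect_equal(a$by_interval$est, 0.81)
  a1 <- annualize_survival(matrix(0.73, 100, 1), delta_days = 365.25)
  expect_equal(a1$by_interval$est, 0.73)
  expect_error(annualize_survival(draws, delta_days = -1), "> 0")
  expect_error(annualize_survival(draws, delta_days = c(1, 2)),
               "one entry per interval")
  # the four printed yr1 annualized point estimates average to 0.710
  yr1 <- c(0.723, 0.812, 0.561, 0.745)
  expect_equal(round(mean(yr1), 3), 0.710)
  d4 <- matrix(rep(yr1, each = 50), 50, 4)
  ay <- annualize_survival(d4, delta_days = rep(365.25, 4),
                           year_map = rep("yr1", 4))
  expect_equal(ay$by_year$est, 0.71025)
  # monotonicity of annualization in phi
  phis <- c(0.3, 0.5, 0.8)
  ann <- phis^(365.25 / 180)
  expect_true(all(diff(ann) > 0))
  # NA year assignment drops the interval from yearly averages
  ay2 <- annualize_survival(d4, delta_days = rep(365.25, 4),
                            year_map = c("yr1", "yr1", "yr1", NA))
  expect_equal(ay2$by_year$est, mean(yr1[1:3]))
})

test_that("density inflation and abundance extrapolation are per-draw identities", {
  # synthetic draws object with known density draws
  Tn <- 2
  dens <- array(0, c(100, Tn, 3),
                dimnames = list(NULL, NULL,
                                c("Inshore", "Island", "Offshore")))
  dens[, , "Inshore"] <- matrix(rep(c(1.05, 0.95), each = 100), 100, 2)
  dens[, , "Island"] <- matrix(rep(c(4.78, 4.2), each = 100), 100, 2)
  draws <- structure(list(density = dens, n_primary = Tn,
                          phi = matrix(0.8, 100, 1)),
                     class = "secr_draws")
  de <- summarize_density(draws, marked_prop = 1.0)
  # marked density 0.8 at proportion 0.8 gives total 1.0
  d8 <- draws; d8$density[, , "Inshore"] <- 0.8
  expect_equal(summarize_density(d8, 0.8)$density[1, 1, "Inshore"], 1.0,
               ignore_attr = TRUE)
  expect_equal(1 / 0.8, 1.25)
  # constant draws give a degenerate CI at the constant
  expect_equal(de$table$lo[de$table$primary == 1 &
                           de$table$stratum == "Inshore"], 1.05)
  expect_equal(de$table$hi[de$table$primary == 1 &
                           de$table$stratum == "Inshore"], 1.05)
  ab <- extrapolate_abundance(de, stratum_areas())
  # period-1 arithmetic: 4.78 * 242 + 1.05 * 2196 = 3462.56, density 1.42
  expect_equal(ab$total$abundance[1], 4.78 * 242 + 1.05 * 2196)
  expect_equal(round(ab$total$density[1], 2), 1.42)
  # per-draw identity: abundance = density x area, exactly
  expect_equal(ab$draws_abundance[, 1, "Island"],
               de$density[, 1, "Island"] * 242)
  expect_equal(ab$draws_total,
               ab$draws_abundance[, , "Inshore"] +
               ab$draws_abundance[, , "Island"], ignore_attr = TRUE)
  expect_equal(ab$draws_overall, ab$draws_total / 2438)
  # zero density gives zero abundance
  z <- draws; z$density[] <- 0
  expect_equal(extrapolate_abundance(summarize_density(z, 1),
                                     stratum_areas())$total$abundance,
               rep(0, Tn))
  # missing area errors
  expect_error(extrapolate_abundance(de, stratum_areas(c(Island = 242))),
               "missing stratum areas")
  expect_error(summarize_density(draws, 0), "positive marked proportion")
})

test_that("stratum mean densities reproduce the printed mean abundances", {
  # means of printed per-period values: 4.43 and 1.09 dolphins km^-2
  expect_equal(round(4.43 * 242, 0), 1072)   # paper prints 1074 (posterior)
  expect_equal(round(1.09 * 2196, 0), 2394)  # paper prints 2395
})

test_that("the complete-detection closed run concentrates on the observed count", {
  m <- water_mask(8)
  tr <- make_world(list(mask = m, density_by_stratum = c(Inshore = 1.5),
                        p0 = 0.95, sigma_det = 1.5,
                        primary_dates = "2010-01-01",
                        phi_by_interval = numeric(0), marked_prop = 1),
                   seed = 52)
  pop <- simulate_population(tr)
  sg <- simulate_captures(tr, pop)
  h <- build_capture_histories(sg, 1, 3)
  fit <- suppressWarnings(
    fit_model(h, m, model_config(M = length(h$ids) + 60,
                                 transects = default_transects(m),
                                 fix_p0 = TRUE, fix_sigma = TRUE,
                                 p0_init = 0.95, sigma_init = 1.5,
                                 n_iter = 800, burn = 300, chains = 2,
                                 seed = 52)))
  n_obs <- length(h$ids)
  Nhat <- mean(fit$N[, 1, "Inshore"])
  # with p0 = 0.95 over 3 occasions the undetected fraction is ~1e-4
  expect_lt(abs(Nhat - n_obs), 1.5)
})

test_that("closed single-primary fit agrees with a brute-force M0 likelihood", {
  m <- water_mask(8)
  tr <- make_world(list(mask = m, density_by_stratum = c(Inshore = 1.5),
                        p0 = 0.45, sigma_det = 2,
                        primary_dates = "2010-01-01",
                        phi_by_interval = numeric(0), marked_prop = 1),
                   seed = 53)
  pop <- simulate_population(tr)
  sg <- simulate_captures(tr, pop)
  h <- build_capture_histories(sg, 1, 3)
  n <- length(h$ids)
  # transects run through every row, so detection is near-uniform in space;
  # brute-force M0: maximize binomial likelihood over (N, p) by enumeration
  ndet_total <- sum(h$n_det)
  ll_m0 <- function(N, p) {
    lchoose(N, n) + ndet_total * log(p) +
      (3 * N - ndet_total) * log(1 - p)
  }
  grid_N <- n:(4 * n)
  grid_p <- seq(0.05, 0.95, by = 0.005)
  ll <- outer(grid_N, grid_p, Vectorize(ll_m0))
  N_mle <- grid_N[which(ll == max(ll), arr.ind = TRUE)[1, 1]]
  fit <- suppressWarnings(
    fit_model(h, m, model_config(M = 4 * n,
                                 n_iter = 1500, burn = 500, chains = 2,
                                 seed = 53)))
  Nhat <- mean(fit$N[, 1, "Inshore"])
  # agreement within Monte Carlo + prior slack on a ~90-animal instance
  expect_lt(abs(Nhat - N_mle) / N_mle, 0.12)
})

test_that("fit_model validates inputs and flags exhausted augmentation", {
  m <- water_mask(6)
  empty <- build_capture_histories(
    triplet_sightings(id = "", primary = 1, secondary = 1), 1, 1)
  expect_error(fit_model(empty, m), "empty capture histories")
  tr <- make_world(list(mask = m, density_by_stratum = c(Inshore = 2),
                        p0 = 0.9, sigma_det = 1.5,
                        primary_dates = c("2010-01-01", "2010-07-01"),
                        phi_by_interval = 0.9, marked_prop = 1), seed = 54)
  sg <- simulate_captures(tr, simulate_population(tr))
  h <- build_capture_histories(sg, 2, 3)
  expect_error(suppressWarnings(
    fit_model(h, m, model_config(M = length(h$ids) + 1, n_iter = 400,
                                 burn = 100, chains = 1, seed = 1))),
    "augmentation exhausted")
  expect_error(fit_model(h, m, model_config(M = length(h$ids) - 5)),
               "exceed observed")
})

test_that("fits are reproducible for a fixed seed", {
  m <- water_mask(6)
  tr <- make_world(list(mask = m, density_by_stratum = c(Inshore = 1.5),
                        p0 = 0.5, sigma_det = 1.5,
                        primary_dates = c("2010-01-01", "2010-07-01"),
                        phi_by_interval = 0.8, marked_prop = 1), seed = 55)
  sg <- simulate_captures(tr, simulate_population(tr))
  h <- build_capture_histories(sg, 2, 3)
  cfg <- model_config(M = 120, n_iter = 400, burn = 100, chains = 2,
                      seed = 9)
  f1 <- suppressWarnings(fit_model(h, m, cfg))
  f2 <- suppressWarnings(fit_model(h, m, cfg))
  expect_identical(f1$p0, f2$p0)
  expect_identical(f1$N, f2$N)
  # posterior draws satisfy their range invariants
  expect_true(all(f1$phi >= 0 & f1$phi <= 1))
  expect_true(all(f1$density >= 0, na.rm = TRUE))
  expect_equal(length(f1$p0), 2 * 300)
})
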