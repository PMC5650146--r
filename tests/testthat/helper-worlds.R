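# Shared fixtures: all built in code, no files.

# small barrier-island world used for parameter-recovery tests:
# a 16 x 10 km sound, mainland strip along the north, one island in the south
recovery_mask <- function() {
  mainland <- list(cbind(c(0, 16, 16, 0), c(9, 9, 10, 10)))
  island <- list(cbind(c(5, 11, 11, 5), c(1.4, 1.4, 2.6, 2.6)))
  build_mask(mainland, island,
             list(origin = c(0, 0), nx = 16, ny = 10, cell_size = 1))
}

# the stated recovery world: D_Inshore = 1, D_Island = 4, p0 = 0.4,
# sigma = 1.5 km, phi = 0.8, 8 primaries x 3 secondaries, all marked
recovery_world <- function(seed) {
  make_world(list(mask = recovery_mask(),
                  density_by_stratum = c(Inshore = 1.0, Island = 4.0,
                                         Offshore = 0),
                  p0 = 0.4, sigma_det = 1.5,
                  phi_by_interval = rep(0.8, 7), marked_prop = 1),
             seed = seed)
}

# all-water square mask
water_mask <- function(n = 10, cell_size = 1) {
  build_mask(list(), list(),
             list(origin = c(0, 0), nx = n, ny = n, cell_size = cell_size))
}

# realized mean marked density per stratum of a simulated population
realized_density <- function(pop, mask, stratum) {
  cells <- mask_cells(mask)
  strat <- cells$stratum[(pop$cell_row - 1L) * mask$nx + pop$cell_col]
  mean(tapply(pop$alive & strat == stratum, pop$primary, sum)) /
    stratum_area(mask, stratum)
}

# hand-rolled hotspot_set for overlap tests
fake_hotset <- function(cells, month = "m", alpha = 0.05, nx = 50, ny = 50) {
  structure(list(month = month, alpha = alpha,
                 cells = matrix(cells, ncol = 2,
                                dimnames = list(NULL, c("row", "col"))),
                 nx = nx, ny = ny), class = "hotspot_set")
}

# small sighting table from explicit (id, primary, secondary) triplets
triplet_sightings <- function(id, primary, secondary,
                              x = 1.5, y = 1.5) {
  data.frame(id = id, primary = primary, secondary = secondary,
             x = x, y = y,
             distinctiveness = ifelse(nzchar(id), "D1", "unmarked"),
             group_id = paste0("G", seq_along(id)),
             group_size = 1L,
             date = as.Date("2010-07-01") + primary,
             stringsAsFactors = FALSE)
}
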