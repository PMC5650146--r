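# Synthetic worlds with known truth: habitat, population dynamics, photo-ID
# captures and Argos-like telemetry. The generator mirrors the structure the
# estimation model assumes (activity centers on water, half-normal detection
# to effort lines, survival between primaries, stationary recruitment) so
# every downstream stage can be tested against known parameter values.

#' Default synthetic habitat mask
#'
#' A reduced-scale barrier-island sound: a 30 x 12 km extent with a mainland
#' strip along the northern edge and two barrier islands in the south,
#' gridded at 1 km. Stratum rules are the standard ones: Island within 1 km
#' of an island (plus the pass corridor between the two islands), Offshore
#' 1-2 km out, Inshore elsewhere.
#'
#' @param nx,ny,cell_size grid dimensions (km).
#' @return a \code{habitat_mask}.
#' @export
default_mask <- function(nx = 30, ny = 12, cell_size = 1) {
  W <- nx * cell_size; H <- ny * cell_size
  mainland <- list(rect_poly(0, H - cell_size, W, H))
  islands <- list(rect_poly(4, 1.4, 10, 2.6), rect_poly(14, 1.4, 22, 2.6))
  pass <- list(rect_poly(10, 0.9, 14, 3.1))   # 2-km-wide pass between islands
  build_mask(land_polygons = mainland, island_polygons = islands,
             grid_spec = list(origin = c(0, 0), nx = nx, ny = ny,
                              cell_size = cell_size),
             pass_corridors = pass)
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Default survey transects
#'
#' East-west effort lines spaced 1 km apart spanning the full water extent,
#' emulating complete coverage of the study area in each secondary occasion.
#'
#' @param mask habitat mask giving the extent.
#' @param spacing line spacing (km).
#' @return list of polyline matrices.
#' @export
default_transects <- function(mask, spacing = 1) {
  x0 <- mask$origin[1]; x1 <- mask$origin[1] + mask$nx * mask$cell_size
  ys <- seq(mask$origin[2] + spacing / 2,
            mask$origin[2] + mask$ny * mask$cell_size - spacing / 2,
            by = spacing)
  lapply(ys, function(y) cbind(c(x0, x1), c(y, y)))
}

#' Assemble a synthetic truth object
#'
#' Packages the generative parameters of a synthetic world. Defaults state
#' the emulated study: 8 primary periods of 3 secondary occasions, stratum
#' densities 1.09 (Inshore) and 4.43 (Island) dolphins per km^2, marked
#' proportion 0.8, and per-interval survival spanning roughly 0.3-0.85.
#'
#' @param config named list overriding any field: \code{mask},
#'   \code{density_by_stratum}, \code{p0}, \code{sigma_det},
#'   \code{sigma_move}, \code{sigma_loc}, \code{phi_by_interval},
#'   \code{marked_prop}, \code{primary_dates}, \code{secondaries_per_primary}.
#' @param seed integer seed recorded in the truth and used by the
#'   simulation functions by default.
#' @return object of class \code{dolphin_truth}.
#' @export
make_world <- function(config = list(), seed = 1L) {
  # YAML-sourced configs arrive with list-valued numeric fields
  for (f in c("density_by_stratum", "phi_by_interval", "primary_dates"))
    if (!is.null(config[[f]])) config[[f]] <- unlist(config[[f]])
  t <- list(
    mask = config$mask %||% default_mask(),
    density_by_stratum = config$density_by_stratum %||%
      c(Inshore = 1.09, Island = 4.43, Offshore = 0),
    p0 = config$p0 %||% 0.4,
    sigma_det = config$sigma_det %||% 1.5,
    sigma_move = config$sigma_move %||% config$sigma_det %||% 1.5,
    sigma_loc = config$sigma_loc %||% config$sigma_det %||% 1.5,
    phi_by_interval = config$phi_by_interval %||%
      c(0.723, 0.812, 0.561, 0.745, 0.520, 0.686, 0.314),
    marked_prop = config$marked_prop %||% 0.8,
    primary_dates = as.Date(config$primary_dates %||%
      c("2010-07-10", "2010-10-17", "2011-03-17", "2011-05-14",
        "2011-07-16", "2011-10-10", "2012-01-10", "2012-05-17")),
    secondaries_per_primary = config$secondaries_per_primary %||% 3L,
    seed = as.integer(seed)
  )
  if (any(t$density_by_stratum < 0)) stop("density_by_stratum must be >= 0")
  # boundary values 0 and 1 are admitted for degenerate test worlds
  if (t$p0 < 0 || t$p0 > 1) stop("p0 must be in [0, 1]")
  if (t$sigma_det <= 0) stop("sigma_det must be > 0")
  if (any(t$phi_by_interval < 0 | t$phi_by_interval > 1))
    stop("phi_by_interval must be in [0, 1]")
  if (t$marked_prop <= 0 || t$marked_prop > 1)
    stop("marked_prop must be in (0, 1]")
  if (any(diff(as.numeric(t$primary_dates)) <= 0))
    stop("primary_dates must be strictly increasing")
  n_int <- length(t$primary_dates) - 1L
  if (n_int == 0L) {
    t$phi_by_interval <- numeric(0)
  } else if (length(t$phi_by_interval) == 1L) {
    t$phi_by_interval <- rep(t$phi_by_interval, n_int)
  }
  if (length(t$phi_by_interval) != n_int)
    stop("phi_by_interval must have one value per inter-primary interval")
  class(t) <- "dolphin_truth"
  t
}

#' @export
print.dolphin_truth <- function(x, ...) {
  cat(sprintf(paste0("dolphin_truth: %d primaries x %d secondaries, ",
                     "p0=%.2f sigma=%.2f marked=%.2f seed=%d\n"),
              length(x$primary_dates), x$secondaries_per_primary,
              x$p0, x$sigma_det, x$marked_prop, x$seed))
  cat("densities (km^-2):",
      paste(names(x$density_by_stratum), x$density_by_stratum,
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

# intensity (expected animals) per water cell
cell_intensity <- function(truth) {
  cells <- mask_cells(truth$mask)
  lam <- rep(0, nrow(cells))
  w <- cells$water
  lam[w] <- truth$density_by_stratum[cells$stratum[w]] *
    truth$mask$cell_size^2
  lam[is.na(lam)] <- 0
  list(cells = cells, lambda = lam)
}

draw_centers <- function(n, cells, lambda) {
  if (n == 0L) return(integer(0))
  sample.int(nrow(cells), n, replace = TRUE, prob = lambda)
}

#' Simulate the latent population across primary periods
#'
#' Primary-1 activity centers are an inhomogeneous Poisson process with the
#' truth's stratum intensities over water cells. Between primaries each
#' animal survives its interval with probability phi and takes a
#' water-restricted Gaussian step (scale \code{sigma_move}); Poisson
#' recruitment with centers drawn from the stationary intensity keeps the
#' expected density constant. Dead animals never return.
#'
#' @param truth a \code{dolphin_truth}.
#' @param seed seed (defaults to the truth's).
#' @return data.frame(primary, id, cell_row, cell_col, x, y, alive, marked)
#'   of class \code{population_state}; one row per ever-recruited animal per
#'   primary from its recruitment onward.
#' @export
simulate_population <- function(truth, seed = truth$seed) {
  set.seed(seed)
  ci <- cell_intensity(truth)
  cells <- ci$cells; lambda <- ci$lambda
  Tn <- length(truth$primary_dates)
  total <- sum(lambda)
  if (total <= 0) stop("truth has zero expected population on water")

  n0 <- stats::rpois(1, total)
  idx <- draw_centers(n0, cells, lambda)
  pop <- data.frame(id = sprintf("M%05d", seq_len(n0)), cell = idx,
                    alive = TRUE,
                    marked = stats::runif(n0) < truth$marked_prop,
                    stringsAsFactors = FALSE)
  next_id <- n0 + 1L
  out <- list()
  snap <- function(t) data.frame(primary = t, id = pop$id,
                                 cell_row = cells$row[pop$cell],
                                 cell_col = cells$col[pop$cell],
                                 x = cells$x[pop$cell], y = cells$y[pop$cell],
                                 alive = pop$alive, marked = pop$marked,
                                 stringsAsFactors = FALSE)
  out[[1]] <- snap(1L)
  for (t in seq_len(Tn - 1L)) {
    phi <- truth$phi_by_interval[t]
    surv <- pop$alive & (stats::runif(nrow(pop)) < phi)
    pop$alive <- surv
    # dispersal of surviving centers: intensity-weighted Gaussian kernel
    # over water cells, so the stratified density stays (near-)stationary
    mv <- which(pop$alive)
    if (length(mv)) {
      pop$cell[mv] <- vapply(pop$cell[mv], function(c0) {
        w <- lambda * exp(-((cells$x - cells$x[c0])^2 +
                            (cells$y - cells$y[c0])^2) /
                          (2 * truth$sigma_move^2))
        sample.int(nrow(cells), 1L, prob = w)
      }, integer(1))
    }
    n_rec <- stats::rpois(1, total * (1 - phi))
    if (n_rec > 0) {
      rec <- data.frame(id = sprintf("M%05d", next_id + seq_len(n_rec) - 1L),
                        cell = draw_centers(n_rec, cells, lambda),
                        alive = TRUE,
                        marked = stats::runif(n_rec) < truth$marked_prop,
                        stringsAsFactors = FALSE)
      next_id <- next_id + n_rec
      pop <- rbind(pop, rec)
    }
    out[[t + 1L]] <- snap(t + 1L)
  }
  res <- do.call(rbind, out)
  class(res) <- c("population_state", "data.frame")
  attr(res, "seed") <- seed
  res
}

# water-restricted point jitter around (x0, y0)
water_jitter <- function(mask, x0, y0, sigma, max_try = 100L) {
  for (i in seq_len(max_try)) {
    x <- x0 + stats::rnorm(1, 0, sigma)
    y <- y0 + stats::rnorm(1, 0, sigma)
    if (on_water(mask, x, y)) return(c(x, y))
  }
  c(x0, y0)
}

#' Simulate photo-ID capture records
#'
#' On each secondary occasion every alive animal is detected with
#' probability p0 * exp(-d^2 / (2 sigma_det^2)), d being the distance from
#' its activity center to the nearest effort line. Detected marked animals
#' yield identified rows; detections of unmarked animals yield count-only
#' rows with blank ID. Recorded locations are the activity center plus
#' water-restricted Gaussian noise (scale \code{sigma_loc}).
#'
#' @param truth a \code{dolphin_truth}; @param population output of
#'   \code{simulate_population}; @param transects list of polylines.
#' @param seed seed.
#' @return a \code{sighting_table} data.frame (id, primary, secondary, x, y,
#'   distinctiveness, group_id, group_size, date).
#' @export
simulate_captures <- function(truth, population,
                              transects = default_transects(truth$mask),
                              seed = truth$seed + 1L) {
  if (length(transects) == 0L) stop("empty transects")
  set.seed(seed)
  cells <- mask_cells(truth$mask)
  d_eff <- dist_to_polylines(cells$x, cells$y, transects)
  Tn <- length(truth$primary_dates); K <- truth$secondaries_per_primary
  # fixed distinctiveness class per marked individual
  ids <- unique(population$id)
  dclass <- stats::setNames(ifelse(stats::runif(length(ids)) < 0.4,
                                   "D1", "D2"), ids)
  rows <- list()
  for (t in seq_len(Tn)) {
    pt <- population[population$primary == t & population$alive, ]
    if (!nrow(pt)) next
    cell_id <- (pt$cell_row - 1L) * truth$mask$nx + pt$cell_col
    d <- d_eff[cell_id]
    p_eff <- truth$p0 * exp(-d^2 / (2 * truth$sigma_det^2))
    for (k in seq_len(K)) {
      det <- stats::runif(nrow(pt)) < p_eff
      if (!any(det)) next
      di <- which(det)
      loc <- t(vapply(di, function(i) {
        water_jitter(truth$mask, pt$x[i], pt$y[i], truth$sigma_loc)
      }, numeric(2)))
      rows[[length(rows) + 1L]] <- data.frame(
        id = ifelse(pt$marked[di], pt$id[di], ""),
        primary = t, secondary = k, x = loc[, 1], y = loc[, 2],
        distinctiveness = ifelse(pt$marked[di], dclass[pt$id[di]],
                                 "unmarked"),
        date = truth$primary_dates[t] + 2L * (k - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    st <- data.frame(id = character(0), primary = integer(0),
                     secondary = integer(0), x = numeric(0), y = numeric(0),
                     distinctiveness = character(0), group_id = character(0),
                     group_size = integer(0), date = as.Date(character(0)))
    class(st) <- c("sighting_table", "data.frame")
    return(st)
  }
  st <- do.call(rbind, rows)
  # group sightings: detections within a 3-km spatial bin on one occasion
  bin <- paste(st$primary, st$secondary,
               floor(st$x / 3), floor(st$y / 3), sep = "_")
  st$group_id <- paste0("G", match(bin, unique(bin)))
  st$group_size <- as.integer(ave(rep(1L, nrow(st)), bin, FUN = sum))
  st <- st[, c("id", "primary", "secondary", "x", "y", "distinctiveness",
               "group_id", "group_size", "date")]
  rownames(st) <- NULL
  class(st) <- c("sighting_table", "data.frame")
  attr(st, "seed") <- seed
  st
}

#' Simulate Argos-like satellite telemetry
#'
#' Each animal follows a water-restricted Ornstein-Uhlenbeck walk around a
#' home center, sampled several times daily. Fixes receive an Argos location
#' class from a multinomial and class-specific Gaussian error (redrawn until
#' on water). Tag failure day is uniform in \code{tag_life} (days).
#'
#' @param truth a \code{dolphin_truth} (supplies the mask).
#' @param n_animals number of tagged animals.
#' @param duration_days maximum tracking window.
#' @param seed seed.
#' @param config optional list: \code{start_date} (default "2013-08-01"),
#'   \code{fixes_per_day} (6), \code{lc_probs} (named, classes 3,2,1,0,A,B),
#'   \code{lc_sd} km (3: 0.125, 2: 0.25, 1: 0.75, others 1.5),
#'   \code{tag_life} c(min, max) days (c(73, 253)), \code{step_sd} (0.7 km),
#'   \code{attraction} (0.05), \code{start_xy} optional n x 2 matrix.
#' @return a \code{telemetry_table} data.frame (id, timestamp, lc, x, y).
#' @export
simulate_telemetry <- function(truth, n_animals = 19L, duration_days = 253L,
                               seed = truth$seed + 2L, config = list()) {
  if (n_animals < 1L) stop("n_animals must be >= 1")
  if (duration_days < 1L) stop("duration_days must be >= 1")
  set.seed(seed)
  mask <- truth$mask
  cells <- mask_cells(mask)
  wat <- which(cells$water)
  fpd <- config$fixes_per_day %||% 6L
  lc_probs <- config$lc_probs %||% c(`3` = 0.35, `2` = 0.35, `1` = 0.15,
                                     `0` = 0.05, A = 0.05, B = 0.05)
  lc_sd <- config$lc_sd %||% c(`3` = 0.125, `2` = 0.25, `1` = 0.75,
                               `0` = 1.5, A = 1.5, B = 1.5)
  tag_life <- config$tag_life %||% c(73, 253)
  step_sd <- config$step_sd %||% 0.7
  kappa <- config$attraction %||% 0.05
  t0 <- as.POSIXct(paste(config$start_date %||% "2013-08-01", "00:00:00"),
                   tz = "UTC")
  out <- list()
  for (a in seq_len(n_animals)) {
    if (!is.null(config$start_xy)) {
      home <- as.numeric(config$start_xy[a, ])
      if (!on_water(mask, home[1], home[2])) stop("start not on water")
    } else {
      c0 <- sample(wat, 1)
      home <- c(cells$x[c0], cells$y[c0])
    }
    life <- min(duration_days,
                floor(stats::runif(1, tag_life[1], tag_life[2] + 1)))
    n_steps <- life * fpd
    pos <- home
    xs <- ys <- numeric(n_steps)
    for (s in seq_len(n_steps)) {
      for (try in seq_len(50L)) {
        cand <- pos + kappa * (home - pos) + stats::rnorm(2, 0, step_sd)
        if (on_water(mask, cand[1], cand[2])) { pos <- cand; break }
      }
      xs[s] <- pos[1]; ys[s] <- pos[2]
    }
    lc <- sample(names(lc_probs), n_steps, replace = TRUE, prob = lc_probs)
    obs <- t(vapply(seq_len(n_steps), function(s) {
      sd_s <- lc_sd[[lc[s]]]
      if (sd_s == 0) c(xs[s], ys[s]) else
        water_jitter(mask, xs[s], ys[s], sd_s)
    }, numeric(2)))
    ts <- t0 + ((seq_len(n_steps) - 1) * (86400 / fpd)) +
      stats::runif(n_steps, 0, 3600)
    out[[a]] <- data.frame(id = sprintf("T%03d", a), timestamp = ts,
                           lc = lc, x = obs[, 1], y = obs[, 2],
                           stringsAsFactors = FALSE)
  }
  tt <- do.call(rbind, out)
  rownames(tt) <- NULL
  class(tt) <- c("telemetry_table", "data.frame")
  attr(tt, "seed") <- seed
  tt
}

#' Serialize / restore a truth configuration (YAML)
#' @export
write_truth_yaml <- function(truth, path, mask_path = NULL) {
  cfg <- truth[setdiff(names(truth), "mask")]
  cfg$primary_dates <- as.character(cfg$primary_dates)
  cfg$mask_path <- mask_path
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path, mask = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(mask) && !is.null(cfg$mask_path)) {
    mask <- read_mask_csv(cfg$mask_path)
  }
  seed <- cfg$seed %||% 1L
  cfg$seed <- NULL; cfg$mask_path <- NULL
  cfg$mask <- mask
  cfg$density_by_stratum <- unlist(cfg$density_by_stratum)
  cfg$phi_by_interval <- unlist(cfg$phi_by_interval)
  make_world(cfg, seed = seed)
}
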