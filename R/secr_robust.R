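# Bayesian spatially-explicit robust-design capture-recapture. The closed
# portion of each primary period is a spatial capture-recapture model on the
# habitat-mask cells (half-normal detection to the surveyed effort lines);
# the open portion links primaries through survival with water-restricted
# activity-center dispersal, with recruitment absorbed by data augmentation.
# Densities come out on the marked-animal scale and are inflated to the
# total-population scale by the per-primary marked proportion downstream.

#' Model configuration for \code{fit_model}
#'
#' @param M data-augmentation size (total real + pseudo individuals); must
#'   comfortably exceed the plausible marked population inside the mask.
#' @param transects effort polylines (list of matrices); detection decays
#'   half-normally with distance from the activity center to the nearest
#'   line.
#' @param sigma_move dispersal scale (km) of activity centers between
#'   primaries; a fixed convention, not estimated.
#' @param n_iter,burn,thin,chains MCMC controls (per chain).
#' @param seed integer; chain c uses seed + c - 1.
#' @param prior_sigma_sd half-normal prior SD for the detection scale (km).
#' @param prior_beta_sd normal prior SD for stratum log-intensity
#'   coefficients.
#' @param prop_p0,prop_sigma,prop_beta random-walk proposal SDs.
#' @param r_prop neighborhood radius (km) for center proposals.
#' @param fix_p0,fix_sigma optionally fix detection parameters (testing).
#' @param p0_init,sigma_init initial values.
#' @param interval_days days between consecutive primary mid-dates (length
#'   T-1); used by survival annualization downstream.
#' @export
model_config <- function(M = NULL, transects = NULL, sigma_move = 1.5,
                         n_iter = 3000L, burn = 1000L, thin = 1L,
                         chains = 3L, seed = 1L,
                         prior_sigma_sd = 10, prior_beta_sd = 3,
                         prop_p0 = 0.15, prop_sigma = 0.08, prop_beta = 0.25,
                         r_prop = 3, fix_p0 = FALSE, fix_sigma = FALSE,
                         p0_init = 0.3, sigma_init = 1.0,
                         interval_days = NULL) {
  if (n_iter <= burn) stop("n_iter must exceed burn")
  as.list(environment())
}

#' Fit the spatially-explicit robust-design model
#'
#' MCMC over data-augmented individuals: monotone alive-intervals (entry by
#' per-primary gamma, exit by per-interval survival phi) sampled exactly by
#' enumeration; activity centers on water cells with stratum log-intensity
#' prior exp(beta_Island or beta_Offshore) and Gaussian between-primary
#' dispersal truncated to water; half-normal detection
#' p = p0 exp(-d^2 / 2 sigma^2) per secondary occasion, with per-primary
#' mean sighting locations Gaussian around the center (shared sigma).
#'
#' @param histories a \code{capture_history_set}.
#' @param mask a \code{habitat_mask}.
#' @param config a \code{model_config()} list.
#' @return object of class \code{secr_draws} with per-draw parameters and
#'   realized marked densities per primary and stratum, plus split-Rhat
#'   diagnostics.
#' @export
fit_model <- function(histories, mask, config = model_config()) {
  n_obs <- length(histories$ids)
  if (n_obs == 0L) stop("empty capture histories")
  Tn <- histories$n_primary; K <- histories$n_secondary
  M <- config$M %||% (n_obs + max(100L, n_obs))
  if (M <= n_obs) stop("augmentation size M must exceed observed count")
  transects <- config$transects %||% default_transects(mask)

  cells <- mask_cells(mask)
  wat <- which(cells$water)
  wx <- cells$x[wat]; wy <- cells$y[wat]
  strat_code <- match(cells$stratum[wat], c("Inshore", "Island", "Offshore"))
  if (anyNA(strat_code)) stop("water cell with unknown stratum")
  effd <- dist_to_polylines(wx, wy, transects)

  # neighbor lists for center proposals (self included)
  ncell <- length(wat)
  D2 <- outer(wx, wx, "-")^2 + outer(wy, wy, "-")^2
  nbr <- apply(D2 <= config$r_prop^2, 1, which, simplify = FALSE)
  nbr_start <- c(0L, cumsum(lengths(nbr)))
  nbr_idx <- unlist(nbr, use.names = FALSE) - 1L
  # per-origin dispersal normalizer components by destination stratum
  Wmv <- exp(-D2 / (2 * config$sigma_move^2))
  Zs0 <- rowSums(Wmv[, strat_code == 1, drop = FALSE])
  Zs1 <- rowSums(Wmv[, strat_code == 2, drop = FALSE])
  Zs2 <- rowSums(Wmv[, strat_code == 3, drop = FALSE])

  # observation matrices, augmented to M rows
  n_det <- matrix(0L, M, Tn)
  obs_x <- obs_y <- matrix(NaN, M, Tn)
  ss <- matrix(0, M, Tn)
  n_det[seq_len(n_obs), ] <- histories$n_det
  obs_x[seq_len(n_obs), ] <- histories$locs[, , 1]
  obs_y[seq_len(n_obs), ] <- histories$locs[, , 2]
  if (!is.null(histories$ss)) ss[seq_len(n_obs), ] <- histories$ss
  # snap mean locations falling off water to the nearest water cell center
  det_idx <- which(n_det[seq_len(n_obs), , drop = FALSE] > 0, arr.ind = TRUE)
  off <- !on_water(mask, obs_x[det_idx], obs_y[det_idx])
  if (any(off)) {
    warning(sprintf("%d detection locations off the water mask; snapped to nearest water cell", sum(off)))
    for (r in which(off)) {
      i <- det_idx[r, 1]; t <- det_idx[r, 2]
      k <- which.min((wx - obs_x[i, t])^2 + (wy - obs_y[i, t])^2)
      obs_x[i, t] <- wx[k]; obs_y[i, t] <- wy[k]
    }
  }

  # initial centers: nearest water cell to the individual's mean location
  s_init <- matrix(0L, M, Tn)
  set.seed(config$seed)
  for (i in seq_len(M)) {
    if (i <= n_obs && any(n_det[i, ] > 0)) {
      mx <- mean(obs_x[i, n_det[i, ] > 0])
      my <- mean(obs_y[i, n_det[i, ] > 0])
      s_init[i, ] <- which.min((wx - mx)^2 + (wy - my)^2) - 1L
    } else {
      s_init[i, ] <- sample.int(ncell, 1L) - 1L
    }
  }
  entry <- death <- integer(M)
  for (i in seq_len(n_obs)) {
    dt <- which(n_det[i, ] > 0)
    entry[i] <- dt[1]; death[i] <- dt[length(dt)]
  }

  data <- list(M = M, T = Tn, K = K, cell_x = wx, cell_y = wy,
               eff_dist = effd, stratum = strat_code - 1L,
               nbr_start = nbr_start, nbr_idx = nbr_idx,
               sigma_move = config$sigma_move,
               Zs0 = Zs0, Zs1 = Zs1, Zs2 = Zs2, D2w = D2,
               n_det = n_det, obs_x = obs_x, obs_y = obs_y, ss = ss)
  ctrl <- config[c("n_iter", "burn", "thin", "prior_sigma_sd",
                   "prior_beta_sd", "prop_p0", "prop_sigma", "prop_beta",
                   "fix_p0", "fix_sigma")]
  init <- list(s = s_init, entry = entry, death = death,
               p0 = config$p0_init, sigma = config$sigma_init,
               beta_island = 0, beta_offshore = 0)

  chains <- lapply(seq_len(config$chains), function(ch) {
    set.seed(config$seed + ch - 1L)
    secr_chain(data, init, ctrl)
  })
  par <- do.call(rbind, lapply(chains, `[[`, "par"))
  Nmat <- do.call(rbind, lapply(chains, `[[`, "N"))
  entered <- unlist(lapply(chains, `[[`, "entered"))
  if (max(entered) >= M) {
    stop(sprintf("augmentation exhausted (all %d slots included); refit with larger M", M))
  }
  n_keep <- nrow(chains[[1]]$par)
  chain_id <- rep(seq_len(config$chains), each = n_keep)

  strata <- c("Inshore", "Island", "Offshore")
  areas_mask <- vapply(strata, function(s) stratum_area(mask, s), numeric(1))
  N <- array(Nmat, dim = c(nrow(Nmat), 3, Tn))   # col index t*3+st, st fastest
  N <- aperm(N, c(1, 3, 2))
  dens <- sweep(N, 3, pmax(areas_mask, .Machine$double.eps), "/")
  dens[, , areas_mask == 0] <- NA_real_
  dimnames(dens) <- list(NULL, NULL, strata)
  dimnames(N) <- list(NULL, NULL, strata)

  draws <- structure(list(
    p0 = par[, 1], sigma = par[, 2],
    beta_island = par[, 3], beta_offshore = par[, 4],
    phi = par[, 4 + seq_len(Tn - 1), drop = FALSE],
    N = N, density = dens, entered = entered,
    chain = chain_id, n_primary = Tn, mask_areas = areas_mask,
    M = M, n_obs = n_obs, config = config
  ), class = "secr_draws")
  draws$rhat <- c(p0 = split_rhat(draws$p0, chain_id),
                  sigma = split_rhat(draws$sigma, chain_id),
                  beta_island = split_rhat(draws$beta_island, chain_id),
                  mean_phi = if (Tn > 1)
                    split_rhat(rowMeans(draws$phi), chain_id) else NA_real_)
  if (any(draws$rhat > 1.1, na.rm = TRUE)) {
    warning(sprintf("possible non-convergence: max split-Rhat %.3f",
                    max(draws$rhat, na.rm = TRUE)))
  }
  draws
}

#' @export
print.secr_draws <- function(x, ...) {
  cat(sprintf("secr_draws: %d draws (%d chains), %d primaries, M=%d, n_obs=%d\n",
              length(x$p0), max(x$chain), x$n_primary, x$M, x$n_obs))
  cat(sprintf("posterior means: p0=%.3f sigma=%.3f beta_island=%.2f mean phi=%.3f\n",
              mean(x$p0), mean(x$sigma), mean(x$beta_island),
              mean(x$phi)))
  cat("split-Rhat:", paste(names(x$rhat), sprintf("%.3f", x$rhat),
                           collapse = " "), "\n")
  invisible(x)
}

# split-Rhat (Gelman) on one scalar parameter
split_rhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  mns <- vapply(halves, mean, numeric(1))
  vrs <- vapply(halves, stats::var, numeric(1))
  n <- length(halves[[1]]); m <- length(halves)
  W <- mean(vrs); B <- n * stats::var(mns)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Percentile credible interval by tail discarding
#'
#' Discards the lowest and highest floor((1 - level)/2 * n) draws and
#' returns the extremes of the remainder.
#'
#' @param samples numeric draws; @param level e.g. 0.95.
#' @return c(low, high).
#' @export
credible_interval <- function(samples, level = 0.95) {
  n <- length(samples)
  k <- floor((1 - level) / 2 * n)
  if (k < 1) stop(sprintf("too few draws (%d) for a %.0f%% interval",
                          n, 100 * level))
  s <- sort(samples)
  c(s[k + 1], s[n - k])
}

#' Inflate marked densities to the total-population scale
#'
#' Divides per-draw marked densities by the per-primary marked proportion
#' (the 1/p inflation); uncertainty in the proportion itself is small and
#' deliberately not propagated.
#'
#' @param draws a \code{secr_draws}.
#' @param marked_prop a data.frame from \code{marked_proportion_table}
#'   (columns primary, proportion), or a single proportion.
#' @param strata strata to report (Offshore is estimable but excluded by
#'   default: its sampling effort does not support reporting).
#' @return object of class \code{density_estimates}: total-scale density
#'   draw array (draw x primary x stratum) and a summary table (posterior
#'   mean and 95% CI).
#' @export
summarize_density <- function(draws, marked_prop,
                              strata = c("Inshore", "Island"),
                              level = 0.95) {
  Tn <- draws$n_primary
  if (is.data.frame(marked_prop)) {
    prop <- marked_prop$proportion[match(seq_len(Tn), marked_prop$primary)]
  } else {
    prop <- rep(marked_prop, Tn)
  }
  if (anyNA(prop) || any(prop <= 0)) stop("need a positive marked proportion per primary")
  dens <- draws$density[, , strata, drop = FALSE]
  total <- sweep(dens, 2, prop, "/")
  tab <- do.call(rbind, lapply(seq_len(Tn), function(t) {
    do.call(rbind, lapply(strata, function(s) {
      d <- total[, t, s]
      ci <- credible_interval(d, level)
      data.frame(primary = t, stratum = s, est = mean(d),
                 lo = ci[1], hi = ci[2])
    }))
  }))
  structure(list(density = total, table = tab, strata = strata,
                 marked_prop = prop, level = level),
            class = "density_estimates")
}

#' Extrapolate stratum densities to abundance
#'
#' Per draw, N_s = D_s * A_s with the configured full-region stratum areas;
#' the total is their sum and the overall density total / sum(A).
#'
#' @param dens a \code{density_estimates}.
#' @param areas a \code{stratum_areas} vector covering every reported
#'   stratum.
#' @return list of summary tables: \code{by_stratum} (per primary x
#'   stratum abundance), \code{total} (per primary total abundance and
#'   overall density), \code{mean} (study-period means), plus the per-draw
#'   arrays.
#' @export
extrapolate_abundance <- function(dens, areas = stratum_areas(),
                                  level = 0.95) {
  strata <- dens$strata
  miss <- setdiff(strata, names(areas))
  if (length(miss)) stop("missing stratum areas: ",
                         paste(miss, collapse = ", "))
  A <- as.numeric(areas[strata])
  Nd <- sweep(dens$density, 3, A, "*")          # draw x primary x stratum
  tot <- apply(Nd, c(1, 2), sum)                # draw x primary
  overall <- tot / sum(A)
  Tn <- dim(Nd)[2]
  by_stratum <- do.call(rbind, lapply(seq_len(Tn), function(t) {
    do.call(rbind, lapply(seq_along(strata), function(si) {
      d <- Nd[, t, si]; ci <- credible_interval(d, level)
      data.frame(primary = t, stratum = strata[si], est = mean(d),
                 lo = ci[1], hi = ci[2])
    }))
  }))
  total <- do.call(rbind, lapply(seq_len(Tn), function(t) {
    ciN <- credible_interval(tot[, t], level)
    ciD <- credible_interval(overall[, t], level)
    data.frame(primary = t, abundance = mean(tot[, t]),
               ab_lo = ciN[1], ab_hi = ciN[2],
               density = mean(overall[, t]),
               d_lo = ciD[1], d_hi = ciD[2])
  }))
  # study-period means: average the per-primary draws, then summarize
  mean_tab <- do.call(rbind, c(
    lapply(seq_along(strata), function(si) {
      d <- rowMeans(Nd[, , si, drop = FALSE], dims = 1)
      ci <- credible_interval(d, level)
      data.frame(quantity = paste0("abundance_", strata[si]),
                 est = mean(d), lo = ci[1], hi = ci[2])
    }),
    list({
      d <- rowMeans(tot); ci <- credible_interval(d, level)
      data.frame(quantity = "abundance_total", est = mean(d),
                 lo = ci[1], hi = ci[2])
    }, {
      d <- rowMeans(overall); ci <- credible_interval(d, level)
      data.frame(quantity = "density_overall", est = mean(d),
                 lo = ci[1], hi = ci[2])
    })))
  list(by_stratum = by_stratum, total = total, mean = mean_tab,
       draws_abundance = Nd, draws_total = tot, draws_overall = overall)
}

#' Equivalent annual survival
#'
#' Rescales each inter-primary survival draw to a 365.25-day exponent,
#' phi_ann = phi^(365.25 / dt), and averages the annualized values over the
#' intervals assigned to each year.
#'
#' @param phi_draws draws x intervals matrix (e.g. \code{draws$phi}).
#' @param delta_days interval lengths in days.
#' @param year_map vector assigning each interval to a year label; NA drops
#'   the interval (e.g. a final partial interval judged unreliable).
#' @return list: \code{by_interval} (annualized per-interval summaries) and
#'   \code{by_year} (posterior mean and 95% CI of the yearly average).
#' @export
annualize_survival <- function(phi_draws, delta_days, year_map = NULL,
                               level = 0.95, year_length = 365.25) {
  phi_draws <- as.matrix(phi_draws)
  if (length(delta_days) != ncol(phi_draws))
    stop("delta_days must have one entry per interval")
  if (any(delta_days <= 0)) stop("delta_days must be > 0")
  ann <- sweep(phi_draws, 2, year_length / delta_days, function(p, e) p^e)
  by_interval <- do.call(rbind, lapply(seq_len(ncol(ann)), function(j) {
    ci <- credible_interval(ann[, j], level)
    data.frame(interval = j, delta_days = delta_days[j],
               est = mean(ann[, j]), lo = ci[1], hi = ci[2])
  }))
  by_year <- NULL
  if (!is.null(year_map)) {
    if (length(year_map) != ncol(ann))
      stop("year_map must have one entry per interval")
    yrs <- unique(year_map[!is.na(year_map)])
    by_year <- do.call(rbind, lapply(yrs, function(y) {
      d <- rowMeans(ann[, which(year_map == y), drop = FALSE])
      ci <- credible_interval(d, level)
      data.frame(year = y, est = mean(d), lo = ci[1], hi = ci[2])
    }))
  }
  list(by_interval = by_interval, by_year = by_year)
}
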