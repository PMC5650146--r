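# Pipeline orchestration: a single YAML config drives the two analyses
# (capture-recapture and telemetry/hot spots), with seeded determinism and
# provenance headers on every output table.

#' Load a pipeline configuration
#'
#' @param config a YAML file path or a named list. Recognized sections:
#'   \code{seed}, \code{out_dir}, \code{world} (truth overrides, see
#'   \code{make_world}), \code{model} (see \code{model_config}),
#'   \code{areas} (named stratum areas), \code{year_map} (per interval),
#'   \code{telemetry} (n_animals, duration_days, ...), \code{hotspot}
#'   (alpha levels, isa_steps), \code{sightings_csv}, \code{mask_csv},
#'   \code{telemetry_csv} for loading instead of simulating.
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  for (f in c("sightings_csv", "mask_csv", "telemetry_csv")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop(sprintf("configured file missing: %s = %s", f, config[[f]]))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% "dolphincr_out"
  config
}

prov_header <- function(config, what) {
  sprintf("# dolphinCR %s %s seed=%d",
          as.character(utils::packageVersion("dolphinCR")), what,
          config$seed)
}

write_table <- function(df, path, header) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the capture-recapture pipeline
#'
#' Simulates (or loads) photo-ID sightings, builds capture histories, fits
#' the spatial robust-design model, and writes density/abundance and
#' survival tables plus a plain-text report. Deterministic for a given
#' config and seed.
#'
#' @param config path or list, see \code{load_pipeline_config}.
#' @return invisible list of all intermediate and final objects.
#' @export
run_cr_pipeline <- function(config) {
  config <- load_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  mask <- if (!is.null(config$mask_csv))
    stage("habitat", read_mask_csv(config$mask_csv)) else NULL
  world_cfg <- config$world %||% list()
  if (!is.null(mask)) world_cfg$mask <- mask
  truth <- stage("synthetic_data", make_world(world_cfg, seed = config$seed))

  if (!is.null(config$sightings_csv)) {
    sightings <- stage("photoid", {
      s <- utils::read.csv(config$sightings_csv,
                           comment.char = "#",
                           colClasses = c(id = "character"))
      s$id[is.na(s$id)] <- ""
      class(s) <- c("sighting_table", "data.frame")
      s
    })
  } else {
    pop <- stage("synthetic_data", simulate_population(truth))
    sightings <- stage("synthetic_data",
                       simulate_captures(truth, pop,
                                         seed = config$seed + 1L))
  }

  histories <- stage("photoid", build_capture_histories(
    sightings, n_primary = length(truth$primary_dates),
    n_secondary = truth$secondaries_per_primary))
  mp <- stage("photoid", marked_proportion_table(sightings))
  disc <- stage("photoid", discovery_curve(histories))
  fid <- stage("photoid", site_fidelity_bins(histories))

  mcfg <- do.call(model_config, c(config$model %||% list()))
  mcfg$seed <- config$seed
  fit <- stage("secr_robust", fit_model(histories, truth$mask, mcfg))
  dens <- stage("secr_robust", summarize_density(fit, mp))
  areas <- stratum_areas(unlist(config$areas %||%
    c(Island = stratum_area(truth$mask, "Island"),
      Inshore = stratum_area(truth$mask, "Inshore"))))
  ab <- stage("secr_robust", extrapolate_abundance(dens, areas))
  delta <- as.numeric(diff(truth$primary_dates))
  year_map <- unlist(config$year_map %||%
    rep(c("yr1", "yr2"),
        c(ceiling(length(delta) / 2), floor(length(delta) / 2))))
  surv <- stage("secr_robust",
                annualize_survival(fit$phi, delta, year_map))

  od <- config$out_dir
  write_table(mp, file.path(od, "marked_proportion.csv"),
              prov_header(config, "marked_proportion"))
  dens_tab <- merge(dens$table,
                    ab$by_stratum[c("primary", "stratum", "est")],
                    by = c("primary", "stratum"),
                    suffixes = c("_density", "_abundance"))
  write_table(dens_tab[order(dens_tab$primary, dens_tab$stratum), ],
              file.path(od, "density_estimates.csv"),
              prov_header(config, "density_estimates"))
  write_table(ab$total, file.path(od, "abundance_total.csv"),
              prov_header(config, "abundance_total"))
  write_table(surv$by_interval, file.path(od, "survival_intervals.csv"),
              prov_header(config, "survival_intervals"))
  if (!is.null(surv$by_year))
    write_table(surv$by_year, file.path(od, "survival_by_year.csv"),
                prov_header(config, "survival_by_year"))

  report <- c(
    prov_header(config, "cr_report"),
    sprintf("R %s; %d chains x %d kept draws; runtime %.1f s",
            as.character(getRversion()), mcfg$chains,
            length(fit$p0) / mcfg$chains,
            as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    sprintf("catalog size %d; discovery curve: %s",
            length(histories$ids), paste(disc, collapse = " ")),
    sprintf("site fidelity: %s",
            paste(names(table(fid)), table(fid), collapse = " ")),
    sprintf("split-Rhat: %s",
            paste(names(fit$rhat), sprintf("%.3f", fit$rhat),
                  collapse = " ")))
  writeLines(report, file.path(od, "cr_report.txt"))
  invisible(list(truth = truth, sightings = sightings,
                 histories = histories, marked_prop = mp,
                 discovery = disc, fidelity = fid, fit = fit,
                 density = dens, abundance = ab, survival = surv))
}

#' Run the telemetry / hot spot pipeline
#'
#' Simulates (or loads) Argos fixes, filters to LC3/LC2 with one fix per
#' animal-day, computes per-animal kernel ranges, then monthly Gi* hot
#' spots with ISA-selected thresholds and consecutive-month overlaps.
#'
#' @param config path or list, see \code{load_pipeline_config}.
#' @return invisible list of intermediates and tables.
#' @export
run_telemetry_pipeline <- function(config) {
  config <- load_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  truth <- stage("synthetic_data",
                 make_world(config$world %||% list(), seed = config$seed))
  tcfg <- config$telemetry %||% list()
  raw <- if (!is.null(config$telemetry_csv)) {
    stage("telemetry_ranges", {
      d <- utils::read.csv(config$telemetry_csv, comment.char = "#",
                           colClasses = c(lc = "character"))
      d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC")
      class(d) <- c("telemetry_table", "data.frame")
      d
    })
  } else {
    stage("synthetic_data",
          simulate_telemetry(truth,
                             n_animals = tcfg$n_animals %||% 19L,
                             duration_days = tcfg$duration_days %||% 153L,
                             seed = config$seed + 2L,
                             config = tcfg))
  }
  filt <- stage("telemetry_ranges", filter_locations(raw,
                                                     seed = config$seed))
  mask <- truth$mask
  metrics <- stage("telemetry_ranges", {
    do.call(rbind, lapply(split(filt, filt$id), function(d)
      range_metrics(d, mask)))
  })
  # assign each animal to a stratum by majority of its fixes
  grouping <- vapply(split(filt, filt$id), function(d) {
    cells <- mask_cells(mask)
    rc <- locate_cell(mask, d$x, d$y)
    st <- mask$stratum[cbind(rc$row, rc$col)]
    if (mean(st %in% c("Island", "Offshore"), na.rm = TRUE) > 0.5)
      "Island" else "Inshore"
  }, character(1))
  summ <- stage("telemetry_ranges",
                range_summary(metrics, grouping[metrics$id]))

  grid_spec <- config$hotspot$grid %||%
    list(origin = mask$origin, nx = mask$nx, ny = mask$ny,
         cell_size = mask$cell_size)
  months <- sort(unique(format(as.POSIXct(filt$timestamp, tz = "UTC"),
                               "%Y-%m")))
  hs05 <- list(); hs01 <- list(); thr <- list()
  for (mth in months) {
    g <- withCallingHandlers(
      grid_counts(filt, mth, grid_spec),
      warning = function(w) invokeRestart("muffleWarning"))
    if (sum(g$counts) == 0 || stats::var(as.vector(g$counts)) == 0) {
      warning(sprintf("month %s skipped (no usable fixes)", mth))
      next
    }
    isa <- stage("hotspots", isa_threshold(g))
    gi <- stage("hotspots", getis_ord_gi_star(g, isa$threshold))
    hs05[[mth]] <- classify_hotspots(gi, 0.05)
    hs01[[mth]] <- classify_hotspots(gi, 0.01)
    thr[[mth]] <- isa$threshold
  }
  mnames <- names(hs05)
  overlap <- NULL
  if (length(mnames) > 1) {
    overlap <- do.call(rbind, lapply(seq_len(length(mnames) - 1), function(k) {
      ov <- hotspot_overlap(hs05[[k]], hs05[[k + 1]])
      data.frame(month_a = mnames[k], month_b = mnames[k + 1],
                 n_overlap = ov$n_overlap, percent = ov$percent)
    }))
  }
  hs_tab <- data.frame(
    month = mnames,
    threshold_km = unlist(thr),
    n_hot_05 = vapply(hs05, function(h) nrow(h$cells), integer(1)),
    n_hot_01 = vapply(hs01, function(h) nrow(h$cells), integer(1)))

  od <- config$out_dir
  write_table(metrics, file.path(od, "range_metrics.csv"),
              prov_header(config, "range_metrics"))
  write_table(summ, file.path(od, "range_summary.csv"),
              prov_header(config, "range_summary"))
  write_table(hs_tab, file.path(od, "hotspots_monthly.csv"),
              prov_header(config, "hotspots_monthly"))
  if (!is.null(overlap))
    write_table(overlap, file.path(od, "hotspot_overlap.csv"),
                prov_header(config, "hotspot_overlap"))
  writeLines(c(prov_header(config, "telemetry_report"),
               sprintf("%d animals tracked; %d fixes retained after filtering",
                       length(unique(filt$id)), nrow(filt)),
               sprintf("months analysed: %s",
                       paste(mnames, collapse = " "))),
             file.path(od, "telemetry_report.txt"))
  invisible(list(truth = truth, raw = raw, filtered = filt,
                 metrics = metrics, summary = summ, hotspots05 = hs05,
                 hotspots01 = hs01, overlap = overlap, table = hs_tab))
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate} (write synthetic sightings + telemetry),
#' \code{cr-fit} (capture-recapture pipeline), \code{telemetry}
#' (ranges + hot spots), \code{report} (both).
#'
#' @param args character vector, e.g. \code{commandArgs(TRUE)}.
#' @export
cli_main <- function(args = commandArgs(TRUE)) {
  if (!length(args)) stop("usage: dolphincr <simulate|cr-fit|telemetry|report> [--config file.yaml] [--seed n] [--out dir]")
  cmd <- args[1]
  opts <- list(config = NULL, seed = NULL, out = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts)) stop("unknown option: ", args[i])
    opts[[key]] <- args[i + 1]; i <- i + 2
  }
  config <- if (!is.null(opts$config)) load_pipeline_config(opts$config)
            else list()
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) config$out_dir <- opts$out
  config <- load_pipeline_config(config)
  switch(cmd,
    simulate = {
      truth <- make_world(config$world %||% list(), seed = config$seed)
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      pop <- simulate_population(truth)
      sg <- simulate_captures(truth, pop, seed = config$seed + 1L)
      tel <- simulate_telemetry(truth, seed = config$seed + 2L)
      write_table(sg, file.path(config$out_dir, "sightings.csv"),
                  prov_header(config, "sightings"))
      write_table(tel, file.path(config$out_dir, "telemetry.csv"),
                  prov_header(config, "telemetry"))
      write_mask_csv(truth$mask, file.path(config$out_dir, "mask.csv"))
    },
    `cr-fit` = run_cr_pipeline(config),
    telemetry = run_telemetry_pipeline(config),
    report = { run_cr_pipeline(config); run_telemetry_pipeline(config) },
    stop("unknown subcommand: ", cmd))
  invisible(NULL)
}
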