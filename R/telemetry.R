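# Argos telemetry filtering and kernel utilization-distribution home
# ranges with shoreline barriers handled by mask-and-renormalize.

#' Filter Argos fixes for home-range analysis
#'
#' Keeps only the high-quality location classes (LC3/LC2 by default), then
#' retains exactly one fix per animal-day, chosen uniformly at random with
#' the given seed. Animals whose retained fix count falls below
#' \code{min_locations} are flagged (not dropped): kernel ranges stabilize
#' only above roughly 150 locations.
#'
#' @param raw a \code{telemetry_table} (id, timestamp, lc, x, y).
#' @param seed integer; the daily subsample is deterministic given it.
#' @param lc_keep character vector of retained classes.
#' @param min_locations flag threshold.
#' @param tz timezone defining the day boundary.
#' @return filtered \code{telemetry_table} with attribute
#'   \code{below_threshold} (character vector of flagged animal IDs).
#' @export
filter_locations <- function(raw, seed = 1L, lc_keep = c("3", "2"),
                             min_locations = 150L, tz = "UTC") {
  keep <- raw[as.character(raw$lc) %in% lc_keep, , drop = FALSE]
  if (!nrow(keep)) {
    attr(keep, "below_threshold") <- character(0)
    return(keep)
  }
  day <- format(as.POSIXct(keep$timestamp, tz = tz), "%Y-%m-%d", tz = tz)
  key <- paste(keep$id, day, sep = "|")
  set.seed(seed)
  # uniform choice within each animal-day, stable under row order
  ord <- order(key, keep$timestamp)
  keep <- keep[ord, , drop = FALSE]
  key <- key[ord]
  pick <- unlist(lapply(split(seq_along(key), key), function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }), use.names = FALSE)
  out <- keep[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  counts <- table(out$id)
  attr(out, "below_threshold") <- names(counts)[counts < min_locations]
  class(out) <- c("telemetry_table", "data.frame")
  out
}

# bivariate normal reference bandwidth (href) used by home-range tools
href_bandwidth <- function(points) {
  n <- nrow(points)
  sqrt(0.5 * (stats::var(points$x) + stats::var(points$y))) * n^(-1 / 6)
}

#' Ad hoc rule-based bandwidth selection
#'
#' Starting from the bivariate-normal reference bandwidth h_ref, candidate
#' multipliers (default 1.0, 0.9, ..., 0.1) are evaluated and the smallest
#' multiplier whose 95% UD contour is still a single connected region
#' containing at least 95% of the fixes is returned (times h_ref). If no
#' candidate qualifies, h_ref itself is returned.
#'
#' @param points data.frame with x, y (km).
#' @param mask habitat mask defining the evaluation grid and barriers.
#' @param multipliers candidate multipliers, descending.
#' @param level contour level for the rule (0.95).
#' @return bandwidth h in km.
#' @export
select_bandwidth <- function(points, mask,
                             multipliers = seq(1, 0.1, by = -0.1),
                             level = 0.95) {
  if (nrow(points) < 5L) stop("need >= 5 points for bandwidth selection")
  h_ref <- href_bandwidth(points)
  if (!is.finite(h_ref) || h_ref <= 0)
    stop("degenerate point variance: bandwidth undefined")
  best <- NA_real_
  for (m in sort(multipliers, decreasing = TRUE)) {
    h <- m * h_ref
    ud <- kernel_ud(points, h, mask)
    cells <- contour_cells(ud, level)
    if (!contour_connected(cells, ud)) next
    if (contour_point_coverage(cells, ud, points) < level) next
    best <- m
  }
  if (is.na(best)) h_ref else best * h_ref
}

#' Kernel utilization distribution on the habitat mask
#'
#' Gaussian kernel density of the fixes evaluated at water-cell centers of
#' the mask; land cells are zero and the remaining mass is renormalized to
#' one (the barrier is handled by mask-and-renormalize rather than a
#' geodesic kernel).
#'
#' @param points data.frame with x, y; @param h bandwidth (km);
#' @param mask habitat mask; @param id optional animal ID label.
#' @return object of class \code{ud_grid}: density matrix aligned to the
#'   mask (sums to 1 over water), h, id.
#' @export
kernel_ud <- function(points, h, mask, id = NA_character_) {
  if (h <= 0) stop("bandwidth must be > 0")
  if (nrow(points) == 0L) stop("no points")
  cells <- mask_cells(mask)
  dens <- rep(0, nrow(cells))
  w <- which(cells$water)
  cx <- cells$x[w]; cy <- cells$y[w]
  inv2h2 <- 1 / (2 * h * h)
  acc <- numeric(length(w))
  for (i in seq_len(nrow(points))) {
    acc <- acc + exp(-((cx - points$x[i])^2 + (cy - points$y[i])^2) * inv2h2)
  }
  dens[w] <- acc
  tot <- sum(dens)
  if (tot <= 0) stop("zero UD mass after masking land")
  dens <- dens / tot
  structure(list(values = matrix(dens, nrow = mask$ny, ncol = mask$nx,
                                 byrow = TRUE),
                 mask = mask, h = h, id = id), class = "ud_grid")
}

# cells (as linear indices into the value matrix) forming the `level`
# highest-density contour: minimal count with cumulative mass >= level
contour_cells <- function(ud, level) {
  v <- as.vector(ud$values)
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(v[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  ord[seq_len(k)]
}

# queen-connectivity check of a contour cell set
contour_connected <- function(cells, ud) {
  if (length(cells) <= 1L) return(TRUE)
  ny <- nrow(ud$values)
  r <- ((cells - 1L) %% ny) + 1L
  c <- ((cells - 1L) %/% ny) + 1L
  n <- length(cells)
  idx <- stats::setNames(seq_len(n), paste(r, c))
  visited <- rep(FALSE, n)
  stack <- 1L; visited[1L] <- TRUE
  while (length(stack)) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- idx[paste(r[i] + dr, c[i] + dc)]
      if (!is.na(j) && !visited[j]) { visited[j] <- TRUE
        stack <- c(stack, j) }
    }
  }
  all(visited)
}

contour_point_coverage <- function(cells, ud, points) {
  mask <- ud$mask
  rc <- locate_cell(mask, points$x, points$y)
  ok <- !is.na(rc$row)
  lin <- (rc$col[ok] - 1L) * mask$ny + rc$row[ok]
  sum(lin %in% cells) / nrow(points)
}

#' Area of a UD contour
#'
#' Area of the minimal set of highest-density cells whose cumulative mass
#' reaches \code{level}; disconnected regions are allowed.
#'
#' @param ud a \code{ud_grid}; @param level 0.50 (core) or 0.95 (home range).
#' @return area in km^2.
#' @export
ud_contour_area <- function(ud, level) {
  length(contour_cells(ud, level)) * ud$mask$cell_size^2
}

#' Per-animal range metrics
#'
#' 95% and 50% UD areas and the maximum distance between locations, using
#' the ad hoc bandwidth unless \code{h} is supplied.
#'
#' @param fixes filtered \code{telemetry_table} for one animal.
#' @param mask habitat mask; @param h optional fixed bandwidth.
#' @return one-row data.frame: id, n_locations, h, area95, area50,
#'   max_dimension.
#' @export
range_metrics <- function(fixes, mask, h = NULL) {
  id <- as.character(fixes$id[1])
  if (is.null(h)) h <- select_bandwidth(fixes, mask)
  ud <- kernel_ud(fixes, h, mask, id = id)
  data.frame(id = id, n_locations = nrow(fixes), h = h,
             area95 = ud_contour_area(ud, 0.95),
             area50 = ud_contour_area(ud, 0.50),
             max_dimension = max_distance(fixes),
             stringsAsFactors = FALSE)
}

#' Group means and SDs of range metrics
#'
#' @param metrics data.frame of per-animal metrics (rows).
#' @param grouping factor/character vector, one per row (e.g. stratum-sex).
#' @param columns metric columns to summarize.
#' @return data.frame of group, n, then mean_* and sd_* columns (SD is NA
#'   for single-animal groups).
#' @export
range_summary <- function(metrics, grouping,
                          columns = c("area95", "area50", "max_dimension")) {
  if (length(grouping) != nrow(metrics))
    stop("grouping must have one entry per animal")
  sp <- split(metrics, grouping)
  do.call(rbind, lapply(names(sp), function(gname) {
    d <- sp[[gname]]
    out <- data.frame(group = gname, n = nrow(d))
    for (col in columns) {
      out[[paste0("mean_", col)]] <- mean(d[[col]])
      out[[paste0("sd_", col)]] <- if (nrow(d) > 1) stats::sd(d[[col]])
                                   else NA_real_
    }
    out
  }))
}

#' Export a UD grid as CSV (row, col, x, y, density)
#' @export
write_ud_csv <- function(ud, path) {
  cells <- mask_cells(ud$mask)
  cells$density <- as.vector(t(ud$values))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# ud_grid id=%s h=%.9g", ud$id, ud$h), con)
  utils::write.csv(cells[, c("row", "col", "x", "y", "density")], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export contour cells as GeoJSON square polygons
#' @export
write_contour_geojson <- function(ud, level, path) {
  cells <- contour_cells(ud, level)
  mask <- ud$mask; cs <- mask$cell_size; ny <- mask$ny
  shapes <- lapply(cells, function(l) {
    r <- ((l - 1L) %% ny) + 1L; c <- ((l - 1L) %/% ny) + 1L
    x0 <- mask$origin[1] + (c - 1) * cs; y0 <- mask$origin[2] + (r - 1) * cs
    rect_poly(x0, y0, x0 + cs, y0 + cs)
  })
  write_geojson_shapes(shapes, path, type = "Polygon")
}
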