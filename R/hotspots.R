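# Monthly gridded hot spot analysis: Global Moran's I with incremental
# spatial autocorrelation (ISA) threshold selection, then the Getis-Ord Gi*
# local statistic with a minimum-8-neighbor distance band.

#' Monthly count grid of telemetry fixes
#'
#' Bins fixes of one calendar month into square cells with the half-open
#' convention [x, x+cs) x [y, y+cs); every fix lands in exactly one cell.
#'
#' @param fixes filtered \code{telemetry_table}.
#' @param month "YYYY-MM" label selecting rows by timestamp.
#' @param grid_spec list(origin, nx, ny, cell_size); cell_size defaults 1 km.
#' @param tz timezone for the month boundary.
#' @return object of class \code{count_grid}: month, counts matrix
#'   (ny x nx), origin, cell_size.
#' @export
grid_counts <- function(fixes, month, grid_spec, tz = "UTC") {
  cs <- grid_spec$cell_size %||% 1
  origin <- as.numeric(grid_spec$origin %||% c(0, 0))
  nx <- as.integer(grid_spec$nx); ny <- as.integer(grid_spec$ny)
  mth <- format(as.POSIXct(fixes$timestamp, tz = tz), "%Y-%m", tz = tz)
  f <- fixes[mth == month, , drop = FALSE]
  counts <- matrix(0L, ny, nx)
  if (!nrow(f)) {
    warning(sprintf("no fixes in month %s", month))
  } else {
    col <- floor((f$x - origin[1]) / cs) + 1L
    row <- floor((f$y - origin[2]) / cs) + 1L
    bad <- which(col < 1L | col > nx | row < 1L | row > ny)
    if (length(bad)) {
      stop(sprintf("fixes outside grid extent (rows of month table): %s",
                   paste(utils::head(bad, 10L), collapse = ", ")))
    }
    for (i in seq_along(row)) counts[row[i], col[i]] <-
        counts[row[i], col[i]] + 1L
  }
  structure(list(month = month, counts = counts, origin = origin,
                 cell_size = cs, nx = nx, ny = ny), class = "count_grid")
}

grid_xy <- function(grid) {
  cs <- grid$cell_size
  list(x = rep(grid$origin[1] + (seq_len(grid$nx) - 0.5) * cs,
               each = grid$ny),
       y = rep(grid$origin[2] + (seq_len(grid$ny) - 0.5) * cs,
               times = grid$nx))
}

#' Global Moran's I with a binary distance band
#'
#' Standard Moran's I over all grid cells with weights w_ij = 1 when
#' 0 < d_ij <= threshold (self excluded), and its z-score under the
#' normality assumption with E[I] = -1/(n-1).
#'
#' @param grid a \code{count_grid}; @param threshold distance band (km).
#' @return list(I, z, expected).
#' @export
morans_i <- function(grid, threshold) {
  x <- as.vector(grid$counts)
  n <- length(x)
  if (stats::var(x) == 0) stop("zero variance: Moran's I undefined")
  xy <- grid_xy(grid)
  z <- x - mean(x)
  d2max <- threshold^2
  S0 <- 0; S1 <- 0; num <- 0
  rowsums <- numeric(n)
  # symmetric binary weights: accumulate over unordered pairs
  for (i in seq_len(n - 1L)) {
    dx <- xy$x[(i + 1L):n] - xy$x[i]
    dy <- xy$y[(i + 1L):n] - xy$y[i]
    nb <- which(dx * dx + dy * dy <= d2max + 1e-9)
    if (!length(nb)) next
    j <- nb + i
    S0 <- S0 + 2 * length(j)
    num <- num + 2 * sum(z[i] * z[j])
    rowsums[i] <- rowsums[i] + length(j)
    rowsums[j] <- rowsums[j] + 1
  }
  if (S0 == 0) stop("no neighbor pairs at this threshold")
  S1 <- 2 * S0            # binary symmetric: sum (w_ij + w_ji)^2 / 2 = 2*S0
  S2 <- sum((2 * rowsums)^2)
  I <- (n / S0) * num / sum(z^2)
  EI <- -1 / (n - 1)
  varI <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  list(I = I, z = (I - EI) / sqrt(varI), expected = EI)
}

#' Average nearest-neighbor distance of occupied cells
#' @export
avg_nn_distance <- function(grid) {
  xy <- grid_xy(grid)
  occ <- which(as.vector(grid$counts) > 0)
  if (length(occ) < 2L) stop("need >= 2 occupied cells")
  px <- xy$x[occ]; py <- xy$y[occ]
  dm <- as.matrix(stats::dist(cbind(px, py)))
  diag(dm) <- Inf
  mean(apply(dm, 1, min))
}

#' Incremental spatial autocorrelation threshold
#'
#' Computes the Moran's I z-score over an increasing series of distance
#' bands and returns the distance of the first local z-score peak - the
#' scale at which clustering is strongest. If z increases monotonically
#' over the scanned range, the last distance is returned with a warning.
#'
#' @param grid a \code{count_grid}.
#' @param start first distance; defaults to the average nearest-neighbor
#'   distance of occupied cells.
#' @param step increment; defaults to \code{start}.
#' @param n_steps number of bands scanned.
#' @return list(threshold, distances, z).
#' @export
isa_threshold <- function(grid, start = NULL, step = NULL, n_steps = 10L) {
  if (stats::var(as.vector(grid$counts)) == 0)
    stop("zero variance: ISA undefined")
  if (is.null(start)) start <- avg_nn_distance(grid)
  if (is.null(step)) step <- start
  dists <- start + step * (seq_len(n_steps) - 1L)
  zs <- vapply(dists, function(d) morans_i(grid, d)$z, numeric(1))
  peak <- NA_integer_
  for (k in seq_along(zs)) {
    left_ok <- k == 1L || zs[k] > zs[k - 1L]
    right_ok <- k == length(zs) || zs[k] >= zs[k + 1L]
    if (left_ok && right_ok) { peak <- k; break }
  }
  if (is.na(peak) || peak == length(zs)) {
    if (all(diff(zs) > 0)) {
      warning("Moran's I z-score monotone increasing; returning last distance")
      peak <- length(zs)
    } else if (is.na(peak)) peak <- which.max(zs)
  }
  list(threshold = dists[peak], distances = dists, z = zs)
}

#' Getis-Ord Gi* statistic per grid cell
#'
#' Binary distance-band weights with self included (the starred form). If
#' fewer than \code{min_neighbors} other cells fall inside the band (e.g.
#' at the grid perimeter), the band is expanded for that cell until the
#' nearest \code{min_neighbors} cells are included. Z follows the standard
#' Gi* formula with the global mean and SD; p is two-sided normal by
#' default.
#'
#' @param grid a \code{count_grid}; @param threshold distance band (km).
#' @param min_neighbors minimum neighboring cells per local sum (8).
#' @param two_sided logical; one- or two-sided p-values.
#' @return object of class \code{gi_grid}: z and p matrices, the weights
#'   spec, and the source grid.
#' @export
getis_ord_gi_star <- function(grid, threshold, min_neighbors = 8L,
                              two_sided = TRUE) {
  x <- as.vector(grid$counts)
  n <- length(x)
  if (stats::var(x) == 0) stop("zero variance: Gi* undefined")
  xy <- grid_xy(grid)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  zs <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xy$x - xy$x[i])^2 + (xy$y - xy$y[i])^2
    nb <- d2 <= threshold^2 + 1e-9        # includes self (d = 0)
    if (sum(nb) - 1L < min_neighbors) {
      # expand to the nearest min_neighbors cells (plus self)
      ord <- order(d2)
      nb <- rep(FALSE, n)
      nb[ord[seq_len(min_neighbors + 1L)]] <- TRUE
    }
    W <- sum(nb)                           # binary weights: sum w = count
    num <- sum(x[nb]) - xbar * W
    den <- S * sqrt((n * W - W^2) / (n - 1))
    zs[i] <- num / den
  }
  p <- if (two_sided) 2 * stats::pnorm(-abs(zs)) else
    stats::pnorm(zs, lower.tail = FALSE)
  structure(list(z = matrix(zs, grid$ny, grid$nx),
                 p = matrix(p, grid$ny, grid$nx),
                 threshold = threshold, min_neighbors = min_neighbors,
                 two_sided = two_sided, grid = grid), class = "gi_grid")
}

#' Significant hot cells at a given alpha
#'
#' Cells with positive Z and p below alpha; no multiple-testing correction
#' is applied (a Bonferroni correction was judged too strict for this
#' exploratory use; pass \code{correct = "bonferroni"} to apply one).
#'
#' @param gi a \code{gi_grid}; @param alpha 0.05 or 0.01.
#' @param correct "none" (default) or "bonferroni".
#' @return object of class \code{hotspot_set}: month, alpha, integer matrix
#'   cell indices (row, col) of hot cells.
#' @export
classify_hotspots <- function(gi, alpha = 0.05,
                              correct = c("none", "bonferroni")) {
  correct <- match.arg(correct)
  a <- if (correct == "bonferroni") alpha / length(gi$z) else alpha
  hot <- which(gi$z > 0 & gi$p < a, arr.ind = TRUE)
  colnames(hot) <- c("row", "col")
  structure(list(month = gi$grid$month, alpha = alpha,
                 cells = hot, nx = gi$grid$nx, ny = gi$grid$ny),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("hotspot_set %s (alpha %.2f): %d hot cells\n",
              x$month, x$alpha, nrow(x$cells)))
  invisible(x)
}

#' Hot spot overlap between two months
#'
#' Number of shared hot cells and the overlap percentage: 100 times the
#' intersection divided by the total hot cells of the two months (their
#' union).
#'
#' @param a,b \code{hotspot_set}s on the same grid and alpha.
#' @return list(n_overlap, percent); percent is NA when both sets are
#'   empty.
#' @export
hotspot_overlap <- function(a, b) {
  if (a$nx != b$nx || a$ny != b$ny || a$alpha != b$alpha)
    stop("hotspot sets must share grid and alpha")
  ka <- paste(a$cells[, 1], a$cells[, 2])
  kb <- paste(b$cells[, 1], b$cells[, 2])
  inter <- length(intersect(ka, kb))
  uni <- length(union(ka, kb))
  list(n_overlap = inter,
       percent = if (uni == 0) NA_real_ else 100 * inter / uni)
}

#' Export hot cells as GeoJSON square polygons
#'
#' @param hs a \code{hotspot_set}; @param grid_spec origin and cell_size of
#'   the grid the set was computed on.
#' @export
write_hotspots_geojson <- function(hs, path,
                                   grid_spec = list(origin = c(0, 0),
                                                    cell_size = 1)) {
  cs <- grid_spec$cell_size %||% 1
  o <- as.numeric(grid_spec$origin %||% c(0, 0))
  shapes <- lapply(seq_len(nrow(hs$cells)), function(k) {
    r <- hs$cells[k, 1]; cc <- hs$cells[k, 2]
    rect_poly(o[1] + (cc - 1) * cs, o[2] + (r - 1) * cs,
              o[1] + cc * cs, o[2] + r * cs)
  })
  write_geojson_shapes(shapes, path, type = "Polygon")
}

#' Export a Gi* grid as CSV (row, col, count, z, p, hot05, hot01)
#' @export
write_gi_csv <- function(gi, path) {
  g <- gi$grid
  df <- data.frame(row = rep(seq_len(g$ny), times = g$nx),
                   col = rep(seq_len(g$nx), each = g$ny),
                   count = as.vector(g$counts),
                   z = as.vector(gi$z), p = as.vector(gi$p))
  df$hot05 <- df$z > 0 & df$p < 0.05
  df$hot01 <- df$z > 0 & df$p < 0.01
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# gi_grid month=%s threshold=%.9g min_neighbors=%d",
                     g$month, gi$threshold, gi$min_neighbors), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
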