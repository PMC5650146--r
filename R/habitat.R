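# Habitat mask: a discretized water/land grid with stratum labels shared by
# the capture-recapture model and the synthetic generator. Cells are square,
# 1 km by default, matching the resolution used to define activity centers.

STRATA <- c("Inshore", "Island", "Offshore", "Land")

#' Build a habitat mask from shoreline polygons
#'
#' Discretizes the study area into square cells and assigns each cell a
#' stratum by its center point: cells inside land or island polygons are
#' \code{Land}; water cells within \code{island_band} km of an island polygon
#' (or inside an explicit pass-corridor polygon) are \code{Island}; water
#' cells between \code{island_band} and \code{offshore_band} km of an island
#' are \code{Offshore}; all remaining water is \code{Inshore}. Boundary
#' points count as inside.
#'
#' @param land_polygons list of n x 2 vertex matrices (km) for mainland.
#' @param island_polygons list of vertex matrices for barrier islands.
#' @param grid_spec list with \code{origin} (x, y of lower-left corner, km),
#'   \code{nx}, \code{ny} (cell counts) and \code{cell_size} (km, default 1).
#' @param pass_corridors optional list of polygons; water cells inside any
#'   corridor are labelled Island regardless of distance (corridors between
#'   islands are explicit inputs, not inferred).
#' @param island_band,offshore_band band widths in km (defaults 1 and 2).
#' @return an object of class \code{habitat_mask}: origin, cell_size,
#'   logical \code{water} matrix and character \code{stratum} matrix
#'   (rows = y from the origin upward, cols = x).
#' @export
build_mask <- function(land_polygons = list(), island_polygons = list(),
                       grid_spec, pass_corridors = list(),
                       island_band = 1, offshore_band = 2) {
  if (is.null(grid_spec$nx) || is.null(grid_spec$ny) ||
      grid_spec$nx < 1 || grid_spec$ny < 1) {
    stop("empty extent: grid_spec must give nx >= 1 and ny >= 1")
  }
  cs <- grid_spec$cell_size %||% 1
  if (cs <= 0) stop("cell_size must be > 0")
  origin <- as.numeric(grid_spec$origin %||% c(0, 0))
  nx <- as.integer(grid_spec$nx); ny <- as.integer(grid_spec$ny)

  cx <- origin[1] + (seq_len(nx) - 0.5) * cs
  cy <- origin[2] + (seq_len(ny) - 0.5) * cs
  gx <- rep(cx, times = ny)            # row-major over (row = y, col = x)
  gy <- rep(cy, each = nx)

  land_all <- c(land_polygons, island_polygons)
  is_land <- if (length(land_all)) in_any_polygon(gx, gy, land_all) else
    rep(FALSE, nx * ny)
  if (all(is_land)) stop("zero water cells in extent")

  stratum <- rep("Inshore", nx * ny)
  if (length(island_polygons)) {
    d_isl <- dist_to_polygons(gx, gy, island_polygons)
    stratum[d_isl <= offshore_band] <- "Offshore"
    stratum[d_isl <= island_band] <- "Island"
  }
  if (length(pass_corridors)) {
    in_pass <- in_any_polygon(gx, gy, pass_corridors)
    stratum[in_pass] <- "Island"
  }
  stratum[is_land] <- "Land"

  m <- structure(list(
    origin = origin, cell_size = cs, nx = nx, ny = ny,
    water = matrix(!is_land, nrow = ny, ncol = nx, byrow = TRUE),
    stratum = matrix(stratum, nrow = ny, ncol = nx, byrow = TRUE)
  ), class = "habitat_mask")
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.habitat_mask <- function(x, ...) {
  tab <- table(factor(x$stratum, levels = STRATA))
  cat(sprintf("habitat_mask: %d x %d cells of %.3g km (origin %.6g, %.6g)\n",
              x$ny, x$nx, x$cell_size, x$origin[1], x$origin[2]))
  cat("cells by stratum:\n")
  print(tab)
  invisible(x)
}

#' Area of one stratum of a habitat mask
#'
#' @param mask a \code{habitat_mask}.
#' @param stratum one of \code{"Inshore"}, \code{"Island"}, \code{"Offshore"},
#'   \code{"Land"}. A known label with zero cells returns 0.
#' @return area in km^2 (cell count times cell_size^2).
#' @export
stratum_area <- function(mask, stratum) {
  if (!stratum %in% STRATA) {
    stop(sprintf("unknown stratum label '%s'", stratum))
  }
  sum(mask$stratum == stratum) * mask$cell_size^2
}

#' Configured stratum areas for abundance extrapolation
#'
#' Defaults are the full-region areas of the Mississippi Sound strata used
#' to extrapolate density to abundance: Island 242 km^2, Inshore 2196 km^2.
#'
#' @param areas named numeric vector of areas (km^2), all > 0.
#' @return named numeric vector of class \code{stratum_areas}.
#' @export
stratum_areas <- function(areas = c(Island = 242, Inshore = 2196)) {
  if (any(areas <= 0) || is.null(names(areas)) || any(!nzchar(names(areas))))
    stop("stratum areas must be named and > 0")
  structure(as.numeric(areas), names = names(areas), class = "stratum_areas")
}

# ---- cell / coordinate bookkeeping -----------------------------------------

#' Cell-center coordinates of a mask
#' @return data.frame(row, col, x, y, water, stratum), row-major.
#' @export
mask_cells <- function(mask) {
  nx <- mask$nx; ny <- mask$ny; cs <- mask$cell_size
  df <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  df <- df[, c("row", "col")]
  df$x <- mask$origin[1] + (df$col - 0.5) * cs
  df$y <- mask$origin[2] + (df$row - 0.5) * cs
  df$water <- as.vector(t(mask$water))
  df$stratum <- as.vector(t(mask$stratum))
  df
}

#' Map point coordinates to mask cell (row, col); NA outside extent
#' @keywords internal
locate_cell <- function(mask, x, y) {
  cs <- mask$cell_size
  col <- as.integer(floor((x - mask$origin[1]) / cs)) + 1L
  row <- as.integer(floor((y - mask$origin[2]) / cs)) + 1L
  bad <- col < 1L | col > mask$nx | row < 1L | row > mask$ny
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Is a point on a water cell of the mask?
#' @keywords internal
on_water <- function(mask, x, y) {
  rc <- locate_cell(mask, x, y)
  ok <- !is.na(rc$row)
  res <- rep(FALSE, length(x))
  res[ok] <- mask$water[cbind(rc$row[ok], rc$col[ok])]
  res
}

# ---- serialization ---------------------------------------------------------

#' Write a habitat mask to CSV (row, col, water, stratum)
#' @export
write_mask_csv <- function(mask, path) {
  df <- mask_cells(mask)[, c("row", "col", "water", "stratum")]
  hdr <- sprintf("# habitat_mask origin=%.9g,%.9g cell_size=%.9g nx=%d ny=%d",
                 mask$origin[1], mask$origin[2], mask$cell_size,
                 mask$nx, mask$ny)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a habitat mask written by \code{write_mask_csv}
#' @export
read_mask_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  gv <- function(key) as.numeric(sub(sprintf(".*%s=([^ ]+).*", key), "\\1",
                                     hdr))
  origin <- as.numeric(strsplit(sub(".*origin=([^ ]+).*", "\\1", hdr),
                                ",")[[1]])
  cs <- gv("cell_size"); nx <- as.integer(gv("nx")); ny <- as.integer(gv("ny"))
  df <- utils::read.csv(path, skip = 1L)
  water <- matrix(FALSE, ny, nx); stratum <- matrix("Land", ny, nx)
  water[cbind(df$row, df$col)] <- as.logical(df$water)
  stratum[cbind(df$row, df$col)] <- as.character(df$stratum)
  structure(list(origin = origin, cell_size = cs, nx = nx, ny = ny,
                 water = water, stratum = stratum), class = "habitat_mask")
}

#' Read polygons or polylines from a GeoJSON file
#'
#' Supports Polygon, MultiPolygon and LineString geometries in a
#' FeatureCollection (or a bare geometry). Only exterior rings are used.
#'
#' @return list of n x 2 coordinate matrices.
#' @export
read_geojson_shapes <- function(path) {
  g <- jsonlite::read_json(path)
  geoms <- if (identical(g$type, "FeatureCollection")) {
    lapply(g$features, function(f) f$geometry)
  } else if (identical(g$type, "Feature")) list(g$geometry) else list(g)
  out <- list()
  ring_to_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # drop duplicated closing vertex of polygon rings
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), ,
                                                           drop = FALSE]
    m
  }
  for (gm in geoms) {
    switch(gm$type,
      Polygon = { out[[length(out) + 1L]] <- ring_to_mat(gm$coordinates[[1]]) },
      MultiPolygon = for (pg in gm$coordinates)
        out[[length(out) + 1L]] <- ring_to_mat(pg[[1]]),
      LineString = {
        m <- do.call(rbind, lapply(gm$coordinates,
                                   function(p) c(p[[1]], p[[2]])))
        out[[length(out) + 1L]] <- m
      },
      stop(sprintf("unsupported GeoJSON geometry '%s'", gm$type)))
  }
  out
}

#' Write polygons (closed) or polylines to GeoJSON
#'
#' @param shapes list of n x 2 matrices.
#' @param type "Polygon" or "LineString".
#' @export
write_geojson_shapes <- function(shapes, path, type = c("Polygon",
                                                        "LineString")) {
  type <- match.arg(type)
  feats <- lapply(shapes, function(m) {
    coords <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    if (type == "Polygon") {
      coords <- c(coords, coords[1])   # close ring
      geom <- list(type = "Polygon", coordinates = list(coords))
    } else {
      geom <- list(type = "LineString", coordinates = coords)
    }
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = geom)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
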