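#' Bin occurrence points into hexagonal zones
#'
#' Assigns every occurrence point to one cell of a flat-topped axial hexagon
#' grid anchored at (0, 0) and returns each occupied hexagon once with its
#' point count. The hexagon containing a point is the one whose centre is
#' nearest (axial cube rounding), so the zones partition the plane.
#'
#' @param points Two-column matrix or data frame of (longitude, latitude), or
#'   a data frame with `decimalLongitude`/`decimalLatitude` columns.
#' @param cell_radius Hexagon circumradius in degrees (> 0).
#' @return List of occurrence zones, ordered by axial coordinates; each zone
#'   is a list with `zone_id`, `polygon` (closed 7x2 lon/lat ring) and
#'   `occurrence_count`.
#' @export
hexbin_occurrences <- function(points, cell_radius) {
  pts <- as_lonlat(points)
  if (nrow(pts) == 0) stop("no occurrence points supplied")
  if (!is.numeric(cell_radius) || cell_radius <= 0) {
    stop("cell_radius must be positive")
  }
  R <- cell_radius
  # flat-topped axial coordinates (pixel -> hex, cube rounding)
  qf <- (2 / 3) * pts[, 1] / R
  rf <- (-pts[, 1] / 3 + sqrt(3) / 3 * pts[, 2]) / R
  ax <- cube_round(qf, rf)
  key <- paste(ax$q, ax$r, sep = ":")
  tab <- table(key)
  qr <- do.call(rbind, strsplit(names(tab), ":", fixed = TRUE))
  q <- as.integer(qr[, 1]); r <- as.integer(qr[, 2])
  ord <- order(q, r)
  zones <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    j <- ord[i]
    zones[[i]] <- list(
      zone_id = sprintf("hex_%d_%d", q[j], r[j]),
      polygon = hex_polygon(q[j], r[j], R),
      occurrence_count = as.integer(tab[[j]])
    )
  }
  zones
}

as_lonlat <- function(points) {
  if (is.data.frame(points) &&
      all(c("decimalLongitude", "decimalLatitude") %in% names(points))) {
    points <- points[, c("decimalLongitude", "decimalLatitude")]
  }
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  if (ncol(m) != 2) stop("points must have two columns (lon, lat)")
  m[stats::complete.cases(m), , drop = FALSE]
}

cube_round <- function(qf, rf) {
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  q[fix_q] <- -r[fix_q] - s[fix_q]
  r[fix_r] <- -q[fix_r] - s[fix_r]
  list(q = as.integer(q), r = as.integer(r))
}

hex_centre <- function(q, r, R) {
  cbind(lon = 1.5 * R * q, lat = sqrt(3) * R * (r + q / 2))
}

hex_polygon <- function(q, r, R) {
  ctr <- hex_centre(q, r, R)
  ang <- (0:5) * pi / 3  # flat-topped: corners at 0, 60, ..., 300 degrees
  ring <- cbind(lon = ctr[1] + R * cos(ang), lat = ctr[2] + R * sin(ang))
  rbind(ring, ring[1, , drop = FALSE])
}

#' Read occurrence records from CSV
#'
#' GBIF occurrence-export column names: `taxonID`, `decimalLatitude`,
#' `decimalLongitude`.
#'
#' @param path CSV file path.
#' @return Data frame with those three columns.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxonID", "decimalLatitude", "decimalLongitude")
  if (!all(need %in% names(df))) {
    stop("occurrence CSV must have columns ", paste(need, collapse = ", "))
  }
  df[, need]
}

check_zone <- function(zone) {
  poly <- zone$polygon
  if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 4) {
    stop("zone polygon must be a closed ring matrix of (lon, lat)")
  }
  if (any(abs(poly[1, ] - poly[nrow(poly), ]) > 1e-9)) {
    stop("zone polygon ring is not closed")
  }
  lon <- poly[, 1]; lat <- poly[, 2]
  if (any(lat < -90 | lat > 90) || any(lon < -180 - 1e-9 | lon > 180 + 1e-9)) {
    stop("zone vertices outside [-180,180] x [-90,90]")
  }
  if (diff(range(lon)) > 180) {
    stop("zone appears to cross the antimeridian; split it before summarising")
  }
  invisible(TRUE)
}

# row-major indices of cells whose centre falls inside the polygon
zone_cell_index <- function(zone, layer) {
  check_zone(zone)
  cc <- cell_centres(layer)
  poly <- zone$polygon
  cols <- which(cc$lon >= min(poly[, 1]) - layer$cell_w &
                cc$lon <= max(poly[, 1]) + layer$cell_w)
  rows <- which(cc$lat >= min(poly[, 2]) - layer$cell_h &
                cc$lat <= max(poly[, 2]) + layer$cell_h)
  if (length(cols) == 0 || length(rows) == 0) return(integer())
  gx <- rep(cc$lon[cols], each = length(rows))
  gy <- rep(cc$lat[rows], times = length(cols))
  inside <- pracma::inpolygon(gx, gy, poly[-nrow(poly), 1],
                              poly[-nrow(poly), 2], boundary = TRUE)
  if (!any(inside)) return(integer())
  ri <- rep(rows, times = length(cols))[inside]
  ci <- rep(cols, each = length(rows))[inside]
  sort((ci - 1L) * nrow(layer$grid) + ri)  # column-major matrix index
}

#' Raster values inside an occurrence zone
#'
#' Values of all non-nodata cells of `layer` whose centre lies inside the
#' zone polygon (centres exactly on the boundary count as inside).
#'
#' @param zone An occurrence zone (list with a closed `polygon` ring).
#' @param layer A `climate_layer`.
#' @return Numeric vector, possibly empty (zone outside the layer extent or
#'   entirely nodata).
#' @export
zonal_values <- function(zone, layer) {
  stopifnot(inherits(layer, "climate_layer"))
  idx <- zone_cell_index(zone, layer)
  vals <- layer$grid[idx]
  vals[!is.na(vals) & vals != layer$nodata]
}

#' Climatic-niche summary over occurrence zones
#'
#' Overlays a taxon's occurrence zones on the monthly climate stack and, for
#' every variable, reports the spatial mean for each month (unweighted over
#' the union of contributing cells across all zones — a cell in two zones is
#' counted once), the annual mean of the twelve monthly means, and the
#' min/max of the monthly means. Nodata cells are excluded before averaging;
#' a variable with no valid cell in any month is flagged missing, not zero.
#'
#' @param zones Non-empty list of occurrence zones (from
#'   [hexbin_occurrences()] or [read_zones_geojson()]).
#' @param layers The 108-layer stack from [load_layers()].
#' @param range_over `"monthly_means"` (default) computes the reported range
#'   over the twelve monthly spatial means; `"cells"` computes it over all
#'   raw cell x month values.
#' @return Object of class `climate_summary`: list with `monthly` (9 x 12
#'   matrix of monthly spatial means), `annual_mean`, `range_min`,
#'   `range_max`, `n_cells` and `missing` (named by variable).
#' @export
climate_summary <- function(zones, layers,
                            range_over = c("monthly_means", "cells")) {
  range_over <- match.arg(range_over)
  if (length(zones) == 0) stop("no occurrence zones supplied")
  vars <- climate_variables()
  got <- vapply(layers, function(l) paste(l$variable, l$month), "")
  want <- as.vector(outer(vars, 1:12, paste))
  if (!setequal(got, want) || length(layers) != 108) {
    stop("layer stack must contain all 9 variables x 12 months")
  }
  check_layer_geometry(layers)
  ref <- layers[[1]]
  idx <- sort(unique(unlist(lapply(zones, zone_cell_index, layer = ref))))
  monthly <- matrix(NA_real_, nrow = length(vars), ncol = 12,
                    dimnames = list(vars, sprintf("m%02d", 1:12)))
  n_cells <- stats::setNames(integer(length(vars)), vars)
  cell_lo <- cell_hi <- stats::setNames(rep(NA_real_, length(vars)), vars)
  if (length(idx) > 0) {
    for (lay in layers) {
      vals <- lay$grid[idx]
      vals <- vals[!is.na(vals) & vals != lay$nodata]
      if (length(vals) > 0) {
        monthly[lay$variable, lay$month] <- mean(vals)
        n_cells[lay$variable] <- max(n_cells[lay$variable], length(vals))
        cell_lo[lay$variable] <- min(cell_lo[lay$variable], min(vals),
                                     na.rm = TRUE)
        cell_hi[lay$variable] <- max(cell_hi[lay$variable], max(vals),
                                     na.rm = TRUE)
      }
    }
  }
  missing <- apply(monthly, 1, function(r) all(is.na(r)))
  if (all(missing)) {
    stop("no variable has any contributing raster cell over the given zones")
  }
  annual <- rowMeans(monthly, na.rm = TRUE)
  annual[missing] <- NA_real_
  if (range_over == "monthly_means") {
    rmin <- apply(monthly, 1, function(r) if (all(is.na(r))) NA_real_
                  else min(r, na.rm = TRUE))
    rmax <- apply(monthly, 1, function(r) if (all(is.na(r))) NA_real_
                  else max(r, na.rm = TRUE))
  } else {
    rmin <- cell_lo
    rmax <- cell_hi
  }
  structure(
    list(monthly = monthly, annual_mean = annual, range_min = rmin,
         range_max = rmax, n_cells = n_cells, missing = missing,
         range_over = range_over),
    class = "climate_summary"
  )
}

#' @export
print.climate_summary <- function(x, ...) {
  cat("Climatic-niche summary (spatial means over occurrence zones)\n")
  df <- data.frame(variable = names(x$annual_mean),
                   annual_mean = round(x$annual_mean, 3),
                   range_min = round(x$range_min, 3),
                   range_max = round(x$range_max, 3),
                   n_cells = x$n_cells, missing = x$missing,
                   row.names = NULL)
  print(df)
  invisible(x)
}

#' Write occurrence zones as GeoJSON
#'
#' FeatureCollection of Polygons with `zone_id` and `occurrence_count`
#' properties.
#'
#' @param zones List of occurrence zones.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(zones, function(z) {
    check_zone(z)
    list(
      type = "Feature",
      properties = list(zone_id = z$zone_id,
                        occurrence_count = z$occurrence_count),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(z$polygon)), function(i) {
          as.numeric(z$polygon[i, ])
        }))
      )
    )
  })
  obj <- list(type = "FeatureCollection", features = feats)
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = NA)), path)
  invisible(path)
}

#' Read occurrence zones from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Polygons, as written by
#'   [write_zones_geojson()].
#' @return List of occurrence zones.
#' @export
read_zones_geojson <- function(path) {
  if (!file.exists(path)) stop("zones file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  lapply(seq_along(obj$features), function(i) {
    f <- obj$features[[i]]
    if (!identical(f$geometry$type, "Polygon")) {
      stop("feature ", i, " is not a Polygon")
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], as.numeric))
    colnames(ring) <- c("lon", "lat")
    z <- list(
      zone_id = if (!is.null(f$properties$zone_id)) f$properties$zone_id
                else sprintf("zone_%d", i),
      polygon = ring,
      occurrence_count = if (!is.null(f$properties$occurrence_count)) {
        as.integer(f$properties$occurrence_count)
      } else 0L
    )
    check_zone(z)
    z
  })
}
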