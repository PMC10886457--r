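#' Climate variables of the niche summary
#'
#' The nine variables tracked by the climate engine, in canonical order:
#' elevation (m), average/max/min precipitation (mm), solar irradiance
#' (kJ m-2 day-1), average/min/max temperature (deg C) and wind speed (m s-1).
#' These identifiers are also the filename stems of the monthly raster files.
#'
#' @return Character vector of the nine variable identifiers.
#' @export
climate_variables <- function() {
  c("elevation", "precip_avg", "precip_max", "precip_min",
    "solar_irradiance", "temp_avg", "temp_min", "temp_max", "wind_speed")
}

new_climate_layer <- function(variable, month, grid, origin_lon, origin_lat,
                              cell_w, cell_h, nodata = -9999) {
  stopifnot(is.matrix(grid), nrow(grid) > 0, ncol(grid) > 0,
            cell_w > 0, cell_h > 0, month %in% 1:12)
  structure(
    list(variable = variable, month = as.integer(month), grid = grid,
         origin_lon = origin_lon, origin_lat = origin_lat,
         cell_w = cell_w, cell_h = cell_h, nodata = nodata),
    class = "climate_layer"
  )
}

#' Read an ESRI ASCII grid
#'
#' Plain-text single-band raster: header lines `ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`, then rows of values from north to
#' south. Coordinates are plate carree longitude/latitude degrees.
#'
#' @param path File path.
#' @param variable,month Metadata attached to the returned layer.
#' @return A `climate_layer`: grid matrix (row 1 = northernmost), top-left
#'   origin, cell sizes in degrees, nodata sentinel.
#' @export
read_ascii_grid <- function(path, variable = NA_character_, month = 1L) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header incomplete in ", path, " (need ",
         paste(setdiff(need, names(hdr)), collapse = ", "), ")")
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc,
         " in ", path)
  }
  grid <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  new_climate_layer(variable, month, grid,
                    origin_lon = hdr$xllcorner,
                    origin_lat = hdr$yllcorner + nr * hdr$cellsize,
                    cell_w = hdr$cellsize, cell_h = hdr$cellsize,
                    nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param layer A `climate_layer` (square cells required by the format).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path) {
  stopifnot(inherits(layer, "climate_layer"))
  if (abs(layer$cell_w - layer$cell_h) > 1e-12) {
    stop("ESRI ASCII grids require square cells")
  }
  nr <- nrow(layer$grid); nc <- ncol(layer$grid)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", layer$origin_lon),
    sprintf("yllcorner %.10g", layer$origin_lat - nr * layer$cell_h),
    sprintf("cellsize %.10g", layer$cell_w),
    sprintf("NODATA_value %.10g", layer$nodata)
  )
  rows <- apply(layer$grid, 1, function(r) paste(format(r, trim = TRUE,
                                                        digits = 15),
                                                 collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Load the full stack of monthly climate layers
#'
#' Expects files `<variable>_<month:02d>.asc` for each of the nine
#' [climate_variables()] and months 01-12. Elevation, which has no seasonal
#' cycle, may instead be supplied as a single `elevation.asc`; it is then
#' replicated across the twelve months so the uniform monthly pipeline
#' applies. All grids must share shape and geotransform.
#'
#' @param raster_dir Directory containing the grids.
#' @return List of 108 `climate_layer` objects (9 variables x 12 months).
#' @export
load_layers <- function(raster_dir) {
  if (!dir.exists(raster_dir)) stop("raster directory not found: ", raster_dir)
  layers <- list()
  for (v in climate_variables()) {
    single <- file.path(raster_dir, paste0(v, ".asc"))
    use_single <- v == "elevation" && file.exists(single) &&
      !file.exists(file.path(raster_dir, sprintf("%s_01.asc", v)))
    if (use_single) {
      base <- read_ascii_grid(single, variable = v, month = 1L)
      for (m in 1:12) {
        lay <- base
        lay$month <- as.integer(m)
        layers[[length(layers) + 1]] <- lay
      }
    } else {
      for (m in 1:12) {
        p <- file.path(raster_dir, sprintf("%s_%02d.asc", v, m))
        if (!file.exists(p)) {
          stop("missing raster for variable '", v, "' month ", m, ": ", p)
        }
        layers[[length(layers) + 1]] <- read_ascii_grid(p, variable = v,
                                                        month = m)
      }
    }
  }
  check_layer_geometry(layers)
  layers
}

check_layer_geometry <- function(layers) {
  ref <- layers[[1]]
  for (lay in layers[-1]) {
    if (nrow(lay$grid) != nrow(ref$grid) || ncol(lay$grid) != ncol(ref$grid)) {
      stop("inconsistent grid shapes across layers (",
           lay$variable, " month ", lay$month, ")")
    }
    if (abs(lay$origin_lon - ref$origin_lon) > 1e-9 ||
        abs(lay$origin_lat - ref$origin_lat) > 1e-9 ||
        abs(lay$cell_w - ref$cell_w) > 1e-12 ||
        abs(lay$cell_h - ref$cell_h) > 1e-12) {
      stop("inconsistent geotransform across layers (",
           lay$variable, " month ", lay$month, ")")
    }
  }
  invisible(TRUE)
}

# lon/lat of all cell centres; rows top to bottom, row-major indexing
cell_centres <- function(layer) {
  nr <- nrow(layer$grid); nc <- ncol(layer$grid)
  lon <- layer$origin_lon + (seq_len(nc) - 0.5) * layer$cell_w
  lat <- layer$origin_lat - (seq_len(nr) - 0.5) * layer$cell_h
  list(lon = lon, lat = lat)
}
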