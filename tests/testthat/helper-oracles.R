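# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain scans and textbook formulas only.

# every record whose scientific name or any vernacular contains the query
oracle_suggest_ids <- function(query, bb) {
  q <- tolower(trimws(query))
  rec <- bb$records
  hit <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    sci <- grepl(q, tolower(rec$scientific_name[i]), fixed = TRUE)
    v <- bb$vernaculars[[rec$taxon_id[i]]]
    vern <- !is.null(v) && any(grepl(q, tolower(v), fixed = TRUE))
    hit[i] <- sci || vern
  }
  sort(rec$taxon_id[hit])
}

# even-odd ray casting, vectorised over points; `ring` is an open ring
oracle_pip <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# exhaustive cell x month scan over the full grids: monthly spatial means
# over the union of cells whose centre falls in any zone polygon
oracle_climate_monthly <- function(zones, layers) {
  ref <- layers[[1]]
  nr <- nrow(ref$grid); nc <- ncol(ref$grid)
  lon <- ref$origin_lon + (rep(seq_len(nc), each = nr) - 0.5) * ref$cell_w
  lat <- ref$origin_lat - (rep(seq_len(nr), times = nc) - 0.5) * ref$cell_h
  in_any <- rep(FALSE, nr * nc)
  for (z in zones) {
    ring <- z$polygon[-nrow(z$polygon), , drop = FALSE]
    in_any <- in_any | oracle_pip(lon, lat, ring)
  }
  vars <- unique(vapply(layers, function(l) l$variable, ""))
  out <- matrix(NA_real_, nrow = length(vars), ncol = 12,
                dimnames = list(vars, NULL))
  for (lay in layers) {
    vals <- as.vector(lay$grid)[in_any]   # column-major, matches lon/lat order
    vals <- vals[vals != lay$nodata]
    if (length(vals) > 0) out[lay$variable, lay$month] <- mean(vals)
  }
  out
}

# nearest-hex-centre assignment over a broad candidate grid of flat-topped
# axial hexagons with circumradius R anchored at the origin
oracle_hex_assign <- function(pts, R) {
  qmax <- ceiling(max(abs(pts[, 1])) / (1.5 * R)) + 2
  rmax <- ceiling(max(abs(pts[, 2])) / (sqrt(3) * R)) + qmax + 2
  cand <- expand.grid(q = -qmax:qmax, r = -rmax:rmax)
  cx <- 1.5 * R * cand$q
  cy <- sqrt(3) * R * (cand$r + cand$q / 2)
  key <- character(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d2 <- (pts[i, 1] - cx)^2 + (pts[i, 2] - cy)^2
    j <- which.min(d2)
    key[i] <- paste(cand$q[j], cand$r[j], sep = ":")
  }
  key
}

# min over matched entries of the cosine formula, written out longhand
oracle_min_cosine_pct <- function(entity_tok, entries, vectors) {
  others <- entries[entries != entity_tok]
  if (length(others) == 0) return(100)
  e <- vectors[entity_tok, ]
  sims <- numeric(length(others))
  for (i in seq_along(others)) {
    u <- vectors[others[i], ]
    sims[i] <- sum(u * e) / (sqrt(sum(u^2)) * sqrt(sum(e^2)))
  }
  100 * min(sims)
}

# small random embedding model whose tokens share query-able segments
random_model <- function(seed, n_tokens = 60, dim = 8) {
  set.seed(seed)
  stems <- c("vespa", "apis", "formica", "corvus", "pica")
  toks <- unique(c(
    stems,
    paste0(sample(stems, n_tokens, replace = TRUE), "_",
           replicate(n_tokens, paste(sample(letters, 5, TRUE), collapse = "")))
  ))
  v <- matrix(stats::rnorm(length(toks) * dim), nrow = length(toks),
              dimnames = list(toks, NULL))
  embedding_model(v)
}

# entity vocabulary covering all tokens of a model, single category
vocab_from_tokens <- function(tokens, category = "HABITAT") {
  tf <- tempfile()
  writeLines(gsub("_", " ", tokens), tf)
  paths <- list(tf)
  names(paths) <- category
  load_entities(paths)
}

# constant-value square zone helper (closed ring)
square_zone <- function(lon0, lon1, lat0, lat1, id = "sq") {
  list(zone_id = id,
       polygon = cbind(lon = c(lon0, lon1, lon1, lon0, lon0),
                       lat = c(lat0, lat0, lat1, lat1, lat0)),
       occurrence_count = 1L)
}

# minimal single-layer constant grid
constant_layer <- function(value, n = 10, variable = "temp_avg", month = 1,
                           origin_lon = 0, origin_lat = 10, cell = 1,
                           nodata = -9999) {
  bioexplore:::new_climate_layer(variable, month,
                                 matrix(value, n, n), origin_lon, origin_lat,
                                 cell, cell, nodata)
}

# full 108-layer stack with per-variable-month constant values
constant_stack <- function(base, n = 10, origin_lon = 0, origin_lat = 10,
                           cell = 1) {
  vars <- climate_variables()
  if (is.vector(base) && length(base) == 12) {
    base <- matrix(rep(base, each = length(vars)), nrow = length(vars),
                   dimnames = list(vars, NULL))
  }
  layers <- list()
  for (v in vars) {
    for (m in 1:12) {
      layers[[length(layers) + 1]] <-
        constant_layer(base[v, m], n = n, variable = v, month = m,
                       origin_lon = origin_lon, origin_lat = origin_lat,
                       cell = cell)
    }
  }
  layers
}
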