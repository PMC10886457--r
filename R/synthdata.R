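#' Paths of the packaged worked-example backbone fixture
#'
#' A small hand-curated backbone holding the seventeen species returned by
#' the worked search examples ("blue whale", "mockingbird", "nikolay")
#' together with their full seven-rank lineages and vernacular names.
#'
#' @return Named list with `backbone` and `vernaculars` file paths.
#' @export
table2_fixture_paths <- function() {
  list(
    backbone = system.file("extdata", "table2_backbone.tsv",
                           package = "bioexplore", mustWork = TRUE),
    vernaculars = system.file("extdata", "table2_vernaculars.tsv",
                              package = "bioexplore", mustWork = TRUE)
  )
}

# substrings that generated names must not contain, so the worked-example
# queries keep their printed result counts on fixtures with distractors
forbidden_name_parts <- function() {
  c("mockingbird", "blue whale", "nikolay", "megachile", "cataglyphis")
}

pseudo_word <- function(n_syll) {
  syll <- c("ba", "ce", "do", "fi", "gu", "la", "me", "ni", "po", "ra",
            "su", "ta", "ve", "xo", "zu", "ka", "li", "mo", "pe", "ru")
  paste(sample(syll, n_syll, replace = TRUE), collapse = "")
}

fresh_word <- function(used, n_syll = 3) {
  repeat {
    w <- pseudo_word(n_syll)
    ok <- !(w %in% used) &&
      !any(vapply(forbidden_name_parts(), grepl, logical(1), x = w,
                  fixed = TRUE))
    if (ok) return(w)
  }
}

cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Generate a synthetic taxonomic backbone
#'
#' Writes a backbone TSV and a vernacular TSV with pronounceable pseudo-Latin
#' names and full seven-rank lineages. All genera share one kingdom, phylum,
#' class and order; each genus sits in its own family, so querying species
#' from two genera bifurcates the merged tree at the order. Generated names
#' are guaranteed not to contain the worked-example query strings, so the
#' generated records act as distractors for those queries. Optionally the
#' packaged worked-example fixture is appended verbatim.
#'
#' @param n_species_per_genus Integer vector; element i is the number of
#'   species in genus i.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; identical seeds give identical files.
#' @param include_table2 Append the packaged fixture records (default FALSE).
#' @param n_vernacular_collisions Number of consecutive species pairs that
#'   share a vernacular name (default 0), for testing shared-vernacular
#'   behaviour.
#' @return Named list with `backbone` and `vernaculars` paths plus
#'   `species_ids` (generated species, by genus).
#' @export
generate_backbone <- function(n_species_per_genus, dir = tempfile("backbone"),
                              seed = 1L, include_table2 = FALSE,
                              n_vernacular_collisions = 0L) {
  stopifnot(length(n_species_per_genus) >= 1, all(n_species_per_genus >= 1))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  used <- character()
  nm <- function(n_syll = 3) {
    w <- fresh_word(used, n_syll)
    used <<- c(used, w)
    w
  }
  rows <- list(
    c("x-k1", cap(nm(3)), "kingdom", ""),
    c("x-p1", cap(nm(3)), "phylum", "x-k1"),
    c("x-c1", cap(nm(3)), "class", "x-p1"),
    c("x-o1", cap(nm(3)), "order", "x-c1")
  )
  vern_rows <- list()
  species_ids <- list()
  vern_pool <- character()
  for (g in seq_along(n_species_per_genus)) {
    fid <- sprintf("x-f%d", g)
    gid <- sprintf("x-g%d", g)
    genus_name <- cap(nm(3))
    rows[[length(rows) + 1]] <- c(fid, cap(nm(4)), "family", "x-o1")
    rows[[length(rows) + 1]] <- c(gid, genus_name, "genus", fid)
    ids <- character(n_species_per_genus[g])
    for (j in seq_len(n_species_per_genus[g])) {
      sid <- sprintf("x-s%d-%d", g, j)
      ids[j] <- sid
      rows[[length(rows) + 1]] <- c(sid, paste(genus_name, nm(3)),
                                    "species", gid)
      vern <- paste(nm(2), nm(2))
      vern_pool <- c(vern_pool, vern)
      vern_rows[[length(vern_rows) + 1]] <- c(sid, vern)
    }
    species_ids[[g]] <- ids
  }
  # planted vernacular collisions: pair 2k shares the vernacular of pair 2k-1
  if (n_vernacular_collisions > 0 && length(vern_rows) >= 2) {
    k <- min(n_vernacular_collisions, floor(length(vern_rows) / 2))
    for (i in seq_len(k)) {
      vern_rows[[2 * i]][2] <- vern_rows[[2 * i - 1]][2]
    }
  }
  b_lines <- c("taxonID\tscientificName\trank\tparentID",
               vapply(rows, paste, "", collapse = "\t"))
  v_lines <- c("taxonID\tvernacularName",
               vapply(vern_rows, paste, "", collapse = "\t"))
  if (include_table2) {
    fx <- table2_fixture_paths()
    b_lines <- c(b_lines, readLines(fx$backbone, warn = FALSE)[-1])
    v_lines <- c(v_lines, readLines(fx$vernaculars, warn = FALSE)[-1])
  }
  b_path <- file.path(dir, "backbone.tsv")
  v_path <- file.path(dir, "vernaculars.tsv")
  writeLines(b_lines, b_path)
  writeLines(v_lines, v_path)
  list(backbone = b_path, vernaculars = v_path, species_ids = species_ids)
}

#' Specification for a synthetic planted-co-occurrence corpus
#'
#' Describes a corpus in which every sentence mentions exactly two entities,
#' drawn from the same planted group with probability `within_group_rate`,
#' embedded among filler words. Entities span the four categories so
#' cross-category expansion is testable.
#'
#' @param n_groups Number of planted groups.
#' @param entities_per_group Entities per group.
#' @param n_sentences Number of sentences.
#' @param within_group_rate Probability in [0, 1] that a sentence's two
#'   entities share a group.
#' @param filler_vocab_size Number of distinct filler words.
#' @param sentence_length Filler words per sentence (entity mentions are
#'   inserted on top).
#' @param seed Integer seed.
#' @return Object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_groups = 3L, entities_per_group = 5L,
                        n_sentences = 5000L, within_group_rate = 0.8,
                        filler_vocab_size = 50L, sentence_length = 8L,
                        seed = 1L) {
  stopifnot(n_groups >= 1, entities_per_group >= 1, n_sentences >= 1,
            within_group_rate >= 0, within_group_rate <= 1,
            filler_vocab_size >= 1, sentence_length >= 1)
  structure(list(n_groups = as.integer(n_groups),
                 entities_per_group = as.integer(entities_per_group),
                 n_sentences = as.integer(n_sentences),
                 within_group_rate = within_group_rate,
                 filler_vocab_size = as.integer(filler_vocab_size),
                 sentence_length = as.integer(sentence_length),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a corpus with planted entity co-occurrence
#'
#' Each sentence embeds two entity mentions (multi-word labels allowed, so
#' phrasing is exercised) at most three words apart, padded with filler
#' words. Entity categories cycle within each group with a per-group offset,
#' so every category is populated and groups span categories. When `dir` is
#' given, writes `corpus.txt` plus one `entities_<category>.txt` per
#' category.
#'
#' @param spec A [corpus_spec()].
#' @param dir Optional output directory.
#' @return List with `sentences` (character vector), `entities` (data frame
#'   with `label`, `category`, `token`, `group`), `same_group` (logical per
#'   sentence) and, when written, `corpus_path` and `entity_paths`.
#' @export
generate_corpus <- function(spec = corpus_spec(), dir = NULL) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  cats <- entity_categories()
  used <- character()
  ents <- list()
  for (g in seq_len(spec$n_groups)) {
    for (j in seq_len(spec$entities_per_group)) {
      w <- fresh_word(used, 3)
      used <- c(used, w)
      # every third entity gets a two-word label to exercise phrasing
      if (j %% 3 == 0) {
        w2 <- fresh_word(used, 2)
        used <- c(used, w2)
        label <- paste(w, w2)
      } else {
        label <- w
      }
      ents[[length(ents) + 1]] <- data.frame(
        label = label,
        category = cats[((j - 1 + g - 1) %% length(cats)) + 1],
        token = entity_token(label),
        group = g,
        stringsAsFactors = FALSE
      )
    }
  }
  entities <- do.call(rbind, ents)
  fillers <- character(spec$filler_vocab_size)
  for (i in seq_len(spec$filler_vocab_size)) {
    fillers[i] <- fresh_word(c(used, fillers), 2)
  }
  groups <- split(seq_len(nrow(entities)), entities$group)
  same_group <- stats::runif(spec$n_sentences) < spec$within_group_rate
  sentences <- character(spec$n_sentences)
  for (s in seq_len(spec$n_sentences)) {
    if (same_group[s] && spec$entities_per_group >= 2) {
      g <- sample.int(spec$n_groups, 1)
      pair <- sample(groups[[g]], 2)
    } else {
      gs <- if (spec$n_groups >= 2) sample.int(spec$n_groups, 2) else c(1, 1)
      pair <- c(sample(groups[[gs[1]]], 1), sample(groups[[gs[2]]], 1))
    }
    w <- sample(fillers, spec$sentence_length, replace = TRUE)
    i1 <- sample.int(spec$sentence_length, 1)
    gap <- sample.int(3, 1)
    left <- append(w[seq_len(i1)], strsplit(entities$label[pair[1]], " ")[[1]],
                   after = i1)
    rest <- w[-seq_len(i1)]
    cut <- min(gap, length(rest))
    words <- c(left, rest[seq_len(cut)],
               strsplit(entities$label[pair[2]], " ")[[1]],
               if (cut < length(rest)) rest[(cut + 1):length(rest)])
    sentences[s] <- paste0(paste(words, collapse = " "), ".")
  }
  out <- list(sentences = sentences, entities = entities,
              same_group = same_group)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    corpus_path <- file.path(dir, "corpus.txt")
    writeLines(sentences, corpus_path)
    entity_paths <- stats::setNames(
      file.path(dir, sprintf("entities_%s.txt", tolower(cats))), cats)
    for (cat in cats) {
      writeLines(entities$label[entities$category == cat], entity_paths[[cat]])
    }
    out$corpus_path <- corpus_path
    out$entity_paths <- as.list(entity_paths)
  }
  out
}

#' Specification for synthetic monthly climate rasters
#'
#' Grid values are `base[variable, month] + amplitude * gx + noise`, where
#' `gx` is a zero-mean west-east gradient, so the full-grid spatial mean of
#' every layer is analytically known. Defaults emulate a temperate
#' mid-latitude seasonal cycle on a 10 x 7.5 degree window at 0.25 degree
#' resolution.
#'
#' @param n_rows,n_cols Grid shape.
#' @param origin_lon,origin_lat Top-left corner, degrees.
#' @param cell_size Cell size in degrees (square cells).
#' @param base_values 9 x 12 matrix of per-variable monthly base values
#'   (rows ordered as [climate_variables()]), or a length-12 vector applied
#'   to every variable, or NULL for seasonal defaults.
#' @param gradient_amplitude Amplitude of the west-east gradient.
#' @param nodata_fraction Probability a cell is nodata, in [0, 1).
#' @param seed Integer seed.
#' @return Object of class `raster_spec`.
#' @export
raster_spec <- function(n_rows = 30L, n_cols = 40L, origin_lon = -10,
                        origin_lat = 55, cell_size = 0.25,
                        base_values = NULL, gradient_amplitude = 0,
                        nodata_fraction = 0, seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0,
            nodata_fraction >= 0, nodata_fraction < 1)
  vars <- climate_variables()
  if (is.null(base_values)) {
    m <- 1:12
    season <- cos(2 * pi * (m - 7) / 12)  # peaks in July
    base_values <- rbind(
      elevation = rep(400, 12),
      precip_avg = 60 - 15 * season,
      precip_max = 100 - 15 * season,
      precip_min = 25 - 10 * season,
      solar_irradiance = 12000 + 7000 * season,
      temp_avg = 10 + 8 * season,
      temp_min = 5 + 8 * season,
      temp_max = 15 + 8 * season,
      wind_speed = 4.5 - 1.5 * season
    )
  } else if (is.vector(base_values) && length(base_values) == 12) {
    base_values <- matrix(rep(base_values, each = length(vars)),
                          nrow = length(vars), ncol = 12)
  }
  stopifnot(is.matrix(base_values), nrow(base_values) == length(vars),
            ncol(base_values) == 12)
  rownames(base_values) <- vars
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_size = cell_size, base_values = base_values,
                 gradient_amplitude = gradient_amplitude,
                 nodata_fraction = nodata_fraction, seed = as.integer(seed)),
            class = "raster_spec")
}

#' Generate synthetic monthly climate rasters
#'
#' Writes the 108 ESRI ASCII grids (9 variables x 12 months) described by a
#' [raster_spec()], plus a `manifest.json` sidecar recording the geometry and
#' the exact spatial mean of every layer over its valid (non-nodata) cells,
#' enabling exact assertions downstream.
#'
#' @param spec A `raster_spec`.
#' @param dir Output directory (created if needed).
#' @return Named list with `dir`, `manifest` path, and `means` (9 x 12
#'   matrix of per-layer spatial means over valid cells).
#' @export
generate_rasters <- function(spec = raster_spec(), dir = tempfile("rasters")) {
  stopifnot(inherits(spec, "raster_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  vars <- climate_variables()
  nr <- spec$n_rows; nc <- spec$n_cols
  gx <- matrix(rep((seq_len(nc) - 0.5) / nc - 0.5, each = nr), nrow = nr)
  nodata <- -9999
  means <- matrix(NA_real_, nrow = length(vars), ncol = 12,
                  dimnames = list(vars, sprintf("m%02d", 1:12)))
  for (v in vars) {
    for (m in 1:12) {
      grid <- spec$base_values[v, m] + spec$gradient_amplitude * gx
      if (spec$nodata_fraction > 0) {
        mask <- stats::runif(nr * nc) < spec$nodata_fraction
        grid[mask] <- nodata
      }
      valid <- grid[grid != nodata]
      means[v, m] <- if (length(valid) > 0) mean(valid) else NA_real_
      lay <- new_climate_layer(v, m, grid, spec$origin_lon, spec$origin_lat,
                               spec$cell_size, spec$cell_size, nodata)
      write_ascii_grid(lay, file.path(dir, sprintf("%s_%02d.asc", v, m)))
    }
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(n_rows = nr, n_cols = nc, origin_lon = spec$origin_lon,
         origin_lat = spec$origin_lat, cell_size = spec$cell_size,
         nodata = nodata,
         monthly_means = as.data.frame(means),
         annual_mean = rowMeans(means)),
    manifest, auto_unbox = TRUE, digits = NA)
  list(dir = dir, manifest = manifest, means = means)
}

#' Generate clustered synthetic occurrence points
#'
#' Draws cluster centres uniformly in the given extent and scatters points
#' normally around them, emulating the spatially clustered occurrence records
#' typical of biodiversity databases.
#'
#' @param n_points Total number of points.
#' @param n_clusters Number of clusters.
#' @param extent Numeric `c(lon_min, lon_max, lat_min, lat_max)`; default
#'   sits inside the default [raster_spec()] window.
#' @param spread Cluster standard deviation in degrees.
#' @param seed Integer seed.
#' @param path Optional CSV output path (GBIF occurrence-export columns).
#' @return Data frame with `taxonID`, `decimalLatitude`, `decimalLongitude`.
#' @export
generate_occurrences <- function(n_points = 200L, n_clusters = 3L,
                                 extent = c(-9, -1, 48.5, 54.5),
                                 spread = 0.6, seed = 1L, path = NULL) {
  stopifnot(n_points >= 1, n_clusters >= 1, spread > 0)
  set.seed(seed)
  cl <- sample.int(n_clusters, n_points, replace = TRUE)
  cx <- stats::runif(n_clusters, extent[1], extent[2])
  cy <- stats::runif(n_clusters, extent[3], extent[4])
  df <- data.frame(
    taxonID = "synthetic-taxon",
    decimalLatitude = pmin(pmax(cy[cl] + stats::rnorm(n_points, 0, spread),
                                -90), 90),
    decimalLongitude = pmin(pmax(cx[cl] + stats::rnorm(n_points, 0, spread),
                                 -180), 180)
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
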