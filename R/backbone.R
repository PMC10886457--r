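#' Load a taxonomic backbone from TSV files
#'
#' Reads a simplified GBIF-style backbone export (tab-separated, header row
#' `taxonID  scientificName  rank  parentID`) together with a vernacular-name
#' table (`taxonID  vernacularName`, one name per row) and builds an in-memory
#' backbone with name indexes ready for [suggest()] and [lineage()].
#'
#' Structural requirements are enforced at load time: every non-kingdom record
#' must reference a parent present in the file, the parent's rank must be
#' strictly higher in the canonical order, parent chains must terminate at a
#' kingdom, and ranks outside [canonical_ranks()] are an error. Malformed rows
#' (wrong field count, empty id or name) are dropped with a warning that
#' reports how many were rejected.
#'
#' @param backbone_path Path to the backbone TSV.
#' @param vernacular_path Path to the vernacular TSV. Optional; when missing
#'   the backbone has no vernacular index.
#' @return An object of class `backbone`: list with `records` (data frame with
#'   columns `taxon_id`, `scientific_name`, `rank`, `parent_id`, rownames =
#'   taxon_id), `vernaculars` (named list taxon_id -> character vector of
#'   lowercase common names), and lowercase search indexes.
#' @export
load_backbone <- function(backbone_path, vernacular_path = NULL) {
  if (!file.exists(backbone_path)) {
    stop("backbone file not found: ", backbone_path)
  }
  raw <- readLines(backbone_path, encoding = "UTF-8", warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0) {
    return(new_backbone(empty_records(), list()))
  }
  header <- strsplit(raw[[1]], "\t", fixed = TRUE)[[1]]
  body <- raw[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 3 && nzchar(trimws(f[[1]])) && nzchar(trimws(f[[2]]))
  }, logical(1))
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("dropped %d malformed backbone row(s)", n_bad))
  }
  fields <- fields[ok]
  if (length(fields) == 0) {
    return(new_backbone(empty_records(), list()))
  }
  rec <- data.frame(
    taxon_id        = trimws(vapply(fields, `[[`, "", 1L)),
    scientific_name = trimws(vapply(fields, `[[`, "", 2L)),
    rank            = tolower(trimws(vapply(fields, `[[`, "", 3L))),
    parent_id       = trimws(vapply(fields, function(f) {
      if (length(f) >= 4) f[[4]] else ""
    }, "")),
    stringsAsFactors = FALSE
  )
  bad_rank <- setdiff(unique(rec$rank), canonical_ranks())
  if (length(bad_rank) > 0) {
    stop("rank outside the canonical set: ", paste(bad_rank, collapse = ", "))
  }
  if (anyDuplicated(rec$taxon_id)) {
    stop("duplicate taxon ids in backbone: ",
         paste(unique(rec$taxon_id[duplicated(rec$taxon_id)]), collapse = ", "))
  }
  rownames(rec) <- rec$taxon_id
  # structural checks: parent resolution, rank ordering, chains end at kingdom
  has_parent <- nzchar(rec$parent_id)
  missing_parent <- rec$parent_id[has_parent][
    !(rec$parent_id[has_parent] %in% rec$taxon_id)]
  if (length(missing_parent) > 0) {
    stop("parent id(s) absent from backbone: ",
         paste(unique(missing_parent), collapse = ", "))
  }
  if (any(!has_parent & rec$rank != "kingdom")) {
    stop("non-kingdom record(s) without a parent: ",
         paste(rec$taxon_id[!has_parent & rec$rank != "kingdom"], collapse = ", "))
  }
  if (any(has_parent & rec$rank == "kingdom")) {
    stop("kingdom record(s) must not have a parent")
  }
  lev <- rank_level(rec$rank)
  plev <- rank_level(rec[rec$parent_id[has_parent], "rank"])
  if (any(plev >= lev[has_parent])) {
    off <- rec$taxon_id[has_parent][plev >= lev[has_parent]]
    stop("parent rank not strictly higher than child for: ",
         paste(off, collapse = ", "))
  }
  vern <- list()
  if (!is.null(vernacular_path)) {
    if (!file.exists(vernacular_path)) {
      stop("vernacular file not found: ", vernacular_path)
    }
    vraw <- readLines(vernacular_path, encoding = "UTF-8", warn = FALSE)
    vraw <- vraw[nzchar(trimws(vraw))]
    if (length(vraw) > 1) {
      vf <- strsplit(vraw[-1], "\t", fixed = TRUE)
      vok <- vapply(vf, function(f) length(f) >= 2 && nzchar(trimws(f[[1]])), logical(1))
      vf <- vf[vok]
      ids <- vapply(vf, `[[`, "", 1L)
      nm <- tolower(trimws(vapply(vf, `[[`, "", 2L)))
      keep <- ids %in% rec$taxon_id & nzchar(nm)
      vern <- split(nm[keep], ids[keep])
    }
  }
  new_backbone(rec, vern)
}

empty_records <- function() {
  data.frame(taxon_id = character(), scientific_name = character(),
             rank = character(), parent_id = character(),
             stringsAsFactors = FALSE)
}

new_backbone <- function(records, vernaculars) {
  structure(
    list(
      records = records,
      vernaculars = vernaculars,
      sci_lower = tolower(records$scientific_name),
      vern_lower = lapply(vernaculars, tolower)
    ),
    class = "backbone"
  )
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone: %d records, %d with vernacular names>\n",
              nrow(x$records), length(x$vernaculars)))
  invisible(x)
}

#' Suggest taxa matching a query
#'
#' Case-insensitive substring search over scientific names (including genus
#' and specific epithet, which are substrings of the full name) and vernacular
#' names, capped at `limit` suggestions. Ordering is deterministic: scientific
#' matches before vernacular-only matches, then by earliest match position,
#' then alphabetically by scientific name.
#'
#' @param query Search text; must be non-empty after trimming.
#' @param backbone A `backbone` from [load_backbone()].
#' @param limit Maximum number of suggestions (default 20).
#' @return Data frame with columns `taxon_id`, `scientific_name`, `rank`,
#'   `parent_id`, `match_kind` ("scientific" or "vernacular") and
#'   `colour_code` (rank palette colour). Zero rows when nothing matches.
#' @export
suggest <- function(query, backbone, limit = 20L) {
  stopifnot(inherits(backbone, "backbone"))
  q <- tolower(trimws(query))
  if (!nzchar(q)) stop("query is empty")
  if (!is.numeric(limit) || length(limit) != 1 || limit < 1) {
    stop("limit must be a positive integer")
  }
  rec <- backbone$records
  if (nrow(rec) == 0) return(empty_suggestions())

  sci_pos <- as.integer(regexpr(q, backbone$sci_lower, fixed = TRUE))
  sci_hit <- sci_pos > 0L

  vern_pos <- rep(NA_integer_, nrow(rec))
  if (length(backbone$vern_lower) > 0) {
    idx <- match(names(backbone$vern_lower), rec$taxon_id)
    pos <- vapply(backbone$vern_lower, function(v) {
      p <- regexpr(q, v, fixed = TRUE)
      p <- p[p > 0]
      if (length(p) == 0) NA_integer_ else as.integer(min(p))
    }, integer(1))
    keep <- !is.na(idx)
    vern_pos[idx[keep]] <- pos[keep]
  }
  vern_hit <- !is.na(vern_pos)

  hit <- sci_hit | vern_hit
  if (!any(hit)) return(empty_suggestions())

  kind <- ifelse(sci_hit[hit], "scientific", "vernacular")
  pos <- ifelse(sci_hit[hit], sci_pos[hit], vern_pos[hit])
  out <- rec[hit, , drop = FALSE]
  ord <- order(match(kind, c("scientific", "vernacular")), pos,
               out$scientific_name)
  out <- out[ord, , drop = FALSE]
  kind <- kind[ord]
  n <- min(nrow(out), as.integer(limit))
  out <- out[seq_len(n), , drop = FALSE]
  out$match_kind <- kind[seq_len(n)]
  out$colour_code <- rank_colour(out$rank)
  rownames(out) <- NULL
  out
}

empty_suggestions <- function() {
  cbind(empty_records(),
        data.frame(match_kind = character(), colour_code = character(),
                   stringsAsFactors = FALSE))
}

#' Lineage of a taxon
#'
#' Follows parent links from the queried taxon up to its kingdom and returns
#' the path in root-first order.
#'
#' @param taxon_id Identifier present in the backbone.
#' @param backbone A `backbone`.
#' @return Data frame of records ordered kingdom first, queried taxon last,
#'   with class `lineage`.
#' @export
lineage <- function(taxon_id, backbone) {
  stopifnot(inherits(backbone, "backbone"))
  rec <- backbone$records
  if (!(taxon_id %in% rec$taxon_id)) {
    stop("unknown taxon id: ", taxon_id)
  }
  path <- character()
  id <- taxon_id
  repeat {
    path <- c(id, path)
    if (length(path) > length(canonical_ranks())) {
      stop("parent chain longer than the canonical rank ladder (cycle?)")
    }
    pid <- rec[id, "parent_id"]
    if (!nzchar(pid)) break
    id <- pid
  }
  out <- rec[path, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lineage", class(out))
  out
}
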