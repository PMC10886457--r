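#' Vocabulary entries matching a query
#'
#' Finds all embedding-vocabulary tokens that "contain" the query: by default
#' the query (lowercased, spaces to underscores) must equal the token or
#' appear as a contiguous run of underscore-delimited segments, so "vespa"
#' matches "vespa_mandarina" but not "vespavirus". `mode = "substring"`
#' relaxes this to plain substring containment.
#'
#' @param query Non-empty query text.
#' @param model An `embedding_model`.
#' @param mode `"word"` (default) or `"substring"`.
#' @return Alphabetically sorted character vector of matching tokens; its
#'   length is the N of the compatibility definition. Errors when nothing
#'   matches (out-of-vocabulary query).
#' @export
match_entries <- function(query, model, mode = c("word", "substring")) {
  stopifnot(inherits(model, "embedding_model"))
  mode <- match.arg(mode)
  q <- entity_token(query)
  toks <- rownames(model$vectors)
  if (mode == "substring") {
    hit <- grepl(q, toks, fixed = TRUE)
  } else {
    qseg <- strsplit(q, "_", fixed = TRUE)[[1]]
    hit <- vapply(strsplit(toks, "_", fixed = TRUE), function(seg) {
      nq <- length(qseg); ns <- length(seg)
      if (nq > ns) return(FALSE)
      for (i in seq_len(ns - nq + 1)) {
        if (all(seg[i:(i + nq - 1)] == qseg)) return(TRUE)
      }
      FALSE
    }, logical(1))
  }
  if (!any(hit)) {
    stop("query '", query, "' matches no entry in the model vocabulary")
  }
  sort(toks[hit])
}

cosine_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# 100 * min over matched entries of cosine(entry, entity), excluding the
# entity's own token from the minimum when other entries exist
score_against_entries <- function(entity_tok, entries, model) {
  v <- model$vectors
  others <- setdiff(entries, entity_tok)
  if (length(others) == 0) return(100)
  en <- cosine_rows(v[others, , drop = FALSE])
  ev <- cosine_rows(v[entity_tok, , drop = FALSE])
  100 * min(as.vector(en %*% t(ev)))
}

#' Compatibility score between a query and an entity
#'
#' The compatibility of an entity with a query word is 100 times the minimum
#' cosine similarity between the entity's vector and the vectors of the N
#' vocabulary entries containing the query (see [match_entries()]); 100
#' means perfect compatibility with every matching entry. When the entity's
#' own token is among the entries it is excluded from the minimum (unless it
#' is the only entry, in which case the score is 100). Scores live in
#' [-100, 100]: cosines can be negative and no floor is applied.
#'
#' @param query Query text; must match at least one vocabulary entry.
#' @param entity An entity row from an `entity_vocabulary` (or a plain token
#'   string) whose token is in the model vocabulary.
#' @param model An `embedding_model`.
#' @param mode Entry-matching mode, see [match_entries()].
#' @return Object of class `compatibility_result`: list with `entity`
#'   (label), `category`, `token`, `score_percent`, `per_anchor` (named
#'   single-anchor scores) and `n_matched_entries` (the N per anchor).
#' @export
compatibility <- function(query, entity, model, mode = c("word", "substring")) {
  mode <- match.arg(mode)
  if (is.character(entity)) {
    entity <- list(label = entity, category = NA_character_,
                   token = entity_token(entity))
  }
  if (!(entity$token %in% rownames(model$vectors))) {
    stop("entity token '", entity$token, "' is not in the model vocabulary")
  }
  entries <- match_entries(query, model, mode = mode)
  sc <- score_against_entries(entity$token, entries, model)
  structure(
    list(entity = entity$label, category = entity$category,
         token = entity$token, score_percent = sc,
         per_anchor = stats::setNames(sc, query),
         n_matched_entries = stats::setNames(length(entries), query)),
    class = "compatibility_result"
  )
}

#' @export
print.compatibility_result <- function(x, ...) {
  cat(sprintf("%s [%s]: %.2f%% (N = %s)\n", x$entity,
              ifelse(is.na(x$category), "-", x$category), x$score_percent,
              paste(x$n_matched_entries, collapse = ", ")))
  invisible(x)
}

#' Semantic expansion: rank entities by compatibility with anchors
#'
#' For every entity of the requested categories whose token is in the model
#' vocabulary, computes the single-anchor compatibility for each anchor and
#' combines them by taking the minimum over anchors — an entity is only as
#' compatible as its weakest link, matching the min-based single-anchor
#' definition. Returns the `top_k` entities by combined score, descending,
#' ties broken alphabetically by token.
#'
#' @param anchors Character vector of one or more anchor queries; each must
#'   match at least one vocabulary entry.
#' @param category One or more of [entity_categories()] (`"measure"`
#'   accepted); default all four.
#' @param vocab An `entity_vocabulary`.
#' @param model An `embedding_model`.
#' @param top_k Maximum number of results (default 20).
#' @param mode Entry-matching mode, see [match_entries()].
#' @return Data frame with columns `label`, `category`, `token`,
#'   `score_percent`, plus one `anchor.<q>` column of single-anchor scores
#'   per anchor; attribute `n_matched_entries` gives N per anchor.
#' @export
expand_entities <- function(anchors, category = entity_categories(), vocab,
                            model, top_k = 20L,
                            mode = c("word", "substring")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vocab, "entity_vocabulary"),
            inherits(model, "embedding_model"))
  if (length(anchors) < 1) stop("at least one anchor query is required")
  if (!is.numeric(top_k) || top_k < 1) stop("top_k must be a positive integer")
  category <- normalise_category(category)
  ents <- vocab[vocab$category %in% category, , drop = FALSE]
  ents <- ents[ents$token %in% rownames(model$vectors), , drop = FALSE]
  if (nrow(ents) == 0) {
    stop("no in-vocabulary entities in category ",
         paste(category, collapse = "/"))
  }
  entries <- lapply(anchors, match_entries, model = model, mode = mode)
  en <- cosine_rows(model$vectors)
  per_anchor <- vapply(seq_along(anchors), function(a) {
    es <- entries[[a]]
    cs <- en[ents$token, , drop = FALSE] %*% t(en[es, , drop = FALSE])
    vapply(seq_len(nrow(ents)), function(i) {
      self <- ents$token[i] == es
      if (all(self)) 100 else 100 * min(cs[i, !self])
    }, numeric(1))
  }, numeric(nrow(ents)))
  per_anchor <- matrix(per_anchor, nrow = nrow(ents),
                       dimnames = list(ents$token, anchors))
  combined <- apply(per_anchor, 1, min)
  ord <- order(-combined, ents$token)
  keep <- ord[seq_len(min(as.integer(top_k), length(ord)))]
  out <- data.frame(label = ents$label[keep], category = ents$category[keep],
                    token = ents$token[keep],
                    score_percent = unname(combined[keep]),
                    stringsAsFactors = FALSE)
  for (a in anchors) out[[paste0("anchor.", a)]] <- unname(per_anchor[keep, a])
  rownames(out) <- NULL
  attr(out, "n_matched_entries") <- stats::setNames(lengths(entries), anchors)
  out
}
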