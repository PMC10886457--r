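#' Entity categories
#'
#' The four entity categories linked by semantic expansion: taxa, biological
#' processes, habitats and physical measurements.
#'
#' @return Character vector of the four category names.
#' @export
entity_categories <- function() {
  c("TAXON", "PROCESS", "HABITAT", "MEASUREMENT")
}

#' Canonical token of an entity label
#'
#' Lowercases the label and replaces internal whitespace runs with a single
#' underscore, so multi-word entities ("Vespa soror") become single embedding
#' tokens ("vespa_soror").
#'
#' @param label Character vector of display labels.
#' @return Character vector of tokens.
#' @export
entity_token <- function(label) {
  tok <- gsub("\\s+", "_", trimws(tolower(label)))
  if (any(!nzchar(tok))) stop("entity label reduces to an empty token")
  tok
}

#' Load entity vocabularies
#'
#' Reads one plain UTF-8 label list per category (one label per line) and
#' builds the categorised entity vocabulary used for phrasing and expansion.
#' Duplicate labels within a category are dropped with a warning; the same
#' token appearing in two categories is an error, as is an empty category
#' file.
#'
#' @param paths Named character vector or list mapping category (any case;
#'   `measure` is accepted for MEASUREMENT) to file path.
#' @return Object of class `entity_vocabulary`: data frame with columns
#'   `label`, `category`, `token`.
#' @export
load_entities <- function(paths) {
  cats <- normalise_category(names(paths))
  if (anyDuplicated(cats)) stop("duplicate category in entity paths")
  rows <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (!file.exists(p)) stop("entity file not found: ", p)
    labels <- trimws(readLines(p, encoding = "UTF-8", warn = FALSE))
    labels <- labels[nzchar(labels)]
    if (length(labels) == 0) {
      stop("entity file for category ", cats[i], " is empty: ", p)
    }
    dup <- duplicated(tolower(labels))
    if (any(dup)) {
      warning(sprintf("dropped %d duplicate label(s) in category %s",
                      sum(dup), cats[i]))
      labels <- labels[!dup]
    }
    rows[[i]] <- data.frame(label = labels, category = cats[i],
                            token = entity_token(labels),
                            stringsAsFactors = FALSE)
  }
  vocab <- do.call(rbind, rows)
  dup_tok <- vocab$token[duplicated(vocab$token)]
  if (length(dup_tok) > 0) {
    stop("token(s) present in more than one category: ",
         paste(unique(dup_tok), collapse = ", "))
  }
  vocab <- vocab[order(vocab$token), , drop = FALSE]
  rownames(vocab) <- NULL
  class(vocab) <- c("entity_vocabulary", class(vocab))
  vocab
}

normalise_category <- function(x) {
  if (is.null(x)) stop("entity paths must be named by category")
  up <- toupper(x)
  up[up %in% c("MEASURE", "MEASUREMENTS")] <- "MEASUREMENT"
  bad <- setdiff(up, entity_categories())
  if (length(bad) > 0) stop("unknown entity category: ",
                            paste(bad, collapse = ", "))
  up
}

#' Tokenize and phrase sentences
#'
#' Lowercases each sentence, strips punctuation, splits on whitespace, then
#' replaces entity word sequences by their underscore tokens using greedy
#' longest-leftmost matching (so of two overlapping entities the one starting
#' earlier wins, and at a given start the longest wins). Non-entity words are
#' kept as-is.
#'
#' @param sentences Character vector, one sentence per element.
#' @param vocab An `entity_vocabulary`, or NULL for plain tokenization.
#' @return List of character vectors of tokens (empty corpus gives an empty
#'   list).
#' @export
phrase_sentences <- function(sentences, vocab = NULL) {
  if (length(sentences) == 0) return(list())
  words <- strsplit(gsub("[^a-z0-9_ ]+", " ", tolower(sentences)), "\\s+")
  words <- lapply(words, function(w) w[nzchar(w)])
  if (is.null(vocab) || nrow(vocab) == 0) return(words)

  # index entity word-sequences by first word, longest first
  seqs <- strsplit(vocab$token, "_", fixed = TRUE)
  first <- vapply(seqs, `[[`, "", 1L)
  by_first <- split(seq_along(seqs), first)
  by_first <- lapply(by_first, function(ix) {
    ix[order(-lengths(seqs[ix]))]
  })
  toks <- vocab$token

  lapply(words, function(w) {
    n <- length(w)
    if (n == 0) return(character())
    out <- character(0)
    i <- 1
    while (i <= n) {
      cand <- by_first[[w[i]]]
      matched <- FALSE
      if (!is.null(cand)) {
        for (ci in cand) {
          sq <- seqs[[ci]]
          L <- length(sq)
          if (i + L - 1 <= n && all(w[i:(i + L - 1)] == sq)) {
            out <- c(out, toks[ci])
            i <- i + L
            matched <- TRUE
            break
          }
        }
      }
      if (!matched) {
        out <- c(out, w[i])
        i <- i + 1
      }
    }
    out
  })
}
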