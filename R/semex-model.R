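#' Train skip-gram word embeddings
#'
#' Trains a skip-gram model with negative sampling on a phrased corpus (see
#' [phrase_sentences()]). Training is single-threaded and fully seeded, so
#' repeated runs on identical input produce bitwise-identical vectors — a
#' requirement for reproducible compatibility scores. Tokens occurring fewer
#' than `min_count` times are dropped before training, as is conventional.
#'
#' @param tokenized List of character vectors of tokens.
#' @param dim Embedding dimension (>= 2). Default 32.
#' @param window Maximum context window; the effective window per position is
#'   drawn uniformly from 1..window. Default 5.
#' @param epochs Passes over the corpus. Default 5.
#' @param min_count Minimum corpus frequency for a token to be embedded.
#'   Default 1 (desk-scale corpora are small).
#' @param negative Negative samples per positive pair. Default 5.
#' @param alpha,min_alpha Initial and floor learning rate (linear decay).
#' @param seed Integer seed controlling initialisation, window draws and
#'   negative sampling.
#' @return Object of class `embedding_model`: list with `vectors` (matrix,
#'   one row per token), `dim` and `training_params`.
#' @export
train_embeddings <- function(tokenized, dim = 32L, window = 5L, epochs = 5L,
                             min_count = 1L, negative = 5L, alpha = 0.025,
                             min_alpha = 1e-4, seed = 1L) {
  if (length(tokenized) == 0) stop("empty corpus")
  if (dim < 2) stop("embedding dimension must be >= 2")
  all_tok <- unlist(tokenized, use.names = FALSE)
  if (length(all_tok) == 0) stop("empty corpus")
  counts <- table(all_tok)
  keep <- counts[counts >= min_count]
  if (length(keep) == 0) stop("all tokens fall below min_count")
  # deterministic vocabulary order: frequency-descending, then alphabetical
  vocab <- names(keep)[order(-as.integer(keep), names(keep))]
  counts <- as.numeric(keep[vocab])
  ids <- lapply(tokenized, function(s) {
    i <- match(s, vocab)
    as.integer(i[!is.na(i)])
  })
  ids <- ids[lengths(ids) > 0]
  if (length(ids) == 0) stop("no sentence survives min_count filtering")
  vec <- .sgns_train(ids, length(vocab), counts, as.integer(dim),
                     as.integer(window), as.integer(epochs),
                     as.integer(negative), alpha, min_alpha,
                     as.integer(seed))
  rownames(vec) <- vocab
  new_embedding_model(vec, list(window = as.integer(window),
                                epochs = as.integer(epochs),
                                min_count = as.integer(min_count),
                                negative = as.integer(negative),
                                alpha = alpha, seed = as.integer(seed)))
}

new_embedding_model <- function(vectors, training_params = list()) {
  stopifnot(is.matrix(vectors), nrow(vectors) > 0,
            !is.null(rownames(vectors)))
  structure(
    list(vectors = vectors, dim = ncol(vectors),
         training_params = training_params),
    class = "embedding_model"
  )
}

#' Build an embedding model from explicit vectors
#'
#' For hand-set vectors in tests, worked examples and score verification.
#'
#' @param vectors Numeric matrix with one row per token; rownames are tokens.
#' @return An `embedding_model`.
#' @export
embedding_model <- function(vectors) {
  new_embedding_model(vectors)
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding model: %d tokens x %d dims>\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Write an embedding model in word2vec text format
#'
#' Header line `vocab_size dimension`, then one `token v1 ... vd` line per
#' token.
#'
#' @param model An `embedding_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  v <- model$vectors
  lines <- c(sprintf("%d %d", nrow(v), ncol(v)),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i],
                       formatC(v[i, ], format = "g", digits = 17)),
                     collapse = " ")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read an embedding model in word2vec text format
#'
#' @param path File written by [write_embeddings()] (or any text-format
#'   word2vec export).
#' @return An `embedding_model`.
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr)) stop("malformed word2vec header")
  n <- hdr[1]; d <- hdr[2]
  if (length(lines) < n + 1) stop("model file truncated")
  parts <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  toks <- vapply(parts, `[[`, "", 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(vec) <- toks
  new_embedding_model(vec)
}
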