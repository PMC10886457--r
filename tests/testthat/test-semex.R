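hand_model <- function() {
  v <- rbind(
    vespa_mandarina = c(1, 0, 0),
    vespa_ducalis   = c(0, 1, 0),
    swarm           = c(1, 1, 0) / sqrt(2),
    wasp            = c(0, 0, 1),
    forest          = c(-1, 0, 0)
  )
  embedding_model(v)
}

test_that("entity vocabularies load, tokenize and collide as specified", {
  d <- tempfile(); dir.create(d)
  paths <- list(
    TAXON = file.path(d, "t.txt"), PROCESS = file.path(d, "p.txt"),
    HABITAT = file.path(d, "h.txt"), MEASUREMENT = file.path(d, "m.txt"))
  writeLines(c("Vespa soror", "Pica pica", "Corvus corone"), paths$TAXON)
  writeLines(c("swarming", "diving"), paths$PROCESS)
  writeLines(c("forest", "tropical"), paths$HABITAT)
  writeLines(c("heat", "frequency"), paths$MEASUREMENT)
  vocab <- load_entities(paths)
  expect_equal(nrow(vocab), 9L)
  expect_equal(vocab$token[vocab$label == "Vespa soror"], "vespa_soror")
  expect_setequal(unique(vocab$category), entity_categories())
  # duplicate within a category: dropped with warning
  writeLines(c("forest", "Forest", "tropical"), paths$HABITAT)
  expect_warning(load_entities(paths), "duplicate")
  # same token in two categories: error
  writeLines(c("swarming", "forest"), paths$PROCESS)
  writeLines(c("forest", "tropical"), paths$HABITAT)
  expect_error(load_entities(paths), "more than one category")
  # empty file: error
  writeLines(character(), paths$PROCESS)
  expect_error(load_entities(paths), "empty")
})

test_that("phrasing replaces entity mentions greedily, longest-leftmost", {
  d <- tempfile(); dir.create(d)
  tf <- file.path(d, "t.txt")
  writeLines(c("vespa soror", "soror hunts", "giant asian hornet"), tf)
  vocab <- load_entities(list(TAXON = tf))
  expect_equal(phrase_sentences("Vespa soror hunts in swarms.", vocab)[[1]],
               c("vespa_soror", "hunts", "in", "swarms"))
  # overlap: leftmost entity wins, the trailing overlap is left as words
  expect_equal(phrase_sentences("the vespa soror hunts", vocab)[[1]],
               c("the", "vespa_soror", "hunts"))
  # longest-at-position wins over shorter prefixes
  writeLines(c("giant asian", "giant asian hornet"), tf)
  vocab2 <- load_entities(list(TAXON = tf))
  expect_equal(phrase_sentences("a giant asian hornet flew", vocab2)[[1]],
               c("a", "giant_asian_hornet", "flew"))
  # no entities: plain lowercase tokens; empty corpus: empty list
  expect_equal(phrase_sentences("Only Plain words!", vocab)[[1]],
               c("only", "plain", "words"))
  expect_equal(phrase_sentences(character(), vocab), list())
})

test_that("training is deterministic and covers the vocabulary", {
  g <- generate_corpus(corpus_spec(n_sentences = 400, seed = 5))
  vocab <- vocab_from_tokens(g$entities$token)
  toks <- phrase_sentences(g$sentences, vocab)
  m1 <- train_embeddings(toks, dim = 16, epochs = 3, seed = 9)
  m2 <- train_embeddings(toks, dim = 16, epochs = 3, seed = 9)
  expect_identical(m1$vectors, m2$vectors)
  expect_true(all(g$entities$token %in% rownames(m1$vectors)))
  expect_equal(ncol(m1$vectors), 16L)
  m3 <- train_embeddings(toks, dim = 16, epochs = 3, seed = 10)
  expect_false(identical(m1$vectors, m3$vectors))
  # degenerate corpora
  expect_error(train_embeddings(list()), "empty corpus")
  expect_error(train_embeddings(list(c("a", "b")), min_count = 5),
               "min_count")
  one <- train_embeddings(rep(list(c("only", "one", "sentence")), 3),
                          dim = 4, seed = 1)
  expect_setequal(rownames(one$vectors), c("only", "one", "sentence"))
})

test_that("within-group similarity exceeds cross-group after training", {
  g <- generate_corpus(corpus_spec(seed = 3))
  vocab <- vocab_from_tokens(g$entities$token)
  m <- train_embeddings(phrase_sentences(g$sentences, vocab), seed = 1)
  en <- m$vectors / sqrt(rowSums(m$vectors^2))
  cs <- en[g$entities$token, ] %*% t(en[g$entities$token, ])
  same <- outer(g$entities$group, g$entities$group, "==") &
    !diag(nrow(cs))
  diff_g <- !outer(g$entities$group, g$entities$group, "==")
  expect_gt(mean(cs[same]), mean(cs[diff_g]))
})

test_that("entry matching is whole-word over underscore segments", {
  m <- hand_model()
  expect_equal(match_entries("vespa", m),
               c("vespa_ducalis", "vespa_mandarina"))
  expect_equal(match_entries("swarm", m), "swarm")
  expect_equal(match_entries("Vespa mandarina", m), "vespa_mandarina")
  expect_error(match_entries("zzz", m), "no entry")
  # substring mode relaxes containment
  v <- rbind(vespavirus = c(1, 0), vespa = c(0, 1))
  m2 <- embedding_model(v)
  expect_equal(match_entries("vespa", m2), "vespa")
  expect_setequal(match_entries("vespa", m2, mode = "substring"),
                  c("vespa", "vespavirus"))
})

test_that("compatibility is the minimum cosine over matched entries", {
  m <- hand_model()
  # min over (1,0,0) and (0,1,0) against (1,1,0)/sqrt(2)
  r <- compatibility("vespa", "swarm", m)
  expect_equal(r$score_percent, 100 / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(r$n_matched_entries), 2L)
  # orthogonal entity scores 0; opposite scores -100
  expect_equal(compatibility("vespa", "wasp", m)$score_percent, 0)
  expect_equal(compatibility("vespa mandarina", "forest", m)$score_percent,
               -100)
  # single matching entry identical to the entity: perfect compatibility
  v <- rbind(anchor_entry = c(2, 1), target = c(2, 1), other = c(0, 1))
  expect_equal(compatibility("anchor", "target",
                             embedding_model(v))$score_percent, 100)
  # self-token query: the entity itself is the only entry, score 100
  expect_equal(compatibility("swarm", "swarm", m)$score_percent, 100)
  expect_error(compatibility("vespa", "zzz", m), "not in the model")
})

test_that("compatibility matches the longhand oracle on random models", {
  for (seed in 1:10) {
    m <- random_model(seed)
    toks <- rownames(m$vectors)
    set.seed(seed)
    entities <- sample(toks, 8)
    for (q in c("vespa", "apis", "formica")) {
      entries <- match_entries(q, m)
      for (e in entities) {
        got <- compatibility(q, e, m)$score_percent
        want <- oracle_min_cosine_pct(e, entries, m$vectors)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("cosine symmetry holds for exact-token anchors", {
  m <- random_model(4)
  singles <- grep("_", rownames(m$vectors), invert = TRUE, value = TRUE)
  for (a in singles) for (b in setdiff(singles, a)) {
    # restrict the model so each query matches only its own token
    mm <- embedding_model(m$vectors[c(a, b), , drop = FALSE])
    expect_equal(compatibility(a, b, mm)$score_percent,
                 compatibility(b, a, mm)$score_percent, tolerance = 1e-12)
  }
})

test_that("expansion ranks, filters by category, and caps at top_k", {
  m <- random_model(7, n_tokens = 120)
  toks <- rownames(m$vectors)
  hab <- toks[seq(1, length(toks), by = 2)]
  tax <- setdiff(toks, hab)
  d <- tempfile(); dir.create(d)
  writeLines(gsub("_", " ", hab), file.path(d, "h.txt"))
  writeLines(gsub("_", " ", tax), file.path(d, "t.txt"))
  vocab <- load_entities(list(HABITAT = file.path(d, "h.txt"),
                              TAXON = file.path(d, "t.txt")))
  res <- expand_entities("vespa", category = "HABITAT", vocab = vocab,
                         model = m)
  expect_equal(nrow(res), 20L)
  expect_true(all(res$category == "HABITAT"))
  expect_true(all(diff(res$score_percent) <= 0))
  res5 <- expand_entities("vespa", category = "HABITAT", vocab = vocab,
                          model = m, top_k = 5)
  expect_equal(res5$token, res$token[1:5])
  # single anchor: combined equals the single-anchor score
  expect_equal(res$score_percent, res$`anchor.vespa`)
  expect_error(expand_entities("zzz", category = "HABITAT", vocab = vocab,
                               model = m), "no entry")
})

test_that("multi-anchor scores are the elementwise min of single-anchor runs", {
  m <- random_model(12)
  vocab <- vocab_from_tokens(rownames(m$vectors))
  k <- nrow(m$vectors)
  r_a <- expand_entities("vespa", vocab = vocab, model = m, top_k = k)
  r_b <- expand_entities("apis", vocab = vocab, model = m, top_k = k)
  r_ab <- expand_entities(c("vespa", "apis"), vocab = vocab, model = m,
                          top_k = k)
  a <- r_a$score_percent[match(r_ab$token, r_a$token)]
  b <- r_b$score_percent[match(r_ab$token, r_b$token)]
  expect_equal(r_ab$score_percent, pmin(a, b), tolerance = 1e-12)
  # adding an anchor never raises any combined score
  r_abc <- expand_entities(c("vespa", "apis", "formica"), vocab = vocab,
                           model = m, top_k = k)
  expect_true(all(r_abc$score_percent[match(r_ab$token, r_abc$token)] <=
                    r_ab$score_percent + 1e-12))
})

test_that("models round-trip through the word2vec text format", {
  g <- generate_corpus(corpus_spec(n_sentences = 200, seed = 6))
  vocab <- vocab_from_tokens(g$entities$token)
  m <- train_embeddings(phrase_sentences(g$sentences, vocab), dim = 8,
                        epochs = 2, seed = 2)
  p <- tempfile(fileext = ".vec")
  write_embeddings(m, p)
  hdr <- strsplit(readLines(p, n = 1), " ")[[1]]
  expect_equal(as.integer(hdr), c(nrow(m$vectors), 8L))
  back <- read_embeddings(p)
  expect_equal(back$vectors[rownames(m$vectors), ], m$vectors,
               tolerance = 1e-15)
})
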