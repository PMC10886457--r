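# bioexplore

Offline toolkit for taxonomy-driven exploration of biodiversity data, aimed
at bioinspired-design practitioners and the biologists who advise them. It
reproduces, as a testable R library plus command line, the three
computational services such exploration needs:

1. **Taxon search and tree building** — load a GBIF-style taxonomic backbone,
   get up to 20 ranked name suggestions for a scientific or vernacular query
   (each suggestion colour-coded by rank, red for species through blue for
   kingdom), extract seven-rank lineages, and accumulate successive queries
   into a merged taxonomy tree that bifurcates where lineages diverge,
   exportable as DOT, JSON or Newick.
2. **Climatic-niche summary** — overlay a taxon's occurrence records, binned
   into hexagonal zones, on a stack of 9 monthly climate variables × 12
   months (elevation, precipitation avg/max/min, solar irradiance,
   temperature avg/min/max, wind speed) and report for each variable the
   monthly spatial means, their annual mean, and the min–max range of the
   monthly means.
3. **Semantic expansion** — phrase a sentence corpus so multi-word entities
   ("Vespa soror" → `vespa_soror`) become single tokens, train seeded
   skip-gram word embeddings, and rank taxa, biological processes, habitats
   and measurements by a *compatibility score*: for a query word *w*, find
   the N vocabulary entries containing *w* and score each entity *e* as

   score(e) = 100 × minᵢ cos(v(entryᵢ), v(e)),

   so 100 % means perfect compatibility with *every* entry containing the
   query. Multi-anchor queries combine by taking the minimum over anchors —
   an entity is only as compatible as its weakest link.

A seeded synthetic-data module generates backbones, clustered occurrence
points, monthly rasters with analytically known means, and corpora with
planted entity co-occurrence, so the whole pipeline runs and is tested
without any network access.

## Worked example

```r
library(bioexplore)

fx <- table2_fixture_paths()           # packaged worked-example backbone
bb <- load_backbone(fx$backbone, fx$vernaculars)
suggest("mockingbird", bb)[, c("scientific_name", "rank", "match_kind")]
#>          scientific_name    rank match_kind
#> 1 Melanotis caerulescens species vernacular
#> 2       Mimus macdonaldi species vernacular
#> 3       Mimus gundlachii species vernacular
#> ...                                          (8 species in total)
```

Eight species match the vernacular "mockingbird"; a "blue whale" query
returns two taxa (the whale and the blue shark, whose common name "blue
whaler" contains the query), and "nikolay" returns seven taxa by substring
match on the specific epithet. Merging two lineages shows the bifurcation at
their deepest shared ancestor:

```r
tr <- taxonomy_tree()
for (id in c("s-mgun", "s-mcae")) tr <- merge_lineage(tr, lineage(id, bb))
export_tree(tr, "newick")
#> ((((((Melanotis_caerulescens)Melanotis,(Mimus_gundlachii)Mimus)Mimidae)Passeriformes)Aves)Chordata)Animalia;
```

Climate summary on synthetic rasters (spatial means over 21 occupied
hexagons, 411 cells; the range is over the 12 monthly means):

```r
r <- generate_rasters(raster_spec(gradient_amplitude = 10, seed = 1), dir = tempfile())
zones <- hexbin_occurrences(generate_occurrences(250, seed = 11), 0.7)
climate_summary(zones, load_layers(r$dir))
#>           variable annual_mean range_min range_max n_cells missing
#> 6         temp_avg      11.472     3.472    19.472     411   FALSE
#> ...
```

Semantic expansion on a corpus with three planted co-occurrence groups: the
top-ranked partners of the anchor entity come from its own group (the anchor
itself scores 100 by definition):

```r
g <- generate_corpus(corpus_spec(seed = 42), dir = tempfile())
vocab <- load_entities(g$entity_paths)
model <- train_embeddings(phrase_sentences(readLines(g$corpus_path), vocab),
                          dim = 32, seed = 1)
expand_entities(g$entities$label[1], vocab = vocab, model = model, top_k = 5)
#>         label    category score_percent      (planted group)
#> 1      liguba       TAXON     100.00000      1  <- the anchor
#> 2 lizume figu     HABITAT      65.22040      1
#> 3      zudopo       TAXON      65.11647      1
#> 4      rafimo     PROCESS      60.09515      1
#> 5      xorumo MEASUREMENT      60.04166      1
```

## Command line

A thin wrapper over the same functions ships at
`system.file("scripts", "bioexplore", package = "bioexplore")`, with
subcommands `suggest`, `tree`, `climate`, `train`, `expand` and `simulate`
(exit 0 success, 2 usage error, 1 data error). Example:

```sh
bioexplore suggest --backbone backbone.tsv --vernaculars vern.tsv \
    --query mockingbird --limit 20
```

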