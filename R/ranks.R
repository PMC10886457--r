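#' Canonical taxonomic ranks
#'
#' The seven major GBIF ranks, ordered from kingdom (highest) to species
#' (lowest). All backbone records must carry one of these ranks; intermediate
#' ranks (subfamily, tribe, ...) are rejected at load time.
#'
#' @return Character vector of the seven ranks, kingdom first.
#' @export
canonical_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

# numeric level: kingdom = 1 ... species = 7; NA for unknown ranks
rank_level <- function(rank) {
  match(rank, canonical_ranks())
}

#' Rank colour code
#'
#' Maps each of the seven canonical ranks to a fixed seven-step palette running
#' from red (species) to blue (kingdom), mirroring the rank colour-coding used
#' in interactive taxon search interfaces.
#'
#' @param rank Character vector of canonical ranks.
#' @return Character vector of hex colours, one per input rank.
#' @export
rank_colour <- function(rank) {
  pal <- c(
    species = "#d73027",
    genus   = "#fc8d59",
    family  = "#fee090",
    order   = "#ffffbf",
    class   = "#e0f3f8",
    phylum  = "#91bfdb",
    kingdom = "#4575b4"
  )
  lev <- rank_level(rank)
  if (anyNA(lev)) {
    stop("unknown rank(s): ", paste(unique(rank[is.na(lev)]), collapse = ", "))
  }
  unname(pal[rank])
}
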