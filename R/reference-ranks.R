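#' Published top-20 priority rankings for the Chilean endemic flora
#'
#' Transcription of the published top-20 priority lists for species of the
#' endemic vascular plant genera of Chile: the RED ranking and the four EDGE
#' rankings (`iucn50`, `iucn100`, `iucn500`, `isaac`), with their dense ranks
#' as printed (tied species share a rank, so a list can carry 21 species over
#' ranks 1 to 20). Used to validate list-comparison behaviour: RED shares 13
#' of 20 species (65%) with each EDGE list and with their four-way
#' intersection.
#'
#' @return A named list of [rank_table()]s, one per metric
#'   (`RED`, `iucn50`, `iucn100`, `iucn500`, `isaac`).
#' @export
chile_top20_ranks <- function() {
  path <- system.file("extdata", "chile_top20_ranks.csv",
                      package = "redmetrics")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, factor(df$metric, unique(df$metric))),
         function(d) rank_table(d$species, d$rank))
}
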