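# Phylostratigraphy: relative gene ages from a homology hit table over an
# ordered taxonomy ladder, and taxonomically-restricted-gene (TRG) flags.

#' Assign phylostratum ages from a homology hit table
#'
#' A gene's age is the oldest stratum (rank 1 = most inclusive clade)
#' holding a hit at or below the e-value threshold. Hits to the focal
#' species itself are ignored (every gene trivially self-matches); genes
#' with no other qualifying hit get the youngest rank, the focal-species
#' stratum.
#'
#' @param hits Tibble with `gene`, `taxon`, `evalue`.
#' @param ladder Tibble with `rank` (1 = oldest), `taxon`; every hit taxon
#'   must appear.
#' @param evalue_threshold Qualifying-hit threshold.
#' @param focal_taxon Taxon name(s) treated as self-hits.
#' @return Tibble with `gene`, `rank`.
#' @export
assign_gene_ages <- function(hits, ladder, evalue_threshold = 1e-5,
                             focal_taxon = NULL) {
  unknown <- setdiff(unique(hits$taxon), ladder$taxon)
  if (length(unknown)) {
    abort(paste0("hit taxon(a) missing from the ladder: ",
                 paste(unknown, collapse = ", ")))
  }
  max_rank <- max(ladder$rank)
  if (is.null(focal_taxon)) {
    focal_taxon <- ladder$taxon[ladder$rank == max_rank]
  }
  qual <- hits |>
    filter(.data$evalue <= evalue_threshold,
           !(.data$taxon %in% focal_taxon)) |>
    left_join(ladder, by = "taxon")
  ages <- if (nrow(qual) == 0L) {
    tibble(gene = character(), rank = integer())
  } else {
    qual |>
      group_by(.data$gene) |>
      summarise(rank = min(.data$rank), .groups = "drop")
  }
  all_genes <- unique(hits$gene)
  tibble(gene = all_genes) |>
    left_join(ages, by = "gene") |>
    mutate(rank = dplyr::coalesce(.data$rank, max_rank))
}

#' Flag taxonomically restricted genes
#'
#' A gene is a TRG when its age rank is at least `cutoff_rank`, i.e. its
#' homologues are confined to the clade that stratum defines (or younger).
#'
#' @param ages Tibble from [assign_gene_ages()].
#' @param cutoff_rank Rank at or above which a gene is restricted.
#' @return `ages` with a logical `trg` column.
#' @export
flag_trg <- function(ages, cutoff_rank) {
  if (cutoff_rank < 1 || cutoff_rank > max(ages$rank)) {
    abort("cutoff_rank outside the ladder's rank range")
  }
  ages |> mutate(trg = .data$rank >= cutoff_rank)
}
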