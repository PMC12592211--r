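# YGS-style k-mer subtraction: score reference windows by the proportion of
# their genome-wide single-copy k-mers that are absent from the opposite-sex
# read k-mer database, then retain windows above a percentage threshold as
# candidate SDR sequence.

#' k-mer counting configuration
#'
#' Defaults mirror standard sexed-read k-mer databases: canonical 15-mers,
#' counts below 5 dropped, bases under Phred 20 excluded.
#'
#' @param k k-mer size (1--26; codes are 2-bit packed into doubles).
#' @param canonical Collapse each k-mer with its reverse complement onto the
#'   lexicographic minimum.
#' @param min_count Minimum count for a read k-mer to be kept.
#' @param min_base_quality Phred cutoff; `NULL` disables quality filtering.
#' @param qual_offset ASCII offset of the quality encoding.
#' @return A `uv_kmer_config` list.
#' @export
kmer_config <- function(k = 15L, canonical = TRUE, min_count = 5L,
                        min_base_quality = 20L, qual_offset = 33L) {
  if (k < 1 || k > 26) abort("k must be in [1, 26]")
  if (min_count < 1) abort("min_count must be >= 1")
  structure(list(k = as.integer(k), canonical = canonical,
                 min_count = as.integer(min_count),
                 min_base_quality = min_base_quality,
                 qual_offset = as.integer(qual_offset)),
            class = "uv_kmer_config")
}

#' Read a FASTQ file into a read tibble
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return Tibble with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(id = names(x),
         seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a read tibble to FASTQ
#'
#' @param reads Tibble with `id`, `seq` and optionally `qual` (defaults to
#'   maximum quality).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual %||% vapply(nchar(reads$seq), function(n)
    strrep("I", n), character(1))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), path)
  invisible(path)
}

#' Count k-mers in a read set
#'
#' k-mers containing an N or a base below `min_base_quality` are skipped;
#' counts below `min_count` are dropped after counting, emulating a
#' lower-count filter on the k-mer database.
#'
#' @param reads Read tibble (`seq`, optional `qual`), character vector of
#'   read sequences, or path to a FASTQ file.
#' @param cfg A [kmer_config()].
#' @return A `uv_kmerset`: list with `k`, `canonical` and a tibble `kmers`
#'   (`code`, `count`) sorted by packed code.
#' @export
count_read_kmers <- function(reads, cfg = kmer_config()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.character(reads)) reads <- tibble(seq = reads)
  seqs <- reads$seq
  quals <- reads[["qual"]]
  if (length(seqs) > 0 && max(nchar(seqs)) < cfg$k) {
    warn("k exceeds every read length; returning an empty k-mer set")
  }
  min_q <- if (is.null(cfg$min_base_quality) || is.null(quals)) -1L
           else as.integer(cfg$min_base_quality)
  res <- cpp_count_kmers(seqs, quals, cfg$k, cfg$canonical, min_q,
                         cfg$qual_offset, cfg$min_count)
  structure(list(k = cfg$k, canonical = cfg$canonical,
                 kmers = tibble(code = res$code, count = res$count)),
            class = "uv_kmerset")
}

#' @export
print.uv_kmerset <- function(x, ...) {
  cat("<uv_kmerset> ", nrow(x$kmers), " distinct ",
      if (x$canonical) "canonical " else "", x$k, "-mers\n", sep = "")
  invisible(x)
}

#' Decode packed k-mer codes to sequence strings
#' @param kset A `uv_kmerset`, or numeric codes (then `k` is required).
#' @param k k-mer size when `kset` is a plain numeric vector.
#' @return Character vector of k-mer strings.
#' @export
decode_kmers <- function(kset, k = NULL) {
  if (inherits(kset, "uv_kmerset")) {
    cpp_decode_kmers(kset$kmers$code, kset$k)
  } else {
    cpp_decode_kmers(kset, k)
  }
}

#' Genome-wide single-copy k-mers of an assembly
#'
#' A k-mer is single-copy when its canonical form occurs exactly once in the
#' whole assembly (an occurrence on the reverse strand counts). Each k-mer
#' is reported with its chromosome and 0-based start position so windows can
#' claim the k-mers starting inside them.
#'
#' @param assembly A [sequence_set()].
#' @param cfg A [kmer_config()] (only `k` and `canonical` are used).
#' @return Tibble with `chrom`, `pos`, `code`.
#' @export
genome_single_copy_kmers <- function(assembly, cfg = kmer_config()) {
  if (length(assembly) == 0L) abort("assembly is empty")
  res <- cpp_single_copy_kmers(unclass(assembly), cfg$k, cfg$canonical)
  tibble(chrom = names(assembly)[res$chrom_idx],
         pos = res$pos, code = res$code)
}

#' Score windows by percent unmatched single-copy k-mers
#'
#' For each window, counts the assembly's genome-wide single-copy k-mers
#' starting inside it and the fraction of those absent from the
#' opposite-sex read k-mer database. Windows with no single-copy k-mers
#' score `NA`.
#'
#' @param assembly A [sequence_set()] (the reference being scored).
#' @param windows Window tibble from [make_windows()] over this assembly.
#' @param opp A `uv_kmerset` built from opposite-sex reads.
#' @param cfg A [kmer_config()]; `k` must match `opp`.
#' @return Tibble `uv_ygs_scores`: windows plus `n_single_copy`,
#'   `n_unmatched`, `pct_unmatched`.
#' @export
ygs_score_windows <- function(assembly, windows, opp,
                              cfg = kmer_config()) {
  if (inherits(opp, "uv_kmerset") && opp$k != cfg$k) {
    abort("k of the opposite-sex k-mer set does not match cfg$k")
  }
  bad <- setdiff(unique(windows$chrom), names(assembly))
  if (length(bad)) {
    abort(paste0("windows on chromosome(s) absent from the assembly: ",
                 paste(bad, collapse = ", ")))
  }
  sc <- genome_single_copy_kmers(assembly, cfg)
  opp_codes <- if (inherits(opp, "uv_kmerset")) opp$kmers$code else opp
  sc$matched <- cpp_codes_in_set(sc$code, opp_codes)

  win <- windows |> mutate(.win = row_number())
  # assign each k-mer to the window containing its start position
  assign_one <- function(sc_chr, win_chr) {
    idx <- findInterval(sc_chr$pos, win_chr$start)
    ok <- idx >= 1 & sc_chr$pos < win_chr$end[pmax(idx, 1L)]
    tibble(.win = win_chr$.win[idx[ok]], matched = sc_chr$matched[ok])
  }
  hits <- purrr::map_dfr(unique(win$chrom), function(ch) {
    s <- sc[sc$chrom == ch, ]
    w <- win[win$chrom == ch, ]
    if (nrow(s) == 0L || nrow(w) == 0L) return(NULL)
    assign_one(s, w)
  })
  if (nrow(hits) == 0L) {
    hits <- tibble(.win = integer(), matched = logical())
  }
  agg <- hits |>
    group_by(.data$.win) |>
    summarise(n_single_copy = n(),
              n_unmatched = sum(!.data$matched), .groups = "drop")
  out <- win |>
    left_join(agg, by = ".win") |>
    mutate(
      n_single_copy = dplyr::coalesce(.data$n_single_copy, 0L),
      n_unmatched = dplyr::coalesce(.data$n_unmatched, 0L),
      pct_unmatched = if_else(.data$n_single_copy > 0L,
                              100 * .data$n_unmatched / .data$n_single_copy,
                              NA_real_)
    ) |>
    select(-".win")
  class(out) <- c("uv_ygs_scores", class(out))
  out
}

#' Call candidate SDR windows from YGS scores
#'
#' Windows with at least `threshold_pct` percent unmatched single-copy
#' k-mers are retained (inclusive threshold) and adjacent retained windows
#' are merged into candidate intervals. `NA` windows are never retained.
#'
#' @param scores Output of [ygs_score_windows()].
#' @param threshold_pct Retention threshold in percent.
#' @return Tibble of merged candidate intervals (`chrom`, `start`, `end`).
#' @export
call_candidate_windows <- function(scores, threshold_pct = 50) {
  keep <- scores |>
    filter(!is.na(.data$pct_unmatched),
           .data$pct_unmatched >= threshold_pct)
  merge_intervals(keep[, c("chrom", "start", "end")])
}
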