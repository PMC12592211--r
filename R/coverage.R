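# Depth-based sex linkage: per-window depth from exactly-placed reads or
# from a precomputed BED, normalization by each sex's genome-wide mean, the
# 75-125% / <50% classification rule, and the log2 M:F fold-change.

#' Coverage classifier configuration
#'
#' A window is a V-SDR candidate when the male normalized coverage falls
#' within `[male_low, male_high]` of the genome average (bounds inclusive)
#' while the female normalized coverage stays strictly below `female_max`;
#' the sex-swapped rule yields U-SDR candidates.
#'
#' @param male_low,male_high Retained-sex band as fractions of the
#'   genome-wide mean.
#' @param female_max Depleted-sex ceiling (strict `<`).
#' @return A `uv_coverage_config` list.
#' @export
coverage_config <- function(male_low = 0.75, male_high = 1.25,
                            female_max = 0.50) {
  if (!(0 < male_low && male_low < male_high)) {
    abort("need 0 < male_low < male_high")
  }
  if (female_max <= 0) abort("female_max must be > 0")
  structure(list(male_low = male_low, male_high = male_high,
                 female_max = female_max),
            class = "uv_coverage_config")
}

#' Per-window depth from error-free reads by unique exact matching
#'
#' Each read is placed at its unique exact match (either strand) in the
#' assembly; reads matching several loci are discarded, emulating a mapping
#' quality filter, and reads with no exact match (for example reads from
#' the opposite sex's SDR) are dropped. Per-window mean depth is covered
#' bases divided by window length.
#'
#' @param assembly A [sequence_set()].
#' @param reads Read tibble (`seq`), character vector, or FASTQ path.
#' @param windows Window tibble from [make_windows()] over this assembly.
#' @param sample_id,sex Labels recorded on the output rows.
#' @return Tibble `uv_depth`: windows plus `sample_id`, `sex`, `depth`;
#'   attributes `n_multi` and `n_unplaced` carry the discard counts.
#' @export
window_depth_from_reads <- function(assembly, reads, windows,
                                    sample_id = "sample", sex = "none") {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  seqs <- if (is.character(reads)) reads else reads$seq
  placed <- cpp_place_reads(unclass(assembly), seqs)
  if (placed$n_multi > 0) {
    inform(paste0("discarded ", placed$n_multi, " multi-mapping read(s)"))
  }
  out <- depth_from_track(placed$coverage, windows)
  out <- out |> mutate(sample_id = sample_id, sex = sex,
                       .before = "chrom")
  attr(out, "n_multi") <- placed$n_multi
  attr(out, "n_unplaced") <- placed$n_unplaced
  class(out) <- c("uv_depth", class(out))
  out
}

# summarise a per-base coverage track into window means
depth_from_track <- function(track, windows) {
  parts <- split(windows, windows$chrom)
  out <- purrr::map_dfr(parts, function(w) {
    cov <- track[[w$chrom[1]]]
    if (is.null(cov)) abort(paste0("no coverage for ", w$chrom[1]))
    cs <- c(0, cumsum(as.numeric(cov)))
    w$depth <- (cs[w$end + 1L] - cs[w$start + 1L]) / (w$end - w$start)
    w
  })
  out[order(match(paste(out$chrom, out$start),
                  paste(windows$chrom, windows$start))), ]
}

#' Read a per-window depth BED into a depth table
#'
#' @param path BED file (`chrom  start  end  depth`), 0-based half-open.
#' @param windows Window tibble the BED must cover; missing windows raise
#'   an error listing them.
#' @param sample_id,sex Labels recorded on the output rows.
#' @return Tibble `uv_depth` (values passed through unchanged, sorted to
#'   window order).
#' @export
read_depth_bed <- function(path, windows, sample_id = "sample",
                           sex = "none") {
  bed <- read_bed(path, col_names = "depth")
  out <- windows |>
    left_join(bed, by = c("chrom", "start", "end"))
  if (anyNA(out$depth)) {
    miss <- out |> filter(is.na(.data$depth))
    abort(paste0("depth missing for window(s): ",
                 paste(utils::head(paste0(miss$chrom, ":", miss$start, "-",
                                          miss$end), 5), collapse = ", ")))
  }
  out <- out |> mutate(sample_id = sample_id, sex = sex, .before = "chrom")
  class(out) <- c("uv_depth", class(out))
  out
}

#' Normalize window depths by each sample's genome-wide mean
#'
#' The genome-wide mean is the length-weighted mean over all windows of the
#' sample, so the length-weighted mean of the normalized values is 1.
#'
#' @param depth_tbl A `uv_depth` tibble (may hold several samples).
#' @return The tibble with an added `norm_depth` column.
#' @export
normalize_by_genome_mean <- function(depth_tbl) {
  out <- depth_tbl |>
    group_by(.data$sample_id) |>
    mutate(.gmean = sum(.data$depth * (.data$end - .data$start)) /
             sum(.data$end - .data$start)) |>
    ungroup()
  if (any(out$.gmean == 0)) {
    abort("a sample has zero depth everywhere; cannot normalize")
  }
  out |>
    mutate(norm_depth = .data$depth / .data$.gmean) |>
    select(-".gmean")
}

#' Classify windows as U/V-SDR candidates from normalized coverage
#'
#' @param norm_male,norm_female Normalized depth tibbles (from
#'   [normalize_by_genome_mean()]) over the same windows.
#' @param cfg A [coverage_config()].
#' @return Tibble with the windows, `norm_male`, `norm_female` and `label`
#'   in `V_candidate` / `U_candidate` / `unclassified`.
#' @export
classify_windows <- function(norm_male, norm_female,
                             cfg = coverage_config()) {
  key <- c("chrom", "start", "end")
  m <- norm_male |> select(dplyr::all_of(key), norm_male = "norm_depth")
  f <- norm_female |> select(dplyr::all_of(key), norm_female = "norm_depth")
  if (nrow(m) != nrow(f)) abort("window sets differ between sexes")
  out <- dplyr::inner_join(m, f, by = key)
  if (nrow(out) != nrow(m)) abort("window sets differ between sexes")
  out |>
    mutate(label = dplyr::case_when(
      .data$norm_male >= cfg$male_low & .data$norm_male <= cfg$male_high &
        .data$norm_female < cfg$female_max ~ "V_candidate",
      .data$norm_female >= cfg$male_low &
        .data$norm_female <= cfg$male_high &
        .data$norm_male < cfg$female_max ~ "U_candidate",
      TRUE ~ "unclassified"
    ))
}

#' log2 male:female coverage fold change
#'
#' `log2((m + pseudocount) / (f + pseudocount))`. With a zero pseudocount a
#' zero female coverage yields `Inf` and a doubly-zero input yields `NA`.
#'
#' @param mean_male_cov,mean_female_cov Mean coverages (vectorized).
#' @param pseudocount Added to both coverages before the ratio.
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(mean_male_cov, mean_female_cov,
                             pseudocount = 0) {
  if (any(mean_male_cov < 0 | mean_female_cov < 0)) {
    abort("coverages must be >= 0")
  }
  m <- mean_male_cov + pseudocount
  f <- mean_female_cov + pseudocount
  out <- log2(m / f)
  out[m == 0 & f == 0] <- NA_real_
  out
}
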