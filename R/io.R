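# Readers/writers for the standard formats the pipeline touches, plus the
# window/interval arithmetic shared by every stage. Coordinates are 0-based
# half-open internally; GFF3/VCF are 1-based on disk, BED is 0-based half-open.

VALID_COMPARTMENTS <- c("autosome", "PAR", "SDR", "UV_homologue", "none")
GT_CODES <- c("hom_ref", "het", "hom_alt", "missing")

#' Construct a sequence set
#'
#' A sequence set is a named character vector of uppercase A/C/G/T/N residue
#' strings with an optional sex tag (`"male"`, `"female"` or `"none"`),
#' the in-memory form of a haploid reference assembly.
#'
#' @param records Named character vector of residue strings.
#' @param sex Optional sex tag for the assembly.
#' @return A `uv_sequences` object (named character vector).
#' @export
sequence_set <- function(records, sex = "none") {
  if (is.null(names(records)) || anyDuplicated(names(records)) ||
      any(!nzchar(names(records)))) {
    abort("sequence ids must be unique and non-empty")
  }
  sex <- match.arg(sex, c("none", "male", "female"))
  records <- toupper(records)
  bad <- grepl("[^ACGTN]", records)
  if (any(bad)) {
    abort(paste0("sequence '", names(records)[bad][1],
                 "' contains residues outside A/C/G/T/N"))
  }
  structure(records, sex = sex, class = "uv_sequences")
}

#' @export
print.uv_sequences <- function(x, ...) {
  cat("<uv_sequences> ", length(x), " sequence(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total, sex tag: ",
      attr(x, "sex") %||% "none", "\n", sep = "")
  invisible(x)
}

#' Sequence lengths of a sequence set
#' @param seqs A `uv_sequences` object or named character vector.
#' @return Named integer vector of lengths in bp.
#' @export
seq_lengths <- function(seqs) {
  setNames(nchar(unclass(seqs)), names(seqs))
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param sex Optional sex tag to attach (`"male"`, `"female"`, `"none"`).
#' @return A [sequence_set()].
#' @export
read_sequences <- function(path, sex = "none") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(paste0("empty FASTA file: ", path))
  if (!startsWith(first, ">")) {
    abort(paste0("malformed FASTA header at line 1 of ", path,
                 ": expected '>'"))
  }
  x <- Biostrings::readDNAStringSet(path)
  recs <- setNames(toupper(as.character(x)),
                   sub("\\s.*$", "", names(x)))
  sequence_set(recs, sex = sex)
}

#' Write sequences to a FASTA file
#'
#' @param seqs A [sequence_set()] or named character vector.
#' @param path Output path.
#' @param line_width Residues per line.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, line_width = 70L) {
  x <- Biostrings::DNAStringSet(unclass(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = line_width)
  invisible(path)
}

#' Read gene/repeat annotations from GFF3
#'
#' GFF3 is 1-based inclusive on disk; the returned tibble uses 0-based
#' half-open intervals. A `compartment` attribute
#' (autosome/PAR/SDR/UV_homologue), when present, is carried through;
#' features without one are labelled `"none"`.
#'
#' @param path Path to a GFF3 file.
#' @param lengths Optional named vector of chromosome lengths; features
#'   extending beyond their chromosome raise an error.
#' @return Tibble with columns `feature_id`, `chrom`, `start`, `end`,
#'   `strand`, `type`, `compartment`.
#' @export
read_annotations <- function(path, lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
  if (anyNA(ids)) {
    ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  }
  comp <- if ("compartment" %in% names(mc)) as.character(mc$compartment)
          else rep(NA_character_, length(gr))
  comp[is.na(comp)] <- "none"
  bad_comp <- setdiff(unique(comp), VALID_COMPARTMENTS)
  if (length(bad_comp)) {
    abort(paste0("unknown compartment label(s): ",
                 paste(bad_comp, collapse = ", ")))
  }
  ann <- tibble(
    feature_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = chartr("*", ".", as.character(GenomicRanges::strand(gr))),
    type = as.character(mc$type),
    compartment = comp
  )
  if (anyDuplicated(ann$feature_id)) abort("feature ids must be unique")
  if (any(ann$end <= ann$start)) abort("annotation with end <= start")
  if (!is.null(lengths)) {
    ln <- lengths[ann$chrom]
    if (anyNA(ln)) {
      abort(paste0("annotation on unknown chromosome: ",
                   ann$chrom[is.na(ln)][1]))
    }
    if (any(ann$end > ln)) {
      abort(paste0("feature '", ann$feature_id[ann$end > ln][1],
                   "' extends beyond its chromosome"))
    }
  }
  ann
}

#' Write annotations to GFF3
#'
#' @param ann Annotation tibble as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  attr_col <- paste0("ID=", ann$feature_id, ";compartment=", ann$compartment)
  lines <- paste(ann$chrom, ".", ann$type, ann$start + 1L, ann$end, ".",
                 ann$strand, ".", attr_col, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read population genotypes from a VCF file
#'
#' Keeps biallelic SNP records only (multiallelic records are skipped with a
#' message); `./.` genotypes become `"missing"`. Only the GT field is used.
#'
#' @param path Path to a VCF file.
#' @param sex_map Data frame with columns `individual` and `sex`
#'   (`"male"`/`"female"`) covering every sample in the VCF.
#' @return A `uv_genotypes` object: list with `sites` (tibble `chrom`,
#'   `pos` 0-based, `ref`, `alt`), `geno` (site x individual character
#'   matrix of `hom_ref`/`het`/`hom_alt`/`missing`) and `sex` (named vector).
#' @export
read_genotypes <- function(path, sex_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  keep <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    inform(paste0("skipped ", n_skip, " non-biallelic-SNP record(s)"))
  }
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]
  geno <- gt_to_code(gt_raw)
  dimnames(geno) <- list(NULL, colnames(gt_raw))
  genotype_table(
    sites = tibble(
      chrom = fix[, "CHROM"],
      pos = as.integer(fix[, "POS"]) - 1L,
      ref = fix[, "REF"],
      alt = fix[, "ALT"]
    ),
    geno = geno,
    sex_map = sex_map
  )
}

gt_to_code <- function(gt_raw) {
  g <- gsub("\\|", "/", gt_raw)
  out <- matrix("missing", nrow = nrow(g), ncol = ncol(g),
                dimnames = dimnames(g))
  out[g %in% c("0/0")] <- "hom_ref"
  out[g %in% c("0/1", "1/0")] <- "het"
  out[g %in% c("1/1")] <- "hom_alt"
  out
}

#' Construct a genotype table
#'
#' @param sites Tibble with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param geno Site x individual character matrix with values in
#'   `hom_ref`/`het`/`hom_alt`/`missing`; column names are individual ids.
#' @param sex_map Data frame with columns `individual`, `sex`.
#' @return A `uv_genotypes` object.
#' @export
genotype_table <- function(sites, geno, sex_map) {
  stopifnot(nrow(sites) == nrow(geno))
  if (!all(geno %in% GT_CODES)) abort("invalid genotype codes")
  inds <- colnames(geno)
  if (is.null(inds)) abort("genotype matrix must have individual ids")
  sex <- setNames(as.character(sex_map$sex), as.character(sex_map$individual))
  missing_ind <- setdiff(inds, names(sex))
  if (length(missing_ind)) {
    abort(paste0("individual(s) absent from sex_map: ",
                 paste(missing_ind, collapse = ", ")))
  }
  if (!all(sex[inds] %in% c("male", "female"))) {
    abort("sex labels must be 'male' or 'female'")
  }
  structure(
    list(sites = as_tibble(sites), geno = geno, sex = sex[inds]),
    class = "uv_genotypes"
  )
}

#' @export
print.uv_genotypes <- function(x, ...) {
  cat("<uv_genotypes> ", nrow(x$sites), " site(s) x ", ncol(x$geno),
      " individual(s) (", sum(x$sex == "male"), " male, ",
      sum(x$sex == "female"), " female)\n", sep = "")
  invisible(x)
}

#' Write a genotype table to a minimal VCF (GT only)
#'
#' @param gt A `uv_genotypes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  code_to_gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                  missing = "./.")
  gtm <- matrix(code_to_gt[gt$geno], nrow = nrow(gt$geno))
  body <- paste(gt$sites$chrom, gt$sites$pos + 1L, ".", gt$sites$ref,
                gt$sites$alt, ".", ".", ".", "GT",
                apply(gtm, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt$geno)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a rooted species tree from a newick file
#'
#' @param path Path to a newick file.
#' @return An [ape::read.tree()] `phylo` object, validated to be rooted
#'   with non-negative branch lengths and unique tip labels.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (is.null(tr)) abort("could not parse newick tree")
  if (!ape::is.rooted(tr)) {
    abort("tree is unrooted (trifurcating root); root it before use")
  }
  if (is.null(tr$edge.length)) abort("tree must have branch lengths")
  if (any(tr$edge.length < 0)) abort("negative branch length in tree")
  if (anyDuplicated(tr$tip.label)) abort("tip labels must be unique")
  tr
}

#' Write a species tree to newick
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Tile chromosomes into windows
#'
#' Windows tile each chromosome left to right; a trailing window shorter
#' than `width` is retained and flagged `partial` so downstream statistics
#' can exclude it.
#'
#' @param lengths Named vector of chromosome lengths in bp.
#' @param width Window width in bp.
#' @param step Step between window starts; defaults to `width`
#'   (non-overlapping tiling).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `partial`.
#' @export
make_windows <- function(lengths, width, step = width) {
  if (width <= 0) abort("window width must be > 0")
  if (step <= 0) abort("window step must be > 0")
  if (is.null(names(lengths)) || any(lengths <= 0)) {
    abort("lengths must be a named vector of positive sizes")
  }
  width <- as.integer(width); step <- as.integer(step)
  purrr::map_dfr(names(lengths), function(chrom) {
    len <- as.integer(lengths[[chrom]])
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + width, len)
    tibble(chrom = chrom, start = starts, end = ends,
           partial = ends - starts < width)
  })
}

#' Merge overlapping or adjacent intervals
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @return Tibble of disjoint merged intervals, sorted by chrom then start.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  intervals |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(grp = cumsum(.data$start > lag(cummax(.data$end),
                                          default = -1L))) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("chrom", "start", "end") |>
    arrange(.data$chrom, .data$start)
}

#' Total overlap and Jaccard index between two interval sets
#'
#' @param a,b Tibbles with `chrom`, `start`, `end`.
#' @return One-row tibble with `intersection_bp`, `union_bp`, `jaccard`.
#' @export
interval_jaccard <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  inter <- 0
  for (ch in union(a$chrom, b$chrom)) {
    ai <- a[a$chrom == ch, ]; bi <- b[b$chrom == ch, ]
    if (nrow(ai) == 0L || nrow(bi) == 0L) next
    for (i in seq_len(nrow(ai))) {
      ov <- pmin(ai$end[i], bi$end) - pmax(ai$start[i], bi$start)
      inter <- inter + sum(pmax(ov, 0))
    }
  }
  total <- sum(a$end - a$start) + sum(b$end - b$start)
  un <- total - inter
  tibble(intersection_bp = inter, union_bp = un,
         jaccard = if (un == 0) NA_real_ else inter / un)
}

#' Read a BED file of window values
#'
#' @param path Path to a BED file (`chrom  start  end  value...`),
#'   0-based half-open.
#' @param col_names Names for columns after `chrom`, `start`, `end`.
#' @return Tibble.
#' @export
read_bed <- function(path, col_names = "value") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end",
                 col_names)[seq_len(ncol(df))]
  as_tibble(df)
}

#' Write a tibble of intervals (plus optional value columns) as BED
#'
#' @param x Tibble whose first columns are `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end",
            setdiff(names(x), c("chrom", "start", "end", "partial")))
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
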