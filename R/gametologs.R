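# Gametologue analysis: reciprocal-best-hit pairing of U and V proteins,
# protein-guided codon back-alignment, and NG86 Ka/Ks with
# Jukes-Cantor correction and saturation flagging.

#' Reciprocal best hits between two protein sets
#'
#' Scores every male x female pair by local protein alignment and reports
#' pairs that are mutually top-scoring. Score ties are broken by longer
#' alignment, then lexicographically smaller partner id; a residual tie is
#' dropped as ambiguous.
#'
#' @param male,female Named character vectors of amino-acid sequences.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param substitution_matrix Substitution matrix name (see
#'   [Biostrings::pairwiseAlignment()]).
#' @param min_score Pairs scoring below this are ignored.
#' @return Tibble with `male_gene`, `female_gene`, `score`.
#' @export
reciprocal_best_hits <- function(male, female, gap_opening = 10,
                                 gap_extension = 0.5,
                                 substitution_matrix = "BLOSUM62",
                                 min_score = 0) {
  if (length(male) == 0L || length(female) == 0L) {
    return(tibble(male_gene = character(), female_gene = character(),
                  score = numeric()))
  }
  score <- matrix(-Inf, length(male), length(female),
                  dimnames = list(names(male), names(female)))
  width <- score
  for (i in seq_along(male)) {
    aln <- Biostrings::pairwiseAlignment(
      rep(Biostrings::AAStringSet(male[i]), length(female)),
      Biostrings::AAStringSet(female),
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_opening, gapExtension = gap_extension,
      type = "local")
    score[i, ] <- Biostrings::score(aln)
    width[i, ] <- Biostrings::nchar(aln)
  }
  # score ties -> longer alignment -> lexicographically smaller id
  best_of <- function(s, w, ids) {
    top <- which(s == max(s))
    top <- top[w[top] == max(w[top])]
    top[order(ids[top])][1]
  }
  m_best <- vapply(seq_along(male), function(i)
    best_of(score[i, ], width[i, ], names(female)), integer(1))
  f_best <- vapply(seq_along(female), function(j)
    best_of(score[, j], width[, j], names(male)), integer(1))
  out <- purrr::map_dfr(seq_along(male), function(i) {
    j <- m_best[i]
    if (is.na(j) || is.na(f_best[j]) || f_best[j] != i) return(NULL)
    if (score[i, j] < min_score) return(NULL)
    tibble(male_gene = names(male)[i], female_gene = names(female)[j],
           score = score[i, j])
  })
  out
}

#' Back-align a protein alignment to codons
#'
#' Expands a gapped amino-acid alignment of two sequences to a codon
#' alignment: each residue becomes its source codon and each gap a `---`
#' triplet, so gaps only occur in whole-codon units.
#'
#' @param prot_a,prot_b Aligned amino-acid strings (equal length, gaps as
#'   `-`).
#' @param cds_a,cds_b In-frame CDSs translating exactly to the ungapped
#'   proteins (a trailing stop codon is tolerated and trimmed).
#' @return List of class `uv_codon_alignment` with elements `a` and `b`.
#' @export
codon_backalign <- function(prot_a, prot_b, cds_a, cds_b) {
  if (nchar(prot_a) != nchar(prot_b)) {
    abort("aligned proteins must have equal length")
  }
  expand <- function(prot, cds, which) {
    cod <- split_codons(cds)
    gc <- genetic_code()
    if (length(cod) > 1 && gc[[cod[length(cod)]]] == "*") {
      cod <- cod[-length(cod)]
    }
    res <- strsplit(prot, "")[[1]]
    n_res <- sum(res != "-")
    if (n_res != length(cod)) {
      abort(paste0("CDS ", which, " length does not match its protein"))
    }
    out <- character(length(res))
    ci <- 0L
    for (i in seq_along(res)) {
      if (res[i] == "-") {
        out[i] <- "---"
      } else {
        ci <- ci + 1L
        aa <- gc[[cod[ci]]]
        if (is.na(aa) || aa != res[i]) {
          abort(paste0("codon ", ci, " of CDS ", which,
                       " does not translate to the aligned residue"))
        }
        out[i] <- cod[ci]
      }
    }
    paste(out, collapse = "")
  }
  structure(list(a = expand(prot_a, cds_a, "a"),
                 b = expand(prot_b, cds_b, "b")),
            class = "uv_codon_alignment")
}

# minimal substitution paths between two codons: average (syn, nonsyn)
# counts over orderings of the differing positions, excluding paths that
# pass through a stop codon (all paths kept if every path hits a stop).
codon_pair_diffs <- function(cod1, cod2) {
  gc <- genetic_code()
  pos <- which(strsplit(cod1, "")[[1]] != strsplit(cod2, "")[[1]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd, through_stop) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(sd, nd, through_stop)
      return(invisible())
    }
    for (p in remaining) {
      nxt_chars <- strsplit(cur, "")[[1]]
      nxt_chars[p] <- substr(cod2, p, p)
      nxt <- paste(nxt_chars, collapse = "")
      syn <- !is.na(gc[[cur]]) && !is.na(gc[[nxt]]) &&
        gc[[cur]] != "*" && gc[[nxt]] != "*" && gc[[cur]] == gc[[nxt]]
      walk(nxt, setdiff(remaining, p),
           sd + as.numeric(syn), nd + as.numeric(!syn),
           through_stop || gc[[nxt]] == "*")
    }
  }
  walk(cod1, pos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

kaks_env <- new.env(parent = emptyenv())

codon_pair_diffs_cached <- function(cod1, cod2) {
  key <- paste0(cod1, cod2)
  hit <- kaks_env[[key]]
  if (!is.null(hit)) return(hit)
  val <- codon_pair_diffs(cod1, cod2)
  kaks_env[[key]] <- val
  kaks_env[[paste0(cod2, cod1)]] <- val
  val
}

#' NG86 Ka/Ks on a codon alignment
#'
#' Synonymous and nonsynonymous sites follow the NG86 one-third-per-change
#' rule averaged between the two sequences; differences in multiply-hit
#' codons are averaged over all minimal substitution paths (paths through
#' stop codons excluded when an alternative exists); proportions are
#' Jukes-Cantor corrected. When `ps >= 3/4` the synonymous distance is
#' saturated: `Ks` is `NA` and the `saturated` flag is set (likewise for
#' `Ka`/`pn`).
#'
#' @param aln A `uv_codon_alignment` from [codon_backalign()], or a list
#'   with aligned codon strings `a` and `b`.
#' @return One-row tibble: `n_codons` (compared), `S`, `N`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ks`, `Ka`, `saturated`.
#' @export
ng86_kaks <- function(aln) {
  cod_a <- split_codons(aln$a)
  cod_b <- split_codons(aln$b)
  if (length(cod_a) != length(cod_b)) {
    abort("aligned codon strings must have equal length")
  }
  gc <- genetic_code()
  clean <- !grepl("[^ACGT]", cod_a) & !grepl("[^ACGT]", cod_b)
  clean <- clean & !is.na(gc[cod_a]) & !is.na(gc[cod_b]) &
    gc[cod_a] != "*" & gc[cod_b] != "*"
  cod_a <- cod_a[clean]; cod_b <- cod_b[clean]
  if (length(cod_a) == 0L) abort("no comparable codons in the alignment")
  sites <- get_ng86_sites()
  S <- (sum(sites[cod_a]) + sum(sites[cod_b])) / 2
  N <- 3 * length(cod_a) - S
  diffs <- vapply(seq_along(cod_a), function(i)
    codon_pair_diffs_cached(cod_a[i], cod_b[i]), numeric(2))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) -0.75 * log(1 - 4 / 3 * p)
  sat_s <- !is.na(ps) && ps >= 0.75
  sat_n <- !is.na(pn) && pn >= 0.75
  tibble(n_codons = length(cod_a), S = S, N = N, Sd = Sd, Nd = Nd,
         ps = ps, pn = pn,
         Ks = if (sat_s || is.na(ps)) NA_real_ else jc(ps),
         Ka = if (sat_n || is.na(pn)) NA_real_ else jc(pn),
         saturated = sat_s || sat_n)
}

#' Classify SDR genes as gametologues or sex-specific
#'
#' A gene is a gametologue when its best-hit partner lies inside the
#' opposite sex's SDR; SDR genes without such a partner (absent or hit
#' outside the SDR) are sex-specific.
#'
#' @param male_sdr_genes,female_sdr_genes Character vectors of SDR gene
#'   ids per sex.
#' @param pairs Tibble with `male_gene`, `female_gene` (for example from
#'   [reciprocal_best_hits()]); partners may lie outside the SDRs.
#' @return Tibble with `gene`, `sex`, `class`
#'   (`gametologue`/`sex_specific`), `partner`.
#' @export
classify_sdr_genes <- function(male_sdr_genes, female_sdr_genes, pairs) {
  gam <- pairs |>
    filter(.data$male_gene %in% male_sdr_genes,
           .data$female_gene %in% female_sdr_genes)
  bind_rows(
    tibble(gene = male_sdr_genes, sex = "male",
           partner = gam$female_gene[match(male_sdr_genes,
                                           gam$male_gene)]),
    tibble(gene = female_sdr_genes, sex = "female",
           partner = gam$male_gene[match(female_sdr_genes,
                                         gam$female_gene)])
  ) |>
    mutate(class = if_else(is.na(.data$partner), "sex_specific",
                           "gametologue"),
           .before = "partner")
}
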