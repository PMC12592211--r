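# Window feature densities and the statistical battery contrasting
# chromosomes and compartments: Wilcoxon rank-sum with BH FDR, seeded
# permutation tests, chi-square orthologue depletion, Pearson standardized
# residuals, OLS R-squared, 2x2 enrichment, and the expression-activity
# threshold.

#' Enrichment testing configuration
#'
#' @param n_perm Label permutations per test.
#' @param fdr_alpha FDR level used by reporting helpers.
#' @param residual_threshold Absolute Pearson standardized residual above
#'   which a cell is flagged.
#' @param seed RNG seed for permutation tests.
#' @return A `uv_enrich_config` list.
#' @export
enrichment_config <- function(n_perm = 10000L, fdr_alpha = 0.05,
                              residual_threshold = 2.4, seed = 1L) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  structure(list(n_perm = as.integer(n_perm), fdr_alpha = fdr_alpha,
                 residual_threshold = residual_threshold,
                 seed = as.integer(seed)),
            class = "uv_enrich_config")
}

#' Fraction of each window covered by a feature type
#'
#' Features of the requested type are unioned (overlaps collapse) before
#' computing covered bp per window, so stacked repeats never push a
#' fraction above 1.
#'
#' @param ann Annotation tibble (see [read_annotations()]).
#' @param windows Window tibble from [make_windows()].
#' @param feature_type Feature type to measure (e.g. `"gene"`,
#'   `"repeat"`).
#' @param col Name of the output column.
#' @return `windows` with the density column added.
#' @export
window_feature_density <- function(ann, windows, feature_type,
                                   col = paste0(feature_type,
                                                "_fraction")) {
  feat <- ann |>
    filter(.data$type == feature_type) |>
    select("chrom", "start", "end") |>
    merge_intervals()
  dens <- vapply(seq_len(nrow(windows)), function(i) {
    f <- feat[feat$chrom == windows$chrom[i], ]
    if (nrow(f) == 0L) return(0)
    ov <- pmin(f$end, windows$end[i]) - pmax(f$start, windows$start[i])
    sum(pmax(ov, 0)) / (windows$end[i] - windows$start[i])
  }, numeric(1))
  windows[[col]] <- dens
  windows
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null when the smaller group has at most 8 observations and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param a,b Numeric samples.
#' @return One-row tibble: `statistic` (W), `p`, `n_a`, `n_b`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  tibble(statistic = unname(wt$statistic), p = wt$p.value,
         n_a = length(a), n_b = length(b),
         method = if (exact) "exact" else "normal_approx")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment (monotone, capped at 1) with the input order
#' restored.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Seeded two-sided permutation test for a group difference
#'
#' The statistic is the difference of group means; the two-sided p-value
#' is `(1 + #{|stat*| >= |stat_obs|}) / (n_perm + 1)`, never exactly zero.
#'
#' @param values Numeric vector.
#' @param labels Two-level grouping vector.
#' @param cfg An [enrichment_config()] (permutations and seed).
#' @param statistic Function of `(values, labels)` returning a scalar;
#'   defaults to the difference of group means.
#' @return One-row tibble: `statistic`, `p`, `n_perm`, group sizes.
#' @export
permutation_test <- function(values, labels, cfg = enrichment_config(),
                             statistic = NULL) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) abort("labels must have exactly two levels")
  if (!all(table(labels) > 0L)) abort("both groups must be non-empty")
  stat_fn <- statistic %||% function(v, lab) {
    mean(v[lab == lv[1]]) - mean(v[lab == lv[2]])
  }
  obs <- stat_fn(values, labels)
  set.seed(cfg$seed)
  perm <- vapply(seq_len(cfg$n_perm), function(i) {
    stat_fn(values, sample(labels)) }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (cfg$n_perm + 1)
  tibble(statistic = obs, p = p, n_perm = cfg$n_perm,
         n_a = sum(labels == lv[1]), n_b = sum(labels == lv[2]))
}

#' Per-chromosome orthologue depletion chi-square
#'
#' The expected orthologue count of each chromosome is proportional to its
#' gene count. Each chromosome is tested against the rest of the genome
#' (1-df chi-square on observed vs expected), with BH correction across
#' chromosomes.
#'
#' @param observed Named vector of detected orthologues per chromosome.
#' @param genes Named vector of gene counts per chromosome.
#' @return Tibble per chromosome: `chrom`, `observed`, `expected`,
#'   `statistic`, `p`, `p_adj`, `depleted`.
#' @export
orthologue_depletion_test <- function(observed, genes) {
  if (!setequal(names(observed), names(genes))) {
    abort("observed and genes must cover the same chromosomes")
  }
  genes <- genes[names(observed)]
  if (sum(observed) <= 0 || sum(genes) <= 0) abort("totals must be > 0")
  tot_o <- sum(observed); tot_g <- sum(genes)
  expected <- tot_o * genes / tot_g
  stat <- vapply(seq_along(observed), function(i) {
    o <- c(observed[i], tot_o - observed[i])
    e <- c(expected[i], tot_o - expected[i])
    sum((o - e)^2 / e)
  }, numeric(1))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  tibble(chrom = names(observed), observed = unname(observed),
         expected = unname(expected), statistic = unname(stat),
         p = p, p_adj = bh_fdr(p),
         depleted = unname(observed < expected))
}

#' Pearson standardized residuals of a contingency table
#'
#' `r_ij = (O - E) / sqrt(E (1 - row/grand)(1 - col/grand))`; cells with
#' `|r|` above the threshold are flagged as driving the association.
#'
#' @param tab Contingency table (matrix).
#' @param residual_threshold Flagging threshold.
#' @return List with `residuals` (matrix) and `flagged` (logical matrix).
#' @export
pearson_std_residuals <- function(tab, residual_threshold = 2.4) {
  tab <- as.matrix(tab)
  grand <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / grand
  if (any(E <= 0)) abort("all expected cell counts must be > 0")
  r <- (tab - E) /
    sqrt(E * outer(1 - rowSums(tab) / grand, 1 - colSums(tab) / grand))
  list(residuals = r, flagged = abs(r) > residual_threshold)
}

#' Ordinary least squares R-squared
#'
#' @param x,y Numeric vectors (n >= 3, `var(x) > 0`).
#' @return R-squared; `NA` with a warning when `y` is constant.
#' @export
linreg_r2 <- function(x, y) {
  if (length(x) < 3L) abort("need at least 3 points")
  if (var(x) == 0) abort("x has zero variance")
  if (var(y) == 0) {
    warn("y is constant: R-squared undefined")
    return(NA_real_)
  }
  fit <- lm(y ~ x)
  suppressWarnings(summary(fit)$r.squared)
}

#' 2x2 enrichment chi-square (e.g. male-biased genes on the PARs)
#'
#' @param tab 2x2 count matrix.
#' @param correct Continuity correction (off by default).
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @export
sbg_compartment_enrichment <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) abort("expected a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero margin in the contingency table")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Transcriptional activity flag
#'
#' A gene is active when `log2(TPM + 1) > 2` (strict).
#'
#' @param tpm Non-negative expression values.
#' @return Logical vector.
#' @export
expression_active <- function(tpm) {
  if (any(tpm < 0)) abort("TPM must be >= 0")
  log2(tpm + 1) > 2
}

#' Per-autosome contrasts of a window feature against the sex chromosome
#'
#' Runs a two-sided Wilcoxon rank-sum test of each autosome's windows
#' against the sex chromosome's windows for the given feature and applies
#' BH correction across autosomes.
#'
#' @param wft Window feature tibble (with `chrom` and the feature column).
#' @param feature Feature column name.
#' @param sex_chrom Sex-chromosome name.
#' @param drop_na Drop windows with NA feature values (per test).
#' @return Tibble per autosome with the test results and `p_adj`.
#' @export
autosome_vs_sex_tests <- function(wft, feature, sex_chrom = "chrUV",
                                  drop_na = TRUE) {
  if (drop_na) wft <- wft |> filter(!is.na(.data[[feature]]))
  sexv <- wft[[feature]][wft$chrom == sex_chrom]
  autos <- setdiff(unique(wft$chrom), sex_chrom)
  out <- purrr::map_dfr(autos, function(a) {
    res <- wilcoxon_rank_sum(wft[[feature]][wft$chrom == a], sexv)
    res |> mutate(chrom = a, feature = feature, .before = 1)
  })
  out |> mutate(p_adj = bh_fdr(.data$p))
}
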