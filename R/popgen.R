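# Population statistics for the sex-chromosome search: per-scaffold
# heterozygosity, the log10 male:female heterozygosity ratio, and the
# Weir-Cockerham (1984) two-population FST estimator between the sexes.

#' Per-individual, per-scaffold heterozygosity
#'
#' Heterozygosity is the fraction of non-missing sites called heterozygous;
#' missing genotypes leave both numerator and denominator.
#'
#' @param gt A `uv_genotypes` object.
#' @return Tibble with `individual`, `sex`, `scaffold`, `n_called`,
#'   `n_het`, `het` (NA with a warning when all sites are missing).
#' @export
heterozygosity_fraction <- function(gt) {
  scaffolds <- gt$sites$chrom
  purrr::map_dfr(unique(scaffolds), function(sc) {
    g <- gt$geno[scaffolds == sc, , drop = FALSE]
    called <- colSums(g != "missing")
    het <- colSums(g == "het")
    tibble(individual = colnames(g), sex = unname(gt$sex),
           scaffold = sc, n_called = unname(called),
           n_het = unname(het),
           het = unname(ifelse(called > 0, het / called, NA_real_)))
  }) -> out
  if (anyNA(out$het)) {
    warn("individual(s) with no called sites on a scaffold: het is NA")
  }
  out
}

#' Sex-biased heterozygosity per scaffold
#'
#' The log10 ratio of mean male to mean female heterozygosity, expected to
#' be zero for autosomal scaffolds and elevated on young sex-linked
#' scaffolds where males carry excess heterozygosity.
#'
#' @param het_tbl Output of [heterozygosity_fraction()], or a
#'   `uv_genotypes` object.
#' @return Tibble with `scaffold`, `h_male`, `h_female`, `log10_ratio`
#'   (`NA` when female heterozygosity is zero, `-Inf` when only male
#'   heterozygosity is zero).
#' @export
sex_biased_heterozygosity <- function(het_tbl) {
  if (inherits(het_tbl, "uv_genotypes")) {
    het_tbl <- heterozygosity_fraction(het_tbl)
  }
  het_tbl |>
    group_by(.data$scaffold) |>
    summarise(
      h_male = mean(.data$het[.data$sex == "male"], na.rm = TRUE),
      h_female = mean(.data$het[.data$sex == "female"], na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(log10_ratio = dplyr::case_when(
      .data$h_female == 0 ~ NA_real_,
      TRUE ~ log10(.data$h_male / .data$h_female)
    ))
}

#' Weir-Cockerham FST between the sexes
#'
#' The two-allele, two-population estimator of Weir & Cockerham (1984):
#' per-site variance components a (among populations), b (among
#' individuals within populations) and c (within individuals), with
#' per-site theta = a/(a+b+c) and windowed/overall theta as the ratio of
#' sums. Monomorphic sites and sites where either sex has fewer than two
#' called individuals are skipped. Negative estimates are reported as
#' computed.
#'
#' @param gt A `uv_genotypes` object; groups are the sex labels.
#' @param by `"site"`, `"scaffold"` or `"overall"` aggregation.
#' @return For `by = "site"`: tibble with `chrom`, `pos`, `a`, `b`, `c`,
#'   `theta`. Otherwise per-scaffold or overall ratio-of-sums theta with
#'   the per-site sums and the skipped-site count as attribute
#'   `n_skipped`.
#' @export
weir_cockerham_fst <- function(gt, by = c("site", "scaffold", "overall")) {
  by <- match.arg(by)
  male <- gt$geno[, gt$sex == "male", drop = FALSE]
  female <- gt$geno[, gt$sex == "female", drop = FALSE]
  comp <- purrr::map_dfr(seq_len(nrow(gt$sites)), function(i) {
    wc_site_components(male[i, ], female[i, ])
  })
  out <- bind_cols(gt$sites[, c("chrom", "pos")], comp)
  n_skipped <- sum(!out$usable)
  if (by == "site") {
    res <- out |>
      filter(.data$usable) |>
      mutate(theta = .data$a / (.data$a + .data$b + .data$c)) |>
      select("chrom", "pos", "a", "b", "c", "theta")
  } else if (by == "scaffold") {
    res <- out |>
      filter(.data$usable) |>
      group_by(chrom = .data$chrom) |>
      summarise(sum_a = sum(.data$a),
                sum_abc = sum(.data$a + .data$b + .data$c),
                n_sites = n(), .groups = "drop") |>
      mutate(theta = .data$sum_a / .data$sum_abc)
  } else {
    use <- out |> filter(.data$usable)
    res <- tibble(sum_a = sum(use$a),
                  sum_abc = sum(use$a + use$b + use$c),
                  n_sites = nrow(use)) |>
      mutate(theta = .data$sum_a / .data$sum_abc)
  }
  attr(res, "n_skipped") <- n_skipped
  res
}

# Weir & Cockerham (1984) variance components for one biallelic site and
# two groups of diploid genotype codes.
wc_site_components <- function(g1, g2) {
  count <- function(g) {
    called <- g != "missing"
    n <- sum(called)
    nalt <- sum(g == "het") + 2L * sum(g == "hom_alt")
    list(n = n, p = if (n > 0) nalt / (2 * n) else NA_real_,
         h = if (n > 0) sum(g == "het") / n else NA_real_)
  }
  c1 <- count(g1); c2 <- count(g2)
  if (c1$n < 2 || c2$n < 2) {
    return(tibble(a = NA_real_, b = NA_real_, c = NA_real_,
                  usable = FALSE))
  }
  r <- 2
  n_i <- c(c1$n, c2$n); p_i <- c(c1$p, c2$p); h_i <- c(c1$h, c2$h)
  nbar <- mean(n_i)
  pbar <- sum(n_i * p_i) / (r * nbar)
  if (pbar == 0 || pbar == 1) {
    return(tibble(a = NA_real_, b = NA_real_, c = NA_real_,
                  usable = FALSE))
  }
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  tibble(a = a, b = b, c = cc, usable = TRUE)
}
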