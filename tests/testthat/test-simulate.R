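# Synthetic-data generators and their ground-truth contracts.

test_that("autosomes and PARs are identical between sexes, SDRs are not", {
  sim <- tiny_sim()
  cfg <- sim$cfg
  expect_identical(sim$male[["autosome_1"]], sim$female[["autosome_1"]])
  expect_identical(substr(sim$male[["chrUV"]], 1, cfg$sdr_start),
                   substr(sim$female[["chrUV"]], 1, cfg$sdr_start))
  expect_identical(substr(sim$male[["chrUV"]], cfg$sdr_end + 1,
                          cfg$uv_len),
                   substr(sim$female[["chrUV"]], cfg$sdr_end + 1,
                          cfg$uv_len))
  expect_false(substr(sim$male[["chrUV"]], cfg$sdr_start + 1,
                      cfg$sdr_end) ==
                 substr(sim$female[["chrUV"]], cfg$sdr_start + 1,
                        cfg$sdr_end))
})

test_that("a zero-length SDR makes the sexes identical", {
  cfg <- sim_config(seed = 5, n_autosomes = 1L, autosome_len = 5e4,
                    uv_len = 1e5, sdr_start = 5e4, sdr_end = 5e4,
                    n_gametologues = 0L, n_sex_specific = 0L)
  sim <- simulate_genome_pair(cfg)
  expect_identical(c(unclass(sim$male)), c(unclass(sim$female)))
})

test_that("identical config and seed reproduce the genome pair exactly", {
  cfg <- tiny_sim_config()
  a <- simulate_genome_pair(cfg)
  b <- simulate_genome_pair(cfg)
  expect_identical(unclass(a$male), unclass(b$male))
  expect_identical(unclass(a$female), unclass(b$female))
  expect_identical(a$male_ann, b$male_ann)
})

test_that("every true gametologue pair has one gene inside each SDR", {
  sim <- tiny_sim()
  sdr <- sim$truth$sdr_bed
  in_sdr <- function(ann, ids, sex) {
    rows <- ann[ann$feature_id %in% ids, ]
    s <- sdr[sdr$sex == sex, ]
    all(rows$chrom == s$chrom & rows$start >= s$start &
          rows$end <= s$end)
  }
  expect_true(in_sdr(sim$male_ann, sim$truth$true_pairs$male_gene,
                     "male"))
  expect_true(in_sdr(sim$female_ann, sim$truth$true_pairs$female_gene,
                     "female"))
  expect_true(all(sim$truth$gene_compartments == "SDR"))
})

test_that("U and V SDR haplotypes share few single-copy k-mers", {
  sim <- tiny_sim()
  cfg <- sim$cfg
  kcfg <- kmer_config(min_count = 1, min_base_quality = NULL)
  m_sdr <- substr(sim$male[["chrUV"]], cfg$sdr_start + 1, cfg$sdr_end)
  f_sdr <- substr(sim$female[["chrUV"]], cfg$sdr_start + 1, cfg$sdr_end)
  m_sc <- genome_single_copy_kmers(sequence_set(c(v = m_sdr)), kcfg)
  f_sc <- genome_single_copy_kmers(sequence_set(c(u = f_sdr)), kcfg)
  shared <- mean(m_sc$code %in% f_sc$code)
  expect_lt(shared, 0.05)
})

test_that("read simulation hits the requested depth and is reproducible", {
  set.seed(8)
  genome <- sequence_set(c(chr = rand_dna(1e5)))
  r <- simulate_reads(genome, depth = 10, read_len = 100,
                      error_rate = 0, seed = 3)
  expect_equal(sum(nchar(r$reads$seq)), 10 * 1e5, tolerance = 100 / 1e6)
  expect_equal(sum(as.numeric(r$depth$chr)), nrow(r$reads) * 100)

  r0 <- simulate_reads(genome, depth = 0, read_len = 100, seed = 3)
  expect_equal(nrow(r0$reads), 0L)

  r2 <- simulate_reads(genome, depth = 10, read_len = 100,
                       error_rate = 0, seed = 3)
  expect_identical(r$reads, r2$reads)

  expect_error(simulate_reads(genome, 1, read_len = 2e5), "read_len")
  # error-free reads are exact substrings of the genome or its complement
  probe <- r$reads$seq[1:20]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(probe)))
  hits <- vapply(seq_along(probe), function(i) {
    grepl(probe[i], genome[["chr"]], fixed = TRUE) ||
      grepl(rc[i], genome[["chr"]], fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
})

test_that("substitution errors appear at the configured rate", {
  set.seed(9)
  genome <- sequence_set(c(chr = rand_dna(5e4)))
  r <- simulate_reads(genome, depth = 4, read_len = 100,
                      error_rate = 0.02, seed = 5)
  # place reads back by alignment-free position lookup is overkill; count
  # mismatching reads against an exact-substring check instead
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r$reads$seq)))
  exact <- vapply(seq_len(nrow(r$reads)), function(i) {
    grepl(r$reads$seq[i], genome[["chr"]], fixed = TRUE) ||
      grepl(rc[i], genome[["chr"]], fixed = TRUE)
  }, logical(1))
  # P(read error-free) = (1 - 0.02)^100 ~ 0.133
  expect_equal(mean(exact), (1 - 0.02)^100, tolerance = 0.05)
})

test_that("population genotypes carry the young-XY signature", {
  cfg <- tiny_sim_config()
  gt <- simulate_population_genotypes(cfg)
  sexl <- gt$geno[attr(gt, "sexlinked"), , drop = FALSE]
  expect_equal(nrow(sexl), cfg$n_sexlinked_sites)
  males <- gt$sex == "male"
  expect_true(all(sexl[, males] == "het"))
  expect_true(all(sexl[, !males] == "hom_ref"))

  # without sex-linked sites both sexes have equal heterozygosity
  cfg0 <- sim_config(seed = 21, n_sexlinked_sites = 0L,
                     n_snp_sites = 4000L)
  gt0 <- simulate_population_genotypes(cfg0)
  het <- colMeans(gt0$geno == "het")
  hm <- mean(het[gt0$sex == "male"]); hf <- mean(het[gt0$sex == "female"])
  expect_equal(hm, hf, tolerance = 0.02)
  expect_equal(mean(het), cfg0$autosomal_het, tolerance = 0.02)

  gt0b <- simulate_population_genotypes(cfg0)
  expect_identical(gt0$geno, gt0b$geno)
})

test_that("family evolution honours absorbing states and stationarity", {
  tr <- demo_species_tree()
  # no loss, stationary root is always present
  fam <- simulate_family_evolution(tr, g = 1, l = 0, alpha = Inf,
                                   n_families = 50, seed = 2)
  expect_true(all(fam$matrix == 1L))
  # no gain: all-absent
  fam0 <- simulate_family_evolution(tr, g = 0, l = 1, alpha = Inf,
                                    n_families = 50, seed = 2)
  expect_true(all(fam0$matrix == 0L))
  expect_error(simulate_family_evolution(tr, 0, 0), "stationary")

  # tip frequency matches the stationary presence probability
  fam2 <- simulate_family_evolution(tr, g = 0.6, l = 0.9, alpha = Inf,
                                    n_families = 3000, seed = 3)
  pi1 <- 0.6 / 1.5
  se <- sqrt(pi1 * (1 - pi1) / 3000)
  for (tip in colnames(fam2$matrix)) {
    expect_equal(mean(fam2$matrix[, tip]), pi1, tolerance = 5 * se)
  }
  # truth covers every node and matches the emitted tip states
  expect_setequal(unique(fam2$node_states$node),
                  c(tr$tip.label, paste0("node_", 7:11)))
  ns <- fam2$node_states
  for (tip in colnames(fam2$matrix)) {
    expect_identical(ns$state[ns$node == tip],
                     unname(fam2$matrix[, tip]))
  }
})

test_that("homology tables encode recoverable true ages", {
  hom <- simulate_homology_table(150, n_strata = 6, seed = 4)
  ages <- assign_gene_ages(hom$hits, hom$ladder,
                           focal_taxon = hom$focal_taxon)
  j <- dplyr::inner_join(ages, hom$true_ages, by = "gene",
                         suffix = c("_est", "_true"))
  expect_equal(j$rank_est, j$rank_true)
  # genes with only the self-hit are youngest by construction
  only_self <- setdiff(hom$true_ages$gene[hom$true_ages$rank == 6],
                       hom$hits$gene[hom$hits$taxon != "focal_sp"])
  if (length(only_self)) {
    expect_true(all(ages$rank[ages$gene %in% only_self] == 6))
  }
})
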