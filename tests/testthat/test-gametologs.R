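# RBH pairing, codon back-alignment and NG86 Ka/Ks.

test_that("reciprocal best hits pick mutual top-scoring partners", {
  p <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  expect_equal(nrow(reciprocal_best_hits(c(a = p), c(b = p))), 1L)

  # a 50%-identical decoy does not displace the true partner
  set.seed(15)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  true_p <- paste(sample(aa, 60, replace = TRUE), collapse = "")
  decoy <- strsplit(true_p, "")[[1]]
  idx <- sample(60, 30)
  decoy[idx] <- sample(aa, 30, replace = TRUE)
  decoy <- paste(decoy, collapse = "")
  pairs <- reciprocal_best_hits(c(m1 = true_p),
                                c(f_true = true_p, f_decoy = decoy))
  expect_equal(pairs$female_gene, "f_true")

  expect_equal(nrow(reciprocal_best_hits(c(a = p),
                                         setNames(character(0),
                                                  character(0)))), 0L)
})

test_that("codon back-alignment expands residues and gaps", {
  ca <- codon_backalign("MK", "MK", "ATGAAA", "ATGAAG")
  expect_equal(ca$a, "ATGAAA")
  expect_equal(ca$b, "ATGAAG")

  ca <- codon_backalign("MGK", "M-K", "ATGGGAAAA", "ATGAAG")
  expect_equal(ca$a, "ATGGGAAAA")
  expect_equal(ca$b, "ATG---AAG")

  expect_error(codon_backalign("MK", "MM", "ATGAAA", "ATGAAG"),
               "codon 2")

  # trailing stop codons are tolerated and trimmed
  ca <- codon_backalign("MK", "MK", "ATGAAATAA", "ATGAAG")
  expect_equal(ca$a, "ATGAAA")
})

test_that("back-aligned codons translate to their aligned residues", {
  set.seed(16)
  for (i in 1:5) {
    cds1 <- paste(c("ATG", sample(setdiff(sense_codons(), "ATG"), 40,
                                  replace = TRUE)), collapse = "")
    cds2 <- paste(c("ATG", sample(setdiff(sense_codons(), "ATG"), 35,
                                  replace = TRUE)), collapse = "")
    p1 <- translate_cds(cds1); p2 <- translate_cds(cds2)
    aln <- Biostrings::pairwiseAlignment(p1, p2,
                                         substitutionMatrix = "BLOSUM62",
                                         gapOpening = 10,
                                         gapExtension = 0.5,
                                         type = "global")
    ca <- codon_backalign(as.character(Biostrings::alignedPattern(aln)),
                          as.character(Biostrings::alignedSubject(aln)),
                          cds1, cds2)
    expect_equal(nchar(ca$a), nchar(ca$b))
    for (side in c("a", "b")) {
      cods <- split_codons(ca[[side]])
      res <- strsplit(as.character(
        if (side == "a") Biostrings::alignedPattern(aln)
        else Biostrings::alignedSubject(aln)), "")[[1]]
      non_gap <- cods != "---"
      expect_equal(paste(res[non_gap], collapse = ""),
                   translate_cds(paste(cods[non_gap], collapse = "")))
    }
  }
})

test_that("NG86 reproduces hand-computed and degenerate cases", {
  same <- list(a = "ATGAAA", b = "ATGAAA")
  r <- ng86_kaks(same)
  expect_equal(r$Ks, 0); expect_equal(r$Ka, 0)
  expect_equal(r$S + r$N, 3 * r$n_codons)

  a <- paste(rep("AAA", 9), collapse = "")
  r <- ng86_kaks(list(a = paste0(a, "GGT"), b = paste0(a, "GGC")))
  expect_equal(r$S, 4)
  expect_equal(r$Sd, 1)
  expect_equal(r$ps, 0.25)
  expect_equal(r$Ks, 0.30410, tolerance = 1e-5)

  # saturation: every codon differs synonymously -> ps = 1 >= 3/4
  r <- ng86_kaks(list(a = strrep("GGA", 10), b = strrep("GGT", 10)))
  expect_true(r$saturated)
  expect_true(is.na(r$Ks))

  # gap and N codons are excluded pairwise
  r <- ng86_kaks(list(a = "ATG---AAA", b = "ATGAAAAAA"))
  expect_equal(r$n_codons, 2L)
  expect_error(ng86_kaks(list(a = "---", b = "AAA")), "no comparable")
})

test_that("NG86 matches the path-enumeration oracle on codon pairs", {
  sense <- sense_codons()
  set.seed(17)
  # all identical-AA pairs plus a random sweep across the 61x61 space
  pick <- rbind(
    expand.grid(a = sense[1:8], b = sense[1:8],
                stringsAsFactors = FALSE),
    data.frame(a = sample(sense, 400, replace = TRUE),
               b = sample(sense, 400, replace = TRUE)))
  for (i in seq_len(nrow(pick))) {
    ca <- pick$a[i]; cb <- pick$b[i]
    got <- ng86_kaks(list(a = ca, b = cb))
    want <- oracle_ng86(ca, cb)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
  }
})

test_that("NG86 is symmetric in its two sequences", {
  set.seed(18)
  for (i in 1:5) {
    cods1 <- sample(sense_codons(), 30, replace = TRUE)
    cods2 <- sample(sense_codons(), 30, replace = TRUE)
    r1 <- ng86_kaks(list(a = paste(cods1, collapse = ""),
                         b = paste(cods2, collapse = "")))
    r2 <- ng86_kaks(list(a = paste(cods2, collapse = ""),
                         b = paste(cods1, collapse = "")))
    expect_equal(r1$Ks, r2$Ks)
    expect_equal(r1$Ka, r2$Ka)
    expect_equal(r1$S, r2$S)
  }
})

test_that("simulated gametologue Ks is recovered within 15%", {
  cfg <- sim_config(seed = 19, uv_len = 6e5, sdr_start = 1e5,
                    sdr_end = 5e5, n_autosomes = 1L, autosome_len = 1e5,
                    n_gametologues = 4L, target_ks = c(0.2, 0.5, 0.8, 1),
                    cds_len = 30000L, n_sex_specific = 0L)
  sim <- simulate_genome_pair(cfg)
  cm <- extract_cds(sim$male, sim$male_ann)
  cf <- extract_cds(sim$female, sim$female_ann)
  for (i in seq_len(4)) {
    pair <- sim$truth$true_pairs[i, ]
    r <- ng86_kaks(list(a = cm[[pair$male_gene]],
                        b = cf[[pair$female_gene]]))
    expect_equal(r$Ks, pair$target_ks, tolerance = 0.15)
    expect_lt(r$Ka, 0.01)
  }
})

test_that("SDR genes classify as gametologue or sex-specific", {
  pairs <- tibble::tibble(male_gene = c("gm1", "gm2", "gm3"),
                          female_gene = c("gf1", "gf2", "auto_f"))
  res <- classify_sdr_genes(c("gm1", "gm2", "gm3", "gm4"),
                            c("gf1", "gf2", "gf3"), pairs)
  get <- function(g) res$class[res$gene == g]
  expect_equal(get("gm1"), "gametologue")
  expect_equal(get("gm3"), "sex_specific")  # partner outside female SDR
  expect_equal(get("gm4"), "sex_specific")
  expect_equal(get("gf3"), "sex_specific")
  expect_equal(res$partner[res$gene == "gf1"], "gm1")
})

test_that("simulator truth is recovered by RBH classification", {
  sim <- tiny_sim()
  msdr <- sim$male_ann[sim$male_ann$compartment == "SDR" &
                         sim$male_ann$type == "gene", ]
  fsdr <- sim$female_ann[sim$female_ann$compartment == "SDR" &
                           sim$female_ann$type == "gene", ]
  cm <- extract_cds(sim$male, msdr)
  cf <- extract_cds(sim$female, fsdr)
  pm <- vapply(cm, translate_cds, character(1))
  pf <- vapply(cf, translate_cds, character(1))
  pairs <- reciprocal_best_hits(pm, pf, min_score = 100)
  expect_equal(nrow(pairs), nrow(sim$truth$true_pairs))
  expect_equal(sort(pairs$male_gene),
               sort(sim$truth$true_pairs$male_gene))
  cls <- classify_sdr_genes(msdr$feature_id, fsdr$feature_id, pairs)
  truth_class <- ifelse(grepl("^gam", cls$gene), "gametologue",
                        "sex_specific")
  expect_equal(cls$class, truth_class)
})
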