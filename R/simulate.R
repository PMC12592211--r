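# Synthetic-data generators. A male and a female haploid assembly share
# autosomes and pseudoautosomal regions exactly; the V- and U-SDR haplotypes
# are independent random sequences carrying gametologue CDS pairs with
# controlled synonymous divergence and sex-specific genes. Companion
# generators emit sexed read sets, population genotypes with male-excess
# heterozygosity at young sex-linked sites, presence/absence matrices
# evolved under a known gain/loss model, and homology tables with known
# phylostratum labels. Every generator returns ground truth for the
# downstream modules.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' a 10-Mb haploid genome (three 2-Mb autosomes plus a 4-Mb U/V chromosome
#' whose central 500 kb is the non-recombining SDR), 15x error-free 100-bp
#' reads per sex, 20 gametologue pairs, repeat densities elevated in the
#' SDR with diverged copies, a 24-individual population, and a
#' gain/loss/gamma model for SDR gene-content evolution.
#'
#' @param seed Integer seed driving every generator.
#' @param n_autosomes,autosome_len Autosome count and length (bp).
#' @param uv_len U/V chromosome length (bp).
#' @param sdr_start,sdr_end SDR interval on the U/V chromosome (0-based
#'   half-open); the flanks are PARs.
#' @param n_gametologues Number of U/V gametologue CDS pairs.
#' @param target_ks Target synonymous divergence per pair (recycled).
#' @param cds_len CDS length in bp (rounded down to a codon multiple).
#' @param n_sex_specific Sex-specific genes per SDR haplotype.
#' @param te_density Named fractions of compartment length covered by
#'   repeats (`autosome`, `PAR`, `SDR`).
#' @param te_len,n_te_families,te_divergence Repeat copy length, number of
#'   repeat families, and per-base divergence between copies of a family.
#' @param gene_density_per_mb Gene count per Mb on autosomes and PARs.
#' @param read_len,depth,error_rate Read simulator settings (bp, fold
#'   coverage, per-base substitution rate).
#' @param n_individuals Diploid individuals per sex in the population.
#' @param n_snp_sites Autosomal SNP sites in the population table.
#' @param autosomal_het Expected heterozygosity at autosomal sites
#'   (must be < 0.5).
#' @param n_sexlinked_sites Young sex-linked sites (every male het, every
#'   female hom-ref).
#' @param gain_rate,loss_rate,gamma_shape Gain/loss model used to evolve
#'   presence/absence matrices.
#' @param n_families Gene families in the presence/absence matrix.
#' @param n_strata,stratum_proportions Phylostrata count and the gene-age
#'   distribution for the homology table.
#' @return A `uv_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_autosomes = 3L, autosome_len = 2e6, uv_len = 4e6,
                       sdr_start = 1.5e6, sdr_end = 2e6,
                       n_gametologues = 20L, target_ks = 0.5,
                       cds_len = 1500L, n_sex_specific = 10L,
                       te_density = c(autosome = 0.10, PAR = 0.10,
                                      SDR = 0.30),
                       te_len = 500L, n_te_families = 20L,
                       te_divergence = 0.10,
                       gene_density_per_mb = 100,
                       read_len = 100L, depth = 15, error_rate = 0,
                       n_individuals = 12L, n_snp_sites = 2000L,
                       autosomal_het = 0.3, n_sexlinked_sites = 100L,
                       gain_rate = 0.5, loss_rate = 1.0, gamma_shape = 1.0,
                       n_families = 500L,
                       n_strata = 8L, stratum_proportions = NULL) {
  if (sdr_start < 0 || sdr_end > uv_len || sdr_start > sdr_end) {
    abort("sdr interval must lie within the U/V chromosome")
  }
  if (depth < 0) abort("depth must be >= 0")
  if (autosomal_het >= 0.5 || autosomal_het <= 0) {
    abort("autosomal_het must be in (0, 0.5)")
  }
  if (is.null(stratum_proportions)) {
    stratum_proportions <- rep(1 / n_strata, n_strata)
  }
  if (abs(sum(stratum_proportions) - 1) > 1e-8) {
    abort("stratum_proportions must sum to 1")
  }
  cfg <- list(
    seed = as.integer(seed), n_autosomes = as.integer(n_autosomes),
    autosome_len = as.integer(autosome_len), uv_len = as.integer(uv_len),
    sdr_start = as.integer(sdr_start), sdr_end = as.integer(sdr_end),
    n_gametologues = as.integer(n_gametologues),
    target_ks = rep_len(target_ks, n_gametologues),
    cds_len = 3L * (as.integer(cds_len) %/% 3L),
    n_sex_specific = as.integer(n_sex_specific),
    te_density = te_density, te_len = as.integer(te_len),
    n_te_families = as.integer(n_te_families),
    te_divergence = te_divergence,
    gene_density_per_mb = gene_density_per_mb,
    read_len = as.integer(read_len), depth = depth,
    error_rate = error_rate,
    n_individuals = as.integer(n_individuals),
    n_snp_sites = as.integer(n_snp_sites),
    autosomal_het = autosomal_het,
    n_sexlinked_sites = as.integer(n_sexlinked_sites),
    gain_rate = gain_rate, loss_rate = loss_rate,
    gamma_shape = gamma_shape, n_families = as.integer(n_families),
    n_strata = as.integer(n_strata),
    stratum_proportions = stratum_proportions
  )
  structure(cfg, class = "uv_sim_config")
}

# -- sequence helpers (integer utf8 codes for speed) ------------------------

BASE_CODES <- c(65L, 67L, 71L, 84L)  # A C G T

random_dna_codes <- function(n) {
  sample(BASE_CODES, n, replace = TRUE)
}

codes_to_string <- function(codes) intToUtf8(codes)

string_to_codes <- function(s) utf8ToInt(s)

# substitute each position independently with a different base
mutate_codes <- function(codes, rate) {
  hit <- which(runif(length(codes)) < rate)
  if (length(hit)) {
    for (i in hit) {
      codes[i] <- sample(setdiff(BASE_CODES, codes[i]), 1L)
    }
  }
  codes
}

random_cds <- function(len) {
  sense <- setdiff(sense_codons(), c("ATG"))  # keep start codon placement free
  body <- sample(sense, len %/% 3L - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""))
}

# Mutate fourfold-degenerate third positions of `cds` so the expected NG86
# synonymous divergence to the original equals target_ks.
diverge_synonymous <- function(cds, target_ks) {
  if (target_ks <= 0) return(cds)
  cod <- split_codons(cds)
  sites <- get_ng86_sites()
  ff <- get_fourfold()
  s_total <- sum(sites[cod])
  ff_idx <- which(vapply(ff[cod], length, integer(1)) > 0)
  n_ff <- length(ff_idx)
  ps <- 0.75 * (1 - exp(-4 / 3 * target_ks))
  n_mut <- ps * s_total
  if (n_mut > n_ff) {
    warn("target_ks beyond what fourfold sites can encode; clamping")
    n_mut <- n_ff
  }
  q <- n_mut / n_ff
  mutate_i <- ff_idx[runif(n_ff) < q]
  for (i in mutate_i) {
    pos <- ff[[cod[i]]][1]  # fourfold position (third base)
    chars <- strsplit(cod[i], "")[[1]]
    chars[pos] <- sample(setdiff(BASES, chars[pos]), 1L)
    cod[i] <- paste(chars, collapse = "")
  }
  paste(cod, collapse = "")
}

# evenly spaced non-overlapping placements of n features of length len
# within [start, end); returns starts, or fewer if they do not fit
spaced_starts <- function(start, end, n, len) {
  if (n == 0L) return(integer(0))
  slot <- (end - start) %/% n
  if (slot < len) {
    n <- max(0L, (end - start) %/% len)
    if (n == 0L) return(integer(0))
    slot <- (end - start) %/% n
  }
  as.integer(start + (seq_len(n) - 1L) * slot)
}

# -- genome pair ------------------------------------------------------------

#' Simulate a male/female haploid genome pair with ground truth
#'
#' Autosomes and PARs are identical between the sexes; the V-SDR (male) and
#' U-SDR (female) are independent random haplotypes. Gametologue CDS pairs
#' are placed at matched ranks in both SDRs with synonymous sites mutated
#' to the configured target Ks; sex-specific genes occur in one SDR only;
#' repeat copies (diverged from family consensi) are laid down at the
#' configured per-compartment density.
#'
#' @param cfg A [sim_config()].
#' @return List with `male`, `female` ([sequence_set()]s), `male_ann`,
#'   `female_ann` (annotation tibbles), and `truth` (list: `sdr_bed`,
#'   `gene_compartments`, `true_pairs`).
#' @export
simulate_genome_pair <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  sdr_len <- cfg$sdr_end - cfg$sdr_start
  auto_names <- paste0("autosome_", seq_len(cfg$n_autosomes))

  te_fams <- replicate(cfg$n_te_families,
                       random_dna_codes(cfg$te_len), simplify = FALSE)

  ann_rows <- list()
  add_ann <- function(sex, id, chrom, start, end, strand, type, comp) {
    ann_rows[[length(ann_rows) + 1L]] <<- tibble(
      sex = sex, feature_id = id, chrom = chrom,
      start = as.integer(start), end = as.integer(end),
      strand = strand, type = type, compartment = comp)
  }

  # scatter repeats over [start,end) of a chromosome's code vector
  lay_repeats <- function(codes, start, end, density, chrom, comp, sexes,
                          prefix) {
    n_copies <- as.integer(floor(density * (end - start) / cfg$te_len))
    if (n_copies == 0L) return(codes)
    starts <- spaced_starts(start, end, n_copies, cfg$te_len)
    fam <- sample.int(cfg$n_te_families, length(starts), replace = TRUE)
    for (i in seq_along(starts)) {
      copy <- mutate_codes(te_fams[[fam[i]]], cfg$te_divergence)
      codes[(starts[i] + 1L):(starts[i] + cfg$te_len)] <- copy
      for (sx in sexes) {
        add_ann(sx, paste0(prefix, "_", i), chrom, starts[i],
                starts[i] + cfg$te_len, ".", "repeat", comp)
      }
    }
    codes
  }

  lay_genes <- function(codes, start, end, n, chrom, comp, sexes, prefix,
                        cds_list = NULL) {
    if (n == 0L) return(codes)
    starts <- spaced_starts(start, end, n,
                            cfg$cds_len + cfg$te_len)  # keep clear of TEs
    # offset genes into the second half of each slot so repeats (laid first
    # at slot starts) are not overwritten
    starts <- starts + cfg$te_len
    starts <- starts[starts + cfg$cds_len <= end]
    for (i in seq_along(starts)) {
      cds <- if (is.null(cds_list)) random_cds(cfg$cds_len)
             else cds_list[[i]]
      codes[(starts[i] + 1L):(starts[i] + nchar(cds))] <-
        string_to_codes(cds)
      for (sx in sexes) {
        add_ann(sx, paste0(prefix, "_", sprintf("%02d", i)), chrom,
                starts[i], starts[i] + nchar(cds), "+", "gene", comp)
      }
    }
    invisible(codes)
  }

  # shared autosomes
  shared <- list()
  for (i in seq_len(cfg$n_autosomes)) {
    codes <- random_dna_codes(cfg$autosome_len)
    codes <- lay_repeats(codes, 0L, cfg$autosome_len,
                         cfg$te_density[["autosome"]], auto_names[i],
                         "autosome", c("male", "female"),
                         paste0("te_a", i))
    n_genes <- as.integer(round(cfg$gene_density_per_mb *
                                  cfg$autosome_len / 1e6))
    codes <- lay_genes(codes, 0L, cfg$autosome_len, n_genes, auto_names[i],
                       "autosome", c("male", "female"), paste0("gene_a", i))
    shared[[auto_names[i]]] <- codes
  }

  # shared PAR sequence (flanks of the U/V chromosome)
  par1 <- random_dna_codes(cfg$sdr_start)
  par2 <- random_dna_codes(cfg$uv_len - cfg$sdr_end)
  if (cfg$sdr_start > 0) {
    par1 <- lay_repeats(par1, 0L, cfg$sdr_start, cfg$te_density[["PAR"]],
                        "chrUV", "PAR", c("male", "female"), "te_p1")
    n_genes <- as.integer(round(cfg$gene_density_per_mb *
                                  cfg$sdr_start / 1e6))
    par1 <- lay_genes(par1, 0L, cfg$sdr_start, n_genes, "chrUV", "PAR",
                      c("male", "female"), "gene_p1")
  }
  if (length(par2) > 0) {
    # PAR2 coordinates are relative within the vector; annotate with offset
    offset <- cfg$sdr_end
    n_copies <- as.integer(floor(cfg$te_density[["PAR"]] *
                                   length(par2) / cfg$te_len))
    starts <- spaced_starts(0L, length(par2), n_copies, cfg$te_len)
    fam <- if (length(starts)) sample.int(cfg$n_te_families, length(starts),
                                          replace = TRUE) else integer(0)
    for (i in seq_along(starts)) {
      copy <- mutate_codes(te_fams[[fam[i]]], cfg$te_divergence)
      par2[(starts[i] + 1L):(starts[i] + cfg$te_len)] <- copy
      for (sx in c("male", "female")) {
        add_ann(sx, paste0("te_p2_", i), "chrUV", offset + starts[i],
                offset + starts[i] + cfg$te_len, ".", "repeat", "PAR")
      }
    }
    n_genes <- as.integer(round(cfg$gene_density_per_mb *
                                  length(par2) / 1e6))
    gstarts <- spaced_starts(0L, length(par2), n_genes,
                             cfg$cds_len + cfg$te_len) + cfg$te_len
    gstarts <- gstarts[gstarts + cfg$cds_len <= length(par2)]
    for (i in seq_along(gstarts)) {
      cds <- random_cds(cfg$cds_len)
      par2[(gstarts[i] + 1L):(gstarts[i] + nchar(cds))] <-
        string_to_codes(cds)
      for (sx in c("male", "female")) {
        add_ann(sx, paste0("gene_p2_", sprintf("%02d", i)), "chrUV",
                offset + gstarts[i], offset + gstarts[i] + nchar(cds),
                "+", "gene", "PAR")
      }
    }
  }

  # SDR haplotypes: independent random sequence per sex
  build_sdr <- function(sex) {
    codes <- random_dna_codes(sdr_len)
    n_copies <- as.integer(floor(cfg$te_density[["SDR"]] * sdr_len /
                                   cfg$te_len))
    starts <- spaced_starts(0L, sdr_len, n_copies, cfg$te_len)
    fam <- if (length(starts)) sample.int(cfg$n_te_families, length(starts),
                                          replace = TRUE) else integer(0)
    for (i in seq_along(starts)) {
      copy <- mutate_codes(te_fams[[fam[i]]], cfg$te_divergence)
      codes[(starts[i] + 1L):(starts[i] + cfg$te_len)] <- copy
      add_ann(sex, paste0("te_sdr_", substr(sex, 1, 1), i), "chrUV",
              cfg$sdr_start + starts[i],
              cfg$sdr_start + starts[i] + cfg$te_len, ".", "repeat", "SDR")
    }
    codes
  }

  male_sdr <- build_sdr("male")
  female_sdr <- build_sdr("female")

  # gametologue pairs: male CDS random, female CDS = synonymous divergence
  n_slots <- cfg$n_gametologues + cfg$n_sex_specific
  slot_len <- cfg$cds_len + 2L * cfg$te_len
  gstarts <- spaced_starts(0L, sdr_len, n_slots, slot_len) + cfg$te_len
  gstarts <- gstarts[gstarts + cfg$cds_len <= sdr_len]
  if (length(gstarts) < n_slots) {
    abort("SDR too short for the requested gene content")
  }
  true_pairs <- NULL
  gene_comp <- list()
  for (i in seq_len(cfg$n_gametologues)) {
    m_cds <- random_cds(cfg$cds_len)
    f_cds <- diverge_synonymous(m_cds, cfg$target_ks[i])
    st <- gstarts[i]
    male_sdr[(st + 1L):(st + cfg$cds_len)] <- string_to_codes(m_cds)
    female_sdr[(st + 1L):(st + cfg$cds_len)] <- string_to_codes(f_cds)
    mid <- sprintf("gam_m_%02d", i); fid <- sprintf("gam_f_%02d", i)
    add_ann("male", mid, "chrUV", cfg$sdr_start + st,
            cfg$sdr_start + st + cfg$cds_len, "+", "gene", "SDR")
    add_ann("female", fid, "chrUV", cfg$sdr_start + st,
            cfg$sdr_start + st + cfg$cds_len, "+", "gene", "SDR")
    true_pairs <- bind_rows(true_pairs,
                            tibble(male_gene = mid, female_gene = fid,
                                   target_ks = cfg$target_ks[i]))
    gene_comp[[mid]] <- "SDR"; gene_comp[[fid]] <- "SDR"
  }
  for (i in seq_len(cfg$n_sex_specific)) {
    st <- gstarts[cfg$n_gametologues + i]
    m_cds <- random_cds(cfg$cds_len)
    f_cds <- random_cds(cfg$cds_len)
    male_sdr[(st + 1L):(st + cfg$cds_len)] <- string_to_codes(m_cds)
    female_sdr[(st + 1L):(st + cfg$cds_len)] <- string_to_codes(f_cds)
    mid <- sprintf("mspec_%02d", i); fid <- sprintf("fspec_%02d", i)
    add_ann("male", mid, "chrUV", cfg$sdr_start + st,
            cfg$sdr_start + st + cfg$cds_len, "+", "gene", "SDR")
    add_ann("female", fid, "chrUV", cfg$sdr_start + st,
            cfg$sdr_start + st + cfg$cds_len, "+", "gene", "SDR")
    gene_comp[[mid]] <- "SDR"; gene_comp[[fid]] <- "SDR"
  }

  male_uv <- codes_to_string(c(par1, male_sdr, par2))
  female_uv <- codes_to_string(c(par1, female_sdr, par2))
  shared_str <- vapply(shared, codes_to_string, character(1))

  male <- sequence_set(c(shared_str, chrUV = male_uv), sex = "male")
  female <- sequence_set(c(shared_str, chrUV = female_uv), sex = "female")

  ann <- bind_rows(ann_rows)
  male_ann <- ann |> filter(.data$sex == "male") |> select(-"sex")
  female_ann <- ann |> filter(.data$sex == "female") |> select(-"sex")

  sdr_bed <- tibble(
    sex = c("male", "female"), chrom = "chrUV",
    start = cfg$sdr_start, end = cfg$sdr_end
  )
  list(male = male, female = female,
       male_ann = male_ann, female_ann = female_ann,
       truth = list(sdr_bed = sdr_bed,
                    gene_compartments = unlist(gene_comp),
                    true_pairs = true_pairs),
       cfg = cfg)
}

# -- reads ------------------------------------------------------------------

#' Simulate uniform short reads from a haploid genome
#'
#' Reads are drawn uniformly along each chromosome (strand chosen at
#' random), with independent per-base substitution errors. Total read bases
#' approximate `depth` times the genome length.
#'
#' @param genome A [sequence_set()].
#' @param depth Fold coverage.
#' @param read_len Read length (bp); must not exceed the shortest sequence.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return List with `reads` (tibble `id`, `seq`, `qual`) and `depth`
#'   (named list of per-base integer coverage vectors, the truth track).
#' @export
simulate_reads <- function(genome, depth, read_len, error_rate = 0,
                           seed = 1L) {
  if (length(genome) == 0L) abort("empty genome")
  lens <- seq_lengths(genome)
  if (read_len > min(lens)) {
    abort("read_len exceeds the shortest sequence")
  }
  set.seed(seed)
  total <- sum(lens)
  n_reads <- as.integer(round(depth * total / read_len))
  depth_truth <- lapply(lens, function(L) integer(L))
  if (n_reads == 0L) {
    return(list(reads = tibble(id = character(), seq = character(),
                               qual = character()),
                depth = depth_truth))
  }
  chrom <- sample(names(lens), n_reads, replace = TRUE,
                  prob = lens / total)
  out_seq <- character(n_reads)
  qual <- strrep("I", read_len)
  for (ch in names(lens)) {
    idx <- which(chrom == ch)
    if (!length(idx)) next
    pos <- sample.int(lens[[ch]] - read_len + 1L, length(idx),
                      replace = TRUE)  # 1-based start
    out_seq[idx] <- substring(genome[[ch]], pos, pos + read_len - 1L)
    tab_s <- tabulate(pos, nbins = lens[[ch]] + 1L)
    tab_e <- tabulate(pos + read_len, nbins = lens[[ch]] + 1L)
    depth_truth[[ch]] <- cumsum(tab_s - tab_e)[seq_len(lens[[ch]])]
  }
  # random strand
  flip <- runif(n_reads) < 0.5
  if (any(flip)) {
    out_seq[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out_seq[flip])))
  }
  if (error_rate > 0) {
    n_err <- rbinom(n_reads, read_len, error_rate)
    for (i in which(n_err > 0)) {
      codes <- string_to_codes(out_seq[i])
      p <- sample.int(read_len, n_err[i])
      for (j in p) codes[j] <- sample(setdiff(BASE_CODES, codes[j]), 1L)
      out_seq[i] <- codes_to_string(codes)
    }
  }
  list(reads = tibble(id = paste0("read_", seq_len(n_reads)),
                      seq = out_seq, qual = qual),
       depth = depth_truth)
}

# -- population genotypes ---------------------------------------------------

#' Simulate a sexed population genotype table
#'
#' Autosomal sites follow Hardy-Weinberg at allele frequencies sampled so
#' the expected heterozygosity matches `autosomal_het`, identically for
#' both sexes. At the young sex-linked sites (on a dedicated
#' `scaffold_sex`), every male is heterozygous and every female
#' homozygous-reference, the signature of a recently sex-linked region.
#'
#' @param cfg A [sim_config()].
#' @return A `uv_genotypes` object (see [genotype_table()]).
#' @export
simulate_population_genotypes <- function(cfg = sim_config()) {
  if (cfg$n_individuals < 2L) abort("need >= 2 individuals per sex")
  set.seed(cfg$seed + 1L)
  inds <- c(paste0("m", sprintf("%02d", seq_len(cfg$n_individuals))),
            paste0("f", sprintf("%02d", seq_len(cfg$n_individuals))))
  sexes <- rep(c("male", "female"), each = cfg$n_individuals)
  n_ind <- length(inds)

  h <- cfg$autosomal_het
  a <- h / (1 - 2 * h)  # Beta(a, a) allele frequencies give E[2p(1-p)] = h
  auto_names <- paste0("autosome_", seq_len(cfg$n_autosomes))

  n_a <- cfg$n_snp_sites
  p <- stats::rbeta(n_a, a, a)
  dosage <- matrix(rbinom(n_a * n_ind, 2L, rep(p, n_ind)),
                   nrow = n_a, ncol = n_ind)
  codes <- matrix(c("hom_ref", "het", "hom_alt")[dosage + 1L],
                  nrow = n_a, dimnames = list(NULL, inds))
  # background variation also falls on the young sex scaffold, so its
  # heterozygosity ratio stays finite
  scaffolds <- c(auto_names,
                 if (cfg$n_sexlinked_sites > 0) "scaffold_sex")
  chrom_a <- sample(scaffolds, n_a, replace = TRUE)
  pos_a <- sample.int(cfg$autosome_len, n_a, replace = TRUE) - 1L

  n_x <- cfg$n_sexlinked_sites
  if (n_x > 0) {
    sex_codes <- matrix(rep(ifelse(sexes == "male", "het", "hom_ref"),
                            each = n_x),
                        nrow = n_x, dimnames = list(NULL, inds))
    codes <- rbind(codes, sex_codes)
    chrom_x <- rep("scaffold_sex", n_x)
    pos_x <- sort(sample.int(cfg$autosome_len, n_x)) - 1L
  } else {
    chrom_x <- character(0); pos_x <- integer(0)
  }

  n_sites <- n_a + n_x
  ra <- t(replicate(n_sites, sample(BASES, 2L)))
  sites <- tibble(chrom = c(chrom_a, chrom_x), pos = c(pos_a, pos_x),
                  ref = ra[, 1], alt = ra[, 2],
                  sexlinked = rep(c(FALSE, TRUE), c(n_a, n_x)))
  ord <- order(sites$chrom, sites$pos)
  gt <- genotype_table(sites[ord, c("chrom", "pos", "ref", "alt")],
                       codes[ord, , drop = FALSE],
                       tibble(individual = inds, sex = sexes))
  attr(gt, "sexlinked") <- sites$sexlinked[ord]
  gt
}

# -- gene-family evolution --------------------------------------------------

#' Evolve a presence/absence matrix on a species tree
#'
#' A two-state gain/loss chain runs down each branch; the root state is
#' drawn from the stationary distribution. Each family carries a rate
#' multiplier drawn from a mean-1 discretized gamma (shape `alpha`,
#' `n_categories` classes), applied jointly to gain and loss by default or
#' independently per rate.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param g,l Gain and loss rates per unit branch length.
#' @param alpha Gamma shape for among-family rate variation (`Inf` for
#'   homogeneous rates).
#' @param n_families Number of families to evolve.
#' @param seed Integer seed.
#' @param n_categories Discrete gamma classes.
#' @param gamma_mode `"joint"` (one multiplier for both rates) or
#'   `"independent"` (separate multipliers for gain and loss).
#' @return List with `matrix` (families x tips 0/1, dimnames set) and
#'   `node_states` (tibble `family`, `node`, `state`; tips and internal
#'   nodes, internal nodes labelled `node_<number>`).
#' @export
simulate_family_evolution <- function(tree, g, l, alpha = 1,
                                      n_families = 500L, seed = 1L,
                                      n_categories = 10L,
                                      gamma_mode = c("joint",
                                                     "independent")) {
  gamma_mode <- match.arg(gamma_mode)
  validate_tree(tree)
  if (g < 0 || l < 0) abort("rates must be >= 0")
  if (g == 0 && l == 0) {
    abort("g = l = 0 leaves the stationary root state undefined")
  }
  set.seed(seed)
  rates <- if (is.finite(alpha)) {
    phangorn::discrete.gamma(alpha, n_categories)
  } else rep(1, n_categories)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  node_lab <- c(tree$tip.label,
                paste0("node_", (n_tip + 1L):n_node))
  root <- n_tip + 1L
  # preorder traversal
  eo <- ape::reorder.phylo(tree, "cladewise")

  states <- matrix(0L, nrow = n_families, ncol = n_node)
  pi1 <- g / (g + l)
  cat_idx <- sample.int(n_categories, n_families, replace = TRUE)
  rg <- rates[cat_idx]
  rl <- if (gamma_mode == "joint") rg
        else rates[sample.int(n_categories, n_families, replace = TRUE)]
  states[, root] <- rbinom(n_families, 1L, pi1)
  for (e in seq_len(nrow(eo$edge))) {
    par <- eo$edge[e, 1]; child <- eo$edge[e, 2]; t <- eo$edge.length[e]
    gv <- g * rg; lv <- l * rl
    tot <- gv + lv
    decay <- exp(-tot * t)
    p1 <- gv / tot  # stationary presence prob per family
    # P(child = 1 | parent)
    prob <- ifelse(states[, par] == 1L,
                   p1 + (1 - p1) * decay,
                   p1 * (1 - decay))
    states[, child] <- rbinom(n_families, 1L, prob)
  }
  fam <- paste0("fam_", sprintf("%04d", seq_len(n_families)))
  mat <- states[, seq_len(n_tip), drop = FALSE]
  dimnames(mat) <- list(fam, tree$tip.label)
  node_states <- tibble(
    family = rep(fam, n_node),
    node = rep(node_lab, each = n_families),
    state = as.integer(states)
  )
  list(matrix = mat, node_states = node_states,
       rate_multiplier = tibble(family = fam, gain_mult = rg,
                                loss_mult = rl))
}

# -- homology table ---------------------------------------------------------

#' Simulate a homology hit table with known phylostratum ages
#'
#' Each gene draws a true age rank (1 = oldest stratum, R = the focal
#' species) and receives qualifying hits (e-value below the threshold) only
#' in strata at or younger than that age, with its oldest qualifying hit in
#' exactly the true stratum. Non-qualifying hits above the threshold are
#' sprinkled into older strata to exercise e-value filtering.
#'
#' @param n_genes Number of genes.
#' @param n_strata Number of phylostrata (rank `n_strata` = focal species).
#' @param stratum_proportions Probability of each true age rank.
#' @param seed Integer seed.
#' @param evalue_threshold The filtering threshold exercised by the table.
#' @return List with `hits` (tibble `gene`, `taxon`, `evalue`), `ladder`
#'   (tibble `rank`, `taxon`), `true_ages` (tibble `gene`, `rank`) and
#'   `focal_taxon`.
#' @export
simulate_homology_table <- function(n_genes, n_strata = 8L,
                                    stratum_proportions =
                                      rep(1 / n_strata, n_strata),
                                    seed = 1L,
                                    evalue_threshold = 1e-5) {
  if (abs(sum(stratum_proportions) - 1) > 1e-8) {
    abort("stratum_proportions must sum to 1")
  }
  set.seed(seed)
  focal <- "focal_sp"
  ladder <- bind_rows(
    purrr::map_dfr(seq_len(n_strata - 1L), function(r) {
      tibble(rank = r, taxon = paste0("taxon_r", r, "_", 1:2))
    }),
    tibble(rank = n_strata, taxon = focal)
  )
  genes <- paste0("g", sprintf("%04d", seq_len(n_genes)))
  true_rank <- sample.int(n_strata, n_genes, replace = TRUE,
                          prob = stratum_proportions)
  rows <- purrr::map_dfr(seq_len(n_genes), function(i) {
    r <- true_rank[i]
    out <- tibble(gene = character(), taxon = character(),
                  evalue = numeric())
    if (r < n_strata) {
      # anchoring qualifying hit in the true (oldest) stratum
      anchor <- ladder$taxon[ladder$rank == r][1]
      out <- bind_rows(out, tibble(gene = genes[i], taxon = anchor,
                                   evalue = evalue_threshold *
                                     10^(-runif(1, 1, 10))))
      # optional qualifying hits in younger (non-focal) strata
      younger <- ladder$taxon[ladder$rank > r & ladder$taxon != focal]
      if (length(younger)) {
        extra <- younger[runif(length(younger)) < 0.5]
        if (length(extra)) {
          out <- bind_rows(out, tibble(
            gene = genes[i], taxon = extra,
            evalue = evalue_threshold * 10^(-runif(length(extra), 1, 10))))
        }
      }
    }
    # decoy hits in older strata, above the threshold (must be ignored)
    older <- ladder$taxon[ladder$rank < r]
    if (length(older) && runif(1) < 0.5) {
      decoy <- sample(older, 1L)
      out <- bind_rows(out, tibble(
        gene = genes[i], taxon = decoy,
        evalue = evalue_threshold * 10^(runif(1, 0.5, 4))))
    }
    # every gene matches itself in the focal species
    bind_rows(out, tibble(gene = genes[i], taxon = focal,
                          evalue = 1e-180))
  })
  list(hits = rows, ladder = ladder,
       true_ages = tibble(gene = genes, rank = true_rank),
       focal_taxon = focal)
}
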