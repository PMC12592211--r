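# Shared builders for small fixtures, all generated in code.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# genotype table from a compact character matrix spec
toy_genotypes <- function(geno, chrom = NULL, sex = NULL) {
  n_site <- nrow(geno)
  n_ind <- ncol(geno)
  if (is.null(colnames(geno))) {
    colnames(geno) <- paste0("ind", seq_len(n_ind))
  }
  if (is.null(chrom)) chrom <- rep("sc1", n_site)
  if (is.null(sex)) {
    sex <- rep(c("male", "female"), length.out = n_ind)
  }
  genotype_table(
    sites = tibble::tibble(chrom = chrom, pos = seq_len(n_site) * 10L,
                           ref = "A", alt = "T"),
    geno = geno,
    sex_map = tibble::tibble(individual = colnames(geno), sex = sex)
  )
}

# tiny simulated genome shared by several test files (computed lazily once)
.tiny_env <- new.env(parent = emptyenv())

tiny_sim_config <- function(seed = 11L) {
  sim_config(seed = seed, n_autosomes = 1L, autosome_len = 3e5,
             uv_len = 4e5, sdr_start = 1.5e5, sdr_end = 2e5,
             n_gametologues = 5L, n_sex_specific = 3L,
             n_snp_sites = 600L, n_sexlinked_sites = 20L,
             n_families = 200L)
}

tiny_sim <- function() {
  if (is.null(.tiny_env$sim)) {
    .tiny_env$sim <- simulate_genome_pair(tiny_sim_config())
  }
  .tiny_env$sim
}

# brute-force canonical k-mer counting by direct substring enumeration
oracle_kmer_counts <- function(seqs, k, canonical = TRUE) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  all_kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, 1:(n - k + 1), k:n)
    km[!grepl("[^ACGT]", km)]
  }))
  if (canonical && length(all_kmers)) {
    rc <- vapply(all_kmers, revcomp, character(1))
    all_kmers <- pmin(all_kmers, rc)
  }
  table(all_kmers)
}
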