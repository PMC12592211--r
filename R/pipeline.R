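# End-to-end orchestration: a one-command synthetic demonstration running
# simulate -> k-mer scan -> coverage scan -> population statistics ->
# gametologues -> ancestral reconstruction -> phylostratigraphy ->
# compartment statistics, plus a thin command-line dispatcher.

#' Extract CDS sequences for annotated genes
#'
#' @param seqs A [sequence_set()].
#' @param ann Annotation tibble; rows with `type == "gene"` are used.
#' @param ids Optional subset of feature ids.
#' @return Named character vector of CDS strings (plus-strand features are
#'   taken verbatim; minus-strand features are reverse-complemented).
#' @export
extract_cds <- function(seqs, ann, ids = NULL) {
  genes <- ann |> filter(.data$type == "gene")
  if (!is.null(ids)) genes <- genes |> filter(.data$feature_id %in% ids)
  out <- vapply(seq_len(nrow(genes)), function(i) {
    s <- substring(seqs[[genes$chrom[i]]], genes$start[i] + 1L,
                   genes$end[i])
    if (genes$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  setNames(out, genes$feature_id)
}

#' Default species tree used by the demonstration pipeline
#'
#' A fixed, rooted 6-tip tree with branch lengths on the order of one
#' expected event per unit rate, standing in for a small clade of sampled
#' species.
#'
#' @return A `phylo` object.
#' @export
demo_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((sp1:0.4,sp2:0.4):0.6,(sp3:0.7,sp4:0.7):0.3):0.5,",
    "(sp5:0.9,sp6:0.9):0.6);"))
}

#' Run the full synthetic demonstration pipeline
#'
#' Simulates a male/female genome pair plus all companion datasets, runs
#' every analysis stage, and reports the calls side by side with the
#' simulation truth: SDR recovery F1 at window resolution, agreement
#' between the k-mer and coverage candidate intervals, gametologue Ks
#' recovery, gain/loss parameter recovery and phylostratum age recovery.
#'
#' @param cfg A [sim_config()].
#' @param kmer_window k-mer scan window width (bp).
#' @param cov_window Coverage window width (bp).
#' @param output_dir Optional directory to write BED/TSV outputs into.
#' @param quiet Suppress progress messages.
#' @return A `uv_demo_report` list; see the elements `summary`,
#'   `ygs_scores`, `coverage`, `popgen`, `gametologs`, `ancestral`,
#'   `phylostrat`.
#' @export
run_demo <- function(cfg = sim_config(), kmer_window = 5e5,
                     cov_window = 1e4, output_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) inform(paste0(...))

  say("simulating genome pair (seed ", cfg$seed, ")")
  sim <- simulate_genome_pair(cfg)
  lens <- seq_lengths(sim$male)

  say("simulating sexed read sets at ", cfg$depth, "x")
  reads_m <- simulate_reads(sim$male, cfg$depth, cfg$read_len,
                            cfg$error_rate, seed = cfg$seed + 10L)
  reads_f <- simulate_reads(sim$female, cfg$depth, cfg$read_len,
                            cfg$error_rate, seed = cfg$seed + 11L)

  say("k-mer subtraction scan of the male assembly")
  kcfg <- kmer_config()
  opp <- count_read_kmers(reads_f$reads, kcfg)
  kwin <- make_windows(lens, kmer_window)
  scores <- ygs_score_windows(sim$male, kwin, opp, kcfg)
  kmer_calls <- call_candidate_windows(scores)

  say("coverage classification")
  cwin <- make_windows(lens, cov_window)
  dep_m <- window_depth_from_reads(sim$male, reads_m$reads, cwin,
                                   "male_reads", "male")
  dep_f <- window_depth_from_reads(sim$male, reads_f$reads, cwin,
                                   "female_reads", "female")
  norm_m <- normalize_by_genome_mean(dep_m)
  norm_f <- normalize_by_genome_mean(dep_f)
  classes <- classify_windows(norm_m, norm_f)
  cov_calls <- classes |>
    filter(.data$label == "V_candidate") |>
    select("chrom", "start", "end") |>
    merge_intervals()

  say("population statistics")
  gt <- simulate_population_genotypes(cfg)
  sbh <- sex_biased_heterozygosity(gt)
  fst <- weir_cockerham_fst(gt, by = "scaffold")

  say("gametologue Ks")
  male_sdr_genes <- sim$male_ann |>
    filter(.data$compartment == "SDR", .data$type == "gene")
  female_sdr_genes <- sim$female_ann |>
    filter(.data$compartment == "SDR", .data$type == "gene")
  cds_m <- extract_cds(sim$male, male_sdr_genes)
  cds_f <- extract_cds(sim$female, female_sdr_genes)
  prot_m <- vapply(cds_m, translate_cds, character(1))
  prot_f <- vapply(cds_f, translate_cds, character(1))
  pairs <- reciprocal_best_hits(prot_m, prot_f, min_score = 100)
  kaks <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    m <- pairs$male_gene[i]; f <- pairs$female_gene[i]
    aln <- Biostrings::pairwiseAlignment(prot_m[[m]], prot_f[[f]],
                                         substitutionMatrix = "BLOSUM62",
                                         gapOpening = 10,
                                         gapExtension = 0.5,
                                         type = "global")
    ca <- codon_backalign(as.character(Biostrings::alignedPattern(aln)),
                          as.character(Biostrings::alignedSubject(aln)),
                          cds_m[[m]], cds_f[[f]])
    ng86_kaks(ca) |>
      mutate(male_gene = m, female_gene = f, .before = 1)
  })
  sdr_classes <- classify_sdr_genes(male_sdr_genes$feature_id,
                                    female_sdr_genes$feature_id, pairs)

  say("ancestral SDR gene content")
  tree <- demo_species_tree()
  fam <- simulate_family_evolution(tree, cfg$gain_rate, cfg$loss_rate,
                                   cfg$gamma_shape, cfg$n_families,
                                   seed = cfg$seed + 20L)
  fitted <- fit_gain_loss(tree, fam$matrix, seed = cfg$seed + 21L)
  post <- ancestral_posteriors(tree, fam$matrix, fitted)
  events <- call_events(post, tree)

  say("phylostratigraphy and compartment statistics")
  hom <- simulate_homology_table(
    n_genes = 400L, n_strata = cfg$n_strata,
    stratum_proportions = cfg$stratum_proportions,
    seed = cfg$seed + 30L)
  ages <- assign_gene_ages(hom$hits, hom$ladder,
                           focal_taxon = hom$focal_taxon)
  dwin <- make_windows(lens, 1e5)
  wft <- sim$male_ann |>
    window_feature_density(dwin, "gene", col = "cds_fraction")
  wft <- window_feature_density(sim$male_ann, wft, "repeat",
                                col = "repeat_fraction")
  rep_tests <- autosome_vs_sex_tests(wft, "repeat_fraction")

  # truth comparison ---------------------------------------------------
  truth_sdr <- sim$truth$sdr_bed |>
    filter(.data$sex == "male") |>
    select("chrom", "start", "end")
  f1 <- window_recovery_f1(scores, truth_sdr)
  agree <- interval_jaccard(kmer_calls, cov_calls)
  ks_rec <- kaks |>
    dplyr::inner_join(sim$truth$true_pairs,
                      by = c("male_gene", "female_gene"))
  summary <- tibble(
    sdr_f1 = f1,
    kmer_cov_jaccard = agree$jaccard,
    n_kmer_windows_called = sum(scores$pct_unmatched >= 50,
                                na.rm = TRUE),
    n_cov_v_windows = sum(classes$label == "V_candidate"),
    mean_abs_ks_error = mean(abs(ks_rec$Ks - ks_rec$target_ks)),
    gain_rate_est = fitted$g, loss_rate_est = fitted$l,
    age_recovery = mean(
      left_join(hom$true_ages, ages, by = "gene",
                suffix = c("_true", "_est"))$rank_true ==
        left_join(hom$true_ages, ages, by = "gene",
                  suffix = c("_true", "_est"))$rank_est)
  )

  report <- structure(list(
    summary = summary, cfg = cfg,
    ygs_scores = scores, kmer_calls = kmer_calls,
    coverage = classes, cov_calls = cov_calls,
    popgen = list(sex_biased_het = sbh, fst = fst),
    gametologs = list(pairs = pairs, kaks = kaks,
                      classes = sdr_classes),
    ancestral = list(fit = fitted, posteriors = post, events = events,
                     truth = fam$node_states),
    phylostrat = list(ages = ages, truth = hom$true_ages),
    compartment = list(features = wft, repeat_tests = rep_tests),
    truth = sim$truth
  ), class = "uv_demo_report")

  if (!is.null(output_dir)) write_demo_outputs(report, output_dir)
  report
}

# F1 of candidate windows against a truth interval, at window resolution:
# a window is truly SDR when at least half of it overlaps the truth BED.
window_recovery_f1 <- function(scores, truth) {
  called <- !is.na(scores$pct_unmatched) & scores$pct_unmatched >= 50
  istrue <- vapply(seq_len(nrow(scores)), function(i) {
    tr <- truth[truth$chrom == scores$chrom[i], ]
    if (nrow(tr) == 0L) return(FALSE)
    ov <- sum(pmax(pmin(tr$end, scores$end[i]) -
                     pmax(tr$start, scores$start[i]), 0))
    ov >= (scores$end[i] - scores$start[i]) / 2
  }, logical(1))
  tp <- sum(called & istrue); fp <- sum(called & !istrue)
  fn <- sum(!called & istrue)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

write_demo_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed(report$kmer_calls, file.path(dir, "kmer_candidates.bed"))
  write_bed(report$cov_calls, file.path(dir, "coverage_candidates.bed"))
  utils::write.table(report$ygs_scores, file.path(dir, "ygs_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$gametologs$kaks,
                     file.path(dir, "gametolog_kaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$popgen$sex_biased_het,
                     file.path(dir, "sex_biased_het.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(summary = as.list(report$summary),
         gain_loss = list(g = report$ancestral$fit$g,
                          l = report$ancestral$fit$l,
                          alpha = report$ancestral$fit$alpha,
                          logLik = report$ancestral$fit$logLik)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.uv_demo_report <- function(x, ...) {
  cat("<uv_demo_report>\n")
  cat("  SDR recovery F1 (window resolution): ",
      round(x$summary$sdr_f1, 3), "\n", sep = "")
  cat("  k-mer vs coverage Jaccard: ",
      round(x$summary$kmer_cov_jaccard, 3), "\n", sep = "")
  cat("  mean |Ks - target|: ",
      signif(x$summary$mean_abs_ks_error, 3), "\n", sep = "")
  cat("  fitted gain/loss: ", signif(x$summary$gain_rate_est, 3), " / ",
      signif(x$summary$loss_rate_est, 3), "\n", sep = "")
  cat("  phylostratum age recovery: ",
      round(x$summary$age_recovery, 3), "\n", sep = "")
  invisible(x)
}

#' Command-line dispatcher
#'
#' A thin shell over the package functions; see the `uvsdr` script in
#' `inst/cli/`. Supported subcommands: `demo`, `simulate`, `kmer-scan`,
#' `cov-scan`, `popgen`, `phylostrat`.
#'
#' @param args Character vector, e.g. `c("demo", "--seed", "1")`.
#' @return Integer exit status (0 on success), invisibly.
#' @export
dispatch <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: uvsdr <subcommand> [options]",
    "  demo       --seed <i> [--out <dir>]",
    "  simulate   --seed <i> --out <dir>",
    "  kmer-scan  --assembly <fasta> --reads <fastq> --out <prefix>",
    "             [--k 15] [--min-count 5] [--window 500000]",
    "             [--threshold 50]",
    "  cov-scan   --assembly <fasta> --male <fastq> --female <fastq>",
    "             --out <prefix> [--window 10000]",
    "  popgen     --vcf <vcf> --sex-map <tsv> --out <prefix>",
    "  phylostrat --hits <tsv> --ladder <tsv> --out <tsv>",
    sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0L) return(default)
    args[i[1] + 1L]
  }
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  sub <- args[1]
  status <- tryCatch({
    switch(sub,
      demo = {
        seed <- as.integer(opt("--seed", "1"))
        out <- opt("--out")
        rep <- run_demo(sim_config(seed = seed), output_dir = out)
        print(rep)
        0L
      },
      simulate = {
        seed <- as.integer(opt("--seed", "1"))
        out <- opt("--out")
        if (is.null(out)) stop("simulate requires --out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        sim <- simulate_genome_pair(sim_config(seed = seed))
        write_sequences(sim$male, file.path(out, "male.fasta"))
        write_sequences(sim$female, file.path(out, "female.fasta"))
        write_annotations(sim$male_ann, file.path(out, "male.gff3"))
        write_annotations(sim$female_ann, file.path(out, "female.gff3"))
        write_bed(sim$truth$sdr_bed |> select("chrom", "start", "end"),
                  file.path(out, "sdr_truth.bed"))
        0L
      },
      `kmer-scan` = {
        assembly <- read_sequences(opt("--assembly"))
        kcfg <- kmer_config(k = as.integer(opt("--k", "15")),
                            min_count = as.integer(opt("--min-count",
                                                       "5")))
        opp <- count_read_kmers(opt("--reads"), kcfg)
        win <- make_windows(seq_lengths(assembly),
                            as.integer(opt("--window", "500000")))
        sc <- ygs_score_windows(assembly, win, opp, kcfg)
        calls <- call_candidate_windows(
          sc, as.numeric(opt("--threshold", "50")))
        prefix <- opt("--out", "ygs")
        utils::write.table(sc, paste0(prefix, "_scores.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        write_bed(calls, paste0(prefix, "_candidates.bed"))
        0L
      },
      `cov-scan` = {
        assembly <- read_sequences(opt("--assembly"))
        win <- make_windows(seq_lengths(assembly),
                            as.integer(opt("--window", "10000")))
        dm <- window_depth_from_reads(assembly, opt("--male"), win,
                                      "male", "male")
        df <- window_depth_from_reads(assembly, opt("--female"), win,
                                      "female", "female")
        cl <- classify_windows(normalize_by_genome_mean(dm),
                               normalize_by_genome_mean(df))
        prefix <- opt("--out", "cov")
        utils::write.table(cl, paste0(prefix, "_classes.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        0L
      },
      popgen = {
        sm <- utils::read.table(opt("--sex-map"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
        gt <- read_genotypes(opt("--vcf"), sm)
        prefix <- opt("--out", "popgen")
        utils::write.table(sex_biased_heterozygosity(gt),
                           paste0(prefix, "_sex_biased_het.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(weir_cockerham_fst(gt, by = "scaffold"),
                           paste0(prefix, "_fst.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      phylostrat = {
        hits <- as_tibble(utils::read.table(opt("--hits"), header = TRUE,
                                            sep = "\t"))
        ladder <- as_tibble(utils::read.table(opt("--ladder"),
                                              header = TRUE, sep = "\t"))
        ages <- assign_gene_ages(hits, ladder)
        utils::write.table(ages, opt("--out", "ages.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        0L
      },
      {
        message("unknown subcommand: ", sub, "\n", usage)
        1L
      })
  }, error = function(e) {
    message("error in '", sub, "': ", conditionMessage(e))
    1L
  })
  invisible(status)
}
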