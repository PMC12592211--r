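# Gain/loss model: transition probabilities, pruning likelihood,
# rate fitting, ancestral posteriors, event calling and mechanisms.

test_that("location codes collapse to SDR presence", {
  loc <- tibble::tibble(
    family = rep(c("f1", "f2", "f3"), each = 3),
    species = rep(c("s1", "s2", "s3"), 3),
    location = c("SDR", "PAR", "AUTOSOME",
                 "SDR", "SDR", "ABSENT",
                 "UNPLACED", "UNPLACED", "UNPLACED"))
  expect_warning(mat <- encode_presence(loc), "unplaced")
  expect_equal(mat["f1", ], c(s1 = 1L, s2 = 0L, s3 = 0L))
  expect_equal(mat["f2", ], c(s1 = 1L, s2 = 1L, s3 = 0L))
  expect_equal(unname(mat["f3", ]), c(0L, 0L, 0L))
  expect_error(encode_presence(dplyr::mutate(loc, location = "XXX")),
               "unknown location")
})

test_that("transition probabilities follow the closed form", {
  expect_equal(transition_matrix(1, 2, 0),
               matrix(c(1, 0, 0, 1), 2), ignore_attr = TRUE)
  P <- transition_matrix(1, 1, 1)
  expect_equal(P["0", "1"], 0.5 * (1 - exp(-2)), tolerance = 1e-12)
  expect_equal(P["0", "1"], 0.43233, tolerance = 1e-5)
  Pinf <- transition_matrix(0.3, 0.7, 1e6)
  expect_equal(Pinf["0", "1"], 0.3, tolerance = 1e-9)
  expect_equal(Pinf["1", "1"], 0.3, tolerance = 1e-9)
  set.seed(20)
  for (i in 1:10) {
    P <- transition_matrix(runif(1, 0, 3), runif(1, 0, 3), runif(1, 0, 5))
    expect_equal(rowSums(P), c(`0` = 1, `1` = 1))
    expect_true(all(P >= 0 & P <= 1))
  }
  expect_warning(Pid <- transition_matrix(0, 0, 1), "identity")
  expect_equal(Pid, diag(2), ignore_attr = TRUE)
})

test_that("pruning equals brute-force enumeration on small trees", {
  trees <- list(
    ape::read.tree(text = "(A:0.5,B:1.2);"),
    ape::read.tree(text = "((A:0.3,B:0.9):0.4,C:1.1);"),
    ape::read.tree(text = "(((A:0.2,B:0.5):0.3,C:0.8):0.2,D:1.0);"))
  models <- list(gain_loss_model(0.7, 1.3, Inf, 1),
                 gain_loss_model(0.4, 0.9, 0.8, 4))
  set.seed(21)
  for (tr in trees) {
    for (m in models) {
      for (i in 1:4) {
        pat <- setNames(sample(0:1, length(tr$tip.label),
                               replace = TRUE), tr$tip.label)
        expect_equal(pattern_likelihood(tr, pat, m),
                     oracle_likelihood(tr, pat, m), tolerance = 1e-10)
      }
    }
  }
})

test_that("pattern likelihoods sum to one over all tip patterns", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.9):0.4,C:1.1);")
  m <- gain_loss_model(0.6, 1.1, 1.2, 5)
  pats <- expand.grid(A = 0:1, B = 0:1, C = 0:1)
  tot <- sum(vapply(seq_len(nrow(pats)), function(i) {
    pattern_likelihood(tr, unlist(pats[i, ]), m)
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("rate fitting recovers simulation truth and handles boundaries", {
  tr <- demo_species_tree()
  fam <- simulate_family_evolution(tr, 0.5, 1.0, 1.0, 500, seed = 1)
  fit <- fit_gain_loss(tr, fam$matrix, seed = 1)
  expect_equal(fit$g, 0.5, tolerance = 0.25)
  expect_equal(fit$l, 1.0, tolerance = 0.25)
  expect_equal(fit$alpha, 1.0, tolerance = 0.5)

  fit2 <- fit_gain_loss(tr, fam$matrix, seed = 1)
  expect_identical(fit[c("g", "l", "alpha", "logLik")],
                   fit2[c("g", "l", "alpha", "logLik")])

  all_present <- matrix(1L, 50, 6,
                        dimnames = list(paste0("f", 1:50), tr$tip.label))
  expect_warning(fitb <- fit_gain_loss(tr, all_present, n_restarts = 3,
                                       fit_alpha = FALSE, seed = 2),
                 "boundary")
  expect_true(fitb$boundary)
  expect_lt(fitb$l / fitb$g, 0.01)
})

test_that("posteriors match observation at tips and enumeration inside", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.9):0.4,C:1.1);")
  m <- gain_loss_model(0.6, 1.1, 1.2, 4)
  mat <- matrix(c(1L, 0L, 1L,
                  0L, 0L, 1L,
                  1L, 1L, 1L), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("f", 1:3), c("A", "B", "C")))
  post <- ancestral_posteriors(tr, mat, m)
  # tips reproduce observations
  for (f in rownames(mat)) {
    for (tip in colnames(mat)) {
      expect_equal(post$posterior[post$family == f & post$node == tip],
                   as.numeric(mat[f, tip]))
    }
  }
  # internal nodes match brute-force Bayes
  for (f in rownames(mat)) {
    pat <- mat[f, ]
    for (nd in c(4L, 5L)) {
      expect_equal(
        post$posterior[post$family == f &
                         post$node == paste0("node_", nd)],
        oracle_posterior(tr, pat, m, nd), tolerance = 1e-10)
    }
  }
})

test_that("a symmetric discordant pair gives root posterior one half", {
  tr <- ape::read.tree(text = "(A:0.7,B:0.7);")
  m <- gain_loss_model(1, 1, Inf, 1)
  mat <- matrix(c(1L, 0L), 1, dimnames = list("f1", c("A", "B")))
  post <- ancestral_posteriors(tr, mat, m)
  expect_equal(post$posterior[post$node == "node_3"], 0.5,
               tolerance = 1e-12)
})

test_that("event calling finds gains, losses and retentions", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,C:0.1);")
  m <- gain_loss_model(0.05, 0.05, Inf, 1)

  all_present <- matrix(1L, 1, 3, dimnames = list("f1", c("A", "B", "C")))
  ev <- call_events(ancestral_posteriors(tr, all_present, m), tr)
  expect_equal(nrow(ev$events), 0L)
  expect_equal(sum(ev$branch_summary$retained), 4L)

  # presence in a single tip under low gain: gain on that terminal branch
  single <- matrix(c(1L, 0L, 0L), 1,
                   dimnames = list("f1", c("A", "B", "C")))
  ev2 <- call_events(ancestral_posteriors(tr, single, m), tr)
  expect_equal(ev2$events$event, "gain")
  expect_equal(ev2$events$child, "A")

  # a posterior of exactly 0.5 counts as present
  fake <- tibble::tibble(
    family = "f1", node = c("A", "B", "C", "node_4", "node_5"),
    posterior = c(1, 1, 1, 0.5, 0.5))
  ev3 <- call_events(fake, tr)
  expect_equal(nrow(ev3$events), 0L)  # 0.5 -> present, so no gains
})

test_that("acquisition mechanisms follow the outside-species vote", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ev <- tibble::tibble(family = "f1", parent = "node_7", child = "A",
                       event = "gain")
  mk_loc <- function(locB, locC, locD) {
    tibble::tibble(family = "f1", species = c("A", "B", "C", "D"),
                   location = c("SDR", locB, locC, locD))
  }
  mech <- function(...) classify_mechanism(ev, mk_loc(...), tr)$mechanism
  expect_equal(mech("PAR", "PAR", "ABSENT"), "boundary_expansion")
  expect_equal(mech("AUTOSOME", "ABSENT", "ABSENT"), "translocation")
  expect_equal(mech("ABSENT", "ABSENT", "ABSENT"), "birth")
  expect_equal(mech("PAR", "AUTOSOME", "ABSENT"), "ambiguous")

  # gain in a clade: only species outside the clade vote
  ev2 <- tibble::tibble(family = "f1", parent = "node_5",
                        child = "node_6", event = "gain")
  # node_6 is the (A,B) clade: only C and D vote, and their SDR/PAR codes
  loc <- tibble::tibble(family = "f1", species = c("A", "B", "C", "D"),
                        location = c("SDR", "SDR", "PAR", "ABSENT"))
  expect_equal(classify_mechanism(ev2, loc, tr)$mechanism,
               "boundary_expansion")
})

test_that("expected gene counts track simulation truth within 10%", {
  tr <- demo_species_tree()
  fam <- simulate_family_evolution(tr, 0.5, 1.0, 1.0, 500, seed = 1)
  fit <- fit_gain_loss(tr, fam$matrix, seed = 1)
  post <- ancestral_posteriors(tr, fam$matrix, fit)
  ev <- call_events(post, tr)
  truth_counts <- fam$node_states |>
    dplyr::group_by(node) |>
    dplyr::summarise(truth = sum(state))
  cmp <- dplyr::inner_join(ev$expected_genes, truth_counts, by = "node")
  internal <- grepl("^node_", cmp$node)
  expect_true(all(abs(cmp$expected_genes[internal] -
                        cmp$truth[internal]) /
                    pmax(cmp$truth[internal], 1) <= 0.10))
})
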