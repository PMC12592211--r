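# Birth-death (2-state gain/loss) reconstruction of SDR gene content on a
# species tree: Felsenstein pruning over a discretized-gamma mixture of
# family rates, maximum-likelihood rate fitting, marginal ancestral
# posteriors by the up-down algorithm, event calling, and classification
# of each gain's acquisition mechanism from orthologue locations.

LOCATION_CODES <- c("SDR", "PAR", "AUTOSOME", "ABSENT", "UNPLACED")

#' Encode orthologue locations as an SDR presence/absence matrix
#'
#' A family is "present" in a species iff its orthologue is SDR-linked
#' there; PAR, autosomal, absent and unplaced orthologues all code 0.
#'
#' @param loc Tibble with `family`, `species`, `location` (one of
#'   `r paste(LOCATION_CODES, collapse = ", ")`).
#' @return Binary matrix (families x species) with dimnames.
#' @export
encode_presence <- function(loc) {
  bad <- setdiff(unique(loc$location), LOCATION_CODES)
  if (length(bad)) {
    abort(paste0("unknown location code(s): ", paste(bad, collapse = ", ")))
  }
  wide <- loc |>
    mutate(present = as.integer(.data$location == "SDR")) |>
    tidyr::pivot_wider(id_cols = "family", names_from = "species",
                       values_from = "present")
  if (anyNA(wide)) abort("location matrix is incomplete")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$family
  all_unplaced <- loc |>
    group_by(.data$family) |>
    summarise(unpl = all(.data$location == "UNPLACED"), .groups = "drop")
  if (any(all_unplaced$unpl)) {
    warn(paste0(sum(all_unplaced$unpl),
                " family(ies) unplaced everywhere code as all-absent"))
  }
  mat
}

#' Two-state gain/loss transition probabilities
#'
#' With stationary presence probability `pi1 = g/(g+l)`:
#' `P(0->1) = pi1 (1 - exp(-(g+l) t))` and symmetrically for loss. Rows
#' index the parent state (absent, present) and sum to 1.
#'
#' @param g,l Gain and loss rates per unit branch length.
#' @param t Branch length (>= 0).
#' @return 2x2 matrix with dimnames `c("0","1")`.
#' @export
transition_matrix <- function(g, l, t) {
  if (t < 0) abort("branch length must be >= 0")
  if (g == 0 && l == 0) {
    warn("g = l = 0: returning the identity transition matrix")
    return(matrix(c(1, 0, 0, 1), 2, dimnames = list(c("0", "1"),
                                                    c("0", "1"))))
  }
  pi1 <- g / (g + l)
  decay <- exp(-(g + l) * t)
  p01 <- pi1 * (1 - decay)
  p10 <- (1 - pi1) * (1 - decay)
  matrix(c(1 - p01, p10, p01, 1 - p10), 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Gain/loss model specification
#'
#' @param g,l Gain and loss rates per unit branch length (`g + l > 0`).
#' @param alpha Gamma shape of among-family rate variation (`Inf` for
#'   homogeneous rates).
#' @param n_categories Discrete gamma classes (default 10).
#' @param root_prior `"stationary"` or a numeric probability that the root
#'   is present (fixed-root option).
#' @return A `uv_gainloss` list.
#' @export
gain_loss_model <- function(g, l, alpha = Inf, n_categories = 10L,
                            root_prior = "stationary") {
  if (g < 0 || l < 0 || g + l <= 0) abort("need g, l >= 0 and g + l > 0")
  if (n_categories < 1) abort("n_categories must be >= 1")
  structure(list(g = g, l = l, alpha = alpha,
                 n_categories = as.integer(n_categories),
                 root_prior = root_prior),
            class = "uv_gainloss")
}

#' @export
print.uv_gainloss <- function(x, ...) {
  cat("<uv_gainloss> gain ", signif(x$g, 4), ", loss ", signif(x$l, 4),
      ", gamma shape ", signif(x$alpha, 4), " (", x$n_categories,
      " categories)\n", sep = "")
  if (!is.null(x$logLik)) cat("  logLik ", round(x$logLik, 3), "\n")
  invisible(x)
}

model_rates <- function(model) {
  if (is.finite(model$alpha) && model$n_categories > 1L) {
    phangorn::discrete.gamma(model$alpha, model$n_categories)
  } else {
    1
  }
}

root_prior_vec <- function(model, g, l) {
  if (identical(model$root_prior, "stationary")) {
    c(l, g) / (g + l)
  } else {
    p <- model$root_prior
    c(1 - p, p)
  }
}

node_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  c(tree$tip.label, paste0("node_", (n_tip + 1L):(n_tip + tree$Nnode)))
}

# Pruning engine: per-family likelihoods (and, if keep_partials, the
# per-category down/up quantities needed for marginal posteriors).
# mat: families x tips binary matrix with tip names as colnames.
prune_engine <- function(tree, mat, model, keep_partials = FALSE) {
  validate_tree(tree)
  if (!all(colnames(mat) %in% tree$tip.label) ||
      ncol(mat) != length(tree$tip.label)) {
    abort("matrix species must match tree tips")
  }
  mat <- mat[, tree$tip.label, drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  fams <- nrow(mat)
  post_tree <- ape::reorder.phylo(tree, "postorder")
  edges <- post_tree$edge
  elens <- post_tree$edge.length
  rates <- model_rates(model)
  K <- length(rates)
  root <- n_tip + 1L

  lik_k <- matrix(0, fams, K)
  partials <- if (keep_partials) vector("list", K) else NULL

  for (k in seq_len(K)) {
    g <- model$g * rates[k]; l <- model$l * rates[k]
    prior <- root_prior_vec(model, g, l)
    P <- lapply(elens, function(t) transition_matrix(g, l, t))
    # down (pruning) pass
    L <- vector("list", n_node)
    for (tip in seq_len(n_tip)) {
      L[[tip]] <- cbind(1 - mat[, tip], mat[, tip])
    }
    for (nd in (n_tip + 1L):n_node) L[[nd]] <- matrix(1, fams, 2)
    contrib <- vector("list", nrow(edges))  # edge contribution to parent
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; ch <- edges[e, 2]
      contrib[[e]] <- L[[ch]] %*% t(P[[e]])
      L[[par]] <- L[[par]] * contrib[[e]]
    }
    lik_k[, k] <- as.vector(L[[root]] %*% prior)
    if (keep_partials) {
      partials[[k]] <- list(L = L, contrib = contrib, P = P,
                            prior = prior)
    }
  }
  lik <- rowMeans(lik_k)
  list(lik = lik, lik_k = lik_k, partials = partials,
       edges = edges, rates = rates, root = root, n_tip = n_tip,
       n_node = n_node)
}

#' Likelihood of one tip presence/absence pattern
#'
#' Felsenstein pruning under the gain/loss model, mixed over the
#' discretized gamma rate categories, with the root weighted by the
#' model's root prior.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param pattern Named 0/1 vector covering all tips.
#' @param model A [gain_loss_model()].
#' @return The pattern likelihood (numeric scalar).
#' @export
pattern_likelihood <- function(tree, pattern, model) {
  if (is.null(names(pattern))) names(pattern) <- tree$tip.label
  if (!setequal(names(pattern), tree$tip.label)) {
    abort("pattern must cover every tip")
  }
  mat <- matrix(pattern[tree$tip.label], nrow = 1,
                dimnames = list("f", tree$tip.label))
  prune_engine(tree, mat, model)$lik
}

#' Fit gain and loss rates (and gamma shape) by maximum likelihood
#'
#' Maximizes the summed per-family log-likelihood over `(g, l, alpha)` on
#' the log scale with multi-start Nelder-Mead. Restarts stop early once an
#' additional round fails to improve the best log-likelihood by at least
#' `tol` three times in a row.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param mat Families x species binary matrix.
#' @param n_categories Discrete gamma classes; 1 fixes homogeneous rates.
#' @param fit_alpha Whether to estimate the gamma shape.
#' @param n_restarts Optimization rounds (multi-starts).
#' @param tol Convergence threshold on the log-likelihood improvement.
#' @param root_prior Passed to [gain_loss_model()].
#' @param seed Seed for the restart draws.
#' @return A fitted `uv_gainloss` with `logLik`, `n_restarts_used` and
#'   `boundary` flag.
#' @export
fit_gain_loss <- function(tree, mat, n_categories = 10L, fit_alpha = TRUE,
                          n_restarts = 10L, tol = 0.1,
                          root_prior = "stationary", seed = 1L) {
  if (nrow(mat) < 1L) abort("need at least one family")
  set.seed(seed)
  fit_alpha <- fit_alpha && n_categories > 1L
  nll <- function(par) {
    g <- exp(par[1]); l <- exp(par[2])
    alpha <- if (fit_alpha) exp(par[3]) else Inf
    if (!is.finite(g) || !is.finite(l) || g + l <= 0) return(1e10)
    m <- gain_loss_model(g, l, alpha, n_categories, root_prior)
    lik <- prune_engine(tree, mat, m)$lik
    if (any(lik <= 0)) return(1e10)
    -sum(log(lik))
  }
  n_par <- if (fit_alpha) 3L else 2L
  starts <- list(rep(0, n_par))
  for (i in seq_len(n_restarts - 1L)) {
    starts[[i + 1L]] <- rnorm(n_par, 0, 1.5)
  }
  best <- NULL; stale <- 0L; used <- 0L
  for (st in starts) {
    used <- used + 1L
    fit <- optim(st, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value - tol) {
      best <- if (is.null(best) || fit$value < best$value) fit else best
      stale <- 0L
    } else {
      if (fit$value < best$value) best <- fit
      stale <- stale + 1L
      if (stale >= 3L) break
    }
  }
  g <- exp(best$par[1]); l <- exp(best$par[2])
  alpha <- if (fit_alpha) exp(best$par[3]) else Inf
  boundary <- g < 1e-6 || l < 1e-6
  if (boundary) {
    warn("fitted rate at boundary (all-identical or near-constant matrix)")
  }
  out <- gain_loss_model(max(g, 1e-12), max(l, 1e-12), alpha,
                         n_categories, root_prior)
  out$logLik <- -best$value
  out$n_restarts_used <- used
  out$boundary <- boundary
  out
}

#' Marginal ancestral posteriors of SDR presence
#'
#' Up-down (outside) algorithm per gamma category, mixed with per-family
#' category weights proportional to the category likelihoods. Tip
#' posteriors equal the observed states.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param mat Families x species binary matrix.
#' @param model A (fitted) [gain_loss_model()].
#' @return Tibble with `family`, `node`, `posterior` (probability
#'   present); internal nodes are labelled `node_<number>`.
#' @export
ancestral_posteriors <- function(tree, mat, model) {
  eng <- prune_engine(tree, mat, model, keep_partials = TRUE)
  fams <- nrow(mat)
  K <- length(eng$rates)
  labs <- node_labels(tree)
  post_mix <- matrix(0, fams, eng$n_node)
  w <- eng$lik_k / rowSums(eng$lik_k)  # per-family category weights
  edges <- eng$edges
  for (k in seq_len(K)) {
    pt <- eng$partials[[k]]
    U <- vector("list", eng$n_node)
    U[[eng$root]] <- matrix(pt$prior, fams, 2, byrow = TRUE)
    # children of each node, as edge indices (postorder edges)
    kids <- split(seq_len(nrow(edges)), edges[, 1])
    for (e in rev(seq_len(nrow(edges)))) {   # preorder
      par <- edges[e, 1]; ch <- edges[e, 2]
      sibs <- setdiff(kids[[as.character(par)]], e)
      excl <- matrix(1, fams, 2)
      for (s in sibs) excl <- excl * pt$contrib[[s]]
      msg <- U[[par]] * excl              # parent message excluding child
      U[[ch]] <- msg %*% pt$P[[e]]
    }
    for (nd in seq_len(eng$n_node)) {
      J <- U[[nd]] * pt$L[[nd]]
      norm <- rowSums(J)
      post_mix[, nd] <- post_mix[, nd] + w[, k] * (J[, 2] / norm)
    }
  }
  tibble(
    family = rep(rownames(mat), eng$n_node),
    node = rep(labs, each = fams),
    posterior = as.vector(post_mix)
  )
}

#' Call gain/loss events from ancestral posteriors
#'
#' Node states are presence posteriors thresholded at `threshold`
#' (ties count as present). A gain lies on a branch whose parent is absent
#' and child present; a loss the converse; a 1->1 branch retains the
#' family.
#'
#' @param posteriors Tibble from [ancestral_posteriors()].
#' @param tree The tree the posteriors were computed on.
#' @param threshold Posterior cutoff for presence.
#' @return List with `events` (tibble `family`, `parent`, `child`,
#'   `event`), `branch_summary` (per-branch gains/losses/retentions),
#'   `node_states` (tibble `family`, `node`, `state`) and
#'   `expected_genes` (per-node sum of posteriors).
#' @export
call_events <- function(posteriors, tree, threshold = 0.5) {
  labs <- node_labels(tree)
  st <- posteriors |>
    mutate(state = as.integer(.data$posterior >= threshold))
  stw <- st |>
    tidyr::pivot_wider(id_cols = "family", names_from = "node",
                       values_from = "state")
  edges <- tree$edge
  ev <- purrr::map_dfr(seq_len(nrow(edges)), function(e) {
    p <- labs[edges[e, 1]]; ch <- labs[edges[e, 2]]
    ps <- stw[[p]]; cs <- stw[[ch]]
    tibble(family = stw$family, parent = p, child = ch,
           event = dplyr::case_when(
             ps == 0L & cs == 1L ~ "gain",
             ps == 1L & cs == 0L ~ "loss",
             ps == 1L & cs == 1L ~ "retention",
             TRUE ~ "none"))
  })
  branch_summary <- ev |>
    group_by(.data$parent, .data$child) |>
    summarise(gains = sum(.data$event == "gain"),
              losses = sum(.data$event == "loss"),
              retained = sum(.data$event == "retention"),
              .groups = "drop")
  expected <- posteriors |>
    group_by(.data$node) |>
    summarise(expected_genes = sum(.data$posterior), .groups = "drop")
  list(events = ev |> filter(.data$event %in% c("gain", "loss")),
       branch_summary = branch_summary,
       node_states = st |> select("family", "node", "state"),
       expected_genes = expected)
}

#' Classify the acquisition mechanism of gained families
#'
#' For each called gain, the species outside the gained clade vote with
#' their orthologue locations: mostly pseudoautosomal orthologues imply
#' the SDR boundary expanded to engulf a PAR gene; mostly autosomal ones
#' imply a translocation into the SDR; no orthologue anywhere outside
#' implies a gene birth inside the SDR; a PAR/autosome tie is ambiguous.
#'
#' @param events Gain events (tibble with `family`, `child`) from
#'   [call_events()].
#' @param loc Tibble `family`, `species`, `location` (see
#'   [encode_presence()]).
#' @param tree The species tree.
#' @return `events` with a `mechanism` column (`boundary_expansion`,
#'   `translocation`, `birth`, `ambiguous`).
#' @export
classify_mechanism <- function(events, loc, tree) {
  labs <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  gains <- events |> filter(.data$event == "gain")
  mech <- vapply(seq_len(nrow(gains)), function(i) {
    ch_idx <- match(gains$child[i], labs)
    inside <- if (ch_idx <= n_tip) tree$tip.label[ch_idx]
              else ape::extract.clade(tree, ch_idx)$tip.label
    outside <- setdiff(tree$tip.label, inside)
    lo <- loc |> filter(.data$family == gains$family[i],
                        .data$species %in% outside)
    informative <- lo$location[lo$location %in% c("PAR", "AUTOSOME")]
    if (length(informative) == 0L) return("birth")
    n_par <- sum(informative == "PAR")
    n_auto <- sum(informative == "AUTOSOME")
    if (n_par > n_auto) "boundary_expansion"
    else if (n_auto > n_par) "translocation"
    else "ambiguous"
  }, character(1))
  gains |> mutate(mechanism = mech)
}
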