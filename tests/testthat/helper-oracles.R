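# Independent brute-force oracles shared across test files.

# independent NG86 oracle: recursive path enumeration and literal
# per-position site counting, written without the package's lookup tables
oracle_ng86 <- function(cod_a, cod_b) {
  gc <- setNames(as.character(Biostrings::GENETIC_CODE),
                 names(Biostrings::GENETIC_CODE))
  syn_sites <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    total <- 0
    for (p in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
        alt <- ch; alt[p] <- b
        if (gc[[paste(alt, collapse = "")]] == gc[[codon]]) {
          total <- total + 1 / 3
        }
      }
    }
    total
  }
  count_paths <- function(from, to) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(matrix(c(0, 0, 0), 1))
    out <- NULL
    for (perm in combinat_perms(pos)) {
      cur <- from; sd <- 0; nd <- 0; stop_hit <- FALSE
      for (p in perm) {
        ch <- strsplit(cur, "")[[1]]
        ch[p] <- substr(to, p, p)
        nxt <- paste(ch, collapse = "")
        if (gc[[nxt]] == "*" || gc[[cur]] == "*") stop_hit <- TRUE
        if (gc[[cur]] != "*" && gc[[nxt]] != "*" &&
            gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      out <- rbind(out, c(sd, nd, stop_hit))
    }
    out
  }
  combinat_perms <- function(x) {
    if (length(x) == 1) return(list(x))
    res <- list()
    for (i in seq_along(x)) {
      for (rest in combinat_perms(x[-i])) res <- c(res, list(c(x[i], rest)))
    }
    res
  }
  S <- (sum(vapply(cod_a, syn_sites, numeric(1))) +
          sum(vapply(cod_b, syn_sites, numeric(1)))) / 2
  N <- 3 * length(cod_a) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(cod_a)) {
    m <- count_paths(cod_a[i], cod_b[i])
    keep <- m[, 3] == 0
    if (any(keep)) m <- m[keep, , drop = FALSE]
    Sd <- Sd + mean(m[, 1]); Nd <- Nd + mean(m[, 2])
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

# brute-force likelihood: enumerate all internal-node state assignments
oracle_likelihood <- function(tree, pattern, model) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  rates <- if (is.finite(model$alpha) && model$n_categories > 1) {
    phangorn::discrete.gamma(model$alpha, model$n_categories)
  } else 1
  root <- n_tip + 1L
  internal <- root:n_node
  total <- 0
  for (r in rates) {
    g <- model$g * r; l <- model$l * r
    prior <- c(l, g) / (g + l)
    lik_r <- 0
    grid <- expand.grid(rep(list(0:1), length(internal)))
    for (gi in seq_len(nrow(grid))) {
      states <- integer(n_node)
      states[seq_len(n_tip)] <- pattern[tree$tip.label]
      states[internal] <- as.integer(grid[gi, ])
      p <- prior[states[root] + 1]
      for (e in seq_len(nrow(tree$edge))) {
        P <- transition_matrix(g, l, tree$edge.length[e])
        p <- p * P[states[tree$edge[e, 1]] + 1,
                   states[tree$edge[e, 2]] + 1]
      }
      lik_r <- lik_r + p
    }
    total <- total + lik_r
  }
  total / length(rates)
}

# brute-force marginal posterior of presence at one node
oracle_posterior <- function(tree, pattern, model, node_idx) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  rates <- if (is.finite(model$alpha) && model$n_categories > 1) {
    phangorn::discrete.gamma(model$alpha, model$n_categories)
  } else 1
  root <- n_tip + 1L
  internal <- root:n_node
  num <- 0; den <- 0
  for (r in rates) {
    g <- model$g * r; l <- model$l * r
    prior <- c(l, g) / (g + l)
    grid <- expand.grid(rep(list(0:1), length(internal)))
    for (gi in seq_len(nrow(grid))) {
      states <- integer(n_node)
      states[seq_len(n_tip)] <- pattern[tree$tip.label]
      states[internal] <- as.integer(grid[gi, ])
      p <- prior[states[root] + 1]
      for (e in seq_len(nrow(tree$edge))) {
        P <- transition_matrix(g, l, tree$edge.length[e])
        p <- p * P[states[tree$edge[e, 1]] + 1,
                   states[tree$edge[e, 2]] + 1]
      }
      den <- den + p
      if (states[node_idx] == 1) num <- num + p
    }
  }
  num / den
}

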