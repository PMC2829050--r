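# Independent oracles used to arbitrate the implementation.

# Brute-force maximum-weight connected subgraph: enumerates every connected
# vertex subset by recursive growth (no bounds, no contraction), fully
# independent of the C++ solver.
oracle_mwcs <- function(g, w) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  best <- list(score = -Inf, set = integer(0))
  lex_less <- function(a, b) {
    for (i in seq_len(min(length(a), length(b)))) {
      if (a[i] != b[i]) return(a[i] < b[i])
    }
    length(a) < length(b)
  }
  consider <- function(set, score) {
    if (score > best$score + 1e-9 ||
        (score > best$score - 1e-9 && lex_less(sort(set), best$set))) {
      best <<- list(score = score, set = sort(set))
    }
  }
  grow <- function(set, frontier, banned, score) {
    consider(set, score)
    while (length(frontier) > 0) {
      v <- frontier[1]
      frontier <- frontier[-1]
      nf <- union(frontier, setdiff(adj[[v]], c(set, v, banned, frontier)))
      grow(c(set, v), nf, banned, score + w[v])
      banned <- c(banned, v)
    }
  }
  for (r in seq_len(n)) {
    grow(r, setdiff(adj[[r]], seq_len(r)), seq_len(r - 1L), w[r])
  }
  # degenerate all-negative handled as best single node by convention
  single <- which.max(w)
  if (all(w <= 0)) best <- list(score = w[single], set = single)
  best
}

# Literal transcription of the published Storey q-value algorithm
# (smoother pi0 over lambda = 0.05..0.95, step-up with cumulative minimum).
oracle_qvalue <- function(p, pi0 = NULL) {
  m <- length(p)
  if (is.null(pi0)) {
    lambda <- seq(0.05, 0.95, 0.05)
    pi0l <- sapply(lambda, function(l) mean(p > l) / (1 - l))
    spi0 <- smooth.spline(lambda, pi0l, df = 3)
    pi0 <- min(predict(spi0, x = 0.95)$y, 1)
  }
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  pmin(q[order(o)], 1)
}

# Bisection solve of FDR(tau) = target under the beta-uniform mixture,
# with FDR(tau) = pi_ub * tau / (pi * tau + (1 - pi) * tau^a).
oracle_tau <- function(pi, a, fdr) {
  pi_ub <- pi + (1 - pi) * a
  f <- function(tau) pi_ub * tau / (pi * tau + (1 - pi) * tau^a) - fdr
  uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
}

# Exhaustive hypergeometric tail: enumerate all queries of size n from a
# universe of size N and count those overlapping the set at least k times.
oracle_hypergeom <- function(N, K, n, k) {
  queries <- combn(N, n)
  mean(colSums(queries <= K) >= k)
}

# Small deterministic scored graph builders -------------------------------

scored_graph <- function(edges, scores) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = names(scores)))
  igraph::V(g)$score <- scores[igraph::V(g)$name]
  g
}

random_scored_graph <- function(n, p_edge = 0.35) {
  g <- igraph::sample_gnp(n, p_edge)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  igraph::V(g)$score <- runif(n, -3, 3)  # continuous: ties have measure zero
  g
}

toy_reaction_file <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "reactions.tsv")
  writeLines(c("reaction_id\treactants\tproducts\tcatalysts\treversible", lines), path)
  path
}

dummy_fit <- function(pi, a, tau = NA_real_, fdr = NA_real_) {
  structure(list(pi = pi, a = a, pi_upper = pi + (1 - pi) * a,
                 log_likelihood = NA_real_, n = 0L, no_signal = FALSE,
                 tau = tau, fdr = fdr), class = "bum_fit")
}
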