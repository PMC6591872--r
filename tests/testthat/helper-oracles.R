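# Independent oracles and small fixture builders used across the suite.

# Random binary association matrix with at least one 1 per matrix.
random_binary <- function(n, m, density = 0.3) {
  Y <- matrix(rbinom(n * m, 1, density), n, m)
  if (sum(Y) == 0) Y[sample(n * m, 1)] <- 1
  Y
}

# Random DAG over `n` labelled nodes: node i > 1 draws 1-2 parents among the
# earlier nodes, so acyclicity holds by construction.
random_dag <- function(n) {
  ids <- sprintf("n%02d", seq_len(n))
  edges <- NULL
  for (i in seq_len(n)[-1]) {
    n_par <- sample.int(min(2L, i - 1L), 1)
    parents <- sample(seq_len(i - 1L), n_par)
    edges <- rbind(edges, cbind(ids[i], ids[parents]))
  }
  disease_dag(edges, nodes = ids)
}

dag_igraph <- function(dag) {
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(dag$nodes), name = dag$nodes)
  if (nrow(dag$edges)) {
    vidx <- match(t(dag$edges), dag$nodes)
    g <- igraph::add_edges(g, vidx)
  }
  g
}

# Closed-form semantic-contribution oracle: with a decay recursion that takes
# the max over children, the contribution of ancestor t for query d is
# delta^(shortest child->parent path length from d to t). Computed with
# igraph shortest paths — fully independent of the package's recursion.
semantic_contribution_oracle <- function(dag, disease, delta) {
  g <- dag_igraph(dag)
  anc <- names(igraph::subcomponent(g, disease, mode = "out"))
  d <- igraph::distances(g, v = disease, to = anc, mode = "out")[1, ]
  stats::setNames(delta^d, anc)
}

semantic_similarity_oracle <- function(dag, ids, delta) {
  contrib <- lapply(ids, semantic_contribution_oracle, dag = dag, delta = delta)
  dv1 <- vapply(contrib, sum, numeric(1))
  S <- diag(1, length(ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      shared <- intersect(names(contrib[[i]]), names(contrib[[j]]))
      S[i, j] <- if (length(shared)) {
        sum(contrib[[i]][shared] + contrib[[j]][shared]) / (dv1[i] + dv1[j])
      } else 0
    }
  }
  dimnames(S) <- list(ids, ids)
  S
}

# Brute-force pairwise AUC: mean over all positive-negative pairs of
# win + half a tie.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force one-step ALS oracle: the closed-form updates written with
# explicit full inverses.
als_step_oracle <- function(Y, A, B, Rm, Rd, ll, ld, lt) {
  k <- ncol(A)
  A1 <- (Y %*% B + ld * Rm %*% A) %*%
    solve(t(B) %*% B + ll * diag(k) + ld * t(A) %*% A)
  B1 <- (t(Y) %*% A1 + lt * Rd %*% B) %*%
    solve(t(A1) %*% A1 + ll * diag(k) + lt * t(B) %*% B)
  list(A = A1, B = B1)
}

# Small synthetic benchmark reused by the evaluation tests.
tiny_sim <- function(seed = 42) {
  simulate_mda(n_mirna = 30, n_disease = 20, planted_rank = 3,
               density = 0.15, mask_fraction = 0.2, seed = seed)
}
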