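# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: shortest paths are enumerated by explicit
# backtracking, eigen-decompositions are done on a hand-built covariance.

# Brute-force centralities by exhaustive shortest-path enumeration.
# edges: data.frame from/to (characters); nodes: character vector.
brute_centralities <- function(nodes, edges) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  nb <- vector("list", n)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      i <- idx[[edges$from[e]]]; j <- idx[[edges$to[e]]]
      nb[[i]] <- union(nb[[i]], j)
      nb[[j]] <- union(nb[[j]], i)
    }
  }
  dmat <- matrix(Inf, n, n); diag(dmat) <- 0
  for (s in seq_len(n)) {          # plain BFS distances
    frontier <- s; d <- 0
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in nb[[v]]) {
        if (!is.finite(dmat[s, w])) {
          dmat[s, w] <- d + 1; nxt <- c(nxt, w)
        }
      }
      frontier <- unique(nxt); d <- d + 1
    }
  }
  # enumerate every shortest path s->t by backtracking from t
  all_paths <- function(s, t) {
    if (s == t) return(list(t))
    out <- list()
    for (w in nb[[t]]) {
      if (is.finite(dmat[s, w]) && dmat[s, w] == dmat[s, t] - 1) {
        for (p in all_paths(s, w)) out <- c(out, list(c(p, t)))
      }
    }
    out
  }
  stress <- numeric(n); btw <- numeric(n)
  degree <- vapply(nb, length, 1L)
  for (s in seq_len(n - 1L)) for (t in seq((s + 1L), n)) {
    if (!is.finite(dmat[s, t]) || dmat[s, t] == 0) next
    paths <- all_paths(s, t)
    sigma <- length(paths)
    inner <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
    if (length(inner)) {
      cnt <- table(inner)
      v <- as.integer(names(cnt))
      stress[v] <- stress[v] + as.numeric(cnt)
      btw[v] <- btw[v] + as.numeric(cnt) / sigma
    }
  }
  data.frame(node = nodes, degree = as.integer(degree), stress = stress,
             betweenness = btw, stringsAsFactors = FALSE)
}

# random graph on <= max_n nodes for the centrality equivalence check
random_toy_network <- function(seed, max_n = 8L) {
  set.seed(seed)
  n <- sample(3:max_n, 1L)
  nodes <- LETTERS[seq_len(n)]
  pairs <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pairs)) < 0.45
  interaction_network(nodes[pairs[1L, keep]], nodes[pairs[2L, keep]],
                      stats::runif(sum(keep), 0.5, 1), nodes = nodes)
}

# tiny GO DAG fixture: root -> {A, B}; A -> {A1, A2}; B -> B1
toy_dag <- function() {
  go_dag(child = c("A", "B", "A1", "A2", "B1"),
         parent = c("root", "root", "A", "A", "B"))
}

# direct fold-table construction for unit fixtures
make_folds <- function(gene_id, fold, scale = "standardized") {
  out <- data.frame(gene_id = toupper(gene_id), fold = fold,
                    stringsAsFactors = FALSE)
  class(out) <- c("fold_table", "data.frame")
  attr(out, "scale") <- scale
  out
}
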