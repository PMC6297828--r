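# Independent oracles, deliberately naive: these never share code with the
# package internals they check.

# Weighted Levenshtein by memoized recursion.
oracle_levenshtein <- function(a, b, del = 1.1, ins = 1.1, sub = 1.9) {
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i == 0) return(j * ins)
    if (j == 0) return(i * del)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cs <- rec(i - 1, j - 1) +
      if (substr(a, i, i) == substr(b, j, j)) 0 else sub
    v <- min(cs, rec(i - 1, j) + del, rec(i, j - 1) + ins)
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

random_aa <- function(n, min_len = 1, max_len = 15) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(sample(min_len:max_len, n, replace = TRUE), function(l) {
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, character(1))
}

# Random undirected graph as an igraph object.
random_small_graph <- function(n, p = 0.4) {
  adj <- matrix(stats::runif(n * n) < p, n, n)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  adj <- adj | t(adj)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Shortest-path edge counts by repeated adjacency multiplication.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n)
  power <- diag(n)
  for (k in seq_len(n)) {
    power <- power %*% adj
    newly <- power > 0 & !(reach > 0)
    D[newly] <- k
    reach <- reach + power
  }
  D
}

# MTI by the literal double sum, per connected component.
oracle_mti <- function(g) {
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  n <- nrow(adj)
  if (n == 0) return(0)
  D <- oracle_distances(adj)
  d <- rowSums(adj)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (is.finite(D[i, j])) total <- total + d[i] * (adj[i, j] + D[i, j])
  }
  total
}

# Betweenness by exhaustive enumeration of all simple paths per pair.
oracle_betweenness <- function(g) {
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  n <- nrow(adj)
  paths_between <- function(j, k) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == k) { out[[length(out) + 1]] <<- path; return(invisible()) }
      for (nxt in which(adj[last, ] > 0)) {
        if (!(nxt %in% path)) walk(c(path, nxt))
      }
    }
    walk(j)
    out
  }
  bwc <- numeric(n)
  if (n < 3) return(bwc)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    ps <- paths_between(j, k)
    if (length(ps) == 0) next
    lens <- lengths(ps)
    shortest <- ps[lens == min(lens)]
    g_jk <- length(shortest)
    for (i in seq_len(n)) {
      if (i == j || i == k) next
      through <- sum(vapply(shortest, function(p) i %in% p, logical(1)))
      bwc[i] <- bwc[i] + through / g_jk
    }
  }
  bwc
}

# Adjusted Rand index between two labelings (contingency-table form).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
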