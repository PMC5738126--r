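# Independent brute-force oracles and tiny fixture builders used across the
# suite. Everything here is deliberately written without igraph or any
# package internals so the oracles stay independent of the code they check.

# All-pairs BFS betweenness: for each source, count shortest paths sigma and
# distances by breadth-first levels; a path j..k passes i iff
# d(j,i) + d(i,k) = d(j,k), contributing sigma_j(i) * sigma_i(k) paths.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  dmat <- matrix(Inf, n, n)
  smat <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sigma <- rep(0, n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    dmat[s, ] <- dist; smat[s, ] <- sigma
  }
  cb <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) {
        if (j == i || k == i || is.infinite(dmat[j, k])) next
        if (dmat[j, i] + dmat[i, k] == dmat[j, k])
          cb[i] <- cb[i] + smat[j, i] * smat[i, k] / smat[j, k]
      }
    }
  }
  cb
}

# Exhaustive triangle enumeration on an adjacency matrix.
brute_triangles <- function(adj) {
  n <- nrow(adj)
  tris <- list()
  if (n < 3) return(tris)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    if (adj[i, j] == 1 && adj[j, k] == 1 && adj[i, k] == 1)
      tris[[length(tris) + 1]] <- c(i, j, k)
  tris
}

# Exhaustive k-NN imputation oracle: all-pairs overlap distances computed
# naively, neighbours ranked by (distance, id), missing cells averaged.
brute_knn_impute <- function(m, k = 7) {
  n <- nrow(m)
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, sd, na.rm = TRUE)
  sdv[is.na(sdv) | sdv == 0] <- 1
  z <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  out <- m
  for (i in seq_len(n)) {
    if (!anyNA(m[i, ])) next
    d <- sapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      ok <- !is.na(z[i, ]) & !is.na(z[j, ])
      if (!any(ok)) return(Inf)
      mean(abs(z[i, ok] - z[j, ok]))
    })
    cand <- which(is.finite(d))
    nb <- cand[order(d[cand], rownames(m)[cand])]
    nb <- nb[seq_len(min(k, length(nb)))]
    for (j in which(is.na(m[i, ]))) {
      v <- m[nb, j]; v <- v[!is.na(v)]
      out[i, j] <- if (length(v) == 0) mu[j] else mean(v)
    }
  }
  out
}

# Labeled graph builder from an edge list over ids with genders.
make_graph <- function(edges, genders) {
  igraph::graph_from_data_frame(
    as.data.frame(edges), directed = FALSE,
    vertices = data.frame(name = names(genders), gender = unname(genders)))
}

# Random G(n, p) adjacency matrix, symmetric, no self loops.
random_adj <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1, p)
  a + t(a)
}

adj_to_graph <- function(adj, genders = NULL) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- as.character(seq_len(nrow(adj)))
  if (!is.null(genders)) igraph::V(g)$gender <- genders
  igraph::E(g)$weight <- 1
  g
}

# Two-participant minimal cohort used by the I/O tests.
tiny_cohort <- function() {
  cohort(data.frame(id = c("a", "b"), gender = c("F", "M")),
         week_range = 0:3,
         active_weeks = list(a = c(0L, 1L), b = c(0L, 1L)))
}
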