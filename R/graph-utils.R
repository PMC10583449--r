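# Small-graph utilities for the descriptor engine. Molecular graphs here
# have at most a few dozen heavy atoms, so plain BFS and path enumeration
# are exact and fast.

# all-pairs shortest-path matrix (unit bond lengths) by BFS
.graph_distances <- function(g) {
  n <- g$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (n == 0L || nrow(g$bonds) == 0L) return(D)
  nbrs <- .neighbour_list(g)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in nbrs[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

.neighbour_list <- function(g) {
  nbrs <- vector("list", g$n)
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds[k, 1]; b <- g$bonds[k, 2]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  nbrs
}

# counts of simple paths with 2 and 3 edges (each path counted once)
.path_counts <- function(g) {
  nbrs <- .neighbour_list(g)
  p2 <- 0L; p3 <- 0L
  p2_paths <- list(); p3_paths <- list()
  for (v in seq_len(g$n)) {
    nb <- nbrs[[v]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(nb, 2L)
      for (c_i in seq_len(ncol(cmb))) {
        p2 <- p2 + 1L
        p2_paths[[p2]] <- c(cmb[1L, c_i], v, cmb[2L, c_i])
      }
    }
  }
  # a 3-edge path x-a-b-y has a unique central edge, so iterating stored
  # edges counts each path exactly once
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds[k, 1]; b <- g$bonds[k, 2]
    for (x in setdiff(nbrs[[a]], b)) {
      for (y in setdiff(nbrs[[b]], a)) {
        if (x == y) next
        p3 <- p3 + 1L
        p3_paths[[p3]] <- c(x, a, b, y)
      }
    }
  }
  list(p2 = p2, p3 = p3, p2_paths = p2_paths, p3_paths = p3_paths)
}
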