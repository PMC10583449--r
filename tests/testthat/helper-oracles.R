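# Independent oracles and fixtures shared across test files.

# apply an atom permutation p (old index -> new index) to a molecular
# graph, exercising the fingerprint engine's numbering invariance
permute_graph <- function(g, p) {
  out <- g
  remap <- function(v) {
    w <- v
    w[p] <- v
    w
  }
  for (field in c("elem", "charge", "nH", "degree", "in_ring", "aromatic"))
    out[[field]] <- remap(g[[field]])
  if (nrow(g$bonds)) {
    out$bonds[, 1] <- p[g$bonds[, 1]]
    out$bonds[, 2] <- p[g$bonds[, 2]]
  }
  adj <- vector("list", g$n)
  for (a in seq_len(g$n)) adj[[p[a]]] <- g$adj[[a]]
  out$adj <- adj
  out
}

# loop-based regression metrics, written independently of the package
oracle_metrics <- function(y, yhat) {
  n <- length(y)
  sae <- 0
  sse <- 0
  for (i in seq_len(n)) {
    sae <- sae + abs(yhat[i] - y[i])
    sse <- sse + (yhat[i] - y[i])^2
  }
  sst <- 0
  m <- sum(y) / n
  for (i in seq_len(n)) sst <- sst + (y[i] - m)^2
  list(mae = sae / n, rmse = sqrt(sse / n), r2 = 1 - sse / sst)
}

# exhaustive pair-checking version of the correlation prune: drop the
# later column of every offending pair among the survivors
oracle_corr_prune <- function(x, cutoff) {
  keep <- rep(TRUE, ncol(x))
  for (j in seq_len(ncol(x))) {
    if (j == 1L) next
    for (i in seq_len(j - 1L)) {
      if (!keep[i]) next
      r <- suppressWarnings(stats::cor(x[, i], x[, j]))
      if (!is.na(r) && abs(r) > cutoff) {
        keep[j] <- FALSE
        break
      }
    }
  }
  colnames(x)[keep]
}

# brute-force subset-enumeration Shapley values of one regression tree
# (arrays 0-based as used by the package's C++ kernels)
oracle_tree_shapley <- function(ld, rd, var, split, value, cover, xrow) {
  p <- length(xrow)
  expvalue <- function(node, inS) {
    if (ld[node] < 0L) return(value[node])
    f <- var[node] + 1L
    l <- ld[node] + 1L
    r <- rd[node] + 1L
    if (inS[f]) {
      if (xrow[f] <= split[node]) expvalue(l, inS) else expvalue(r, inS)
    } else {
      (cover[l] * expvalue(l, inS) + cover[r] * expvalue(r, inS)) /
        cover[node]
    }
  }
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (j in seq_len(p)) {
    for (s in seq_len(nrow(subsets))) {
      inS <- as.logical(subsets[s, ])
      if (inS[j]) next
      k <- sum(inS)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      withj <- inS
      withj[j] <- TRUE
      phi[j] <- phi[j] + w * (expvalue(1L, withj) - expvalue(1L, inS))
    }
  }
  phi
}

# 20 structurally varied fixture molecules used across tests
fixture_smiles <- function() {
  c("C", "CC", "CCO", "OCC(O)CO", "CC(=O)O", "c1ccccc1", "Cc1ccccc1",
    "Oc1ccccc1", "Nc1ccccc1", "Clc1ccccc1", "CC(C)CC(C)(C)C", "CCN",
    "CC(=O)Nc1ccccc1", "FC(F)(F)c1ccccc1", "CCOC(=O)C", "C1CCCCC1",
    "OC1CCCCC1", "BrCCBr", "CC#N", "CS(=O)(=O)C")
}
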