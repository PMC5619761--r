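# Independent oracles used to validate the package's computations.  Each is
# written from first principles (textbook recursions, exhaustive
# enumeration, grid scans) and deliberately shares no code with the
# implementation it checks.

# --- affine-gap global alignment score (Gotoh three-matrix recursion) -----
# Convention: a gap run of length L costs open + L * extend.
oracle_align_score <- function(a, b, submat, open = 10, extend = 0.5) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # x[i] aligned to y[j]
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in y (x[i] against '-')
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in x
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[x[i - 1], y[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend,
                      Iy[i - 1, j] - open - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend,
                      Ix[i, j - 1] - open - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# --- least-squares branch-length fit of a fixed topology ------------------
# Returns the sum of squared residuals of the OLS fit of pairwise distances
# to path lengths on the given (unrooted, binary) topology.
ols_tree_fit <- function(phy, dm) {
  tips <- phy$tip.label
  n <- length(tips)
  pairs <- t(utils::combn(n, 2))
  edges <- phy$edge
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (p in seq_len(nrow(pairs))) {
    path <- ape::nodepath(phy, pairs[p, 1], pairs[p, 2])
    for (k in seq_len(length(path) - 1)) {
      e <- which((edges[, 1] == path[k] & edges[, 2] == path[k + 1]) |
                 (edges[, 2] == path[k] & edges[, 1] == path[k + 1]))
      A[p, e] <- 1
    }
  }
  dvec <- dm[cbind(tips[pairs[, 1]], tips[pairs[, 2]])]
  fit <- stats::lm.fit(A, dvec)
  list(sse = sum(fit$residuals^2), lengths = fit$coefficients)
}

# Brute-force least-squares topology search: enumerate every unrooted
# topology, OLS-fit branch lengths, return the topology with minimal SSE.
oracle_ls_topology <- function(dm) {
  tips <- rownames(dm)
  all_t <- phangorn::allTrees(length(tips), rooted = FALSE, tip.label = tips)
  sse <- vapply(all_t, function(tr) ols_tree_fit(tr, dm)$sse, numeric(1))
  all_t[[which.min(sse)]]
}

# Random additive distance matrix from a random binary tree with positive
# branch lengths; returns both.
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.6)
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
  list(tree = tr, dm = dm)
}

# --- exhaustive agglomeration oracle --------------------------------------
# Recomputes every inter-cluster linkage distance from the original item
# distance matrix at every step (no Lance-Williams update), merging the
# closest pair; ties broken by leftmost original index.  Returns the merge
# history as a list of sorted member-index pairs plus merge heights.
oracle_agglomerate <- function(d, linkage = "average") {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  merges <- list(); heights <- numeric(0)
  link <- function(ci, cj) {
    vals <- d[ci, cj, drop = FALSE]
    switch(linkage, average = mean(vals), complete = max(vals),
           single = min(vals))
  }
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL; bd <- Inf; bkey <- c(Inf, Inf)
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      dd <- link(clusters[[i]], clusters[[j]])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      better <- dd < bd - 1e-12 ||
        (abs(dd - bd) <= 1e-12 &&
         (key[1] < bkey[1] || (key[1] == bkey[1] && key[2] < bkey[2])))
      if (better) { bd <- dd; best <- c(i, j); bkey <- key }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, bd)
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# Members of each merge step of an hclust object, as sorted index vectors.
hclust_merge_members <- function(h) {
  out <- list()
  for (s in seq_len(nrow(h$merge))) {
    grab <- function(id) if (id < 0) -id else out[[id]]
    out[[s]] <- sort(c(grab(h$merge[s, 1]), grab(h$merge[s, 2])))
  }
  out
}

# --- isoelectric point by brute-force pH grid scan ------------------------
oracle_pi_grid <- function(sequence, step = 1e-4) {
  ph <- seq(0, 14, by = step)
  q <- vapply(ph, function(p) protein_net_charge(sequence, p), numeric(1))
  ph[which.min(abs(q))]
}

# --- misc -----------------------------------------------------------------
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}
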