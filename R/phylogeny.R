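# Distance-based phylogenetics: pairwise p-distances from an alignment or
# from pairwise global alignments, neighbor joining with deterministic
# tie-breaking and PHYLIP-style negative-branch clamping, column bootstrap,
# and anchor-based subfamily assignment.

#' Pairwise distance matrix between proteins
#'
#' In `msa_pdist` mode the input sequences must already be aligned (equal
#' lengths, `-` for gaps); the p-distance for a pair is the fraction of
#' mismatching columns among columns where both sequences carry a residue
#' (gap-containing columns are excluded pairwise).  In `pairwise_global`
#' mode each pair is aligned globally first (see [global_align()]) and the
#' p-distance computed on that alignment.
#'
#' The optional Kimura protein correction transforms
#' `d = -ln(1 - p - 0.2 p^2)` for `p < 0.854`, and uses `ceiling` beyond.
#'
#' @param records protein records with `protein_id` and `sequence`.
#' @param mode `"msa_pdist"` or `"pairwise_global"`.
#' @param correction `"none"` (default) or `"kimura"`.
#' @param ceiling distance used where the Kimura transform diverges.
#' @param scoring scoring passed to [global_align()] in pairwise mode.
#' @return symmetric numeric matrix with zero diagonal, dimnames = protein
#'   ids.
#' @export
pairwise_distance_matrix <- function(records,
                                     mode = c("msa_pdist", "pairwise_global"),
                                     correction = c("none", "kimura"),
                                     ceiling = 5,
                                     scoring = default_scoring()) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  stopifnot(nrow(records) >= 3L)
  ids <- records$protein_id
  n <- length(ids)
  seqs <- records$sequence
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (mode == "msa_pdist") {
    if (length(unique(nchar(seqs))) != 1L)
      stop("value error: msa_pdist mode requires aligned sequences of equal length")
    chars <- do.call(rbind, strsplit(seqs, ""))
    res <- chars != "-" & chars != "."
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      ok <- res[i, ] & res[j, ]
      if (!any(ok))
        stop("value error: no comparable columns for pair ", ids[i], "/", ids[j])
      p <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
      d[i, j] <- d[j, i] <- p
    }
  } else {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      al <- global_align(seqs[i], seqs[j], scoring)
      a <- strsplit(al$aligned_a, "")[[1L]]
      b <- strsplit(al$aligned_b, "")[[1L]]
      ok <- a != "-" & b != "-"
      if (!any(ok))
        stop("value error: no comparable columns for pair ", ids[i], "/", ids[j])
      d[i, j] <- d[j, i] <- sum(a[ok] != b[ok]) / sum(ok)
    }
  }
  if (correction == "kimura") {
    p <- d[upper.tri(d)]
    k <- rep(ceiling, length(p))
    ok <- p < 0.854
    k[ok] <- -log(1 - p[ok] - 0.2 * p[ok]^2)
    d[upper.tri(d)] <- k
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining: iteratively join the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j` (with `R_i` the row sum over the `r`
#' active nodes); branch lengths at a join are
#' `v_i = d(i,j)/2 + (R_i - R_j)/(2(r-2))`, and the new node's distances are
#' `d(u,m) = (d(i,m) + d(j,m) - d(i,j))/2`.  Ties in Q are broken by the
#' lexicographically smallest pair of labels.  A negative branch length is
#' clamped to zero with the deficit transferred to its sibling edge
#' (PHYLIP-compatible).  The returned tree is unrooted (trifurcating root
#' node).
#'
#' @param dm symmetric distance matrix with dimnames (>= 3 taxa).
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L) stop("value error: neighbor joining needs >= 3 taxa")
  labels <- rownames(dm)
  stopifnot(!is.null(labels))
  d <- dm
  # active node "fragments": newick subtrees keyed by a sort label
  frag <- sanitize_labels(labels)
  key <- labels
  clamp2 <- function(v) {
    if (v[1] < 0) { v[2] <- v[2] + v[1]; v[1] <- 0 }
    if (v[2] < 0) { v[1] <- max(0, v[1] + v[2]); v[2] <- 0 }
    v
  }
  while (length(frag) > 3L) {
    r <- length(frag)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    pk <- apply(best, 1L, function(ij) {
      p <- sort(c(key[ij[1]], key[ij[2]])); paste(p[1], p[2], sep = "\r")
    })
    sel <- best[order(pk)[1L], ]
    i <- sel[[1L]]; j <- sel[[2L]]
    vi <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    vj <- d[i, j] - vi
    v <- clamp2(c(vi, vj))
    newfrag <- sprintf("(%s:%.12f,%s:%.12f)", frag[i], v[1], frag[j], v[2])
    newkey <- min(key[i], key[j])
    m <- setdiff(seq_len(r), c(i, j))
    dnew <- (d[i, m] + d[j, m] - d[i, j]) / 2
    d <- rbind(cbind(d[m, m, drop = FALSE], dnew), c(dnew, 0))
    frag <- c(frag[m], newfrag)
    key <- c(key[m], newkey)
  }
  # final trifurcation: closed-form terminal branch lengths
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  c3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- pmax(c(a, b, c3), 0)
  nwk <- sprintf("(%s:%.12f,%s:%.12f,%s:%.12f);",
                 frag[1], v[1], frag[2], v[2], frag[3], v[3])
  ape::read.tree(text = nwk)
}

sanitize_labels <- function(x) gsub("[(),:;[:space:]]", "_", x)

# Non-trivial bipartitions of an unrooted tree, canonicalized as the sorted
# leaf-name set on the side NOT containing the alphabetically first leaf.
tree_bipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  anchor <- min(phy$tip.label)
  parts <- ape::prop.part(phy)
  out <- character(0)
  nodes <- integer(0)
  root <- ntip + 1L
  for (k in seq_along(parts)) {
    node <- k + ntip
    if (node == root) next
    leaves <- phy$tip.label[parts[[k]]]
    if (anchor %in% leaves) leaves <- setdiff(phy$tip.label, leaves)
    if (length(leaves) < 2L || length(leaves) > ntip - 2L) next
    out <- c(out, paste(sort(leaves), collapse = "\r"))
    nodes <- c(nodes, node)
  }
  stats::setNames(out, nodes)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_replicates` times (replicate `r`
#' seeds the RNG with `seed + r`), rebuilds the tree, and annotates each
#' internal edge of the reference tree with the percentage of replicates
#' containing the same bipartition (rounded to the nearest integer), stored
#' as `node.label`.
#'
#' @param records aligned protein records (equal-length sequences).
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @param correction distance correction, see [pairwise_distance_matrix()].
#' @return an [ape::phylo] tree with integer `node.label` supports (empty
#'   label on the root).
#' @export
bootstrap_support <- function(records, n_replicates, seed,
                              correction = "none") {
  stopifnot(n_replicates >= 1L, is.numeric(seed))
  if (length(unique(nchar(records$sequence))) != 1L)
    stop("value error: bootstrap requires aligned sequences of equal length")
  chars <- do.call(rbind, strsplit(records$sequence, ""))
  rownames(chars) <- records$protein_id
  L <- ncol(chars)
  ref <- nj_tree(pairwise_distance_matrix(records, "msa_pdist", correction))
  bip <- tree_bipartitions(ref)
  hits <- stats::setNames(rep(0L, length(bip)), bip)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    cols <- sample.int(L, L, replace = TRUE)
    rec_r <- data.frame(protein_id = records$protein_id,
                        sequence = apply(chars[, cols, drop = FALSE], 1L,
                                         paste, collapse = ""),
                        stringsAsFactors = FALSE)
    tr <- nj_tree(pairwise_distance_matrix(rec_r, "msa_pdist", correction))
    rb <- tree_bipartitions(tr)
    hits[bip %in% rb] <- hits[bip %in% rb] + 1L
  }
  support <- as.integer(round(hits / n_replicates * 100))
  ntip <- length(ref$tip.label)
  nnode <- ref$Nnode
  labs <- rep("", nnode)
  labs[as.integer(names(bip)) - ntip] <- as.character(support)
  ref$node.label <- labs
  ref
}

#' Assign subfamilies from anchor leaves
#'
#' The tree is midpoint-rooted, then each non-anchor leaf is labeled by the
#' majority anchor label in the smallest clade (strictly below the root)
#' that contains the leaf and at least one anchor.  A tie, or no anchor
#' below the root on the leaf's path, yields `"UNASSIGNED"`.
#'
#' @param tree an [ape::phylo] tree containing all anchors as leaves.
#' @param anchors named character vector: names are anchor leaf ids, values
#'   subfamily labels.
#' @return named character vector: label per non-anchor leaf.
#' @export
assign_subfamilies <- function(tree, anchors) {
  if (length(anchors) == 0L || is.null(names(anchors)))
    stop("value error: empty anchor set")
  missing <- setdiff(names(anchors), tree$tip.label)
  if (length(missing) > 0L)
    stop("value error: anchor(s) not in tree: ", paste(missing, collapse = ", "))
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  root <- ntip + 1L
  parent <- integer(max(rooted$edge))
  parent[rooted$edge[, 2]] <- rooted$edge[, 1]
  clades <- ape::prop.part(rooted)
  anchor_idx <- match(names(anchors), rooted$tip.label)
  queries <- setdiff(rooted$tip.label, names(anchors))
  out <- stats::setNames(rep("UNASSIGNED", length(queries)), queries)
  for (q in queries) {
    node <- match(q, rooted$tip.label)
    repeat {
      node <- parent[node]
      if (node == 0L || node == root) break
      members <- clades[[node - ntip]]
      hit <- anchor_idx[anchor_idx %in% members]
      if (length(hit) > 0L) {
        tab <- sort(table(anchors[match(hit, anchor_idx)]), decreasing = TRUE)
        if (length(tab) > 1L && tab[1L] == tab[2L]) break  # tie -> UNASSIGNED
        out[q] <- names(tab)[1L]
        break
      }
    }
  }
  out
}
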