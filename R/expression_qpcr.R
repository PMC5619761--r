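# Expression-matrix scaling and hierarchical clustering (heatmap analog),
# duplicate-pair expression-similarity calls, and comparative-Ct (2^-ddCt)
# qPCR quantification.

#' Scale matrix rows for heatmap display
#'
#' @param mat numeric matrix (genes x tissues), NA allowed.
#' @param method `"zscore"` ((x - row mean)/row sd, NA skipped; rows with
#'   zero sd map to all-zeros), `"unit_max"` (x / row max) or `"none"`.
#' @return scaled matrix of the same shape.
#' @export
scale_rows <- function(mat, method = c("zscore", "unit_max", "none")) {
  method <- match.arg(method)
  all_na <- apply(mat, 1L, function(r) all(is.na(r)))
  if (any(all_na))
    stop("validation error: all-NA row(s): ",
         paste(rownames(mat)[all_na], collapse = ", "))
  if (method == "none") return(mat)
  t(apply(mat, 1L, function(r) {
    if (method == "unit_max") return(r / max(r, na.rm = TRUE))
    s <- stats::sd(r, na.rm = TRUE)
    if (is.na(s) || s == 0) return(ifelse(is.na(r), NA_real_, 0))
    (r - mean(r, na.rm = TRUE)) / s
  }))
}

# Pairwise item distances with pairwise-complete NA handling.
item_distances <- function(m, distance) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    if (distance == "pearson") {
      if (sum(ok) < 3L)
        stop("value error: fewer than 3 shared observations for items '",
             rownames(m)[i], "'/'", rownames(m)[j], "'")
      r <- suppressWarnings(stats::cor(m[i, ok], m[j, ok]))
      if (is.na(r)) r <- 0  # a constant profile carries no correlation signal
      d[i, j] <- d[j, i] <- 1 - r
    } else {
      if (!any(ok))
        stop("value error: no shared observations for items '",
             rownames(m)[i], "'/'", rownames(m)[j], "'")
      d[i, j] <- d[j, i] <-
        sqrt(sum((m[i, ok] - m[j, ok])^2) * ncol(m) / sum(ok))
    }
  }
  d
}

#' Agglomerative hierarchical clustering of an expression matrix
#'
#' Clusters rows (genes) or columns (tissues) with centered Pearson distance
#' (`d = 1 - r`) or Euclidean distance, and average, complete or single
#' linkage.  Missing values are handled by pairwise-complete observations;
#' genes observed in fewer than half the tissues are excluded with a
#' warning.  When two candidate merges are exactly tied, the pair whose
#' clusters contain the leftmost original rows is merged first, making the
#' dendrogram deterministic across platforms.
#'
#' @param mat numeric matrix.
#' @param axis `"rows"` or `"cols"`.
#' @param distance `"pearson"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param min_obs_frac minimum fraction of observed values per item.
#' @return an object of class `hclust` (merge, height, order, labels).
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "cols"),
                                 distance = c("pearson", "euclidean"),
                                 linkage = c("average", "complete", "single"),
                                 min_obs_frac = 0.5) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- if (axis == "rows") mat else t(mat)
  obs <- rowMeans(!is.na(m))
  if (any(obs < min_obs_frac)) {
    warning("excluding item(s) with <", min_obs_frac * 100,
            "% observed values: ",
            paste(rownames(m)[obs < min_obs_frac], collapse = ", "))
    m <- m[obs >= min_obs_frac, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 2L) stop("value error: need >= 2 items to cluster")
  d <- item_distances(m, distance)
  # active cluster bookkeeping: id < 0 -> singleton -i, id > 0 -> merge row
  active <- as.list(-seq_len(n))       # member item indices are tracked below
  members <- lapply(seq_len(n), identity)
  cd <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  ids <- -seq_len(n)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    best <- c(NA_integer_, NA_integer_); bd <- Inf; bkey <- c(Inf, Inf)
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      dij <- cd[i, j]
      key <- sort(c(min(members[[i]]), min(members[[j]])))
      if (dij < bd - 1e-12 ||
          (abs(dij - bd) <= 1e-12 &&
           (key[1] < bkey[1] || (key[1] == bkey[1] && key[2] < bkey[2])))) {
        bd <- dij; best <- c(i, j); bkey <- key
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- bd
    ni <- length(members[[i]]); nj <- length(members[[j]])
    newrow <- vapply(seq_len(k), function(l) {
      if (l == i || l == j) return(NA_real_)
      switch(linkage,
             average = (ni * cd[i, l] + nj * cd[j, l]) / (ni + nj),
             complete = max(cd[i, l], cd[j, l]),
             single = min(cd[i, l], cd[j, l]))
    }, numeric(1))
    keep <- setdiff(seq_len(k), c(i, j))
    cd <- rbind(cbind(cd[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    ids <- c(ids[keep], step)
  }
  ord <- integer(0)
  walk <- function(id) {
    if (id < 0L) ord <<- c(ord, -id)
    else { walk(merge[id, 1L]); walk(merge[id, 2L]) }
  }
  walk(n - 1L)
  structure(list(merge = merge, height = height, order = ord,
                 labels = rownames(m),
                 method = linkage, dist.method = distance,
                 call = match.call()),
            class = "hclust")
}

#' Expression similarity of duplicate gene pairs
#'
#' Pearson correlation of the two genes' expression profiles across tissues
#' (pairwise-complete).  A pair is `similar` when `r >= r_threshold`,
#' `divergent` otherwise, and `undeterminable` with fewer than 3 shared
#' observed tissues.
#'
#' @param mat expression matrix (genes x tissues).
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param r_threshold similarity threshold on Pearson r (default 0.8).
#' @return data.frame `gene_a`, `gene_b`, `r`, `call`.
#' @export
pair_expression_similarity <- function(mat, pairs, r_threshold = 0.8) {
  missing <- setdiff(c(pairs$gene_a, pairs$gene_b), rownames(mat))
  if (length(missing) > 0L)
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- mat[pairs$gene_a[k], ]; b <- mat[pairs$gene_b[k], ]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3L)
      return(data.frame(r = NA_real_, call = "undeterminable"))
    r <- stats::cor(a[ok], b[ok])
    data.frame(r = r, call = if (!is.na(r) && r >= r_threshold) "similar"
               else "divergent")
  })
  cbind(pairs[, c("gene_a", "gene_b")], do.call(rbind, res))
}

#' Construct and validate a qPCR Ct table
#'
#' @param df data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @param reference_gene housekeeping gene used for normalization (must be
#'   measured in every sample).
#' @param calibrator_sample default calibrator for [ddct()].
#' @return the validated data.frame with attributes `reference_gene` and
#'   `calibrator_sample`, class `qpcr_table`.
#' @export
qpcr_table <- function(df, reference_gene, calibrator_sample = NULL) {
  need <- c("sample", "gene", "replicate", "ct")
  stopifnot(all(need %in% names(df)))
  if (any(df$ct <= 0)) stop("validation error: Ct values must be positive")
  samples <- unique(df$sample)
  ref_samples <- unique(df$sample[df$gene == reference_gene])
  if (!all(samples %in% ref_samples))
    stop("validation error: reference gene '", reference_gene,
         "' not measured in sample(s): ",
         paste(setdiff(samples, ref_samples), collapse = ", "))
  structure(df, reference_gene = reference_gene,
            calibrator_sample = calibrator_sample, class = c("qpcr_table",
                                                             "data.frame"))
}

#' Relative expression by the comparative-Ct method (2^-ddCt)
#'
#' Ct replicates are averaged per (sample, gene) first; then
#' `dCt(s) = Ct(target, s) - Ct(reference, s)`,
#' `ddCt = dCt(sample) - dCt(calibrator)`, and the relative expression is
#' `2^-ddCt`.  Per-replicate values (each target replicate against the mean
#' reference Ct) are returned for error bars.
#'
#' @param table a [qpcr_table()].
#' @param target_gene gene to quantify.
#' @param sample sample of interest.
#' @param calibrator calibrator sample; defaults to the table's
#'   `calibrator_sample` attribute.
#' @return list with `relative_expression`, `ddct`, `dct_sample`,
#'   `dct_calibrator` and `per_replicate` (vector of 2^-ddCt values, one
#'   per target replicate in `sample`).
#' @export
ddct <- function(table, target_gene, sample,
                 calibrator = attr(table, "calibrator_sample")) {
  ref <- attr(table, "reference_gene")
  if (is.null(ref)) stop("table must be a qpcr_table()")
  if (is.null(calibrator)) stop("value error: no calibrator sample given")
  mean_ct <- function(gene, smp) {
    x <- table$ct[table$gene == gene & table$sample == smp]
    if (length(x) == 0L)
      stop("value error: no Ct for gene '", gene, "' in sample '", smp, "'")
    mean(x)
  }
  dct_s <- mean_ct(target_gene, sample) - mean_ct(ref, sample)
  dct_c <- mean_ct(target_gene, calibrator) - mean_ct(ref, calibrator)
  dd <- dct_s - dct_c
  reps <- table$ct[table$gene == target_gene & table$sample == sample]
  per_rep <- 2^-((reps - mean_ct(ref, sample)) - dct_c)
  list(relative_expression = 2^-dd, ddct = dd,
       dct_sample = dct_s, dct_calibrator = dct_c,
       per_replicate = per_rep)
}
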