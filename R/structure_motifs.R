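# Exon-intron structure statistics and motif-occurrence matrices with
# subfamily-specific motif detection.

#' Intron-count statistics over a gene set
#'
#' Counts introns of each gene's representative transcript (number of exons
#' minus one) and tabulates the histogram with percentages.
#'
#' @param models named list of [gene_model()]s.
#' @param representative optional named character vector gene -> transcript
#'   id; default: the first transcript of each gene.
#' @return list with `counts` (named integer vector, intron count ->
#'   genes), `percent` (to 2 decimals), `n_genes`, and `per_gene` (named
#'   integer vector of intron counts).
#' @export
intron_statistics <- function(models, representative = NULL) {
  per_gene <- vapply(models, function(gm) {
    tid <- if (!is.null(representative)) representative[[gm$gene_id]] else
      names(gm$transcripts)[1L]
    if (is.null(tid) || is.na(tid) || !tid %in% names(gm$transcripts))
      stop("lookup error: no representative transcript for gene '",
           gm$gene_id, "'")
    nrow(gm$transcripts[[tid]]) - 1L
  }, integer(1))
  tab <- table(per_gene)
  counts <- stats::setNames(as.integer(tab), names(tab))
  list(counts = counts,
       percent = stats::setNames(round(counts / length(per_gene) * 100, 2),
                                 names(counts)),
       n_genes = length(per_gene),
       per_gene = per_gene)
}

#' Build a motif presence/occurrence matrix
#'
#' @param occurrences motif occurrence table (see [read_motif_tsv()]).
#' @param genes character vector of all gene ids (rows of the matrix; genes
#'   with no occurrence get all-absent rows).
#' @param n_motifs number of motif columns; default the largest observed id.
#' @return list with `presence` (logical genes x motifs matrix, columns
#'   `motif1..motifM`), `counts` (integer occurrence counts), `ordered`
#'   (named character vector: per gene, motif ids sorted by start position,
#'   comma-separated as `"m15,m3"`), and the `occurrences` table.
#' @export
build_motif_matrix <- function(occurrences, genes,
                               n_motifs = max(1L, occurrences$motif_id)) {
  unknown <- setdiff(occurrences$gene, genes)
  if (length(unknown) > 0L)
    stop("validation error: occurrence(s) for unknown gene(s): ",
         paste(unique(unknown), collapse = ", "))
  m <- length(genes)
  counts <- matrix(0L, m, n_motifs,
                   dimnames = list(genes, paste0("motif", seq_len(n_motifs))))
  if (nrow(occurrences) > 0L) {
    tab <- table(factor(occurrences$gene, levels = genes),
                 factor(occurrences$motif_id, levels = seq_len(n_motifs)))
    counts[] <- as.integer(tab)
  }
  ordered <- vapply(genes, function(g) {
    occ <- occurrences[occurrences$gene == g, , drop = FALSE]
    if (nrow(occ) == 0L) return("")
    paste(paste0("m", occ$motif_id[order(occ$start)]), collapse = ",")
  }, "")
  list(presence = counts > 0L, counts = counts, ordered = ordered,
       occurrences = occurrences)
}

#' Subfamily-specific motifs
#'
#' A motif is specific to a subfamily when its presence rate within the
#' subfamily is at least `in_frac` and its presence rate outside is at most
#' `out_frac`.  Empty subfamilies are skipped with a warning.
#'
#' @param matrix motif matrix from [build_motif_matrix()].
#' @param assignment named character vector gene -> subfamily label covering
#'   every gene in the matrix.
#' @param in_frac,out_frac specificity thresholds (defaults 0.7 / 0.2).
#' @return named list: subfamily -> integer vector of specific motif ids.
#' @export
subfamily_specific_motifs <- function(matrix, assignment, in_frac = 0.7,
                                      out_frac = 0.2) {
  pres <- matrix$presence
  genes <- rownames(pres)
  if (any(!genes %in% names(assignment)))
    stop("every gene in the matrix needs a subfamily label")
  labels <- assignment[genes]
  out <- list()
  for (s in sort(unique(labels))) {
    inside <- pres[labels == s, , drop = FALSE]
    outside <- pres[labels != s, , drop = FALSE]
    if (nrow(inside) == 0L) {
      warning("empty subfamily '", s, "' skipped")
      next
    }
    rate_in <- colMeans(inside)
    rate_out <- if (nrow(outside) > 0L) colMeans(outside) else
      rep(0, ncol(pres))
    hit <- which(rate_in >= in_frac & rate_out <= out_frac)
    out[[s]] <- as.integer(sub("motif", "", colnames(pres)[hit]))
  }
  out
}
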