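# Paralog detection by the census' coverage/identity criteria: global
# pairwise protein alignment, strict >80%/>80% thresholds, collapsing of
# tightly linked events, tandem/segmental classification and chromosome
# distribution statistics.

#' Default alignment scoring
#'
#' BLOSUM62 with affine gaps: a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param matrix substitution matrix name (a matrix shipped with Biostrings).
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return list with elements `matrix`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function(matrix = "BLOSUM62", gap_open = 10,
                            gap_extend = 0.5) {
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (Biostrings).  Identity is the fraction of identical-residue columns
#' among columns where both sequences carry a residue; coverage is the
#' number of both-residue columns divided by the length of the longer input
#' sequence.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @param scoring see [default_scoring()].
#' @param id_a,id_b optional sequence ids carried through.
#' @return list of class `pairwise_alignment` with `id_a`, `id_b`,
#'   `aligned_a`, `aligned_b`, `score`, `identity`, `coverage`.
#' @export
global_align <- function(seq_a, seq_b, scoring = default_scoring(),
                         id_a = NA_character_, id_b = NA_character_) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("value error: empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  a <- as.character(Biostrings::alignedPattern(pa))
  b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  both <- ca != "-" & cb != "-"
  structure(list(
    id_a = id_a, id_b = id_b, aligned_a = a, aligned_b = b,
    score = Biostrings::score(pa),
    identity = if (any(both)) sum(ca[both] == cb[both]) / sum(both) else 0,
    coverage = sum(both) / max(nchar(seq_a), nchar(seq_b))),
    class = "pairwise_alignment")
}

# Tightly-linked groups: genes on the same chromosome are chained into one
# group when the gap between consecutive gene spans is <= window_bp.  The
# intervening-gene criterion is deliberately not used for grouping: among
# family genes alone every consecutive pair has zero intervening members,
# which would chain whole chromosomes.  Returns a group id per gene.
tight_linkage_groups <- function(census, window_bp, max_intervening) {
  group <- stats::setNames(seq_len(nrow(census)), census$gene_locus)
  for (chr in unique(census$chromosome)) {
    idx <- which(census$chromosome == chr)
    idx <- idx[order(census$start[idx])]
    if (length(idx) < 2L) next
    for (k in seq_len(length(idx) - 1L)) {
      gap <- census$start[idx[k + 1L]] - census$end[idx[k]]
      if (gap <= window_bp)
        group[idx[k + 1L]] <- group[idx[k]]
    }
  }
  group
}

#' Find duplicate gene pairs
#'
#' Implements the duplication criteria: a pair of genes is a candidate
#' duplication event when the global protein alignment covers more than
#' `cov_threshold` of the longer protein AND the aligned region's identity
#' exceeds `id_threshold` (both strictly greater).  Tightly linked genes
#' (same chromosome, gap `<= tandem_window_bp` or `<= tandem_max_intervening`
#' census genes between them) contribute a single duplication event: among
#' passing pairs falling within one linked group (or the same unordered
#' group pair), only the highest-identity pair is retained.
#'
#' Pairs whose length ratio already bounds coverage below the threshold are
#' skipped without alignment; this cannot change the result because
#' `coverage <= min(len)/max(len)`.
#'
#' @param census census data.frame with `gene_locus`, `chromosome`, `start`,
#'   `end`.
#' @param proteins per-locus representative records (`gene_locus`,
#'   `sequence`).
#' @param id_threshold,cov_threshold thresholds in (0,1); defaults 0.80.
#' @param tandem_window_bp,tandem_max_intervening tight-linkage parameters.
#' @param scoring see [default_scoring()].
#' @return data.frame with one row per duplication event: `gene_a`,
#'   `gene_b`, `identity`, `coverage`, `same_chromosome`, `gap_bp`
#'   (`NA` across chromosomes), `dup_class`; sorted by chromosome and
#'   position of `gene_a`.
#' @export
find_duplicate_pairs <- function(census, proteins,
                                 id_threshold = 0.80, cov_threshold = 0.80,
                                 tandem_window_bp = 200000L,
                                 tandem_max_intervening = 5L,
                                 scoring = default_scoring()) {
  stopifnot(id_threshold > 0, id_threshold < 1,
            cov_threshold > 0, cov_threshold < 1)
  seqs <- stats::setNames(proteins$sequence, proteins$gene_locus)
  loci <- sort(intersect(census$gene_locus, names(seqs)))
  census <- census[match(loci, census$gene_locus), , drop = FALSE]
  n <- length(loci)
  lens <- nchar(seqs[loci])
  rows <- list()
  # one vectorized alignment call per query keeps the scan fast; pairs whose
  # length ratio already bounds coverage below the threshold are skipped
  if (n >= 2L) for (i in seq_len(n - 1L)) {
    js <- seq(i + 1L, n)
    js <- js[pmin(lens[i], lens[js]) / pmax(lens[i], lens[js]) > cov_threshold]
    if (length(js) == 0L) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[loci[js]]), seqs[[loci[i]]],
      type = "global", substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    # nmatch/nmismatch count residue-residue columns only, so
    # both-residue columns = nmatch + nmismatch
    nm <- Biostrings::nmatch(pa)
    nmm <- Biostrings::nmismatch(pa)
    for (k in seq_along(js)) {
      j <- js[k]
      both <- nm[k] + nmm[k]
      identity <- if (both > 0L) nm[k] / both else 0
      coverage <- both / max(lens[i], lens[j])
      if (identity > id_threshold && coverage > cov_threshold)
        rows[[length(rows) + 1L]] <-
          data.frame(gene_a = loci[i], gene_b = loci[j],
                     identity = identity, coverage = coverage,
                     stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      same_chromosome = logical(0), gap_bp = integer(0),
                      dup_class = character(0)))
  pairs <- do.call(rbind, rows)
  # one event per tightly-linked group pair, keeping the highest identity
  grp <- tight_linkage_groups(census, tandem_window_bp, tandem_max_intervening)
  gkey <- apply(cbind(grp[pairs$gene_a], grp[pairs$gene_b]), 1L,
                function(g) paste(sort(g), collapse = "_"))
  keep <- unlist(lapply(split(seq_len(nrow(pairs)), gkey), function(ii)
    ii[which.max(pairs$identity[ii])]), use.names = FALSE)
  pairs <- pairs[keep, , drop = FALSE]
  pos <- census[match(pairs$gene_a, census$gene_locus), ]
  posb <- census[match(pairs$gene_b, census$gene_locus), ]
  pairs$same_chromosome <- pos$chromosome == posb$chromosome
  pairs$gap_bp <- ifelse(pairs$same_chromosome,
                         pmax(0L, pmax(pos$start, posb$start) -
                                pmin(pos$end, posb$end) - 1L),
                         NA_integer_)
  pairs$dup_class <- vapply(seq_len(nrow(pairs)), function(k)
    classify_duplication(pairs[k, ], census, tandem_window_bp,
                         tandem_max_intervening), "")
  o <- order(pos$chromosome, pos$start)
  pairs <- pairs[o, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Classify a duplication event as tandem or segmental
#'
#' Tandem: both genes on the same chromosome and either the genomic gap
#' between their spans is `<= tandem_window_bp` or at most
#' `tandem_max_intervening` annotated genes lie between them.  Everything
#' else is segmental.
#'
#' @param pair list/row with `gene_a`, `gene_b`.
#' @param positions data.frame of annotated genes with `gene_locus`,
#'   `chromosome`, `start`, `end` (a census works).
#' @param tandem_window_bp,tandem_max_intervening classification parameters.
#' @return `"tandem"` or `"segmental"`.
#' @export
classify_duplication <- function(pair, positions, tandem_window_bp = 200000L,
                                 tandem_max_intervening = 5L) {
  ia <- match(pair$gene_a, positions$gene_locus)
  ib <- match(pair$gene_b, positions$gene_locus)
  if (is.na(ia) || is.na(ib))
    stop("lookup error: unmapped gene in pair ", pair$gene_a, "/", pair$gene_b)
  if (positions$chromosome[ia] != positions$chromosome[ib]) return("segmental")
  gap <- max(0L, max(positions$start[ia], positions$start[ib]) -
               min(positions$end[ia], positions$end[ib]) - 1L)
  lo <- min(positions$start[ia], positions$start[ib])
  hi <- max(positions$start[ia], positions$start[ib])
  between <- sum(positions$chromosome == positions$chromosome[ia] &
                   positions$start > lo & positions$start < hi) -
    0L  # endpoints excluded by strict inequalities
  if (gap <= tandem_window_bp || between <= tandem_max_intervening)
    "tandem" else "segmental"
}

#' Chromosome distribution of census genes
#'
#' @param census census data.frame.
#' @return data.frame with `chromosome`, `count`, `percent` (2 decimals),
#'   sorted by chromosome name.
#' @export
chromosome_distribution <- function(census) {
  stopifnot(nrow(census) >= 1L)
  tab <- table(census$chromosome)
  data.frame(chromosome = names(tab), count = as.integer(tab),
             percent = round(as.integer(tab) / nrow(census) * 100, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
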