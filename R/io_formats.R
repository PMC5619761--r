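# Readers/writers for the external formats the pipeline touches.
# Every coordinate crossing this API is 1-based inclusive (GFF3 convention).

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y","X")

#' Read a protein FASTA file
#'
#' Reads an amino-acid FASTA file and returns one record per sequence with a
#' gene locus derived from the sequence identifier.  The locus rule is a
#' regular expression stripped from the end of the protein id; the default
#' removes common transcript/protein suffixes such as `_P01`, `_T01`, `-T01`
#' or a trailing `.1`, so that splice variants of one gene share a locus.
#'
#' Sequences are uppercased and a single terminal `*` (stop) is removed.
#'
#' @param path path to a FASTA file (optionally gzipped).
#' @param locus_rule regular expression removed from the end of the protein
#'   id to obtain the gene locus.
#' @return a `data.frame` with columns `protein_id`, `gene_locus`,
#'   `sequence`, in file order.
#' @export
read_fasta <- function(path, locus_rule = "([_-][PT][0-9]+|\\.[0-9]+)$") {
  stopifnot(file.exists(path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: '", path, "' contains no records")
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate protein_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs)
  if (any(bad)) {
    off <- setdiff(unique(strsplit(paste(seqs[bad], collapse = ""), "")[[1]]),
                   AA_ALPHABET)
    stop("illegal residue character(s) [", paste(off, collapse = ""),
         "] in record(s): ", paste(ids[bad], collapse = ", "))
  }
  data.frame(protein_id = unname(ids),
             gene_locus = sub(locus_rule, "", unname(ids)),
             sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records data.frame with `protein_id` and `sequence` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("protein_id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$protein_id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Construct and validate a gene model
#'
#' A gene model is a gene span on a chromosome with one or more transcripts,
#' each an ordered list of exon intervals (1-based inclusive, sorted in
#' genome coordinates, non-overlapping).
#'
#' @param gene_id gene identifier.
#' @param chromosome chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive gene span.
#' @param transcripts named list; each element a two-column matrix of exon
#'   `start`, `end` coordinates.
#' @return a list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, start, end, transcripts) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"), start <= end,
            is.list(transcripts), length(transcripts) >= 1L)
  for (tid in names(transcripts)) {
    ex <- transcripts[[tid]]
    if (is.null(dim(ex)) || nrow(ex) < 1L)
      stop("transcript '", tid, "' of gene '", gene_id, "' has no exons")
    if (any(ex[, 1] > ex[, 2]))
      stop("exon with end < start in transcript '", tid, "'")
    if (any(ex[, 1] < start | ex[, 2] > end))
      stop("exon outside gene span in transcript '", tid, "'")
    o <- order(ex[, 1])
    ex <- ex[o, , drop = FALSE]
    if (nrow(ex) > 1L && any(ex[-1L, 1] <= ex[-nrow(ex), 2]))
      stop("overlapping exons in transcript '", tid, "' of gene '", gene_id, "'")
    colnames(ex) <- c("start", "end")
    transcripts[[tid]] <- ex
  }
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 transcripts = transcripts),
            class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA` and `exon` features linked by `ID`/`Parent`
#' attributes into one [gene_model()] per gene.  Coordinates are kept
#' 1-based inclusive as in GFF3.
#'
#' @param path path to a GFF3 file.
#' @return named list of `gene_model` objects (keyed by gene id), in file
#'   order of the gene features.
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("GFF3 format error: '", path, "' has no features")
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop("GFF3 format error: expected 9 tab-separated columns")
  f <- do.call(rbind, f)
  attr_field <- function(attrs, key) {
    pat <- paste0("(^|;)", key, "=[^;]*")
    out <- rep(NA_character_, length(attrs))
    hit <- grepl(pat, attrs)
    m <- regmatches(attrs[hit], regexpr(pat, attrs[hit]))
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  type <- f[, 3]; start <- as.integer(f[, 4]); end <- as.integer(f[, 5])
  if (any(is.na(start)) || any(is.na(end)) || any(end < start))
    stop("GFF3 validation error: feature with end < start or non-numeric coordinates")
  id <- attr_field(f[, 9], "ID")
  parent <- attr_field(f[, 9], "Parent")
  gi <- which(type == "gene"); mi <- which(type == "mRNA"); ei <- which(type == "exon")
  if (length(gi) == 0L) stop("GFF3 validation error: no gene features")
  mrna_gene <- parent[mi]
  if (any(is.na(id[mi]))) stop("GFF3 validation error: mRNA without ID")
  if (any(!mrna_gene %in% id[gi]))
    stop("GFF3 validation error: mRNA with Parent not matching any gene")
  exon_mrna <- parent[ei]
  if (any(!exon_mrna %in% id[mi]))
    stop("GFF3 validation error: exon with Parent not matching any mRNA: ",
         paste(unique(exon_mrna[!exon_mrna %in% id[mi]]), collapse = ", "))
  models <- list()
  for (g in gi) {
    gid <- id[g]
    mids <- mi[mrna_gene == gid]
    if (length(mids) == 0L)
      stop("GFF3 validation error: gene '", gid, "' has no mRNA")
    tr <- list()
    for (m in mids) {
      tid <- id[m]
      ex <- ei[exon_mrna == tid]
      if (length(ex) == 0L)
        stop("GFF3 validation error: mRNA '", tid, "' has no exons")
      tr[[tid]] <- cbind(start = start[ex], end = end[ex])[order(start[ex]), , drop = FALSE]
    }
    models[[gid]] <- gene_model(gid, f[g, 1], f[g, 7], start[g], end[g], tr)
  }
  models
}

#' Write gene models to a GFF3 file
#'
#' @param models named list of `gene_model` objects.
#' @param path output path.
#' @param source source column value.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, source = "grascensus") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gm in models) {
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       gm$chromosome, source, gm$start, gm$end, gm$strand,
                       gm$gene_id), con)
    for (tid in names(gm$transcripts)) {
      ex <- gm$transcripts[[tid]]
      writeLines(sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         gm$chromosome, source, min(ex[, 1]), max(ex[, 2]),
                         gm$strand, tid, gm$gene_id), con)
      for (i in seq_len(nrow(ex)))
        writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                           gm$chromosome, source, ex[i, 1], ex[i, 2],
                           gm$strand, tid, i, tid), con)
    }
  }
  invisible(path)
}

#' Intron intervals of a transcript
#'
#' @param model a `gene_model`.
#' @param transcript_id transcript id; default the first transcript.
#' @return two-column matrix of 1-based inclusive intron intervals (zero rows
#'   for single-exon transcripts).
#' @export
introns_of <- function(model, transcript_id = names(model$transcripts)[1L]) {
  ex <- model$transcripts[[transcript_id]]
  if (is.null(ex)) stop("unknown transcript '", transcript_id, "' for gene '",
                        model$gene_id, "'")
  if (nrow(ex) < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = ex[-nrow(ex), 2] + 1L, end = ex[-1L, 1] - 1L)
}

#' Read a HMMER per-domain table (domtblout dialect)
#'
#' Whitespace-delimited per-domain output; `#` lines are comments.  Only the
#' target name (column 1), query/model name (column 4), full-sequence
#' E-value (column 7) and alignment coordinates (columns 18-19) are used;
#' extra columns are ignored, which keeps the reader tolerant to minor HMMER
#' version differences.  No E-value filtering happens here.
#'
#' @param path path to a domtblout file.
#' @return data.frame with columns `protein_id`, `model_name`,
#'   `full_sequence_evalue`, `ali_from`, `ali_to`, in file order.
#' @export
read_domtbl <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep))
    return(data.frame(protein_id = character(0), model_name = character(0),
                      full_sequence_evalue = numeric(0),
                      ali_from = integer(0), ali_to = integer(0)))
  idx <- which(keep)
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  short <- lengths(parts) < 19L
  if (any(short))
    stop("domtbl validation error: line ", idx[short][1L],
         " has fewer than 19 columns")
  get <- function(k) vapply(parts, `[[`, "", k)
  ev <- suppressWarnings(as.numeric(get(7L)))
  if (anyNA(ev))
    stop("domtbl validation error: unparseable E-value at line ",
         idx[which(is.na(ev))[1L]])
  af <- suppressWarnings(as.integer(get(18L)))
  at <- suppressWarnings(as.integer(get(19L)))
  if (anyNA(af) || anyNA(at))
    stop("domtbl validation error: unparseable alignment coordinate at line ",
         idx[which(is.na(af) | is.na(at))[1L]])
  data.frame(protein_id = get(1L), model_name = get(4L),
             full_sequence_evalue = ev, ali_from = af, ali_to = at,
             stringsAsFactors = FALSE)
}

#' Write domain hits in the per-domain table dialect
#'
#' @param hits data.frame as returned by [read_domtbl()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domtbl <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
               "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
             con)
  for (i in seq_len(nrow(hits))) {
    writeLines(sprintf("%-20s -          %5d %-20s PF03514.11 %5d %9.3g %6.1f %5.1f %3d %3d %9.3g %9.3g %6.1f %5.1f %5d %5d %5d %5d %5d %5d 0.99 -",
                       hits$protein_id[i], hits$ali_to[i], hits$model_name[i],
                       380L, hits$full_sequence_evalue[i], 250.0, 0.1, 1L, 1L,
                       hits$full_sequence_evalue[i], hits$full_sequence_evalue[i],
                       250.0, 0.1, 1L, 380L, hits$ali_from[i], hits$ali_to[i],
                       hits$ali_from[i], hits$ali_to[i]), con)
  }
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are printed with 6 decimals and internal-node bootstrap
#' supports (if present as `node.label`) as integer labels.  Leaf names
#' containing characters forbidden in Newick (`(`, `)`, `,`, `:`, `;`,
#' whitespace) are sanitized to `_` rather than quoted, for maximal
#' downstream-tool compatibility.
#'
#' @param tree an [ape::phylo] tree with >= 2 leaves.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 2L)
  tree$tip.label <- gsub("[(),:;[:space:]]", "_", tree$tip.label)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- tree$edge.length
  edge_of <- integer(max(tree$edge))
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  lab <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    nl <- tree$node.label[node - ntip]
    if (is.null(nl) || is.na(nl) || !nzchar(nl)) "" else
      as.character(as.integer(round(as.numeric(nl))))
  }
  rec <- function(node) {
    if (node <= ntip) return(lab(node))
    inner <- vapply(kids[[as.character(node)]], function(ch) {
      bl <- if (is.null(elen)) "" else sprintf(":%.6f", elen[edge_of[ch]])
      paste0(rec(ch), bl)
    }, "")
    paste0("(", paste(inner, collapse = ","), ")", lab(node))
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1L]
  writeLines(paste0(rec(root), ";"), path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Read an expression matrix TSV
#'
#' First row holds tissue names, first column gene ids; the body is numeric
#' with empty cells read as `NA`.
#'
#' @param path path to a TSV file.
#' @return numeric matrix (genes x tissues) with dimnames.
#' @export
read_expression_tsv <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(raw) < 2L) stop("expression table needs a gene column and >=1 tissue")
  genes <- raw[[1L]]
  if (anyDuplicated(genes))
    stop("validation error: duplicated gene id row(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  body[body == ""] <- NA_character_
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("validation error: non-numeric cell at gene '", genes[bad[1L, 1]],
         "', tissue '", colnames(body)[bad[1L, 2]], "'")
  dimnames(vals) <- list(genes, colnames(raw)[-1L])
  vals
}

#' Write an expression matrix TSV
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param gene_col name for the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path, gene_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1L] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif-occurrence table
#'
#' TSV with columns `gene` (or `protein_id`), `motif_id`, `start`, `end`,
#' `p_value`; 1-based inclusive coordinates on the protein.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns `gene`, `motif_id`, `start`, `end`,
#'   `p_value`.
#' @export
read_motif_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("protein_id" %in% names(df) && !"gene" %in% names(df))
    names(df)[names(df) == "protein_id"] <- "gene"
  need <- c("gene", "motif_id", "start", "end", "p_value")
  if (!all(need %in% names(df)))
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  if (any(df$start > df$end)) stop("motif occurrence with end < start")
  if (any(df$motif_id < 1L)) stop("motif_id must be >= 1")
  if (any(df$p_value <= 0 | df$p_value > 1)) stop("p_value must be in (0,1]")
  df[need]
}
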