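# Family-member nomination, splice-variant collapsing and the Table-1-style
# census: per-gene length, molecular weight, isoelectric point, coordinates.

# Average (isotope-averaged) residue masses in Daltons, i.e. the free amino
# acid minus one water; summing residues and adding back 18.01524 Da gives
# the average mass of the unmodified peptide.
RESIDUE_MASS_DA <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

WATER_MASS_DA <- 18.01524

#' Default pKa set for isoelectric-point calculation
#'
#' EMBOSS-style pKa values for the ionizable groups considered by
#' [protein_pi()]: the two termini, the basic side chains (K, R, H) and the
#' acidic side chains (D, E, C, Y).
#'
#' @return named numeric vector with elements `Nterm`, `Cterm`, `K`, `R`,
#'   `H`, `D`, `E`, `C`, `Y`.
#' @export
pka_emboss <- function() {
  c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
    D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
}

#' Nominate family members from domain hits
#'
#' Returns the ids of proteins with at least one domain hit at or below the
#' full-sequence E-value cutoff (set semantics: a protein with several
#' passing hits appears once).  The comparison is `<=` the cutoff.
#'
#' @param hits data.frame of domain hits (see [read_domtbl()]).
#' @param evalue_cutoff positive E-value cutoff; default `1e-5`.
#' @return character vector of unique passing protein ids, in first-hit order.
#' @export
filter_family_hits <- function(hits, evalue_cutoff = 1e-5) {
  stopifnot(is.numeric(evalue_cutoff), evalue_cutoff > 0)
  if (nrow(hits) == 0L) return(character(0))
  unique(hits$protein_id[hits$full_sequence_evalue <= evalue_cutoff])
}

#' Collapse transcripts to gene loci
#'
#' Groups member proteins by gene locus and keeps one representative per
#' locus: the longest protein, with ties broken by the lexicographically
#' smallest protein id.  The number of member proteins at the locus is
#' recorded as the number of splice forms.
#'
#' @param members character vector of member protein ids.
#' @param records protein records (see [read_fasta()]); must contain every
#'   member.
#' @return data.frame with one row per locus (sorted by `gene_locus`):
#'   `gene_locus`, `protein_id` (representative), `sequence`,
#'   `n_splice_forms`.
#' @export
collapse_to_genes <- function(members, records) {
  missing <- setdiff(members, records$protein_id)
  if (length(missing) > 0L)
    stop("lookup error: member protein(s) absent from records: ",
         paste(missing, collapse = ", "))
  sub <- records[records$protein_id %in% members, , drop = FALSE]
  sub <- sub[order(sub$gene_locus, -nchar(sub$sequence), sub$protein_id), ]
  first <- !duplicated(sub$gene_locus)
  out <- sub[first, c("gene_locus", "protein_id", "sequence")]
  out$n_splice_forms <- as.integer(table(sub$gene_locus)[out$gene_locus])
  rownames(out) <- NULL
  out
}

#' Average molecular weight of a protein, in Daltons
#'
#' Sum of average residue masses plus one water (18.01524 Da).  The ambiguity
#' code `X` has no defined mass and is rejected.
#'
#' @param sequence amino-acid string (20 canonical letters).
#' @return molecular weight in Da.
#' @export
protein_mw <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("value error: empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1L]]
  if (any(!aa %in% names(RESIDUE_MASS_DA)))
    stop("value error: sequence contains residue(s) without defined mass: ",
         paste(unique(aa[!aa %in% names(RESIDUE_MASS_DA)]), collapse = ""))
  sum(RESIDUE_MASS_DA[aa]) + WATER_MASS_DA
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch model: basic groups (N-terminus, K, R, H) contribute
#' `1/(1 + 10^(pH - pKa))`, acidic groups (C-terminus, D, E, C, Y) contribute
#' `-1/(1 + 10^(pKa - pH))`.
#'
#' @param sequence amino-acid string; `X` is ignored (non-ionizable).
#' @param ph pH value.
#' @param pka named pKa vector, see [pka_emboss()].
#' @return net charge (elementary charges).
#' @export
protein_net_charge <- function(sequence, ph, pka = pka_emboss()) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  n <- table(factor(aa, levels = c("K", "R", "H", "D", "E", "C", "Y")))
  basic <- c(pka["Nterm"], rep(pka["K"], n["K"]), rep(pka["R"], n["R"]),
             rep(pka["H"], n["H"]))
  acidic <- c(pka["Cterm"], rep(pka["D"], n["D"]), rep(pka["E"], n["E"]),
              rep(pka["C"], n["C"]), rep(pka["Y"], n["Y"]))
  sum(1 / (1 + 10^(ph - basic))) - sum(1 / (1 + 10^(acidic - ph)))
}

#' Theoretical isoelectric point of a protein
#'
#' The pH at which the modeled net charge is zero, found by bisection on
#' `[0, 14]` until `|charge| < 1e-4` or 100 iterations.
#'
#' @inheritParams protein_net_charge
#' @return the isoelectric point (pH units).
#' @export
protein_pi <- function(sequence, pka = pka_emboss()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("value error: empty sequence")
  lo <- 0; hi <- 14
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    q <- protein_net_charge(sequence, mid, pka)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Build the family census
#'
#' One entry per gene locus, named `<prefix>1 ... <prefix>N` in ascending
#' locus order (the deterministic ordering used for family numbering), with
#' coordinates from the gene model and length/MW/pI from the representative
#' protein.  Proteins containing `X` keep their census row but get `NA`
#' MW/pI with a warning.
#'
#' @param genes per-locus representatives from [collapse_to_genes()].
#' @param models named list of [gene_model()]s keyed by locus; every locus
#'   must be present.
#' @param naming_prefix prefix for gene names, e.g. `"ZmGRAS"`.
#' @param pka pKa set for [protein_pi()].
#' @return data.frame with columns `gene_name`, `gene_locus`, `chromosome`,
#'   `start`, `end`, `length_aa`, `mw_da`, `pi`, `n_splice_forms`,
#'   `subgroup`.
#' @export
build_census <- function(genes, models, naming_prefix = "ZmGRAS",
                         pka = pka_emboss()) {
  missing <- setdiff(genes$gene_locus, names(models))
  if (length(missing) > 0L)
    stop("lookup error: locus without gene model: ",
         paste(missing, collapse = ", "))
  genes <- genes[order(genes$gene_locus), , drop = FALSE]
  n <- nrow(genes)
  mw <- pi_ <- rep(NA_real_, n)
  has_x <- grepl("X", genes$sequence, fixed = TRUE)
  if (any(has_x))
    warning("protein(s) containing X excluded from MW/pI: ",
            paste(genes$protein_id[has_x], collapse = ", "))
  for (i in which(!has_x)) {
    mw[i] <- protein_mw(genes$sequence[i])
    pi_[i] <- protein_pi(genes$sequence[i], pka)
  }
  gm <- models[genes$gene_locus]
  data.frame(
    gene_name = paste0(naming_prefix, seq_len(n)),
    gene_locus = genes$gene_locus,
    chromosome = vapply(gm, `[[`, "", "chromosome"),
    start = vapply(gm, `[[`, integer(1), "start"),
    end = vapply(gm, `[[`, integer(1), "end"),
    length_aa = nchar(genes$sequence),
    mw_da = mw,
    pi = pi_,
    n_splice_forms = genes$n_splice_forms,
    subgroup = NA_character_,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a census
#'
#' @param entries census data.frame (see [build_census()] or
#'   [table1_fixture()]).
#' @return list with `n_genes`, `per_chromosome_counts` (named integer),
#'   `per_chromosome_percent` (to 2 decimals), and `min`/`max`/`mean` for
#'   `length_aa`, `mw_da` and `pi` (NA values skipped).
#' @export
summarize_census <- function(entries) {
  if (!is.data.frame(entries) || nrow(entries) == 0L)
    stop("value error: empty census")
  counts <- table(entries$chromosome)
  stats <- lapply(c(length_aa = "length_aa", mw_da = "mw_da", pi = "pi"),
                  function(col) {
                    x <- entries[[col]][!is.na(entries[[col]])]
                    c(min = min(x), max = max(x), mean = mean(x))
                  })
  list(n_genes = nrow(entries),
       per_chromosome_counts = stats::setNames(as.integer(counts), names(counts)),
       per_chromosome_percent = stats::setNames(
         round(as.integer(counts) / nrow(entries) * 100, 2), names(counts)),
       length_aa = stats$length_aa, mw_da = stats$mw_da, pi = stats$pi)
}

#' Write a census TSV
#'
#' @param census census data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_census_tsv <- function(census, path) {
  utils::write.table(census, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
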