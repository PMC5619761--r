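# Planted-truth synthetic genome generator.  Emulates the study inputs --
# a proteome with a conserved C-terminal domain architecture (LHRI, VHIID,
# LHRII, PFYRE, SAW blocks), splice variants, decoys, domain-hit tables,
# gene models on chromosomes, motif tables, expression matrices and Ct
# tables -- with every planted fact recorded so each pipeline stage can be
# validated offline.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")

DEFAULT_SUBFAMILIES <- c(SCL3 = 10L, HAM = 10L, LS = 4L, SCR = 4L,
                         DELLA = 10L, SHR = 10L, PAT1 = 10L, LISCL = 28L)

#' Specification for a synthetic family genome
#'
#' The defaults mirror the magnitudes of the maize GRAS census this package
#' emulates: 86 genes over 8 subfamilies (LISCL the largest), 11 duplicate
#' pairs of which 9 share expression patterns, 80% intronless genes, 10
#' chromosomes, 13 tissues, and 18 loci with alternative splice forms (104
#' transcripts in total).
#'
#' @param genes_per_subfamily named integer vector: subfamily label ->
#'   number of genes (duplicates included).
#' @param n_duplicate_pairs planted duplicate pairs (default 11).
#' @param duplicate_identity_target protein identity of planted pairs
#'   (default 0.92).
#' @param background_max_identity calibration ceiling for the identity of
#'   unrelated same-subfamily proteins (default 0.5); must be below the
#'   duplicate identity target.
#' @param n_tandem_pairs how many duplicate pairs are placed adjacently on
#'   one chromosome (tandem); the rest go to different chromosomes
#'   (segmental).
#' @param intronless_fraction fraction of genes without introns (default
#'   0.80).
#' @param n_chromosomes,n_tissues genome and expression dimensions.
#' @param n_similar_pairs duplicate pairs sharing an expression archetype
#'   (default 9; must be <= `n_duplicate_pairs`).
#' @param n_alt_splice_loci loci that receive one extra splice form.
#' @param n_decoys non-family decoy proteins in the proteome.
#' @param n_anchors_per_subfamily reference-species anchor proteins emitted
#'   per subfamily for subfamily assignment.
#' @param seed mandatory integer seed; all outputs are reproducible
#'   bit-for-bit from (spec, seed).
#' @return list of class `synthetic_family_spec`.
#' @export
synthetic_family_spec <- function(genes_per_subfamily = DEFAULT_SUBFAMILIES,
                                  n_duplicate_pairs = 11L,
                                  duplicate_identity_target = 0.92,
                                  background_max_identity = 0.5,
                                  n_tandem_pairs = 3L,
                                  intronless_fraction = 0.80,
                                  n_chromosomes = 10L,
                                  n_tissues = 13L,
                                  n_similar_pairs = 9L,
                                  n_alt_splice_loci = 18L,
                                  n_decoys = 40L,
                                  n_anchors_per_subfamily = 2L,
                                  seed) {
  if (missing(seed)) stop("value error: seed is mandatory")
  stopifnot(!is.null(names(genes_per_subfamily)),
            all(genes_per_subfamily >= 1L),
            n_similar_pairs <= n_duplicate_pairs,
            intronless_fraction >= 0, intronless_fraction <= 1,
            duplicate_identity_target > 0, duplicate_identity_target <= 1,
            background_max_identity > 0, background_max_identity < 1,
            n_tandem_pairs <= n_duplicate_pairs)
  if (duplicate_identity_target <= background_max_identity)
    stop("value error: infeasible spec: duplicate identity target must ",
         "exceed the background identity ceiling")
  structure(list(genes_per_subfamily = genes_per_subfamily,
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 duplicate_identity_target = duplicate_identity_target,
                 background_max_identity = background_max_identity,
                 n_tandem_pairs = as.integer(n_tandem_pairs),
                 intronless_fraction = intronless_fraction,
                 n_chromosomes = as.integer(n_chromosomes),
                 n_tissues = as.integer(n_tissues),
                 n_similar_pairs = as.integer(n_similar_pairs),
                 n_alt_splice_loci = as.integer(n_alt_splice_loci),
                 n_decoys = as.integer(n_decoys),
                 n_anchors_per_subfamily = as.integer(n_anchors_per_subfamily),
                 seed = as.integer(seed)),
            class = "synthetic_family_spec")
}

random_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Substitute a fraction of sites, drawing replacements uniformly from the 19
# alternative residues (no indels: keeps planted identities analytic).
mutate_seq <- function(seq, rate) {
  aa <- strsplit(seq, "")[[1L]]
  k <- round(length(aa) * rate)
  if (k == 0L) return(seq)
  pos <- sample.int(length(aa), k)
  aa[pos] <- vapply(aa[pos], function(x) sample(setdiff(AA20, x), 1L), "")
  paste(aa, collapse = "")
}

#' Generate a synthetic gene family
#'
#' Each family protein is a subfamily-specific N-terminal block followed by
#' the shared ordered C-terminal blocks (LHRI, VHIID, LHRII, PFYRE, SAW
#' analogs), with per-subfamily divergence of the shared blocks and
#' per-gene substitutions calibrated so that unrelated proteins stay near
#' the configured background identity.  Duplicate genes are copies of a
#' source gene substituted to the identity target.  Genes are laid out on
#' chromosomes with tandem pairs adjacent (small gaps) and segmental pairs
#' on different chromosomes; intergenic gaps are drawn log-uniform with a
#' floor above the default tandem window so only planted tandems are
#' tightly linked.  Alternative splice forms are N-terminal-truncated
#' copies.  Domain-hit rows carry passing E-values (1e-30..1e-6) for family
#' transcripts and failing ones (1e-4..1) for decoys.  Three motif ids (15,
#' 16, 17) are emitted only in the designated largest subfamily.
#'
#' @param spec a [synthetic_family_spec()].
#' @return list with `proteins` (all transcripts + decoys, FASTA-ready),
#'   `models` (named list of [gene_model()]), `hits` (domain-hit table),
#'   `motifs` (motif occurrence table), `anchors` (records with `label`
#'   column), and `truth` (planted facts: `subfamily`, `duplicate_pairs`,
#'   `intron_counts`, `specific_motifs`, `alt_splice_loci`, `anchor_labels`).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "synthetic_family_spec"))
  set.seed(spec$seed)
  subs <- names(spec$genes_per_subfamily)
  n_genes <- sum(spec$genes_per_subfamily)
  n_len <- 120L
  c_lens <- c(LHRI = 30L, VHIID = 30L, LHRII = 30L, PFYRE = 40L, SAW = 40L)
  s_div <- 0.10                                   # subfamily divergence of shared blocks
  m_rate <- 1 - sqrt(spec$background_max_identity) # per-gene substitution rate
  c_base <- lapply(c_lens, random_seq)
  consensus <- lapply(subs, function(s) {
    nb <- random_seq(n_len)
    cb <- vapply(c_base, mutate_seq, "", rate = s_div)
    paste0(nb, paste(cb, collapse = ""))
  })
  names(consensus) <- subs

  # base genes per subfamily (duplicates replace the last genes of their
  # subfamily so totals match genes_per_subfamily)
  dup_quota <- integer(length(subs)); names(dup_quota) <- subs
  bigger <- order(spec$genes_per_subfamily, decreasing = TRUE)
  k <- spec$n_duplicate_pairs
  i <- 1L
  while (k > 0L) {                     # spread pairs over the larger subfamilies
    s <- subs[bigger[(i - 1L) %% length(subs) + 1L]]
    if (spec$genes_per_subfamily[s] >= 2L * (dup_quota[s] + 1L)) {
      dup_quota[s] <- dup_quota[s] + 1L
      k <- k - 1L
    }
    i <- i + 1L
    if (i > 1000L) stop("value error: cannot place duplicate pairs in spec")
  }
  loci <- character(0); seqs <- character(0); subfam <- character(0)
  dup_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                          dup_class = character(0), stringsAsFactors = FALSE)
  idx <- 0L
  for (s in subs) {
    n_s <- spec$genes_per_subfamily[[s]]
    n_dup <- dup_quota[[s]]
    n_base <- n_s - n_dup
    base_seqs <- vapply(seq_len(n_base), function(i)
      mutate_seq(consensus[[s]], m_rate), "")
    base_ids <- sprintf("SYNGRAS%03d", idx + seq_len(n_base))
    idx <- idx + n_base
    dup_src <- if (n_dup > 0L) sample.int(n_base, n_dup) else integer(0)
    dup_seqs <- vapply(dup_src, function(i)
      mutate_seq(base_seqs[i], 1 - spec$duplicate_identity_target), "")
    dup_ids <- if (n_dup > 0L) sprintf("SYNGRAS%03d", idx + seq_len(n_dup))
    else character(0)
    idx <- idx + n_dup
    loci <- c(loci, base_ids, dup_ids)
    seqs <- c(seqs, base_seqs, dup_seqs)
    subfam <- c(subfam, rep(s, n_s))
    if (n_dup > 0L)
      dup_pairs <- rbind(dup_pairs,
                         data.frame(gene_a = base_ids[dup_src],
                                    gene_b = dup_ids,
                                    dup_class = NA_character_,
                                    stringsAsFactors = FALSE))
  }
  names(seqs) <- loci
  truth_subfam <- stats::setNames(subfam, loci)

  # tandem/segmental assignment of planted pairs
  n_pairs <- nrow(dup_pairs)
  tandem <- seq_len(n_pairs) <= spec$n_tandem_pairs
  dup_pairs$dup_class <- ifelse(tandem, "tandem", "segmental")

  # chromosome layout: queue of (chromosome, gap-class) slots
  chrom_of <- stats::setNames(rep(NA_character_, n_genes), loci)
  for (k in seq_len(n_pairs)) {
    if (dup_pairs$dup_class[k] == "tandem") {
      chr <- sprintf("chr%d", sample.int(spec$n_chromosomes, 1L))
      chrom_of[c(dup_pairs$gene_a[k], dup_pairs$gene_b[k])] <- chr
    } else {
      two <- sample.int(spec$n_chromosomes, 2L)
      chrom_of[dup_pairs$gene_a[k]] <- sprintf("chr%d", two[1L])
      chrom_of[dup_pairs$gene_b[k]] <- sprintf("chr%d", two[2L])
    }
  }
  rest <- is.na(chrom_of)
  chrom_of[rest] <- sprintf("chr%d", sample.int(spec$n_chromosomes,
                                                sum(rest), replace = TRUE))

  # intron counts (iid Bernoulli at the intronless fraction; genes with
  # introns draw 1..5 with the census' observed weighting)
  n_introns <- ifelse(stats::runif(n_genes) < spec$intronless_fraction, 0L,
                      sample(1:5, n_genes, replace = TRUE,
                             prob = c(9, 5, 2, 0, 1)))
  names(n_introns) <- loci

  # per-chromosome coordinates: tandem partners adjacent with small gaps,
  # everything else separated by gaps above the tight-linkage window
  tandem_partner <- stats::setNames(rep(NA_character_, n_genes), loci)
  tp <- dup_pairs[dup_pairs$dup_class == "tandem", , drop = FALSE]
  tandem_partner[tp$gene_a] <- tp$gene_b
  models <- list()
  truth_alt <- sample(loci, min(spec$n_alt_splice_loci, n_genes))
  proteins <- data.frame(protein_id = character(0), gene_locus = character(0),
                         sequence = character(0), stringsAsFactors = FALSE)
  for (chr in unique(chrom_of)) {
    members <- names(chrom_of)[chrom_of == chr]
    # keep tandem partners adjacent: partners are appended directly after
    # their source gene, never placed independently
    partners <- stats::na.omit(tandem_partner[members])
    ord <- character(0)
    for (g in sample(setdiff(members, partners))) {
      ord <- c(ord, g)
      p <- tandem_partner[[g]]
      if (!is.na(p) && p %in% members) ord <- c(ord, p)
    }
    pos <- 1L
    prev <- NULL
    for (g in ord) {
      gap <- if (!is.null(prev) && !is.na(tandem_partner[[prev]]) &&
                 tandem_partner[[prev]] == g)
        round(exp(stats::runif(1, log(5e3), log(5e4))))       # tandem gap
      else round(exp(stats::runif(1, log(2.5e5), log(2e6))))  # background gap
      pos <- pos + gap
      cds_len <- 3L * nchar(seqs[[g]]) + 3L
      ni <- n_introns[[g]]
      intron_lens <- if (ni > 0L) sample(100:2000, ni, replace = TRUE)
      else integer(0)
      cuts <- if (ni > 0L) sort(sample(seq_len(cds_len - 1L), ni)) else integer(0)
      exon_lens <- diff(c(0L, cuts, cds_len))
      starts <- pos + cumsum(c(0L, exon_lens[-length(exon_lens)] +
                                 intron_lens))
      ex <- cbind(start = as.integer(starts),
                  end = as.integer(starts + exon_lens - 1L))
      gene_end <- max(ex[, 2])
      tr <- stats::setNames(list(ex), paste0(g, "_T01"))
      if (g %in% truth_alt) {
        # extra splice form: keep a 5' subset of the CDS (shorter protein)
        keep_aa <- floor(nchar(seqs[[g]]) * stats::runif(1, 0.55, 0.85))
        keep_bp <- 3L * keep_aa
        ex2 <- ex
        cum <- cumsum(ex2[, 2] - ex2[, 1] + 1L)
        last <- which(cum >= keep_bp)[1L]
        ex2 <- ex2[seq_len(last), , drop = FALSE]
        ex2[last, 2] <- ex2[last, 1] + (keep_bp - c(0L, cum)[last]) - 1L
        tr[[paste0(g, "_T02")]] <- ex2
      }
      models[[g]] <- gene_model(g, chr, sample(c("+", "-"), 1L), pos,
                                gene_end, tr)
      pos <- gene_end
      prev <- g
    }
  }
  models <- models[loci]
  # transcript proteins (representative _P01 per locus + truncated _P02)
  for (g in loci) {
    proteins <- rbind(proteins,
                      data.frame(protein_id = paste0(g, "_P01"),
                                 gene_locus = g, sequence = seqs[[g]],
                                 stringsAsFactors = FALSE))
    if (g %in% truth_alt) {
      ex2 <- models[[g]]$transcripts[[paste0(g, "_T02")]]
      keep_aa <- sum(ex2[, 2] - ex2[, 1] + 1L) / 3L
      proteins <- rbind(proteins,
                        data.frame(protein_id = paste0(g, "_P02"),
                                   gene_locus = g,
                                   sequence = substr(seqs[[g]], 1L, keep_aa),
                                   stringsAsFactors = FALSE))
    }
  }
  decoys <- data.frame(protein_id = sprintf("DECOY%03d", seq_len(spec$n_decoys)),
                       gene_locus = sprintf("DECOY%03d", seq_len(spec$n_decoys)),
                       sequence = vapply(seq_len(spec$n_decoys), function(i)
                         random_seq(sample(150:500, 1L)), ""),
                       stringsAsFactors = FALSE)
  proteins <- rbind(proteins, decoys)

  # domain hits: members pass the 1e-5 cutoff comfortably, decoys fail
  fam_rows <- proteins$gene_locus %in% loci
  hits <- data.frame(
    protein_id = proteins$protein_id,
    model_name = "GRAS",
    full_sequence_evalue = ifelse(fam_rows,
                                  10^stats::runif(nrow(proteins), -30, -6),
                                  10^stats::runif(nrow(proteins), -4, 0)),
    ali_from = ifelse(fam_rows, n_len + 1L, 1L),
    ali_to = pmin(nchar(proteins$sequence),
                  ifelse(fam_rows, n_len + sum(c_lens), 100L)),
    stringsAsFactors = FALSE)

  # motifs: ubiquitous C-terminal motifs on every family gene, three motifs
  # private to the largest subfamily, the rest sprinkled at ~30%
  big_sub <- names(which.max(spec$genes_per_subfamily))
  ubiq <- c(1L, 2L, 3L, 4L, 5L, 6L, 9L, 11L)
  private <- c(15L, 16L, 17L)
  sprinkle <- setdiff(1:20, c(ubiq, private))
  mot <- list()
  for (g in loci) {
    off <- n_len
    width <- 20L
    for (m in ubiq) {
      mot[[length(mot) + 1L]] <- data.frame(
        gene = g, motif_id = m, start = off + 1L, end = off + width,
        p_value = 10^-stats::runif(1, 5, 50))
      off <- off + width
    }
    if (truth_subfam[[g]] == big_sub) {
      poff <- off
      for (m in private) {
        mot[[length(mot) + 1L]] <- data.frame(
          gene = g, motif_id = m, start = poff + 1L, end = poff + 15L,
          p_value = 10^-stats::runif(1, 5, 50))
        poff <- poff + 15L
      }
    }
    for (m in sprinkle) if (stats::runif(1) < 0.3) {
      st <- sample.int(n_len - 15L, 1L)
      mot[[length(mot) + 1L]] <- data.frame(
        gene = g, motif_id = m, start = st, end = st + 14L,
        p_value = 10^-stats::runif(1, 3, 20))
    }
  }
  motifs <- do.call(rbind, mot)

  # reference-species anchors per subfamily
  anchors <- do.call(rbind, lapply(subs, function(s) {
    data.frame(protein_id = sprintf("REF_%s_%d", s,
                                    seq_len(spec$n_anchors_per_subfamily)),
               gene_locus = sprintf("REF_%s_%d", s,
                                    seq_len(spec$n_anchors_per_subfamily)),
               sequence = vapply(seq_len(spec$n_anchors_per_subfamily),
                                 function(i) mutate_seq(consensus[[s]], m_rate),
                                 ""),
               label = s, stringsAsFactors = FALSE)
  }))

  list(proteins = proteins, models = models, hits = hits, motifs = motifs,
       anchors = anchors,
       truth = list(subfamily = truth_subfam,
                    duplicate_pairs = dup_pairs,
                    intron_counts = n_introns,
                    specific_motifs = list(subfamily = big_sub,
                                           motif_ids = private),
                    alt_splice_loci = sort(truth_alt),
                    anchor_labels = stats::setNames(anchors$label,
                                                    anchors$protein_id)))
}

#' Generate synthetic expression and qPCR data
#'
#' Subfamily-level tissue archetypes (three high-expression tissues each)
#' plus per-gene lognormal noise.  The first `n_similar_pairs` planted
#' duplicate pairs share their source gene's archetype (target correlation
#' r >= 0.9); the remaining pairs get an independent archetype.  The Ct
#' table follows `Ct = a - b log2(expr) + N(0, sd)` with 3 replicates and a
#' reference gene of constant expression.
#'
#' @param spec a [synthetic_family_spec()].
#' @param truth the `truth` element of [generate_family()].
#' @param ct_genes genes to include in the Ct table (default: all planted
#'   duplicate-pair members plus the planted-fold gene, the qPCR-validation
#'   analog); the reference gene `ACTIN` is always added.
#' @param a,b,noise_sd Ct model parameters (defaults 28, 1, 0.15).
#' @param planted_fold exact expression fold planted between
#'   `planted_fold_tissue` and the calibrator (first tissue) for one
#'   non-duplicate gene, so comparative-Ct recovery has a closed-form truth;
#'   default 4.  Set to `NULL` to disable.
#' @param planted_fold_tissue tissue carrying the planted fold (default the
#'   second tissue).
#' @return list with `expression` (matrix genes x tissues), `ct`
#'   (a [qpcr_table()], calibrator = first tissue), and
#'   `expression_clusters` (named archetype id per gene, the planted
#'   clustering truth).
#' @export
generate_expression <- function(spec, truth, ct_genes = NULL,
                                a = 28, b = 1, noise_sd = 0.15,
                                planted_fold = 4, planted_fold_tissue = 2L) {
  stopifnot(inherits(spec, "synthetic_family_spec"))
  set.seed(spec$seed + 1L)
  loci <- names(truth$subfamily)
  tissues <- paste0("tissue", seq_len(spec$n_tissues))
  subs <- unique(truth$subfamily)
  make_archetype <- function() {
    prof <- rep(1, spec$n_tissues)
    prof[sample.int(spec$n_tissues, 3L)] <- 8
    prof
  }
  archetypes <- lapply(subs, function(s) make_archetype())
  names(archetypes) <- subs
  cluster_of <- stats::setNames(truth$subfamily[loci], loci)
  dp <- truth$duplicate_pairs
  dissimilar <- dp[seq_len(nrow(dp)) > spec$n_similar_pairs, , drop = FALSE]
  for (k in seq_len(nrow(dissimilar))) {
    id <- paste0("private", k)
    archetypes[[id]] <- make_archetype()
    cluster_of[dissimilar$gene_b[k]] <- id
  }
  expr <- t(vapply(loci, function(g) {
    archetypes[[cluster_of[[g]]]] * exp(stats::rnorm(spec$n_tissues, 0, noise_sd))
  }, numeric(spec$n_tissues)))
  dimnames(expr) <- list(loci, tissues)

  fold_gene <- NULL
  if (!is.null(planted_fold)) {
    fold_gene <- setdiff(loci, c(dp$gene_a, dp$gene_b))[1L]
    expr[fold_gene, planted_fold_tissue] <- expr[fold_gene, 1L] * planted_fold
  }

  if (is.null(ct_genes))
    ct_genes <- unique(c(dp$gene_a, dp$gene_b, fold_gene))
  rows <- list()
  for (smp in tissues) {
    for (g in ct_genes) for (r in 1:3)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, gene = g, replicate = r,
        ct = a - b * log2(expr[g, smp]) + stats::rnorm(1, 0, noise_sd))
    for (r in 1:3)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, gene = "ACTIN", replicate = r,
        ct = 20 + stats::rnorm(1, 0, noise_sd))
  }
  ct <- qpcr_table(do.call(rbind, rows), reference_gene = "ACTIN",
                   calibrator_sample = tissues[1L])
  list(expression = expr, ct = ct,
       expression_clusters = cluster_of,
       planted_fold = if (is.null(planted_fold)) NULL else
         list(gene = fold_gene, tissue = tissues[planted_fold_tissue],
              fold = planted_fold))
}

#' Write a synthetic data set to disk
#'
#' Emits FASTA (family transcripts + decoys), anchors FASTA + label TSV,
#' GFF3, domain-hit table, motif TSV, expression TSV, Ct TSV and the truth
#' as JSON.
#'
#' @param fam result of [generate_family()].
#' @param expr result of [generate_expression()] (optional).
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_synthetic <- function(fam, expr = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(fam$proteins, p("proteome.fasta"))
  write_fasta(fam$anchors, p("anchors.fasta"))
  utils::write.table(fam$anchors[, c("protein_id", "label")],
                     p("anchors.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gff3(fam$models, p("genes.gff3"))
  write_domtbl(fam$hits, p("hits.domtbl"))
  utils::write.table(fam$motifs, p("motifs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- c(proteome = p("proteome.fasta"), anchors = p("anchors.fasta"),
           anchor_labels = p("anchors.tsv"), gff = p("genes.gff3"),
           domtbl = p("hits.domtbl"), motifs = p("motifs.tsv"))
  truth <- fam$truth
  if (!is.null(expr)) {
    write_expression_tsv(expr$expression, p("expression.tsv"))
    utils::write.table(as.data.frame(expr$ct), p("ct.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth$expression_clusters <- as.list(expr$expression_clusters)
    out <- c(out, expression = p("expression.tsv"), ct = p("ct.tsv"))
  }
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  out <- c(out, truth = p("truth.json"))
  invisible(out)
}
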