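# Pipeline orchestration: census -> phylogeny -> duplication ->
# structure/motifs -> expression -> qPCR, with a reproducibility manifest,
# plus the packaged census fixture.

TABLE1_MD5 <- "abc671c5b301d8efe663b1a3f0ac9a5e"

#' The packaged maize GRAS census fixture
#'
#' The 86-row characterization table of the maize GRAS family (gene name,
#' locus, chromosome coordinates, protein length, molecular weight,
#' isoelectric point, subgroup where published) shipped with the package.
#' Molecular weights are stored in Daltons as printed (the published table
#' header says kDa but the values are Daltons; the unit is kept as printed
#' and documented, not reinterpreted).
#'
#' @return data.frame with columns `gene_name`, `gene_locus`, `chromosome`,
#'   `start`, `end`, `length_aa`, `mw_da`, `pi`, `subgroup`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "maize_gras_table1.tsv",
                      package = "grascensus", mustWork = TRUE)
  if (unname(tools::md5sum(path)) != TABLE1_MD5)
    stop("packaging error: census fixture checksum mismatch")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  stopifnot(nrow(df) == 86L,
            identical(names(df), c("gene_name", "gene_locus", "chromosome",
                                   "start", "end", "length_aa", "mw_da",
                                   "pi", "subgroup")))
  df
}

#' Run the full census pipeline
#'
#' Runs every stage whose inputs are present in the configuration and
#' writes stage outputs plus a reproducibility manifest under
#' `config$out_dir`.  Stages with missing inputs are skipped cleanly.
#'
#' Configuration fields (paths unless noted): `fasta`, `gff`, `domtbl`,
#' `anchors` (TSV: `protein_id`, `label`), `aligned_fasta` (for the
#' phylogeny stage; sequences must be aligned), `motifs`, `expression`,
#' `ct` plus `ct_reference` and `ct_calibrator`; and parameters
#' `evalue_cutoff` (default 1e-5), `id_threshold`/`cov_threshold` (default
#' 0.80), `tandem_window_bp` (200 kb), `tandem_max_intervening` (5),
#' `bootstrap` (default 1000), `naming_prefix` (default "ZmGRAS"), `seed`
#' (default 1), `out_dir` (required).
#'
#' @param config named list, or path to a YAML file with these fields.
#' @return named list of stage outputs (also written to disk), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  defaults <- list(evalue_cutoff = 1e-5, id_threshold = 0.80,
                   cov_threshold = 0.80, tandem_window_bp = 200000L,
                   tandem_max_intervening = 5L, bootstrap = 1000L,
                   naming_prefix = "ZmGRAS", seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  stopifnot(config$evalue_cutoff > 0,
            config$id_threshold > 0, config$id_threshold < 1,
            config$cov_threshold > 0, config$cov_threshold < 1)
  inputs <- intersect(names(config),
                      c("fasta", "gff", "domtbl", "anchors", "aligned_fasta",
                        "motifs", "expression", "ct"))
  for (nm in inputs)
    if (!file.exists(config[[nm]]))
      stop("config validation error: input '", nm, "' does not exist: ",
           config[[nm]])
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  has <- function(...) all(c(...) %in% inputs)
  stage_dir <- function(s) {
    d <- file.path(out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  outputs <- list()
  log_stage <- function(s, msg) message("[", s, "] ", msg)

  census <- NULL; genes <- NULL; models <- NULL
  if (has("fasta", "gff", "domtbl")) {
    log_stage("census", "nominating family members")
    records <- read_fasta(config$fasta)
    models <- read_gff3(config$gff)
    hits <- read_domtbl(config$domtbl)
    members <- filter_family_hits(hits, config$evalue_cutoff)
    genes <- collapse_to_genes(members, records)
    census <- build_census(genes, models, config$naming_prefix)
    f <- file.path(stage_dir("census"), "census.tsv")
    write_census_tsv(census, f)
    summ <- summarize_census(census)
    jsonlite::write_json(summ, file.path(stage_dir("census"), "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs$census <- f
  } else log_stage("census", "skipped (needs fasta, gff, domtbl)")

  if (has("aligned_fasta", "anchors")) {
    log_stage("phylogeny", "building NJ tree with bootstrap")
    aln <- read_fasta(config$aligned_fasta, locus_rule = "$")
    anc <- utils::read.delim(config$anchors, stringsAsFactors = FALSE)
    anchors <- stats::setNames(anc$label, anc$protein_id)
    tree <- if (config$bootstrap >= 1L)
      bootstrap_support(aln, config$bootstrap, config$seed)
    else nj_tree(pairwise_distance_matrix(aln, "msa_pdist"))
    assign <- assign_subfamilies(tree, anchors)
    d <- stage_dir("phylogeny")
    write_newick(tree, file.path(d, "tree.nwk"))
    utils::write.table(data.frame(gene = names(assign), subfamily = assign),
                       file.path(d, "subfamilies.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs$phylogeny <- file.path(d, "tree.nwk")
  } else log_stage("phylogeny", "skipped (needs aligned_fasta, anchors)")

  if (!is.null(census)) {
    log_stage("duplication", "scanning for duplicate pairs")
    reps <- genes[, c("gene_locus", "sequence")]
    dupes <- find_duplicate_pairs(census, reps, config$id_threshold,
                                  config$cov_threshold,
                                  config$tandem_window_bp,
                                  config$tandem_max_intervening)
    d <- stage_dir("duplication")
    utils::write.table(dupes, file.path(d, "duplicate_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(chromosome_distribution(census),
                       file.path(d, "chromosome_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$duplication <- file.path(d, "duplicate_pairs.tsv")
  } else log_stage("duplication", "skipped (needs census)")

  if (!is.null(models) && !is.null(census)) {
    log_stage("structure", "computing exon-intron statistics")
    stats_ <- intron_statistics(models[census$gene_locus])
    d <- stage_dir("structure")
    utils::write.table(
      data.frame(n_introns = names(stats_$counts), count = stats_$counts,
                 percent = stats_$percent),
      file.path(d, "intron_histogram.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    outputs$structure <- file.path(d, "intron_histogram.tsv")
    if (has("motifs")) {
      occ <- read_motif_tsv(config$motifs)
      mm <- build_motif_matrix(occ, census$gene_locus)
      utils::write.table(
        data.frame(gene = rownames(mm$presence), mm$presence * 1L,
                   check.names = FALSE),
        file.path(d, "motif_matrix.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
  } else log_stage("structure", "skipped (needs gff and census)")

  if (has("expression")) {
    log_stage("expression", "clustering expression matrix")
    mat <- read_expression_tsv(config$expression)
    hc <- hierarchical_cluster(mat, "rows")
    d <- stage_dir("expression")
    write_expression_tsv(scale_rows(mat, "zscore")[hc$order, , drop = FALSE],
                         file.path(d, "scaled_clustered.tsv"))
    outputs$expression <- file.path(d, "scaled_clustered.tsv")
  } else log_stage("expression", "skipped (needs expression)")

  if (has("ct")) {
    log_stage("qpcr", "computing relative expression (2^-ddCt)")
    ctdf <- utils::read.delim(config$ct, stringsAsFactors = FALSE)
    qt <- qpcr_table(ctdf, config$ct_reference, config$ct_calibrator)
    targets <- setdiff(unique(ctdf$gene), config$ct_reference)
    samples <- unique(ctdf$sample)
    rel <- do.call(rbind, lapply(targets, function(g)
      data.frame(gene = g, sample = samples,
                 relative_expression = vapply(samples, function(s)
                   ddct(qt, g, s)$relative_expression, numeric(1)))))
    d <- stage_dir("qpcr")
    utils::write.table(rel, file.path(d, "relative_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$qpcr <- file.path(d, "relative_expression.tsv")
  } else log_stage("qpcr", "skipped (needs ct)")

  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    seed = config$seed,
    package_version = as.character(utils::packageVersion("grascensus")),
    input_checksums = as.list(vapply(inputs, function(nm)
      unname(tools::md5sum(config[[nm]])), "")),
    stage_outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outputs)
}
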