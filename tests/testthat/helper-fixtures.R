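# Shared fixtures built once per test run.  The default synthetic genome is
# the package's study-condition emulation (86 genes, 8 subfamilies, 11
# duplicate pairs of which 9 share expression, 80% intronless, 13 tissues).

default_spec <- function(seed = 42L) synthetic_family_spec(seed = seed)

.fixture_cache <- new.env(parent = emptyenv())

default_family <- function() {
  if (is.null(.fixture_cache$fam))
    .fixture_cache$fam <- generate_family(default_spec())
  .fixture_cache$fam
}

default_expression <- function() {
  if (is.null(.fixture_cache$expr))
    .fixture_cache$expr <- generate_expression(default_spec(),
                                               default_family()$truth)
  .fixture_cache$expr
}

default_census <- function() {
  if (is.null(.fixture_cache$census)) {
    fam <- default_family()
    members <- filter_family_hits(fam$hits)
    genes <- collapse_to_genes(members, fam$proteins)
    .fixture_cache$census <- list(genes = genes,
                                  census = build_census(genes, fam$models,
                                                        "SYN"))
  }
  .fixture_cache$census
}

# small in-code GFF3 fixture: one gene, one mRNA, three exons
write_three_exon_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t100\t900\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t100\t900\t.\t+\t.\tID=g1_T01;Parent=g1",
    "chr1\ttest\texon\t100\t200\t.\t+\t.\tID=e1;Parent=g1_T01",
    "chr1\ttest\texon\t301\t500\t.\t+\t.\tID=e2;Parent=g1_T01",
    "chr1\ttest\texon\t701\t900\t.\t+\t.\tID=e3;Parent=g1_T01"), path)
  path
}
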