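test_that("filter_family_hits applies the E-value cutoff inclusively", {
  hits <- data.frame(protein_id = c("a", "b", "c", "a"),
                     model_name = "GRAS",
                     full_sequence_evalue = c(1e-6, 1e-4, 1e-5, 1e-30),
                     ali_from = 1L, ali_to = 10L)
  kept <- filter_family_hits(hits, 1e-5)
  expect_setequal(kept, c("a", "c"))          # 1e-4 dropped, boundary kept
  expect_equal(sum(kept == "a"), 1L)          # set semantics
  expect_equal(filter_family_hits(hits[0, ]), character(0))
})

test_that("collapse_to_genes keeps the longest isoform and counts forms", {
  rec <- data.frame(protein_id = c("g1_P01", "g1_P02", "g2_P01"),
                    gene_locus = c("g1", "g1", "g2"),
                    sequence = c(strrep("A", 480), strrep("A", 500), "MKV"))
  out <- collapse_to_genes(rec$protein_id, rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$protein_id[out$gene_locus == "g1"], "g1_P02")
  expect_equal(out$n_splice_forms, c(2L, 1L))

  # tie broken by lexicographically smallest protein id
  rec2 <- data.frame(protein_id = c("g1_P02", "g1_P01"),
                     gene_locus = "g1", sequence = c("MKVA", "MKVC"))
  expect_equal(collapse_to_genes(rec2$protein_id, rec2)$protein_id, "g1_P01")

  expect_error(collapse_to_genes("missing", rec), "lookup")
})

test_that("collapse_to_genes is idempotent and order-independent", {
  fam <- default_family()
  members <- filter_family_hits(fam$hits)
  g1 <- collapse_to_genes(members, fam$proteins)
  shuf <- fam$proteins[rev(seq_len(nrow(fam$proteins))), ]
  g2 <- collapse_to_genes(sample(members), shuf)
  expect_equal(g1, g2)
  # idempotence: collapsing the representatives changes nothing
  g3 <- collapse_to_genes(g1$protein_id, fam$proteins)
  expect_equal(g3$protein_id, g1$protein_id)
})

test_that("splice-variant collapsing reduces 104 transcripts to 86 loci", {
  fam <- default_family()
  members <- filter_family_hits(fam$hits)
  expect_equal(length(members), 104L)
  genes <- collapse_to_genes(members, fam$proteins)
  expect_equal(nrow(genes), 86L)
  expect_true(all(genes$n_splice_forms >= 1L & genes$n_splice_forms <= 4L))
  expect_equal(sum(genes$n_splice_forms > 1L), 18L)
})

test_that("protein_mw matches a hand-summed residue-mass oracle", {
  # oracle: average residue masses + one water, summed by hand
  expect_equal(protein_mw("G"), 57.0519 + 18.01524, tolerance = 1e-6)
  expect_equal(protein_mw("GG"), 2 * 57.0519 + 18.01524, tolerance = 1e-6)
  expect_equal(protein_mw("MKV"),
               131.1926 + 128.1741 + 99.1326 + 18.01524, tolerance = 1e-6)
  expect_error(protein_mw(""), "empty")
  expect_error(protein_mw("MXK"), "X")
})

test_that("protein_mw is additive over concatenation", {
  set.seed(11)
  for (i in 1:10) {
    a <- random_protein(sample(5:50, 1))
    b <- random_protein(sample(5:50, 1))
    expect_equal(protein_mw(paste0(a, b)),
                 protein_mw(a) + protein_mw(b) - 18.01524, tolerance = 1e-9)
  }
})

test_that("protein_pi agrees with a brute-force pH grid scan", {
  # GG has only the two termini; the zero crossing is their pKa midpoint
  expect_equal(protein_pi("GG"), (8.6 + 3.6) / 2, tolerance = 0.01)
  expect_equal(protein_pi("GG"), oracle_pi_grid("GG"), tolerance = 0.01)
  set.seed(12)
  for (i in 1:5) {
    s <- random_protein(30)
    expect_equal(protein_pi(s), oracle_pi_grid(s), tolerance = 0.01)
  }
  expect_gt(protein_pi(strrep("K", 10)), 9)
  expect_lt(protein_pi(strrep("D", 10)), 5)
  expect_error(protein_pi(""), "empty")
})

test_that("protein_pi moves monotonically with charged residues", {
  set.seed(13)
  for (i in 1:10) {
    s <- random_protein(sample(10:60, 1))
    expect_gte(protein_pi(paste0(s, "K")) + 1e-9, protein_pi(s))
    expect_lte(protein_pi(paste0(s, "D")) - 1e-9, protein_pi(s))
  }
})

test_that("build_census names, orders and populates entries", {
  rec <- data.frame(protein_id = paste0(c("b", "a", "c"), "_P01"),
                    gene_locus = c("b", "a", "c"),
                    sequence = c("MKV", "MKVAW", "MK"))
  genes <- collapse_to_genes(rec$protein_id, rec)
  models <- list(
    a = gene_model("a", "chr1", "+", 10, 100, list(t1 = cbind(10, 100))),
    b = gene_model("b", "chr2", "-", 5, 50, list(t1 = cbind(5, 50))),
    c = gene_model("c", "chr1", "+", 200, 300, list(t1 = cbind(200, 300))))
  cen <- build_census(genes, models, "ZmGRAS")
  expect_equal(cen$gene_name, c("ZmGRAS1", "ZmGRAS2", "ZmGRAS3"))
  expect_equal(cen$gene_locus, c("a", "b", "c"))    # locus-ascending order
  expect_equal(cen$length_aa, nchar(genes$sequence[order(genes$gene_locus)]))
  expect_equal(cen$chromosome, c("chr1", "chr2", "chr1"))
  expect_error(build_census(genes, models[1:2]), "lookup")
})

test_that("proteins containing X keep their row but lose MW/pI", {
  rec <- data.frame(protein_id = c("a_P01", "b_P01"), gene_locus = c("a", "b"),
                    sequence = c("MKXV", "MKV"))
  genes <- collapse_to_genes(rec$protein_id, rec)
  models <- list(a = gene_model("a", "chr1", "+", 1, 12, list(t = cbind(1, 12))),
                 b = gene_model("b", "chr1", "+", 20, 30, list(t = cbind(20, 30))))
  expect_warning(cen <- build_census(genes, models), "X")
  expect_equal(nrow(cen), 2L)
  expect_true(is.na(cen$mw_da[cen$gene_locus == "a"]))
  expect_false(is.na(cen$mw_da[cen$gene_locus == "b"]))
})

test_that("summarize_census computes counts and statistics", {
  cen <- table1_fixture()
  s <- summarize_census(cen)
  expect_equal(s$n_genes, 86L)
  expect_equal(unname(s$per_chromosome_counts["chr4"]), 17L)
  expect_equal(s$pi[["min"]], 4.4973)
  expect_equal(s$length_aa[["min"]], 111)
  # percentages sum to 100 within rounding
  expect_lt(abs(sum(s$per_chromosome_percent) - 100), 0.05)

  one <- cen[1, ]
  s1 <- summarize_census(one)
  expect_equal(s1$length_aa[["min"]], s1$length_aa[["max"]])
  expect_equal(s1$length_aa[["mean"]], s1$length_aa[["min"]])
  expect_error(summarize_census(cen[0, ]), "empty")
})
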