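# Frozen NG86 reference values were computed with an independent
# implementation of the Nei-Gojobori method on the same fixtures.

test_that("NG86 matches independent reference values on frozen fixtures", {
  ref <- "CCATTTAGCCGCGGCAATACATCGGAGACGCCTGCCAATTTCGAAATCAAGACCCGTCGGACAATTACCGATCGTAATTCGGCAACTTTT"
  qry <- "CCATTTAGCTTCGGCAATACATCGGAGACGGGAGCCAATTTCGAAATCAAGACCCGTCGGAAAATTACCGATCGTAATTCGGCAACTTTT"
  est <- ng86(codon_align(ref, qry))
  expect_equal(est[["ka"]], 0.0769906155, tolerance = 1e-9)
  expect_equal(est[["ks"]], 0.0476350543, tolerance = 1e-9)

  single <- function(a, b) ng86(codon_align(strrep(a, 10),
                                            paste0(b, strrep(a, 9))))
  e <- single("TTT", "TTC")   # Phe -> Phe, purely synonymous
  expect_equal(e[["ka"]], 0)
  expect_equal(e[["ks"]], 0.3831192178, tolerance = 1e-9)
  expect_equal(e[["Sd"]], 1); expect_equal(e[["Nd"]], 0)
  e <- single("ATG", "ATA")   # Met -> Ile, purely non-synonymous
  expect_equal(e[["ka"]], 0.0344888349, tolerance = 1e-9)
  expect_equal(e[["ks"]], 0)
  e <- single("AAA", "AGC")   # two-position difference, pathway averaging
  expect_equal(e[["ka"]], 0.0790203867, tolerance = 1e-9)
  e <- single("CCC", "CCA")   # 4-fold degenerate third position
  expect_equal(e[["ks"]], 0.1073256327, tolerance = 1e-9)
})

test_that("identical sequences give ka = ks = 0 and NG86 is symmetric", {
  set.seed(301)
  cds <- plastcomp:::random_cds(300)
  est <- ng86(codon_align(cds, cds))
  expect_equal(est[["ka"]], 0); expect_equal(est[["ks"]], 0)
  mut <- mutate_codons(cds, n_syn = 4, n_nonsyn = 3, seed = 302)
  e1 <- ng86(codon_align(cds, mut$cds))
  e2 <- ng86(codon_align(mut$cds, cds))
  expect_equal(e1[["ka"]], e2[["ka"]])
  expect_equal(e1[["ks"]], e2[["ks"]])
})

test_that("planted synonymous edits give ka 0; non-synonymous give ks 0", {
  set.seed(303)
  cds <- plastcomp:::random_cds(600)
  syn <- mutate_codons(cds, n_syn = 6, n_nonsyn = 0, seed = 304)
  e <- ng86(codon_align(cds, syn$cds))
  expect_equal(e[["ka"]], 0)
  expect_gt(e[["ks"]], 0)
  non <- mutate_codons(cds, n_syn = 0, n_nonsyn = 6, seed = 305)
  e <- ng86(codon_align(cds, non$cds))
  expect_equal(e[["ks"]], 0)
  expect_gt(e[["ka"]], 0)
})

test_that("codon pairing excludes an inserted codon and keeps the rest", {
  cds <- "ATGAAACCCGGGTTTTAA"
  ins <- "ATGAAACCCTGGGGGTTTTAA"  # one extra codon TGG after position 3
  pairs <- codon_align(cds, ins)
  expect_equal(nrow(pairs), 5L)  # stop trimmed, inserted codon dropped
  expect_true(all(pairs$ref_codon == pairs$qry_codon))
})

test_that("internal stop codons are rejected with gene and position", {
  bad <- "ATGAAATAACCCGGGTTTTAA"
  expect_error(codon_align(bad, bad, gene = "rbcL"), "rbcL.*codon 3")
})

test_that("selection categories follow the documented banding", {
  expect_equal(categorize_selection(1.92), "positive")
  expect_equal(categorize_selection(1.23), "positive")
  expect_equal(categorize_selection(0.96), "neutral")
  expect_equal(categorize_selection(0.86), "~neutral")
  expect_equal(categorize_selection(0.50), "purifying")
  expect_equal(categorize_selection(NA), "unclassified")
  expect_equal(categorize_selection(c(1.06, 1.05, 0.95, 0.949, 0.80, 0.799)),
               c("positive", "neutral", "neutral", "~neutral", "~neutral",
                 "purifying"))
})

test_that("gene-level selection estimates run on annotated records", {
  sim <- generate_plastome(small_config(seed = 63))
  dv_cds <- sim$record
  ann <- sim$record$annotations
  pc_genes <- unique(ann$gene[ann$category == "protein_coding"])[1:3]
  # mutate one gene's CDS synonymously in a copy of the record
  sv <- strsplit(sim$record$sequence, "")[[1L]]
  g <- pc_genes[1L]
  loc <- unique(ann$locus[ann$gene == g])[1L]
  ex <- ann[ann$locus == loc, ]
  cds <- plastcomp:::splice_locus(sim$record, loc)
  mut <- mutate_codons(cds, n_syn = 3, n_nonsyn = 0, seed = 64)
  content <- if (ex$strand[1L] == "+") mut$cds else revcomp(mut$cds)
  sv[ex$exon_start:ex$exon_end] <- strsplit(content, "")[[1L]]
  rec2 <- plastome_record("qry", paste0(sv, collapse = ""), ann)
  tab <- gene_selection(sim$record, rec2, pc_genes)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$ka[tab$gene == g], 0)
  expect_gt(tab$ks[tab$gene == g], 0)
  expect_equal(tab$category[tab$gene == g], "purifying")
  other <- tab[tab$gene != g, ]
  expect_true(all(other$ka == 0 & other$ks == 0))
})

test_that("codon profile: trivial CDS, RSCU normalization, third position", {
  cp <- codon_profile("ATGTTAAGA")
  expect_equal(unname(cp$aa_freq[c("M", "L", "R")]), rep(1 / 3, 3))
  # RSCU averages 1 within every family with observations
  set.seed(306)
  cds <- replicate(10, plastcomp:::random_cds(600))
  cp2 <- codon_profile(cds)
  gen <- Biostrings::GENETIC_CODE
  for (aa in setdiff(unique(gen), "*")) {
    fam <- names(gen)[gen == aa]
    if (length(fam) >= 2L && sum(cp2$codon_counts[fam]) > 0L)
      expect_equal(mean(cp2$rscu[fam]), 1, tolerance = 1e-12)
  }
  expect_equal(sum(cp2$aa_freq), 1, tolerance = 1e-12)
  # A/T-rich plastome-style CDS prefer A/T-ending codons
  expect_gt(cp2$third_position[["AT"]], cp2$third_position[["GC"]])
  # non-ACGT codons are skipped with a warning
  expect_warning(cp3 <- codon_profile("ATGNNNTAA"), "skipped")
  expect_equal(cp3$skipped, 1L)
})
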