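test_that("identical sequences align gap-free with zero events", {
  set.seed(201)
  s <- random_seq(10000)
  aln <- align_near_identical(s, s)
  expect_equal(aln$ref_aln, s)
  expect_equal(aln$qry_aln, s)
  ev <- extract_events(aln)
  expect_equal(nrow(ev$substitutions), 0L)
  expect_equal(nrow(ev$indels), 0L)
})

test_that("a planted substitution and deletion are recovered exactly", {
  set.seed(202)
  ref <- random_seq(5000)
  rv <- strsplit(ref, "")[[1L]]
  rv[1200] <- setdiff(ACGT, rv[1200])[1L]
  qry <- paste0(paste0(rv[1:2999], collapse = ""),
                paste0(rv[3005:5000], collapse = ""))  # 5 bp deletion
  aln <- align_near_identical(ref, qry)
  ev <- extract_events(aln)
  expect_equal(ev$substitutions$ref_pos, 1200L)
  expect_equal(nrow(ev$indels), 1L)
  expect_equal(ev$indels$kind, "deletion")
  expect_equal(ev$indels$length, 5L)
  expect_equal(ev$indels$ref_pos, 3000L)
})

test_that("columns with N produce no substitution event", {
  aln <- plastcomp:::new_alignment("r", "q", "ACNGT", "ACAGT")
  ev <- extract_events(aln)
  expect_equal(nrow(ev$substitutions), 0L)
})

test_that("worked alignment example: one A/G substitution, one 2 bp deletion", {
  aln <- plastcomp:::new_alignment("r", "q", "ACTT", "GC--")
  ev <- extract_events(aln)
  expect_equal(nrow(ev$substitutions), 1L)
  expect_equal(ev$substitutions$pair_category, "A/G")
  expect_true(ev$substitutions$is_transition)
  expect_equal(ev$indels$length, 2L)
  expect_equal(ev$indels$kind, "deletion")
  expect_equal(ev$indels$ref_pos, 3L)
})

test_that("gap runs are left-shifted to the lowest reference coordinate", {
  # deleting any of the A's in CAAAT is the same event; the reported
  # coordinate must be the leftmost
  ref <- paste0("GCGCGCGGCC", "CAAAT", "GGCCGCGCGC")
  qry <- paste0("GCGCGCGGCC", "CAAT", "GGCCGCGCGC")
  aln <- align_near_identical(ref, qry, k = 5L)
  ev <- extract_events(aln)
  expect_equal(ev$indels$ref_pos, 12L)  # first A of the run
})

test_that("extraction agrees with an unbanded DP oracle around planted edits", {
  sim <- generate_plastome(small_config(seed = 61))
  dv <- diverge(sim, divergence = list(sub_rate = 0.003, indel_rate = 3e-4),
                seed = 611)
  aln <- align_near_identical(sim$record, dv$record)
  ev <- extract_events(aln)
  truth <- dv$events
  # full-genome closed loop first
  expect_setequal(ev$substitutions$ref_pos,
                  truth$pos[truth$type == "substitution"])
  expect_equal(nrow(ev$indels), sum(truth$type != "substitution"))
  # windows around each InDel: anchored alignment equals unbanded DP
  ind <- truth[truth$type != "substitution", ]
  qmap <- cumsum(rep(1L, nchar(sim$record$sequence)))
  for (i in seq_len(nrow(ind))) {
    a <- max(1L, ind$pos[i] - 400L)
    b <- min(nchar(sim$record$sequence), ind$pos[i] + 400L)
    # map the window into the derived genome through the event list
    shift_before <- sum(ifelse(truth$type == "insertion", truth$length,
                               -truth$length)[truth$type != "substitution" &
                                              truth$pos < a])
    qa <- a + shift_before
    qb <- qa + (b - a) + sum(ifelse(ind$type == "insertion", ind$length,
                                    -ind$length)[ind$pos >= a & ind$pos <= b])
    refw <- substring(sim$record$sequence, a, b)
    qryw <- substring(dv$record$sequence, max(1L, qa), qb)
    oracle <- oracle_dp_events(refw, qryw)
    mine <- ev$indels[ev$indels$ref_pos >= a & ev$indels$ref_pos <= b, ]
    expect_equal(sort(mine$length), sort(oracle$indels$len),
                 info = paste("window", i))
    expect_equal(nrow(mine), nrow(oracle$indels))
  }
})

test_that("swapping ref and qry preserves categories and swaps InDel kinds", {
  sim <- generate_plastome(small_config(seed = 62))
  dv <- diverge(sim, divergence = list(sub_rate = 0.004, indel_rate = 2e-4),
                seed = 621)
  a1 <- align_near_identical(sim$record, dv$record)
  a2 <- align_near_identical(dv$record, sim$record)
  e1 <- extract_events(a1); e2 <- extract_events(a2)
  s1 <- summarize_substitutions(e1$substitutions)
  s2 <- summarize_substitutions(e2$substitutions)
  expect_equal(s1$counts, s2$counts)
  expect_equal(s1$ts_tv_ratio, s2$ts_tv_ratio)
  expect_equal(sum(e1$indels$kind == "insertion"),
               sum(e2$indels$kind == "deletion"))
  expect_equal(sum(e1$indels$kind == "deletion"),
               sum(e2$indels$kind == "insertion"))
  # conservation: Ts + Tv equals the number of substitution events
  expect_equal(s1$ts_count + s1$tv_count, nrow(e1$substitutions))
})

test_that("too-divergent input is rejected with advice", {
  set.seed(203)
  expect_error(align_near_identical(random_seq(3000), random_seq(3000)),
               "divergent")
})

test_that("substitution summary accepts counts and computes the ratio", {
  s <- summarize_substitutions(c("A/C" = 57, "C/T" = 106, "A/G" = 101,
                                 "A/T" = 16, "C/G" = 12, "G/T" = 58))
  expect_equal(s$ts_count, 207)
  expect_equal(s$tv_count, 143)
  expect_equal(s$ts_tv_ratio, 1.45)
  empty <- summarize_substitutions(
    data.frame(pair_category = character(0)))
  expect_equal(empty$ts_count, 0L)
  expect_true(is.na(empty$ts_tv_ratio))
})

test_that("gene concatenation splices, strand-corrects, and is deterministic", {
  seqs <- list(g1 = "ATGAAACCCGGGTAA", g2 = "ATGTTTACATAA")
  backbone <- paste0(random_seq(50), seqs$g1, random_seq(30),
                     revcomp(seqs$g2), random_seq(40))
  ann <- data.frame(
    gene = c("g1", "g2"), category = "protein_coding",
    strand = c("+", "-"),
    exon_start = c(51L, 51L + 15L + 30L),
    exon_end = c(50L + 15L, 50L + 15L + 30L + 12L),
    locus = 1:2)
  rec <- plastome_record("r", backbone, ann)
  cat1 <- concatenate_genes(rec, c("g1", "g2"))
  expect_equal(cat1, paste0(seqs$g1, seqs$g2))
  # gene order follows genome order of the first exon, not list order
  expect_equal(concatenate_genes(rec, c("g2", "g1")), cat1)
  expect_identical(concatenate_genes(rec, c("g1", "g2")), cat1)
  expect_error(concatenate_genes(rec, c("g1", "nope")), "nope")
})
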