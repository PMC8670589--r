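test_that("planted exact IRs are recovered at exact coordinates", {
  set.seed(404)
  # 10 kb genome: LSC 6,000 | IRb 1,000 | SSC 2,000 | IRa 1,000; the first
  # and last bases of each single-copy region are set to A so the planted
  # IR cannot extend across a junction by a chance complementary match
  lsc <- paste0("A", random_seq(5998), "A")
  irb <- random_seq(1000)
  ssc <- paste0("A", random_seq(1998), "A")
  g <- paste0(lsc, irb, ssc, revcomp(irb))
  rec <- plastome_record("planted", g)
  st <- detect_quadripartite(rec, min_ir_len = 500L)
  expect_equal(st$lsc, c(1L, 6000L))
  expect_equal(st$irb, c(6001L, 7000L))
  expect_equal(st$ssc, c(7001L, 9000L))
  expect_equal(st$ira, c(9001L, 10000L))
  expect_equal(st$ir_identity, 1.0)
  expect_equal(st$offset, 0L)
})

test_that("detector agrees with a brute-force inverted-duplication oracle", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    sc1 <- paste0("A", random_seq(1798), "A")   # junction guards as above
    sc2 <- paste0("A", random_seq(1198), "A")
    ir <- random_seq(600)
    g <- paste0(sc1, ir, sc2, revcomp(ir))
    st <- detect_quadripartite(plastome_record("x", g), min_ir_len = 300L)
    oracle <- oracle_longest_inverted(g)
    expect_equal(unname(st$irb), unname(oracle$copy1))
    expect_equal(unname(st$ira), unname(oracle$copy2))
  }
})

test_that("structure tiles the genome and region lengths satisfy the sum rule", {
  sim <- generate_plastome(small_config(seed = 31))
  st <- detect_quadripartite(sim$record, min_ir_len = 1000L)
  n <- nchar(sim$record$sequence)
  expect_equal(st$lsc[1L], 1L)
  expect_equal(st$irb[1L], st$lsc[2L] + 1L)
  expect_equal(st$ssc[1L], st$irb[2L] + 1L)
  expect_equal(st$ira[1L], st$ssc[2L] + 1L)
  expect_equal(st$ira[2L], n)
  len <- function(iv) iv[2L] - iv[1L] + 1L
  expect_equal(len(st$lsc) + len(st$ssc) + len(st$irb) + len(st$ira), n)
  expect_equal(len(st$irb), len(st$ira))
  expect_gt(len(st$lsc), len(st$ssc))
  # concatenating the four regions reproduces the sequence
  s <- sim$record$sequence
  expect_identical(
    paste0(substring(s, st$lsc[1], st$lsc[2]), substring(s, st$irb[1], st$irb[2]),
           substring(s, st$ssc[1], st$ssc[2]), substring(s, st$ira[1], st$ira[2])),
    s)
})

test_that("detection is invariant to rotation and reverse complement", {
  sim <- generate_plastome(small_config(seed = 32))
  seq0 <- sim$record$sequence
  lens <- function(st) c(diff(st$lsc), diff(st$irb), diff(st$ssc), diff(st$ira)) + 1L
  base <- lens(detect_quadripartite(sim$record, min_ir_len = 1000L))
  for (off in c(500L, 9000L, 13000L)) {
    r <- plastome_record("rot", plastcomp:::rotate_sequence(seq0, off))
    st <- detect_quadripartite(r, min_ir_len = 1000L)
    expect_equal(lens(st), base)
    # rotating by the reported offset restores the canonical frame
    expect_identical(rotate_plastome(r, st$offset)$sequence, seq0)
  }
  rc <- plastome_record("rc", revcomp(seq0))
  expect_equal(lens(detect_quadripartite(rc, min_ir_len = 1000L)), base)
})

test_that("a genome without an inverted duplication is rejected", {
  set.seed(7)
  expect_error(
    detect_quadripartite(plastome_record("r", random_seq(20000)),
                         min_ir_len = 1000L),
    "no IR found")
})

test_that("region stats: lengths, GC oracle, all-G, and revcomp invariance", {
  sim <- generate_plastome(small_config(seed = 33))
  norm <- normalize_plastome(sim$record, min_ir_len = 1000L)
  rs <- region_stats(norm$record, norm$structure)
  expect_equal(rs$length[rs$region == "genome"], 15000L)
  expect_equal(sum(rs$length[rs$region != "genome"]), 15000L)
  # GC equals a direct-count oracle, region by region
  for (r in c("LSC", "IRb", "SSC", "IRa")) {
    iv <- rs[rs$region == r, ]
    sub <- substring(norm$record$sequence, iv$start, iv$end)
    expect_equal(iv$gc, oracle_gc(sub))
  }
  # GC is invariant under reverse complement
  expect_equal(oracle_gc(revcomp(norm$record$sequence)),
               rs$gc[rs$region == "genome"])
  # all-G sequence has GC 1 everywhere; N is excluded from GC entirely
  expect_equal(plastcomp:::gc_fraction(strrep("G", 50)), 1.0)
  expect_equal(plastcomp:::gc_fraction("GGNNAA"), 0.5)
})

test_that("gene census counts IR duplicates and warns on extra copies", {
  sim <- generate_plastome(small_config(seed = 34))
  st <- detect_quadripartite(sim$record, min_ir_len = 1000L)
  cen <- gene_census(sim$record, st)
  expect_equal(cen$unique_genes, 9L)
  expect_equal(cen$duplicated_in_ir, 3L)
  expect_equal(cen$total_genes, 12L)
  expect_equal(unname(cen$unique_by_category),
               c(5L, 3L, 1L))
  # empty annotations give the all-zero census
  bare <- plastome_record("bare", sim$record$sequence)
  cen0 <- gene_census(bare, st)
  expect_equal(cen0$total_genes, 0L)
  # a third copy of an IR-duplicated gene triggers the >2-loci warning path
  ann <- sim$record$annotations
  lg <- unique(ann[, c("gene", "locus")])
  two_loci <- names(which(table(lg$gene) == 2L))[1L]
  extra <- ann[ann$gene == two_loci, ][1L, ]
  extra$exon_start <- 50L; extra$exon_end <- 80L
  extra$locus <- max(ann$locus) + 1L
  rec3 <- plastome_record("x", sim$record$sequence, rbind(ann, extra))
  expect_warning(cen3 <- gene_census(rec3, st), "loci")
  expect_equal(cen3$total_genes, cen3$unique_genes + cen3$duplicated_in_ir)
})
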