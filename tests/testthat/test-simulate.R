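test_that("generation is deterministic for a fixed seed", {
  s1 <- generate_plastome(small_config(seed = 81))
  s2 <- generate_plastome(small_config(seed = 81))
  expect_identical(s1$record$sequence, s2$record$sequence)
  expect_identical(s1$record$annotations, s2$record$annotations)
  expect_identical(s1$truth$ssrs, s2$truth$ssrs)
  s3 <- generate_plastome(small_config(seed = 82))
  expect_false(identical(s1$record$sequence, s3$record$sequence))
  # writing twice gives byte-identical FASTA
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_plastome(s1$record, f1)
  write_plastome(s2$record, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the emitted genome has the configured layout and exact IR mirror", {
  cfg <- small_config(seed = 83)
  sim <- generate_plastome(cfg)
  n <- nchar(sim$record$sequence)
  expect_equal(n, cfg$lsc + cfg$ssc + 2L * cfg$ir)
  st <- sim$truth$structure
  ira <- substring(sim$record$sequence, st$ira[1L], st$ira[2L])
  irb <- substring(sim$record$sequence, st$irb[1L], st$irb[2L])
  expect_identical(ira, revcomp(irb))
  # detection recovers the planted boundaries exactly (closed loop)
  det <- detect_quadripartite(sim$record, min_ir_len = 1000L)
  expect_equal(det$lsc, st$lsc)
  expect_equal(det$irb, st$irb)
  expect_equal(det$ssc, st$ssc)
  expect_equal(det$ira, st$ira)
})

test_that("the SSR truth log matches the scanner exactly (closed loop)", {
  for (seed in c(84, 85)) {
    sim <- generate_plastome(small_config(seed = seed))
    loci <- find_ssrs(sim$record)
    tr <- sim$truth$ssrs[order(sim$truth$ssrs$start), ]
    expect_equal(nrow(loci), nrow(tr))
    expect_equal(loci$start, tr$start)
    expect_equal(loci$motif, tr$motif)
    expect_equal(loci$copies, tr$copies)
  }
})

test_that("IR-planted SSRs are logged for both copies", {
  cfg <- small_config(seed = 86,
                      ssr_plant = data.frame(motif = "A", copies = 11L,
                                             region = "IRb", count = 1L))
  sim <- generate_plastome(cfg)
  tr <- sim$truth$ssrs
  expect_equal(nrow(tr), 2L)
  expect_setequal(tr$region, c("IRb", "IRa"))
  loci <- find_ssrs(sim$record)
  expect_setequal(loci$start, pmin(tr$start, tr$end))
})

test_that("zero divergence returns the input unchanged", {
  sim <- generate_plastome(small_config(seed = 87))
  dv <- diverge(sim, divergence = list(sub_rate = 0, indel_rate = 0))
  expect_identical(dv$record$sequence, sim$record$sequence)
  expect_equal(nrow(dv$events), 0L)
})

test_that("divergence events are logged faithfully (closed-loop recovery)", {
  sim <- generate_plastome(small_config(seed = 88))
  dv <- diverge(sim, divergence = list(sub_rate = 0.005, indel_rate = 4e-4),
                seed = 880)
  ev <- extract_events(align_near_identical(sim$record, dv$record))
  tru <- dv$events
  expect_setequal(ev$substitutions$ref_pos, tru$pos[tru$type == "substitution"])
  ti <- tru[tru$type != "substitution", ]
  expect_equal(nrow(ev$indels), nrow(ti))
  expect_equal(sort(ev$indels$length), sort(ti$length))
  # positions agree up to left-shift normalization in repeat context
  expect_true(all(abs(sort(ev$indels$ref_pos) - sort(ti$pos)) <= 10L))
})

test_that("preserve_ir keeps the IR copies identical after divergence", {
  sim <- generate_plastome(small_config(seed = 89))
  dv <- diverge(sim, divergence = list(sub_rate = 0.01, indel_rate = 0),
                seed = 890)
  st <- detect_quadripartite(dv$record, min_ir_len = 1000L)
  expect_equal(st$ir_identity, 1.0)
  # mirrored IR events appear twice in the log with complementary bases
  irb <- sim$truth$structure$irb
  in_irb <- dv$events$pos >= irb[1L] & dv$events$pos <= irb[2L]
  expect_gt(sum(in_irb), 0L)
  expect_equal(sum(in_irb),
               sum(dv$events$pos > sim$truth$structure$ssc[2L]))
})

test_that("configured Ts:Tv bias is recovered from the event log", {
  sim <- generate_plastome(small_config(seed = 90))
  ts <- 0L; tv <- 0L
  for (s in 1:6) {
    dv <- diverge(sim, divergence = list(sub_rate = 0.02, indel_rate = 0),
                  seed = 900 + s)
    sub <- dv$events[dv$events$type == "substitution", ]
    pair <- paste(pmin(sub$ref_base, sub$new_base),
                  pmax(sub$ref_base, sub$new_base), sep = "/")
    ts <- ts + sum(pair %in% c("A/G", "C/T"))
    tv <- tv + sum(!pair %in% c("A/G", "C/T"))
  }
  expect_gt(ts + tv, 1500L)
  expect_equal(ts / tv, 1.5, tolerance = 0.08)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(lsc = 1000, ssc = 2000, ir = 500, seed = 1),
               "LSC")
  expect_error(generator_config(gc = 1.2, seed = 1), "gc")
  expect_error(generator_config(seed = 1,
                                divergence = list(sub_rate = 2, tstv = 1.5,
                                                  indel_rate = 0)),
               "rates")
  expect_error(generator_config(), "seed")
  # planting beyond capacity fails loudly
  cfg <- small_config(seed = 91,
                      ssr_plant = data.frame(motif = "AT", copies = 1000L,
                                             region = "SSC", count = 5L))
  expect_error(generate_plastome(cfg), "capacity")
})

test_that("mutate_codons plants exactly the requested edit classes", {
  set.seed(92)
  cds <- plastcomp:::random_cds(300)
  mut <- mutate_codons(cds, n_syn = 5, n_nonsyn = 4, seed = 93)
  expect_equal(sum(mut$edits$synonymous), 5L)
  expect_equal(sum(!mut$edits$synonymous), 4L)
  gen <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(mut$edits))) {
    e <- mut$edits[i, ]
    expect_equal(gen[[e$from]] == gen[[e$to]], e$synonymous)
  }
  # edits land where claimed
  cods <- plastcomp:::codon_split(mut$cds)
  expect_equal(cods[mut$edits$codon_index], mut$edits$to)
})
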