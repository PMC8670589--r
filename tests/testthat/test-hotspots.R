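test_that("bins anchor at position 1 and retain the final partial bin", {
  tr <- bin_events(c(1, 250, 251), integer(0), integer(0),
                   ref_length = 1000, bin_size = 250)
  expect_equal(tr$n_bins, 4L)
  expect_equal(tr$substitutions, c(2L, 1L, 0L, 0L))
  tr2 <- bin_events(integer(0), integer(0), integer(0),
                    ref_length = 900, bin_size = 250)
  expect_equal(tr2$n_bins, 4L)
  expect_equal(tr2$bin_end[4L] - tr2$bin_start[4L] + 1L, 150L)
  expect_error(bin_events(1001, integer(0), integer(0), ref_length = 1000),
               "outside")
})

test_that("binned counts equal an independent histogram oracle", {
  set.seed(401)
  L <- 20000L
  subs <- sample.int(L, 300)
  inds <- sample.int(L, 40)
  reps <- sample.int(L, 30)
  tr <- bin_events(subs, inds, reps, ref_length = L)
  oracle <- function(p) {
    idx <- cut(p, breaks = seq(0, 20250, by = 250), labels = FALSE)
    t <- table(idx)
    out <- integer(tr$n_bins)
    out[as.integer(names(t))] <- as.integer(t)
    out
  }
  expect_equal(tr$substitutions, oracle(subs))
  expect_equal(tr$indels, oracle(inds))
  expect_equal(tr$repeats, oracle(reps))
  expect_equal(sum(tr$substitutions), length(subs))
})

test_that("each repeat pair contributes both copies to the repeat track", {
  reps <- data.frame(kind = "forward", length = 40L, pos1 = 10L, pos2 = 600L,
                     identity = 1, mismatches = 0L, is_genomic_ir = FALSE)
  tr <- bin_events(integer(0), integer(0), reps, ref_length = 1000)
  expect_equal(sum(tr$repeats), 2L)
  expect_equal(tr$repeats[c(1L, 3L)], c(1L, 1L))
  # flagged genomic IR pairs are dropped
  reps$is_genomic_ir <- TRUE
  tr2 <- bin_events(integer(0), integer(0), reps, ref_length = 1000)
  expect_equal(sum(tr2$repeats), 0L)
})

test_that("Pearson values: identical, opposed, and degenerate tracks", {
  tr <- list(substitutions = c(1, 0, 1, 0), indels = c(1, 0, 1, 0),
             repeats = c(0, 1, 0, 1))
  class(tr) <- "BinnedEventTracks"
  r <- correlate_tracks(tr)
  expect_equal(unname(r[["r_sub_indel"]]), 1.0)
  expect_equal(unname(r[["r_sub_repeat"]]), -1.0)
  tr$repeats <- c(2, 2, 2, 2)
  # both repeat-involving pairs warn
  expect_warning(expect_warning(r2 <- correlate_tracks(tr), "zero-variance"))
  expect_true(is.na(r2[["r_sub_repeat"]]))
})

test_that("strength labels follow the half-open banding", {
  expect_equal(strength_label(0.43), "strong")
  expect_equal(strength_label(1.0), "perfect")
  expect_equal(strength_label(0.195), "negligible/very weak")
  expect_equal(strength_label(c(0.05, 0.10, 0.199, 0.20, 0.30, 0.40, 0.69,
                                0.70, 0.99, -0.55)),
               c("none", "negligible/very weak", "negligible/very weak",
                 "weak", "moderate", "strong", "strong", "very strong",
                 "very strong", "strong"))
  expect_true(is.na(strength_label(NA)))
})

test_that("co-occurrence percentages are event-level with 2-decimal rounding", {
  # 23 InDel events, 15 of them in substitution-bearing bins -> 65.22
  sub <- c(rep(1, 15), rep(0, 8), 0)
  ind <- c(rep(1, 23), 0)
  tr <- list(substitutions = sub, indels = ind, repeats = rep(0, 24))
  class(tr) <- "BinnedEventTracks"
  co <- cooccurrence(tr)
  expect_equal(unname(co[["pct_indels_in_sub_bins"]]), 65.22)
  expect_true(is.na(co[["pct_repeats_in_indel_bins"]]))  # zero repeats
  # all InDels in substitution bins -> 100; disjoint -> 0
  tr2 <- list(substitutions = c(1, 1, 0), indels = c(2, 3, 0), repeats = c(0, 0, 4))
  class(tr2) <- "BinnedEventTracks"
  co2 <- cooccurrence(tr2)
  expect_equal(unname(co2[["pct_indels_in_sub_bins"]]), 100)
  expect_equal(unname(co2[["pct_repeats_in_sub_bins"]]), 0)
  # duplicating the Y track does not change the percentage
  tr3 <- tr2; tr3$substitutions <- tr2$substitutions * 7L
  expect_equal(cooccurrence(tr3), co2)
})

test_that("joint permutation preserves r; independent shuffling destroys it", {
  set.seed(402)
  z <- rpois(200, 2)
  tr <- list(substitutions = z + rpois(200, 1), indels = z + rpois(200, 1),
             repeats = rpois(200, 2))
  class(tr) <- "BinnedEventTracks"
  r0 <- correlate_tracks(tr)[["r_sub_indel"]]
  perm <- sample.int(200)
  trp <- tr
  trp$substitutions <- tr$substitutions[perm]
  trp$indels <- tr$indels[perm]
  trp$repeats <- tr$repeats[perm]
  expect_equal(correlate_tracks(trp)[["r_sub_indel"]], r0)
  rs <- replicate(1000, {
    tri <- tr
    tri$indels <- sample(tr$indels)
    correlate_tracks(tri)[["r_sub_indel"]]
  })
  expect_lt(mean(abs(rs)), 0.06)
  expect_lt(abs(mean(rs)), 0.01)
})

test_that("correlation report combines r, labels, and co-occurrence", {
  set.seed(403)
  z <- rpois(300, 3)
  tr <- list(substitutions = z + rpois(300, 1), indels = z + rpois(300, 1),
             repeats = z + rpois(300, 1))
  class(tr) <- "BinnedEventTracks"
  rep_ <- correlation_report(tr)
  expect_s3_class(rep_, "CorrelationReport")
  expect_equal(rep_$strength, strength_label(rep_$r))
  expect_true(all(rep_$r >= -1 & rep_$r <= 1))
  expect_true(all(rep_$cooccurrence >= 0 & rep_$cooccurrence <= 100))
})
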