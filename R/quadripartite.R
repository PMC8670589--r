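## Quadripartite structure: automated detection of the two inverted repeats
## by seed-and-extend on shared 21-mers between the genome and its reverse
## complement, followed by rotation normalization so the large single copy
## region starts at position 1 and the copy order is LSC-IRb-SSC-IRa.

#' Detect the quadripartite structure of a plastome
#'
#' Finds the largest inverted duplication (the IR pair) by matching k-mers
#' of the sequence against its reverse complement, merging co-diagonal seed
#' runs across isolated mismatches, and extending ends. The genome is
#' treated as circular: the structure is reported in coordinates of the
#' rotation that puts the LSC start at position 1 (the rotation offset is
#' returned so the caller can rotate the record with [rotate_plastome()]).
#'
#' @param rec a [plastome_record()].
#' @param min_ir_len minimum IR length in bp (default 10000).
#' @param min_identity minimum identity between the two IR copies
#'   (default 0.99).
#' @param k seed length for the k-mer match (default 21).
#' @return object of class `QuadripartiteStructure`: a list with 1-based
#'   inclusive intervals `lsc`, `irb`, `ssc`, `ira` (in LSC-normalized
#'   coordinates), `ir_identity`, and `offset`, the rotation (in bp) that
#'   was applied to the input coordinates.
#' @export
detect_quadripartite <- function(rec, min_ir_len = 10000L, min_identity = 0.99,
                                 k = 21L) {
  s <- rec$sequence
  n <- nchar(s)
  if (n < 2L * min_ir_len) stopf("no IR found: genome shorter than two IR copies")
  # the genome is circular: an IR copy may straddle the linearization
  # origin, so detection runs in two frames half a genome apart (a copy
  # cannot straddle the origin in both). Candidates are pooled across the
  # frames: a copy split by one frame's origin appears whole, and longer,
  # in the other frame. Ambiguity (distinct physical duplications tied for
  # maximal length) is judged on the pooled set.
  half <- n %/% 2L
  cand0 <- find_inverted_duplication(s, min_ir_len, min_identity, k)
  cand1 <- find_inverted_duplication(rotate_sequence(s, half),
                                     min_ir_len, min_identity, k)
  pool <- c(lapply(cand0, function(cc) c(cc, frame = 0L)),
            lapply(cand1, function(cc) c(cc, frame = half)))
  if (!length(pool))
    stopf("no IR found: no inverted duplication >= %d bp at >= %.2f identity",
          min_ir_len, min_identity)
  lens <- vapply(pool, function(cc) cc$a2 - cc$a1 + 1L, 0L)
  pool <- pool[lens == max(lens)]
  # canonical key in original circular coordinates: the two copy start
  # positions (mod n) plus the length identify a physical duplication
  keys <- vapply(pool, function(cc) {
    starts <- sort(c((cc$a1 - 1L + cc$frame) %% n,
                     (cc$b1 - 1L + cc$frame) %% n))
    paste(starts[1L], starts[2L], cc$a2 - cc$a1 + 1L)
  }, "")
  distinct <- !duplicated(keys)
  if (sum(distinct) > 1L) {
    desc <- vapply(pool[distinct], function(cc)
      sprintf("[%d,%d]/[%d,%d] (frame offset %d)", cc$a1, cc$a2, cc$b1,
              cc$b2, cc$frame), "")
    stopf("ambiguous IR: multiple maximal inverted duplications: %s",
          paste(desc, collapse = "; "))
  }
  best <- pool[[1L]]
  st <- build_structure(rec, best, min_identity)
  st$offset <- as.integer((best$frame + st$offset) %% n)
  st
}

# Locate maximal inverted duplication candidates. Returns the best candidate
# as list(a1, a2, b1, b2, identity) in input coordinates (copy A before
# copy B along the linear sequence), or NULL.
find_inverted_duplication <- function(s, min_ir_len, min_identity, k,
                                      max_kmer_occ = 25L) {
  n <- nchar(s)
  rc <- revcomp(s)
  ks <- kmer_strings(s, k)
  krc <- kmer_strings(rc, k)
  # drop high-copy k-mers (SSR/low-complexity) before joining
  tab <- table(ks)
  keep <- names(tab)[tab <= max_kmer_occ]
  pos_s <- split(seq_along(ks), factor(ks, levels = keep))
  hit_rc <- which(krc %in% keep)
  if (!length(hit_rc)) return(NULL)
  pos_list <- pos_s[krc[hit_rc]]
  i <- rep.int(hit_rc, lengths(pos_list))   # position in rc
  j <- unlist(pos_list, use.names = FALSE)  # position in s
  # a contiguous inverted duplication is colinear between s and rc, so the
  # offset j - i is constant along it
  d <- j - i
  ord <- order(d, j)
  d <- d[ord]; j <- j[ord]; i <- i[ord]
  # within each diagonal, find runs of consecutive j; merge runs whose gap is
  # small (isolated mismatches break k consecutive seeds)
  newdiag <- c(TRUE, diff(d) != 0L)
  gap <- c(Inf, diff(j))
  brk <- newdiag | gap > (k + 60L)  # allow a few near-adjacent mismatches
  grp <- cumsum(brk)
  j_min <- tapply(j, grp, min)
  j_max <- tapply(j, grp, max)
  d_grp <- tapply(d, grp, "[", 1L)
  span <- j_max - j_min + k
  ok <- which(span >= min_ir_len * 0.8)
  if (!length(ok)) return(NULL)
  cands <- lapply(ok, function(g) {
    # s[j .. j+k-1] matches rc[i .. i+k-1]; rc interval [i, i+L-1] maps back
    # to the s interval [n - i - L + 2, n - i + 1]
    a1 <- as.integer(j_min[g]); a2 <- as.integer(j_max[g] + k - 1L)
    i1 <- j_min[g] - d_grp[g]; i2 <- j_max[g] - d_grp[g] + k - 1L
    b1 <- as.integer(n - i2 + 1L); b2 <- as.integer(n - i1 + 1L)
    list(a1 = a1, a2 = a2, b1 = b1, b2 = b2)
  })
  # orient, drop self-overlapping (the two copies must be disjoint) and
  # deduplicate the (A,B)/(B,A) mirror of the same physical pair
  cands <- lapply(cands, function(cc) {
    if (cc$a1 > cc$b1) list(a1 = cc$b1, a2 = cc$b2, b1 = cc$a1, b2 = cc$a2) else cc
  })
  key <- vapply(cands, function(cc) paste(cc$a1, cc$a2, cc$b1, cc$b2), "")
  cands <- cands[!duplicated(key)]
  cands <- Filter(function(cc) cc$a2 < cc$b1, cands)
  if (!length(cands)) return(NULL)
  # extend exact ends, then score identity
  sv <- s2c(s)
  cands <- lapply(cands, extend_inverted, sv = sv, n = n)
  cands <- Filter(function(cc) {
    len <- cc$a2 - cc$a1 + 1L
    len >= min_ir_len && cc$identity >= min_identity
  }, cands)
  if (!length(cands)) return(NULL)
  lens <- vapply(cands, function(cc) cc$a2 - cc$a1 + 1L, 0L)
  cands[lens == max(lens)]   # all maximal-length candidates of this frame
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# extend both ends of a candidate inverted pair while bases match exactly,
# keeping the two copies disjoint; then compute identity
extend_inverted <- function(cc, sv, n) {
  a1 <- cc$a1; a2 <- cc$a2; b1 <- cc$b1; b2 <- cc$b2
  # outward: grow a1 down and b2 up together
  while (a1 > 1L && b2 < n && a2 < b1 &&
         sv[a1 - 1L] == COMP[[sv[b2 + 1L]]] && sv[a1 - 1L] != "N") {
    a1 <- a1 - 1L; b2 <- b2 + 1L
  }
  # inward: grow a2 up and b1 down together
  while (a2 + 1L < b1 - 1L &&
         sv[a2 + 1L] == COMP[[sv[b1 - 1L]]] && sv[a2 + 1L] != "N") {
    a2 <- a2 + 1L; b1 <- b1 - 1L
  }
  la <- a2 - a1 + 1L; lb <- b2 - b1 + 1L
  len <- min(la, lb)
  # identity over the aligned extent (copies are equal length by construction
  # of the diagonal, but guard anyway)
  x <- sv[a1:(a1 + len - 1L)]
  y <- rev(unname(COMP[sv[b1:(b1 + len - 1L)]]))
  cc$identity <- mean(x == y)
  cc$a1 <- a1; cc$a2 <- a1 + len - 1L
  cc$b1 <- b2 - len + 1L; cc$b2 <- b2
  cc
}

# turn the chosen inverted pair into the LSC-normalized structure
build_structure <- function(rec, cand, min_identity) {
  n <- nchar(rec$sequence)
  ir_len <- cand$a2 - cand$a1 + 1L
  # the two single-copy segments on the circle between the IR copies
  gap_mid_len <- cand$b1 - cand$a2 - 1L               # between copy A and B
  gap_out_len <- n - (cand$b2 - cand$a1 + 1L)         # wrapping segment
  if (gap_mid_len <= 0L || gap_out_len <= 0L)
    stopf("no IR found: single-copy segments empty")
  if (gap_out_len > gap_mid_len) {
    # LSC is the wrapping segment: LSC starts just after copy B;
    # order LSC-IRb(copy A)-SSC-IRa(copy B) after rotation
    offset <- cand$b2 %% n
    lsc_len <- gap_out_len; ssc_len <- gap_mid_len
  } else {
    # LSC is the middle segment: LSC starts just after copy A
    offset <- cand$a2 %% n
    lsc_len <- gap_mid_len; ssc_len <- gap_out_len
  }
  lsc <- c(1L, lsc_len)
  irb <- c(lsc_len + 1L, lsc_len + ir_len)
  ssc <- c(lsc_len + ir_len + 1L, lsc_len + ir_len + ssc_len)
  ira <- c(lsc_len + ir_len + ssc_len + 1L, n)
  structure(
    list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
         ir_identity = cand$identity, offset = as.integer(offset)),
    class = "QuadripartiteStructure")
}

#' @export
print.QuadripartiteStructure <- function(x, ...) {
  cat(sprintf(
    "QuadripartiteStructure: LSC %s | IRb %s | SSC %s | IRa %s bp (IR identity %.4f, rotation offset %d)\n",
    format(diff(x$lsc) + 1L, big.mark = ","),
    format(diff(x$irb) + 1L, big.mark = ","),
    format(diff(x$ssc) + 1L, big.mark = ","),
    format(diff(x$ira) + 1L, big.mark = ","),
    x$ir_identity, x$offset))
  invisible(x)
}

#' Rotate a circular plastome record
#'
#' Rotates sequence and annotations so that input position `offset + 1`
#' becomes position 1. Annotations whose exons would wrap across the new
#' origin are kept intact by shifting modulo the genome length; an exon that
#' itself spans the origin after rotation is not representable and raises an
#' error (choose a rotation between genes, as [detect_quadripartite()] does).
#'
#' @param rec a [plastome_record()].
#' @param offset rotation in bp.
#' @return rotated [plastome_record()].
#' @export
rotate_plastome <- function(rec, offset) {
  n <- nchar(rec$sequence)
  offset <- offset %% n
  if (offset == 0L) return(rec)
  seq2 <- rotate_sequence(rec$sequence, offset)
  ann <- rec$annotations
  if (nrow(ann)) {
    shift <- function(p) ((p - offset - 1L) %% n) + 1L
    s2 <- shift(ann$exon_start); e2 <- shift(ann$exon_end)
    if (any(e2 < s2))
      stopf("rotation by %d splits an annotated exon across the origin", offset)
    ann$exon_start <- s2; ann$exon_end <- e2
  }
  plastome_record(rec$id, seq2, ann, source = rec$source)
}

#' Normalize a record to its quadripartite structure
#'
#' Convenience wrapper: detects the structure and rotates the record so the
#' LSC starts at position 1.
#'
#' @inheritParams detect_quadripartite
#' @return list with elements `record` (rotated) and `structure` (with
#'   `offset` 0 relative to the returned record).
#' @export
normalize_plastome <- function(rec, min_ir_len = 10000L, min_identity = 0.99) {
  st <- detect_quadripartite(rec, min_ir_len, min_identity)
  list(record = rotate_plastome(rec, st$offset), structure = st)
}

region_intervals <- function(structure) {
  list(LSC = structure$lsc, IRb = structure$irb,
       SSC = structure$ssc, IRa = structure$ira)
}

#' Region-level length and GC statistics
#'
#' @param rec a [plastome_record()] whose coordinates match `structure`
#'   (i.e. LSC starting at position 1; see [normalize_plastome()]).
#' @param structure a `QuadripartiteStructure`.
#' @return data frame with one row per region (`LSC`, `IRb`, `SSC`, `IRa`)
#'   plus a `genome` row: `length` in bp and `gc` as a fraction with `N`
#'   bases excluded from numerator and denominator.
#' @export
region_stats <- function(rec, structure) {
  n <- nchar(rec$sequence)
  if (structure$ira[2L] != n)
    stopf("structure does not tile this record (length %d vs %d)",
          structure$ira[2L], n)
  regs <- region_intervals(structure)
  rows <- lapply(names(regs), function(r) {
    iv <- regs[[r]]
    sub <- substring(rec$sequence, iv[1L], iv[2L])
    data.frame(region = r, start = iv[1L], end = iv[2L],
               length = iv[2L] - iv[1L] + 1L, gc = gc_fraction(sub))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(region = "genome", start = 1L, end = n,
                               length = n, gc = gc_fraction(rec$sequence)))
  out
}

#' Gene census with IR duplication accounting
#'
#' Counts unique genes by name and genes duplicated in the inverted repeats.
#' A gene counts as IR-duplicated when two of its loci lie (by midpoint of
#' their spans) in the two different IR copies; the unique count collapses
#' such pairs to one. A gene name with more than two loci triggers a
#' validation warning and is counted once unique plus (n - 1) duplicated.
#'
#' @inheritParams region_stats
#' @return list of class `GeneCensus`: `unique_genes`, `duplicated_in_ir`,
#'   `total_genes`, and `unique_by_category` (named counts for
#'   protein_coding/tRNA/rRNA).
#' @export
gene_census <- function(rec, structure) {
  ann <- rec$annotations
  empty <- list(unique_genes = 0L, duplicated_in_ir = 0L, total_genes = 0L,
                unique_by_category = c(protein_coding = 0L, tRNA = 0L, rRNA = 0L))
  class(empty) <- "GeneCensus"
  if (!nrow(ann)) return(empty)
  # one row per locus
  loci <- do.call(rbind, lapply(split(ann, ann$locus), function(ex) {
    data.frame(gene = ex$gene[1L], category = ex$category[1L],
               start = min(ex$exon_start), end = max(ex$exon_end))
  }))
  loci$mid <- (loci$start + loci$end) / 2
  in_ira <- loci$mid >= structure$ira[1L] & loci$mid <= structure$ira[2L]
  in_irb <- loci$mid >= structure$irb[1L] & loci$mid <= structure$irb[2L]
  uniq <- !duplicated(loci$gene)
  unique_genes <- sum(uniq)
  dup <- 0L
  for (g in unique(loci$gene)) {
    idx <- which(loci$gene == g)
    if (length(idx) > 2L) {
      warnf("gene '%s' has %d loci; counted once unique + %d duplicated",
            g, length(idx), length(idx) - 1L)
      dup <- dup + length(idx) - 1L
    } else if (length(idx) == 2L && any(in_ira[idx]) && any(in_irb[idx])) {
      dup <- dup + 1L
    }
  }
  by_cat <- table(factor(loci$category[uniq], levels = GENE_CATEGORIES))
  out <- list(unique_genes = unique_genes, duplicated_in_ir = dup,
              total_genes = unique_genes + dup,
              unique_by_category = setNames(as.integer(by_cat), GENE_CATEGORIES))
  class(out) <- "GeneCensus"
  out
}

#' @export
print.GeneCensus <- function(x, ...) {
  cat(sprintf("GeneCensus: %d unique (+%d IR-duplicated) = %d total [pc %d, tRNA %d, rRNA %d]\n",
              x$unique_genes, x$duplicated_in_ir, x$total_genes,
              x$unique_by_category[["protein_coding"]],
              x$unique_by_category[["tRNA"]], x$unique_by_category[["rRNA"]]))
  invisible(x)
}
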