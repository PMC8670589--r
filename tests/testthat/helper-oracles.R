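# Independent oracles used across the suite. Each one recomputes a result
# by a different route than the package implementation (regex
# backreferences for SSRs, dense offset scans for repeats and inverted
# duplications, Biostrings dynamic programming for alignments, direct
# counting for GC), so agreement is meaningful.

ACGT <- c("A", "C", "G", "T")

random_seq <- function(n, gc = 0.38) {
  paste0(sample(ACGT, n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# --- SSR oracle: perl regex with backreferences ---------------------------
oracle_find_ssrs <- function(s, thresholds = ssr_thresholds()) {
  out <- list()
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, thr - 1L)
    m <- gregexpr(pat, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (i in seq_along(m)) {
      start <- m[i]
      len <- attr(m, "match.length")[i]
      copies <- len %/% u
      motif <- substring(s, start, start + u - 1L)
      # report only at the smallest unit: primitive motifs only
      prim <- TRUE
      if (u > 1L) for (p in seq_len(u %/% 2L)) {
        if (u %% p == 0L &&
            motif == strrep(substring(motif, 1L, p), u %/% p)) prim <- FALSE
      }
      if (!prim) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_length = u, copies = copies,
        start = start, end = start + copies * u - 1L)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(), unit_length = integer(),
                      copies = integer(), start = integer(), end = integer()))
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$start, loci$unit_length), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

# --- direct-count GC oracle ----------------------------------------------
oracle_gc <- function(s) {
  v <- strsplit(s, "")[[1L]]
  v <- v[v %in% ACGT]
  sum(v %in% c("G", "C")) / length(v)
}

# --- brute-force longest inverted duplication ----------------------------
# dense scan over all offsets between the sequence and its reverse
# complement; returns the longest exact run as the two s-intervals
oracle_longest_inverted <- function(s) {
  sv <- strsplit(s, "")[[1L]]
  n <- length(sv)
  rcv <- rev(c("A" = "T", "C" = "G", "G" = "C", "T" = "A", "N" = "N")[sv])
  best <- list(len = 0L)
  for (d in (-(n - 1L)):(n - 1L)) {
    j <- max(1L, 1L + d):min(n, n + d)   # positions in s
    i <- j - d                           # positions in rc
    m <- sv[j] == rcv[i]
    r <- rle(m)
    if (!any(r$values)) next
    lmax <- max(r$lengths[r$values])
    if (lmax > best$len) {
      ends <- cumsum(r$lengths)
      w <- which(r$values & r$lengths == lmax)[1L]
      a2 <- j[ends[w]]; a1 <- a2 - lmax + 1L
      i2 <- a2 - d; i1 <- a1 - d
      b1 <- n - i2 + 1L; b2 <- n - i1 + 1L
      best <- list(len = lmax, copy1 = c(min(a1, b1), min(a1, b1) + lmax - 1L),
                   copy2 = c(max(a1, b1), max(a1, b1) + lmax - 1L))
    }
  }
  best
}

# --- oligonucleotide repeat screen ---------------------------------------
# TRUE when some kind/offset carries a window of `len` with at most
# floor((1-min_id)*len) mismatches, i.e. when any repeat pair could exist
oracle_has_oligo_repeat <- function(s, len = 30L, min_id = 0.90) {
  sv <- strsplit(s, "")[[1L]]
  n <- length(sv)
  budget <- floor((1 - min_id) * len)
  comp <- c("A" = "T", "C" = "G", "G" = "C", "T" = "A", "N" = "N")
  targets <- list(forward = sv, reverse = rev(sv),
                  complement = unname(comp[sv]),
                  palindromic = unname(comp[rev(sv)]))
  for (kind in names(targets)) {
    tv <- targets[[kind]]
    for (d in (-(n - len)):(n - len)) {
      j <- max(1L, 1L + d):min(n, n + d)
      if (length(j) < len) next
      i <- j - d
      mism <- cumsum(c(0L, as.integer(sv[j] != tv[i])))
      w <- mism[(len + 1L):length(mism)] - mism[1L:(length(mism) - len)]
      hits <- which(w <= budget)
      for (h in hits) {
        # exclude the trivial self-match
        a <- j[h]
        b <- switch(kind, forward = i[h], complement = i[h],
                    reverse = n - (i[h] + len - 1L) + 1L,
                    palindromic = n - (i[h] + len - 1L) + 1L)
        if (a != b) return(TRUE)
      }
    }
  }
  FALSE
}

# --- unbanded DP alignment oracle (Biostrings) ---------------------------
# aligns two windows with the same affine scoring as the package aligner
# and walks the columns independently to list events
oracle_dp_events <- function(ref, qry) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(qry),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 1)
  ra <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  qa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  rp <- 0L
  subs <- integer(0); dels <- list(); inss <- list()
  cur_gap <- NULL
  for (col in seq_along(ra)) {
    if (ra[col] != "-") rp <- rp + 1L
    if (ra[col] != "-" && qa[col] != "-") {
      if (!is.null(cur_gap)) {
        if (cur_gap$kind == "deletion") dels[[length(dels) + 1L]] <- cur_gap
        else inss[[length(inss) + 1L]] <- cur_gap
        cur_gap <- NULL
      }
      if (ra[col] != qa[col]) subs <- c(subs, rp)
    } else {
      kind <- if (qa[col] == "-") "deletion" else "insertion"
      pos <- if (kind == "deletion") rp else max(1L, rp)
      if (is.null(cur_gap) || cur_gap$kind != kind) {
        if (!is.null(cur_gap)) {
          if (cur_gap$kind == "deletion") dels[[length(dels) + 1L]] <- cur_gap
          else inss[[length(inss) + 1L]] <- cur_gap
        }
        cur_gap <- list(kind = kind, pos = pos, len = 1L)
      } else cur_gap$len <- cur_gap$len + 1L
    }
  }
  if (!is.null(cur_gap)) {
    if (cur_gap$kind == "deletion") dels[[length(dels) + 1L]] <- cur_gap
    else inss[[length(inss) + 1L]] <- cur_gap
  }
  list(subs = subs,
       indels = do.call(rbind, lapply(c(dels, inss), as.data.frame)))
}

# --- shared small generator configs --------------------------------------
small_config <- function(seed, junction_layout = FALSE, ...) {
  generator_config(
    lsc = 8000L, ssc = 2000L, ir = 2500L,
    genes = list(protein_coding = 5L, trna = 3L, rrna = 1L,
                 ir_dup = c(protein_coding = 1L, trna = 1L, rrna = 1L)),
    junction_layout = junction_layout, seed = seed, ...)
}
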