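## Long oligonucleotide repeat pairs (forward, reverse, complement,
## palindromic) of length >= 30 bp at >= 90% identity, detected by
## seed-and-extend: exact 11-bp seeds, co-diagonal seed merging, then greedy
## maximal extension under a Hamming mismatch budget (no gaps). Kind
## transforms follow the REPuter definitions: forward = identical substring,
## reverse = reversed, complement = complemented (not reversed),
## palindromic = reverse complement.

REPEAT_KINDS <- c("forward", "reverse", "complement", "palindromic")

#' Find long oligonucleotide repeat pairs
#'
#' Reports maximal repeat pairs: a pair is extended outward run-by-run as
#' long as the total Hamming mismatches stay within
#' `floor((1 - min_identity) * length)` and each absorbed mismatch block,
#' together with the match run that follows it, itself meets
#' `min_identity` (so extension crosses the isolated mismatches of a
#' degraded copy but does not creep into unrelated flanking sequence). Pair
#' ends always fall on matching bases. Pairs wholly contained in a longer reported pair of the
#' same kind are suppressed, as is the trivial self-match. `N` never matches
#' anything. The genome-scale IR duplication is itself a palindromic repeat;
#' it is reported with `is_genomic_ir = TRUE` (palindromic pairs of length
#' `>= ir_flag_min_len`) so per-genome tallies can exclude it.
#'
#' @param rec a [plastome_record()] or DNA string.
#' @param min_len minimum repeat length in bp (default 30).
#' @param min_identity minimum identity of the two copies (default 0.90).
#' @param kinds subset of `c("forward","reverse","complement","palindromic")`.
#' @param seed_len exact seed length (default 11).
#' @param ir_flag_min_len palindromic pairs at least this long are flagged
#'   as the genomic IR (default 1000).
#' @param max_seed_occ seeds occurring more often than this in the genome
#'   (low-complexity/tandem contexts) are skipped (default 40).
#' @return data frame: `kind`, `length`, `pos1`, `pos2` (1-based starts of
#'   the two copies, `pos1 <= pos2`), `identity`, `mismatches`,
#'   `is_genomic_ir`.
#' @export
find_oligo_repeats <- function(rec, min_len = 30L, min_identity = 0.90,
                               kinds = REPEAT_KINDS, seed_len = 11L,
                               ir_flag_min_len = 1000L, max_seed_occ = 40L) {
  s <- if (inherits(rec, "PlastomeRecord")) rec$sequence else normalize_sequence(rec)
  n <- nchar(s)
  if (n < 2L * min_len) stopf("sequence shorter than two copies of min_len")
  kinds <- match.arg(kinds, REPEAT_KINDS, several.ok = TRUE)
  sv <- s2c(s)
  sv[!sv %in% c("A", "C", "G", "T")] <- NA  # N never matches
  res <- list()
  for (kind in kinds) {
    tv <- transform_kind(sv, kind)
    t_str <- c2s(ifelse(is.na(tv), "N", tv))
    cand <- seed_candidates(s, t_str, seed_len, max_seed_occ)
    for (ci in seq_len(nrow(cand))) {
      ext <- extend_candidate(sv, tv, cand$i[ci], cand$p[ci], cand$len[ci],
                              min_identity)
      if (is.null(ext) || ext$len < min_len) next
      pair <- map_pair(kind, ext$i, ext$p, ext$len, n)
      if (is.null(pair)) next
      res[[length(res) + 1L]] <- data.frame(
        kind = kind, length = ext$len, pos1 = pair[1L], pos2 = pair[2L],
        identity = ext$identity, mismatches = ext$mism)
    }
  }
  if (!length(res)) {
    return(data.frame(kind = character(), length = integer(),
                      pos1 = integer(), pos2 = integer(),
                      identity = numeric(), mismatches = integer(),
                      is_genomic_ir = logical()))
  }
  out <- unique(do.call(rbind, res))
  out <- drop_contained(out)
  out$is_genomic_ir <- out$kind == "palindromic" & out$length >= ir_flag_min_len
  out <- out[order(out$kind, out$pos1, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-kind comparison target, as a character vector aligned with s positions
transform_kind <- function(sv, kind) {
  comp_na <- function(x) {
    y <- unname(COMP[ifelse(is.na(x), "N", x)])
    y[y == "N"] <- NA
    y
  }
  switch(kind,
    forward = sv,
    reverse = rev(sv),
    complement = comp_na(sv),
    palindromic = comp_na(rev(sv)))
}

# shared exact seeds between s and its transform, merged along diagonals
seed_candidates <- function(s, t_str, k, max_occ) {
  ks <- kmer_strings(s, k)
  kt <- kmer_strings(t_str, k)
  tab <- table(ks)
  keep <- names(tab)[tab <= max_occ]
  pos_s <- split(seq_along(ks), factor(ks, levels = keep))
  hit <- which(kt %in% keep)
  if (!length(hit))
    return(data.frame(i = integer(), p = integer(), len = integer()))
  pl <- pos_s[kt[hit]]
  p <- rep.int(hit, lengths(pl))       # position in transform
  i <- unlist(pl, use.names = FALSE)   # position in s
  d <- i - p
  ord <- order(d, i)
  d <- d[ord]; i <- i[ord]; p <- p[ord]
  brk <- c(TRUE, diff(d) != 0L | diff(i) > (k + 20L))
  grp <- cumsum(brk)
  i1 <- tapply(i, grp, min); i2 <- tapply(i, grp, max)
  p1 <- tapply(p, grp, min)
  data.frame(i = as.integer(i1), p = as.integer(p1),
             len = as.integer(i2 - i1 + k))
}

# greedy maximal extension of a co-diagonal core under the mismatch budget;
# ends are trimmed to matches; returns NULL if the core itself is invalid
extend_candidate <- function(sv, tv, i0, p0, core_len, min_identity) {
  n <- length(sv)
  slack <- max(200L, core_len %/% 4L)
  lo <- max(1L - min(i0, p0), -slack)           # relative offsets
  hi <- min(n - max(i0 + core_len - 1L, p0 + core_len - 1L), slack)
  idx <- (i0 + lo):(i0 + core_len - 1L + hi)
  pdx <- (p0 + lo):(p0 + core_len - 1L + hi)
  m <- !is.na(sv[idx]) & !is.na(tv[pdx]) & sv[idx] == tv[pdx]
  r <- rle(m)
  re <- cumsum(r$lengths); rs <- re - r$lengths + 1L
  # locate the match-run containing/overlapping the core
  core_a <- 1L - lo
  runs <- which(r$values)
  if (!length(runs)) return(NULL)
  # pick the longest match-run overlapping the core region
  core_b <- core_a + core_len - 1L
  ov <- runs[rs[runs] <= core_b & re[runs] >= core_a]
  if (!length(ov)) return(NULL)
  cur <- ov[which.max(r$lengths[ov])]
  a <- rs[cur]; b <- re[cur]; mism <- 0L
  budget_ok <- function(mm, len) mm <= floor((1 - min_identity) * len)
  # an absorbed mismatch block must keep the extension itself at the
  # minimum identity (its following match run long enough), as well as the
  # whole pair: this stops extension into unrelated flanking sequence while
  # still crossing the isolated mismatches of a degraded repeat copy
  local_ok <- function(mm_blk, match_run)
    match_run / (match_run + mm_blk) >= min_identity
  left <- cur; right <- cur
  repeat {
    moved <- FALSE
    # absorb one mismatch-run + match-run to the right
    if (right + 2L <= length(r$lengths)) {
      mm_blk <- r$lengths[right + 1L]
      mm2 <- mism + mm_blk
      b2 <- re[right + 2L]
      if (local_ok(mm_blk, r$lengths[right + 2L]) &&
          budget_ok(mm2, b2 - a + 1L)) {
        mism <- mm2; b <- b2; right <- right + 2L; moved <- TRUE
      }
    }
    if (left - 2L >= 1L) {
      mm_blk <- r$lengths[left - 1L]
      mm2 <- mism + mm_blk
      a2 <- rs[left - 2L]
      if (local_ok(mm_blk, r$lengths[left - 2L]) &&
          budget_ok(mm2, b - a2 + 1L)) {
        mism <- mm2; a <- a2; left <- left - 2L; moved <- TRUE
      }
    }
    if (!moved) break
  }
  len <- b - a + 1L
  list(i = i0 + lo + a - 1L, p = p0 + lo + a - 1L, len = len,
       mism = mism, identity = 1 - mism / len)
}

# map (position in s, position in transform, length) to the two copy starts
# in s coordinates, canonically ordered; NULL for the trivial self-match
map_pair <- function(kind, i, p, len, n) {
  j <- switch(kind,
    forward = p,
    complement = p,
    reverse = n - (p + len - 1L) + 1L,
    palindromic = n - (p + len - 1L) + 1L)
  if (i == j && kind %in% c("forward", "complement")) return(NULL)
  if (i == j && len %% 2L == 0L && kind %in% c("reverse", "palindromic")) {
    # a self-reverse(-complement) span pairs with itself; keep only if the
    # two halves are distinct copies, i.e. never for the same start
    return(NULL)
  }
  if (i == j) return(NULL)
  as.integer(sort(c(i, j)))
}

# suppress pairs wholly contained in a longer same-kind pair, and collapse
# overlapping pairs that lie on the same match diagonal (alternative greedy
# extensions of one physical repeat), keeping the longest
drop_contained <- function(df) {
  diag_of <- function(df) ifelse(df$kind %in% c("forward", "complement"),
                                 df$pos2 - df$pos1,
                                 df$pos1 + df$pos2 + df$length)
  df$.diag <- diag_of(df)
  ord <- order(-df$length, df$pos1)
  df <- df[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (a in seq_len(nrow(df))) {
    if (!keep[a]) next
    for (b in seq_len(nrow(df))) {
      if (a == b || !keep[b] || df$kind[a] != df$kind[b]) next
      if (df$length[b] > df$length[a]) next
      same_diag <- df$.diag[a] == df$.diag[b]
      overlap1 <- df$pos1[b] <= df$pos1[a] + df$length[a] - 1L &&
                  df$pos1[b] + df$length[b] - 1L >= df$pos1[a]
      nested <- df$pos1[b] >= df$pos1[a] &&
        df$pos1[b] + df$length[b] <= df$pos1[a] + df$length[a] &&
        df$pos2[b] >= df$pos2[a] &&
        df$pos2[b] + df$length[b] <= df$pos2[a] + df$length[a]
      if ((same_diag && overlap1 && df$length[b] < df$length[a]) || nested)
        keep[b] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  df$.diag <- NULL
  df
}

#' Tally repeat pairs by kind
#'
#' @param repeats output of [find_oligo_repeats()].
#' @param drop_genomic_ir exclude pairs flagged as the genome-scale IR
#'   (default TRUE, matching how per-genome repeat tallies are reported).
#' @return named integer vector with counts for forward, reverse,
#'   complement, palindromic.
#' @export
summarize_repeat_kinds <- function(repeats, drop_genomic_ir = TRUE) {
  if (drop_genomic_ir && nrow(repeats))
    repeats <- repeats[!repeats$is_genomic_ir, , drop = FALSE]
  tab <- table(factor(repeats$kind, levels = REPEAT_KINDS))
  setNames(as.integer(tab), REPEAT_KINDS)
}
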