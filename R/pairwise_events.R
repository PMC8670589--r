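## Anchored global alignment of near-identical sequences and extraction of
## substitution / InDel events with transition-transversion classification.
## The aligner chains k-mers that are unique in both sequences, merges them
## into exact blocks, and closes the short segments between blocks with a
## dense affine-gap dynamic program (match +1, mismatch -2, gap open -5,
## gap extend -1; a gap of length L costs 5 + L). Gap runs are left-shifted
## to the lowest reference coordinate so event coordinates are deterministic
## in homopolymer and repeat contexts.

#' @useDynLib plastcomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SUB_CATEGORIES <- c("A/C", "C/T", "A/G", "A/T", "C/G", "G/T")

#' Globally align two near-identical DNA sequences
#'
#' @param ref,qry DNA strings (or [plastome_record()]s) at roughly >= 95%
#'   identity; more divergent inputs raise an error advising an external
#'   aligner.
#' @param k anchor k-mer length (default 21).
#' @param max_segment largest inter-anchor segment closed by dense dynamic
#'   programming (default 2500 bp); longer unanchored segments indicate the
#'   sequences are too divergent for this aligner.
#' @param ref_id,qry_id identifiers recorded in the alignment.
#' @return object of class `PairwiseAlignment`: `ref_id`, `qry_id`, and the
#'   two equal-length gapped rows `ref_aln`, `qry_aln`.
#' @export
align_near_identical <- function(ref, qry, k = 21L, max_segment = 2500L,
                                 ref_id = "ref", qry_id = "qry") {
  if (inherits(ref, "PlastomeRecord")) { ref_id <- ref$id; ref <- ref$sequence }
  if (inherits(qry, "PlastomeRecord")) { qry_id <- qry$id; qry <- qry$sequence }
  ref <- normalize_sequence(ref); qry <- normalize_sequence(qry)
  if (ref == qry) {
    aln <- new_alignment(ref_id, qry_id, ref, qry)
    return(aln)
  }
  blocks <- anchor_blocks(ref, qry, k)
  if (is.null(blocks) || nrow(blocks) == 0L)
    stopf("sequences too divergent: no shared unique %d-mer anchors; use an external aligner", k)
  ra <- character(0); qa <- character(0)
  # positions consumed so far (exclusive end of previous block)
  rprev <- 0L; qprev <- 0L
  segs <- rbind(blocks, data.frame(r = nchar(ref) + 1L, q = nchar(qry) + 1L,
                                   len = 0L))
  for (b in seq_len(nrow(segs))) {
    r1 <- rprev + 1L; q1 <- qprev + 1L
    r2 <- segs$r[b] - 1L; q2 <- segs$q[b] - 1L
    piece <- align_segment(substring(ref, r1, max(r1 - 1L, r2)),
                           substring(qry, q1, max(q1 - 1L, q2)), max_segment)
    ra <- c(ra, piece$ref); qa <- c(qa, piece$qry)
    if (segs$len[b] > 0L) {
      blk <- substring(ref, segs$r[b], segs$r[b] + segs$len[b] - 1L)
      ra <- c(ra, blk); qa <- c(qa, blk)
    }
    rprev <- segs$r[b] + segs$len[b] - 1L
    qprev <- segs$q[b] + segs$len[b] - 1L
  }
  ref_aln <- paste0(ra, collapse = ""); qry_aln <- paste0(qa, collapse = "")
  shifted <- left_shift_gaps(ref_aln, qry_aln)
  aln <- new_alignment(ref_id, qry_id, shifted[1L], shifted[2L])
  ident <- alignment_identity(aln)
  if (ident < 0.95)
    stopf("sequences too divergent (%.1f%% identity); use an external aligner",
          100 * ident)
  aln
}

new_alignment <- function(ref_id, qry_id, ref_aln, qry_aln) {
  stopifnot(nchar(ref_aln) == nchar(qry_aln))
  structure(list(ref_id = ref_id, qry_id = qry_id,
                 ref_aln = ref_aln, qry_aln = qry_aln),
            class = "PairwiseAlignment")
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  cat(sprintf("PairwiseAlignment %s vs %s: %d columns, %.2f%% identity\n",
              x$ref_id, x$qry_id, nchar(x$ref_aln),
              100 * alignment_identity(x)))
  invisible(x)
}

alignment_identity <- function(aln) {
  rv <- s2c(aln$ref_aln); qv <- s2c(aln$qry_aln)
  both <- rv != "-" & qv != "-"
  if (!any(both)) return(0)
  mean(rv[both] == qv[both])
}

# chain k-mers unique in both sequences into colinear exact blocks
anchor_blocks <- function(ref, qry, k) {
  kr <- kmer_strings(ref, k); kq <- kmer_strings(qry, k)
  ur <- !(duplicated(kr) | duplicated(kr, fromLast = TRUE))
  uq <- !(duplicated(kq) | duplicated(kq, fromLast = TRUE))
  ri <- which(ur)
  qi_of <- match(kr[ri], kq)
  ok <- !is.na(qi_of) & uq[pmax(qi_of, 1L)]
  ri <- ri[ok]; qi <- qi_of[ok]
  if (!length(ri)) return(NULL)
  # longest increasing subsequence over qi (ri already increasing)
  sel <- lis_indices(qi)
  ri <- ri[sel]; qi <- qi[sel]
  # merge anchors on the same diagonal that overlap or touch
  d <- ri - qi
  new_blk <- c(TRUE, !(d[-1L] == d[-length(d)] &
                       ri[-1L] <= ri[-length(ri)] + k))
  grp <- cumsum(new_blk)
  r1 <- tapply(ri, grp, min); rend <- tapply(ri, grp, max) + k - 1L
  q1 <- tapply(qi, grp, min)
  blocks <- data.frame(r = as.integer(r1), q = as.integer(q1),
                       len = as.integer(rend - r1 + 1L))
  # guard against rare crossing blocks after merging
  keep <- rep(TRUE, nrow(blocks))
  last_r <- 0L; last_q <- 0L
  for (b in seq_len(nrow(blocks))) {
    if (blocks$r[b] <= last_r || blocks$q[b] <= last_q) { keep[b] <- FALSE; next }
    last_r <- blocks$r[b] + blocks$len[b] - 1L
    last_q <- blocks$q[b] + blocks$len[b] - 1L
  }
  blocks[keep, , drop = FALSE]
}

# indices of a longest strictly increasing subsequence (patience sorting)
lis_indices <- function(x) lis_indices_cpp(as.integer(x))

align_segment <- function(r, q, max_segment) {
  if (!nzchar(r) && !nzchar(q)) return(list(ref = character(0), qry = character(0)))
  if (!nzchar(r)) return(list(ref = strrep("-", nchar(q)), qry = q))
  if (!nzchar(q)) return(list(ref = r, qry = strrep("-", nchar(r))))
  if (r == q) return(list(ref = r, qry = q))
  if (max(nchar(r), nchar(q)) > max_segment)
    stopf("sequences too divergent: unanchored segment of %d bp; use an external aligner",
          max(nchar(r), nchar(q)))
  piece <- nw_affine(r, q)
  list(ref = piece$ref, qry = piece$qry)
}

# shift every gap run to the lowest reference coordinate that yields an
# equivalent alignment: a run can move one column left when the retained
# base at its left equals the base at its right end in the gapless row
left_shift_gaps <- function(ref_aln, qry_aln) {
  rows <- list(r = s2c(ref_aln), q = s2c(qry_aln))
  for (gapped in c("r", "q")) {
    other <- if (gapped == "r") "q" else "r"
    g <- rows[[gapped]]; o <- rows[[other]]
    runs <- rle(g == "-")
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (ri in which(runs$values)) {
      a <- starts[ri]; b <- ends[ri]
      while (a > 1L && g[a - 1L] != "-" && o[a - 1L] == o[b]) {
        g[b] <- g[a - 1L]; g[a - 1L] <- "-"
        # rotate the gapless row's content: the other row is unchanged;
        # only the gapped row's base moves from the left edge to the end
        a <- a - 1L; b <- b - 1L
      }
    }
    rows[[gapped]] <- g
  }
  c(c2s(rows$r), c2s(rows$q))
}

#' Extract substitution and InDel events from a pairwise alignment
#'
#' One substitution per mismatching non-gap column (columns containing `N`
#' are skipped); one InDel event per maximal gap run in either row.
#' Deletions (gaps in the query row) are anchored at the first deleted
#' reference base; insertions (gaps in the reference row) at the reference
#' base preceding the run (position 1 if the run starts the alignment).
#'
#' @param aln a `PairwiseAlignment`.
#' @return list with `substitutions` (data frame `ref_pos`, `ref_base`,
#'   `qry_base`, `pair_category`, `is_transition`) and `indels` (data frame
#'   `ref_pos`, `length`, `kind`).
#' @export
extract_events <- function(aln) {
  rv <- s2c(aln$ref_aln); qv <- s2c(aln$qry_aln)
  refpos <- cumsum(rv != "-")
  acgt <- c("A", "C", "G", "T")
  is_sub <- rv != "-" & qv != "-" & rv != qv & rv %in% acgt & qv %in% acgt
  subs <- data.frame(ref_pos = refpos[is_sub],
                     ref_base = rv[is_sub], qry_base = qv[is_sub])
  if (nrow(subs)) {
    pair <- t(apply(cbind(subs$ref_base, subs$qry_base), 1L, sort))
    subs$pair_category <- paste(pair[, 1L], pair[, 2L], sep = "/")
    subs$is_transition <- subs$pair_category %in% c("A/G", "C/T")
  } else {
    subs$pair_category <- character(0); subs$is_transition <- logical(0)
  }
  indels <- list()
  for (row in c("del", "ins")) {
    v <- if (row == "del") qv else rv
    runs <- rle(v == "-")
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (ri in which(runs$values)) {
      pos <- if (row == "del") refpos[starts[ri]]
             else max(1L, refpos[starts[ri]])
      indels[[length(indels) + 1L]] <- data.frame(
        ref_pos = pos, length = runs$lengths[ri],
        kind = if (row == "del") "deletion" else "insertion")
    }
  }
  indels <- if (length(indels)) do.call(rbind, indels)
            else data.frame(ref_pos = integer(), length = integer(),
                            kind = character())
  indels <- indels[order(indels$ref_pos), , drop = FALSE]
  rownames(indels) <- NULL
  list(substitutions = subs, indels = indels)
}

#' Summarize substitutions by pair category with Ts/Tv ratio
#'
#' @param events substitution data frame from [extract_events()], or a named
#'   vector/list of counts for the six unordered base-pair categories
#'   `A/C, C/T, A/G, A/T, C/G, G/T`.
#' @return list of class `SubstitutionSummary`: `counts` (named, six
#'   categories), `ts_count` (`C/T + A/G`), `tv_count`, and `ts_tv_ratio`
#'   rounded to 2 decimals (`NA` when there are no transversions).
#' @export
summarize_substitutions <- function(events) {
  if (is.data.frame(events)) {
    counts <- table(factor(events$pair_category, levels = SUB_CATEGORIES))
    counts <- setNames(as.integer(counts), SUB_CATEGORIES)
  } else {
    events <- unlist(events)
    if (!all(SUB_CATEGORIES %in% names(events)))
      stopf("counts must be named with the six categories %s",
            paste(SUB_CATEGORIES, collapse = ", "))
    counts <- setNames(as.integer(events[SUB_CATEGORIES]), SUB_CATEGORIES)
  }
  ts <- counts[["C/T"]] + counts[["A/G"]]
  tv <- sum(counts) - ts
  ratio <- if (tv > 0L) round(ts / tv, 2L) else NA_real_
  structure(list(counts = counts, ts_count = ts, tv_count = tv,
                 ts_tv_ratio = ratio),
            class = "SubstitutionSummary")
}

#' @export
print.SubstitutionSummary <- function(x, ...) {
  cat("SubstitutionSummary\n")
  for (cat_ in names(x$counts))
    cat(sprintf("  %-4s %d\n", cat_, x$counts[[cat_]]))
  cat(sprintf("  Ts %d, Tv %d, Ts/Tv %s\n", x$ts_count, x$tv_count,
              ifelse(is.na(x$ts_tv_ratio), "NA", format(x$ts_tv_ratio))))
  invisible(x)
}

#' Concatenate protein-coding genes of a record
#'
#' Splices each listed gene (exons joined in genome order, reverse
#' complemented for minus-strand genes) and concatenates the genes in genome
#' order of their first exon. For IR-duplicated genes the locus with the
#' smallest start coordinate is used.
#'
#' @param rec a [plastome_record()].
#' @param gene_list character vector of gene names; all must be annotated.
#' @return DNA string.
#' @export
concatenate_genes <- function(rec, gene_list) {
  ann <- rec$annotations
  missing <- setdiff(gene_list, ann$gene)
  if (length(missing))
    stopf("gene(s) not annotated: %s", paste(missing, collapse = ", "))
  first_locus <- vapply(gene_list, function(g) {
    loci <- unique(ann$locus[ann$gene == g])
    starts <- vapply(loci, function(l) min(ann$exon_start[ann$locus == l]), 0L)
    loci[which.min(starts)]
  }, 0L)
  starts <- vapply(first_locus, function(l) min(ann$exon_start[ann$locus == l]), 0L)
  ord <- order(starts)
  paste0(vapply(first_locus[ord], function(l) splice_locus(rec, l), ""),
         collapse = "")
}
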