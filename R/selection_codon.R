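## Per-gene Ka/Ks by the Nei-Gojobori (1986) counting method with
## Jukes-Cantor multiple-hit correction, selection categorization, and
## codon-usage / amino-acid-frequency profiling. The standard genetic code
## is used; internal stop codons are treated as errors. Pathways through
## stop codons are excluded from multi-hit pathway averaging (weight is
## redistributed over the remaining minimal paths).

GENCODE <- NULL  # populated at load; codon -> amino acid ('*' = stop)

.onLoad <- function(libname, pkgname) {
  gc_tab <- Biostrings::GENETIC_CODE
  utils::assignInMyNamespace("GENCODE", setNames(as.character(gc_tab), names(gc_tab)))
}

codon_split <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

translate_codons <- function(codons) {
  aa <- GENCODE[codons]
  aa[is.na(aa)] <- "X"  # non-ACGT codon
  unname(aa)
}

#' Pair the codons of two homologous coding sequences
#'
#' Terminal stop codons are trimmed, the sequences are translated, and the
#' proteins are globally aligned to guide codon pairing. Codon pairs
#' involving an alignment gap or a non-ACGT base are excluded from
#' counting.
#'
#' @param ref_cds,qry_cds in-frame coding sequences (length divisible by 3
#'   after terminal-stop trimming).
#' @param gene gene name used in error messages.
#' @return data frame with columns `ref_codon`, `qry_codon`.
#' @export
codon_align <- function(ref_cds, qry_cds, gene = "cds") {
  prep <- function(cds, which) {
    cds <- normalize_sequence(cds)
    if (nchar(cds) %% 3L != 0L)
      stopf("%s (%s): length %d not divisible by 3", gene, which, nchar(cds))
    codons <- codon_split(cds)
    aa <- translate_codons(codons)
    if (length(aa) && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]; aa <- aa[-length(aa)]
    }
    stops <- which(aa == "*")
    if (length(stops))
      stopf("internal stop codon in %s (%s) at codon %d", gene, which, stops[1L])
    list(codons = codons, aa = aa)
  }
  r <- prep(ref_cds, "ref"); q <- prep(qry_cds, "qry")
  if (identical(r$aa, q$aa) || length(r$aa) == length(q$aa)) {
    pairs <- data.frame(ref_codon = r$codons, qry_codon = q$codons)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(c2s(r$aa)), Biostrings::AAString(c2s(q$aa)),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    pa <- s2c(as.character(Biostrings::alignedPattern(aln)))
    sa <- s2c(as.character(Biostrings::alignedSubject(aln)))
    ri <- cumsum(pa != "-"); qi <- cumsum(sa != "-")
    both <- pa != "-" & sa != "-"
    pairs <- data.frame(ref_codon = r$codons[ri[both]],
                        qry_codon = q$codons[qi[both]])
  }
  acgt_only <- function(x) !grepl("[^ACGT]", x)
  pairs[acgt_only(pairs$ref_codon) & acgt_only(pairs$qry_codon), , drop = FALSE]
}

# synonymous/non-synonymous site counts of one codon, normalized to 3 sites;
# changes creating a stop codon count as non-synonymous
codon_sites <- function(codon) {
  aa <- GENCODE[[codon]]
  s <- 0; nn <- 0
  chars <- s2c(codon)
  for (p in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == chars[p]) next
      mut <- chars; mut[p] <- b
      maa <- GENCODE[[c2s(mut)]]
      if (maa != "*" && maa == aa) s <- s + 1 else nn <- nn + 1
    }
  }
  c(S = 3 * s / (s + nn), N = 3 * nn / (s + nn))
}

# Sd/Nd between two codons, averaged over minimal mutational pathways;
# pathways visiting a stop codon are dropped and the weight redistributed;
# if every pathway is blocked, all are used
codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  pos <- which(s2c(c1) != s2c(c2))
  paths <- if (length(pos) == 1L) list(pos) else
    lapply(asplit(permutations_of(pos), 1L), as.integer)
  step_counts <- function(order_) {
    cur <- s2c(c1); sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order_) {
      nxt <- cur; nxt[p] <- s2c(c2)[p]
      a1 <- GENCODE[[c2s(cur)]]; a2 <- GENCODE[[c2s(nxt)]]
      if (a2 == "*") blocked <- TRUE
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  }
  res <- vapply(paths, step_counts, numeric(3))
  ok <- res[3L, ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  c(Sd = mean(res[1L, ok]), Nd = mean(res[2L, ok]))
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], permutations_of(x[-i])))
  out
}

#' Nei-Gojobori (1986) Ka and Ks from paired codons
#'
#' Synonymous (S) and non-synonymous (N) site counts are averaged over the
#' two sequences; observed synonymous/non-synonymous differences are
#' averaged over all minimal mutational pathways between differing codons
#' (pathways through stop codons excluded). Proportions are corrected for
#' multiple hits with the Jukes-Cantor formula
#' `d = -(3/4) * log(1 - (4/3) * p)`; a proportion at or above 3/4 yields
#' `NA`.
#'
#' @param pairs data frame from [codon_align()] (columns `ref_codon`,
#'   `qry_codon`), with at least one codon pair.
#' @return named numeric vector with `ka`, `ks`, and the intermediate
#'   quantities `S`, `N`, `Sd`, `Nd`, `pS`, `pN`.
#' @export
ng86 <- function(pairs) {
  if (!nrow(pairs)) stopf("ng86 requires at least one codon pair")
  sites_r <- vapply(pairs$ref_codon, codon_sites, numeric(2))
  sites_q <- vapply(pairs$qry_codon, codon_sites, numeric(2))
  S <- (sum(sites_r["S", ]) + sum(sites_q["S", ])) / 2
  N <- (sum(sites_r["N", ]) + sum(sites_q["N", ])) / 2
  diffs <- mapply(codon_diffs, pairs$ref_codon, pairs$qry_codon)
  Sd <- sum(diffs["Sd", ]); Nd <- sum(diffs["Nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p <= 0) return(0)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - (4 / 3) * p)
  }
  c(ka = jc(pN), ks = jc(pS), S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN)
}

#' Selection category from a Ka/Ks ratio
#'
#' Banding: `> 1.05` positive; `0.95`-`1.05` neutral; `0.80` up to (but not
#' including) `0.95` approximately neutral; below `0.80` purifying; `NA`
#' unclassified. The bands reproduce the field's customary labels for
#' ratios such as 0.96 ("neutral") and 0.86 ("approximately neutral").
#'
#' @param ratio Ka/Ks value (>= 0) or NA.
#' @return character vector of categories.
#' @export
categorize_selection <- function(ratio) {
  vapply(ratio, function(r) {
    if (is.na(r)) return("unclassified")
    if (r > 1.05) "positive"
    else if (r >= 0.95) "neutral"
    else if (r >= 0.80) "~neutral"
    else "purifying"
  }, "")
}

#' Per-gene selection estimates for two plastome records
#'
#' Splices each listed gene from both records, pairs codons with
#' [codon_align()], estimates Ka/Ks with [ng86()], and attaches the
#' selection category.
#'
#' @param ref_rec,qry_rec [plastome_record()]s annotated with the listed
#'   genes.
#' @param genes character vector of protein-coding gene names.
#' @return data frame: `gene`, `ka`, `ks`, `ratio`, `category`.
#' @export
gene_selection <- function(ref_rec, qry_rec, genes) {
  rows <- lapply(genes, function(g) {
    pairs <- codon_align(extract_gene_cds(ref_rec, g),
                         extract_gene_cds(qry_rec, g), gene = g)
    est <- ng86(pairs)
    ratio <- if (!is.na(est[["ks"]]) && est[["ks"]] > 0)
      est[["ka"]] / est[["ks"]] else NA_real_
    data.frame(gene = g, ka = est[["ka"]], ks = est[["ks"]], ratio = ratio,
               category = categorize_selection(ratio))
  })
  do.call(rbind, rows)
}

extract_gene_cds <- function(rec, gene) {
  ann <- rec$annotations
  loci <- unique(ann$locus[ann$gene == gene & ann$category == "protein_coding"])
  if (!length(loci)) stopf("protein-coding gene '%s' not annotated in %s",
                           gene, rec$id)
  starts <- vapply(loci, function(l) min(ann$exon_start[ann$locus == l]), 0L)
  splice_locus(rec, loci[which.min(starts)])
}

#' Codon usage and amino acid frequency profile
#'
#' Pools codon counts over a set of coding sequences. Amino-acid
#' frequencies are computed over non-stop residues. RSCU (relative
#' synonymous codon usage) is the observed codon count divided by the mean
#' count of its synonymous family, so every family averages 1; families
#' with zero observations get `NA`. The third-position A/T vs G/C tally is
#' included.
#'
#' @param cds_set character vector (or list) of in-frame coding sequences.
#' @return list of class `CodonProfile`: `codon_counts` (64), `aa_freq`
#'   (over non-stop residues, sums to 1), `rscu`, `third_position`
#'   (`AT`/`GC` codon counts), `skipped` (non-ACGT codons skipped).
#' @export
codon_profile <- function(cds_set) {
  cds_set <- vapply(as.list(cds_set), normalize_sequence, "")
  bad_len <- which(nchar(cds_set) %% 3L != 0L)
  if (length(bad_len))
    stopf("CDS %d has length not divisible by 3", bad_len[1L])
  codons <- unlist(lapply(cds_set, codon_split))
  valid <- !grepl("[^ACGT]", codons)
  skipped <- sum(!valid)
  if (skipped) warnf("%d non-ACGT codon(s) skipped", skipped)
  codons <- codons[valid]
  counts <- table(factor(codons, levels = names(GENCODE)))
  counts <- setNames(as.integer(counts), names(GENCODE))
  aa <- translate_codons(codons)
  aa_counts <- table(aa[aa != "*"])
  aa_freq <- as.numeric(aa_counts) / sum(aa_counts)
  names(aa_freq) <- names(aa_counts)
  # RSCU over sense codons
  rscu <- setNames(rep(NA_real_, 64L), names(GENCODE))
  for (a in unique(GENCODE)) {
    if (a == "*") next
    fam <- names(GENCODE)[GENCODE == a]
    fam_counts <- counts[fam]
    if (sum(fam_counts) > 0L) rscu[fam] <- fam_counts / mean(fam_counts)
  }
  third <- substring(codons, 3L, 3L)
  third_position <- c(AT = sum(third %in% c("A", "T")),
                      GC = sum(third %in% c("G", "C")))
  structure(list(codon_counts = counts, aa_freq = aa_freq, rscu = rscu,
                 third_position = third_position, skipped = skipped),
            class = "CodonProfile")
}

#' @export
print.CodonProfile <- function(x, ...) {
  top <- sort(x$aa_freq, decreasing = TRUE)[1:3]
  cat(sprintf("CodonProfile: %d codons; top residues %s; third position AT:GC = %d:%d\n",
              sum(x$codon_counts),
              paste(sprintf("%s %.1f%%", names(top), 100 * top), collapse = ", "),
              x$third_position[["AT"]], x$third_position[["GC"]]))
  invisible(x)
}
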