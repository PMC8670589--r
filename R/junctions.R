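## Genes at the four single-copy/inverted-repeat junctions. Junction naming
## follows the standard plastome convention for the LSC-IRb-SSC-IRa layout:
## JLB = LSC/IRb, JSB = IRb/SSC, JSA = SSC/IRa, JLA = IRa/LSC (the circular
## wrap back to position 1). Distances count the bases strictly between the
## junction and the nearest annotated base; a gene whose span contains the
## junction is reported as spanning, with the base count on each side.

#' Characterize genes at the SC/IR junctions
#'
#' For each junction the gene locus whose span contains it is reported
#' (`relation = "spans"`, with per-side base counts), otherwise the nearest
#' locus on each side within `window` bp (`relation = "upstream"` /
#' `"downstream"` of the junction, with the distance in bases strictly
#' between junction and locus). An IR-truncated copy is recognized when a
#' locus shares its name with a locus spanning the corresponding junction
#' on the opposite IR copy and is reported with `pseudogene = TRUE`.
#'
#' @param rec a [plastome_record()] in LSC-normalized coordinates.
#' @param structure the matching `QuadripartiteStructure`.
#' @param window search window for nearest genes in bp (default 2000);
#'   junctions with no annotation within the window report gene `"none"`.
#' @return data frame: `junction`, `gene`, `relation`, `side_a_bp` (bases
#'   on the upstream-region side for spanning loci, or the distance for
#'   near loci), `side_b_bp`, `pseudogene`.
#' @export
junction_report <- function(rec, structure, window = 2000L) {
  n <- nchar(rec$sequence)
  ann <- rec$annotations
  # junction position = last base of the upstream region
  junctions <- c(JLB = structure$lsc[2L], JSB = structure$irb[2L],
                 JSA = structure$ssc[2L], JLA = structure$ira[2L])
  loci <- if (nrow(ann)) do.call(rbind, lapply(split(ann, ann$locus), function(ex)
    data.frame(gene = ex$gene[1L], start = min(ex$exon_start),
               end = max(ex$exon_end)))) else
    data.frame(gene = character(), start = integer(), end = integer())
  # circular distance from junction j (between j and j+1) to a locus
  rows <- lapply(names(junctions), function(jn) {
    j <- junctions[[jn]]
    spanning <- loci[loci$start <= j & loci$end > j, , drop = FALSE]
    if (nrow(spanning)) {
      g <- spanning[which.max(spanning$end - spanning$start), , drop = FALSE]
      return(data.frame(junction = jn, gene = g$gene, relation = "spans",
                        side_a_bp = j - g$start + 1L, side_b_bp = g$end - j,
                        pseudogene = FALSE))
    }
    # JLA wraps: genes at the genome start are downstream of the junction
    up_gap <- j - loci$end                      # locus entirely before j
    down_start <- if (jn == "JLA") loci$start + n else loci$start
    down_gap <- down_start - j - 1L             # bases strictly between
    up_ok <- which(up_gap >= 0L & up_gap <= window)
    down_ok <- which(down_gap >= 0L & down_gap <= window)
    out <- NULL
    if (length(up_ok)) {
      b <- up_ok[which.min(up_gap[up_ok])]
      out <- rbind(out, data.frame(junction = jn, gene = loci$gene[b],
                                   relation = "upstream",
                                   side_a_bp = up_gap[b], side_b_bp = NA_integer_,
                                   pseudogene = FALSE))
    }
    if (length(down_ok)) {
      b <- down_ok[which.min(down_gap[down_ok])]
      out <- rbind(out, data.frame(junction = jn, gene = loci$gene[b],
                                   relation = "downstream",
                                   side_a_bp = NA_integer_, side_b_bp = down_gap[b],
                                   pseudogene = FALSE))
    }
    if (is.null(out))
      out <- data.frame(junction = jn, gene = "none", relation = "none",
                        side_a_bp = NA_integer_, side_b_bp = NA_integer_,
                        pseudogene = FALSE)
    out
  })
  rep_ <- do.call(rbind, rows)
  # truncated IR copies: a non-spanning locus named like a locus that spans
  # the mirrored junction on the other IR copy
  spans <- rep_[rep_$relation == "spans", , drop = FALSE]
  mirror <- c(JLB = "JLA", JLA = "JLB", JSB = "JSA", JSA = "JSB")
  for (i in seq_len(nrow(rep_))) {
    if (rep_$relation[i] %in% c("upstream", "downstream") &&
        rep_$gene[i] %in% spans$gene[spans$junction == mirror[[rep_$junction[i]]]])
      rep_$pseudogene[i] <- TRUE
  }
  rownames(rep_) <- NULL
  rep_
}
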