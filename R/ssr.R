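## Microsatellite (SSR) scanning under MISA-style unit-length thresholds:
## mono >= 10 copies, di >= 5, tri >= 4, tetra/penta/hexa >= 3. Only perfect
## (uninterrupted) repeats are reported; a run whose unit is itself periodic
## is reported only at the smallest unit.

#' Default MISA-style copy-number thresholds by unit length
#' @return named integer vector for unit lengths 1..6.
#' @export
ssr_thresholds <- function() {
  c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)
}

#' Find microsatellites (SSRs)
#'
#' Scans for maximal, non-extendable perfect tandem repeats of unit length
#' 1-6 meeting the per-unit-length copy thresholds. `N` bases terminate any
#' run. A run whose unit is a repetition of a shorter unit (e.g. `AAAAAA`
#' seen as `AA` x 3) is reported only at the smallest unit.
#'
#' @param rec a [plastome_record()] or a plain DNA string.
#' @param thresholds named vector mapping unit length (`"1"`..`"6"`) to the
#'   minimum copy number; defaults to [ssr_thresholds()].
#' @return data frame of loci sorted by start: `motif` (repeat unit as read
#'   on the + strand, starting at the locus start), `unit_length`, `copies`,
#'   `start`, `end` (1-based inclusive).
#' @export
find_ssrs <- function(rec, thresholds = ssr_thresholds()) {
  s <- if (inherits(rec, "PlastomeRecord")) rec$sequence else normalize_sequence(rec)
  units <- as.integer(names(thresholds))
  if (!all(1:6 %in% units)) stopf("thresholds must cover unit lengths 1..6")
  sv <- s2c(s)
  n <- length(sv)
  valid <- sv %in% c("A", "C", "G", "T")
  out <- list()
  for (u in sort(units)) {
    thr <- thresholds[[as.character(u)]]
    if (n < u * thr) next
    eq <- sv[1:(n - u)] == sv[(u + 1L):n] & valid[1:(n - u)] & valid[(u + 1L):n]
    r <- rle(eq)
    ends_at <- cumsum(r$lengths)
    starts_at <- ends_at - r$lengths + 1L
    hit <- which(r$values & r$lengths >= u * (thr - 1L))
    for (h in hit) {
      start <- starts_at[h]
      m <- r$lengths[h]              # periodic stretch length = m + u
      copies <- (m + u) %/% u
      if (copies < thr) next
      motif <- substring(s, start, start + u - 1L)
      if (!is_primitive(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_length = u, copies = copies,
        start = start, end = start + copies * u - 1L)
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(), unit_length = integer(),
                      copies = integer(), start = integer(), end = integer()))
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$start, loci$unit_length), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

# TRUE unless the motif is a whole-number repetition of a shorter unit
is_primitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (p in seq_len(u %/% 2)) {
    if (u %% p == 0L &&
        motif == strrep(substring(motif, 1L, p), u %/% p)) return(FALSE)
  }
  TRUE
}

#' Canonical motif class of an SSR
#'
#' Reporting class used in plastome surveys: the lexicographically smallest
#' rotation of the unit, paired with the smallest rotation of its reverse
#' complement (e.g. motif `T` is class `"A/T"`, motif `TA` is `"AT/AT"`).
#'
#' @param motif repeat unit string.
#' @return character scalar class label.
#' @export
ssr_class <- function(motif) {
  vapply(motif, function(m) {
    a <- min_rotation(m)
    b <- min_rotation(revcomp(m))
    paste(sort(c(a, b)), collapse = "/")
  }, "", USE.NAMES = FALSE)
}

min_rotation <- function(x) {
  u <- nchar(x)
  rots <- vapply(seq_len(u), function(i)
    paste0(substring(x, i, u), substring(x, 1L, i - 1L)), "")
  min(rots)
}

#' Classify SSR loci by region and genic context
#'
#' Assigns each locus the quadripartite region containing its start, the
#' coding/non-coding context (coding when the start falls inside any
#' annotated exon), and the canonical motif class, then tabulates counts by
#' class x region x context. A locus spanning a region junction is assigned
#' to its start's region and flagged.
#'
#' @param loci output of [find_ssrs()].
#' @param structure a `QuadripartiteStructure` for the same record.
#' @param annotations exon-level annotation data frame (may be empty).
#' @param unique_ir count the IR only once: loci starting in IRa are
#'   dropped before summarizing (default FALSE, i.e. the whole genome is
#'   tallied as scanned).
#' @return list with `loci` (input plus `class`, `region`, `context`,
#'   `spans_junction`) and `summary` (counts by class, region, context).
#' @export
classify_ssrs <- function(loci, structure, annotations = NULL,
                          unique_ir = FALSE) {
  if (unique_ir && nrow(loci)) {
    loci <- loci[!(loci$start >= structure$ira[1L] &
                   loci$start <= structure$ira[2L]), , drop = FALSE]
  }
  if (nrow(loci) == 0L) {
    return(list(loci = cbind(loci, class = character(), region = character(),
                             context = character(), spans_junction = logical()),
                summary = data.frame(class = character(), region = character(),
                                     context = character(), n = integer())))
  }
  regs <- region_intervals(structure)
  region_of <- function(p) {
    for (r in names(regs)) {
      if (p >= regs[[r]][1L] && p <= regs[[r]][2L]) return(r)
    }
    NA_character_
  }
  loci$class <- ssr_class(loci$motif)
  loci$region <- vapply(loci$start, region_of, "")
  end_region <- vapply(loci$end, region_of, "")
  loci$spans_junction <- loci$region != end_region
  coding <- rep(FALSE, nrow(loci))
  if (!is.null(annotations) && nrow(annotations)) {
    for (i in seq_len(nrow(loci))) {
      coding[i] <- any(loci$start[i] >= annotations$exon_start &
                       loci$start[i] <= annotations$exon_end)
    }
  }
  loci$context <- ifelse(coding, "coding", "non-coding")
  summ <- as.data.frame(table(class = loci$class, region = loci$region,
                              context = loci$context),
                        responseName = "n", stringsAsFactors = FALSE)
  summ <- summ[summ$n > 0L, , drop = FALSE]
  summ <- summ[order(summ$class, summ$region, summ$context), , drop = FALSE]
  rownames(summ) <- NULL
  list(loci = loci, summary = summ)
}
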