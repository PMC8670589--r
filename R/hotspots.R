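## Mutation-hotspot analysis: substitutions, InDels and oligonucleotide
## repeat copies are binned into fixed windows along the reference
## (default 250 bp, anchored at position 1, final partial bin retained),
## then correlated pairwise (Pearson) and summarized as event-level
## co-occurrence percentages.

#' Bin mutational events along the reference
#'
#' Bins are `[1,250], [251,500], ...` for the default bin size; the final
#' partial bin is retained. Substitutions and InDels are assigned by their
#' reference position; each repeat COPY is assigned by its start, so a
#' repeat pair contributes two counts.
#'
#' @param substitutions integer vector of substitution positions (or the
#'   data frame from [extract_events()], whose `ref_pos` is used).
#' @param indels integer vector of InDel anchor positions (or the event
#'   data frame).
#' @param repeats integer vector of repeat copy starts, or the data frame
#'   from [find_oligo_repeats()] (both `pos1` and `pos2` are counted;
#'   pairs flagged `is_genomic_ir` are dropped).
#' @param ref_length reference length in bp.
#' @param bin_size bin width in bp (default 250).
#' @return list of class `BinnedEventTracks`: `bin_size`, `n_bins`,
#'   `bin_start`, `bin_end`, and integer count vectors `substitutions`,
#'   `indels`, `repeats`.
#' @export
bin_events <- function(substitutions, indels, repeats, ref_length,
                       bin_size = 250L) {
  pos_of <- function(x, what) {
    if (is.data.frame(x)) {
      x <- if (what == "repeats") {
        if (nrow(x) && !is.null(x$is_genomic_ir))
          x <- x[!x$is_genomic_ir, , drop = FALSE]
        c(x$pos1, x$pos2)
      } else x$ref_pos
    }
    x <- as.integer(x)
    if (length(x) && (min(x) < 1L || max(x) > ref_length))
      stopf("%s coordinates outside [1, %d]", what, ref_length)
    x
  }
  subs <- pos_of(substitutions, "substitution")
  ind <- pos_of(indels, "indel")
  rep_ <- pos_of(repeats, "repeats")
  n_bins <- as.integer(ceiling(ref_length / bin_size))
  binize <- function(p) tabulate((p - 1L) %/% bin_size + 1L, n_bins)
  structure(list(
    bin_size = as.integer(bin_size), n_bins = n_bins,
    bin_start = (seq_len(n_bins) - 1L) * as.integer(bin_size) + 1L,
    bin_end = pmin(seq_len(n_bins) * as.integer(bin_size), as.integer(ref_length)),
    substitutions = binize(subs), indels = binize(ind), repeats = binize(rep_)),
    class = "BinnedEventTracks")
}

#' Pairwise Pearson correlations among binned event tracks
#'
#' All bins (including empty ones) enter the computation; set
#' `drop_empty = TRUE` to restrict to bins carrying at least one event of
#' any class.
#'
#' @param tracks a `BinnedEventTracks`.
#' @param drop_empty drop bins with no events of any class (default FALSE).
#' @return named numeric vector `r_sub_indel`, `r_indel_repeat`,
#'   `r_sub_repeat`; a zero-variance track yields `NA` with a warning.
#' @export
correlate_tracks <- function(tracks, drop_empty = FALSE) {
  x <- tracks$substitutions; y <- tracks$indels; z <- tracks$repeats
  if (drop_empty) {
    keep <- (x + y + z) > 0L
    x <- x[keep]; y <- y[keep]; z <- z[keep]
  }
  if (length(x) < 3L) stopf("need at least 3 bins")
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warnf("zero-variance track; correlation undefined")
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  c(r_sub_indel = safe_cor(x, y),
    r_indel_repeat = safe_cor(y, z),
    r_sub_repeat = safe_cor(x, z))
}

#' Correlation strength label
#'
#' Half-open bands on `|r|`: `[0, 0.10)` none; `[0.10, 0.20)`
#' negligible/very weak; `[0.20, 0.30)` weak; `[0.30, 0.40)` moderate;
#' `[0.40, 0.70)` strong; `[0.70, 1.0)` very strong; `1.0` perfect.
#'
#' @param r numeric vector of correlations in `[-1, 1]` (NA allowed).
#' @return character vector of labels.
#' @export
strength_label <- function(r) {
  vapply(r, function(v) {
    if (is.na(v)) return(NA_character_)
    a <- abs(v)
    if (a >= 1) "perfect"
    else if (a >= 0.70) "very strong"
    else if (a >= 0.40) "strong"
    else if (a >= 0.30) "moderate"
    else if (a >= 0.20) "weak"
    else if (a >= 0.10) "negligible/very weak"
    else "none"
  }, "")
}

#' Event-level co-occurrence percentages
#'
#' `"X with Y"` is the percentage of X events lying in bins that contain at
#' least one Y event. The three reported pairs mirror the customary
#' qualitative summary: InDels with substitutions, repeat copies with
#' InDels, and repeat copies with substitutions.
#'
#' @param tracks a `BinnedEventTracks`.
#' @return named numeric vector (`pct_indels_in_sub_bins`,
#'   `pct_repeats_in_indel_bins`, `pct_repeats_in_sub_bins`), each rounded
#'   to 2 decimals; `NA` when the X class has no events.
#' @export
cooccurrence <- function(tracks) {
  pct <- function(x_counts, y_counts) {
    tot <- sum(x_counts)
    if (tot == 0L) return(NA_real_)
    round(100 * sum(x_counts[y_counts > 0L]) / tot, 2L)
  }
  c(pct_indels_in_sub_bins = pct(tracks$indels, tracks$substitutions),
    pct_repeats_in_indel_bins = pct(tracks$repeats, tracks$indels),
    pct_repeats_in_sub_bins = pct(tracks$repeats, tracks$substitutions))
}

#' Full correlation report for one genome pair
#'
#' @param tracks a `BinnedEventTracks`.
#' @param drop_empty passed to [correlate_tracks()].
#' @return list of class `CorrelationReport`: `r` (three Pearson values),
#'   `strength` (labels), `cooccurrence` (three percentages).
#' @export
correlation_report <- function(tracks, drop_empty = FALSE) {
  r <- correlate_tracks(tracks, drop_empty = drop_empty)
  structure(list(r = r, strength = strength_label(r),
                 cooccurrence = cooccurrence(tracks)),
            class = "CorrelationReport")
}

#' @export
print.CorrelationReport <- function(x, ...) {
  cat("CorrelationReport\n")
  for (i in seq_along(x$r))
    cat(sprintf("  %-15s r = %s (%s)\n", names(x$r)[i],
                ifelse(is.na(x$r[i]), "NA", sprintf("%.2f", x$r[i])),
                x$strength[i]))
  for (i in seq_along(x$cooccurrence))
    cat(sprintf("  %-26s %s%%\n", names(x$cooccurrence)[i],
                format(x$cooccurrence[i])))
  invisible(x)
}
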