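## Plastome records: construction, validation, and reading/writing the two
## supported input layouts (GenBank flat file; FASTA plus a tab-separated
## exon table). Coordinates are 1-based inclusive throughout, the GenBank
## convention. Annotations are kept as an exon-level data frame with one row
## per exon and a `locus` id grouping exons of the same gene copy, so that
## IR-duplicated genes (same name, two loci) stay distinguishable.

ANNOT_COLS <- c("gene", "category", "strand", "exon_start", "exon_end", "locus")
GENE_CATEGORIES <- c("protein_coding", "tRNA", "rRNA")

#' Construct a plastome record
#'
#' A `PlastomeRecord` bundles a circular plastid genome sequence with its
#' gene annotations. It is the unit every analysis stage consumes.
#'
#' @param id non-empty record identifier.
#' @param sequence DNA string over `{A,C,G,T,N}`; lower case and `U` are
#'   normalized on input.
#' @param annotations data frame with columns `gene`, `category` (one of
#'   `protein_coding`, `tRNA`, `rRNA`), `strand` (`+`/`-`), `exon_start`,
#'   `exon_end` (1-based inclusive) and optionally `locus` (integer id
#'   grouping exons of one gene copy). One row per exon. If `locus` is
#'   absent, exons sharing a gene name are grouped into loci by proximity
#'   (a gap of more than 5 kb between consecutive exons starts a new locus).
#' @param source free-text provenance (file path or accession).
#' @return object of class `PlastomeRecord`.
#' @export
plastome_record <- function(id, sequence, annotations = NULL, source = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stopf("record id must be a non-empty string")
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  if (n == 0L) stopf("sequence must be non-empty")
  annotations <- normalize_annotations(annotations, n)
  structure(
    list(id = id, sequence = sequence, annotations = annotations,
         source = source),
    class = "PlastomeRecord"
  )
}

normalize_annotations <- function(ann, seq_len) {
  if (is.null(ann) || nrow(as.data.frame(ann)) == 0L) {
    return(data.frame(gene = character(), category = character(),
                      strand = character(), exon_start = integer(),
                      exon_end = integer(), locus = integer()))
  }
  ann <- as.data.frame(ann)
  need <- setdiff(c("gene", "category", "strand", "exon_start", "exon_end"),
                  names(ann))
  if (length(need))
    stopf("annotation table lacks column(s): %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(ann$category), GENE_CATEGORIES)
  if (length(bad))
    stopf("unknown gene category: %s", paste(bad, collapse = ", "))
  if (!all(ann$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  ann$exon_start <- as.integer(ann$exon_start)
  ann$exon_end <- as.integer(ann$exon_end)
  if (any(ann$exon_start < 1L) || any(ann$exon_end > seq_len) ||
      any(ann$exon_start > ann$exon_end))
    stopf("annotation interval outside [1, %d] or inverted", seq_len)
  if (is.null(ann$locus)) ann$locus <- infer_loci(ann)
  ann$locus <- as.integer(ann$locus)
  ann[ANNOT_COLS]
}

# group exon rows that share a gene name into loci by positional proximity
infer_loci <- function(ann, max_gap = 5000L) {
  loc <- integer(nrow(ann))
  next_id <- 1L
  for (g in unique(ann$gene)) {
    idx <- which(ann$gene == g)
    idx <- idx[order(ann$exon_start[idx])]
    starts <- ann$exon_start[idx]
    ends <- ann$exon_end[idx]
    cur <- next_id
    loc[idx[1L]] <- cur
    if (length(idx) > 1L) {
      for (i in 2L:length(idx)) {
        if (starts[i] - ends[i - 1L] > max_gap) cur <- cur + 1L
        loc[idx[i]] <- cur
      }
    }
    next_id <- cur + 1L
  }
  loc
}

#' @export
print.PlastomeRecord <- function(x, ...) {
  cat(sprintf("PlastomeRecord '%s': %s bp, %d annotation exon(s), %d gene locus/loci\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$annotations),
              length(unique(x$annotations$locus))))
  invisible(x)
}

#' Read a plastome record from disk
#'
#' Supports a GenBank flat file (`format = "genbank"`: LOCUS, FEATURES with
#' `gene`/`CDS`/`tRNA`/`rRNA` keys and `join`/`complement` locations, ORIGIN
#' sequence) or a FASTA file accompanied by a tab-separated exon table
#' (`format = "fasta+gff"`) with columns
#' `gene, category, strand, exon_start, exon_end` (optionally `locus`).
#'
#' @param path input file (the FASTA file for `fasta+gff`).
#' @param format `"genbank"` or `"fasta+gff"`.
#' @param annotation_path exon table path for `fasta+gff`; defaults to
#'   `path` with its extension replaced by `.tsv`.
#' @return [plastome_record()] with upper-cased sequence (`U` mapped to `T`)
#'   and normalized 1-based inclusive exon intervals.
#' @export
read_plastome <- function(path, format = c("genbank", "fasta+gff"),
                          annotation_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "genbank") {
    read_plastome_genbank(path)
  } else {
    if (is.null(annotation_path))
      annotation_path <- paste0(tools::file_path_sans_ext(path), ".tsv")
    read_plastome_fasta_tsv(path, annotation_path)
  }
}

read_plastome_fasta_tsv <- function(fasta_path, tsv_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stopf("no sequence in FASTA: %s", fasta_path)
  id <- sub("\\s.*$", "", names(seqs)[1L])
  sequence <- as.character(seqs[[1L]])
  ann <- NULL
  if (file.exists(tsv_path)) {
    ann <- read.delim(tsv_path, stringsAsFactors = FALSE,
                      comment.char = "#")
  }
  plastome_record(id, sequence, ann, source = fasta_path)
}

# --- minimal GenBank flat-file parser -------------------------------------
# Handles the subset needed for annotated plastomes: the LOCUS name, the
# FEATURES table (feature keys gene/CDS/tRNA/rRNA; locations as ranges,
# join(...) and complement(...)), and the ORIGIN sequence block.

read_plastome_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_line <- grep("^LOCUS", lines)
  if (!length(locus_line)) stopf("GenBank parse error: no LOCUS line in %s", path)
  id <- strsplit(trimws(sub("^LOCUS", "", lines[locus_line[1L]])), "\\s+")[[1L]][1L]

  origin <- grep("^ORIGIN", lines)
  if (!length(origin))
    stopf("GenBank parse error: no ORIGIN block in %s", path)
  seq_lines <- lines[(origin[1L] + 1L):length(lines)]
  end <- grep("^//", seq_lines)
  if (length(end)) seq_lines <- seq_lines[seq_len(end[1L] - 1L)]
  sequence <- gsub("[0-9/ ]", "", paste0(seq_lines, collapse = ""))

  feat_start <- grep("^FEATURES", lines)
  ann <- NULL
  if (length(feat_start)) {
    feat_lines <- lines[(feat_start[1L] + 1L):(origin[1L] - 1L)]
    ann <- parse_genbank_features(feat_lines, path)
  }
  plastome_record(id, sequence, ann, source = path)
}

parse_genbank_features <- function(feat_lines, path) {
  key_map <- c(CDS = "protein_coding", tRNA = "tRNA", rRNA = "rRNA")
  # a new feature starts with a key in column 6; qualifiers start with '/'
  is_key <- grepl("^ {2,8}\\S", feat_lines) & !grepl("^\\s*/", feat_lines)
  idx <- which(is_key)
  out <- list(); locus_id <- 0L
  for (i in seq_along(idx)) {
    first <- idx[i]
    last <- if (i < length(idx)) idx[i + 1L] - 1L else length(feat_lines)
    block <- feat_lines[first:last]
    key <- sub("^\\s*(\\S+).*$", "\\1", block[1L])
    if (!key %in% names(key_map)) next
    # the location may continue over lines until the first qualifier
    qual_at <- grep("^\\s*/", block)
    loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(block)
    loc <- gsub("\\s", "", paste0(
      c(sub("^\\s*\\S+\\s*", "", block[1L]),
        if (loc_end >= 2L) block[2L:loc_end] else character(0)),
      collapse = ""))
    parsed <- tryCatch(parse_genbank_location(loc), error = function(e)
      stopf("GenBank parse error in %s, feature near line '%s': %s",
            path, trimws(block[1L]), conditionMessage(e)))
    gene <- NA_character_
    gq <- grep("^\\s*/gene=", block, value = TRUE)
    if (length(gq)) gene <- gsub('^\\s*/gene="?|"$', "", gq[1L])
    if (is.na(gene)) {
      pq <- grep("^\\s*/product=", block, value = TRUE)
      gene <- if (length(pq)) gsub('^\\s*/product="?|"$', "", pq[1L]) else key
    }
    locus_id <- locus_id + 1L
    out[[length(out) + 1L]] <- data.frame(
      gene = gene, category = unname(key_map[key]),
      strand = if (parsed$complement) "-" else "+",
      exon_start = parsed$starts, exon_end = parsed$ends,
      locus = locus_id)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

parse_genbank_location <- function(loc) {
  complement <- FALSE
  while (grepl("^(complement|join|order)\\(", loc)) {
    op <- sub("^([a-z]+)\\(.*$", "\\1", loc)
    if (op == "complement") complement <- !complement
    loc <- sub("^[a-z]+\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  parts <- sub("^complement\\((.*)\\)$", "\\1", parts)
  rng <- regmatches(parts, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", parts))
  single <- grepl("^[0-9]+$", parts)
  starts <- integer(length(parts)); ends <- integer(length(parts))
  for (j in seq_along(parts)) {
    if (single[j]) {
      starts[j] <- ends[j] <- as.integer(parts[j])
    } else if (length(rng[[j]]) == 3L) {
      starts[j] <- as.integer(rng[[j]][2L]); ends[j] <- as.integer(rng[[j]][3L])
    } else stopf("unsupported location '%s'", parts[j])
  }
  list(starts = starts, ends = ends, complement = complement)
}

#' Write a plastome record as FASTA plus an exon table
#'
#' @param rec a [plastome_record()].
#' @param fasta_path output FASTA path.
#' @param annotation_path output TSV path; defaults to `fasta_path` with the
#'   extension replaced by `.tsv`.
#' @return invisibly, the two paths written.
#' @export
write_plastome <- function(rec, fasta_path, annotation_path = NULL) {
  if (is.null(annotation_path))
    annotation_path <- paste0(tools::file_path_sans_ext(fasta_path), ".tsv")
  seq <- Biostrings::DNAStringSet(rec$sequence)
  names(seq) <- rec$id
  Biostrings::writeXStringSet(seq, fasta_path, width = 70L)
  write.table(rec$annotations, annotation_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, annotations = annotation_path))
}

# exon rows of one locus, ordered along the genome
locus_exons <- function(rec, locus_id) {
  ex <- rec$annotations[rec$annotations$locus == locus_id, , drop = FALSE]
  ex[order(ex$exon_start), , drop = FALSE]
}

# spliced, strand-corrected sequence of one gene locus
splice_locus <- function(rec, locus_id) {
  ex <- locus_exons(rec, locus_id)
  pieces <- substring(rec$sequence, ex$exon_start, ex$exon_end)
  out <- c2s(pieces)
  if (ex$strand[1L] == "-") out <- revcomp(out)
  out
}
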