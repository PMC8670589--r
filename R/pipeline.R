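## Pipeline orchestration: runs the per-genome stages (structure, region
## stats, census, SSRs, repeats, codon profile, junctions) and the per-pair
## stages (events/Ts-Tv, Ka/Ks, binned correlation and co-occurrence)
## against a declared reference, and writes every table as TSV with a
## header comment naming the producing stage, parameters, and config hash.

#' Pipeline configuration
#'
#' @param records named list of [plastome_record()]s (the first is used as
#'   reference unless `reference` says otherwise).
#' @param reference name of the reference record for pairwise stages.
#' @param kaks_genes protein-coding gene names for the selection stage
#'   (default: every protein-coding gene annotated in the reference).
#' @param bin_size hotspot bin width in bp (default 250).
#' @param ssr_thresholds per-unit-length SSR copy thresholds.
#' @param repeat_min_len,repeat_min_identity oligonucleotide repeat
#'   detection settings.
#' @param min_ir_len,min_ir_identity IR detection settings.
#' @param stages character vector naming the stages to run (default all):
#'   `structure`, `ssr`, `repeats`, `codon`, `junctions`, `events`,
#'   `kaks`, `hotspots`.
#' @param out_dir output directory for TSV tables (NULL = no files).
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(records, reference = names(records)[1L],
                            kaks_genes = NULL, bin_size = 250L,
                            ssr_thresholds = plastcomp::ssr_thresholds(),
                            repeat_min_len = 30L, repeat_min_identity = 0.90,
                            min_ir_len = 10000L, min_ir_identity = 0.99,
                            stages = c("structure", "ssr", "repeats", "codon",
                                       "junctions", "events", "kaks",
                                       "hotspots"),
                            out_dir = NULL) {
  if (!length(records) || is.null(names(records)))
    stopf("records must be a named list of PlastomeRecord objects")
  if (!reference %in% names(records))
    stopf("reference '%s' is not among the records", reference)
  structure(list(records = records, reference = reference,
                 kaks_genes = kaks_genes, bin_size = as.integer(bin_size),
                 ssr_thresholds = ssr_thresholds,
                 repeat_min_len = repeat_min_len,
                 repeat_min_identity = repeat_min_identity,
                 min_ir_len = min_ir_len, min_ir_identity = min_ir_identity,
                 stages = stages, out_dir = out_dir),
            class = "PipelineConfig")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  slim <- config[setdiff(names(config), c("records", "out_dir"))]
  slim$record_ids <- names(config$records)
  writeLines(deparse(slim), f)
  unname(tools::md5sum(f))
}

#' Run the comparative plastome pipeline
#'
#' Per-genome stages run on every record; pairwise stages compare each
#' non-reference record to the reference. Any stage failure aborts with the
#' stage name and cause. Output is deterministic for fixed inputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `PipelineReport`: `per_genome` (named list with
#'   `structure`, `regions`, `census`, `ssr`, `repeats`, `junctions`,
#'   `codon_profile` per record), `per_pair` (named list with `summary`,
#'   `events`, `kaks`, `correlation` per non-reference record), `region_table`
#'   (combined per-species region sizes), and `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  on_stage <- function(s) s %in% config$stages
  per_genome <- list()
  for (id in names(config$records)) {
    rec <- config$records[[id]]
    res <- list()
    norm <- stage("structure", normalize_plastome(rec, config$min_ir_len,
                                                  config$min_ir_identity))
    res$structure <- norm$structure
    rec_n <- norm$record
    res$regions <- stage("structure", region_stats(rec_n, res$structure))
    res$census <- stage("structure", gene_census(rec_n, res$structure))
    if (on_stage("ssr")) {
      loci <- stage("ssr", find_ssrs(rec_n, config$ssr_thresholds))
      res$ssr <- stage("ssr", classify_ssrs(loci, res$structure,
                                            rec_n$annotations))
    }
    if (on_stage("repeats"))
      res$repeats <- stage("repeats", find_oligo_repeats(
        rec_n, min_len = config$repeat_min_len,
        min_identity = config$repeat_min_identity))
    if (on_stage("junctions") && nrow(rec_n$annotations))
      res$junctions <- stage("junctions", junction_report(rec_n, res$structure))
    if (on_stage("codon") && nrow(rec_n$annotations)) {
      pc <- unique(rec_n$annotations$gene[
        rec_n$annotations$category == "protein_coding"])
      if (length(pc)) {
        cds <- vapply(pc, function(g) extract_gene_cds(rec_n, g), "")
        ok <- nchar(cds) %% 3L == 0L
        res$codon_profile <- stage("codon", codon_profile(cds[ok]))
      }
    }
    res$record <- rec_n
    per_genome[[id]] <- res
  }
  ref_id <- config$reference
  ref <- per_genome[[ref_id]]$record
  per_pair <- list()
  for (id in setdiff(names(config$records), ref_id)) {
    qry <- per_genome[[id]]$record
    pres <- list()
    if (any(c("events", "hotspots") %in% config$stages)) {
      aln <- stage("events", align_near_identical(ref, qry))
      ev <- stage("events", extract_events(aln))
      pres$events <- ev
      pres$summary <- stage("events", summarize_substitutions(ev$substitutions))
    }
    if (on_stage("kaks")) {
      genes <- config$kaks_genes
      if (is.null(genes))
        genes <- unique(ref$annotations$gene[
          ref$annotations$category == "protein_coding" &
          ref$annotations$gene %in% qry$annotations$gene])
      if (length(genes))
        pres$kaks <- stage("kaks", gene_selection(ref, qry, genes))
    }
    if (on_stage("hotspots")) {
      reps <- per_genome[[ref_id]]$repeats
      if (is.null(reps)) reps <- integer(0)
      tracks <- stage("hotspots", bin_events(
        pres$events$substitutions, pres$events$indels, reps,
        ref_length = nchar(ref$sequence), bin_size = config$bin_size))
      pres$tracks <- tracks
      pres$correlation <- stage("hotspots", correlation_report(tracks))
    }
    per_pair[[id]] <- pres
  }
  region_table <- do.call(rbind, lapply(names(per_genome), function(id) {
    st <- per_genome[[id]]$structure
    data.frame(species = id,
               total = st$ira[2L],
               lsc = st$lsc[2L] - st$lsc[1L] + 1L,
               ssc = st$ssc[2L] - st$ssc[1L] + 1L,
               ir = st$irb[2L] - st$irb[1L] + 1L,
               source = config$records[[id]]$source)
  }))
  report <- structure(list(per_genome = per_genome, per_pair = per_pair,
                           region_table = region_table, config_hash = hash,
                           config = config),
                      class = "PipelineReport")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- report$config_hash
  emit <- function(df, file, stage, params = "") {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(sprintf("# stage: %s | params: %s | config: %s",
                       stage, params, hash), con)
    close(con)
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
  }
  emit(report$region_table, "regions.tsv", "structure",
       sprintf("min_ir_len=%d", report$config$min_ir_len))
  for (id in names(report$per_genome)) {
    pg <- report$per_genome[[id]]
    if (!is.null(pg$ssr))
      emit(pg$ssr$loci, sprintf("ssr_%s.tsv", id), "ssr",
           paste(names(report$config$ssr_thresholds),
                 report$config$ssr_thresholds, sep = "=", collapse = ","))
    if (!is.null(pg$repeats))
      emit(pg$repeats, sprintf("repeats_%s.tsv", id), "repeats",
           sprintf("min_len=%d,min_identity=%.2f",
                   report$config$repeat_min_len,
                   report$config$repeat_min_identity))
    if (!is.null(pg$junctions))
      emit(pg$junctions, sprintf("junctions_%s.tsv", id), "junctions", "")
  }
  for (id in names(report$per_pair)) {
    pp <- report$per_pair[[id]]
    if (!is.null(pp$summary)) {
      sdf <- data.frame(category = c(names(pp$summary$counts), "Ts/Tv"),
                        count = c(unname(pp$summary$counts),
                                  pp$summary$ts_tv_ratio))
      emit(sdf, sprintf("substitutions_%s.tsv", id), "events", "")
    }
    if (!is.null(pp$kaks))
      emit(pp$kaks, sprintf("kaks_%s.tsv", id), "kaks", "NG86+JC")
    if (!is.null(pp$correlation)) {
      cr <- pp$correlation
      cdf <- data.frame(metric = c(names(cr$r), names(cr$cooccurrence)),
                        value = c(round(unname(cr$r), 2L),
                                  unname(cr$cooccurrence)),
                        label = c(cr$strength, rep("", 3L)))
      emit(cdf, sprintf("correlation_%s.tsv", id), "hotspots",
           sprintf("bin_size=%d", report$config$bin_size))
    }
    if (!is.null(pp$tracks)) {
      tr <- pp$tracks
      emit(data.frame(bin_start = tr$bin_start, bin_end = tr$bin_end,
                      n_sub = tr$substitutions, n_indel = tr$indels,
                      n_repeat = tr$repeats),
           sprintf("bins_%s.tsv", id), "hotspots",
           sprintf("bin_size=%d", tr$bin_size))
    }
  }
  invisible(out_dir)
}

#' Compare a report's tables against expected tables
#'
#' Cell-by-cell comparison with per-column tolerance: integer columns must
#' match exactly, ratio columns within 0.005, percentage columns within
#' 0.01, other numeric columns within 1e-9.
#'
#' @param tables named list of data frames (e.g. pieces of a
#'   `PipelineReport`).
#' @param expected named list of data frames with identical schema.
#' @param ratio_cols,percent_cols column names given the looser tolerances.
#' @return data frame of differences (`table`, `row`, `column`, `value`,
#'   `expected`); zero rows when everything matches.
#' @export
compare_to_reference_tables <- function(tables, expected,
                                        ratio_cols = c("ratio", "ka", "ks"),
                                        percent_cols = c("pct", "gc")) {
  diffs <- list()
  for (nm in names(expected)) {
    if (!nm %in% names(tables)) {
      diffs[[length(diffs) + 1L]] <- data.frame(
        table = nm, row = NA_integer_, column = NA_character_,
        value = NA_character_, expected = "<table missing>")
      next
    }
    a <- tables[[nm]]; b <- expected[[nm]]
    if (!identical(sort(names(a)), sort(names(b))) || nrow(a) != nrow(b))
      stopf("schema mismatch for table '%s'", nm)
    for (col in names(b)) {
      av <- a[[col]]; bv <- b[[col]]
      tol <- if (col %in% ratio_cols) 0.005
             else if (col %in% percent_cols) 0.01
             else if (is.numeric(bv) && !is.integer(bv)) 1e-9
             else 0
      for (i in seq_len(nrow(b))) {
        same <- if (is.numeric(bv)) {
          (is.na(av[i]) && is.na(bv[i])) ||
            (!is.na(av[i]) && !is.na(bv[i]) && abs(av[i] - bv[i]) <= tol)
        } else identical(av[i], bv[i])
        if (!same)
          diffs[[length(diffs) + 1L]] <- data.frame(
            table = nm, row = i, column = col,
            value = as.character(av[i]), expected = as.character(bv[i]))
      }
    }
  }
  if (!length(diffs))
    return(data.frame(table = character(), row = integer(),
                      column = character(), value = character(),
                      expected = character()))
  do.call(rbind, diffs)
}
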