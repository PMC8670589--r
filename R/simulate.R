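## Synthetic quadripartite plastomes with ground-truth logs. The generator
## emits a circular genome laid out LSC + IRb + SSC + IRa with IRa the exact
## reverse complement of IRb, a gene catalog with IR-duplicated genes, an
## optional junction layout mimicking the canonical gene arrangement at the
## SC/IR boundaries (trnH near the LSC start, rpl2 spanning JLB, ycf1
## spanning JSA with an IR-side overhang and its truncated mirror at JSB,
## ndhF ending exactly at JSB), planted SSRs and oligonucleotide repeats,
## and a divergence operator with controllable Ts:Tv bias and InDel rate.
## Everything planted is logged so each analysis stage can be tested
## against known truth without external data.

#' Generator configuration for synthetic plastomes
#'
#' Defaults emulate a real plastome: ~153 kb quadripartite genome
#' (LSC 87 kb, SSC 20 kb, IR 23 kb), 38% GC, a catalog of 113 unique genes
#' (79 protein-coding, 30 tRNA, 4 rRNA) of which 15 are IR-duplicated
#' (4 protein-coding, 7 tRNA, 4 rRNA), roughly 50 planted SSRs dominated by
#' A/T mononucleotide runs, a handful of long repeats, and a divergence
#' model producing hundreds of substitutions per genome with a Ts:Tv ratio
#' of 1.5 and geometric InDel lengths (mean 4 bp, capped at 50 bp).
#'
#' @param lsc,ssc,ir region lengths in bp.
#' @param gc background GC fraction.
#' @param genes named list: unique counts `protein_coding`, `trna`, `rrna`,
#'   and `ir_dup` (named counts of IR-duplicated genes per category, which
#'   are part of the unique counts).
#' @param cds_len_range protein-coding gene length range (rounded to
#'   multiples of 3, includes start/stop).
#' @param junction_layout plant the canonical junction genes (logical).
#' @param junction_offsets list: `trnh_gap` (bases between LSC start and
#'   trnH), `rpl2_ir_overhang` (bases of rpl2 inside IRb), `ycf1_ir_overhang`
#'   (bases of ycf1 inside IRa), `ndhf_gap` (bases between JSB and ndhF).
#' @param ssr_plant data frame `motif`, `copies`, `region`, `count`;
#'   defaults to a realistic A/T-dominated set scaled to the genome.
#' @param repeat_plant data frame `kind`, `length`, `count`.
#' @param divergence list: `sub_rate` (substitutions per bp), `tstv`
#'   (Ts:Tv ratio), `indel_rate` (events per bp), `indel_mean`, `indel_max`
#'   (geometric length model), `preserve_ir` (mirror events so the IR
#'   copies stay identical), `hotspot_cv` and `hotspot_window` (gamma
#'   mutation-intensity landscape shared by substitutions and InDels;
#'   `hotspot_cv = 0` gives a uniform landscape).
#' @param seed mandatory integer seed.
#' @return list of class `GeneratorConfig`.
#' @export
generator_config <- function(lsc = 87000L, ssc = 20000L, ir = 23000L,
                             gc = 0.38,
                             genes = list(protein_coding = 79L, trna = 30L,
                                          rrna = 4L,
                                          ir_dup = c(protein_coding = 4L,
                                                     trna = 7L, rrna = 4L)),
                             cds_len_range = c(300L, 1500L),
                             junction_layout = TRUE,
                             junction_offsets = list(trnh_gap = 12L,
                                                     rpl2_ir_overhang = 3L,
                                                     ycf1_ir_overhang = 266L,
                                                     ndhf_gap = 0L),
                             ssr_plant = NULL,
                             repeat_plant = NULL,
                             divergence = list(sub_rate = 0.0023, tstv = 1.5,
                                               indel_rate = 2e-4,
                                               indel_mean = 4, indel_max = 50L,
                                               preserve_ir = TRUE,
                                               hotspot_cv = 1,
                                               hotspot_window = 500L),
                             seed) {
  if (missing(seed)) stopf("generator_config requires a seed")
  if (min(lsc, ssc, ir) <= 0L) stopf("region lengths must be positive")
  if (lsc <= ssc) stopf("LSC must be longer than SSC")
  if (gc <= 0 || gc >= 1) stopf("gc must be in (0, 1)")
  if (divergence$tstv <= 0) stopf("Ts:Tv ratio must be > 0")
  if (divergence$sub_rate < 0 || divergence$sub_rate >= 1 ||
      divergence$indel_rate < 0 || divergence$indel_rate >= 1)
    stopf("rates must be in [0, 1)")
  if (is.null(ssr_plant)) ssr_plant <- default_ssr_plant(lsc, ssc)
  if (is.null(repeat_plant))
    repeat_plant <- data.frame(kind = c("forward", "forward", "palindromic"),
                               length = c(40L, 35L, 40L), count = c(2L, 1L, 2L))
  structure(list(lsc = as.integer(lsc), ssc = as.integer(ssc),
                 ir = as.integer(ir), gc = gc, genes = genes,
                 cds_len_range = as.integer(cds_len_range),
                 junction_layout = junction_layout,
                 junction_offsets = junction_offsets,
                 ssr_plant = ssr_plant, repeat_plant = repeat_plant,
                 divergence = divergence, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

default_ssr_plant <- function(lsc, ssc) {
  # A/T mononucleotide runs dominate, mostly in the LSC, a couple of G/C
  # runs and a few di-/trinucleotide loci: the canonical plastome picture
  scale <- min(1, max(0.02, lsc / 87000))
  data.frame(
    motif = c("A", "T", "A", "G", "AT", "TA", "AAT", "A", "T"),
    copies = c(10L, 11L, 12L, 10L, 5L, 6L, 4L, 10L, 11L),
    region = c("LSC", "LSC", "LSC", "LSC", "LSC", "LSC", "LSC", "SSC", "SSC"),
    count = pmax(1L, as.integer(round(c(12, 10, 6, 1, 3, 2, 2, 4, 3) * scale))))
}

random_dna <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

sense_codons <- function() {
  names(GENCODE)[GENCODE != "*"]
}

# codon weights proportional to the product of base frequencies at the
# configured GC: coding sequences inherit the genome's A/T richness, which
# is what drives the leucine/isoleucine-dominated amino acid profile and
# the A/T-ending third-position bias of real plastomes
codon_weights <- function(gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  cods <- setdiff(sense_codons(), "ATG")
  w <- vapply(cods, function(cd) prod(p[s2c(cd)]), 0)
  w / sum(w)
}

random_cds <- function(len, gc = 0.38) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  cods <- setdiff(sense_codons(), "ATG")
  body <- sample(cods, len / 3L - 2L, replace = TRUE, prob = codon_weights(gc))
  paste0("ATG", paste0(body, collapse = ""), "TAA")
}

#' Generate a synthetic plastome with ground truth
#'
#' @param config a [generator_config()].
#' @return list with `record` (a [plastome_record()], LSC starting at
#'   position 1) and `truth` (list with `structure` intervals, `genes`
#'   layout, `ssrs`, `repeats`, and the `config`).
#' @export
generate_plastome <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed)
  lsc <- config$lsc; ssc <- config$ssc; ir <- config$ir
  n <- lsc + ssc + 2L * ir
  irb1 <- lsc + 1L; irb2 <- lsc + ir
  ssc1 <- irb2 + 1L; ssc2 <- irb2 + ssc
  core_len <- lsc + ir + ssc
  core <- c(random_dna(lsc, config$gc), random_dna(ir, config$gc),
            random_dna(ssc, config$gc))
  # map an IRa genome position into the core (IRb, complemented)
  mirror_pos <- function(g) irb1 + (n - g)
  plant <- function(core, start, content) {
    cv <- s2c(content)
    for (q in seq_along(cv)) {
      g <- start + q - 1L
      if (g <= core_len) core[g] <- cv[q]
      else core[mirror_pos(g)] <- COMP[[cv[q]]]
    }
    core
  }
  occupied <- logical(core_len)  # genes + planted elements, core coordinates
  mark <- function(occupied, start, end) {
    idx <- pmin(pmax(seq.int(start, end), 1L), n)
    idx <- ifelse(idx > core_len, irb1 + (n - idx), idx)
    occupied[idx] <- TRUE
    occupied
  }

  ann <- list(); truth_genes <- list(); locus_id <- 0L
  add_gene <- function(name, category, strand, start, end, region,
                       mirror = FALSE) {
    locus_id <<- locus_id + 1L
    ann[[length(ann) + 1L]] <<- data.frame(
      gene = name, category = category, strand = strand,
      exon_start = start, exon_end = end, locus = locus_id)
    truth_genes[[length(truth_genes) + 1L]] <<- data.frame(
      gene = name, category = category, strand = strand,
      start = start, end = end, region = region, mirrored = mirror)
  }

  # --- junction layout ----------------------------------------------------
  jo <- config$junction_offsets
  reserve <- list(LSC = c(1L, 0L), SSC = c(1L, 0L))  # filled below
  if (config$junction_layout) {
    # trnH: a tRNA `trnh_gap` bases downstream of the LSC start
    trnh_len <- 75L
    s <- jo$trnh_gap + 1L
    core <- plant(core, s, random_dna_str(trnh_len, config$gc))
    add_gene("trnH", "tRNA", "-", s, s + trnh_len - 1L, "LSC")
    occupied <- mark(occupied, max(1L, s - 2L), s + trnh_len + 1L)
    # rpl2: protein gene ending `rpl2_ir_overhang` bases inside IRb
    rpl2_len <- 822L
    e <- lsc + jo$rpl2_ir_overhang
    s <- e - rpl2_len + 1L
    core <- plant(core, s, revcomp(random_cds(rpl2_len, config$gc)))
    add_gene("rpl2", "protein_coding", "-", s, e, "LSC/IRb")
    occupied <- mark(occupied, s - 2L, e + 2L)
    # its IR mirror fragment sits at the very end of IRa (upstream of JLA)
    add_gene("rpl2", "protein_coding", "+", mirror_pos(e), n, "IRa",
             mirror = TRUE)
    # ndhF length is chosen first so ndhF and ycf1 both fit in the SSC
    ndhf_len <- min(741L, max(150L, ((ssc %/% 4L) %/% 3L) * 3L))
    # ycf1: protein gene spanning JSA with `ycf1_ir_overhang` bases in IRa
    avail <- ssc - jo$ndhf_gap - ndhf_len - 30L
    if (avail < 60L) stopf("SSC too short for the junction gene layout")
    ycf1_len <- ((min(1432L, avail) + jo$ycf1_ir_overhang) %/% 3L) * 3L
    e <- ssc2 + jo$ycf1_ir_overhang
    s <- e - ycf1_len + 1L
    core <- plant(core, s, revcomp(random_cds(ycf1_len, config$gc)))
    add_gene("ycf1", "protein_coding", "-", s, e, "SSC/IRa")
    occupied <- mark(occupied, s - 2L, e + 2L)
    # truncated mirror copy at the tail of IRb (ends exactly at JSB)
    add_gene("ycf1", "protein_coding", "+",
             mirror_pos(e), irb2, "IRb", mirror = TRUE)
    # ndhF: wholly in SSC, `ndhf_gap` bases after JSB
    s <- ssc1 + jo$ndhf_gap
    core <- plant(core, s, revcomp(random_cds(ndhf_len, config$gc)))
    add_gene("ndhF", "protein_coding", "-", s, s + ndhf_len - 1L, "SSC")
    occupied <- mark(occupied, s - 2L, s + ndhf_len + 1L)
  }

  # --- gene catalog -------------------------------------------------------
  g <- config$genes
  ir_dup <- g$ir_dup
  catalog <- data.frame(
    name = c(sprintf("pcg%02d", seq_len(g$protein_coding)),
             sprintf("trn%02d", seq_len(g$trna)),
             sprintf("rrn%02d", seq_len(g$rrna))),
    category = rep(c("protein_coding", "tRNA", "rRNA"),
                   c(g$protein_coding, g$trna, g$rrna)))
  in_ir <- c(seq_len(ir_dup[["protein_coding"]]),
             g$protein_coding + seq_len(ir_dup[["trna"]]),
             g$protein_coding + g$trna + seq_len(ir_dup[["rrna"]]))
  catalog$in_ir <- seq_len(nrow(catalog)) %in% in_ir

  gene_seq <- function(category, in_ir = FALSE) {
    ir_cap <- max(150L, config$ir %/% 4L)
    len <- switch(category,
      protein_coding = {
        hi <- config$cds_len_range[2L]
        if (in_ir) hi <- min(hi, ir_cap)
        raw <- sample(seq(min(config$cds_len_range[1L], hi), hi), 1L)
        max(9L, (raw %/% 3L) * 3L)
      },
      tRNA = 75L,
      rRNA = {
        cap <- max(150L, min(2800L, ir_cap))
        sample(seq.int(min(1200L, cap), cap), 1L)
      })
    for (try in 1:20) {
      s <- if (category == "protein_coding") random_cds(len, config$gc)
           else random_dna_str(len, config$gc)
      if (nrow(find_ssrs(s)) == 0L) return(s)
    }
    stopf("could not generate SSR-free gene sequence")
  }

  try_place <- function(occupied, lo, hi, len) {
    # random placement among all starts whose footprint (2 bp clearance on
    # each side) is free
    if (hi - len + 1L < lo) return(NA_integer_)
    occ <- c(0L, cumsum(as.integer(occupied)))
    starts <- seq.int(lo, hi - len + 1L)
    a <- pmax(1L, starts - 2L)
    b <- pmin(core_len, starts + len + 1L)
    free <- (occ[b + 1L] - occ[a]) == 0L
    starts <- starts[free]
    if (!length(starts)) return(NA_integer_)
    starts[sample.int(length(starts), 1L)]
  }
  place_in <- function(occupied, lo, hi, len) {
    s <- try_place(occupied, lo, hi, len)
    if (is.na(s))
      stopf("planting demands exceed region capacity (%d bp in [%d,%d])",
            len, lo, hi)
    s
  }

  # draw all gene sequences first, then place the longest first: greedy
  # big-to-small packing avoids fragmentation failures in tight regions
  gene_seqs <- vapply(seq_len(nrow(catalog)), function(i)
    gene_seq(catalog$category[i], in_ir = catalog$in_ir[i]), "")
  for (i in order(-nchar(gene_seqs))) {
    cat_ <- catalog$category[i]
    seqi <- gene_seqs[i]
    len <- nchar(seqi)
    strand <- sample(c("+", "-"), 1L)
    if (catalog$in_ir[i]) {
      ir_margin <- min(300L, ir %/% 12L)
      s <- place_in(occupied, irb1 + ir_margin, irb2 - ir_margin, len)
      region <- "IRb"
    } else {
      # split the single-copy catalog genes across LSC and SSC, falling
      # back to the other region when the preferred one is too full
      to_ssc <- runif(1) < ssc / (lsc + ssc)
      s <- if (to_ssc) try_place(occupied, ssc1 + 60L, ssc2 - 60L, len)
           else try_place(occupied, 120L, lsc - 60L, len)
      if (is.na(s)) {
        to_ssc <- !to_ssc
        s <- if (to_ssc) place_in(occupied, ssc1 + 60L, ssc2 - 60L, len)
             else place_in(occupied, 120L, lsc - 60L, len)
      }
      region <- if (to_ssc) "SSC" else "LSC"
    }
    content <- if (strand == "+") seqi else revcomp(seqi)
    core <- plant(core, s, content)
    occupied <- mark(occupied, s - 2L, s + len + 1L)
    add_gene(catalog$name[i], cat_, strand, s, s + len - 1L, region)
    if (catalog$in_ir[i]) {
      add_gene(catalog$name[i], cat_,
               if (strand == "+") "-" else "+",
               mirror_pos(s + len - 1L), mirror_pos(s), "IRa", mirror = TRUE)
    }
  }

  # --- scrub accidental SSRs in unoccupied background ---------------------
  core <- scrub_ssrs(core, occupied, core_len)

  # --- planted SSRs -------------------------------------------------------
  truth_ssrs <- list()
  sp <- config$ssr_plant
  region_bounds <- list(LSC = c(60L, lsc - 60L),
                        SSC = c(ssc1 + 60L, ssc2 - 60L),
                        IRb = c(irb1 + 60L, irb2 - 60L))
  if (!is.null(sp) && nrow(sp)) {
    for (i in seq_len(nrow(sp))) {
      for (j in seq_len(sp$count[i])) {
        motif <- sp$motif[i]; u <- nchar(motif); cp <- sp$copies[i]
        len <- u * cp
        b <- region_bounds[[sp$region[i]]]
        if (is.null(b)) stopf("unsupported SSR plant region '%s'", sp$region[i])
        s <- place_in(occupied, b[1L], b[2L], len + 2L) + 1L
        run <- strrep(motif, cp)
        core <- plant(core, s, run)
        # flank guards: break periodicity on both sides
        mv <- s2c(motif)
        left_guard <- setdiff(c("C", "G", "A", "T"), mv[u])[1L]
        right_guard <- setdiff(c("C", "G", "A", "T"), mv[(len %% u) + 1L])[1L]
        core <- plant(core, s - 1L, left_guard)
        core <- plant(core, s + len, right_guard)
        occupied <- mark(occupied, s - 2L, s + len + 1L)
        truth_ssrs[[length(truth_ssrs) + 1L]] <- data.frame(
          motif = motif, unit_length = u, copies = cp,
          start = s, end = s + len - 1L, region = sp$region[i])
        if (sp$region[i] == "IRb") {
          truth_ssrs[[length(truth_ssrs) + 1L]] <- data.frame(
            motif = revcomp(motif), unit_length = u, copies = cp,
            start = mirror_pos(s + len - 1L), end = mirror_pos(s),
            region = "IRa")
        }
      }
    }
  }

  # --- planted oligonucleotide repeats ------------------------------------
  truth_repeats <- list()
  rp <- config$repeat_plant
  if (!is.null(rp) && nrow(rp)) {
    for (i in seq_len(nrow(rp))) {
      for (j in seq_len(rp$count[i])) {
        len <- rp$length[i]
        s1 <- place_in(occupied, 60L, lsc - 60L, len)
        seg <- c2s(core[s1:(s1 + len - 1L)])
        occupied <- mark(occupied, s1 - 2L, s1 + len + 1L)
        # second copy preferentially in the SSC, else elsewhere in the LSC
        s2 <- try_place(occupied, ssc1 + 60L, ssc2 - 60L, len)
        if (is.na(s2)) s2 <- place_in(occupied, 60L, lsc - 60L, len)
        copy <- switch(rp$kind[i],
          forward = seg, reverse = reverse_seq(seg),
          complement = complement_seq(seg), palindromic = revcomp(seg))
        # optional degradation: evenly spaced mismatches down to the
        # requested identity (never at the copy ends)
        id <- if (is.null(rp$identity)) 1 else rp$identity[i]
        n_mm <- floor((1 - id) * len)
        if (n_mm > 0L) {
          cv <- s2c(copy)
          at <- round(seq_len(n_mm) * len / (n_mm + 1L))
          cv[at] <- vapply(cv[at], function(b)
            setdiff(c("A", "C", "G", "T"), b)[1L], "")
          copy <- c2s(cv)
        }
        core <- plant(core, s2, copy)
        occupied <- mark(occupied, s2 - 2L, s2 + len + 1L)
        truth_repeats[[length(truth_repeats) + 1L]] <- data.frame(
          kind = rp$kind[i], length = len,
          pos1 = min(s1, s2), pos2 = max(s1, s2),
          identity = 1 - n_mm / len)
      }
    }
  }

  # enforce IR maximality on the circle: the planted IR must not be
  # extendable by chance base matches across its four junctions, or the
  # detected structure would overshoot the planted truth by a few bases.
  # Outward extension pairs the last LSC base with the first LSC base;
  # inward extension pairs the first and last SSC bases.
  ann_df <- if (length(ann)) do.call(rbind, ann) else NULL
  core <- enforce_ir_maximality(core, list(c(lsc, 1L), c(irb2 + 1L, core_len)),
                                ann_df, n, irb1)

  genome <- paste0(c2s(core), revcomp(c2s(core[irb1:irb2])))
  annotations <- if (length(ann)) do.call(rbind, ann) else NULL
  rec <- plastome_record(sprintf("synthetic_seed%d", config$seed), genome,
                         annotations, source = "synthetic")
  truth <- list(
    structure = list(lsc = c(1L, lsc), irb = c(irb1, irb2),
                     ssc = c(ssc1, ssc2), ira = c(ssc2 + 1L, n)),
    genes = if (length(truth_genes)) do.call(rbind, truth_genes) else NULL,
    ssrs = if (length(truth_ssrs)) do.call(rbind, truth_ssrs) else
      data.frame(motif = character(), unit_length = integer(),
                 copies = integer(), start = integer(), end = integer(),
                 region = character()),
    repeats = if (length(truth_repeats)) do.call(rbind, truth_repeats) else
      data.frame(kind = character(), length = integer(),
                 pos1 = integer(), pos2 = integer(), identity = numeric()),
    config = config)
  list(record = rec, truth = truth)
}

random_dna_str <- function(n, gc) c2s(random_dna(n, gc))

# break every background SSR meeting the detection thresholds by flipping a
# base mid-run; genes and planted elements are left untouched
scrub_ssrs <- function(core, occupied, core_len) {
  for (pass in 1:8) {
    loci <- find_ssrs(c2s(core))
    loci <- loci[loci$end <= core_len, , drop = FALSE]
    if (!nrow(loci)) break
    fixed <- FALSE
    for (i in seq_len(nrow(loci))) {
      span <- loci$start[i]:min(core_len, loci$end[i])
      # a run crossing a gene boundary is broken at a background base; runs
      # wholly inside genes cannot occur (gene sequences are SSR-free)
      open <- span[!occupied[span]]
      if (!length(open)) next
      at <- open[(length(open) + 1L) %/% 2L]
      core[at] <- setdiff(c("A", "C", "G", "T"), core[at])[1L]
      fixed <- TRUE
    }
    if (!fixed) break
  }
  core
}

# For each position pair (pa, pb): ensure core[pa] != COMP[core[pb]], i.e.
# the IR cannot extend across that junction. A violating base is flipped,
# preferring a position outside protein-coding exons; flips inside a CDS
# pick a replacement that keeps the reading frame free of internal stops.
enforce_ir_maximality <- function(core, pairs, ann_df, n, irb1) {
  core_len <- length(core)
  cds_rows <- if (!is.null(ann_df))
    ann_df[ann_df$category == "protein_coding", , drop = FALSE] else NULL
  in_cds <- function(p) !is.null(cds_rows) &&
    any(cds_rows$exon_start <= p & cds_rows$exon_end >= p)
  frame_ok <- function(core, p) {
    if (!in_cds(p)) return(TRUE)
    genome_char <- function(g) {
      if (g <= core_len) core[g] else COMP[[core[irb1 + (n - g)]]]
    }
    rows <- cds_rows[cds_rows$exon_start <= p & cds_rows$exon_end >= p, ]
    for (ri in seq_len(nrow(rows))) {
      cds <- c2s(vapply(rows$exon_start[ri]:rows$exon_end[ri], genome_char, ""))
      if (rows$strand[ri] == "-") cds <- revcomp(cds)
      aa <- translate_codons(codon_split(cds))
      if (any(aa[-length(aa)] == "*")) return(FALSE)
    }
    TRUE
  }
  for (pr in pairs) {
    pa <- pr[1L]; pb <- pr[2L]
    if (core[pa] != COMP[[core[pb]]]) next
    flip <- if (!in_cds(pb)) pb else if (!in_cds(pa)) pa else pb
    other <- if (flip == pb) pa else pb
    forbidden <- COMP[[core[other]]]
    for (cand in setdiff(c("A", "C", "G", "T"), c(core[flip], forbidden))) {
      old <- core[flip]
      core[flip] <- cand
      if (frame_ok(core, flip)) break
      core[flip] <- old
    }
  }
  core
}

#' Diverge a synthetic plastome
#'
#' Applies substitutions (per-site rate, transition probability
#' `tstv / (tstv + 1)`) and InDels (geometric lengths) to a generated
#' record, logging every event in ancestor coordinates. With
#' `preserve_ir = TRUE` events are drawn in the LSC/IRb/SSC core and
#' mirrored into IRa so the two IR copies stay identical. InDels are kept
#' at least 100 bp apart and away from planted SSR runs so event recovery
#' from a pairwise alignment is unambiguous.
#'
#' @param sim list from [generate_plastome()] (elements `record`, `truth`),
#'   or a [plastome_record()] together with a `truth` argument.
#' @param divergence overrides for the config's divergence list.
#' @param seed seed for this divergence draw (defaults to config seed + 1).
#' @return list with `record` (derived genome, annotations dropped) and
#'   `events` (data frame `type`, `pos`, `ref_base`, `new_base`, `length`
#'   in ancestor coordinates, including IR-mirrored events).
#' @export
diverge <- function(sim, divergence = list(), seed = NULL) {
  rec <- sim$record; truth <- sim$truth
  dv <- utils::modifyList(truth$config$divergence, divergence)
  if (is.null(seed)) seed <- truth$config$seed + 1L
  set.seed(seed)
  sv <- s2c(rec$sequence)
  n <- length(sv)
  st <- truth$structure
  core_len <- st$ssc[2L]
  irb1 <- st$irb[1L]
  mirror_pos <- function(g) irb1 + (n - g)
  in_irb <- function(p) p >= st$irb[1L] & p <= st$irb[2L]
  draw_range <- if (isTRUE(dv$preserve_ir)) core_len else n

  # shared mutation-intensity landscape: per-window gamma multipliers (mean
  # 1, coefficient of variation `hotspot_cv`) applied to substitution and
  # InDel placement alike, emulating the mutational hotspots that make the
  # two event classes co-occur along real genomes; cv = 0 gives a uniform
  # landscape
  cv <- if (is.null(dv$hotspot_cv)) 1 else dv$hotspot_cv
  win <- if (is.null(dv$hotspot_window)) 500L else dv$hotspot_window
  weight <- if (cv > 0) {
    shape <- 1 / cv^2
    m <- stats::rgamma(ceiling(draw_range / win), shape = shape, rate = shape)
    rep(m, each = win)[seq_len(draw_range)]
  } else rep(1, draw_range)

  events <- list()
  # substitutions
  k <- rbinom(1L, draw_range, dv$sub_rate)
  if (k > 0L) {
    pos <- sort(sample.int(draw_range, k, prob = weight))
    p_ts <- dv$tstv / (dv$tstv + 1)
    TS <- c(A = "G", G = "A", C = "T", T = "C")
    for (p in pos) {
      b <- sv[p]
      if (!b %in% c("A", "C", "G", "T")) next
      new <- if (runif(1) < p_ts) TS[[b]] else
        sample(setdiff(c("A", "C", "G", "T"), c(b, TS[[b]])), 1L)
      sv[p] <- new
      events[[length(events) + 1L]] <- data.frame(
        type = "substitution", pos = p, ref_base = b, new_base = new,
        length = 1L)
      if (isTRUE(dv$preserve_ir) && in_irb(p)) {
        mp <- mirror_pos(p)
        events[[length(events) + 1L]] <- data.frame(
          type = "substitution", pos = mp, ref_base = COMP[[b]],
          new_base = COMP[[new]], length = 1L)
        sv[mp] <- COMP[[new]]
      }
    }
  }

  # InDels: well-separated, outside planted SSR runs and away from the
  # region boundaries (a gap across a junction would complicate mirroring)
  k2 <- rbinom(1L, draw_range, dv$indel_rate)
  indel_events <- list()
  if (k2 > 0L) {
    forbid <- logical(draw_range)
    if (nrow(truth$ssrs)) {
      for (i in seq_len(nrow(truth$ssrs))) {
        a <- max(1L, min(truth$ssrs$start[i], truth$ssrs$end[i]) - 2L)
        b <- min(draw_range, max(truth$ssrs$start[i], truth$ssrs$end[i]) + 2L)
        forbid[a:b] <- TRUE
      }
    }
    bounds <- c(st$lsc[2L], st$irb[2L], st$ssc[2L])
    for (b in bounds) forbid[max(1L, b - 60L):min(draw_range, b + 60L)] <- TRUE
    chosen <- integer(0)
    cand <- sample.int(draw_range - 100L, min(k2 * 5L, draw_range %/% 10L),
                       prob = weight[seq_len(draw_range - 100L)])
    for (p in cand) {
      if (length(chosen) >= k2) break
      if (forbid[p]) next
      if (length(chosen) && min(abs(chosen - p)) < 100L) next
      chosen <- c(chosen, p)
    }
    for (p in sort(chosen)) {
      len <- min(1L + rgeom(1L, 1 / dv$indel_mean), dv$indel_max)
      kind <- sample(c("insertion", "deletion"), 1L)
      indel_events[[length(indel_events) + 1L]] <- data.frame(
        type = kind, pos = p, ref_base = NA_character_,
        new_base = if (kind == "insertion")
          random_dna_str(len, 0.4) else NA_character_,
        length = len)
      if (isTRUE(dv$preserve_ir) && in_irb(p)) {
        # a deletion of [p, p+len-1] mirrors to [mirror(p+len-1), mirror(p)];
        # an insertion after p mirrors to after mirror(p) - 1
        indel_events[[length(indel_events) + 1L]] <- data.frame(
          type = kind,
          pos = if (kind == "deletion") mirror_pos(p + len - 1L)
                else mirror_pos(p) - 1L,
          ref_base = NA_character_,
          new_base = if (kind == "insertion")
            revcomp(indel_events[[length(indel_events)]]$new_base)
            else NA_character_,
          length = len)
      }
    }
  }

  ev <- c(events, indel_events)
  ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(type = character(), pos = integer(), ref_base = character(),
               new_base = character(), length = integer())
  ev <- ev[order(ev$pos), , drop = FALSE]
  rownames(ev) <- NULL

  # apply InDels from the highest coordinate down
  ind <- ev[ev$type %in% c("insertion", "deletion"), , drop = FALSE]
  if (nrow(ind)) {
    for (i in rev(seq_len(nrow(ind)))) {
      p <- ind$pos[i]; len <- ind$length[i]
      if (ind$type[i] == "deletion") {
        sv <- sv[-(p:(p + len - 1L))]
      } else {
        sv <- append(sv, s2c(ind$new_base[i]), after = p)
      }
    }
  }
  derived <- plastome_record(paste0(rec$id, "_div"), c2s(sv),
                             source = "synthetic divergence")
  list(record = derived, events = ev)
}

#' Plant synonymous and non-synonymous edits in a coding sequence
#'
#' Utility for closed-loop Ka/Ks tests: introduces the requested numbers of
#' strictly synonymous and strictly non-synonymous single-base codon edits
#' (never creating a stop) at distinct codons.
#'
#' @param cds in-frame coding sequence.
#' @param n_syn,n_nonsyn numbers of edits.
#' @param seed RNG seed.
#' @return list with `cds` (edited sequence) and `edits` (data frame
#'   `codon_index`, `position_in_codon`, `from`, `to`, `synonymous`).
#' @export
mutate_codons <- function(cds, n_syn, n_nonsyn, seed) {
  set.seed(seed)
  codons <- codon_split(normalize_sequence(cds))
  n <- length(codons)
  edit_one <- function(idx, want_syn) {
    base_codon <- codons[idx]
    aa <- GENCODE[[base_codon]]
    cand <- list()
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      cv <- s2c(base_codon)
      if (b == cv[p]) next
      cv2 <- cv; cv2[p] <- b
      mut <- c2s(cv2)
      maa <- GENCODE[[mut]]
      if (maa == "*") next
      if ((maa == aa) == want_syn)
        cand[[length(cand) + 1L]] <- list(p = p, b = b, mut = mut)
    }
    if (!length(cand)) return(NULL)
    cand[[sample.int(length(cand), 1L)]]
  }
  # keep first/last codon untouched (start/stop context)
  pool <- sample(2:(n - 1L))
  edits <- list()
  want <- c(rep(TRUE, n_syn), rep(FALSE, n_nonsyn))
  wi <- 1L
  for (idx in pool) {
    if (wi > length(want)) break
    e <- edit_one(idx, want[wi])
    if (is.null(e)) next
    edits[[length(edits) + 1L]] <- data.frame(
      codon_index = idx, position_in_codon = e$p,
      from = codons[idx], to = e$mut, synonymous = want[wi])
    codons[idx] <- e$mut
    wi <- wi + 1L
  }
  if (wi <= length(want))
    stopf("could not place all requested edits")
  list(cds = paste0(codons, collapse = ""),
       edits = do.call(rbind, edits))
}
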