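# Synthetic genomes with planted RT-associated CRISPR-cas loci.
#
# Genes are diverged copies of the package's consensus profiles, so profile
# annotation behaves like a matched library search; decoy genes are
# codon-shuffled and audited to have no profile hit at e <= 0.01; arrays
# carry the two orientation signals real arrays show (AT-rich leader,
# degenerate trailer-side repeat). All coordinates are 1-based inclusive on
# the forward strand (GFF3 convention).

DNA4 <- c("A", "C", "G", "T")

random_dna <- function(n, gc = 0.5) {
  paste(sample(DNA4, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# uniform synonymous reverse translation; translation starts with its own Met
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  chars[chars == "X"] <- "A"
  codons <- vapply(chars, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Specification of a planted CRISPR array
#'
#' @param repeat_seq DNA repeat (19-48 bp) or `NULL` to draw one at random
#'   (or from [repeat_db()] when `from_db = TRUE`).
#' @param n_repeats number of repeat copies, >= 3.
#' @param spacer_len_range spacer length interval in bp.
#' @param leader_at_enrichment how much the AT fraction of the 200 bp leader
#'   flank is raised above background (0 = no signal).
#' @param terminal_repeat_mutations substitutions planted in the trailer-side
#'   (last) repeat copy.
#' @param orientation `"forward"` (leader on the left) or `"reverse"`.
#' @param from_db draw `repeat_seq` from the oriented repeat database so the
#'   database criterion of the orientation cascade can recover orientation.
#' @return An `array_spec` list.
#' @export
array_spec <- function(repeat_seq = NULL, n_repeats = 6,
                       spacer_len_range = c(30, 40),
                       leader_at_enrichment = 0.18,
                       terminal_repeat_mutations = 3,
                       orientation = c("forward", "reverse"),
                       from_db = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(n_repeats >= 3, leader_at_enrichment >= 0,
            terminal_repeat_mutations >= 0,
            spacer_len_range[1] >= 17, spacer_len_range[2] <= 72)
  if (!is.null(repeat_seq)) {
    repeat_seq <- toupper(repeat_seq)
    stopifnot(nchar(repeat_seq) >= 19, nchar(repeat_seq) <= 48)
  }
  structure(list(repeat_seq = repeat_seq, n_repeats = n_repeats,
                 spacer_len_range = spacer_len_range,
                 leader_at_enrichment = leader_at_enrichment,
                 terminal_repeat_mutations = terminal_repeat_mutations,
                 orientation = orientation, from_db = from_db),
            class = "array_spec")
}

#' Template for one planted CRISPR-cas locus
#'
#' `gene_order` lists gene units left to right; the RT-bearing unit is the
#' label `"RT"` and its realised protein depends on `fusion_class` (for
#' `"RT-Cas1"` the RT and Cas1 domains share one translation; for
#' `"Cas6-RT-Cas1"` a Cas6 domain is added at the N-terminus). The token
#' `"array"` positions the CRISPR array; if absent it is inserted right
#' after the RT unit. Defaults reproduce canonical type III architectures:
#' Csm (III-A/D) and Cmr (III-B/C) effector operons with the adaptation
#' module at the RT-proximal end.
#'
#' @param subtype `"III-A/D"` or `"III-B/C"`.
#' @param fusion_class `"RT"`, `"RT-Cas1"` or `"Cas6-RT-Cas1"`.
#' @param gene_order character vector of unit labels, or `NULL` for the
#'   canonical architecture of the subtype/fusion combination.
#' @param array an [array_spec()] (or `NULL` for no array).
#' @param intergenic_gaps_bp gaps between consecutive units in bp (recycled);
#'   `NULL` draws each gap uniformly from 50-300 bp.
#' @param array_gap_bp gap between the array and the preceding unit.
#' @param clade clade label recorded in the truth ledger.
#' @return A `locus_template` list.
#' @export
locus_template <- function(subtype = c("III-A/D", "III-B/C"),
                           fusion_class = c("RT-Cas1", "RT", "Cas6-RT-Cas1"),
                           gene_order = NULL, array = array_spec(),
                           intergenic_gaps_bp = NULL, array_gap_bp = 300,
                           clade = "unassigned") {
  subtype <- match.arg(subtype)
  fusion_class <- match.arg(fusion_class)
  if (is.null(gene_order)) {
    effector <- if (subtype == "III-A/D") {
      c("cas10", "csm2", "csm3", "csm4", "csm5")
    } else {
      c("cas10", "cmr1", "cmr3", "cmr4", "cmr5", "cmr6")
    }
    gene_order <- switch(fusion_class,
      "RT" = c(effector, "cas6", "RT", "cas1", "cas2"),
      "RT-Cas1" = c(effector, "cas6", "RT", "cas2"),
      "Cas6-RT-Cas1" = c(effector, "RT", "cas2"))
  }
  if (sum(gene_order == "RT") != 1) {
    stop("gene_order must contain exactly one RT unit")
  }
  if (fusion_class != "RT" && "cas1" %in% gene_order) {
    stop("fused templates must not carry a separate cas1 gene")
  }
  if (fusion_class == "Cas6-RT-Cas1" && "cas6" %in% gene_order) {
    stop("Cas6-RT-Cas1 templates must not carry a separate cas6 gene")
  }
  if (!"array" %in% gene_order && !is.null(array)) {
    i <- which(gene_order == "RT")
    gene_order <- append(gene_order, "array", after = i)
  }
  structure(list(subtype = subtype, fusion_class = fusion_class,
                 gene_order = gene_order, array = array,
                 intergenic_gaps_bp = intergenic_gaps_bp,
                 array_gap_bp = array_gap_bp, clade = clade),
            class = "locus_template")
}

#' Canonical locus template library
#'
#' All six subtype x fusion-class architectures, one template each.
#' @param ... passed to [locus_template()] (e.g. a shared `array`).
#' @export
template_library <- function(...) {
  combos <- expand.grid(subtype = c("III-A/D", "III-B/C"),
                        fusion = c("RT", "RT-Cas1", "Cas6-RT-Cas1"),
                        stringsAsFactors = FALSE)
  purrr::pmap(combos, function(subtype, fusion) {
    locus_template(subtype = subtype, fusion_class = fusion, ...)
  })
}

#' Specification of a synthetic genome
#'
#' @param length_bp genome length.
#' @param gc_content background GC fraction.
#' @param loci list of [locus_template()]s, realised left to right.
#' @param decoy_gene_count codon-shuffled decoy genes (no Cas similarity,
#'   audited at generation time) placed between loci.
#' @param seed integer; fully determines the genome.
#' @param contig contig name.
#' @export
genome_spec <- function(length_bp = 100000, gc_content = 0.45, loci = list(),
                        decoy_gene_count = 5, seed = 1,
                        contig = "synth_contig") {
  stopifnot(length_bp > 0, gc_content >= 0, gc_content <= 1,
            decoy_gene_count >= 0)
  structure(list(length_bp = length_bp, gc_content = gc_content,
                 loci = loci, decoy_gene_count = decoy_gene_count,
                 seed = seed, contig = contig),
            class = "genome_spec")
}

# realise the protein (and its true domain table) for one gene unit
realize_unit <- function(unit, fusion_class, profiles, divergence = 0.12) {
  parts <- if (unit == "RT") {
    switch(fusion_class,
           "RT" = "RT",
           "RT-Cas1" = c("RT", "cas1"),
           "Cas6-RT-Cas1" = c("cas6", "RT", "cas1"))
  } else {
    unit
  }
  segs <- vapply(parts, function(fam) {
    p <- profiles$sequence[profiles$id == fam]
    mutate_protein(p, round(divergence * nchar(p)))
  }, character(1))
  protein <- paste(segs, collapse = "")
  ends <- cumsum(nchar(segs))
  starts <- c(1L, head(ends, -1) + 1L)
  list(protein = protein,
       domains = tibble(family = parts, start = as.integer(starts),
                        end = as.integer(ends)))
}

# build the array segment (already in final orientation) plus metadata
realize_array <- function(aspec, gc) {
  rep_seq <- aspec$repeat_seq
  if (is.null(rep_seq)) {
    rep_seq <- if (aspec$from_db) {
      db <- repeat_db()
      db$sequence[sample.int(nrow(db), 1)]
    } else {
      random_dna(32, gc = 0.4)
    }
  }
  n <- aspec$n_repeats
  lens <- seq(aspec$spacer_len_range[1], aspec$spacer_len_range[2])
  spacers <- character(0)
  while (length(spacers) < n - 1) {
    sl <- lens[sample.int(length(lens), 1)]
    cand <- random_dna(sl, gc)
    if (!cand %in% spacers) spacers <- c(spacers, cand)
  }
  reps <- rep(rep_seq, n)
  if (aspec$terminal_repeat_mutations > 0) {
    chars <- strsplit(rep_seq, "", fixed = TRUE)[[1]]
    pos <- sample(length(chars), min(aspec$terminal_repeat_mutations,
                                     length(chars)))
    for (p in pos) chars[p] <- sample(setdiff(DNA4, chars[p]), 1)
    reps[n] <- paste(chars, collapse = "")  # trailer-side copy degenerate
  }
  seg <- paste(rbind(reps, c(spacers, "")), collapse = "")
  if (aspec$orientation == "reverse") seg <- revcomp(seg)
  list(segment = seg, repeat_seq = rep_seq, n_repeats = n,
       orientation = aspec$orientation,
       leader_at_enrichment = aspec$leader_at_enrichment)
}

decoy_protein <- function(profiles, params) {
  base <- profiles$sequence[sample.int(nrow(profiles), 1)]
  for (try in 1:25) {
    cand <- paste(sample(strsplit(base, "", fixed = TRUE)[[1]]),
                  collapse = "")
    hits <- local_search(cand, profiles[, c("id", "sequence")], params)
    if (nrow(hits) == 0 || min(hits$evalue) > 0.01) return(cand)
  }
  stop("internal: could not build a clean decoy in 25 shuffles")
}

#' Generate a synthetic genome with planted truth
#'
#' Realises every [locus_template()] of the spec left to right, plants the
#' CRISPR arrays with their orientation signals, interleaves audited decoy
#' genes, and returns both the genome and a truth ledger recording
#' everything planted. Identical specs (including the seed) give
#' byte-identical output.
#'
#' @param spec a [genome_spec()].
#' @return List with `sequence` (character scalar), `features` (tibble:
#'   contig, type, start, end, strand, locus_tag, family, locus_id, decoy,
#'   protein, domains list-column), and `truth` (list: `planted_arrays`,
#'   `planted_loci`, `distribution_table`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  profiles <- cas_profiles()
  params <- search_params()
  n <- spec$length_bp
  genome <- strsplit(random_dna(n, spec$gc_content), "", fixed = TRUE)[[1]]

  feats <- list()
  arrays <- list()
  loci_rows <- list()
  occupied <- integer(0)   # feature spans, kept off-limits for flank editing
  cursor <- 501L
  gene_i <- 0L

  place <- function(segment, start) {
    stopifnot(start >= 1, start + nchar(segment) - 1 <= n)
    idx <- start:(start + nchar(segment) - 1)
    genome[idx] <<- strsplit(segment, "", fixed = TRUE)[[1]]
    occupied <<- c(occupied, idx)
    c(start, start + nchar(segment) - 1L)
  }

  for (li in seq_along(spec$loci)) {
    tpl <- spec$loci[[li]]
    gaps <- tpl$intergenic_gaps_bp
    gi <- 0L
    locus_elements <- list()
    first <- TRUE
    for (unit in tpl$gene_order) {
      gap <- if (first) {
        0L
      } else if (unit == "array") {
        as.integer(tpl$array_gap_bp)
      } else if (!is.null(gaps)) {
        gi <- gi + 1L
        as.integer(gaps[(gi - 1L) %% length(gaps) + 1L])
      } else {
        sample(50:300, 1)
      }
      first <- FALSE
      cursor <- cursor + gap
      if (unit == "array") {
        if (is.null(tpl$array)) next
        ar <- realize_array(tpl$array, spec$gc_content)
        if (cursor + nchar(ar$segment) + 500 > n) {
          stop("locus template ", li, " does not fit in ", n, " bp")
        }
        span <- place(ar$segment, cursor)
        arrays[[length(arrays) + 1]] <- tibble(
          contig = spec$contig, start = span[1], end = span[2],
          orientation = ar$orientation, repeat_seq = ar$repeat_seq,
          n_repeats = ar$n_repeats,
          leader_at_enrichment = ar$leader_at_enrichment,
          locus_id = sprintf("locus%02d", li))
        locus_elements[[length(locus_elements) + 1]] <- span
        cursor <- span[2] + 1L
        # make sure a reverse array's leader flank stays free background
        cursor <- cursor + 250L
      } else {
        ru <- realize_unit(unit, tpl$fusion_class, profiles)
        dna <- paste0("TAA", "ATG", reverse_translate(ru$protein), "TAA")
        if (cursor + nchar(dna) + 500 > n) {
          stop("locus template ", li, " does not fit in ", n, " bp")
        }
        span <- place(dna, cursor)
        gene_i <- gene_i + 1L
        fam_label <- if (unit == "RT") {
          switch(tpl$fusion_class, "RT" = "RT", "RT-Cas1" = "RT-cas1",
                 "Cas6-RT-Cas1" = "cas6-RT-cas1")
        } else {
          unit
        }
        feats[[length(feats) + 1]] <- tibble(
          contig = spec$contig, type = "gene",
          start = span[1] + 3L, end = span[2], strand = "+",
          locus_tag = sprintf("SYN_%04d", gene_i),
          family = fam_label, locus_id = sprintf("locus%02d", li),
          decoy = FALSE, protein = paste0("M", ru$protein),
          domains = list(dplyr::mutate(ru$domains, start = .data$start + 1L,
                                       end = .data$end + 1L)))
        locus_elements[[length(locus_elements) + 1]] <- c(span[1] + 3L, span[2])
        cursor <- span[2] + 1L
      }
    }
    if (length(locus_elements)) {
      spans <- do.call(rbind, locus_elements)
      loci_rows[[length(loci_rows) + 1]] <- tibble(
        locus_id = sprintf("locus%02d", li), contig = spec$contig,
        start = min(spans[, 1]), end = max(spans[, 2]),
        subtype = tpl$subtype, fusion_class = tpl$fusion_class,
        clade = tpl$clade)
    }
    # distinct loci must not chain together under the <5 kb trimming rule
    cursor <- cursor + sample(7000:12000, 1)
  }

  for (di in seq_len(spec$decoy_gene_count)) {
    prot <- decoy_protein(profiles, params)
    dna <- paste0("TAA", "ATG", reverse_translate(prot), "TAA")
    if (cursor + nchar(dna) + 500 > n) break
    span <- place(dna, cursor)
    gene_i <- gene_i + 1L
    feats[[length(feats) + 1]] <- tibble(
      contig = spec$contig, type = "gene",
      start = span[1] + 3L, end = span[2], strand = "+",
      locus_tag = sprintf("SYN_%04d", gene_i),
      family = "decoy", locus_id = NA_character_,
      decoy = TRUE, protein = paste0("M", prot),
      domains = list(empty_domains()[, c("family", "start", "end")]))
    cursor <- span[2] + 1L + sample(500:1500, 1)
  }

  arrays_tb <- if (length(arrays)) dplyr::bind_rows(arrays) else tibble(
    contig = character(), start = integer(), end = integer(),
    orientation = character(), repeat_seq = character(),
    n_repeats = integer(), leader_at_enrichment = numeric(),
    locus_id = character())

  # leader-flank AT enrichment (only free background positions are edited)
  occ <- logical(n); occ[occupied] <- TRUE
  if (nrow(arrays_tb)) {
    for (k in seq_len(nrow(arrays_tb))) {
      enr <- arrays_tb$leader_at_enrichment[k]
      if (enr <= 0) next
      if (arrays_tb$orientation[k] == "forward") {
        win <- (arrays_tb$start[k] - 200):(arrays_tb$start[k] - 1)
      } else {
        win <- (arrays_tb$end[k] + 1):(arrays_tb$end[k] + 200)
      }
      win <- win[win >= 1 & win <= n & !occ[win]]
      gcpos <- win[genome[win] %in% c("G", "C")]
      p <- min(1, enr / max(spec$gc_content, 1e-6))
      flip <- gcpos[runif(length(gcpos)) < p]
      genome[flip] <- sample(c("A", "T"), length(flip), replace = TRUE)
    }
  }

  feats_tb <- if (length(feats)) dplyr::bind_rows(feats) else tibble(
    contig = character(), type = character(), start = integer(),
    end = integer(), strand = character(), locus_tag = character(),
    family = character(), locus_id = character(), decoy = logical(),
    protein = character(), domains = list())
  loci_tb <- if (length(loci_rows)) dplyr::bind_rows(loci_rows) else tibble(
    locus_id = character(), contig = character(), start = integer(),
    end = integer(), subtype = character(), fusion_class = character(),
    clade = character())

  truth <- list(
    planted_arrays = arrays_tb,
    planted_loci = loci_tb,
    distribution_table = truth_distribution(loci_tb)
  )
  list(sequence = paste(genome, collapse = ""), features = feats_tb,
       truth = truth, contig = spec$contig)
}

# Table-1-shaped counts straight from the truth ledger
truth_distribution <- function(loci_tb) {
  if (nrow(loci_tb) == 0) {
    return(tibble(clade = character(), effector = character(),
                  fusion_class = character(), n = integer()))
  }
  loci_tb |>
    dplyr::mutate(effector = dplyr::case_when(
      .data$subtype == "III-B/C" ~ "Cmr (B-C)",
      .data$subtype == "III-A/D" ~ "Csm (A-D)",
      TRUE ~ "partial/unknown")) |>
    dplyr::count(.data$clade, .data$effector, .data$fusion_class)
}

#' Generate a single-array contig
#'
#' A small contig holding exactly one planted array, for orientation-scoring
#' studies: flank sizes control whether the >200 nt flank rule can apply.
#'
#' @param aspec an [array_spec()].
#' @param left_flank,right_flank background flank sizes in bp.
#' @param gc background GC fraction.
#' @param seed integer seed.
#' @return List with `sequence` and a one-row `truth` tibble.
#' @export
generate_array_contig <- function(aspec, left_flank = 500, right_flank = 500,
                                  gc = 0.45, seed = 1) {
  set.seed(seed)
  ar <- realize_array(aspec, gc)
  left <- if (left_flank > 0) random_dna(left_flank, gc) else ""
  right <- if (right_flank > 0) random_dna(right_flank, gc) else ""
  seqv <- strsplit(paste0(left, ar$segment, right), "", fixed = TRUE)[[1]]
  start <- left_flank + 1L
  end <- left_flank + nchar(ar$segment)
  enr <- aspec$leader_at_enrichment
  if (enr > 0) {
    win <- if (ar$orientation == "forward") {
      (start - 200):(start - 1)
    } else {
      (end + 1):(end + 200)
    }
    win <- win[win >= 1 & win <= length(seqv)]
    gcpos <- win[seqv[win] %in% c("G", "C")]
    flip <- gcpos[runif(length(gcpos)) < min(1, enr / max(gc, 1e-6))]
    seqv[flip] <- sample(c("A", "T"), length(flip), replace = TRUE)
  }
  list(sequence = paste(seqv, collapse = ""),
       truth = tibble(contig = "array_contig", start = start, end = end,
                      orientation = ar$orientation,
                      repeat_seq = ar$repeat_seq, n_repeats = ar$n_repeats))
}

#' Generate a genome containing only planted arrays
#'
#' Places each array at a random position, mutually separated and away from
#' the contig edges, on a plain background. Used for detection and
#' orientation benchmarking where no cas genes are required.
#'
#' @param array_specs list of [array_spec()]s.
#' @param length_bp genome length.
#' @param gc background GC fraction.
#' @param min_separation minimum bp between arrays.
#' @param seed integer seed.
#' @param contig contig name.
#' @return List with `sequence` and `truth` (tibble of planted arrays).
#' @export
generate_array_genome <- function(array_specs, length_bp = 100000,
                                  gc = 0.45, min_separation = 2000,
                                  seed = 1, contig = "array_genome") {
  set.seed(seed)
  genome <- strsplit(random_dna(length_bp, gc), "", fixed = TRUE)[[1]]
  placed <- tibble(contig = character(), start = integer(), end = integer(),
                   orientation = character(), repeat_seq = character(),
                   n_repeats = integer())
  occ_start <- integer(0); occ_end <- integer(0)
  for (aspec in array_specs) {
    ar <- realize_array(aspec, gc)
    alen <- nchar(ar$segment)
    for (try in 1:200) {
      s <- sample(500:(length_bp - alen - 500), 1)
      e <- s + alen - 1L
      clash <- any(s - min_separation <= occ_end &
                     e + min_separation >= occ_start)
      if (!clash) break
      if (try == 200) stop("could not place all arrays: genome too crowded")
    }
    genome[s:e] <- strsplit(ar$segment, "", fixed = TRUE)[[1]]
    occ_start <- c(occ_start, s); occ_end <- c(occ_end, e)
    if (aspec$leader_at_enrichment > 0) {
      win <- if (ar$orientation == "forward") (s - 200):(s - 1) else
        (e + 1):(e + 200)
      win <- win[win >= 1 & win <= length_bp]
      gcpos <- win[genome[win] %in% c("G", "C")]
      flip <- gcpos[runif(length(gcpos)) <
                      min(1, aspec$leader_at_enrichment / max(gc, 1e-6))]
      genome[flip] <- sample(c("A", "T"), length(flip), replace = TRUE)
    }
    placed <- dplyr::bind_rows(placed, tibble(
      contig = contig, start = s, end = e, orientation = ar$orientation,
      repeat_seq = ar$repeat_seq, n_repeats = ar$n_repeats))
  }
  placed <- placed[order(placed$start), , drop = FALSE]
  list(sequence = paste(genome, collapse = ""), truth = placed,
       contig = contig)
}
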