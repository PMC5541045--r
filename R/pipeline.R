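# End-to-end orchestration: genomes in, classified loci and reports out.

#' Pipeline configuration
#'
#' Collects inputs and thresholds for [run_pipeline()]. Inputs may be given
#' in-memory (sequences, tibbles, `phylo` objects) or as file paths
#' (FASTA/GFF3/TSV/Newick). All thresholds default to the pipeline's
#' standard values: 85% identity / 200 aa dereplication, e-value 0.01
#' (annotation) and 1e-6 (subtype specificity), support 0.92 (clades),
#' 50 kb neighborhood, strict 5 kb trimming gap, 1 kb RT-array proximity.
#'
#' @param genomes named character vector of contig sequences, or a FASTA
#'   path.
#' @param features optional gene feature tibble or GFF3 path (takes
#'   precedence over de novo ORF calling).
#' @param profiles Cas profile tibble or FASTA path; default
#'   [cas_profiles()].
#' @param repeats oriented repeat database tibble or TSV path; default
#'   [repeat_db()].
#' @param rt_tree,cas1_tree optional support-annotated trees (phylo or
#'   Newick path) for the RT and Cas1 phylogenies.
#' @param metadata optional leaf metadata tibble or TSV (id, phylum,
#'   crispr_associated).
#' @param max_identity,min_len dereplication thresholds.
#' @param evalue,subtype_evalue annotation thresholds.
#' @param support_min clade support threshold.
#' @param window,gap_max,array_link locus extraction thresholds in bp.
#' @param seed integer seed for every stochastic step.
#' @param out_dir optional output directory (TSV/FASTA/GFF3/JSON reports).
#' @return A `run_config` list.
#' @export
run_config <- function(genomes, features = NULL, profiles = NULL,
                       repeats = NULL, rt_tree = NULL, cas1_tree = NULL,
                       metadata = NULL, max_identity = 85, min_len = 200,
                       evalue = 0.01, subtype_evalue = 1e-6,
                       support_min = 0.92, window = 50000, gap_max = 5000,
                       array_link = 1000, seed = 1, out_dir = NULL) {
  stopifnot(max_identity > 0, min_len > 0, evalue > 0, subtype_evalue > 0,
            support_min > 0, window > 0, gap_max > 0, array_link > 0)
  structure(list(genomes = genomes, features = features,
                 profiles = profiles, repeats = repeats, rt_tree = rt_tree,
                 cas1_tree = cas1_tree, metadata = metadata,
                 max_identity = max_identity, min_len = min_len,
                 evalue = evalue, subtype_evalue = subtype_evalue,
                 support_min = support_min, window = window,
                 gap_max = gap_max, array_link = array_link, seed = seed,
                 out_dir = out_dir), class = "run_config")
}

load_input <- function(x, loader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1 && file.exists(x)) loader(x) else x
}

stage_log <- function(log, stage, n_in, n_out, t0) {
  dt <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  message(sprintf("[%s] in=%d out=%d (%.2fs)", stage, n_in, n_out, dt))
  dplyr::bind_rows(log, tibble(stage = stage, n_in = n_in, n_out = n_out,
                               seconds = dt))
}

#' Run the full locus-discovery pipeline
#'
#' Stages, in order: gene calling (unless features are supplied), array
#' detection, the orientation cascade, cas annotation, RT collection and
#' dereplication, locus extraction and trimming, fusion and subtype
#' classification, clade assignment (from a supplied tree, or a
#' neighbor-joining tree built from the RT representatives when at least
#' four are available), subclade splitting, membership screening of all RT
#' proteins, distribution tabulation and (when both trees are supplied)
#' RT/Cas1 congruence. Identical configuration and seed give identical
#' outputs, byte-identical on disk.
#'
#' @param config a [run_config()].
#' @return A `pipeline_result` list: `loci` (tibble), `arrays`, `cas_hits`,
#'   `representatives`, `partition`, `screening`, `distribution`,
#'   `congruence`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  params <- search_params()
  genomes <- load_input(config$genomes, read_fasta)
  stopifnot(length(genomes) >= 1, !is.null(names(genomes)))
  profiles <- load_input(config$profiles, read_fasta)
  if (is.null(profiles)) profiles <- cas_profiles()
  if (is.character(profiles)) {
    profiles <- tibble(id = names(profiles), sequence = unname(profiles))
  }
  repeats <- load_input(config$repeats, read_repeat_db)
  if (is.null(repeats)) repeats <- repeat_db()
  features <- load_input(config$features, read_gff3)
  metadata <- load_input(config$metadata,
                         function(p) readr::read_tsv(p,
                                                     show_col_types = FALSE))
  rt_tree <- load_input(config$rt_tree, ape::read.tree)
  cas1_tree <- load_input(config$cas1_tree, ape::read.tree)
  log <- tibble(stage = character(), n_in = integer(), n_out = integer(),
                seconds = numeric())

  # gene calling
  t0 <- Sys.time()
  if (is.null(features)) {
    features <- purrr::imap_dfr(genomes, function(s, nm) {
      call_orfs(s, contig_name = nm)
    })
  }
  log <- stage_log(log, "genes", length(genomes), nrow(features), t0)

  # array detection + orientation cascade
  t0 <- Sys.time()
  arrays <- purrr::imap_dfr(genomes, function(s, nm) {
    detect_arrays(s, contig_name = nm)
  })
  log <- stage_log(log, "arrays", length(genomes), nrow(arrays), t0)
  t0 <- Sys.time()
  arrays <- purrr::imap_dfr(genomes, function(s, nm) {
    a <- arrays[arrays$contig == nm, , drop = FALSE]
    if (nrow(a)) resolve_orientation(a, s, db = repeats) else a
  })
  log <- stage_log(log, "orientation", nrow(arrays),
                   sum(arrays$orientation != "undetermined"), t0)

  # cas annotation
  t0 <- Sys.time()
  cas_hits <- annotate_cas(features, profiles, params,
                           max_evalue = config$evalue,
                           subtype_evalue = config$subtype_evalue)
  log <- stage_log(log, "annotate", nrow(features), nrow(cas_hits), t0)

  # RT collection + dereplication
  t0 <- Sys.time()
  rt_hits <- cas_hits[cas_hits$family == "RT", , drop = FALSE]
  rt_recs <- if (nrow(rt_hits)) {
    protein_records(id = paste(rt_hits$contig, rt_hits$locus_tag, sep = ":"),
                    sequence = rt_hits$translation)
  } else {
    protein_records(character(0), character(0))
  }
  reps <- dereplicate(rt_recs, max_identity = config$max_identity,
                      min_len = config$min_len, params = params)
  log <- stage_log(log, "dereplicate", nrow(rt_recs), nrow(reps), t0)

  # locus extraction + classification
  t0 <- Sys.time()
  loci <- vector("list", nrow(rt_hits))
  for (i in seq_len(nrow(rt_hits))) {
    rt <- rt_hits[i, , drop = FALSE]
    loc <- extract_locus(rt, cas_hits, arrays[arrays$contig == rt$contig, ,
                                              drop = FALSE],
                         window = config$window, gap_max = config$gap_max,
                         array_link = config$array_link)
    loc$fusion_class <- detect_fusion(rt$domains[[1]])
    loc$subtype <- classify_subtype(loc)
    loci[[i]] <- loc
  }
  loci_tb <- purrr::map_dfr(loci, function(l) {
    tibble(contig = l$region$contig, start = l$region$start,
           end = l$region$end, rt_locus_tag = l$rt_locus_tag,
           n_cas_genes = nrow(l$features), n_arrays = nrow(l$arrays),
           array_near_rt = l$array_near_rt, fusion_class = l$fusion_class,
           subtype = l$subtype, clade = l$clade)
  })
  log <- stage_log(log, "loci", nrow(rt_hits), nrow(loci_tb), t0)

  # clade assignment
  t0 <- Sys.time()
  partition <- NULL
  if (!is.null(rt_tree)) {
    stopifnot(!is.null(metadata))
    partition <- assign_clades(rt_tree, metadata,
                               support_min = config$support_min)
    if ("phylum" %in% names(metadata)) {
      partition <- split_subclades(partition, metadata)
    }
  } else if (nrow(reps) >= 4) {
    aln <- align_progressive(setNames(reps$sequence, reps$id), params)
    tr <- build_tree(aln, bootstrap_n = 100, seed = config$seed)
    md <- tibble(id = reps$id, phylum = "unknown", crispr_associated = TRUE)
    partition <- assign_clades(tr, md, support_min = config$support_min)
  }
  n_assigned <- if (is.null(partition)) {
    0L
  } else {
    sum(partition$clade != "unassigned")
  }
  log <- stage_log(log, "clades", nrow(reps), n_assigned, t0)

  # membership screening of all RT proteins against clade consensus models
  t0 <- Sys.time()
  screening <- NULL
  if (!is.null(partition) && any(partition$clade != "unassigned") &&
      nrow(rt_recs)) {
    pool <- rt_recs[rt_recs$id %in% partition$id, , drop = FALSE]
    if (nrow(pool) >= 2) {
      models <- build_clade_models(pool, partition, params)
      screening <- purrr::map_dfr(seq_len(nrow(rt_recs)), function(i) {
        s <- screen_membership(rt_recs$sequence[i], models, params)
        tibble(id = rt_recs$id[i], clade = s$clade, evalue = s$evalue)
      })
      hit_ids <- paste(loci_tb$contig, loci_tb$rt_locus_tag, sep = ":")
      m <- match(hit_ids, screening$id)
      loci_tb$clade <- ifelse(!is.na(m) & screening$clade[m] != "none",
                              screening$clade[m], loci_tb$clade)
    }
  }
  log <- stage_log(log, "screening", nrow(rt_recs),
                   if (is.null(screening)) 0L else nrow(screening), t0)

  # distribution + congruence
  distribution <- tabulate_distribution(loci_tb)
  congruence <- NULL
  if (!is.null(partition) && !is.null(cas1_tree)) {
    cas1_part <- assign_clades(cas1_tree, metadata,
                               support_min = config$support_min)
    congruence <- partition_congruence(partition, cas1_part)
  }

  result <- structure(
    list(loci = loci_tb, arrays = arrays, cas_hits = cas_hits,
         representatives = reps, partition = partition,
         screening = screening, distribution = distribution,
         congruence = congruence, log = log, loci_objects = loci),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  readr::write_tsv(result$loci, out("loci.tsv"))
  write_array_tsv(result$arrays, out("arrays.tsv"))
  readr::write_tsv(result$cas_hits[, c("contig", "locus_tag", "start",
                                       "end", "strand", "family",
                                       "bitscore", "evalue",
                                       "subtype_specific")],
                   out("cas_hits.tsv"))
  if (nrow(result$representatives)) {
    write_fasta(setNames(result$representatives$sequence,
                         result$representatives$id),
                out("representatives.faa"))
  }
  readr::write_tsv(result$distribution, out("distribution.tsv"))
  if (!is.null(result$partition)) {
    readr::write_tsv(as_tibble(result$partition), out("partition.tsv"))
  }
  if (!is.null(result$congruence)) {
    jsonlite::write_json(
      list(ari = result$congruence$ari,
           n_shared = result$congruence$n_shared,
           per_label = result$congruence$per_label),
      out("congruence.json"), auto_unbox = TRUE, digits = NA)
  }
  # wall times stay in the in-memory log; the file must be reproducible
  readr::write_tsv(result$log[, c("stage", "n_in", "n_out")],
                   out("run_log.tsv"))
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  loci:", nrow(x$loci), " arrays:", nrow(x$arrays),
      " cas hits:", nrow(x$cas_hits), "\n")
  cat("  RT representatives:", nrow(x$representatives), "\n")
  if (!is.null(x$partition)) {
    cat("  clades:", length(setdiff(unique(x$partition$clade),
                                    "unassigned")), "\n")
  }
  invisible(x)
}
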