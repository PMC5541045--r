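# Genomic locus extraction with the strict <5 kb trimming rule, type III
# subtype classification, and distribution tabulation.

#' Extract and trim the CRISPR-cas locus around an RT gene
#'
#' Candidate elements are the annotated cas genes and detected arrays lying
#' within `window` bp of the RT gene. Starting from the RT gene the locus is
#' extended greedily left and right over elements whose intervening gap to
#' the previously retained element is strictly less than `gap_max` bp
#' (4,999 bp retained, 5,000 bp excluded), then trimmed to the outermost
#' retained cas gene or array. Whether an array lies within `array_link` bp
#' of the RT gene is recorded. Re-running the extraction on an already
#' trimmed locus returns it unchanged.
#'
#' @param rt_hit one cas-hit row (the RT-bearing gene).
#' @param cas_hits cas-hit tibble from [annotate_cas()] (may include
#'   `rt_hit`).
#' @param arrays `crispr_arrays` tibble (may be empty).
#' @param window neighborhood half-width in bp.
#' @param gap_max strict gap ceiling in bp.
#' @param array_link RT-array proximity threshold in bp.
#' @return A `locus` list: `region` (contig/start/end), `features` (ordered
#'   retained cas hits), `arrays` (retained arrays), `rt_locus_tag`,
#'   `array_near_rt`, plus `fusion_class`, `subtype`, `clade` slots
#'   initialised to `NA`/`"unassigned"`.
#' @export
extract_locus <- function(rt_hit, cas_hits, arrays, window = 50000,
                          gap_max = 5000, array_link = 1000) {
  stopifnot(nrow(rt_hit) == 1)
  if (!rt_hit$contig %in% c(cas_hits$contig, rt_hit$contig)) {
    stop("RT feature is not on the supplied contig")
  }
  cas_hits <- cas_hits[cas_hits$contig == rt_hit$contig, , drop = FALSE]
  if (!rt_hit$locus_tag %in% cas_hits$locus_tag) {
    cas_hits <- dplyr::bind_rows(cas_hits, rt_hit)
  }
  el <- dplyr::bind_rows(
    tibble(kind = "gene", key = cas_hits$locus_tag,
           start = cas_hits$start, end = cas_hits$end),
    if (!is.null(arrays) && nrow(arrays)) {
      tibble(kind = "array", key = sprintf("array@%d", arrays$start),
             start = arrays$start, end = arrays$end)
    }
  )
  el <- el[el$start <= rt_hit$end + window & el$end >= rt_hit$start - window,
           , drop = FALSE]
  el <- el[order(el$start, el$end), , drop = FALSE]
  ri <- which(el$kind == "gene" & el$key == rt_hit$locus_tag)[1]
  if (is.na(ri)) stop("RT feature absent from the element set")
  keep <- ri
  i <- ri
  while (i > 1) {
    gap <- el$start[i] - el$end[i - 1] - 1
    if (gap >= gap_max) break
    i <- i - 1
    keep <- c(i, keep)
  }
  i <- ri
  while (i < nrow(el)) {
    gap <- el$start[i + 1] - el$end[i] - 1
    if (gap >= gap_max) break
    i <- i + 1
    keep <- c(keep, i)
  }
  kept <- el[keep, , drop = FALSE]
  feats <- cas_hits[match(kept$key[kept$kind == "gene"], cas_hits$locus_tag),
                    , drop = FALSE]
  feats <- feats[order(feats$start), , drop = FALSE]
  arr <- if (!is.null(arrays) && nrow(arrays)) {
    arrays[arrays$start %in% kept$start[kept$kind == "array"], , drop = FALSE]
  } else {
    arrays
  }
  near <- FALSE
  if (!is.null(arr) && nrow(arr)) {
    gaps <- pmax(arr$start - rt_hit$end - 1, rt_hit$start - arr$end - 1, 0)
    near <- any(gaps < array_link)
  }
  structure(list(
    region = tibble(contig = rt_hit$contig, start = min(kept$start),
                    end = max(kept$end)),
    features = feats, arrays = arr, rt_locus_tag = rt_hit$locus_tag,
    array_near_rt = near, fusion_class = NA_character_,
    subtype = NA_character_, clade = "unassigned"), class = "locus")
}

#' Classify the type III subtype of a locus
#'
#' `"III-A/D"` iff subtype-specific Csm-family hits (csm2-csm5) are present,
#' `"III-B/C"` iff subtype-specific Cmr-family hits (cmr1, cmr3-cmr6) are
#' present; both present yields `"ambiguous"` (reported, not an error);
#' cas genes present without a subtype signature yields `"partial"`; no cas
#' genes yields `"unknown"`. cas10 alone is deliberately not discriminative.
#'
#' @param locus a `locus` from [extract_locus()].
#' @return Subtype label.
#' @export
classify_subtype <- function(locus) {
  f <- locus$features
  sig <- f[f$subtype_specific %in% TRUE, , drop = FALSE]
  has_csm <- any(sig$family %in% CSM_SIGNATURES)
  has_cmr <- any(sig$family %in% CMR_SIGNATURES)
  if (has_csm && has_cmr) return("ambiguous")
  if (has_csm) return("III-A/D")
  if (has_cmr) return("III-B/C")
  cas_fams <- setdiff(unique(f$family), c("RT"))
  if (length(cas_fams) > 0) return("partial")
  "unknown"
}

#' Tabulate loci as a clade x effector x fusion-class distribution
#'
#' Pure counting of classified loci into the standard reporting shape:
#' rows are clades, effector columns are Cmr (B-C), Csm (A-D) and
#' partial/unknown, crossed with the three RT fusion classes. Marginals
#' equal the locus count and the result is invariant to input order.
#'
#' @param loci tibble with columns `clade`, `subtype`, `fusion_class`
#'   (e.g. from [run_pipeline()]'s locus table), or a list of `locus`
#'   objects.
#' @return Count tibble: `clade`, `effector`, `fusion_class`, `n`.
#' @export
tabulate_distribution <- function(loci) {
  if (is.list(loci) && !is.data.frame(loci)) {
    loci <- dplyr::bind_rows(lapply(loci, function(l) {
      tibble(clade = l$clade, subtype = l$subtype,
             fusion_class = l$fusion_class)
    }))
  }
  if (nrow(loci) == 0) {
    return(tibble(clade = character(), effector = character(),
                  fusion_class = character(), n = integer()))
  }
  loci |>
    dplyr::mutate(effector = dplyr::case_when(
      .data$subtype == "III-B/C" ~ "Cmr (B-C)",
      .data$subtype == "III-A/D" ~ "Csm (A-D)",
      TRUE ~ "partial/unknown")) |>
    dplyr::count(.data$clade, .data$effector, .data$fusion_class) |>
    dplyr::arrange(.data$clade, .data$effector, .data$fusion_class)
}
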