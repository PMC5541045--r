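# Cas-gene annotation against consensus profiles, domain location, and
# RT fusion-class calling.

#' Locate Cas-family domains on a protein
#'
#' Runs [local_search()] of the translation against every profile and keeps
#' hits at or below `max_evalue`; query-side alignment coordinates become
#' the domain coordinates.
#'
#' @param translation amino-acid sequence.
#' @param profiles tibble with `id`, `sequence` (e.g. [cas_profiles()]).
#' @param params a [search_params()].
#' @param max_evalue reporting threshold.
#' @return Domain-hit tibble: `family`, `start`, `end` (1-based inclusive
#'   aa), `bitscore`, `evalue`.
#' @export
detect_domains <- function(translation, profiles, params = search_params(),
                           max_evalue = 0.01) {
  hits <- local_search(translation, profiles[, c("id", "sequence")], params,
                       max_evalue = max_evalue)
  tibble(family = hits$id, start = hits$q_start, end = hits$q_end,
         bitscore = hits$bitscore, evalue = hits$evalue)
}

#' Annotate gene features as Cas-family genes
#'
#' Each feature's translation is searched against all profiles; the best
#' (lowest e-value) family is kept iff its e-value is at most `max_evalue`
#' (0.01), and the hit is flagged subtype-specific iff the e-value is at
#' most `subtype_evalue` (1e-6) and the family is a type III subtype
#' signature (csm2-csm5 for III-A/D; cmr1, cmr3-cmr6 for III-B/C). Features
#' with no qualifying hit are excluded.
#'
#' @param features tibble from [call_orfs()] or a GFF3 reader: needs
#'   `locus_tag`, `start`, `end`, `strand`, `translation`.
#' @param profiles profile tibble ([cas_profiles()] format, optionally with
#'   `subtype_signature`).
#' @param params a [search_params()].
#' @param max_evalue,subtype_evalue the two e-value thresholds.
#' @return Cas-hit tibble: the feature columns plus `family`, `bitscore`,
#'   `evalue`, `subtype_specific`, and a `domains` list-column of all
#'   qualifying domain hits on the feature.
#' @export
annotate_cas <- function(features, profiles, params = search_params(),
                         max_evalue = 0.01, subtype_evalue = 1e-6) {
  stopifnot(nrow(profiles) > 0)
  if (nrow(features) == 0) return(empty_cas_hits())
  sig <- if ("subtype_signature" %in% names(profiles)) {
    profiles$id[!is.na(profiles$subtype_signature)]
  } else {
    c(CSM_SIGNATURES, CMR_SIGNATURES)
  }
  rows <- lapply(seq_len(nrow(features)), function(i) {
    dom <- detect_domains(features$translation[i], profiles, params,
                          max_evalue = max_evalue)
    if (nrow(dom) == 0) return(NULL)
    best <- dom[which.min(dom$evalue), ]
    tibble(
      contig = features$contig[i], locus_tag = features$locus_tag[i],
      start = features$start[i], end = features$end[i],
      strand = features$strand[i], family = best$family,
      bitscore = best$bitscore, evalue = best$evalue,
      subtype_specific = best$evalue <= subtype_evalue &&
        best$family %in% sig,
      translation = features$translation[i], domains = list(dom))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty_cas_hits())
  out
}

empty_cas_hits <- function() {
  tibble(contig = character(), locus_tag = character(), start = integer(),
         end = integer(), strand = character(), family = character(),
         bitscore = numeric(), evalue = numeric(),
         subtype_specific = logical(), translation = character(),
         domains = list())
}

#' Call the RT fusion class from domain architecture
#'
#' `"RT-Cas1"` iff a Cas1 domain lies C-terminal to the RT domain on the
#' same translation; `"Cas6-RT-Cas1"` additionally requires a Cas6 domain
#' N-terminal to the RT; otherwise `"RT"`. Domain order is compared by
#' midpoint.
#'
#' @param domains domain-hit tibble (from [detect_domains()] or the truth
#'   ledger) for one protein; must contain an RT domain.
#' @return One of `"RT"`, `"RT-Cas1"`, `"Cas6-RT-Cas1"`.
#' @export
detect_fusion <- function(domains) {
  rt <- domains[domains$family == "RT", , drop = FALSE]
  if (nrow(rt) == 0) stop("detect_fusion: no RT domain on this protein")
  rt_mid <- (rt$start[1] + rt$end[1]) / 2
  mids <- (domains$start + domains$end) / 2
  has_c_cas1 <- any(domains$family == "cas1" & mids > rt_mid &
                      domains$end > rt$end[1])
  has_n_cas6 <- any(domains$family == "cas6" & mids < rt_mid &
                      domains$start < rt$start[1])
  if (has_c_cas1 && has_n_cas6) return("Cas6-RT-Cas1")
  if (has_c_cas1) return("RT-Cas1")
  "RT"
}
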