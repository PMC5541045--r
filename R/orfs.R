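#' Call open reading frames on both strands
#'
#' Finds all ORFs of at least `min_len` bp running from a canonical ATG to
#' the next in-frame stop (stop codon included in the span), taking the
#' longest ORF per stop (i.e. the first ATG after the previous in-frame
#' stop). Used only when no gene annotation is supplied. Ordering is
#' deterministic by (start, strand).
#'
#' @param contig DNA sequence.
#' @param min_len minimum ORF length in bp (ATG through stop).
#' @param contig_name contig id recorded in the output.
#' @return Tibble with columns `contig`, `start`, `end`, `strand`,
#'   `locus_tag`, `translation` (leading Met, stop removed).
#' @export
call_orfs <- function(contig, min_len = 300, contig_name = "contig") {
  contig <- toupper(contig)
  n <- nchar(contig)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    for (f in 0:2) {
      last <- f + 3 * ((n - f) %/% 3)
      if (last - f < 6) next
      starts <- seq(f + 1, last - 2, 3)
      codons <- substring(s, starts, starts + 2)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      stop_i <- which(is_stop)
      atg_i <- which(is_atg)
      if (!length(stop_i) || !length(atg_i)) next
      # next in-frame stop for each ATG; first (leftmost) ATG per stop wins
      nx <- findInterval(atg_i, stop_i) + 1
      okm <- nx <= length(stop_i)
      atg_i <- atg_i[okm]; nx <- nx[okm]
      if (!length(atg_i)) next
      first_atg <- tapply(atg_i, nx, min)
      stop_sel <- stop_i[as.integer(names(first_atg))]
      len_bp <- (stop_sel - first_atg + 1) * 3
      okl <- len_bp >= min_len
      if (!any(okl)) next
      a <- as.integer(first_atg[okl]); z <- stop_sel[okl]
      s_start <- f + (a - 1L) * 3L + 1L
      s_end <- f + z * 3L
      if (strand == "+") {
        st <- s_start; en <- s_end
      } else {
        st <- n - s_end + 1L; en <- n - s_start + 1L
      }
      res[[length(res) + 1]] <- tibble(
        contig = contig_name, start = st, end = en, strand = strand,
        nt = substring(s, s_start, s_end - 3L))
    }
  }
  if (!length(res)) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), locus_tag = character(),
                  translation = character()))
  }
  out <- dplyr::bind_rows(res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out$translation <- vapply(out$nt, function(x) {
    as.character(Biostrings::translate(Biostrings::DNAString(x)))
  }, character(1), USE.NAMES = FALSE)
  out$nt <- NULL
  out$locus_tag <- sprintf("orf_%04d", seq_len(nrow(out)))
  out[, c("contig", "start", "end", "strand", "locus_tag", "translation")]
}
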