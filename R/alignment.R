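# Pairwise alignment wrappers around the compiled affine-gap kernels.

encode_seq <- function(x, submat) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(submat))
  if (anyNA(idx)) {
    xi <- match("X", rownames(submat))
    if (is.na(xi)) xi <- match("N", rownames(submat))
    if (is.na(xi)) stop("sequence contains characters outside the matrix ",
                        "alphabet: ", paste(unique(chars[is.na(idx)]),
                                            collapse = ","))
    idx[is.na(idx)] <- xi
  }
  as.integer(idx - 1L)
}

align_overlap <- function(a, b, params = search_params(), traceback = FALSE) {
  sm <- params$substitution_matrix
  nw_overlap_cpp(encode_seq(a, sm), encode_seq(b, sm), sm,
                 params$gap_open, params$gap_extend, traceback)
}

align_local <- function(a, b, params = search_params()) {
  sm <- params$substitution_matrix
  sw_local_cpp(encode_seq(a, sm), encode_seq(b, sm), sm,
               params$gap_open, params$gap_extend)
}

#' Percent identity between two sequences
#'
#' Identity is the number of identical aligned positions on an optimal
#' end-gap-free (overlap) global alignment, divided by the length of the
#' shorter sequence, times 100 (the CD-HIT denominator convention). Among
#' co-optimal alignments the one with the most identical positions is used,
#' which makes the value symmetric in its arguments and independent of
#' traceback order.
#'
#' @param a,b non-empty character scalars (amino-acid or DNA, matching the
#'   alphabet of `params$substitution_matrix`).
#' @param params a [search_params()] object.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("HEAGAWGHEE", "HEAGAWGHEE")
#' @export
pairwise_identity <- function(a, b, params = search_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_identity: empty sequence")
  res <- align_overlap(a, b, params)
  100 * res$matches / min(nchar(a), nchar(b))
}

# gapped alignment strings from an overlap traceback
aligned_strings <- function(a, b, aln) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  sa <- ifelse(aln$a_idx == 0L, "-", ac[pmax(aln$a_idx, 1L)])
  sb <- ifelse(aln$b_idx == 0L, "-", bc[pmax(aln$b_idx, 1L)])
  c(paste(sa, collapse = ""), paste(sb, collapse = ""))
}

bit_score <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}

effective_space <- function(qlen, tlen, params) {
  if (params$search_space_policy == "product-of-lengths") {
    return(as.numeric(qlen) * as.numeric(tlen))
  }
  # BLAST-style edge correction: l = ln(K m n) / H with a crude H default
  H <- 0.14
  l <- log(params$K * qlen * tlen) / H
  l <- min(l, qlen - 1, tlen - 1)
  max(qlen - l, 1) * max(tlen - l, 1)
}

evalue_from_score <- function(score, qlen, tlen, params) {
  effective_space(qlen, tlen, params) * 2^(-bit_score(score, params))
}
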