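#' Scoring and extreme-value parameters for similarity search
#'
#' Bundles the substitution matrix, affine gap penalties and gapped
#' Karlin-Altschul parameters used by [pairwise_identity()], [local_search()]
#' and everything built on them. A gap of length L costs
#' `gap_open + L * gap_extend`, so the defaults (11, 1) reproduce the familiar
#' BLAST 11/1 gap accounting. `lambda` and `K` default to values calibrated
#' on this implementation's random-score (Gumbel) distribution for gapped
#' BLOSUM62 at these penalties; e-values are computed as
#' `search_space * 2^(-bitscore)` with
#' `bitscore = (lambda * score - log(K)) / log(2)`.
#'
#' @param substitution_matrix `"BLOSUM62"`, `"DNA"` (match +5 / mismatch -4),
#'   or a named square numeric matrix.
#' @param gap_open,gap_extend positive gap penalties.
#' @param lambda,K positive Karlin-Altschul parameters for the chosen scoring.
#' @param search_space_policy `"product-of-lengths"` (m * n) or
#'   `"effective-length"` (BLAST-style length correction).
#' @return An object of class `search_params`.
#' @examples
#' p <- search_params()
#' p$lambda
#' @export
search_params <- function(substitution_matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1,
                          lambda = 0.22, K = 0.021,
                          search_space_policy = c("product-of-lengths",
                                                  "effective-length")) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  search_space_policy <- match.arg(search_space_policy)
  if (is.character(substitution_matrix)) {
    substitution_matrix <- switch(
      substitution_matrix,
      BLOSUM62 = blosum62_matrix(),
      DNA = dna_matrix(),
      stop("unknown substitution matrix: ", substitution_matrix)
    )
  }
  stopifnot(is.matrix(substitution_matrix),
            nrow(substitution_matrix) == ncol(substitution_matrix),
            !is.null(rownames(substitution_matrix)))
  structure(
    list(substitution_matrix = substitution_matrix,
         gap_open = gap_open, gap_extend = gap_extend,
         lambda = lambda, K = K,
         search_space_policy = search_space_policy),
    class = "search_params"
  )
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  storage.mode(m) <- "double"
  m
}

dna_matrix <- function(match = 5, mismatch = -4) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' @export
print.search_params <- function(x, ...) {
  cat("<search_params> ", nrow(x$substitution_matrix), "x",
      ncol(x$substitution_matrix), " matrix; gap ", x$gap_open, "/",
      x$gap_extend, "; lambda=", x$lambda, " K=", x$K, "; ",
      x$search_space_policy, "\n", sep = "")
  invisible(x)
}
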