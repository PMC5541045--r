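#' Construct a protein record table
#'
#' The package's tabular protein container: one row per protein, with an
#' optional `domains` list-column of per-protein domain-hit tibbles
#' (columns `family`, `start`, `end`, `bitscore`, `evalue`; 1-based inclusive
#' amino-acid coordinates).
#'
#' @param id character vector of unique ids.
#' @param sequence amino-acid sequences (20 residues plus X), same length.
#' @param organism,phylum optional character vectors (recycled).
#' @param domains optional list of domain-hit tibbles.
#' @return A tibble of class `protein_records`.
#' @export
protein_records <- function(id, sequence, organism = "", phylum = "",
                            domains = NULL) {
  stopifnot(length(id) == length(sequence), !anyDuplicated(id),
            all(nchar(sequence) >= 1))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", toupper(sequence))
  if (any(bad)) stop("non-amino-acid characters in sequences: ",
                     paste(id[bad], collapse = ", "))
  if (is.null(domains)) domains <- rep(list(empty_domains()), length(id))
  out <- tibble(id = as.character(id), organism = organism, phylum = phylum,
                sequence = toupper(sequence), domains = domains)
  class(out) <- c("protein_records", class(out))
  out
}

empty_domains <- function() {
  tibble(family = character(), start = integer(), end = integer(),
         bitscore = numeric(), evalue = numeric())
}

#' Greedy identity-threshold dereplication
#'
#' Reduces a protein set to representatives: records shorter than `min_len`
#' are dropped, the rest are processed longest-first (ties broken by input
#' order), and a record is kept iff its identity to every already-kept
#' representative is at most `max_identity` percent. The defaults implement
#' the common ">= 200 aa, <= 85% identity" dereplication rule used when
#' compiling RT datasets.
#'
#' @param records a [protein_records()] tibble (or any tibble with `id` and
#'   `sequence` columns).
#' @param max_identity identity ceiling in percent.
#' @param min_len minimum sequence length in residues.
#' @param params a [search_params()] object.
#' @return The kept rows, in input order.
#' @export
dereplicate <- function(records, max_identity = 85, min_len = 200,
                        params = search_params()) {
  if (nrow(records) == 0) return(records)
  keep_pool <- records[nchar(records$sequence) >= min_len, , drop = FALSE]
  if (nrow(keep_pool) == 0) return(keep_pool)
  ord <- order(-nchar(keep_pool$sequence), seq_len(nrow(keep_pool)))
  reps <- character(0)
  for (i in ord) {
    s <- keep_pool$sequence[i]
    dup <- any(vapply(keep_pool$sequence[match(reps, keep_pool$id)],
                      function(r) pairwise_identity(s, r, params) > max_identity,
                      logical(1)))
    if (!dup) reps <- c(reps, keep_pool$id[i])
  }
  keep_pool[keep_pool$id %in% reps, , drop = FALSE]
}

# Progressive (center-star) multiple alignment: sequences are added in
# decreasing identity to the first/center sequence; each new sequence is
# aligned to the running consensus and gaps are propagated into all rows.
align_progressive <- function(seqs, params = search_params()) {
  stopifnot(length(seqs) >= 1)
  if (length(seqs) == 1) {
    return(matrix(strsplit(seqs, "", fixed = TRUE)[[1]], nrow = 1))
  }
  center <- which.max(nchar(seqs))
  idents <- vapply(seqs, function(s) pairwise_identity(seqs[center], s, params),
                   numeric(1))
  ord <- order(-idents, seq_along(seqs))
  ord <- c(center, setdiff(ord, center))
  rows <- list(strsplit(seqs[[ord[1]]], "", fixed = TRUE)[[1]])
  for (k in ord[-1]) {
    cons <- profile_consensus(do.call(rbind, rows), majority = 0)
    aln <- align_overlap(cons, seqs[[k]], params, traceback = TRUE)
    # expand existing rows wherever the consensus picked up a gap
    newrows <- lapply(rows, function(r) {
      out <- rep("-", length(aln$a_idx))
      out[aln$a_idx != 0L] <- r[aln$a_idx[aln$a_idx != 0L]]
      out
    })
    newb <- rep("-", length(aln$b_idx))
    bc <- strsplit(seqs[[k]], "", fixed = TRUE)[[1]]
    newb[aln$b_idx != 0L] <- bc[aln$b_idx[aln$b_idx != 0L]]
    rows <- c(newrows, list(newb))
  }
  m <- do.call(rbind, rows)
  # restore input order
  res <- matrix("-", length(seqs), ncol(m))
  for (i in seq_along(ord)) res[ord[i], ] <- m[i, ]
  rownames(res) <- names(seqs)
  res
}

# column-wise consensus of a character alignment matrix; majority = 0 gives
# plurality calls (used internally as the running profile)
profile_consensus <- function(alnmat, majority = 0.5) {
  cols <- apply(alnmat, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return("-")
    tab <- sort(table(col), decreasing = TRUE)
    if (tab[1] / sum(tab) > majority || majority == 0) names(tab)[1] else "X"
  })
  paste(cols[cols != "-"], collapse = "")
}

#' Majority-rule consensus sequence of a protein set
#'
#' Aligns the records progressively (pairwise overlap alignments merged along
#' an identity-ordered guide) and emits, per alignment column, the residue
#' whose frequency among non-gap characters exceeds `majority`, else `X`.
#' Columns that are all-gap are dropped, so the consensus is never longer
#' than the alignment.
#'
#' @inheritParams dereplicate
#' @param majority fraction in `[0, 1)` a residue must exceed to be called.
#' @return A single consensus amino-acid string.
#' @export
build_consensus <- function(records, majority = 0.5,
                            params = search_params()) {
  if (nrow(records) == 0) stop("build_consensus: no records")
  if (nrow(records) == 1) return(records$sequence[[1]])
  m <- align_progressive(records$sequence, params)
  profile_consensus(m, majority)
}

#' Smith-Waterman search of a query against a target set
#'
#' Optimal local alignment score per target, converted to a bitscore
#' `(lambda * S - ln K) / ln 2` and an e-value `space * 2^(-bitscore)` where
#' the search space follows `params$search_space_policy`. Hits are returned
#' sorted by ascending e-value with ties broken by target id.
#'
#' @param query non-empty sequence.
#' @param targets tibble with `id` and `sequence` columns (or a named
#'   character vector).
#' @param params a [search_params()] object.
#' @param max_evalue optional ceiling; hits above it are dropped.
#' @return Tibble with columns `id`, `score`, `bitscore`, `evalue`, and the
#'   local-alignment coordinates `q_start`, `q_end`, `t_start`, `t_end`.
#' @export
local_search <- function(query, targets, params = search_params(),
                         max_evalue = Inf) {
  if (!nzchar(query)) stop("local_search: empty query")
  if (is.character(targets)) {
    targets <- tibble(id = names(targets), sequence = unname(targets))
  }
  if (nrow(targets) == 0) {
    return(tibble(id = character(), score = numeric(), bitscore = numeric(),
                  evalue = numeric(), q_start = integer(), q_end = integer(),
                  t_start = integer(), t_end = integer()))
  }
  hits <- purrr::map2_dfr(targets$id, targets$sequence, function(id, tseq) {
    r <- align_local(query, tseq, params)
    tibble(id = id, score = r$score,
           bitscore = bit_score(r$score, params),
           evalue = evalue_from_score(r$score, nchar(query), nchar(tseq),
                                      params),
           q_start = r$a_start, q_end = r$a_end,
           t_start = r$b_start, t_end = r$b_end)
  })
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  hits[order(hits$evalue, hits$id), , drop = FALSE]
}
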