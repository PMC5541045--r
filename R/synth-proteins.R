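#' Generate protein families with a controlled identity structure
#'
#' Builds `n_clusters` independent clusters. Each cluster starts from a
#' random founder of `founder_len` residues; for every value `t` in
#' `identity_ladder` one member is emitted whose global identity to the
#' founder is `100 * t` percent (substitutions at distinct positions, so the
#' target is hit exactly up to rounding; verified internally against
#' [pairwise_identity()] within +/- 2 percentage points). Founders are
#' redrawn if any cross-cluster identity reaches `min(ladder) - 10`
#' percentage points, so clusters are well separated by construction.
#'
#' @param n_clusters number of clusters (founders), >= 1.
#' @param identity_ladder fractions in (0, 1]; one member per value.
#' @param founder_len founder length in residues.
#' @param seed integer; fully determines the output.
#' @return List with `records` (a [protein_records()] tibble, ids
#'   `c<k>_r<j>`) and `truth_clusters` (named character vector, id ->
#'   cluster id).
#' @export
generate_protein_family <- function(n_clusters, identity_ladder = 1.0,
                                    founder_len = 300, seed = 1) {
  stopifnot(n_clusters >= 1, founder_len >= 20)
  if (any(identity_ladder <= 0 | identity_ladder > 1)) {
    stop("identity_ladder values must lie in (0, 1]")
  }
  set.seed(seed)
  sep_floor <- min(identity_ladder) * 100 - 10
  founders <- character(0)
  for (k in seq_len(n_clusters)) {
    repeat {
      cand <- paste(sample(AA20, founder_len, replace = TRUE), collapse = "")
      ok <- all(vapply(founders,
                       function(f) pairwise_identity(cand, f) < sep_floor,
                       logical(1)))
      if (ok) break
    }
    founders <- c(founders, cand)
  }
  ids <- character(0); seqs <- character(0); clus <- character(0)
  for (k in seq_len(n_clusters)) {
    for (j in seq_along(identity_ladder)) {
      t <- identity_ladder[j]
      memb <- mutate_protein(founders[k], round((1 - t) * founder_len))
      got <- pairwise_identity(founders[k], memb)
      if (abs(got - 100 * t) > 2) {
        stop("internal: identity target ", 100 * t, " missed (got ",
             round(got, 1), ")")
      }
      ids <- c(ids, sprintf("c%d_r%d", k, j))
      seqs <- c(seqs, memb)
      clus <- c(clus, sprintf("cluster%d", k))
    }
  }
  list(records = protein_records(ids, seqs),
       truth_clusters = setNames(clus, ids))
}

#' Generate a hierarchical clade-structured protein family
#'
#' Emulates a single homologous protein family (e.g. the RTs of CRISPR-cas
#' loci) that has radiated into well-separated clades: one global ancestor
#' is diverged into per-clade founders (`clade_divergence` substitutions per
#' site), and each founder into its members (`member_divergence`). All
#' sequences are homologous over their full length, so the family can be
#' aligned and used for tree inference, consensus building and membership
#' screening.
#'
#' @param n_clades number of clades.
#' @param members_per_clade members emitted per clade.
#' @param clade_divergence,member_divergence per-site substitution
#'   fractions founder-vs-ancestor and member-vs-founder.
#' @param len sequence length in residues.
#' @param n_background lineages of non-CRISPR-associated relatives (e.g.
#'   group II intron RTs) drawn from the same ancestor; they bound the
#'   clades in support-threshold extraction exactly as related outgroup
#'   sequences do on real trees.
#' @param seed integer seed.
#' @return List with `records` ([protein_records()], ids `clade<k>_m<j>`
#'   and `bg<k>`), `truth_clades` (named vector id -> `clade<k>` or
#'   `"unassigned"`), and `metadata` (id, phylum, crispr_associated).
#' @export
generate_rt_clades <- function(n_clades, members_per_clade = 4,
                               clade_divergence = 0.35,
                               member_divergence = 0.08,
                               len = 250, n_background = 0, seed = 1) {
  stopifnot(n_clades >= 1, members_per_clade >= 1)
  set.seed(seed)
  anc <- paste(sample(AA20, len, replace = TRUE), collapse = "")
  ids <- character(0); seqs <- character(0); labs <- character(0)
  for (k in seq_len(n_clades)) {
    founder <- mutate_protein(anc, round(clade_divergence * len))
    for (j in seq_len(members_per_clade)) {
      ids <- c(ids, sprintf("clade%d_m%d", k, j))
      seqs <- c(seqs, mutate_protein(founder, round(member_divergence * len)))
      labs <- c(labs, sprintf("clade%d", k))
    }
  }
  for (k in seq_len(n_background)) {
    ids <- c(ids, sprintf("bg%d", k))
    seqs <- c(seqs, mutate_protein(anc, round(clade_divergence * len)))
    labs <- c(labs, "unassigned")
  }
  metadata <- tibble(id = ids,
                     phylum = ifelse(labs == "unassigned", "mixed", labs),
                     crispr_associated = labs != "unassigned")
  list(records = protein_records(ids, seqs),
       truth_clades = setNames(labs, ids),
       metadata = metadata)
}

# substitute n_sub distinct positions, always to a different residue
mutate_protein <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  }
  paste(chars, collapse = "")
}
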