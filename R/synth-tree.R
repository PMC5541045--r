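# Support-annotated trees with planted, well-supported clades.

# random binary newick over a set of labels; every internal node gets the
# given support label (the subtree root's label is set by the caller)
random_binary_newick <- function(labels, support) {
  if (length(labels) == 1) return(labels)
  k <- sample(seq_len(length(labels) - 1), 1)
  sh <- sample(labels)
  left <- random_binary_newick(sh[seq_len(k)], support)
  right <- random_binary_newick(sh[-seq_len(k)], support)
  sprintf("(%s,%s)%s", left, right, support)
}

#' Construct a clade partition object
#'
#' The package's leaf-to-clade labelling container: a tibble with one row
#' per leaf (`id`, `clade`, `subclade`), carrying the tree it was derived
#' from and a per-clade summary as attributes.
#'
#' @param df tibble with columns `id`, `clade` (and optionally `subclade`).
#' @param tree an [ape::phylo] (optional but required for monophyly-based
#'   congruence).
#' @param clades optional per-clade summary tibble.
#' @export
clade_partition <- function(df, tree = NULL, clades = NULL) {
  stopifnot(all(c("id", "clade") %in% names(df)))
  if (!"subclade" %in% names(df)) df$subclade <- NA_character_
  out <- as_tibble(df[, c("id", "clade", "subclade")])
  attr(out, "tree") <- tree
  attr(out, "clades") <- clades
  class(out) <- c("clade_partition", class(out))
  out
}

#' Generate a support-annotated tree with planted clades
#'
#' Builds a random binary tree over `n_leaves` leaves in which each planted
#' clade is monophyletic and its defining node carries support
#' `support_high`; every other internal node carries `support_low`
#' (< 0.92), so clade extraction at the 0.92 rule recovers exactly the
#' planted partition. Leaves inside planted clades are flagged as
#' CRISPR-associated; leaves outside are not and are labelled
#' `"unassigned"` in the truth.
#'
#' @param n_leaves total number of leaves (ids `t1..tn`).
#' @param planted_clades named list: clade label -> character vector of
#'   leaf ids (pairwise disjoint).
#' @param support_high support on planted clade roots (>= 0.92).
#' @param support_low support on all other internal nodes (< 0.92).
#' @param seed integer seed.
#' @param phyla optional named character vector mapping clade label ->
#'   phylum; defaults to one phylum per clade, `"mixed"` outside.
#' @return List with `tree` (phylo, supports in `node.label`), `metadata`
#'   (tibble: id, phylum, crispr_associated) and `truth` (a
#'   [clade_partition()]).
#' @export
generate_clade_tree <- function(n_leaves, planted_clades = list(),
                                support_high = 0.95, support_low = 0.5,
                                seed = 1, phyla = NULL) {
  stopifnot(support_high >= 0.92, support_low < 0.92)
  all_planted <- unlist(planted_clades, use.names = FALSE)
  if (anyDuplicated(all_planted)) {
    stop("planted clades must be pairwise disjoint")
  }
  leaves <- sprintf("t%d", seq_len(n_leaves))
  stopifnot(all(all_planted %in% leaves))
  set.seed(seed)
  units <- character(0)
  for (lab in names(planted_clades)) {
    members <- planted_clades[[lab]]
    sub <- if (length(members) == 1) {
      members
    } else {
      # clade root support is set afterwards; inner nodes stay low
      s <- random_binary_newick(members, support_low)
      sub_root <- sub("\\)[0-9.]*$", ")", s)
      paste0(sub_root, support_high)
    }
    units <- c(units, sub)
  }
  units <- c(units, setdiff(leaves, all_planted))
  nwk <- if (length(units) == 1) {
    paste0(units, ";")
  } else {
    paste0(random_binary_newick_units(units, support_low), ";")
  }
  tree <- ape::read.tree(text = nwk)
  # the (arbitrary) root node carries no support, unless it defines a clade
  if (!is.null(tree$node.label) && length(tree$node.label) &&
      tree$node.label[1] == as.character(support_low)) {
    tree$node.label[1] <- ""
  }
  if (is.null(phyla)) {
    phyla <- setNames(sprintf("phylum_%02d", seq_along(planted_clades)),
                      names(planted_clades))
  }
  leaf_clade <- rep("unassigned", n_leaves)
  names(leaf_clade) <- leaves
  for (lab in names(planted_clades)) {
    leaf_clade[planted_clades[[lab]]] <- lab
  }
  metadata <- tibble(
    id = leaves,
    phylum = ifelse(leaf_clade == "unassigned", "mixed",
                    unname(phyla[leaf_clade])),
    crispr_associated = leaf_clade != "unassigned")
  truth <- clade_partition(tibble(id = leaves, clade = unname(leaf_clade)),
                           tree = tree)
  list(tree = tree, metadata = metadata, truth = truth)
}

# join prebuilt newick units (subtrees or leaves) under a random backbone
random_binary_newick_units <- function(units, support) {
  if (length(units) == 1) return(units)
  k <- sample(seq_len(length(units) - 1), 1)
  sh <- sample(units)
  left <- random_binary_newick_units(sh[seq_len(k)], support)
  right <- random_binary_newick_units(sh[-seq_len(k)], support)
  sprintf("(%s,%s)%s", left, right, support)
}
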