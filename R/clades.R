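# Support-threshold clade extraction, phylum subclades, consensus-based
# membership screening, and tree-congruence (coevolution) tests.

node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Distances are Poisson-corrected fractions of differing columns (gapped
#' columns ignored per pair); the topology is neighbor joining and node
#' supports are bootstrap replicate frequencies of each bipartition
#' (column resampling, `bootstrap_n` replicates, seed-deterministic).
#' Intended for desk-scale work; externally inferred support-annotated
#' Newick trees can be used everywhere a tree is consumed.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences, or a character matrix (rows = sequences).
#' @param bootstrap_n bootstrap replicates.
#' @param seed integer seed.
#' @return An [ape::phylo] with supports (0-1) in `node.label`.
#' @export
build_tree <- function(alignment, bootstrap_n = 100, seed = 1) {
  m <- if (is.matrix(alignment)) {
    alignment
  } else {
    stopifnot(length(unique(nchar(alignment))) == 1)
    do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  }
  if (is.null(rownames(m)) && !is.matrix(alignment)) {
    rownames(m) <- names(alignment)
  }
  if (nrow(m) < 3) stop("build_tree: need at least 3 sequences")
  if (ncol(m) == 0) stop("build_tree: zero-length alignment")
  nj_fun <- function(x) ape::nj(poisson_dist(x))
  tree <- nj_fun(m)
  if (nrow(m) == 3) {
    # the unique unrooted topology: no non-trivial bipartition to test
    tree$node.label <- rep("1.00", tree$Nnode)
    return(tree)
  }
  set.seed(seed)
  counts <- ape::boot.phylo(tree, m, nj_fun, B = bootstrap_n,
                            quiet = TRUE, rooted = FALSE)
  supp <- counts / bootstrap_n
  supp[1] <- NA  # root of the unrooted representation
  tree$node.label <- ifelse(is.na(supp), "", format(supp, trim = TRUE))
  tree
}

poisson_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-" | m == "."
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- !gap[i, ] & !gap[j, ]
      # pairs with (almost) no overlapping columns are maximally distant
      p <- if (sum(use) >= 10) mean(m[i, use] != m[j, use]) else 0.95
      p <- min(p, 0.95)
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  stats::as.dist(d)
}

#' Assign clades at a support threshold
#'
#' Candidate nodes are internal nodes whose support is at least
#' `support_min`, whose leaf set contains at least `min_size`
#' CRISPR-associated leaves and no leaf lacking that flag; clades are the
#' maximal candidates (no candidate ancestor also qualifies). Labels
#' `clade1, clade2, ...` are assigned in order of first leaf appearance;
#' all other leaves are `"unassigned"`.
#'
#' @param tree an [ape::phylo] with supports in `node.label`.
#' @param metadata tibble with `id`, `crispr_associated` (and `phylum`,
#'   used by [split_subclades()]).
#' @param support_min support threshold.
#' @param min_size minimum number of flagged leaves in a clade.
#' @return A [clade_partition()].
#' @export
assign_clades <- function(tree, metadata, support_min = 0.92, min_size = 2) {
  supp <- node_supports(tree)
  if (all(is.na(supp))) stop("assign_clades: tree carries no support values")
  ntip <- length(tree$tip.label)
  flags <- setNames(metadata$crispr_associated, metadata$id)
  if (!all(tree$tip.label %in% names(flags))) {
    stop("assign_clades: metadata missing for some leaves")
  }
  desc <- phangorn::Descendants(tree, (ntip + 1):(ntip + tree$Nnode), "tips")
  cand <- vapply(seq_len(tree$Nnode), function(k) {
    tips <- tree$tip.label[desc[[k]]]
    !is.na(supp[k]) && supp[k] >= support_min &&
      sum(flags[tips]) >= min_size && all(flags[tips])
  }, logical(1))
  cand_nodes <- which(cand) + ntip
  # maximality: drop candidates with a qualifying ancestor
  keep <- cand_nodes[vapply(cand_nodes, function(nd) {
    anc <- phangorn::Ancestors(tree, nd, "all")
    !any(anc %in% cand_nodes)
  }, logical(1))]
  leaf_clade <- setNames(rep("unassigned", ntip), tree$tip.label)
  if (length(keep)) {
    first_tip <- vapply(keep, function(nd) min(desc[[nd - ntip]]), numeric(1))
    keep <- keep[order(first_tip)]
    for (k in seq_along(keep)) {
      tips <- tree$tip.label[desc[[keep[k] - ntip]]]
      leaf_clade[tips] <- sprintf("clade%d", k)
    }
  }
  summary_tb <- if (length(keep)) {
    tibble(clade = sprintf("clade%d", seq_along(keep)), node = keep,
           support = supp[keep - ntip],
           n_leaves = vapply(keep, function(nd) length(desc[[nd - ntip]]),
                             numeric(1)))
  } else {
    tibble(clade = character(), node = integer(), support = numeric(),
           n_leaves = numeric())
  }
  clade_partition(tibble(id = tree$tip.label, clade = unname(leaf_clade)),
                  tree = tree, clades = summary_tb)
}

#' Split phylum-restricted subclades
#'
#' Within each clade of a partition, well-supported descendant nodes
#' (support >= `support_min`) of at least `min_size` leaves in which at
#' least `phylum_purity` of the leaves belong to one phylum become lettered
#' subclades (`clade8A`, `clade8B`, ...); remaining leaves keep the parent
#' label. Clades whose leaves all belong to a single phylum are never
#' split.
#'
#' @param partition a [clade_partition()] from [assign_clades()].
#' @param metadata tibble with `id` and `phylum`.
#' @param phylum_purity required majority-phylum fraction.
#' @param min_size minimum subclade size in leaves.
#' @param support_min support threshold for subclade nodes.
#' @return The refined [clade_partition()].
#' @export
split_subclades <- function(partition, metadata, phylum_purity = 0.9,
                            min_size = 3, support_min = 0.92) {
  tree <- attr(partition, "tree")
  clades_tb <- attr(partition, "clades")
  stopifnot(!is.null(tree), !is.null(clades_tb))
  supp <- node_supports(tree)
  ntip <- length(tree$tip.label)
  phyl <- setNames(metadata$phylum, metadata$id)
  desc <- phangorn::Descendants(tree, (ntip + 1):(ntip + tree$Nnode), "tips")
  out <- partition
  for (ci in seq_len(nrow(clades_tb))) {
    cnode <- clades_tb$node[ci]
    ctips <- tree$tip.label[desc[[cnode - ntip]]]
    if (length(unique(phyl[ctips])) < 2) next
    inner <- setdiff(unlist(phangorn::Descendants(tree, cnode, "all")),
                     seq_len(ntip))
    qual <- inner[vapply(inner, function(nd) {
      tips <- tree$tip.label[desc[[nd - ntip]]]
      !is.na(supp[nd - ntip]) && supp[nd - ntip] >= support_min &&
        length(tips) >= min_size &&
        max(table(phyl[tips])) / length(tips) >= phylum_purity
    }, logical(1))]
    qual <- qual[vapply(qual, function(nd) {
      anc <- phangorn::Ancestors(tree, nd, "all")
      !any(anc %in% qual)
    }, logical(1))]
    if (!length(qual)) next
    first_tip <- vapply(qual, function(nd) min(desc[[nd - ntip]]), numeric(1))
    qual <- qual[order(first_tip)]
    for (k in seq_along(qual)) {
      tips <- tree$tip.label[desc[[qual[k] - ntip]]]
      out$subclade[out$id %in% tips] <-
        paste0(clades_tb$clade[ci], LETTERS[k])
    }
  }
  out
}

#' Build calibrated clade membership models
#'
#' Per clade: a majority consensus of the member sequences, the e-value
#' window observed for members against their own consensus, and an
#' exclusion threshold placed at the log-midpoint between the worst member
#' e-value and the best non-member e-value (the data-driven analogue of a
#' fixed "no outsider below e-75" style cutoff).
#'
#' @param records [protein_records()] tibble covering all leaves.
#' @param partition a [clade_partition()].
#' @param params a [search_params()].
#' @return List of clade models (label, members, consensus, evalue_window,
#'   exclusion_threshold).
#' @export
build_clade_models <- function(records, partition, params = search_params()) {
  labs <- setdiff(unique(partition$clade), "unassigned")
  models <- lapply(labs, function(lab) {
    ids <- partition$id[partition$clade == lab]
    mem <- records[records$id %in% ids, , drop = FALSE]
    cons <- build_consensus(mem, params = params)
    ev <- vapply(mem$sequence, function(s) {
      local_search(s, c(cons = cons), params)$evalue[1]
    }, numeric(1))
    list(label = lab, members = mem$id, consensus = cons,
         evalue_window = range(ev), worst_member = max(ev))
  })
  for (k in seq_along(models)) {
    non <- records[!records$id %in% models[[k]]$members, , drop = FALSE]
    thr <- if (nrow(non)) {
      nev <- vapply(non$sequence, function(s) {
        local_search(s, c(cons = models[[k]]$consensus), params)$evalue[1]
      }, numeric(1))
      10^((log10(models[[k]]$worst_member) + log10(min(nev))) / 2)
    } else {
      models[[k]]$worst_member * 1e5
    }
    models[[k]]$exclusion_threshold <- thr
  }
  models
}

#' Screen a query against clade membership models
#'
#' The model with the best e-value wins iff that e-value is at or below the
#' model's exclusion threshold; ambiguous ties and all-excluded queries
#' return `"none"`.
#'
#' @param query amino-acid sequence.
#' @param models list from [build_clade_models()].
#' @param params a [search_params()].
#' @return List with `clade` (label or `"none"`) and `evalue`.
#' @export
screen_membership <- function(query, models, params = search_params()) {
  stopifnot(length(models) > 0)
  ev <- vapply(models, function(m) {
    local_search(query, c(cons = m$consensus), params)$evalue[1]
  }, numeric(1))
  best <- which(ev == min(ev))
  if (length(best) > 1) return(list(clade = "none", evalue = min(ev)))
  if (ev[best] <= models[[best]]$exclusion_threshold) {
    list(clade = models[[best]]$label, evalue = ev[best])
  } else {
    list(clade = "none", evalue = ev[best])
  }
}

#' Test monophyly of leaf labels on an unrooted tree
#'
#' A label is monophyletic iff its leaf set forms one side of a bipartition
#' of the unrooted tree (equivalently, the minimal spanning subtree of the
#' label, rooted with the label complement as outgroup, contains no other
#' leaf). The defining node's support is reported when available.
#'
#' @param tree an [ape::phylo].
#' @param labels named character vector leaf id -> label; `"unassigned"`
#'   and `NA` leaves are ignored as labels but still count as outsiders.
#' @return Tibble: `label`, `n`, `monophyletic`, `support`.
#' @export
test_monophyly <- function(tree, labels) {
  labels <- labels[!is.na(labels) & labels != "unassigned"]
  if (!all(names(labels) %in% tree$tip.label)) {
    stop("test_monophyly: labels refer to leaves absent from the tree")
  }
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, (ntip + 1):(ntip + tree$Nnode), "tips")
  supp <- node_supports(tree)
  sets <- lapply(desc, function(ix) tree$tip.label[ix])
  purrr::map_dfr(unique(labels), function(lab) {
    L <- names(labels)[labels == lab]
    if (length(L) == ntip || length(L) == 1) {
      return(tibble(label = lab, n = length(L), monophyletic = TRUE,
                    support = NA_real_))
    }
    hit <- which(vapply(sets, function(S) {
      setequal(S, L) || setequal(S, setdiff(tree$tip.label, L))
    }, logical(1)))
    tibble(label = lab, n = length(L), monophyletic = length(hit) > 0,
           support = if (length(hit)) supp[hit[1]] else NA_real_)
  })
}

#' Congruence between two clade partitions
#'
#' Computes the adjusted Rand index over the leaves shared by both
#' partitions, and (when both partitions carry trees) a per-label
#' coevolution surface: for every clade of the first partition, whether its
#' leaf set is monophyletic in each tree and hence whether the two
#' phylogenies agree on it.
#'
#' @param p1,p2 [clade_partition()] objects.
#' @return A `partition_congruence` list: `ari`, `n_shared`, `per_label`
#'   tibble (`label`, `mono_1`, `mono_2`, `agree`).
#' @export
partition_congruence <- function(p1, p2) {
  shared <- intersect(p1$id, p2$id)
  if (length(shared) < 2) {
    stop("partition_congruence: fewer than 2 shared leaves")
  }
  l1 <- p1$clade[match(shared, p1$id)]
  l2 <- p2$clade[match(shared, p2$id)]
  ari <- mclust::adjustedRandIndex(l1, l2)
  t1 <- attr(p1, "tree"); t2 <- attr(p2, "tree")
  per_label <- NULL
  if (!is.null(t1) && !is.null(t2)) {
    labs1 <- setNames(l1, shared)
    keep1 <- ape::keep.tip(t1, shared)
    keep2 <- ape::keep.tip(t2, shared)
    m1 <- test_monophyly(keep1, labs1)
    m2 <- test_monophyly(keep2, labs1)
    per_label <- tibble(label = m1$label, mono_1 = m1$monophyletic,
                        mono_2 = m2$monophyletic[match(m1$label, m2$label)])
    per_label$agree <- per_label$mono_1 & per_label$mono_2
  }
  structure(list(ari = ari, n_shared = length(shared),
                 per_label = per_label),
            class = "partition_congruence")
}

#' @export
print.partition_congruence <- function(x, ...) {
  cat("<partition_congruence> ARI =", round(x$ari, 4), "on", x$n_shared,
      "shared leaves\n")
  if (!is.null(x$per_label)) {
    cat(sum(x$per_label$agree), "of", nrow(x$per_label),
        "labels monophyletic in both trees\n")
  }
  invisible(x)
}
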