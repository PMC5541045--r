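meta_all <- function(ids, phylum = "p") {
  tibble::tibble(id = ids, phylum = phylum, crispr_associated = TRUE)
}

test_that("tree building handles minimal and degenerate alignments", {
  aln3 <- c(a = "AAAAAAAAAAAA", b = "AAAAAAAATTTT", c = "TTTTTTTTTTTT")
  tr <- build_tree(aln3, bootstrap_n = 20, seed = 1)
  expect_equal(ape::Ntip(tr), 3)

  # two clear pairs: the pairing bipartition must be strongly supported
  aln4 <- c(a = strrep("AC", 30), b = strrep("AC", 30),
            c = strrep("TG", 30), d = strrep("TG", 30))
  aln4 <- vapply(seq_along(aln4), function(i) {
    s <- strsplit(aln4[[i]], "")[[1]]
    s[seq(i, 60, 7)] <- "K"   # leaf-specific noise so distances differ
    paste(s, collapse = "")
  }, character(1))
  names(aln4) <- c("a", "b", "c", "d")
  tr4 <- build_tree(aln4, bootstrap_n = 100, seed = 2)
  supp <- suppressWarnings(as.numeric(tr4$node.label))
  expect_true(ape::is.monophyletic(tr4, c("a", "b")))
  expect_gte(max(supp, na.rm = TRUE), 0.9)

  # all-equal distances must still return a tree
  alneq <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC",
             d = "ACGTACGTAC")
  expect_s3_class(build_tree(alneq, bootstrap_n = 10, seed = 3), "phylo")

  expect_error(build_tree(c(a = "AA", b = "AA"), 10, 1), "at least 3")
  expect_error(build_tree(c(a = "", b = "", c = ""), 10, 1), "zero-length")
})

test_that("clade assignment needs supports and respects the threshold", {
  star <- ape::read.tree(text = "(t1,t2,t3,t4)0.5;")
  p <- assign_clades(star, meta_all(sprintf("t%d", 1:4)))
  expect_true(all(p$clade == "unassigned"))
  nosupp <- ape::read.tree(text = "(t1,(t2,t3),t4);")
  expect_error(assign_clades(nosupp, meta_all(sprintf("t%d", 1:4))),
               "no support")
})

test_that("nested qualifying nodes collapse to the maximal clade", {
  tr <- ape::read.tree(text = "(((a,b)0.95,(c,d)0.95)0.95,(e,f)0.5);")
  p <- assign_clades(tr, meta_all(letters[1:6]))
  expect_equal(sum(p$clade != "unassigned"), 4)
  expect_equal(length(unique(p$clade[p$clade != "unassigned"])), 1)
})

test_that("planted clade partitions are recovered exactly and supports
           gate assignment monotonically", {
  set.seed(19)
  sizes <- sample(4:8, 12, replace = TRUE)
  ids <- sprintf("t%d", 1:100)
  members <- sample(ids, sum(sizes))
  clades <- split(members, rep(1:12, sizes))
  names(clades) <- sprintf("pc%d", 1:12)
  g <- generate_clade_tree(100, clades, support_high = 0.95,
                           support_low = 0.5, seed = 20)
  p <- assign_clades(g$tree, g$metadata)
  expect_equal(mclust::adjustedRandIndex(
    p$clade, g$truth$clade[match(p$id, g$truth$id)]), 1)
  expect_setequal(p$id[p$clade == "unassigned"],
                  g$truth$id[g$truth$clade == "unassigned"])
  # raising the threshold never assigns more leaves
  p99 <- assign_clades(g$tree, g$metadata, support_min = 0.99)
  expect_lte(sum(p99$clade != "unassigned"), sum(p$clade != "unassigned"))
  # assigned clades are pairwise disjoint connected subtrees by construction
  cl <- attr(p, "clades")
  expect_equal(nrow(cl), 12)
  expect_true(all(cl$support >= 0.92))
})

test_that("phylum subclades split only mixed, well-supported clades", {
  tr <- ape::read.tree(
    text = "(((a,(b,c)0.95)0.95,(d,(e,f)0.95)0.95)0.95,(g,h)0.3);")
  md <- tibble::tibble(id = letters[1:8],
                       phylum = c("P1", "P1", "P1", "P2", "P2", "P2",
                                  "X", "X"),
                       crispr_associated = c(rep(TRUE, 6), FALSE, FALSE))
  p <- assign_clades(tr, md, min_size = 2)
  expect_equal(sum(p$clade == "clade1"), 6)
  sp <- split_subclades(p, md, min_size = 3)
  expect_setequal(unique(stats::na.omit(sp$subclade)),
                  c("clade1A", "clade1B"))
  expect_equal(sum(sp$subclade == "clade1A", na.rm = TRUE), 3)

  # single-phylum clade: never split
  md1 <- md; md1$phylum <- c(rep("P1", 6), "X", "X")
  sp1 <- split_subclades(assign_clades(tr, md1, min_size = 2), md1)
  expect_true(all(is.na(sp1$subclade)))

  # purity below threshold: no split
  md2 <- md; md2$phylum <- c("P1", "P1", "P2", "P2", "P2", "P1", "X", "X")
  sp2 <- split_subclades(assign_clades(tr, md2, min_size = 2), md2,
                         phylum_purity = 0.9, min_size = 3)
  expect_true(all(is.na(sp2$subclade)))
})

test_that("membership screening self-assigns members inside the calibrated
           window and rejects shuffled or foreign queries", {
  fam <- generate_rt_clades(3, 4, seed = 23)
  part <- clade_partition(tibble::tibble(id = names(fam$truth_clades),
                                         clade = unname(fam$truth_clades)))
  models <- build_clade_models(fam$records, part)
  for (m in models) {
    expect_lte(m$evalue_window[2], m$exclusion_threshold)
  }
  r <- screen_membership(fam$records$sequence[1], models)
  expect_equal(r$clade, "clade1")
  expect_lte(r$evalue, models[[1]]$exclusion_threshold)

  set.seed(24)
  shuf <- paste(sample(strsplit(fam$records$sequence[1], "")[[1]]),
                collapse = "")
  expect_equal(screen_membership(shuf, models)$clade, "none")
})

test_that("monophyly testing agrees with exhaustive bipartition
           enumeration on random trees", {
  set.seed(25)
  for (i in 1:25) {
    tr <- ape::rtree(12)
    labs <- setNames(sample(c("A", "A", "A", "B", "B", rep("u", 7))),
                     tr$tip.label)
    labs <- labs[labs != "u"]
    got <- test_monophyly(tr, labs)
    for (lab in c("A", "B")) {
      expect_equal(got$monophyletic[got$label == lab],
                   oracle_is_clan(tr, names(labs)[labs == lab]),
                   info = sprintf("trial %d label %s", i, lab))
    }
  }
  # simple fixed cases
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_true(test_monophyly(tr, c(a = "x", b = "x"))$monophyletic)
  expect_false(test_monophyly(tr, c(a = "x", c = "x", b = "y"))$monophyletic[1])
  expect_error(test_monophyly(tr, c(zz = "x", a = "x")), "absent")
})

test_that("partition congruence: identity, permutation null, and error on
           disjoint leaf sets", {
  set.seed(26)
  sizes <- rep(5, 8)
  ids <- sprintf("t%d", 1:60)
  members <- sample(ids, sum(sizes))
  clades <- split(members, rep(1:8, sizes))
  names(clades) <- sprintf("pc%d", 1:8)
  g <- generate_clade_tree(60, clades, seed = 27)
  p <- assign_clades(g$tree, g$metadata)
  self <- partition_congruence(p, p)
  expect_equal(self$ari, 1.0)
  expect_true(all(self$per_label$agree))

  # permutation null: ARI ~ 0
  aris <- replicate(50, {
    q <- p; q$clade <- sample(q$clade)
    partition_congruence(p, q)$ari
  })
  expect_lt(abs(mean(aris)), 0.1)

  q2 <- clade_partition(tibble::tibble(id = c("zz1", "zz2"),
                                       clade = c("a", "b")))
  expect_error(partition_congruence(p, q2), "shared")
})
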