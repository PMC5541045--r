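test_that("an empty genome spec yields an empty truth ledger,
           deterministically", {
  spec <- genome_spec(length_bp = 10000, loci = list(),
                      decoy_gene_count = 0, seed = 1)
  g <- generate_genome(spec)
  expect_equal(nchar(g$sequence), 10000)
  expect_equal(nrow(g$truth$planted_arrays), 0)
  expect_equal(nrow(g$truth$planted_loci), 0)
  expect_identical(g, generate_genome(spec))
})

test_that("the truth ledger reads back the planted locus and everything in
           it is physically present in the sequence", {
  tpl <- locus_template("III-B/C", "RT-Cas1",
                        gene_order = c("cas10", "cmr1", "cmr3", "cmr4",
                                       "cmr5", "RT", "cas2"))
  g <- generate_genome(genome_spec(60000, loci = list(tpl),
                                   decoy_gene_count = 2, seed = 3))
  expect_equal(nrow(g$truth$planted_loci), 1)
  expect_equal(g$truth$planted_loci$subtype, "III-B/C")
  expect_equal(g$truth$planted_loci$fusion_class, "RT-Cas1")
  # plantedness audit: genes translate back to their recorded proteins
  for (i in which(!g$features$decoy)) {
    f <- g$features[i, ]
    nt <- substr(g$sequence, f$start, f$end - 3)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    expect_equal(aa, f$protein)
  }
  # arrays: the repeat occurs inside the recorded span
  a <- g$truth$planted_arrays
  span <- substr(g$sequence, a$start, a$end)
  rep_on_span <- if (a$orientation == "forward") a$repeat_seq else
    rtcrispr:::revcomp(a$repeat_seq)
  expect_gte(lengths(gregexpr(rep_on_span, span, fixed = TRUE)),
             a$n_repeats - 1)
  # coordinates in bounds
  expect_true(all(a$start >= 1 & a$end <= nchar(g$sequence)))
})

test_that("templates that do not fit raise a sizing error naming the
           template", {
  expect_error(
    generate_genome(genome_spec(5000, loci = list(locus_template()),
                                decoy_gene_count = 0, seed = 1)),
    "template 1")
})

test_that("template invariants are enforced", {
  expect_error(locus_template("III-A/D", "RT-Cas1",
                              gene_order = c("RT", "cas1")),
               "separate cas1")
  expect_error(locus_template("III-A/D", "Cas6-RT-Cas1",
                              gene_order = c("cas6", "RT")),
               "separate cas6")
  expect_error(locus_template("III-A/D", "RT",
                              gene_order = c("cas10", "cas2")),
               "exactly one RT")
})

test_that("protein families hit their identity ladder and separate
           between clusters", {
  one <- generate_protein_family(1, seed = 2)
  expect_equal(nrow(one$records), 1)
  expect_equal(unname(one$truth_clusters), "cluster1")

  fam <- generate_protein_family(2, c(1.0, 0.90, 0.80), founder_len = 300,
                                 seed = 4)
  expect_equal(nrow(fam$records), 6)
  id13 <- pairwise_identity(fam$records$sequence[1], fam$records$sequence[3])
  expect_gte(id13, 78); expect_lte(id13, 82)
  cross <- pairwise_identity(fam$records$sequence[1],
                             fam$records$sequence[4])
  expect_lt(cross, 70)
  expect_identical(fam$truth_clusters,
                   generate_protein_family(2, c(1.0, 0.90, 0.80),
                                           founder_len = 300,
                                           seed = 4)$truth_clusters)
  expect_error(generate_protein_family(1, c(1.5)), "identity_ladder")
})

test_that("clade trees plant exactly the requested well-supported clades", {
  g <- generate_clade_tree(4, list(A = c("t1", "t2")),
                           support_high = 0.99, support_low = 0.5, seed = 1)
  supp <- suppressWarnings(as.numeric(g$tree$node.label))
  expect_equal(sum(supp >= 0.92, na.rm = TRUE), 1)
  expect_setequal(g$truth$id[g$truth$clade == "A"], c("t1", "t2"))

  cherry <- generate_clade_tree(2, list(A = c("t1", "t2")), seed = 2)
  expect_equal(ape::Ntip(cherry$tree), 2)
  expect_true(all(cherry$truth$clade == "A"))

  expect_error(generate_clade_tree(4, list(A = c("t1", "t2"),
                                           B = c("t2", "t3"))),
               "disjoint")
})

test_that("decoy genes have no profile similarity at the annotation
           threshold", {
  g <- generate_genome(genome_spec(40000, loci = list(),
                                   decoy_gene_count = 3, seed = 6))
  prof <- cas_profiles()
  for (i in which(g$features$decoy)) {
    hits <- local_search(g$features$protein[i],
                         prof[, c("id", "sequence")])
    expect_gt(min(hits$evalue), 0.01)
  }
})

test_that("array genomes place arrays apart and in bounds", {
  g <- generate_array_genome(list(array_spec(), array_spec(n_repeats = 4)),
                             length_bp = 30000, seed = 8)
  expect_equal(nrow(g$truth), 2)
  expect_true(all(g$truth$start >= 1 & g$truth$end <= 30000))
  expect_gt(g$truth$start[2] - g$truth$end[1], 2000)
})
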