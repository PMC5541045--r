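make_hit <- function(tag, start, end, family, subtype_specific = TRUE,
                     contig = "c") {
  tibble::tibble(contig = contig, locus_tag = tag, start = start, end = end,
                 strand = "+", family = family, bitscore = 100,
                 evalue = 1e-50, subtype_specific = subtype_specific,
                 translation = "M", domains = list(tibble::tibble()))
}

test_that("ORF calling handles degenerate input and is strand-symmetric", {
  expect_equal(nrow(call_orfs(strrep("N", 2000))), 0)
  set.seed(71)
  contig <- rand_dna_seq(20000)
  fwd <- call_orfs(contig)
  rev <- call_orfs(rtcrispr:::revcomp(contig))
  n <- nchar(contig)
  mir <- tibble::tibble(start = n - rev$end + 1L, end = n - rev$start + 1L,
                        strand = ifelse(rev$strand == "+", "-", "+"))
  expect_setequal(paste(fwd$start, fwd$end, fwd$strand),
                  paste(mir$start, mir$end, mir$strand))
})

test_that("planted genes are recovered with exact coordinates and
           annotated to the right family at subtype stringency", {
  g <- generate_genome(genome_spec(60000, loci = list(locus_template()),
                                   decoy_gene_count = 2, seed = 2))
  orfs <- call_orfs(g$sequence, contig_name = g$contig)
  planted <- g$features[!g$features$decoy, ]
  expect_true(all(paste(planted$start, planted$end) %in%
                    paste(orfs$start, orfs$end)))
  hits <- annotate_cas(orfs, cas_profiles())
  cas10 <- hits[hits$family == "cas10", ]
  expect_equal(nrow(cas10), 1)
  expect_lte(cas10$evalue, 1e-6)
  # decoys never qualify
  decoys <- g$features[g$features$decoy, ]
  expect_false(any(paste(decoys$start, decoys$end) %in%
                     paste(hits$start, hits$end)))
})

test_that("hits between 1e-6 and 0.01 are annotated but never
           subtype-specific", {
  prof <- cas_profiles()
  set.seed(60)
  frag <- substr(prof$sequence[prof$id == "csm2"], 40, 51)
  weak <- paste0(paste(sample(rtcrispr:::AA20, 150, TRUE), collapse = ""),
                 frag,
                 paste(sample(rtcrispr:::AA20, 150, TRUE), collapse = ""))
  feats <- tibble::tibble(contig = "c", start = 1, end = 3 * nchar(weak) + 6,
                          strand = "+", locus_tag = "w1", translation = weak)
  hits <- annotate_cas(feats, prof)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$family, "csm2")
  expect_gt(hits$evalue, 1e-6)
  expect_lte(hits$evalue, 0.01)
  expect_false(hits$subtype_specific)
})

test_that("fusion classes follow domain architecture", {
  d1 <- tibble::tibble(family = "RT", start = 1, end = 400)
  expect_equal(detect_fusion(d1), "RT")
  d2 <- tibble::tibble(family = c("RT", "cas1"), start = c(1, 420),
                       end = c(400, 700))
  expect_equal(detect_fusion(d2), "RT-Cas1")
  d3 <- tibble::tibble(family = c("cas6", "RT", "cas1"),
                       start = c(1, 200, 620), end = c(180, 600, 900))
  expect_equal(detect_fusion(d3), "Cas6-RT-Cas1")
  expect_error(detect_fusion(tibble::tibble(family = "cas1", start = 1,
                                            end = 10)), "no RT domain")
})

test_that("fusion classes of planted RT genes are read back from
           detected domains", {
  for (fc in c("RT", "RT-Cas1", "Cas6-RT-Cas1")) {
    tpl <- locus_template("III-B/C", fc)
    g <- generate_genome(genome_spec(60000, loci = list(tpl),
                                     decoy_gene_count = 0,
                                     seed = 100 + nchar(fc)))
    rt_feat <- g$features[grepl("RT", g$features$family), ]
    dom <- detect_domains(rt_feat$protein[[1]], cas_profiles())
    expect_equal(detect_fusion(dom), fc)
  }
})

test_that("locus trimming applies the strict 5 kb rule at the boundary", {
  rt <- make_hit("rt", 10000, 11000, "RT", FALSE)
  near <- make_hit("g1", 16000, 16500, "csm2")    # gap = 4999
  far <- make_hit("g2", 16001, 16500, "csm2")     # gap = 5000
  loc_near <- extract_locus(rt, dplyr::bind_rows(rt, near), NULL)
  expect_equal(nrow(loc_near$features), 2)
  expect_equal(loc_near$region$end, 16500)
  loc_far <- extract_locus(rt, dplyr::bind_rows(rt, far), NULL)
  expect_equal(nrow(loc_far$features), 1)
  expect_equal(loc_far$region$end, 11000)
})

test_that("locus extraction is idempotent and chains through both sides", {
  rt <- make_hit("rt", 50000, 51000, "RT", FALSE)
  others <- dplyr::bind_rows(
    make_hit("l2", 40000, 41000, "cmr1"),
    make_hit("l1", 44000, 45500, "cmr3"),
    make_hit("r1", 53000, 54000, "cas2"),
    make_hit("x", 62000, 63000, "cas1"))   # gap 7999 from r1: excluded
  loc <- extract_locus(rt, dplyr::bind_rows(rt, others), NULL)
  expect_setequal(loc$features$locus_tag, c("l2", "l1", "rt", "r1"))
  loc2 <- extract_locus(rt, loc$features, loc$arrays)
  expect_equal(loc$region, loc2$region)
  expect_equal(loc$features$locus_tag, loc2$features$locus_tag)
  # every retained inter-element gap < 5000
  f <- loc$features[order(loc$features$start), ]
  expect_true(all(f$start[-1] - f$end[-nrow(f)] - 1 < 5000))
})

test_that("a planted oversized internal gap truncates the locus exactly
           at the gap", {
  tpl <- locus_template("III-B/C", "RT-Cas1",
                        gene_order = c("cas10", "cmr1", "cmr3", "cmr4",
                                       "cmr5", "RT", "cas2"),
                        intergenic_gaps_bp = c(100, 6000, 100, 100, 100,
                                               100))
  g <- generate_genome(genome_spec(70000, loci = list(tpl),
                                   decoy_gene_count = 0, seed = 9))
  orfs <- call_orfs(g$sequence, contig_name = g$contig)
  hits <- annotate_cas(orfs, cas_profiles())
  arrays <- detect_arrays(g$sequence, contig_name = g$contig)
  rt <- hits[hits$family == "RT", ]
  loc <- extract_locus(rt, hits, arrays)
  # cas10 and cmr1 sit left of the 6 kb gap and must be trimmed away
  expect_false(any(c("cas10", "cmr1") %in% loc$features$family))
  keep <- g$features[!g$features$family %in% c("cas10", "cmr1"), ]
  expect_equal(loc$region$start, min(keep$start))
})

test_that("subtype classification follows the signature families", {
  g <- generate_genome(genome_spec(60000,
                                   loci = list(locus_template("III-A/D")),
                                   decoy_gene_count = 0, seed = 12))
  orfs <- call_orfs(g$sequence, contig_name = g$contig)
  hits <- annotate_cas(orfs, cas_profiles())
  rt <- hits[hits$family == "RT", ]
  loc <- extract_locus(rt, hits, detect_arrays(g$sequence,
                                               contig_name = g$contig))
  expect_equal(classify_subtype(loc), "III-A/D")

  rt2 <- make_hit("rt", 1000, 2000, "RT", FALSE)
  partial <- list(features = dplyr::bind_rows(
    rt2, make_hit("a", 3000, 3500, "cas1", FALSE),
    make_hit("b", 3600, 3900, "cas2", FALSE)))
  expect_equal(classify_subtype(partial), "partial")
  expect_equal(classify_subtype(list(features = rt2)), "unknown")
  both <- list(features = dplyr::bind_rows(
    rt2, make_hit("a", 3000, 3500, "csm2"),
    make_hit("b", 3600, 3900, "cmr1")))
  expect_equal(classify_subtype(both), "ambiguous")
})

test_that("the distribution table is pure order-invariant counting", {
  expect_equal(nrow(tabulate_distribution(tibble::tibble(
    clade = character(), subtype = character(),
    fusion_class = character()))), 0)
  loci <- tibble::tibble(
    clade = c("clade1", "clade1", "clade2", "unassigned"),
    subtype = c("III-A/D", "III-A/D", "III-B/C", "partial"),
    fusion_class = c("RT-Cas1", "RT-Cas1", "Cas6-RT-Cas1", "RT"))
  tb <- tabulate_distribution(loci)
  expect_equal(sum(tb$n), 4)
  expect_equal(tb$n[tb$clade == "clade1"], 2)
  perm <- tabulate_distribution(loci[c(3, 1, 4, 2), ])
  expect_equal(tb, perm)
})
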