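test_that("identity of identical sequences is 100 and bounded in [0, 100]", {
  set.seed(1)
  s <- rand_aa(200)
  expect_equal(pairwise_identity(s, s), 100)
  for (i in 1:20) {
    a <- rand_aa(sample(20:60, 1)); b <- rand_aa(sample(20:60, 1))
    v <- pairwise_identity(a, b)
    expect_gte(v, 0); expect_lte(v, 100)
  }
  expect_error(pairwise_identity("", "AA"), "empty")
})

test_that("identity matches the exhaustive DP oracle on a classic pair", {
  got <- pairwise_identity("HEAGAWGHEE", "PAWHEAE")
  expect_equal(got, oracle_identity("HEAGAWGHEE", "PAWHEAE"))
})

test_that("identity is symmetric on random pairs", {
  set.seed(42)
  for (i in 1:30) {
    a <- rand_aa(sample(10:40, 1)); b <- rand_aa(sample(10:40, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("overlap scores/matches and local scores equal pure-R DP oracles", {
  set.seed(7)
  p <- search_params()
  for (i in 1:40) {
    a <- rand_aa(sample(5:30, 1)); b <- rand_aa(sample(5:30, 1))
    got <- rtcrispr:::align_overlap(a, b, p)
    ora <- oracle_nw_overlap(a, b)
    expect_equal(got$score, ora$score)
    expect_equal(got$matches, ora$matches)
    expect_equal(rtcrispr:::align_local(a, b, p)$score, oracle_sw_score(a, b))
  }
})

test_that("local_search ranks a self-hit first with the smallest e-value", {
  set.seed(3)
  q <- rand_aa(80)
  targets <- c(self = q, o1 = rand_aa(80), o2 = rand_aa(90))
  hits <- local_search(q, targets)
  expect_equal(hits$id[1], "self")
  expect_true(all(hits$evalue[1] <= hits$evalue))
})

test_that("e-values scale linearly with search space and drop with score", {
  p <- search_params()
  e1 <- rtcrispr:::evalue_from_score(60, 100, 200, p)
  e2 <- rtcrispr:::evalue_from_score(60, 200, 200, p)
  expect_equal(e2 / e1, 2)
  expect_lt(rtcrispr:::evalue_from_score(61, 100, 200, p), e1)
})

test_that("dereplication collapses duplicates and matches the greedy oracle", {
  recs <- protein_records(c("a", "b"), rep(strrep("MKVLA", 50), 2))
  expect_equal(nrow(dereplicate(recs)), 1)

  fam <- generate_protein_family(4, c(1, 0.92, 0.84, 0.75), founder_len = 220,
                                 seed = 11)
  got <- dereplicate(fam$records, max_identity = 85, min_len = 200)
  expect_setequal(got$id, oracle_dereplicate_ids(fam$records))
  # output preserves input order
  expect_equal(got$id, fam$records$id[fam$records$id %in% got$id])
})

test_that("dereplication is idempotent and drops short sequences", {
  fam <- generate_protein_family(3, c(1, 0.9, 0.8), founder_len = 250,
                                 seed = 5)
  once <- dereplicate(fam$records)
  twice <- dereplicate(once)
  expect_equal(once$id, twice$id)
  short <- protein_records("s", rand_aa(150))
  expect_equal(nrow(dereplicate(dplyr::bind_rows(fam$records, short))),
               nrow(once))
  # every dropped record is >85% identical to some representative
  dropped <- fam$records[!fam$records$id %in% once$id, ]
  for (i in seq_len(nrow(dropped))) {
    ids <- vapply(once$sequence,
                  function(r) pairwise_identity(dropped$sequence[i], r),
                  numeric(1))
    expect_gt(max(ids), 85)
  }
})

test_that("consensus building recovers founders and flags ambiguity as X", {
  rec1 <- protein_records("x", "MKVLAWHE")
  expect_equal(build_consensus(rec1), "MKVLAWHE")
  rec3 <- protein_records(c("a", "b", "c"), rep(strrep("MKVLAWHE", 10), 3))
  cons <- build_consensus(rec3)
  expect_equal(cons, strrep("MKVLAWHE", 10))
  expect_false(grepl("X", cons))

  set.seed(9)
  founder <- rand_aa(200)
  membs <- vapply(1:5, function(i) {
    rtcrispr:::mutate_protein(founder, 20)
  }, character(1))
  cons <- build_consensus(protein_records(paste0("m", 1:5), membs))
  expect_gte(pairwise_identity(cons, founder), 95)
  expect_error(build_consensus(protein_records(character(0), character(0))),
               "no records")
})
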