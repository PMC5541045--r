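# Independent pure-R oracles used to validate the compiled alignment
# kernels and the higher-level clustering / tree operations. These follow
# the same operation definitions but share no code with the implementation.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_aa <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")
rand_dna_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

oracle_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  storage.mode(m) <- "double"
  m
}

# End-gap-free global alignment by explicit affine-gap DP over three state
# matrices, carrying (score, max matches among co-optimal paths).
oracle_nw_overlap <- function(a, b, sub = oracle_submat(), go = 11, ge = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e30
  Ms <- matrix(NEG, n + 1, m + 1); Mm <- matrix(0L, n + 1, m + 1)
  Xs <- matrix(NEG, n + 1, m + 1); Xm <- matrix(0L, n + 1, m + 1)
  Ys <- matrix(NEG, n + 1, m + 1); Ym <- matrix(0L, n + 1, m + 1)
  Ms[1, ] <- 0; Ms[, 1] <- 0
  pickmax <- function(ss, mm) {
    best <- max(ss)
    list(s = best, m = max(mm[ss == best]))
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[av[i - 1], bv[j - 1]]
      hit <- as.integer(av[i - 1] == bv[j - 1])
      d <- pickmax(c(Ms[i - 1, j - 1], Xs[i - 1, j - 1], Ys[i - 1, j - 1]),
                   c(Mm[i - 1, j - 1], Xm[i - 1, j - 1], Ym[i - 1, j - 1]))
      Ms[i, j] <- d$s + s; Mm[i, j] <- d$m + hit
      x <- pickmax(c(Ms[i - 1, j] - go - ge, Xs[i - 1, j] - ge,
                     Ys[i - 1, j] - go - ge),
                   c(Mm[i - 1, j], Xm[i - 1, j], Ym[i - 1, j]))
      Xs[i, j] <- x$s; Xm[i, j] <- x$m
      y <- pickmax(c(Ms[i, j - 1] - go - ge, Xs[i, j - 1] - go - ge,
                     Ys[i, j - 1] - ge),
                   c(Mm[i, j - 1], Xm[i, j - 1], Ym[i, j - 1]))
      Ys[i, j] <- y$s; Ym[i, j] <- y$m
    }
  }
  ss <- c(Ms[, m + 1], Xs[, m + 1], Ys[, m + 1],
          Ms[n + 1, ], Xs[n + 1, ], Ys[n + 1, ])
  mm <- c(Mm[, m + 1], Xm[, m + 1], Ym[, m + 1],
          Mm[n + 1, ], Xm[n + 1, ], Ym[n + 1, ])
  best <- max(ss)
  list(score = best, matches = max(mm[ss == best]))
}

oracle_identity <- function(a, b, ...) {
  100 * oracle_nw_overlap(a, b, ...)$matches / min(nchar(a), nchar(b))
}

# Smith-Waterman optimal local score, affine gaps, explicit DP.
oracle_sw_score <- function(a, b, sub = oracle_submat(), go = 11, ge = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e30
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1], 0) + s)
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge,
                     Y[i - 1, j] - go - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - go - ge,
                     Y[i, j - 1] - ge)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Greedy longest-first dereplication re-implemented directly from the rule,
# over a precomputed identity matrix.
oracle_dereplicate_ids <- function(records, max_identity = 85,
                                   min_len = 200) {
  recs <- records[nchar(records$sequence) >= min_len, , drop = FALSE]
  if (nrow(recs) == 0) return(character(0))
  idm <- outer(seq_len(nrow(recs)), seq_len(nrow(recs)),
               Vectorize(function(i, j) {
                 if (i == j) 100 else
                   pairwise_identity(recs$sequence[i], recs$sequence[j])
               }))
  ord <- order(-nchar(recs$sequence), seq_len(nrow(recs)))
  kept <- integer(0)
  for (i in ord) {
    if (all(idm[i, kept] <= max_identity)) kept <- c(kept, i)
  }
  sort(recs$id[kept])
}

# Is the leaf set `L` one side of a bipartition of the unrooted tree?
# Independent check by edge removal + component traversal on the edge list.
oracle_is_clan <- function(tree, L) {
  tips <- tree$tip.label
  if (length(L) <= 1 || length(L) == length(tips)) return(TRUE)
  edges <- tree$edge
  nn <- max(edges)
  for (k in seq_len(nrow(edges))) {
    adj <- edges[-k, , drop = FALSE]
    # component containing edges[k,2]
    comp <- edges[k, 2]
    repeat {
      nb <- unique(c(adj[adj[, 1] %in% comp, 2], adj[adj[, 2] %in% comp, 1]))
      new <- setdiff(nb, comp)
      if (!length(new)) break
      comp <- c(comp, new)
    }
    side <- tips[comp[comp <= length(tips)]]
    if (setequal(side, L) || setequal(setdiff(tips, side), L)) return(TRUE)
  }
  FALSE
}
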