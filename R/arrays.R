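# De novo CRISPR repeat-spacer array detection and the three-criterion
# orientation cascade.

empty_arrays <- function() {
  out <- tibble(contig = character(), start = integer(), end = integer(),
                n_repeats = integer(), repeat_consensus = character(),
                repeats = list(), spacers = list(),
                orientation = character(), band = character(),
                criterion = character(), score = numeric())
  class(out) <- c("crispr_arrays", class(out))
  out
}

#' Detect CRISPR repeat-spacer arrays
#'
#' K-mer-seeded (k = 8) detector: positions sharing an 8-mer at a periodic
#' spacing compatible with the repeat/spacer length windows seed candidate
#' arrays; each candidate's repeat unit is extended maximally by column
#' majority across the copies; candidates must satisfy the length windows,
#' a per-copy identity floor against the repeat consensus, and a minimum
#' copy number. Overlapping candidates are resolved by keeping the one with
#' more repeats, then the longer span, then the leftmost. Coordinates are
#' 1-based inclusive; orientation is left `"undetermined"` for the
#' orientation cascade ([resolve_orientation()]).
#'
#' @param contig DNA sequence (character scalar).
#' @param min_repeats minimum number of repeat copies.
#' @param repeat_len,spacer_len allowed length windows in bp.
#' @param repeat_id_min per-copy percent identity floor vs the consensus.
#' @param contig_name name recorded in the output.
#' @return A `crispr_arrays` tibble (possibly empty) with list-columns
#'   `repeats` and `spacers` holding per-unit coordinates and sequences.
#' @export
detect_arrays <- function(contig, min_repeats = 3, repeat_len = c(19, 48),
                          spacer_len = c(17, 72), repeat_id_min = 85,
                          contig_name = "contig") {
  contig <- toupper(contig)
  n <- nchar(contig)
  k <- 8L
  min_fp <- min_repeats * repeat_len[1] + (min_repeats - 1) * spacer_len[1]
  if (n < min_fp) return(empty_arrays())
  chars <- strsplit(contig, "", fixed = TRUE)[[1]]
  kmers <- substring(contig, 1:(n - k + 1), k:n)
  dup <- kmers %in% unique(kmers[duplicated(kmers)])
  pos <- which(dup)
  if (length(pos) < min_repeats) return(empty_arrays())
  km <- kmers[pos]
  ord <- order(km, pos)
  pos <- pos[ord]; km <- km[ord]
  period <- c(repeat_len[1] + spacer_len[1], repeat_len[2] + spacer_len[2])
  ok <- diff(pos) >= period[1] & diff(pos) <= period[2] &
    km[-length(km)] == km[-1]
  # periodic runs of >= min_repeats seed positions
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- list()
  for (i in which(r$values & r$lengths >= min_repeats - 1)) {
    seed_pos <- pos[starts[i]:(ends[i] + 1)]
    a <- extend_candidate(chars, seed_pos, k, repeat_len, spacer_len,
                          repeat_id_min, min_repeats)
    if (!is.null(a)) cand[[length(cand) + 1]] <- a
  }
  if (!length(cand)) return(empty_arrays())
  cd <- dplyr::bind_rows(lapply(cand, function(a) {
    tibble(start = a$start, end = a$end, n_repeats = a$n_repeats)
  }))
  cd$idx <- seq_len(nrow(cd))
  cd <- cd[order(-cd$n_repeats, -(cd$end - cd$start), cd$start), ]
  keep <- integer(0)
  for (i in seq_len(nrow(cd))) {
    ov <- any(cd$start[i] <= cd$end[keep] & cd$end[i] >= cd$start[keep])
    if (!length(keep) || !ov) keep <- c(keep, i)
  }
  kept <- cand[cd$idx[sort(keep)]]
  kept <- kept[order(vapply(kept, function(a) a$start, numeric(1)))]
  out <- dplyr::bind_rows(lapply(kept, function(a) {
    tibble(contig = contig_name, start = a$start, end = a$end,
           n_repeats = a$n_repeats, repeat_consensus = a$consensus,
           repeats = list(a$repeats), spacers = list(a$spacers),
           orientation = "undetermined", band = NA_character_,
           criterion = "none", score = NA_real_)
  }))
  class(out) <- c("crispr_arrays", class(out))
  out
}

# grow a seeded candidate into a validated array, or NULL
extend_candidate <- function(chars, seed_pos, k, repeat_len, spacer_len,
                             repeat_id_min, min_repeats) {
  n <- length(chars)
  m <- length(seed_pos)
  cap <- min(repeat_len[2], min(diff(seed_pos)) - spacer_len[1])
  # left extension
  dl <- 0L
  while (k + dl < cap && seed_pos[1] - dl - 1 >= 1) {
    col <- chars[seed_pos - dl - 1]
    if (max(table(col)) / m < 0.7) break
    dl <- dl + 1L
  }
  dr <- 0L
  while (k + dl + dr < cap && seed_pos[m] + k + dr <= n) {
    col <- chars[seed_pos + k + dr]
    if (max(table(col)) / m < 0.7) break
    dr <- dr + 1L
  }
  rs <- seed_pos - dl
  re <- seed_pos + k - 1L + dr
  rlen <- k + dl + dr
  if (rlen < repeat_len[1] || rlen > repeat_len[2]) return(NULL)
  seqs <- vapply(seq_len(m), function(i) {
    paste(chars[rs[i]:re[i]], collapse = "")
  }, character(1))
  cons <- consensus_dna(seqs)
  idf <- function(s) {
    100 * sum(strsplit(s, "")[[1]] == strsplit(cons, "")[[1]]) / nchar(cons)
  }
  idok <- vapply(seqs, idf, numeric(1)) >= repeat_id_min
  # trim low-identity or bad-spacer copies from the run ends
  lo <- 1L; hi <- m
  repeat {
    changed <- FALSE
    if (lo < hi && !idok[lo]) { lo <- lo + 1L; changed <- TRUE }
    if (hi > lo && !idok[hi]) { hi <- hi - 1L; changed <- TRUE }
    if (lo < hi) {
      sp1 <- rs[lo + 1L] - re[lo] - 1L
      if (sp1 < spacer_len[1] || sp1 > spacer_len[2]) {
        lo <- lo + 1L; changed <- TRUE
      }
      spl <- rs[hi] - re[hi - 1L] - 1L
      if (spl < spacer_len[1] || spl > spacer_len[2]) {
        hi <- hi - 1L; changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (hi - lo + 1L < min_repeats) return(NULL)
  rs <- rs[lo:hi]; re <- re[lo:hi]; seqs <- seqs[lo:hi]
  m <- length(rs)
  cons <- consensus_dna(seqs)
  gaps <- rs[-1] - re[-m] - 1L
  if (any(gaps < spacer_len[1] | gaps > spacer_len[2])) return(NULL)
  spac <- tibble(start = re[-m] + 1L, end = rs[-1] - 1L,
                 sequence = vapply(seq_len(m - 1), function(i) {
                   paste(chars[(re[i] + 1L):(rs[i + 1L] - 1L)], collapse = "")
                 }, character(1)))
  list(start = rs[1], end = re[m], n_repeats = m, consensus = cons,
       repeats = tibble(start = rs, end = re, sequence = seqs),
       spacers = spac)
}

consensus_dna <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  paste(apply(mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  }), collapse = "")
}

at_fraction <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  mean(ch %in% c("A", "T"))
}

#' Score the orientation of a detected array
#'
#' Combines two signals into one signed score, positive meaning the leader
#' is on the left (forward orientation): (a) the AT-fraction difference of
#' the 200 nt flanks (the leader flank is AT-richer) and (b) the terminal-
#' repeat degeneracy asymmetry (the trailer-side copy is the most diverged
#' from the consensus). The absolute score maps to confidence bands H
#' (>= 0.12), M (>= 0.05) or L; if either flank is shorter than 200 nt the
#' band is `"NA"` regardless of the score.
#'
#' @param array one row of a [detect_arrays()] tibble.
#' @param contig the contig sequence the array was detected on.
#' @param band_h,band_m band thresholds on the absolute score.
#' @return List with `orientation`, `band` and `score`.
#' @export
score_orientation <- function(array, contig, band_h = 0.12, band_m = 0.05) {
  contig <- toupper(contig)
  n <- nchar(contig)
  if (array$start < 1 || array$end > n) {
    stop("array coordinates outside the contig")
  }
  lf <- array$start - 1L
  rf <- n - array$end
  reps <- array$repeats[[1]]
  cons <- array$repeat_consensus
  mm <- function(s) {
    a <- strsplit(s, "")[[1]]; b <- strsplit(cons, "")[[1]]
    sum(a != b)
  }
  deg <- (mm(reps$sequence[nrow(reps)]) - mm(reps$sequence[1])) / nchar(cons)
  dat <- 0
  if (lf >= 200 && rf >= 200) {
    left <- substr(contig, array$start - 200L, array$start - 1L)
    right <- substr(contig, array$end + 1L, array$end + 200L)
    dat <- at_fraction(left) - at_fraction(right)
  }
  s <- dat + deg
  band <- if (lf < 200 || rf < 200) {
    "NA"
  } else if (abs(s) >= band_h) {
    "H"
  } else if (abs(s) >= band_m) {
    "M"
  } else {
    "L"
  }
  list(orientation = if (s >= 0) "forward" else "reverse",
       band = band, score = s)
}

#' Resolve array orientations with the three-criterion cascade
#'
#' Criterion (i): accept the [score_orientation()] call iff its band is H or
#' M. Criterion (ii), for bands L and NA: an exact match of the repeat
#' consensus to an oriented repeat-database entry fixes the orientation
#' (reverse-complement match means the array is reverse). Criterion (iii):
#' if the consensus has >= 90% identity (either strand) to the repeat of an
#' array already oriented by (i) or (ii), the orientation is inherited.
#' Arrays exhausting the cascade stay `"undetermined"` with criterion
#' `"none"`. A criterion-(i) H/M call is never downgraded.
#'
#' @param arrays a `crispr_arrays` tibble from [detect_arrays()].
#' @param contig the contig sequence.
#' @param db optional oriented repeat database ([repeat_db()] format).
#' @param group optional additional already-oriented arrays (criterion-iii
#'   reference set, e.g. other members of the same clade); defaults to the
#'   arrays oriented by (i)/(ii) within `arrays` itself.
#' @param iii_id_min criterion-(iii) identity threshold in percent.
#' @return `arrays` with `orientation`, `band`, `criterion`, `score` filled.
#' @export
resolve_orientation <- function(arrays, contig, db = NULL, group = NULL,
                                iii_id_min = 90) {
  if (nrow(arrays) == 0) return(arrays)
  for (i in seq_len(nrow(arrays))) {
    sc <- score_orientation(arrays[i, ], contig)
    arrays$band[i] <- sc$band
    arrays$score[i] <- sc$score
    if (sc$band %in% c("H", "M")) {
      arrays$orientation[i] <- sc$orientation
      arrays$criterion[i] <- "i"
    }
  }
  need <- which(arrays$criterion != "i")
  if (length(need) && !is.null(db)) {
    for (i in need) {
      cons <- arrays$repeat_consensus[i]
      if (cons %in% db$sequence) {
        arrays$orientation[i] <- "forward"
        arrays$criterion[i] <- "ii"
      } else if (revcomp(cons) %in% db$sequence) {
        arrays$orientation[i] <- "reverse"
        arrays$criterion[i] <- "ii"
      }
    }
  }
  need <- which(arrays$criterion == "none")
  if (length(need)) {
    refs <- arrays[arrays$criterion %in% c("i", "ii"), , drop = FALSE]
    if (!is.null(group) && nrow(group)) {
      refs <- dplyr::bind_rows(refs, group[group$criterion %in%
                                             c("i", "ii"), , drop = FALSE])
    }
    dpar <- search_params("DNA", lambda = 0.28, K = 0.05)
    for (i in need) {
      cons <- arrays$repeat_consensus[i]
      best <- NULL
      for (j in seq_len(nrow(refs))) {
        fwd <- pairwise_identity(cons, refs$repeat_consensus[j], dpar)
        rev <- pairwise_identity(cons, revcomp(refs$repeat_consensus[j]), dpar)
        if (max(fwd, rev) >= iii_id_min) {
          o <- refs$orientation[j]
          if (rev > fwd) o <- if (o == "forward") "reverse" else "forward"
          best <- o
          break
        }
      }
      if (!is.null(best)) {
        arrays$orientation[i] <- best
        arrays$criterion[i] <- "iii"
      }
    }
  }
  arrays$orientation[arrays$criterion == "none"] <- "undetermined"
  arrays
}
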