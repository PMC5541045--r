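# Synthetic Cas-family consensus profiles and oriented-repeat database.
#
# Real pipelines screen candidate genes against curated profile libraries and
# orient arrays with curated repeat databases. Neither resource is
# redistributable here, so the package ships deterministic synthetic
# stand-ins: one consensus sequence per Cas family, and a table of oriented
# direct repeats. The synthetic-genome generator plants genes and arrays
# derived from these same sequences, so annotation against them behaves like
# profile search against a matched library.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CAS_FAMILY_LENGTHS <- c(
  RT = 420, cas1 = 300, cas2 = 120, cas6 = 240, cas10 = 750,
  csm2 = 140, csm3 = 230, csm4 = 300, csm5 = 350,
  cmr1 = 400, cmr3 = 340, cmr4 = 300, cmr5 = 150, cmr6 = 280
)

CSM_SIGNATURES <- c("csm2", "csm3", "csm4", "csm5")
CMR_SIGNATURES <- c("cmr1", "cmr3", "cmr4", "cmr5", "cmr6")

# evaluate code under a local RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic Cas-family consensus profile set
#'
#' One consensus amino-acid sequence per supported Cas family (RT, cas1,
#' cas2, cas6, cas10, csm2-csm5, cmr1/cmr3-cmr6), generated deterministically
#' (independent of the caller's RNG state). These are synthetic stand-ins for
#' a curated profile library, paired with the genome generator which plants
#' diverged copies of the same sequences.
#'
#' @return Tibble with columns `id` (family), `sequence`, and
#'   `subtype_signature` (`"III-A/D"`, `"III-B/C"`, or `NA`).
#' @export
cas_profiles <- function() {
  seqs <- with_seed(104729L, {
    vapply(names(CAS_FAMILY_LENGTHS), function(fam) {
      paste(sample(AA20, CAS_FAMILY_LENGTHS[[fam]], replace = TRUE),
            collapse = "")
    }, character(1))
  })
  tibble(
    id = names(CAS_FAMILY_LENGTHS),
    sequence = unname(seqs),
    subtype_signature = dplyr::case_when(
      names(CAS_FAMILY_LENGTHS) %in% CSM_SIGNATURES ~ "III-A/D",
      names(CAS_FAMILY_LENGTHS) %in% CMR_SIGNATURES ~ "III-B/C",
      TRUE ~ NA_character_
    )
  )
}

#' Synthetic oriented direct-repeat database
#'
#' A deterministic table of CRISPR direct repeats stored on their leader-to-
#' trailer (forward) strand, emulating a curated repeat-orientation database.
#' Used by the orientation cascade's database criterion and by the genome
#' generator when planting arrays whose orientation should be recoverable
#' from the database.
#'
#' @param n number of repeat entries.
#' @return Tibble with columns `sequence`, `orientation` (always
#'   `"forward"`, i.e. as stored), and `family` id.
#' @export
repeat_db <- function(n = 30) {
  with_seed(28657L, {
    lens <- sample(28:37, n, replace = TRUE)
    seqs <- vapply(lens, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE,
                   prob = c(0.28, 0.22, 0.22, 0.28)), collapse = "")
    }, character(1))
    tibble(sequence = seqs, orientation = "forward",
           family = sprintf("DRF%02d", seq_len(n)))
  })
}

#' @rdname repeat_db
#' @param path output TSV path.
#' @export
write_repeat_db <- function(path, n = 30) {
  readr::write_tsv(repeat_db(n), path)
  invisible(path)
}

#' Read an oriented repeat database from TSV
#'
#' @param path TSV with columns `sequence`, `orientation`, `family`.
#' @export
read_repeat_db <- function(path) {
  db <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sequence", "orientation", "family") %in% names(db)))
  db$sequence <- toupper(db$sequence)
  db
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
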