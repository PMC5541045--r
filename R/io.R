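# FASTA / GFF3 / TSV interfaces.

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping the package's plain
#' character-vector convention (named vectors in and out).
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write gene features and arrays as GFF3
#'
#' Genes become `gene` records (with `locus_tag`, `family` and
#' `translation` attributes); arrays become `repeat_region` records with
#' child `direct_repeat` and `spacer` features. Coordinates are 1-based
#' inclusive.
#'
#' @param features gene feature tibble (`contig`, `start`, `end`, `strand`,
#'   `locus_tag`, optional `family`, `translation`/`protein`).
#' @param path output path.
#' @param arrays optional `crispr_arrays` tibble.
#' @export
write_gff3 <- function(features, path, arrays = NULL) {
  esc <- function(x) gsub("[;=,\t]", "_", x)
  lines <- "##gff-version 3"
  if (!is.null(features) && nrow(features)) {
    prot <- if ("translation" %in% names(features)) {
      features$translation
    } else if ("protein" %in% names(features)) {
      features$protein
    } else {
      rep(NA_character_, nrow(features))
    }
    fam <- if ("family" %in% names(features)) features$family else NA
    attrs <- sprintf("ID=%s%s%s", esc(features$locus_tag),
                     ifelse(is.na(fam), "", paste0(";family=", esc(fam))),
                     ifelse(is.na(prot), "", paste0(";translation=", prot)))
    lines <- c(lines, sprintf("%s\trtcrispr\tgene\t%d\t%d\t.\t%s\t0\t%s",
                              features$contig, features$start, features$end,
                              features$strand, attrs))
  }
  if (!is.null(arrays) && nrow(arrays)) {
    for (i in seq_len(nrow(arrays))) {
      aid <- sprintf("array%03d", i)
      strand <- switch(arrays$orientation[i], forward = "+", reverse = "-",
                       ".")
      lines <- c(lines, sprintf(
        "%s\trtcrispr\trepeat_region\t%d\t%d\t.\t%s\t.\tID=%s;n_repeats=%d;consensus=%s;band=%s;criterion=%s",
        arrays$contig[i], arrays$start[i], arrays$end[i], strand, aid,
        arrays$n_repeats[i], arrays$repeat_consensus[i], arrays$band[i],
        arrays$criterion[i]))
      reps <- arrays$repeats[[i]]
      spac <- arrays$spacers[[i]]
      lines <- c(lines,
        sprintf("%s\trtcrispr\tdirect_repeat\t%d\t%d\t.\t%s\t.\tParent=%s",
                arrays$contig[i], reps$start, reps$end, strand, aid),
        if (nrow(spac)) {
          sprintf("%s\trtcrispr\tspacer\t%d\t%d\t.\t%s\t.\tParent=%s",
                  arrays$contig[i], spac$start, spac$end, strand, aid)
        })
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Reads `gene`/`CDS` records; `translation` attributes (as written by
#' [write_gff3()]) are carried through so annotated proteins need not be
#' re-predicted.
#'
#' @param path GFF3 path.
#' @return Gene feature tibble compatible with [annotate_cas()].
#' @export
read_gff3 <- function(path) {
  ln <- readr::read_lines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 1L) == 9]
  tb <- tibble(
    contig = vapply(f, `[[`, "", 1), type = vapply(f, `[[`, "", 3),
    start = as.integer(vapply(f, `[[`, "", 4)),
    end = as.integer(vapply(f, `[[`, "", 5)),
    strand = vapply(f, `[[`, "", 7),
    attr = vapply(f, `[[`, "", 9))
  tb <- tb[tb$type %in% c("gene", "CDS"), , drop = FALSE]
  getattr <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }
  tb$locus_tag <- getattr(tb$attr, "ID")
  tb$family <- getattr(tb$attr, "family")
  tb$translation <- getattr(tb$attr, "translation")
  tb$attr <- NULL
  tb$type <- NULL
  tb
}

#' Write an arrays summary table
#'
#' One row per array: contig, span, repeat count, consensus, orientation,
#' band, criterion.
#' @param arrays `crispr_arrays` tibble.
#' @param path output TSV.
#' @export
write_array_tsv <- function(arrays, path) {
  readr::write_tsv(
    arrays[, c("contig", "start", "end", "n_repeats", "repeat_consensus",
               "orientation", "band", "criterion")], path)
  invisible(path)
}
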