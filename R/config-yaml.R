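#' Read a genome specification from YAML
#'
#' The YAML mirrors [genome_spec()]: top-level `length_bp`, `gc_content`,
#' `decoy_gene_count`, `contig`, and a `loci` list whose entries mirror
#' [locus_template()] (with a nested `array` block mirroring
#' [array_spec()]).
#'
#' @param path YAML file.
#' @param seed seed override (e.g. from the command line); `NULL` keeps the
#'   file's value.
#' @return A [genome_spec()].
#' @export
genome_spec_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  loci <- lapply(y$loci %||% list(), function(l) {
    ar <- if (is.null(l$array)) {
      array_spec()
    } else {
      do.call(array_spec, l$array)
    }
    locus_template(
      subtype = l$subtype %||% "III-A/D",
      fusion_class = l$fusion_class %||% "RT-Cas1",
      gene_order = l$gene_order,
      array = ar,
      intergenic_gaps_bp = l$intergenic_gaps_bp,
      array_gap_bp = l$array_gap_bp %||% 300,
      clade = l$clade %||% "unassigned")
  })
  genome_spec(length_bp = y$length_bp %||% 100000,
              gc_content = y$gc_content %||% 0.45,
              loci = loci,
              decoy_gene_count = y$decoy_gene_count %||% 5,
              seed = seed %||% y$seed %||% 1,
              contig = y$contig %||% "synth_contig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
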