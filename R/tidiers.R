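# broom-style tidy()/glance() methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a clade partition
#'
#' @param x a [clade_partition()].
#' @param ... ignored.
#' @return One row per leaf: `id`, `clade`, `subclade`.
#' @export
tidy.clade_partition <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.clade_partition
#' @return `glance()`: one row with `n_leaves`, `n_clades`, `n_assigned`,
#'   `mean_support`.
#' @export
glance.clade_partition <- function(x, ...) {
  cl <- attr(x, "clades")
  tibble(n_leaves = nrow(x),
         n_clades = length(setdiff(unique(x$clade), "unassigned")),
         n_assigned = sum(x$clade != "unassigned"),
         mean_support = if (!is.null(cl) && nrow(cl)) {
           mean(cl$support)
         } else {
           NA_real_
         })
}

#' Tidy a congruence result
#'
#' @param x a `partition_congruence`.
#' @param ... ignored.
#' @return Per-label monophyly agreement tibble.
#' @export
tidy.partition_congruence <- function(x, ...) {
  if (is.null(x$per_label)) return(tibble(label = character(),
                                          mono_1 = logical(),
                                          mono_2 = logical(),
                                          agree = logical()))
  x$per_label
}

#' @rdname tidy.partition_congruence
#' @return `glance()`: one row with `ari`, `n_shared`, `n_labels`,
#'   `n_agree`.
#' @export
glance.partition_congruence <- function(x, ...) {
  tibble(ari = x$ari, n_shared = x$n_shared,
         n_labels = if (is.null(x$per_label)) NA_integer_
                    else nrow(x$per_label),
         n_agree = if (is.null(x$per_label)) NA_integer_
                   else sum(x$per_label$agree))
}

#' Tidy an extracted locus
#'
#' @param x a `locus`.
#' @param ... ignored.
#' @return The retained cas-gene table of the locus.
#' @export
tidy.locus <- function(x, ...) {
  x$features[, c("locus_tag", "start", "end", "strand", "family",
                 "evalue", "subtype_specific")]
}

#' @rdname tidy.locus
#' @export
glance.locus <- function(x, ...) {
  tibble(contig = x$region$contig, start = x$region$start,
         end = x$region$end, n_cas_genes = nrow(x$features),
         n_arrays = if (is.null(x$arrays)) 0L else nrow(x$arrays),
         array_near_rt = x$array_near_rt, fusion_class = x$fusion_class,
         subtype = x$subtype, clade = x$clade)
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus> %s:%d-%d  %d cas genes, %d arrays\n",
              x$region$contig, x$region$start, x$region$end,
              nrow(x$features),
              if (is.null(x$arrays)) 0L else nrow(x$arrays)))
  cat("  architecture:", paste(x$features$family, collapse = "-"), "\n")
  cat(sprintf("  fusion=%s subtype=%s clade=%s array_near_rt=%s\n",
              x$fusion_class, x$subtype, x$clade, x$array_near_rt))
  invisible(x)
}
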