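#' Build a binarized reference profile from differential-expression results
#'
#' Converts a differential-expression table (log2 fold changes and p-values,
#' e.g. a knockdown or loss-of-function contrast) into the trinary reference
#' profile the screen matches against: `call = sign(log2fc)` for genes
#' passing both thresholds, 0 otherwise. The default rule is the strict
#' `|log2fc| > fc_threshold` with `pval <= p_threshold`; set
#' `inclusive = TRUE` to use `>=` on the fold change, matching the inclusive
#' boundary used when binarizing Z-scores.
#'
#' @param data data frame with columns `gene`, `log2fc`, `pval`.
#' @param fc_threshold positive log2 fold-change threshold (default 1).
#' @param p_threshold p-value threshold in (0, 1\] (default 0.05).
#' @param inclusive use `|log2fc| >= fc_threshold` instead of strict `>`.
#' @return an object of class `reference_profile`: calls (named integer
#'   vector over the full gene universe), the DEG set, the original `fc` and
#'   `pval` vectors and the thresholds used.
#' @examples
#' ref <- build_reference(data.frame(
#'   gene = c("a", "b", "c"), log2fc = c(1.5, -2, 0.5), pval = c(0.01, 0.2, 0.001)))
#' tidy(ref)
#' @export
build_reference <- function(data, fc_threshold = 1, p_threshold = 0.05,
                            inclusive = FALSE) {
  data <- as_tibble(data)
  need <- c("gene", "log2fc", "pval")
  if (!all(need %in% names(data))) {
    stop_bad_arg("`data` must have columns %s", paste(need, collapse = ", "))
  }
  if (fc_threshold <= 0 || p_threshold <= 0 || p_threshold > 1) {
    stop_bad_arg("thresholds must satisfy fc_threshold > 0 and 0 < p_threshold <= 1")
  }
  gene <- as.character(data$gene)
  if (anyDuplicated(gene)) {
    stop_bad_arg("duplicate genes in reference table: %s",
                 paste(head(unique(gene[duplicated(gene)]), 5), collapse = ", "))
  }
  fc <- as.numeric(data$log2fc)
  pv <- as.numeric(data$pval)
  if (any(is.na(pv) & !is.na(fc))) {
    stop_bad_arg("missing p-value for gene(s) with a fold change: %s",
                 paste(head(gene[is.na(pv) & !is.na(fc)], 5), collapse = ", "))
  }
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) stop_bad_arg("p-values must lie in [0, 1]")
  pass_fc <- if (inclusive) abs(fc) >= fc_threshold else abs(fc) > fc_threshold
  is_deg <- !is.na(fc) & !is.na(pv) & pass_fc & pv <= p_threshold
  calls <- setNames(ifelse(is_deg, sign(fc), 0L), gene)
  storage.mode(calls) <- "integer"
  structure(
    list(calls = calls,
         deg_set = gene[is_deg],
         fc = setNames(fc, gene),
         pval = setNames(pv, gene),
         thresholds = c(fc = fc_threshold, p = p_threshold),
         inclusive = inclusive,
         provenance = "built from differential-expression table"),
    class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("<reference_profile> %d genes, %d DEGs (%d up / %d down)\n",
              length(x$calls), length(x$deg_set),
              sum(x$calls == 1), sum(x$calls == -1)))
  cat(sprintf("  thresholds: |log2fc| %s %g, p <= %g\n",
              if (isTRUE(x$inclusive)) ">=" else ">",
              x$thresholds[["fc"]], x$thresholds[["p"]]))
  if (!is.null(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @rdname build_reference
#' @param x a `reference_profile`.
#' @param ... unused.
#' @method tidy reference_profile
#' @export
tidy.reference_profile <- function(x, ...) {
  tibble(gene = names(x$calls), call = as.integer(x$calls),
         log2fc = unname(x$fc[names(x$calls)]),
         pval = unname(x$pval[names(x$calls)]))
}

#' @rdname build_reference
#' @method glance reference_profile
#' @export
glance.reference_profile <- function(x, ...) {
  tibble(n_genes = length(x$calls), n_deg = length(x$deg_set),
         n_up = sum(x$calls == 1L), n_down = sum(x$calls == -1L),
         fc_threshold = x$thresholds[["fc"]], p_threshold = x$thresholds[["p"]])
}

#' Restrict a reference profile to a gene set
#'
#' Used by the pathway-restricted screen: calls are subset to `genes`, the
#' DEG count |A| becomes the DEGs inside the set, and provenance records the
#' parent and the set name. Restricting to a set disjoint from the DEG set
#' produces an unusable reference and errors.
#'
#' @param reference a [build_reference()] profile.
#' @param genes character vector of gene ids to keep.
#' @param set_name optional label recorded in provenance.
#' @return a restricted `reference_profile`.
#' @export
restrict_reference <- function(reference, genes, set_name = NULL) {
  stopifnot(inherits(reference, "reference_profile"))
  if (!length(genes)) stop_bad_arg("`genes` must be non-empty")
  keep <- intersect(names(reference$calls), genes)
  out <- reference
  out$calls <- reference$calls[keep]
  out$deg_set <- intersect(reference$deg_set, keep)
  out$fc <- reference$fc[keep]
  out$pval <- reference$pval[keep]
  out$provenance <- sprintf("restricted to %s (%d genes, |A| = %d)",
                            set_name %||% "a gene set", length(keep),
                            length(out$deg_set))
  if (!length(out$deg_set)) {
    stop_bad_arg("restriction%s leaves no reference DEGs; pathway unusable",
                 if (is.null(set_name)) "" else paste0(" to '", set_name, "'"))
  }
  out
}

# Intersect the reference universe with the genes measured in the drug
# platform. |A| is recomputed within the intersection; dropped reference DEGs
# are reported because they silently shrink the NCR denominator.
intersect_universe <- function(reference, genes, quiet = FALSE) {
  shared <- intersect(names(reference$calls), genes)
  if (!length(shared)) stop_bad_arg("reference and drug matrix share no genes")
  dropped_deg <- length(reference$deg_set) -
    length(intersect(reference$deg_set, shared))
  if (dropped_deg > 0 && !quiet) {
    inform(sprintf(
      "%d reference DEG(s) are not measured in the drug matrix and were dropped; |A| = %d",
      dropped_deg, length(intersect(reference$deg_set, shared))))
  }
  out <- reference
  out$calls <- reference$calls[shared]
  out$deg_set <- intersect(reference$deg_set, shared)
  out$fc <- reference$fc[shared]
  out$pval <- reference$pval[shared]
  out
}
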