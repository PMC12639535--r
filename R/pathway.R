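#' Pathway-restricted concordance screen
#'
#' Recomputes the concordance screen within each gene set of a collection,
#' yielding a multidimensional concordance profile per signature: the
#' reference is restricted to the set (see [restrict_reference()]), every
#' signature is scored against that restricted reference, and BH correction
#' is applied per pathway across signatures — each pathway is its own
#' multiple-testing family. Pathways whose restriction leaves no reference
#' DEGs are skipped with a message.
#'
#' @inheritParams screen_concordance
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]).
#' @return a `pathway_screen` tibble: the [screen_concordance()] columns plus
#'   `set_name`.
#' @export
pathway_screen <- function(x, reference, gene_sets, z_threshold = 1,
                           n_perm = 1000, seed = 1,
                           alternative = c("greater", "two.sided"),
                           quiet = FALSE) {
  stopifnot(inherits(x, "signature_matrix"))
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop_bad_arg("`n_perm` must be >= 1")
  if (!length(gene_sets) || is.null(names(gene_sets))) {
    stop_bad_arg("`gene_sets` must be a non-empty named list")
  }
  ref0 <- intersect_universe(reference, rownames(x$values), quiet = quiet)
  bin_full <- binarize_zscores(x, z_threshold)
  per_set <- lapply(names(gene_sets), function(nm) {
    ref_s <- tryCatch(restrict_reference(ref0, gene_sets[[nm]], set_name = nm),
                      orthoscreen_error = function(e) {
                        if (!quiet) inform(sprintf("pathway '%s' skipped: %s",
                                                   nm, conditionMessage(e)))
                        NULL
                      })
    if (is.null(ref_s)) return(NULL)
    bin <- bin_full[names(ref_s$calls), , drop = FALSE]
    # master seed, not a per-set substream: a pathway equal to the whole
    # universe then reproduces screen_concordance() bit-for-bit
    out <- screen_concordance_core(bin, ref_s, n_perm, seed, alternative)
    mutate(out, set_name = nm, .before = 1)
  })
  out <- dplyr::bind_rows(per_set)
  if (!nrow(out)) stop_bad_arg("every pathway was skipped; no usable gene set")
  out <- dplyr::left_join(out,
    select(x$meta, "signature_id", "compound_id", "cell_line"),
    by = "signature_id")
  out <- select(out, "set_name", "signature_id", "compound_id", "cell_line",
                dplyr::everything())
  structure(out, class = c("pathway_screen", class(out)),
            context = list(z_threshold = z_threshold, n_perm = n_perm,
                           seed = seed, alternative = alternative,
                           n_sets = length(unique(out$set_name))))
}

#' Concordance rate of a screen table
#'
#' The proportion of signatures called significantly concordant: rows with
#' `ncr > 0` and `q_value <= q_max`, relative to all rows of the table.
#'
#' @param table a screen tibble with `ncr` and `q_value` columns.
#' @param q_max FDR cutoff (default 0.05).
#' @return a scalar in \[0, 1\].
#' @export
concordance_rate <- function(table, q_max = 0.05) {
  if (!nrow(table)) stop_bad_arg("empty table: concordance rate undefined")
  if (!all(c("ncr", "q_value") %in% names(table))) {
    stop_bad_arg("`table` needs `ncr` and `q_value` columns")
  }
  mean(table$ncr > 0 & table$q_value <= q_max)
}

#' Agreement between two enrichment-labelling methods
#'
#' Cross-tabulates per-compound enriched/not-enriched labels from two methods
#' (e.g. the full-profile and the pathway-restricted screens) and reports the
#' sample odds ratio with a two-sided Fisher exact p-value. A zero cell
#' triggers the Haldane-Anscombe 0.5 correction (flagged in the output).
#'
#' @param labels_full,labels_pathway named logical vectors over the same ids,
#'   or two-column data frames with `compound_id` and `enriched`.
#' @return a `method_agreement` object: the 2x2 `table` (rows = method 1,
#'   cols = method 2), `odds_ratio`, `p_value`, `corrected` flag.
#' @examples
#' a <- c(x = TRUE, y = TRUE, z = FALSE)
#' b <- c(x = TRUE, y = FALSE, z = FALSE)
#' compare_methods(a, b)
#' @export
compare_methods <- function(labels_full, labels_pathway) {
  as_named <- function(l) {
    if (is.data.frame(l)) setNames(as.logical(l$enriched), l$compound_id) else l
  }
  f <- as_named(labels_full); p <- as_named(labels_pathway)
  if (is.null(names(f)) || is.null(names(p)) || !setequal(names(f), names(p)) ||
      length(f) != length(p)) {
    stop_bad_arg("the two label vectors must cover identical id sets")
  }
  p <- p[names(f)]
  tab <- matrix(c(sum(f & p), sum(f & !p), sum(!f & p), sum(!f & !p)),
                nrow = 2, byrow = TRUE,
                dimnames = list(method1 = c("enriched", "not"),
                                method2 = c("enriched", "not")))
  corrected <- any(tab == 0)
  tc <- if (corrected) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  pv <- fisher.test(tab, alternative = "two.sided")$p.value
  structure(list(table = tab, odds_ratio = or, p_value = pv,
                 corrected = corrected),
            class = "method_agreement")
}

#' @export
print.method_agreement <- function(x, ...) {
  cat("<method_agreement>\n")
  print(x$table)
  cat(sprintf("odds ratio = %.4g%s, Fisher p = %.3g\n", x$odds_ratio,
              if (x$corrected) " (Haldane-Anscombe corrected)" else "",
              x$p_value))
  invisible(x)
}

#' @rdname compare_methods
#' @param x a `method_agreement` object.
#' @param ... unused.
#' @method tidy method_agreement
#' @export
tidy.method_agreement <- function(x, ...) {
  as_tibble(as.data.frame(x$table, responseName = "n"))
}

#' @rdname compare_methods
#' @method glance method_agreement
#' @export
glance.method_agreement <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_value = x$p_value,
         n = sum(x$table), corrected = x$corrected)
}
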