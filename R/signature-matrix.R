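#' Drug-signature matrix with per-signature metadata
#'
#' Container for LINCS L1000-style Level 5 data: a genes x signatures matrix
#' of replicate-averaged, normalized Z-scores plus one metadata record per
#' signature (compound, cell line, dose, time, transcriptional activity
#' score). The metadata tibble always carries the columns `signature_id`,
#' `compound_id`, `cell_line`, `dose`, `time`, `tas`; fields absent from a
#' file are set to `NA`.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   signatures in columns (colnames = signature ids).
#' @param meta data frame with one row per signature. Must contain
#'   `signature_id` matching `colnames(values)`; other standard columns are
#'   added as `NA` when missing.
#' @return an object of class `signature_matrix`: a list with elements
#'   `values` (the matrix) and `meta` (a tibble).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("G", 1:3), c("s1", "s2")))
#' sm <- signature_matrix(m, data.frame(signature_id = c("s1", "s2"),
#'                                      compound_id = c("a", "b")))
#' sm
#' @export
signature_matrix <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_bad_arg("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_bad_arg("`values` must have gene rownames and signature colnames")
  }
  meta <- as_tibble(meta)
  if (!"signature_id" %in% names(meta)) {
    stop_bad_arg("`meta` must contain a `signature_id` column")
  }
  meta$signature_id <- as.character(meta$signature_id)
  for (col in c("compound_id", "cell_line", "dose", "time")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  if (!"tas" %in% names(meta)) meta$tas <- NA_real_
  meta$tas <- as.numeric(meta$tas)
  meta <- meta[, c("signature_id", "compound_id", "cell_line", "dose", "time", "tas",
                   setdiff(names(meta), c("signature_id", "compound_id", "cell_line",
                                          "dose", "time", "tas")))]
  x <- structure(list(values = values, meta = meta), class = "signature_matrix")
  validate_signature_matrix(x)
}

validate_signature_matrix <- function(x) {
  g <- rownames(x$values)
  s <- colnames(x$values)
  dup_g <- unique(g[duplicated(g)])
  if (length(dup_g)) {
    stop_bad_arg("duplicate gene ids: %s", paste(head(dup_g, 5), collapse = ", "))
  }
  dup_s <- unique(s[duplicated(s)])
  if (length(dup_s)) {
    stop_bad_arg("duplicate signature ids: %s", paste(head(dup_s, 5), collapse = ", "))
  }
  if (nrow(x$meta) != ncol(x$values)) {
    stop_bad_arg("metadata has %d rows but matrix has %d signatures",
                 nrow(x$meta), ncol(x$values))
  }
  if (!identical(x$meta$signature_id, s)) {
    if (!setequal(x$meta$signature_id, s)) {
      stop_bad_arg("metadata signature_ids do not match matrix column names")
    }
    x$meta <- x$meta[match(s, x$meta$signature_id), ]
  }
  tas <- x$meta$tas
  if (any(!is.na(tas) & (tas < 0 | tas > 1))) {
    stop_bad_arg("TAS values must lie in [0, 1]")
  }
  x
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d genes x %d signatures\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  compounds: %d | cell lines: %s\n",
              dplyr::n_distinct(x$meta$compound_id),
              paste(unique(stats::na.omit(x$meta$cell_line)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.signature_matrix <- function(x) dim(x$values)

#' @rdname signature_matrix
#' @param x a `signature_matrix`.
#' @param ... unused.
#' @method tidy signature_matrix
#' @export
tidy.signature_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "signature_id", values_to = "z") |>
    dplyr::left_join(x$meta, by = "signature_id")
}

#' Filter signatures on treatment condition and signal quality
#'
#' Subsets the signature (column) axis to the experimental condition of the
#' screen: exact dose and time matches after unit canonicalization (see
#' [canonical_unit()]) and a minimum transcriptional activity score
#' (TAS >= `tas_min`, boundary kept). Signatures with missing TAS are dropped
#' when a TAS filter is requested (with a warning) and retained otherwise.
#' The gene axis is untouched.
#'
#' @param x a [signature_matrix()].
#' @param dose,time optional condition to match exactly (e.g. `"10 uM"`,
#'   `"24 h"`); `NULL` skips that criterion.
#' @param tas_min optional minimum TAS in \[0, 1\]; `NULL` skips the filter.
#' @param quiet suppress the per-criterion retention messages.
#' @return the filtered `signature_matrix`.
#' @examples
#' sm <- simulate_drug_matrix(simulate_reference(screen_config(seed = 1)),
#'                            screen_config(n_compounds = 10, seed = 1))$matrix
#' filter_signatures(sm, dose = "10 uM", time = "24 h", tas_min = 0.4)
#' @export
filter_signatures <- function(x, dose = NULL, time = NULL, tas_min = NULL,
                              quiet = FALSE) {
  stopifnot(inherits(x, "signature_matrix"))
  keep <- rep(TRUE, ncol(x$values))
  note <- function(what, kept) {
    if (!quiet) inform(sprintf("filter_signatures: %s kept %d / %d signatures",
                               what, sum(kept), length(kept)))
  }
  if (!is.null(dose)) {
    if (all(is.na(x$meta$dose))) stop_bad_arg("dose filter requested but `dose` metadata is absent")
    keep <- keep & !is.na(x$meta$dose) &
      canonical_unit(x$meta$dose) == canonical_unit(dose)
    note(sprintf("dose == %s", dose), keep)
  }
  if (!is.null(time)) {
    if (all(is.na(x$meta$time))) stop_bad_arg("time filter requested but `time` metadata is absent")
    keep <- keep & !is.na(x$meta$time) &
      canonical_unit(x$meta$time) == canonical_unit(time)
    note(sprintf("time == %s", time), keep)
  }
  if (!is.null(tas_min)) {
    if (anyNA(x$meta$tas) && !all(is.na(x$meta$tas))) {
      warn("signatures with missing TAS are excluded by the TAS filter")
    }
    if (all(is.na(x$meta$tas))) {
      warn("TAS filter requested but all TAS are missing; excluding everything")
    }
    keep <- keep & !is.na(x$meta$tas) & x$meta$tas >= tas_min
    note(sprintf("TAS >= %g", tas_min), keep)
  }
  if (!any(keep)) {
    stop_bad_arg("no signatures satisfy the requested filters; screen cannot proceed")
  }
  signature_matrix(x$values[, keep, drop = FALSE], x$meta[keep, ])
}

#' Binarize Z-score signatures into trinary regulation calls
#'
#' Standardizes continuous signatures into per-gene regulation calls:
#' Z >= `z_threshold` maps to +1 (up), Z <= -`z_threshold` to -1 (down),
#' anything in the dead zone to 0 (non-significant). The boundary is
#' inclusive. This is the cross-platform step that puts drug Z-scores and a
#' fold-change reference on the same \{-1, 0, +1\} alphabet.
#'
#' @param x a [signature_matrix()] or a numeric matrix / named numeric vector.
#' @param z_threshold positive call threshold (default 1).
#' @return an integer matrix (genes x signatures) of values in \{-1, 0, +1\};
#'   for a vector input, a named integer vector.
#' @examples
#' binarize_zscores(c(g1 = 1.0, g2 = -1.0, g3 = 0.99, g4 = -0.5))
#' @export
binarize_zscores <- function(x, z_threshold = 1) {
  if (!is.numeric(z_threshold) || length(z_threshold) != 1 || z_threshold <= 0) {
    stop_bad_arg("`z_threshold` must be a single positive number")
  }
  v <- if (inherits(x, "signature_matrix")) x$values else x
  if (anyNA(v) || any(!is.finite(v))) {
    idx <- which(!is.finite(v), arr.ind = is.matrix(v))
    if (is.matrix(v)) {
      stop_bad_arg("non-finite Z-score at gene %s, signature %s",
                   rownames(v)[idx[1, 1]] %||% idx[1, 1],
                   colnames(v)[idx[1, 2]] %||% idx[1, 2])
    }
    stop_bad_arg("non-finite Z-score at position %d", idx[1])
  }
  out <- (v >= z_threshold) - (v <= -z_threshold)
  storage.mode(out) <- "integer"
  out
}
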