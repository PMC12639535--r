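# Text I/O for the formats the screen consumes: GCT 1.3 (genes x signatures
# with embedded column metadata), a TSV dialect with sidecar metadata, the
# reference-profile TSV (gene, log2fc, pval) and GMT gene-set collections.
# The CMAP missing marker "-666" and blank/"NA" cells all read as NA.

.gct_na <- function(x) {
  x[x %in% c("", "NA", "na", "-666", "-666.0")] <- NA
  x
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) "NA" else sprintf("%.17g", v), character(1))
  unname(out)
}

#' Read a GCT 1.3 text file into a signature matrix
#'
#' Parses the GCT 1.3 layout: a version line (`#1.3`), a dimension line
#' (rows, columns, row-metadata fields, column-metadata fields), a header
#' row, one row per column-metadata field, then one row per gene. Column
#' metadata fields named `compound_id`, `cell_line`, `dose`, `time`, `tas`
#' populate the standard metadata slots; absent fields are `NA`. GCT 1.2
#' files (no metadata) are accepted.
#'
#' @param path path to a GCT text file.
#' @return a [signature_matrix()].
#' @seealso [write_gct()] for the companion writer; the pair round-trips
#'   bit-exactly.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop_bad_arg("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop_bad_arg("GCT file too short: %s", path)
  version <- trimws(lines[1])
  if (!version %in% c("#1.3", "#1.2")) {
    stop_bad_arg("line 1: unsupported GCT version marker '%s'", version)
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\t| +")[[1]]))
  if (version == "#1.2") dims <- c(dims, 0L, 0L)
  if (length(dims) != 4 || anyNA(dims) || any(dims < 0)) {
    stop_bad_arg("line 2: malformed dimension line '%s' (expected 4 non-negative integers)",
                 lines[2])
  }
  nr <- dims[1]; nc <- dims[2]; nrmeta <- dims[3]; ncmeta <- dims[4]
  expect_lines <- 3 + ncmeta + nr
  if (length(lines) < expect_lines) {
    stop_bad_arg("GCT declares %d genes and %d column-metadata rows but has %d lines",
                 nr, ncmeta, length(lines))
  }
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != 1 + nrmeta + nc) {
    stop_bad_arg("line 3: header has %d fields, expected %d", length(header),
                 1 + nrmeta + nc)
  }
  sig_ids <- header[(2 + nrmeta):length(header)]

  meta <- tibble(signature_id = sig_ids)
  if (ncmeta > 0) {
    for (i in seq_len(ncmeta)) {
      f <- strsplit(lines[3 + i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 1 + nrmeta + nc) {
        stop_bad_arg("line %d: column-metadata row has %d fields, expected %d",
                     3 + i, length(f), 1 + nrmeta + nc)
      }
      meta[[f[1]]] <- .gct_na(f[(2 + nrmeta):length(f)])
    }
  }
  if ("tas" %in% names(meta)) meta$tas <- as.numeric(meta$tas)

  body <- strsplit(lines[(4 + ncmeta):(3 + ncmeta + nr)], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != 1 + nrmeta + nc)) {
    bad <- which(nf != 1 + nrmeta + nc)[1]
    stop_bad_arg("line %d: data row has %d fields, expected %d",
                 3 + ncmeta + bad, nf[bad], 1 + nrmeta + nc)
  }
  gene_ids <- vapply(body, `[`, character(1), 1)
  vals <- matrix(as.numeric(.gct_na(unlist(
    lapply(body, `[`, (2 + nrmeta):(1 + nrmeta + nc))
  ))), nrow = nr, ncol = nc, byrow = TRUE,
  dimnames = list(gene_ids, sig_ids))
  signature_matrix(vals, meta)
}

#' Write a signature matrix as GCT 1.3 text
#'
#' @param x a [signature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path) {
  stopifnot(inherits(x, "signature_matrix"))
  meta_cols <- setdiff(names(x$meta), "signature_id")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(sprintf("%d\t%d\t%d\t%d", nrow(x$values), ncol(x$values),
                     0L, length(meta_cols)), con)
  writeLines(paste(c("id", colnames(x$values)), collapse = "\t"), con)
  for (mc in meta_cols) {
    v <- x$meta[[mc]]
    v <- if (is.numeric(v)) .fmt_num(v) else ifelse(is.na(v), "NA", as.character(v))
    writeLines(paste(c(mc, v), collapse = "\t"), con)
  }
  for (i in seq_len(nrow(x$values))) {
    writeLines(paste(c(rownames(x$values)[i], .fmt_num(x$values[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write the TSV dialect (matrix + sidecar metadata)
#'
#' The TSV dialect stores the genes x signatures matrix with the gene id in
#' the first column (`gene`) and one column per signature, plus a sidecar
#' metadata TSV keyed by `signature_id`.
#'
#' @param path matrix TSV path.
#' @param meta_path sidecar metadata TSV path; `NULL` leaves metadata empty.
#' @return a [signature_matrix()].
#' @export
read_signature_tsv <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop_bad_arg("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop_bad_arg("matrix TSV needs a gene column plus >= 1 signature")
  genes <- df[[1]]
  vals <- as.matrix(vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(df)[-1]))
  rownames(vals) <- genes
  meta <- if (is.null(meta_path)) {
    tibble(signature_id = colnames(vals))
  } else {
    as_tibble(utils::read.delim(meta_path, check.names = FALSE))
  }
  signature_matrix(vals, meta)
}

#' @rdname read_signature_tsv
#' @param x a [signature_matrix()].
#' @export
write_signature_tsv <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "signature_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a reference differential-expression profile TSV
#'
#' Expects columns `gene`, `log2fc`, `pval` and feeds them to
#' [build_reference()].
#'
#' @param path TSV path.
#' @inheritParams build_reference
#' @return a [build_reference()] reference profile.
#' @export
read_reference <- function(path, fc_threshold = 1, p_threshold = 0.05,
                           inclusive = FALSE) {
  df <- as_tibble(utils::read.delim(path, check.names = FALSE))
  need <- c("gene", "log2fc", "pval")
  if (!all(need %in% names(df))) {
    stop_bad_arg("reference TSV must have columns %s", paste(need, collapse = ", "))
  }
  build_reference(df, fc_threshold = fc_threshold, p_threshold = p_threshold,
                  inclusive = inclusive)
}

#' @rdname read_reference
#' @param x a reference profile.
#' @export
write_reference <- function(x, path) {
  stopifnot(inherits(x, "reference_profile"))
  utils::write.table(
    data.frame(gene = names(x$fc), log2fc = x$fc, pval = x$pval),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, `name TAB description TAB gene1 TAB ...`,
#' at least one gene per set. Set order is preserved; duplicate genes within
#' a set are dropped.
#'
#' @param path GMT path.
#' @return a named list of character vectors of gene ids, with the per-set
#'   descriptions in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_bad_arg("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_bad_arg("GMT line %d has %d fields; need name, description and >= 1 gene",
                 which(nf < 3)[1], nf[which(nf < 3)[1]])
  }
  nm <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop_bad_arg("duplicate gene-set names: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(fields, `[`, character(1), 2), nm)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors (a gene-set collection).
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_bad_arg("gene sets must be named")
  }
  desc <- attr(sets, "description") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    if (!length(sets[[nm]])) stop_bad_arg("gene set '%s' is empty", nm)
    d <- if (nm %in% names(desc) && !is.na(desc[[nm]])) desc[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
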