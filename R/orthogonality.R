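#' Aggregate binarized replicate profiles by per-gene mode
#'
#' Collapses replicate trinary profiles of one compound into a consensus
#' profile: per gene, the most frequent value among \{-1, 0, +1\}; when no
#' value is strictly most frequent the gene is called 0 (no majority
#' direction = non-significant).
#'
#' @param x trinary integer matrix, genes x replicates (>= 1 column), or a
#'   list of named trinary vectors over the same gene universe.
#' @return named integer vector of consensus calls with the replicate count
#'   in attribute `"n_replicates"`.
#' @examples
#' aggregate_profile(cbind(r1 = c(g = 1L), r2 = c(g = 1L), r3 = c(g = 0L)))
#' @export
aggregate_profile <- function(x) {
  if (is.list(x) && !is.matrix(x)) {
    if (!length(x)) stop_bad_arg("need at least one replicate")
    genes <- names(x[[1]])
    if (any(!vapply(x, function(v) identical(names(v), genes), logical(1)))) {
      stop_bad_arg("replicates must share one gene universe (same names, same order)")
    }
    x <- do.call(cbind, x)
  }
  if (!is.matrix(x) || ncol(x) < 1) stop_bad_arg("need at least one replicate")
  check_trinary(x, "replicate calls")
  npos <- rowSums(x == 1L)
  nneg <- rowSums(x == -1L)
  nzero <- ncol(x) - npos - nneg
  out <- integer(nrow(x))
  out[npos > nneg & npos > nzero] <- 1L
  out[nneg > npos & nneg > nzero] <- -1L
  names(out) <- rownames(x)
  attr(out, "n_replicates") <- ncol(x)
  out
}

#' Aggregate a binarized signature matrix per compound
#'
#' Applies [aggregate_profile()] within each compound (optionally within one
#' cell line at a fixed treatment condition, the setting in which aggregate
#' signatures are meaningful).
#'
#' @param x a [signature_matrix()] of Z-scores (binarized internally) or a
#'   trinary integer matrix.
#' @param meta metadata tibble with `signature_id` and `compound_id`;
#'   defaults to `x$meta` for a signature matrix.
#' @param cell_line optional cell line to restrict to.
#' @param z_threshold binarization threshold for Z-score input.
#' @return integer matrix genes x compounds of consensus calls, with
#'   per-compound replicate counts in attribute `"n_replicates"`.
#' @export
aggregate_by_compound <- function(x, meta = NULL, cell_line = NULL,
                                  z_threshold = 1) {
  if (inherits(x, "signature_matrix")) {
    meta <- meta %||% x$meta
    x <- binarize_zscores(x, z_threshold)
  }
  if (is.null(meta)) stop_bad_arg("`meta` is required for a plain matrix")
  if (!is.null(cell_line)) {
    meta <- meta[!is.na(meta$cell_line) & meta$cell_line == cell_line, ]
    if (!nrow(meta)) stop_bad_arg("no signatures for cell line '%s'", cell_line)
  }
  meta <- meta[meta$signature_id %in% colnames(x), ]
  groups <- split(meta$signature_id, meta$compound_id)
  out <- vapply(groups, function(sids) {
    aggregate_profile(x[, sids, drop = FALSE])
  }, integer(nrow(x)))
  rownames(out) <- rownames(x)
  attr(out, "n_replicates") <- lengths(groups)
  out
}

#' Orthogonality score
#'
#' `OS = sqrt(NCR_target^2 + (1 - NCR_drug)^2)`: large when a compound
#' matches the reference target profile (|NCR_target| high) while differing
#' from an anchor drug's profile (NCR_drug low). Ranges from 0 (no target
#' concordance, identical to the anchor) to sqrt(5).
#'
#' @param ncr_target,ncr_drug concordance ratios in \[-1, 1\] (vectorized).
#' @return numeric vector of scores.
#' @examples
#' orthogonality_score(0.6, 0.2)  # sqrt(0.36 + 0.64) = 1
#' @export
orthogonality_score <- function(ncr_target, ncr_drug) {
  if (any(abs(ncr_target) > 1 + 1e-12) || any(abs(ncr_drug) > 1 + 1e-12)) {
    stop_bad_arg("NCR inputs must lie in [-1, 1]")
  }
  sqrt(ncr_target^2 + (1 - ncr_drug)^2)
}

# NCR of `calls` against an aggregate anchor profile: the anchor's nonzero
# calls play the role of the reference DEG set A.
ncr_vs_anchor <- function(anchor, calls) {
  nz <- anchor != 0L
  if (!any(nz)) stop_bad_arg("anchor profile has no nonzero calls")
  a <- anchor[nz]
  b <- calls[match(names(a), names(calls))]
  b[is.na(b)] <- 0L
  unname(ncr_core(a, b, sum(nz))[["ncr"]])
}

#' Orthogonality screen of candidate compounds against anchor drugs
#'
#' For every (anchor, candidate) pair: `ncr_target` is the candidate's NCR
#' against the reference profile, `ncr_drug` its NCR against the anchor's
#' aggregate profile (the anchor's nonzero calls acting as the reference
#' set), and `os` the orthogonality score. A candidate identical to the
#' anchor collapses to `os = |ncr_target|`; an anchor equals itself is
#' excluded.
#'
#' @param reference a [build_reference()] profile.
#' @param anchors trinary integer matrix genes x anchor compounds (e.g. from
#'   [aggregate_by_compound()]), or a single named vector.
#' @param candidates trinary integer matrix genes x candidate compounds.
#' @return tibble: `anchor_id`, `candidate_id`, `ncr_target`, `ncr_drug`,
#'   `os`.
#' @export
orthogonality_screen <- function(reference, anchors, candidates) {
  stopifnot(inherits(reference, "reference_profile"))
  if (!is.matrix(anchors)) anchors <- cbind(anchor = anchors)
  if (!is.matrix(candidates)) stop_bad_arg("`candidates` must be a genes x compounds matrix")
  check_trinary(anchors, "anchor calls"); check_trinary(candidates, "candidate calls")
  ref <- intersect_universe(reference, rownames(candidates), quiet = TRUE)
  a_ref <- ref$calls[ref$deg_set]
  tgt <- vapply(colnames(candidates), function(cid) {
    b <- candidates[match(names(a_ref), rownames(candidates)), cid]
    b[is.na(b)] <- 0L
    unname(ncr_core(a_ref, b, length(a_ref))[["ncr"]])
  }, numeric(1))
  grid <- tidyr::expand_grid(anchor_id = colnames(anchors),
                             candidate_id = colnames(candidates))
  grid <- filter(grid, .data$anchor_id != .data$candidate_id)
  grid$ncr_target <- unname(tgt[grid$candidate_id])
  grid$ncr_drug <- purrr::map2_dbl(grid$anchor_id, grid$candidate_id,
    function(aid, cid) {
      anc <- setNames(anchors[, aid], rownames(anchors))
      ncr_vs_anchor(anc, setNames(candidates[, cid], rownames(candidates)))
    })
  mutate(grid, os = orthogonality_score(.data$ncr_target, .data$ncr_drug))
}

#' Binary orthogonality-enrichment profile matrix
#'
#' Converts an [orthogonality_screen()] table into the anchors x candidates
#' binary matrix used for combination nomination: entry (a, c) is 1 when
#' candidate c is itself target-enriched AND its orthogonality score against
#' anchor a exceeds that anchor's `os_quantile` quantile across candidates
#' (strictly; default top quartile). The criterion is recorded in
#' attributes.
#'
#' @param os_results an [orthogonality_screen()] tibble.
#' @param enriched_ids character vector of target-enriched compound ids
#'   (e.g. hits from [compound_enrichment()]).
#' @param os_quantile quantile of the per-anchor OS distribution a candidate
#'   must exceed (default 0.75).
#' @return binary integer matrix, anchors in rows, candidates in columns.
#' @export
orthogonality_enrichment_profile <- function(os_results, enriched_ids,
                                             os_quantile = 0.75) {
  need <- c("anchor_id", "candidate_id", "os")
  if (!all(need %in% names(os_results))) {
    stop_bad_arg("`os_results` needs columns %s", paste(need, collapse = ", "))
  }
  if (os_quantile < 0 || os_quantile >= 1) stop_bad_arg("`os_quantile` must be in [0, 1)")
  res <- os_results |>
    group_by(.data$anchor_id) |>
    mutate(os_cut = quantile(.data$os, os_quantile, names = FALSE)) |>
    ungroup() |>
    mutate(hit = as.integer(.data$candidate_id %in% enriched_ids &
                              .data$os > .data$os_cut))
  wide <- tidyr::pivot_wider(select(res, "anchor_id", "candidate_id", "hit"),
                             names_from = "candidate_id", values_from = "hit",
                             values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$anchor_id
  storage.mode(m) <- "integer"
  structure(m, os_quantile = os_quantile,
            criterion = sprintf(
              "candidate target-enriched AND os > per-anchor %g quantile",
              os_quantile))
}
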