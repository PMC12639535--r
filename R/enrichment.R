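#' Rank signatures by similarity to the reference
#'
#' Deterministic ranking for the compound-level enrichment step: descending
#' NCR, ties broken by ascending p-value, then lexicographic signature id.
#'
#' @param table a screen tibble with `signature_id`, `ncr`, `p_value`.
#' @return character vector of signature ids, best first.
#' @export
rank_by_score <- function(table) {
  if (!nrow(table)) stop_bad_arg("cannot rank an empty table")
  ord <- order(-table$ncr, table$p_value, table$signature_id, method = "radix")
  table$signature_id[ord]
}

#' Unweighted KS-style enrichment score
#'
#' Walks down a ranked list of signature ids, adding `1/|members|` at member
#' positions and subtracting `1/(N - |members|)` elsewhere. The enrichment
#' score is the running sum at its maximum absolute excursion, signed: +1
#' when all members sit at the very top, negative when they cluster at the
#' bottom; when the maximal positive and negative excursions tie in
#' magnitude the positive one is reported (deterministic). The running sum
#' returns to 0 after the last position.
#'
#' @param ranked character vector of ranked ids (no duplicates).
#' @param members subset of `ranked`: the replicate signatures of one
#'   compound.
#' @return the enrichment score, a scalar in \[-1, 1\].
#' @examples
#' enrichment_score(letters[1:4], c("a", "c"))  # running sum .5 0 .5 0 -> 0.5
#' @export
enrichment_score <- function(ranked, members) {
  if (!length(members)) stop_bad_arg("`members` must be non-empty")
  if (!all(members %in% ranked)) stop_bad_arg("`members` must all appear in `ranked`")
  N <- length(ranked); m <- length(unique(members))
  if (m == N) stop_bad_arg("members cover the whole ranked list; ES undefined (no misses)")
  es_from_positions(sort(match(unique(members), ranked)), m, N)
}

# ES from sorted member positions. The running sum is piecewise linear and
# its extremes can only occur just after a member step (upper candidates) or
# just before one (lower candidates), so only 2m points are inspected.
es_from_positions <- function(pos, m, N) {
  j <- seq_len(m)
  miss <- 1 / (N - m)
  after <- j / m - (pos - j) * miss        # value right after member j
  before <- (j - 1) / m - (pos - 1 - (j - 1)) * miss  # value right before member j
  hi <- max(after, 0)
  lo <- min(before, 0)
  # tie (to rounding) between the extremes -> report the positive one
  if (hi >= -lo - 1e-9) hi else lo
}

#' Full running sum of the enrichment walk
#'
#' @inheritParams enrichment_score
#' @return tibble with `rank`, `id`, `is_member`, `running_sum`.
#' @export
enrichment_running_sum <- function(ranked, members) {
  N <- length(ranked); m <- length(unique(members))
  if (m == 0 || m == N) stop_bad_arg("need 0 < |members| < N")
  hit <- ranked %in% members
  steps <- ifelse(hit, 1 / m, -1 / (N - m))
  tibble(rank = seq_len(N), id = ranked, is_member = hit,
         running_sum = cumsum(steps))
}

#' Compound-level enrichment over a concordance screen
#'
#' Collapses signature-level concordance to per-compound calls: signatures
#' are ranked with [rank_by_score()], each compound's replicates define the
#' member set of an unweighted KS enrichment score, and significance comes
#' from a positional permutation null — `n_perm` uniform reassignments of
#' the member positions over the ranked list, preserving the replicate
#' count. The null is shared by all compounds with the same replicate count
#' (the score distribution depends only on it) and each count's null stream
#' is seeded from `seed`, so results are invariant to compound order.
#'
#' `nes` divides the observed ES by the mean |null ES| of matching sign
#' (`nes_method = "mean_sign"`, the GSEA convention) or standardizes against
#' the full null (`"zscore"`). The p-value is the add-one tail fraction of
#' null scores at least as extreme in the observed direction; BH correction
#' runs across compounds.
#'
#' @param table a [screen_concordance()] tibble (needs `signature_id`,
#'   `compound_id`, `ncr`, `p_value`).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param nes_method `"mean_sign"` (default) or `"zscore"`.
#' @return a `compound_enrichment` tibble: `compound_id`, `n_signatures`,
#'   `es`, `nes`, `p_value`, `q_value`.
#' @export
compound_enrichment <- function(table, n_perm = 1000, seed = 1,
                                nes_method = c("mean_sign", "zscore")) {
  nes_method <- match.arg(nes_method)
  if (n_perm < 1) stop_bad_arg("`n_perm` must be >= 1")
  if (anyDuplicated(table$signature_id)) {
    stop_bad_arg("signature_ids must be unique within a screen table")
  }
  ranked <- rank_by_score(table)
  N <- length(ranked)
  comp <- split(table$signature_id, table$compound_id)
  comp <- comp[lengths(comp) < N]   # a compound owning every rank has no ES
  sizes <- sort(unique(lengths(comp)))
  nulls <- lapply(setNames(sizes, sizes), function(m) {
    with_substream(substream_seed(seed, paste0("esnull:", m)),
                   vapply(seq_len(n_perm), function(i) {
                     es_from_positions(sort(sample.int(N, m)), m, N)
                   }, numeric(1)))
  })
  rows <- purrr::imap(comp, function(sigs, cid) {
    m <- length(sigs)
    es <- es_from_positions(sort(match(sigs, ranked)), m, N)
    null <- nulls[[as.character(m)]]
    if (es >= 0) {
      p <- (1 + sum(null >= es - 1e-12)) / (1 + n_perm)
      denom <- mean(abs(null[null >= 0]))
    } else {
      p <- (1 + sum(null <= es + 1e-12)) / (1 + n_perm)
      denom <- mean(abs(null[null < 0]))
    }
    nes <- switch(nes_method,
      mean_sign = {
        if (!is.finite(denom) || denom == 0) denom <- mean(abs(null))
        es / denom
      },
      zscore = (es - mean(null)) / stats::sd(null))
    tibble(compound_id = cid, n_signatures = m, es = es, nes = nes, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out <- arrange(mutate(out, q_value = bh_adjust(.data$p_value)),
                 desc(.data$nes))
  structure(out, class = c("compound_enrichment", class(out)),
            context = list(n_perm = n_perm, seed = seed,
                           nes_method = nes_method, n_ranked = N))
}

#' Enrichment labels from a pathway screen
#'
#' Runs [compound_enrichment()] on each pathway's score ranking and combines
#' the per-pathway calls into one label per compound: enriched in `"any"`
#' pathway (default, most inclusive), a `"majority"`, or `"all"` of them. A
#' pathway-level call requires `nes > 0` and `q_value <= fdr_max`.
#'
#' @param pathway_table a [pathway_screen()] tibble.
#' @param n_perm,seed,nes_method passed to [compound_enrichment()].
#' @param fdr_max FDR cutoff for a per-pathway call (default 0.05).
#' @param combine aggregation rule over pathways.
#' @return tibble: `compound_id`, `n_sets_enriched`, `n_sets`, `enriched`,
#'   with the per-pathway enrichment tables in the `"per_set"` attribute.
#' @export
pathway_enrichment_labels <- function(pathway_table, n_perm = 1000, seed = 1,
                                      nes_method = c("mean_sign", "zscore"),
                                      fdr_max = 0.05,
                                      combine = c("any", "majority", "all")) {
  combine <- match.arg(combine)
  nes_method <- match.arg(nes_method)
  per_set <- lapply(split(as_tibble(pathway_table), pathway_table$set_name),
                    function(tab) {
                      compound_enrichment(tab, n_perm = n_perm,
                                          seed = substream_seed(seed, tab$set_name[1]),
                                          nes_method = nes_method)
                    })
  calls <- dplyr::bind_rows(per_set, .id = "set_name") |>
    mutate(hit = .data$nes > 0 & .data$q_value <= fdr_max) |>
    group_by(.data$compound_id) |>
    summarise(n_sets_enriched = sum(.data$hit), n_sets_scored = dplyr::n(),
              .groups = "drop")
  n_sets <- length(per_set)
  calls$enriched <- switch(combine,
    any = calls$n_sets_enriched >= 1,
    majority = calls$n_sets_enriched > n_sets / 2,
    all = calls$n_sets_enriched == n_sets)
  calls$n_sets <- n_sets
  structure(calls, per_set = per_set, combine = combine)
}

#' Recurrent hits across cell lines
#'
#' A compound counts as enriched in a cell line only when it passes
#' `nes > 0` (or `enriched` label) with `q_value <= fdr_max` under BOTH the
#' full-profile and the pathway method for that line; it is a recurrent hit
#' when that happens in at least `min_lines` lines.
#'
#' @param results tibble with columns `cell_line`, `method` (`"full"` or
#'   `"pathway"`), `compound_id` and `enriched` (logical). For the full
#'   method, build `enriched` from a [compound_enrichment()] table as
#'   `nes > 0 & q_value <= fdr_max`; for the pathway method use
#'   [pathway_enrichment_labels()].
#' @param min_lines minimum number of cell lines (default 3).
#' @return tibble: `compound_id`, `cell_lines_enriched` (list column),
#'   `n_enriched`, `passes`, sorted by decreasing `n_enriched`.
#' @export
recurrent_hits <- function(results, min_lines = 3) {
  need <- c("cell_line", "method", "compound_id", "enriched")
  if (!all(need %in% names(results))) {
    stop_bad_arg("`results` needs columns %s", paste(need, collapse = ", "))
  }
  if (min_lines < 1) stop_bad_arg("`min_lines` must be >= 1")
  bad <- setdiff(unique(results$method), c("full", "pathway"))
  if (length(bad)) stop_bad_arg("unknown method label(s): %s", paste(bad, collapse = ", "))
  per_line <- results |>
    group_by(.data$cell_line, .data$compound_id) |>
    summarise(both = sum(.data$enriched & .data$method == "full") > 0 &
                sum(.data$enriched & .data$method == "pathway") > 0,
              .groups = "drop")
  out <- per_line |>
    filter(.data$both) |>
    group_by(.data$compound_id) |>
    summarise(cell_lines_enriched = list(sort(unique(.data$cell_line))),
              .groups = "drop") |>
    mutate(n_enriched = lengths(.data$cell_lines_enriched),
           passes = .data$n_enriched >= min_lines) |>
    arrange(desc(.data$n_enriched), .data$compound_id)
  # compounds never enriched under both methods still appear, with 0 lines
  missing <- setdiff(unique(results$compound_id), out$compound_id)
  if (length(missing)) {
    out <- dplyr::bind_rows(out, tibble(
      compound_id = sort(missing),
      cell_lines_enriched = rep(list(character(0)), length(missing)),
      n_enriched = 0L, passes = FALSE))
  }
  out
}

#' @rdname compound_enrichment
#' @param object a `compound_enrichment` tibble.
#' @param ... unused.
#' @method glance compound_enrichment
#' @export
glance.compound_enrichment <- function(object, ...) {
  ctx <- attr(object, "context")
  tibble(n_compounds = nrow(object), n_ranked = ctx$n_ranked,
         n_perm = ctx$n_perm, nes_method = ctx$nes_method,
         n_enriched = sum(object$nes > 0 & object$q_value <= 0.05))
}

#' Plot the enrichment running sum for one compound
#'
#' @param table a screen tibble.
#' @param compound_id compound whose replicates to trace.
#' @return a ggplot.
#' @export
plot_running_sum <- function(table, compound_id) {
  ranked <- rank_by_score(table)
  members <- table$signature_id[table$compound_id == compound_id]
  if (!length(members)) stop_bad_arg("compound '%s' not in table", compound_id)
  rs <- enrichment_running_sum(ranked, members)
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$rank, y = .data$running_sum)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_rug(data = rs[rs$is_member, ], sides = "b") +
    ggplot2::labs(title = sprintf("Enrichment walk: %s", compound_id),
                  x = "signature rank (most concordant first)",
                  y = "running sum") +
    ggplot2::theme_minimal()
}
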