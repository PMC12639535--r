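#' Configuration for a synthetic screen
#'
#' Collects the generator's knobs with defaults emulating the shape of an
#' L1000-style screen: 978 landmark genes, a 728-gene reference DEG set
#' (half up), 200 compounds per cell line with 3 replicate signatures each,
#' planted antagonists that copy half of the reference DEG calls
#' concordantly and 10% discordantly, and a 30% background nonzero-call rate
#' shared by null compounds so the permutation null is exercised at matched
#' sparsity. Planted calls receive Z-score magnitudes uniform in
#' \[1.2, 3\] — beyond the binarization boundary with margin — so additive
#' noise with `noise_sd <= 0.1` cannot flip a planted call.
#'
#' @param n_genes gene-universe size.
#' @param n_deg number of reference DEGs.
#' @param frac_up fraction of DEGs upregulated.
#' @param n_compounds compounds per cell line.
#' @param replicates_per_compound replicate signatures per compound.
#' @param n_cell_lines cell lines for multi-line bundles.
#' @param n_antagonists planted concordant compounds per screen.
#' @param antagonist_overlap fraction of reference DEG calls each antagonist
#'   replicate copies concordantly.
#' @param discordant_rate fraction copied with flipped sign.
#' @param background_nonzero_rate nonzero-call rate for unplanted genes.
#' @param noise_sd additive Gaussian Z-score noise.
#' @param low_tas_fraction fraction of null-compound signatures given a
#'   decoy TAS < 0.4 (dropped by the standard quality filter).
#' @param n_line_decoys compounds planted as antagonists in exactly one cell
#'   line (recurrence-filter decoys).
#' @param fc_threshold,p_threshold reference DEG thresholds.
#' @param seed integer seed; all generation is reproducible from
#'   (config, seed).
#' @return a `screen_config` list.
#' @export
screen_config <- function(n_genes = 978, n_deg = 728, frac_up = 0.5,
                          n_compounds = 200, replicates_per_compound = 3,
                          n_cell_lines = 10, n_antagonists = 5,
                          antagonist_overlap = 0.5, discordant_rate = 0.1,
                          background_nonzero_rate = 0.3, noise_sd = 0.05,
                          low_tas_fraction = 0.1, n_line_decoys = 5,
                          fc_threshold = 1, p_threshold = 0.05, seed = 1) {
  cfg <- list(n_genes = n_genes, n_deg = n_deg, frac_up = frac_up,
              n_compounds = n_compounds,
              replicates_per_compound = replicates_per_compound,
              n_cell_lines = n_cell_lines, n_antagonists = n_antagonists,
              antagonist_overlap = antagonist_overlap,
              discordant_rate = discordant_rate,
              background_nonzero_rate = background_nonzero_rate,
              noise_sd = noise_sd, low_tas_fraction = low_tas_fraction,
              n_line_decoys = n_line_decoys, fc_threshold = fc_threshold,
              p_threshold = p_threshold, seed = as.integer(seed))
  if (cfg$n_deg > cfg$n_genes) stop_bad_arg("n_deg must not exceed n_genes")
  props <- c(cfg$frac_up, cfg$antagonist_overlap, cfg$discordant_rate,
             cfg$background_nonzero_rate, cfg$low_tas_fraction)
  if (any(props < 0 | props > 1)) stop_bad_arg("proportions must lie in [0, 1]")
  if (cfg$antagonist_overlap + cfg$discordant_rate > 1) {
    stop_bad_arg("antagonist_overlap + discordant_rate must not exceed 1")
  }
  if (cfg$n_antagonists + cfg$n_line_decoys > cfg$n_compounds) {
    stop_bad_arg("planted compounds exceed n_compounds")
  }
  structure(cfg, class = "screen_config")
}

# planted magnitudes: beyond the |z| >= 1 boundary with margin
.planted_mag <- function(n) runif(n, 1.2, 3)

#' Simulate a reference differential-expression profile
#'
#' Draws exactly `n_deg` DEGs (`round(frac_up * n_deg)` up) with fold
#' changes beyond the threshold (|log2fc| in \[1.2, 3\]) and p-values below
#' `p_threshold`; non-DEGs fall inside the dead zone with uniform p-values.
#'
#' @param config a [screen_config()].
#' @return a [build_reference()] profile; the planted up/down gene sets are
#'   in the `"truth"` attribute.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  with_substream(substream_seed(config$seed, "reference"), {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    n_up <- round(config$frac_up * config$n_deg)
    deg <- sample(genes, config$n_deg)
    up <- deg[seq_len(n_up)]
    down <- setdiff(deg, up)
    fc <- setNames(runif(config$n_genes, -0.8, 0.8) * config$fc_threshold, genes)
    fc[up] <- .planted_mag(length(up)) * config$fc_threshold
    fc[down] <- -.planted_mag(length(down)) * config$fc_threshold
    pv <- setNames(runif(config$n_genes), genes)
    pv[deg] <- runif(config$n_deg, 0, config$p_threshold * 0.9)
    ref <- build_reference(
      tibble(gene = genes, log2fc = unname(fc), pval = unname(pv)),
      fc_threshold = config$fc_threshold, p_threshold = config$p_threshold)
    attr(ref, "truth") <- list(up = up, down = down)
    ref
  })
}

# one signature's Z-scores: planted concordant/discordant DEG copies plus
# trinary background independent of the reference, then additive noise
.simulate_signature_z <- function(ref_calls, deg, overlap, discordant,
                                  bg_rate, noise_sd) {
  n <- length(ref_calls)
  z <- runif(n, -0.85, 0.85)
  n_conc <- round(overlap * length(deg))
  n_disc <- round(discordant * length(deg))
  picked <- sample(deg, n_conc + n_disc)
  conc <- picked[seq_len(n_conc)]
  disc <- setdiff(picked, conc)
  z[match(conc, names(ref_calls))] <- ref_calls[conc] * .planted_mag(n_conc)
  z[match(disc, names(ref_calls))] <- -ref_calls[disc] * .planted_mag(n_disc)
  bg <- setdiff(names(ref_calls), picked)
  on <- bg[runif(length(bg)) < bg_rate]
  z[match(on, names(ref_calls))] <- sample(c(-1, 1), length(on), TRUE) *
    .planted_mag(length(on))
  z + rnorm(n, 0, noise_sd)
}

#' Simulate a drug-signature matrix with planted antagonists
#'
#' Generates one cell line's screen: `n_compounds` compounds with
#' `replicates_per_compound` signatures each at the fixed condition
#' (10 uM, 24 h). The first `n_antagonists` compounds are planted
#' antagonists: each replicate copies `antagonist_overlap` of the reference
#' DEG calls concordantly and `discordant_rate` discordantly into Z-scores
#' beyond the binarization boundary (expected NCR ~ overlap - discordant).
#' Null compounds make calls independent of the reference at the same
#' marginal nonzero rate. Antagonist signatures draw TAS in \[0.4, 1\];
#' a `low_tas_fraction` of null signatures get a decoy TAS < 0.4.
#'
#' @param reference a [simulate_reference()] profile (or any reference over
#'   the same gene universe size).
#' @param config a [screen_config()].
#' @param cell_line cell-line label for the metadata.
#' @return list with `matrix` (a [signature_matrix()]) and `truth` (tibble:
#'   one row per signature with every planted property).
#' @export
simulate_drug_matrix <- function(reference, config, cell_line = "CL1") {
  stopifnot(inherits(config, "screen_config"),
            inherits(reference, "reference_profile"))
  with_substream(substream_seed(config$seed, paste0("matrix:", cell_line)), {
    genes <- names(reference$calls)
    deg <- reference$deg_set
    n_sig <- config$n_compounds * config$replicates_per_compound
    compounds <- sprintf("cmpd%03d", seq_len(config$n_compounds))
    is_antag <- seq_len(config$n_compounds) <= config$n_antagonists
    meta <- tibble(
      compound_id = rep(compounds, each = config$replicates_per_compound),
      replicate = rep(seq_len(config$replicates_per_compound),
                      times = config$n_compounds))
    meta$signature_id <- sprintf("%s_%s_r%d", meta$compound_id, cell_line,
                                 meta$replicate)
    antag_sig <- rep(is_antag, each = config$replicates_per_compound)
    # null compounds match the planted marginal nonzero rate on the DEG axis
    null_deg_rate <- config$antagonist_overlap + config$discordant_rate
    vals <- vapply(seq_len(n_sig), function(i) {
      if (antag_sig[i]) {
        .simulate_signature_z(reference$calls, deg, config$antagonist_overlap,
                              config$discordant_rate,
                              config$background_nonzero_rate, config$noise_sd)
      } else {
        z <- runif(length(genes), -0.85, 0.85)
        p_on <- ifelse(genes %in% deg, null_deg_rate,
                       config$background_nonzero_rate)
        on <- runif(length(genes)) < p_on
        z[on] <- sample(c(-1, 1), sum(on), TRUE) * .planted_mag(sum(on))
        z + rnorm(length(genes), 0, config$noise_sd)
      }
    }, numeric(length(genes)))
    dimnames(vals) <- list(genes, meta$signature_id)
    tas <- runif(n_sig, 0.4, 1)
    decoy <- !antag_sig & runif(n_sig) < config$low_tas_fraction
    tas[decoy] <- runif(sum(decoy), 0.05, 0.39)
    meta <- mutate(meta,
                   cell_line = cell_line, dose = "10 uM", time = "24 h",
                   tas = tas)
    truth <- tibble(signature_id = meta$signature_id,
                    compound_id = meta$compound_id, cell_line = cell_line,
                    is_antagonist = antag_sig,
                    planted_overlap = ifelse(antag_sig, config$antagonist_overlap, 0),
                    planted_discordant = ifelse(antag_sig, config$discordant_rate, 0),
                    tas = tas, retained_after_tas = tas >= 0.4)
    list(matrix = signature_matrix(
           vals, select(meta, "signature_id", "compound_id", "cell_line",
                        "dose", "time", "tas")),
         truth = truth)
  })
}

#' Simulate a complementary (orthogonal) compound pair
#'
#' Plants two compounds whose concordant gene sets are disjoint blocks of
#' the reference DEG set: each is concordant with the reference only on its
#' own block, so both have positive target concordance while their mutual
#' drug concordance is ~0.
#'
#' @param reference a reference profile.
#' @param blocks list of two disjoint character vectors of reference DEGs;
#'   `NULL` splits the DEG set into halves.
#' @param ids names for the two compounds.
#' @return list with `profiles` (trinary matrix genes x 2) and `truth`.
#' @export
simulate_orthogonal_pair <- function(reference, blocks = NULL,
                                     ids = c("orthoA", "orthoB")) {
  stopifnot(inherits(reference, "reference_profile"))
  deg <- reference$deg_set
  if (is.null(blocks)) {
    half <- seq_len(floor(length(deg) / 2))
    blocks <- list(deg[half], deg[-half])
  }
  if (length(blocks) != 2) stop_bad_arg("`blocks` must be a list of two gene sets")
  if (length(intersect(blocks[[1]], blocks[[2]]))) {
    stop_bad_arg("the two blocks must be disjoint")
  }
  if (!all(unlist(blocks) %in% deg)) {
    stop_bad_arg("blocks must be subsets of the reference DEG set")
  }
  profiles <- matrix(0L, nrow = length(reference$calls), ncol = 2,
                     dimnames = list(names(reference$calls), ids))
  profiles[blocks[[1]], 1] <- reference$calls[blocks[[1]]]
  profiles[blocks[[2]], 2] <- reference$calls[blocks[[2]]]
  list(profiles = profiles,
       truth = tibble(compound_id = ids,
                      block_size = lengths(blocks),
                      expected_ncr_target = lengths(blocks) / length(deg)))
}

#' Simulate a multi-cell-line screen bundle
#'
#' One [simulate_drug_matrix()] screen per cell line with a shared compound
#' namespace. Pan-line antagonists (`n_antagonists`) are planted in every
#' line; `n_line_decoys` extra compounds are planted as antagonists in
#' exactly one line each (they must fail any recurrence filter with
#' `min_lines > 1`).
#'
#' @param config a [screen_config()].
#' @return list with `reference`, `screens` (named list of per-line
#'   [simulate_drug_matrix()] results) and `truth` (compound-level tibble:
#'   `compound_id`, `planted_in` list column, `is_pan_antagonist`,
#'   `is_line_decoy`).
#' @export
simulate_multi_cell_line <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  reference <- simulate_reference(config)
  lines <- sprintf("CL%d", seq_len(config$n_cell_lines))
  decoy_ids <- sprintf("cmpd%03d",
                       config$n_antagonists + seq_len(config$n_line_decoys))
  decoy_line <- with_substream(
    substream_seed(config$seed, "decoy_lines"),
    setNames(sample(lines, config$n_line_decoys, replace = TRUE), decoy_ids))
  screens <- lapply(setNames(lines, lines), function(cl) {
    sim <- simulate_drug_matrix(reference, config, cell_line = cl)
    # promote this line's decoys: replace their signatures with antagonist draws
    promote <- names(decoy_line)[decoy_line == cl]
    if (length(promote)) {
      sel <- sim$matrix$meta$compound_id %in% promote
      sids <- sim$matrix$meta$signature_id[sel]
      newv <- with_substream(
        substream_seed(config$seed, paste0("decoy:", cl)),
        vapply(sids, function(s) {
          .simulate_signature_z(reference$calls, reference$deg_set,
                                config$antagonist_overlap,
                                config$discordant_rate,
                                config$background_nonzero_rate, config$noise_sd)
        }, numeric(length(reference$calls))))
      sim$matrix$values[, sids] <- newv
      sim$matrix$meta$tas[sel] <- pmax(sim$matrix$meta$tas[sel], 0.4)
      sim$truth$is_antagonist[sel] <- TRUE
      sim$truth$planted_overlap[sel] <- config$antagonist_overlap
      sim$truth$planted_discordant[sel] <- config$discordant_rate
      sim$truth$tas[sel] <- sim$matrix$meta$tas[sel]
      sim$truth$retained_after_tas[sel] <- TRUE
    }
    sim
  })
  pan <- sprintf("cmpd%03d", seq_len(config$n_antagonists))
  all_cmpds <- sprintf("cmpd%03d", seq_len(config$n_compounds))
  truth <- tibble(
    compound_id = all_cmpds,
    is_pan_antagonist = all_cmpds %in% pan,
    is_line_decoy = all_cmpds %in% decoy_ids,
    planted_in = lapply(all_cmpds, function(cid) {
      if (cid %in% pan) lines
      else if (cid %in% decoy_ids) unname(decoy_line[cid])
      else character(0)
    }))
  list(reference = reference, screens = screens, truth = truth)
}
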