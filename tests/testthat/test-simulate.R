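test_that("reference generation is exact in counts and reproducible", {
  cfg <- screen_config(n_genes = 978, n_deg = 728, frac_up = 0.5, seed = 12)
  ref <- simulate_reference(cfg)
  expect_length(ref$calls, 978)
  expect_length(ref$deg_set, 728)
  expect_equal(sum(ref$calls == 1L), 364)
  expect_identical(simulate_reference(cfg)$calls, ref$calls)

  truth <- attr(ref, "truth")
  expect_setequal(c(truth$up, truth$down), ref$deg_set)
  # every DEG really passes the thresholds; non-DEGs fail them
  expect_true(all(abs(ref$fc[ref$deg_set]) > 1 & ref$pval[ref$deg_set] <= 0.05))
  non <- setdiff(names(ref$calls), ref$deg_set)
  expect_true(all(abs(ref$fc[non]) < 1))
})

test_that("config validation rejects impossible settings", {
  expect_error(screen_config(n_genes = 10, n_deg = 11), "exceed")
  expect_error(screen_config(antagonist_overlap = 0.8, discordant_rate = 0.3),
               "exceed 1")
  expect_error(screen_config(frac_up = 1.2), "proportions")
  expect_error(screen_config(n_compounds = 5, n_antagonists = 4, n_line_decoys = 3),
               "planted")
})

test_that("a perfect-copy antagonist reaches NCR 1 and planting hits its expectation", {
  cfg <- screen_config(n_genes = 300, n_deg = 100, n_compounds = 5,
                       n_antagonists = 1, antagonist_overlap = 1,
                       discordant_rate = 0, noise_sd = 0,
                       background_nonzero_rate = 0.2, low_tas_fraction = 0,
                       n_line_decoys = 0, replicates_per_compound = 2, seed = 13)
  ref <- simulate_reference(cfg)
  sim <- simulate_drug_matrix(ref, cfg)
  bin <- binarize_zscores(sim$matrix)
  for (sid in sim$truth$signature_id[sim$truth$is_antagonist]) {
    expect_equal(ncr(ref, bin[, sid])$ncr, 1)
  }

  cfg2 <- screen_config(n_genes = 978, n_deg = 728, n_compounds = 12,
                        n_antagonists = 4, antagonist_overlap = 0.5,
                        discordant_rate = 0.1, low_tas_fraction = 0,
                        n_line_decoys = 0, seed = 14)
  ref2 <- simulate_reference(cfg2)
  sim2 <- simulate_drug_matrix(ref2, cfg2)
  bin2 <- binarize_zscores(sim2$matrix)
  ant <- sim2$truth$signature_id[sim2$truth$is_antagonist]
  ncrs <- vapply(ant, function(s) ncr(ref2, bin2[, s])$ncr, numeric(1))
  expect_equal(mean(ncrs), 0.4, tolerance = 0.05)
})

test_that("low-TAS decoys are exactly the signatures dropped by the quality filter", {
  cfg <- screen_config(n_genes = 100, n_deg = 30, n_compounds = 30,
                       n_antagonists = 2, low_tas_fraction = 0.25, seed = 15)
  ref <- simulate_reference(cfg)
  sim <- simulate_drug_matrix(ref, cfg)
  filt <- filter_signatures(sim$matrix, tas_min = 0.4, quiet = TRUE)
  expect_setequal(colnames(filt$values),
                  sim$truth$signature_id[sim$truth$retained_after_tas])
  expect_gt(sum(!sim$truth$retained_after_tas), 0)
})

test_that("orthogonal pair planting yields complementary half-profiles", {
  cfg <- screen_config(n_genes = 978, n_deg = 728, seed = 16)
  ref <- simulate_reference(cfg)
  pair <- simulate_orthogonal_pair(ref)
  A <- pair$profiles[, 1]; B <- pair$profiles[, 2]
  expect_equal(ncr(ref, A)$ncr, 364 / 728)
  expect_equal(ncr(ref, B)$ncr, 0.5)
  expect_length(intersect(names(A[A != 0]), names(B[B != 0])), 0)

  res <- orthogonality_screen(ref, pair$profiles[, 1, drop = FALSE], pair$profiles)
  expect_equal(res$ncr_drug, 0)
  # negative control: identical blocks are maximally non-orthogonal
  clone <- cbind(orthoA = A, clone = A)
  colnames(clone) <- c("orthoA", "clone")
  res_clone <- orthogonality_screen(ref, clone[, 1, drop = FALSE], clone)
  expect_equal(res_clone$ncr_drug, 1)
  expect_gt(res$os, res_clone$os)

  expect_error(simulate_orthogonal_pair(ref, blocks = list(ref$deg_set[1:3],
                                                           ref$deg_set[3:5])),
               "disjoint")
})

test_that("multi-cell-line bundles plant pan-line hits and one-line decoys", {
  cfg <- screen_config(n_genes = 120, n_deg = 40, n_compounds = 20,
                       n_antagonists = 3, n_line_decoys = 4, n_cell_lines = 5,
                       seed = 17)
  bundle <- simulate_multi_cell_line(cfg)
  expect_length(bundle$screens, 5)
  tr <- bundle$truth
  expect_equal(sum(tr$is_pan_antagonist), 3)
  expect_equal(sum(tr$is_line_decoy), 4)
  expect_true(all(lengths(tr$planted_in[tr$is_pan_antagonist]) == 5))
  expect_true(all(lengths(tr$planted_in[tr$is_line_decoy]) == 1))
  # per-line truth agrees with the bundle-level plan
  for (cl in names(bundle$screens)) {
    line_truth <- bundle$screens[[cl]]$truth
    planted <- unique(line_truth$compound_id[line_truth$is_antagonist])
    expected <- tr$compound_id[vapply(tr$planted_in, function(p) cl %in% p,
                                      logical(1))]
    expect_setequal(planted, expected)
  }
  # reproducibility of the whole bundle
  bundle2 <- simulate_multi_cell_line(cfg)
  expect_identical(bundle$screens$CL3$matrix$values,
                   bundle2$screens$CL3$matrix$values)
})

test_that("screen sensitivity rises with the planted overlap", {
  med_ncr <- vapply(c(0.2, 0.5, 0.8), function(ov) {
    cfg <- screen_config(n_genes = 200, n_deg = 80, n_compounds = 10,
                         n_antagonists = 3, antagonist_overlap = ov,
                         discordant_rate = 0.05, low_tas_fraction = 0,
                         n_line_decoys = 0, seed = 18)
    ref <- simulate_reference(cfg)
    sim <- simulate_drug_matrix(ref, cfg)
    bin <- binarize_zscores(sim$matrix)
    ant <- sim$truth$signature_id[sim$truth$is_antagonist]
    median(vapply(ant, function(s) ncr(ref, bin[, s])$ncr, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_ncr) > 0))
})
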