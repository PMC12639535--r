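test_that("per-gene mode aggregation follows the tie-to-zero rule", {
  expect_identical(unname(aggregate_profile(cbind(c(g = 1L), c(g = 1L), c(g = 0L)))[1]), 1L)
  expect_identical(unname(aggregate_profile(cbind(c(g = 1L), c(g = -1L)))[1]), 0L)
  one <- stats::setNames(c(1L, -1L, 0L), paste0("g", 1:3))
  expect_identical(as.integer(aggregate_profile(cbind(one))), as.integer(one))

  # exhaustive check against the frequency-table oracle, all multisets <= 4
  for (n_rep in 1:4) {
    combos <- expand.grid(rep(list(c(-1L, 0L, 1L)), n_rep))
    for (i in seq_len(nrow(combos))) {
      reps <- matrix(as.integer(combos[i, ]), nrow = 1,
                     dimnames = list("g", NULL))
      expect_identical(unname(aggregate_profile(reps)[1]),
                       mode_oracle(as.integer(combos[i, ])))
    }
  }
})

test_that("aggregation is replicate-order invariant and idempotent", {
  set.seed(51)
  genes <- paste0("g", 1:50)
  reps <- sapply(1:5, function(i) random_trinary(genes, 0.4))
  rownames(reps) <- genes
  agg <- aggregate_profile(reps)
  expect_identical(as.integer(aggregate_profile(reps[, sample(5)])),
                   as.integer(agg))
  expect_identical(as.integer(aggregate_profile(cbind(agg, agg, agg))),
                   as.integer(agg))
  expect_error(aggregate_profile(list()), "at least one")
})

test_that("orthogonality score matches its closed forms and bounds", {
  expect_equal(orthogonality_score(0, 1), 0)
  expect_equal(orthogonality_score(0.6, 0.2), 1.0)
  expect_equal(orthogonality_score(1, -1), sqrt(5))
  expect_error(orthogonality_score(1.5, 0), "\\[-1, 1\\]")

  grid <- seq(-1, 1, length.out = 101)
  os <- outer(grid, grid, orthogonality_score)
  expect_true(all(os >= 0 & os <= sqrt(5) + 1e-12))
  # monotone increasing in |ncr_target| (rows), decreasing in ncr_drug (cols)
  pos <- grid >= 0
  expect_true(all(diff(os[pos, 1]) >= -1e-12))
  expect_true(all(apply(os, 1, function(r) all(diff(r) <= 1e-12))))
})

test_that("orthogonality screen collapses correctly for identical and disjoint profiles", {
  genes <- paste0("g", 1:40)
  calls <- stats::setNames(rep(c(1L, -1L, 0L), c(10, 10, 20)), genes)
  ref <- make_reference(calls)
  anchor <- calls
  identical_cand <- calls
  disjoint <- stats::setNames(rep(0L, 40), genes)
  disjoint[21:30] <- 1L   # support disjoint from the anchor's
  cands <- cbind(same = identical_cand, disj = disjoint)
  res <- orthogonality_screen(ref, cbind(anchor = anchor), cands)

  same <- res[res$candidate_id == "same", ]
  expect_equal(same$ncr_drug, 1)
  expect_equal(same$os, abs(same$ncr_target))

  dis <- res[res$candidate_id == "disj", ]
  expect_equal(dis$ncr_drug, 0)
  expect_equal(dis$os, sqrt(dis$ncr_target^2 + 1))
})

test_that("anchoring on the reference itself makes the two NCRs coincide", {
  set.seed(52)
  genes <- paste0("g", 1:60)
  calls <- random_trinary(genes, 0.5)
  calls[1] <- 1L  # ensure a nonempty DEG set
  ref <- make_reference(calls)
  cands <- sapply(1:6, function(i) random_trinary(genes, 0.4))
  colnames(cands) <- paste0("c", 1:6)
  rownames(cands) <- genes
  res <- orthogonality_screen(ref, cbind(refprof = calls), cands)
  expect_equal(res$ncr_drug, res$ncr_target)
})

test_that("a planted orthogonal pair outranks non-orthogonal candidates", {
  cfg <- screen_config(n_genes = 200, n_deg = 80, seed = 6)
  ref <- simulate_reference(cfg)
  pair <- simulate_orthogonal_pair(ref)
  set.seed(53)
  noise <- sapply(1:10, function(i) random_trinary(names(ref$calls), 0.2))
  colnames(noise) <- paste0("rand", 1:10)
  rownames(noise) <- names(ref$calls)
  cands <- cbind(pair$profiles, noise)
  res <- orthogonality_screen(ref, pair$profiles[, 1, drop = FALSE], cands)
  best <- res$candidate_id[which.max(res$os)]
  expect_equal(best, "orthoB")
  # each planted compound recovers about half the reference
  expect_equal(res$ncr_target[res$candidate_id == "orthoB"],
               pair$truth$expected_ncr_target[2], tolerance = 0.05)
})

test_that("orthogonality-enrichment profiles implement the binary criterion", {
  genes <- paste0("g", 1:30)
  calls <- stats::setNames(rep(c(1L, 0L), c(10, 20)), genes)
  ref <- make_reference(calls)
  # candidates all identical to both anchors: no orthogonality anywhere
  same <- calls
  cands <- cbind(a1 = same, a2 = same, c1 = same, c2 = same)
  res <- orthogonality_screen(ref, cands[, c("a1", "a2")], cands)
  prof <- orthogonality_enrichment_profile(res, enriched_ids = colnames(cands))
  expect_true(all(prof == 0L))
  expect_equal(dim(prof), c(2L, 4L))

  # one candidate orthogonal to one anchor only
  other <- stats::setNames(rep(0L, 30), genes)
  other[6:10] <- 1L
  half <- stats::setNames(rep(0L, 30), genes)
  half[1:5] <- 1L
  cands2 <- cbind(a1 = half, a2 = same, ortho = other, c1 = same, c2 = same)
  res2 <- orthogonality_screen(ref, cands2[, c("a1", "a2")], cands2)
  prof2 <- orthogonality_enrichment_profile(res2, enriched_ids = colnames(cands2))
  expect_equal(sum(prof2), 1L)
  expect_equal(prof2["a1", "ortho"], 1L)
})
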