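test_that("ranking is by descending score with deterministic tie-breaks", {
  tab <- tibble::tibble(signature_id = c("s1", "s2", "s3"),
                        ncr = c(0.3, 0.9, 0.1), p_value = c(0.2, 0.01, 0.5))
  expect_identical(rank_by_score(tab), c("s2", "s1", "s3"))

  tie <- tibble::tibble(signature_id = c("b", "a"),
                        ncr = c(0.5, 0.5), p_value = c(0.01, 0.2))
  expect_identical(rank_by_score(tie), c("b", "a"))
  tie2 <- tibble::tibble(signature_id = c("b", "a"),
                         ncr = 0.5, p_value = 0.1)
  expect_identical(rank_by_score(tie2), c("a", "b"))

  set.seed(41)
  big <- tibble::tibble(signature_id = sprintf("s%04d", 1:1000),
                        ncr = runif(1000), p_value = runif(1000))
  ord <- big[order(big$ncr, decreasing = TRUE), ]  # scores unique a.s.
  expect_identical(rank_by_score(big), ord$signature_id)
})

test_that("enrichment score matches hand-enumerated running sums", {
  # all members at the top
  expect_equal(enrichment_score(paste0("s", 1:10), paste0("s", 1:3)), 1)
  # members at the very bottom of N=10: running sum dives to -1
  expect_equal(enrichment_score(paste0("s", 1:10), c("s9", "s10")), -1)
  # N=4, members at positions 1 and 3: running sum .5, 0, .5, 0
  expect_equal(enrichment_score(letters[1:4], c("a", "c")), 0.5)
  expect_error(enrichment_score(letters[1:3], letters[1:3]), "no misses")
  expect_error(enrichment_score(letters[1:3], "z"), "appear in")
})

test_that("enrichment score equals the brute-force walk for every subset, N <= 8", {
  for (N in 3:8) {
    ranked <- paste0("x", seq_len(N))
    for (mask in 1:(2^N - 2)) {
      members <- ranked[as.logical(bitwAnd(mask, 2^(seq_len(N) - 1)))]
      if (!length(members) || length(members) == N) next
      expect_equal(enrichment_score(ranked, members),
                   es_oracle(ranked, members))
      expect_lt(abs(es_terminal_oracle(ranked, members)), 1e-12)
    }
  }
})

test_that("running sum terminates at zero and reflects under list reversal", {
  set.seed(42)
  for (i in 1:25) {
    N <- sample(5:40, 1)
    ranked <- paste0("s", seq_len(N))
    members <- sample(ranked, sample(N - 1, 1))
    rs <- enrichment_running_sum(ranked, members)
    expect_lt(abs(rs$running_sum[N]), 1e-12)
    # implementation agrees with the explicit walk on the mirrored list too
    expect_equal(enrichment_score(ranked, members), es_oracle(ranked, members))
    expect_equal(enrichment_score(rev(ranked), members),
                 es_oracle(rev(ranked), members))
  }
})

test_that("compound enrichment flags planted top compounds and is deterministic", {
  set.seed(43)
  n_cmpd <- 40
  tab <- tibble::tibble(
    signature_id = sprintf("sig%03d", 1:(3 * n_cmpd)),
    compound_id = rep(sprintf("c%02d", 1:n_cmpd), each = 3),
    ncr = runif(3 * n_cmpd, -0.2, 0.2),
    p_value = runif(3 * n_cmpd, 0.05, 1))
  # plant compound c01 at the top
  tab$ncr[tab$compound_id == "c01"] <- c(0.9, 0.85, 0.8)
  tab$p_value[tab$compound_id == "c01"] <- 0.001
  res <- compound_enrichment(tab, n_perm = 500, seed = 6)
  top <- res[res$compound_id == "c01", ]
  expect_gt(top$nes, 0)
  expect_equal(top$p_value, 1 / 501)
  expect_equal(top$n_signatures, 3L)

  res2 <- compound_enrichment(tab, n_perm = 500, seed = 6)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  # compound-order invariance
  res3 <- compound_enrichment(tab[sample(nrow(tab)), ], n_perm = 500, seed = 6)
  res3 <- res3[match(res$compound_id, res3$compound_id), ]
  expect_equal(res$nes, res3$nes)
})

test_that("a label-randomized screen yields almost no enrichment calls", {
  set.seed(44)
  n_cmpd <- 200
  tab <- tibble::tibble(
    signature_id = sprintf("sig%04d", 1:(3 * n_cmpd)),
    compound_id = sample(rep(sprintf("c%03d", 1:n_cmpd), each = 3)),
    ncr = runif(3 * n_cmpd, -0.5, 0.5),
    p_value = runif(3 * n_cmpd))
  res <- compound_enrichment(tab, n_perm = 500, seed = 7)
  expect_lte(sum(res$nes > 0 & res$q_value <= 0.05) / n_cmpd, 0.02)
})

test_that("ES is exactly invariant under adjacent replicate duplication", {
  set.seed(45)
  tab <- tibble::tibble(
    signature_id = sprintf("s%02d", 1:30),
    compound_id = rep(sprintf("c%02d", 1:10), each = 3),
    ncr = runif(30), p_value = runif(30))
  ranked <- rank_by_score(tab)
  dup_ranked <- as.vector(rbind(paste0(ranked, "_a"), paste0(ranked, "_b")))
  for (cid in unique(tab$compound_id)) {
    members <- tab$signature_id[tab$compound_id == cid]
    dup_members <- c(paste0(members, "_a"), paste0(members, "_b"))
    expect_equal(enrichment_score(dup_ranked, dup_members),
                 enrichment_score(ranked, members))
  }
})

test_that("recurrence requires both methods in at least min_lines lines", {
  lines <- sprintf("CL%d", 1:10)
  grid <- tidyr::expand_grid(cell_line = lines, method = c("full", "pathway"),
                             compound_id = c("hit3", "hit2", "fullonly", "never"))
  grid$enriched <- FALSE
  grid$enriched[grid$compound_id == "hit3" & grid$cell_line %in% lines[1:3]] <- TRUE
  grid$enriched[grid$compound_id == "hit2" & grid$cell_line %in% lines[1:2]] <- TRUE
  grid$enriched[grid$compound_id == "fullonly" & grid$method == "full"] <- TRUE
  res <- recurrent_hits(grid, min_lines = 3)
  expect_true(res$passes[res$compound_id == "hit3"])
  expect_equal(res$n_enriched[res$compound_id == "hit3"], 3L)
  expect_false(res$passes[res$compound_id == "hit2"])
  expect_equal(res$n_enriched[res$compound_id == "fullonly"], 0L)
  expect_equal(res$n_enriched[res$compound_id == "never"], 0L)
  expect_error(recurrent_hits(grid, min_lines = 0), ">= 1")
})
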