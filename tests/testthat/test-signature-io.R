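test_that("GCT writer and reader round-trip bit-exactly", {
  sm <- tiny_matrix()
  path <- withr::local_tempfile(fileext = ".gct")
  write_gct(sm, path)
  back <- read_gct(path)
  expect_identical(back$values, sm$values)
  expect_identical(back$meta$compound_id, sm$meta$compound_id)
  expect_identical(back$meta$tas, sm$meta$tas)
  # byte-level stability: re-writing what was read reproduces the file
  path2 <- withr::local_tempfile(fileext = ".gct")
  write_gct(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("GCT parser reports malformed input precisely", {
  path <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.3", "two\tsigs", "id\ts1"), path)
  expect_error(read_gct(path), "line 2")

  # duplicate gene row
  sm <- tiny_matrix()
  ok <- withr::local_tempfile(fileext = ".gct")
  write_gct(sm, ok)
  lines <- readLines(ok)
  lines[length(lines)] <- sub("^G3", "G1", lines[length(lines)])
  writeLines(lines, ok)
  expect_error(read_gct(ok), "G1")
})

test_that("TSV dialect with sidecar metadata round-trips", {
  sm <- tiny_matrix()
  mp <- withr::local_tempfile(fileext = ".tsv")
  meta_p <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tsv(sm, mp, meta_p)
  back <- read_signature_tsv(mp, meta_p)
  expect_equal(back$values, sm$values)
  expect_equal(back$meta$cell_line, sm$meta$cell_line)
})

test_that("signature_matrix enforces its invariants", {
  vals <- matrix(0, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(signature_matrix(vals, data.frame(signature_id = c("s1", "s2"))),
               "duplicate gene")
  vals2 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("s1", "s1")))
  expect_error(signature_matrix(vals2, data.frame(signature_id = c("s1", "s1"))),
               "duplicate signature")
  vals3 <- matrix(0, 1, 2, dimnames = list("a", c("s1", "s2")))
  expect_error(
    signature_matrix(vals3, data.frame(signature_id = c("s1", "s2"), tas = c(0.5, 1.2))),
    "TAS")
})

test_that("condition filtering keeps the TAS boundary and matches exact dose", {
  vals <- matrix(rnorm(9), 3, 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  sm <- signature_matrix(vals, data.frame(
    signature_id = paste0("s", 1:3), dose = c("10 uM", "10uM", "1 uM"),
    time = c("24 h", "24 hr", "24 h"), tas = c(0.3, 0.4, 0.9)))
  expect_equal(ncol(filter_signatures(sm, tas_min = 0.4, quiet = TRUE)$values), 2)
  expect_equal(colnames(filter_signatures(sm, dose = "10 µM", quiet = TRUE)$values),
               c("s1", "s2"))
  expect_equal(colnames(filter_signatures(sm, time = "24h", quiet = TRUE)$values),
               paste0("s", 1:3))
  expect_error(filter_signatures(sm, tas_min = 0.95, quiet = TRUE),
               "cannot proceed")
})

test_that("filtering a generated screen retains exactly the enumerated subset", {
  set.seed(404)
  n <- 50
  vals <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:n)))
  meta <- data.frame(signature_id = paste0("s", 1:n),
                     dose = sample(c("10 uM", "1 uM"), n, TRUE),
                     time = sample(c("24 h", "6 h"), n, TRUE),
                     tas = round(runif(n), 2))
  sm <- signature_matrix(vals, meta)
  want <- meta$signature_id[meta$dose == "10 uM" & meta$time == "24 h" &
                              meta$tas >= 0.4]
  got <- filter_signatures(sm, dose = "10 uM", time = "24 h", tas_min = 0.4,
                           quiet = TRUE)
  expect_setequal(colnames(got$values), want)
  # gene-axis operations commute with column filtering
  sub <- sm
  sub$values <- sub$values[1:5, ]
  got2 <- filter_signatures(signature_matrix(sub$values, sub$meta),
                            dose = "10 uM", time = "24 h", tas_min = 0.4,
                            quiet = TRUE)
  expect_identical(got2$values, got$values[1:5, ])
})

test_that("binarization is inclusive at the threshold and matches the dead-zone oracle", {
  expect_identical(unname(binarize_zscores(c(a = 1.0, b = -1.0, c = 0.99, d = -0.5))),
                   c(1L, -1L, 0L, 0L))
  expect_true(all(binarize_zscores(matrix(0, 3, 2,
    dimnames = list(letters[1:3], c("x", "y")))) == 0L))
  set.seed(7)
  z <- stats::setNames(rnorm(200, sd = 1.5), paste0("g", 1:200))
  oracle <- ifelse(z >= 1, 1L, ifelse(z <= -1, -1L, 0L))
  expect_identical(unname(binarize_zscores(z)), unname(oracle))
  expect_error(binarize_zscores(c(a = NA_real_)), "non-finite")
})

test_that("binarization is idempotent and monotone in the threshold", {
  set.seed(8)
  m <- matrix(rnorm(300, sd = 2), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  b1 <- binarize_zscores(m, 1)
  b1_numeric <- b1
  storage.mode(b1_numeric) <- "double"
  expect_identical(binarize_zscores(b1_numeric, 1), b1)
  for (t2 in c(1.5, 2, 3)) {
    b2 <- binarize_zscores(m, t2)
    expect_true(all(b1[b2 != 0] != 0))  # nonzero at t2 => nonzero at t1
  }
})

test_that("reference construction applies the fold-change and p-value rule", {
  ref <- build_reference(data.frame(gene = c("a", "b", "c"),
                                    log2fc = c(1.5, -2, 0.5),
                                    pval = c(0.01, 0.2, 0.001)))
  expect_identical(unname(ref$calls), c(1L, 0L, 0L))
  expect_identical(ref$deg_set, "a")
  # strict by default at the boundary, inclusive via the flag
  at1 <- data.frame(gene = "g", log2fc = 1, pval = 0.01)
  expect_identical(unname(build_reference(at1)$calls), 0L)
  expect_identical(unname(build_reference(at1, inclusive = TRUE)$calls), 1L)
  # empty table -> unusable downstream
  empty <- build_reference(data.frame(gene = "g", log2fc = 0.1, pval = 0.9))
  expect_length(empty$deg_set, 0)
  expect_error(ncr(empty, c(g = 1L)), "undefined")
  expect_error(build_reference(data.frame(gene = "g", log2fc = 2, pval = NA)),
               "missing p-value")
})

test_that("simulated reference plants the configured DEG count", {
  cfg <- screen_config(n_genes = 1000, n_deg = 728, seed = 3)
  ref <- simulate_reference(cfg)
  expect_length(ref$deg_set, 728)
  expect_equal(sum(ref$calls == 1L), 364)
})

test_that("GMT reader validates, preserves order, and round-trips", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_B\tdesc b\tg3\tg1", "SET_A\tdesc a\tg2"), path)
  sets <- read_gmt(path)
  expect_identical(names(sets), c("SET_B", "SET_A"))
  expect_identical(sets$SET_B, c("g3", "g1"))

  writeLines(c("ONLY_NAME\tdesc"), path)
  expect_error(read_gmt(path), "line 1")

  sets2 <- list(UP = c("a", "b"), DOWN = "c")
  attr(sets2, "description") <- c(UP = "up genes", DOWN = "down genes")
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets2, out)
  back <- read_gmt(out)
  expect_identical(back$UP, sets2$UP)
  expect_identical(back$DOWN, sets2$DOWN)
  expect_identical(readLines(out),
                   c("UP\tup genes\ta\tb", "DOWN\tdown genes\tc"))
  # independent reader agrees
  skip_if_not_installed("fgsea")
  expect_equal(fgsea::gmtPathways(out), sets2[c("UP", "DOWN")],
               ignore_attr = TRUE)
})
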