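test_that("TPM normalization matches closed forms", {
  d <- data.frame(sample_id = "s1", condition = "vehicle",
                  timepoint = 1, replicate = 1)
  one <- expr_set(gene_matrix(37, "solo"), d, scale = "counts")
  expect_equal(unname(compute_tpm(one, c(solo = 500))$values[1, 1]), 1e6)

  m <- matrix(c(10, 90), 2, dimnames = list(c("gA", "gB"), "s1"))
  tpm <- compute_tpm(expr_set(m, d, scale = "counts"),
                     c(gA = 1000, gB = 3000))
  expect_equal(unname(tpm$values[, 1]), c(250000, 750000))

  # permuting gene order permutes TPM identically
  tpm2 <- compute_tpm(expr_set(m[2:1, , drop = FALSE], d, scale = "counts"),
                      c(gA = 1000, gB = 3000))
  expect_equal(tpm2$values[c("gA", "gB"), 1], tpm$values[, 1])
})

test_that("TPM column sums are conserved on random fixtures", {
  set.seed(41)
  des <- make_design(1:3, reps = 2)
  vals <- matrix(rpois(50 * nrow(des), 40), 50,
                 dimnames = list(sprintf("g%02d", 1:50), des$sample_id))
  lens <- setNames(sample(200:3000, 50), rownames(vals))
  tpm <- compute_tpm(expr_set(vals, des, scale = "counts"), lens)
  expect_true(all(abs(colSums(tpm$values) - 1e6) / 1e6 < 1e-6))
  expect_identical(tpm$scale, "tpm")
})

test_that("TPM errors name the offending gene or sample", {
  d <- data.frame(sample_id = c("sGood", "sZero"),
                  condition = c("vehicle", "drug"),
                  timepoint = 1, replicate = 1)
  m <- matrix(c(5, 0, 3, 0), 2, dimnames = list(c("gA", "gB"), d$sample_id))
  x <- expr_set(m, d, scale = "counts")
  expect_error(compute_tpm(x, c(gA = 100)), "gB")
  m0 <- matrix(c(5, 3, 0, 0), 2, byrow = TRUE,
               dimnames = list(c("gA", "gB"), d$sample_id))
  m0 <- rbind(gA = c(5, 0), gB = c(3, 0))
  colnames(m0) <- d$sample_id
  expect_error(compute_tpm(expr_set(m0, d, scale = "counts"),
                           c(gA = 100, gB = 100)), "sZero")
})

test_that("gene filtering applies annotation and expression criteria", {
  des <- make_design(1:2, reps = 2)
  vals <- rbind(allzero = 0,
                unannot = 5,
                dupA = 8, dupB = 9,
                good = 10,
                low = 0.1)
  vals <- matrix(rep(vals, nrow(des)), nrow = 6,
                 dimnames = list(c("allzero", "unannot", "dupA", "dupB",
                                   "good", "low"), des$sample_id))
  vals["allzero", ] <- 0
  x <- expr_set(vals, des, scale = "abundance")
  sym <- c(allzero = "AZ", dupA = "DUP", dupB = "DUP", good = "GOOD",
           low = "LOW")
  suppressMessages(f <- filter_genes(x, symbols = sym))
  expect_identical(rownames(f$values), "good")
  rep1 <- attr(f, "filter_report")
  expect_equal(unname(rep1["removed_annotation"]), 3)  # unannot + dup pair

  # no-op thresholds with full annotation: identity
  suppressMessages(id <- filter_genes(x, min_expressed_frac = 0,
                                      min_mean = 0))
  expect_identical(id$values, x$values)

  # idempotence
  suppressMessages(f2 <- filter_genes(f, symbols = sym))
  expect_identical(f2$values, f$values)

  # removing everything is an error
  expect_error(suppressMessages(filter_genes(x, min_mean = 1e9)),
               "every gene")
})

test_that("expr_set validates its invariants", {
  d <- data.frame(sample_id = "s1", condition = "vehicle",
                  timepoint = 1, replicate = 1)
  expect_error(expr_set(gene_matrix(-1), d, scale = "tpm"), "negative")
  expect_error(expr_set(matrix(1, 1, 1), d), "rownames")
  m <- rbind(g1 = 1, g1 = 2)
  expect_error(expr_set(m[c(1, 1), , drop = FALSE][, 1, drop = FALSE], d),
               "unique")
  expect_error(expr_set(gene_matrix(5), d, scale = "tpm"), "1e6")
  d2 <- d; d2$condition <- "placebo"
  expect_error(expr_set(gene_matrix(5), d2), "vehicle")
})

test_that("TSV round trips are byte-stable after one write-read cycle", {
  set.seed(7)
  des <- make_design(0:3, reps = 2)
  vals <- matrix(round(rlnorm(20 * nrow(des), 4, 1), 3), 20,
                 dimnames = list(sprintf("g%02d", 1:20), des$sample_id))
  x <- expr_set(vals, des, scale = "abundance")
  p1 <- tempfile(); s1 <- tempfile()
  p2 <- tempfile(); s2 <- tempfile()
  write_expr_set(x, p1, s1)
  y <- read_expr_set(p1, s1, scale = "abundance")
  write_expr_set(y, p2, s2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(s1), readLines(s2))
  expect_equal(y$values, x$values)
  expect_equal(y$design$timepoint, x$design$timepoint)
})

test_that("log transform tags scale and respects the offset", {
  d <- data.frame(sample_id = "s1", condition = "vehicle",
                  timepoint = 1, replicate = 1)
  m <- matrix(c(0, 3), 2, dimnames = list(c("gA", "gB"), "s1"))
  x <- expr_set(m, d, scale = "abundance")
  lx <- log_transform(x)
  expect_identical(lx$scale, "log2")
  expect_equal(unname(lx$values[, 1]), log2(c(0, 3) + 1))
  expect_equal(unname(log_transform(x, offset = 0)$values["gB", 1]),
               log2(3))
})
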