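test_that("library size and shape identities hold for 6 timepoints", {
  lib <- build_template_library(1:6)
  expect_equal(nrow(lib$shapes), 21)
  expect_equal(nrow(lib$patterns), 63)
  expect_equal(anyDuplicated(lib$patterns$pattern), 0L)
  expect_true(all(lib$shapes["00", ] == 0))
  expect_true(all(diff(lib$shapes["10a", ]) > 0))
  for (code in setdiff(lib$codes, "00")) {
    if (grepl("b$", code))
      expect_identical(unname(lib$shapes[code, ]),
                       unname(-lib$shapes[sub("b$", "a", code), ]))
    expect_gt(stats::var(lib$shapes[code, ]), 0)
  }
  # no two candidate shapes are positively collinear (reflection pairs
  # are r = -1 by construction; assignment distinguishes them by sign)
  R <- cor(t(lib$shapes[setdiff(lib$codes, "00"), ]))
  expect_lt(max(R[upper.tri(R)]), 1 - 1e-8)
})

test_that("library generalizes to other timepoint counts", {
  expect_equal(nrow(build_template_library(1:4)$shapes), 4 * 4 - 3)
  expect_equal(nrow(build_template_library(c(2, 4, 8))$patterns),
               3 * (4 * 3 - 3))
  expect_error(build_template_library(1:2), "3 timepoints")
})

test_that("templates assign themselves and their reflections exactly", {
  lib <- build_template_library(1:6)
  for (code in setdiff(lib$codes, "00")) {
    res <- assign_template(lib$shapes[code, ], lib)
    expect_identical(res$shape, code)
    expect_equal(res$r, 1)
    # negating a profile maps a <-> b
    flip <- assign_template(-lib$shapes[code, ], lib)
    expect_identical(flip$shape,
                     if (grepl("a$", code)) sub("a$", "b", code)
                     else sub("b$", "a", code))
  }
  # flat profile routes to 00 with undefined r
  res0 <- assign_template(rep(3, 6), lib)
  expect_identical(res0$shape, "00")
  expect_true(is.na(res0$r))
})

test_that("sub-threshold profiles stay unassigned and r matches brute force", {
  lib <- build_template_library(1:6)
  set.seed(604)
  found <- FALSE
  for (i in 1:50) {
    prof <- rnorm(6)
    brute <- vapply(setdiff(lib$codes, "00"),
                    function(cc) cor(prof, lib$shapes[cc, ]), numeric(1))
    res <- assign_template(prof, lib)
    expect_equal(res$r, unname(max(brute)), tolerance = 1e-12)
    if (max(brute) <= 0.85) {
      expect_true(is.na(res$shape))
      found <- TRUE
    } else {
      expect_identical(res$shape, names(brute)[which.max(brute)])
    }
  }
  expect_true(found)  # the loop exercised the unassigned branch
  expect_error(assign_template(rnorm(5), lib), "timepoints")
  expect_error(assign_template(c(1, NA, 0, 0, 0, 0), lib), "finite")
})

test_that("drug-effect classification follows the drug term and means", {
  fake <- function(p_drug, mv, md) {
    Tn <- 6
    M <- matrix(0, length(p_drug), 2 * Tn)
    M[, seq(1, 2 * Tn, 2)] <- mv   # vehicle columns
    M[, seq(2, 2 * Tn, 2)] <- md   # drug columns
    structure(list(table = data.frame(gene = paste0("g", seq_along(p_drug)),
                                      p_drug = p_drug),
                   cell_means = M, timepoints = 1:Tn, n_rep = 3),
              class = "chrono_anova")
  }
  expect_equal(unname(classify_drug_effect(fake(0.001, 1, 2))), "up")
  expect_equal(unname(classify_drug_effect(fake(0.001, 2, 1))), "down")
  expect_equal(unname(classify_drug_effect(fake(0.5, 1, 5))), "nc")
  expect_warning(cls <- classify_drug_effect(fake(0.001, 3, 3)),
                 "equal")
  expect_equal(unname(cls), "nc")
})

test_that("binomial template enrichment matches exact tail sums", {
  lib <- build_template_library(1:6)
  pats <- lib$patterns$pattern
  # one gene per pattern: observed equals expected, nothing flagged
  even <- data.frame(pattern = pats)
  e1 <- template_enrichment(even, lib)
  expect_true(all(!e1$flagged))
  expect_equal(sum(e1$observed), 63)
  expect_equal(unique(e1$expected), 1)

  # all genes concentrated in one pattern
  n <- 6
  conc <- data.frame(pattern = rep(pats[5], n))
  e2 <- template_enrichment(conc, lib)
  expect_equal(e2$p[e2$pattern == pats[5]], (1 / 63)^n)
  expect_true(e2$flagged[e2$pattern == pats[5]])

  # exact enumeration oracle: P(X >= k) as a binomial tail sum
  enum_tail <- function(k, n, p)
    sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
               numeric(1)))
  mix <- data.frame(pattern = c(rep(pats[1], 10), sample(pats, 53,
                                                         replace = TRUE)))
  e3 <- template_enrichment(mix, lib)
  for (pp in unique(mix$pattern)) {
    k <- sum(mix$pattern == pp)
    expect_equal(e3$p[e3$pattern == pp], enum_tail(k, 63, 1 / 63),
                 tolerance = 1e-12)
  }
  expect_error(template_enrichment(data.frame(pattern = NA_character_),
                                   lib), "no assigned")
})

test_that("pattern assignment covers T/D/T&D sectors and routes D-only to 00", {
  tp <- 1:6
  lib <- build_template_library(tp)
  base <- 6
  mu_t <- base + rbind(gT = 1.5 * lib$shapes["04a", ],
                       gTD = 1.5 * lib$shapes["10b", ],
                       gD = rep(0, 6))
  mu_d <- mu_t
  mu_d["gTD", ] <- mu_d["gTD", ] + 1   # level shift -> D term
  mu_d["gD", ] <- mu_d["gD", ] + 1
  x <- make_cellmean_set(mu_t, mu_d, tp)
  fit <- fit_twoway_anova(x)
  asg <- assign_patterns(fit, lib)
  asg <- asg[match(c("gT", "gTD", "gD"), asg$gene), ]
  expect_equal(asg$sector, c("T", "T&D", "D"))
  expect_equal(asg$shape, c("04a", "10b", "00"))
  expect_equal(asg$class, c("nc", "up", "up"))
  expect_equal(asg$pattern, c("04a(nc)", "10b(up)", "00(up)"))
  expect_true(all(asg$r[1:2] > 0.99))
})
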