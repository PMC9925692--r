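test_that("interaction grid places constructed genes in the right cell", {
  tp <- 1:6
  lib <- build_template_library(tp)
  base <- 7
  # flat under vehicle, linear rise under drug
  mu_v <- matrix(base, 3, 6, dimnames = list(paste0("g", 1:3), NULL))
  mu_d <- mu_v + 1.5 * matrix(lib$shapes["10a", ], 3, 6, byrow = TRUE)
  x <- make_cellmean_set(mu_v, mu_d, tp)
  fit <- fit_twoway_anova(x)
  expect_true(all(fit$table$p_interaction < 0.01))
  grid <- build_interaction_grid(fit, lib, flag_threshold = 2)
  expect_equal(unname(grid$counts["00", "10a"]), 3)
  expect_equal(sum(grid$counts), 3)
  expect_equal(sum(grid$counts),
               sum(!is.na(grid$assignments$veh_shape) &
                     !is.na(grid$assignments$drug_shape)))
  expect_equal(grid$members[["00|10a"]], paste0("g", 1:3))
  # threshold is exclusive: 3 > 2 flags, 3 > 3 would not
  expect_equal(nrow(grid$flagged), 1)
  expect_equal(nrow(build_interaction_grid(fit, lib,
                                           flag_threshold = 3)$flagged), 0)
})

test_that("a planted cohort above the flag threshold is flagged", {
  tp <- 1:6
  lib <- build_template_library(tp)
  n <- 150
  mu_v <- matrix(6, n, 6, dimnames = list(sprintf("g%03d", 1:n), NULL))
  mu_v <- mu_v + 1.2 * matrix(lib$shapes["05a", ], n, 6, byrow = TRUE)
  mu_d <- matrix(6, n, 6, dimnames = list(sprintf("g%03d", 1:n), NULL)) +
    1.2 * matrix(lib$shapes["04a", ], n, 6, byrow = TRUE)
  x <- make_cellmean_set(mu_v, mu_d, tp)
  fit <- fit_twoway_anova(x)
  grid <- build_interaction_grid(fit, lib, flag_threshold = 100)
  expect_equal(grid$flagged$veh_shape, "05a")
  expect_equal(grid$flagged$drug_shape, "04a")
  expect_equal(grid$flagged$count, 150)
})

test_that("grid marginals agree with standalone drug-profile shapes", {
  sim <- simulate_timecourse(synth_config(n_genes = 300,
                                          frac_patterned = 0.6,
                                          drug_timepoints = 4:6,
                                          seed = 31))
  fit <- fit_twoway_anova(log_transform(sim$data))
  lib <- sim$library
  if (any(fit$table$p_interaction <= 0.01)) {
    grid <- build_interaction_grid(fit, lib)
    both <- !is.na(grid$assignments$veh_shape) &
      !is.na(grid$assignments$drug_shape)
    marg <- colSums(grid$counts)
    tab <- table(factor(grid$assignments$drug_shape[both],
                        levels = lib$codes))
    expect_equal(unname(marg), as.vector(tab))
  }
  expect_error(build_interaction_grid(
    fit, lib, alpha = 0), "no interaction-significant")
})

test_that("timepoint LSD handles zero differences and the MSE -> 0 limit", {
  tp <- 1:6
  # equal cell means, strong time effect so the omnibus gate passes
  mu <- matrix(5 + (1:6) / 2, 1, 6, byrow = TRUE,
               dimnames = list("gEq", NULL))
  x <- make_cellmean_set(mu, mu, tp)
  fit <- fit_twoway_anova(x)
  res <- timepoint_lsd(fit, "gEq")
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$class == "ns"))

  # drug abundance exactly twice vehicle, near-zero MSE
  mu_v <- matrix(log2(100), 1, 6, dimnames = list(gX = "gX", NULL))
  mu_d <- matrix(log2(200), 1, 6, dimnames = list(gX = "gX", NULL))
  x2 <- make_cellmean_set(mu_v, mu_d, tp, eps = 1e-4)
  ab2 <- expr_set(2^x2$values, x2$design, scale = "abundance")
  fit2 <- fit_twoway_anova(x2)
  res2 <- timepoint_lsd(fit2, "gX", abundance = ab2, offset = 0)
  expect_equal(res2$log2fc, rep(1, 6), tolerance = 1e-8)
  expect_true(all(res2$class == "up"))
})

test_that("LSD p-values match an independent pooled-variance computation", {
  sim <- simulate_timecourse(synth_config(n_genes = 60,
                                          frac_patterned = 0.5,
                                          drug_timepoints = 5:6,
                                          seed = 19))
  lx <- log_transform(sim$data)
  fit <- fit_twoway_anova(lx)
  gated <- fit$table$gene[pmin(fit$table$p_time, fit$table$p_drug,
                               fit$table$p_interaction) <= 0.01]
  g <- gated[1]
  res <- timepoint_lsd(fit, g)
  keep <- lx$design$timepoint != 0
  des <- lx$design[keep, ]
  y <- lx$values[g, keep]
  # oracle: MSE and df from aov, cell means from tapply
  a <- stats::aov(y ~ factor(des$condition) * factor(des$timepoint))
  mse <- sum(stats::residuals(a)^2) / a$df.residual
  cm <- tapply(y, list(des$condition, des$timepoint), mean)
  for (t in 1:6) {
    tt <- (cm["drug", as.character(t)] - cm["vehicle", as.character(t)]) /
      sqrt(mse * 2 / 3)
    p <- 2 * stats::pt(abs(tt), a$df.residual, lower.tail = FALSE)
    row <- res[res$timepoint == t, ]
    expect_equal(row$t, unname(tt), tolerance = 1e-10)
    expect_equal(row$p, unname(p), tolerance = 1e-10)
  }
})

test_that("protection: LSD refuses genes that fail the omnibus gate", {
  sim <- simulate_timecourse(synth_config(n_genes = 100,
                                          frac_patterned = 0, seed = 8))
  fit <- fit_twoway_anova(log_transform(sim$data))
  ns_gene <- fit$table$gene[which.max(pmin(fit$table$p_time,
                                           fit$table$p_drug,
                                           fit$table$p_interaction))]
  expect_error(timepoint_lsd(fit, ns_gene), "omnibus")
})

test_that("late planted drug shifts are called up at late hours", {
  sim <- simulate_timecourse(synth_config(n_genes = 200,
                                          frac_patterned = 0.5,
                                          amplitude = 1, drug_shift = 1,
                                          drug_timepoints = 5:6,
                                          seed = 23))
  fit <- fit_twoway_anova(log_transform(sim$data))
  up_genes <- sim$truth$gene[sim$truth$class == "up" &
                               sim$truth$amplitude > 0]
  gated <- fit$table$gene[pmin(fit$table$p_time, fit$table$p_drug,
                               fit$table$p_interaction) <= 0.01]
  g <- intersect(up_genes, gated)
  res <- timepoint_lsd(fit, g, abundance = sim$data)
  late <- res[res$timepoint %in% 5:6, ]
  expect_gt(mean(late$class == "up"), 0.9)
  early <- res[res$timepoint %in% 1:3, ]
  expect_lt(mean(early$class == "up"), 0.2)
})
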