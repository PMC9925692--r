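# Fixture builders shared across test files. Everything is generated in
# code; no data files are read.

# balanced design: 2 conditions x timepoints x reps, condition-major
make_design <- function(timepoints = 1:6, reps = 3) {
  d <- expand.grid(replicate = seq_len(reps), timepoint = timepoints,
                   condition = c("vehicle", "drug"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("condition", "timepoint", "replicate")]
  d$sample_id <- sprintf("%s_t%g_r%d",
                         ifelse(d$condition == "vehicle", "veh", "drug"),
                         d$timepoint, d$replicate)
  d
}

# expr_set whose cell means are exactly mu_veh/mu_drug (genes x T);
# replicate offsets sum to zero within every cell, so cell means are
# exact while the residual mean square is eps^2 * reps/(reps-1) ... > 0,
# making every planted effect ANOVA-detectable without randomness.
make_cellmean_set <- function(mu_veh, mu_drug, timepoints = 1:6,
                              reps = 3, eps = 0.01, scale = "log2") {
  stopifnot(reps >= 2)
  offs <- seq(-1, 1, length.out = reps) * eps
  offs <- offs - mean(offs)
  des <- make_design(timepoints, reps)
  vals <- matrix(NA_real_, nrow(mu_veh), nrow(des))
  for (j in seq_len(nrow(des))) {
    mu <- if (des$condition[j] == "vehicle") mu_veh else mu_drug
    tcol <- match(des$timepoint[j], timepoints)
    vals[, j] <- mu[, tcol] + offs[des$replicate[j]]
  }
  rownames(vals) <- rownames(mu_veh)
  colnames(vals) <- des$sample_id
  if (scale != "log2") vals <- 2^vals
  expr_set(vals, des, scale = scale)
}

# single-gene helpers
gene_matrix <- function(v, gene = "g1")
  matrix(v, nrow = 1, dimnames = list(gene, NULL))
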