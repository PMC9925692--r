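#' Configuration for the synthetic time-course generator
#'
#' Defines a balanced two-condition (vehicle vs. drug) time-course design
#' with planted temporal templates, drug effects and log2-scale replicate
#' noise. Defaults mirror a typical bulk RNA-seq longevity time course:
#' ~5,000 genes, hours 0–6 sampled hourly, 3 replicates per condition and
#' timepoint.
#'
#' @param n_genes Number of genes (>= 1), default 5000.
#' @param timepoints Sampled hours, default `0:6`. Hour 0 is generated at
#'   baseline and excluded from analysis by default downstream.
#' @param n_replicates Replicates per condition x timepoint (>= 2),
#'   default 3.
#' @param frac_patterned Fraction of genes following a planted template,
#'   default 0.3; the rest are null (flat, no drug effect).
#' @param amplitude Template effect size on the log2 scale, default 1.5.
#' @param drug_shift log2 offset applied to drug samples of drug-affected
#'   genes, default 1.
#' @param noise_sd Standard deviation of additive log2-scale noise,
#'   default 0.15.
#' @param drug_timepoints Hours at which the drug shift applies for
#'   affected genes; `NULL` (default) applies it at every timepoint
#'   (a pure main effect). Restricting it to late hours plants a
#'   time-by-drug interaction.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 abundance is
#'   drawn Normal(`baseline_mean`, `baseline_sd`); defaults 6 and 2, a
#'   TPM-like dynamic range.
#' @param seed Integer random seed.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_genes = 5000, timepoints = 0:6,
                         n_replicates = 3, frac_patterned = 0.3,
                         amplitude = 1.5, drug_shift = 1,
                         noise_sd = 0.15, drug_timepoints = NULL,
                         baseline_mean = 6, baseline_sd = 2, seed = 1) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_replicates < 2)
    stop("n_replicates must be >= 2 (ANOVA needs within-cell replication)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (frac_patterned < 0 || frac_patterned > 1)
    stop("frac_patterned must be in [0, 1]")
  if (length(setdiff(timepoints, 0)) < 3)
    stop("need at least 3 non-zero timepoints for temporal templates")
  structure(list(n_genes = as.integer(n_genes), timepoints = timepoints,
                 n_replicates = as.integer(n_replicates),
                 frac_patterned = frac_patterned, amplitude = amplitude,
                 drug_shift = drug_shift, noise_sd = noise_sd,
                 drug_timepoints = drug_timepoints,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate a two-condition time-course expression dataset
#'
#' Generates a balanced vehicle/drug time course in which a configurable
#' fraction of genes follows a planted temporal template with a planted
#' drug effect, the remainder being null. Each gene's expected log2
#' profile over the analysis timepoints is `baseline + amplitude *
#' template`, plus `drug_shift` on drug samples of drug-affected genes
#' (restricted to `drug_timepoints` when set); hour 0, when present, sits
#' at baseline. Independent Normal(0, `noise_sd`) noise is added per
#' observation on the log2 scale and values are returned on the linear
#' (`"abundance"`) scale. Output is a pure function of the config (which
#' includes the seed).
#'
#' Planted shapes are drawn uniformly from the library's 20 non-flat
#' shapes and drug classes uniformly from up/down/nc; truth labels share
#' the template vocabulary, so recovery is a direct join.
#'
#' @param config A [synth_config()].
#' @return List with `data` (an [expr_set()], scale `"abundance"`),
#'   `truth` (data.frame `gene`, `shape`, `class`, `amplitude`) and
#'   `library` (the [build_template_library()] used for planting).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  old <- .Random.seed_backup()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  tp_analysis <- setdiff(sort(cfg$timepoints), 0)
  lib <- build_template_library(tp_analysis)
  nonflat <- setdiff(lib$codes, "00")
  n <- cfg$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  n_pat <- round(cfg$frac_patterned * n)
  is_pat <- seq_len(n) <= n_pat
  shape <- rep("00", n)
  cls <- rep("nc", n)
  if (n_pat > 0) {
    shape[is_pat] <- sample(nonflat, n_pat, replace = TRUE)
    cls[is_pat] <- sample(lib$classes, n_pat, replace = TRUE)
  }
  baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  amp <- ifelse(is_pat, cfg$amplitude, 0)

  tps <- sort(cfg$timepoints)
  des <- expand.grid(replicate = seq_len(cfg$n_replicates),
                     timepoint = tps,
                     condition = c("vehicle", "drug"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  des <- des[, c("condition", "timepoint", "replicate")]
  des$sample_id <- sprintf("%s_t%g_r%d",
                           ifelse(des$condition == "vehicle", "veh", "drug"),
                           des$timepoint, des$replicate)

  # template value per gene x timepoint (0 at hour 0 and for null genes)
  V <- matrix(0, n, length(tps), dimnames = list(genes, as.character(tps)))
  ia <- match(shape, rownames(lib$shapes))
  for (j in seq_along(tp_analysis)) {
    col <- as.character(tp_analysis[j])
    V[, col] <- lib$shapes[ia, j]
  }
  mu <- baseline + amp * V[, as.character(des$timepoint), drop = FALSE]
  shift_tp <- if (is.null(cfg$drug_timepoints)) tps else cfg$drug_timepoints
  on_drug <- des$condition == "drug" & des$timepoint %in% shift_tp
  dsign <- ifelse(cls == "up", 1, ifelse(cls == "down", -1, 0))
  mu[, on_drug] <- mu[, on_drug] + dsign * cfg$drug_shift
  y <- mu + matrix(stats::rnorm(n * nrow(des), 0, cfg$noise_sd), n)
  vals <- 2^y
  colnames(vals) <- des$sample_id
  truth <- data.frame(gene = genes, shape = shape, class = cls,
                      amplitude = amp, stringsAsFactors = FALSE)
  list(data = expr_set(vals, des, scale = "abundance"),
       truth = truth, library = lib)
}

# save/restore the global RNG state so simulation is side-effect free
.Random.seed_backup <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate gene-set collections from generator truth
#'
#' Builds a GMT-compatible collection over the simulated universe: one
#' set per planted (shape, class) pattern among the most populated
#' patterns — exactly the genes carrying that truth label, so
#' overrepresentation analysis should flag it for a query drawn from the
#' pattern — padded with random sets drawn from the whole universe.
#'
#' @param truth Truth table from [simulate_timecourse()].
#' @param n_sets Total number of sets (>= 1).
#' @param set_size Size of the random sets, default 50 (capped at the
#'   universe size).
#' @param n_pattern_sets Number of pattern-derived sets, default 1
#'   (capped at the number of planted patterns and `n_sets`).
#' @param seed Integer random seed.
#' @return Named list of gene-id vectors (writable with [write_gmt()]);
#'   pattern-derived sets are named `pattern_<shape>(<class>)`.
#' @export
simulate_genesets <- function(truth, n_sets = 10, set_size = 50,
                              n_pattern_sets = 1, seed = 1) {
  if (nrow(truth) == 0) stop("empty truth table")
  if (n_sets < 1) stop("n_sets must be >= 1")
  old <- .Random.seed_backup()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  universe <- truth$gene
  set_size <- min(set_size, length(universe))
  planted <- truth[truth$amplitude > 0, , drop = FALSE]
  sets <- list()
  if (nrow(planted) > 0 && n_pattern_sets > 0) {
    pat <- paste0(planted$shape, "(", planted$class, ")")
    top <- names(sort(table(pat), decreasing = TRUE))
    top <- utils::head(top, min(n_pattern_sets, n_sets))
    for (p in top)
      sets[[paste0("pattern_", p)]] <- planted$gene[pat == p]
  }
  i <- 1
  while (length(sets) < n_sets) {
    sets[[sprintf("random_%02d", i)]] <- sample(universe, set_size)
    i <- i + 1
  }
  sets
}
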