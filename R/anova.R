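#' Per-gene balanced two-way ANOVA (condition x timepoint)
#'
#' Fits the classical fixed-effects two-factor decomposition to every gene
#' of a balanced design: sums of squares for the drug main effect, the time
#' main effect and their interaction, with F statistics against the pooled
#' residual mean square. The computation is closed-form on cell means, so
#' all genes are handled in a handful of matrix operations.
#'
#' By default hour 0 is excluded, leaving the 6 time levels the downstream
#' pattern analysis expects; any balanced subset of timepoints can be
#' selected. Genes with zero residual variance (all 2 x T x r observations
#' identical up to cell means) are flagged degenerate and get p = 1 on all
#' three terms.
#'
#' @param x An [expr_set()] on the `"log2"` scale.
#' @param timepoints Hours to analyze; default all timepoints except 0.
#' @return An object of class `"chrono_anova"`: a list with
#'   \describe{
#'     \item{table}{data.frame with one row per gene: `gene`, `F_time`,
#'       `F_drug`, `F_interaction`, `p_time`, `p_drug`, `p_interaction`,
#'       `mse`, `degenerate`.}
#'     \item{cell_means}{genes x (2T) matrix of per-cell means on the input
#'       scale, columns named `condition.timepoint`.}
#'     \item{timepoints, n_rep, df}{design bookkeeping; `df` holds the
#'       (time, drug, interaction, error) degrees of freedom.}
#'   }
#' @export
fit_twoway_anova <- function(x, timepoints = NULL) {
  stopifnot(inherits(x, "expr_set"))
  if (x$scale != "log2")
    stop("fit_twoway_anova expects a log2-scale expr_set; see log_transform()")
  des <- x$design
  if (is.null(timepoints))
    timepoints <- setdiff(sort(unique(des$timepoint)), 0)
  timepoints <- sort(timepoints)
  keep <- des$timepoint %in% timepoints
  des <- des[keep, , drop = FALSE]
  Y <- x$values[, keep, drop = FALSE]
  conds <- c("vehicle", "drug")
  Tn <- length(timepoints)
  cell <- interaction(factor(des$condition, conds),
                      factor(des$timepoint, timepoints), sep = ".")
  counts <- table(cell)
  if (any(counts == 0))
    stop("unbalanced design: missing cell(s) ",
         paste(names(counts)[counts == 0], collapse = ", "))
  if (length(unique(counts)) != 1)
    stop("unbalanced design: unequal replication across cells (",
         paste(unique(counts), collapse = ", "), ")")
  r <- unname(counts[1])
  if (r < 2)
    stop("two-way ANOVA needs >= 2 replicates per cell; found ", r)

  # cell means via an averaging indicator matrix: genes x (2T)
  A <- stats::model.matrix(~ 0 + cell)
  M <- (Y %*% A) / r
  colnames(M) <- levels(cell)

  grand <- rowMeans(M)
  # marginal means: conditions are the odd/even interleave of cell levels
  idx_cond <- matrix(seq_len(2 * Tn), nrow = 2)  # row 1 vehicle, row 2 drug
  Mc <- cbind(rowMeans(M[, idx_cond[1, ], drop = FALSE]),
              rowMeans(M[, idx_cond[2, ], drop = FALSE]))
  Mt <- sapply(seq_len(Tn), function(j)
    rowMeans(M[, idx_cond[, j], drop = FALSE]))
  if (is.null(dim(Mt))) Mt <- matrix(Mt, nrow = 1)

  ss_d <- Tn * r * rowSums((Mc - grand)^2)
  ss_t <- 2 * r * rowSums((Mt - grand)^2)
  # interaction residual of the additive cell-mean model
  fit_add <- Mc[, rep(1:2, Tn), drop = FALSE] +
    Mt[, rep(seq_len(Tn), each = 2), drop = FALSE] - grand
  ss_i <- r * rowSums((M - fit_add)^2)
  ss_tot <- rowSums((Y - grand)^2)
  ss_e <- ss_tot - ss_d - ss_t - ss_i
  ss_e[ss_e < 0] <- 0  # floating-point guard

  df <- c(time = Tn - 1, drug = 1L, interaction = Tn - 1,
          error = 2 * Tn * (r - 1))
  mse <- ss_e / df["error"]
  degen <- mse <= .Machine$double.eps * pmax(ss_tot, 1)
  f_t <- (ss_t / df["time"]) / mse
  f_d <- (ss_d / df["drug"]) / mse
  f_i <- (ss_i / df["interaction"]) / mse
  p_t <- stats::pf(f_t, df["time"], df["error"], lower.tail = FALSE)
  p_d <- stats::pf(f_d, df["drug"], df["error"], lower.tail = FALSE)
  p_i <- stats::pf(f_i, df["interaction"], df["error"], lower.tail = FALSE)
  f_t[degen] <- f_d[degen] <- f_i[degen] <- 0
  p_t[degen] <- p_d[degen] <- p_i[degen] <- 1

  tab <- data.frame(gene = rownames(Y),
                    F_time = f_t, F_drug = f_d, F_interaction = f_i,
                    p_time = p_t, p_drug = p_d, p_interaction = p_i,
                    mse = mse, degenerate = degen,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, cell_means = M, timepoints = timepoints,
                 n_rep = r, df = df),
            class = "chrono_anova")
}

#' @export
print.chrono_anova <- function(x, ...) {
  cat("chrono_anova: ", nrow(x$table), " genes, ",
      length(x$timepoints), " timepoints x 2 conditions x ",
      x$n_rep, " replicates\n", sep = "")
  cat("  df: time ", x$df["time"], ", drug ", x$df["drug"],
      ", interaction ", x$df["interaction"],
      ", error ", x$df["error"], "\n", sep = "")
  invisible(x)
}

#' Euler-sector classification of ANOVA results
#'
#' Each gene's sector is the set of ANOVA terms on which it is significant
#' at `alpha` (inclusive threshold): `"T"`, `"D"`, `"I"` and their
#' combinations `"T&D"`, `"T&I"`, `"D&I"`, `"T&D&I"`, or `"ns"` when no
#' term passes. The union of all non-`"ns"` sectors is the DEG set.
#'
#' @param fit A `"chrono_anova"` object (or its `table`).
#' @param alpha Significance threshold, default 0.01; `p <= alpha` counts.
#' @return Character vector of sector labels, one per gene, named by gene.
#' @export
classify_euler_sector <- function(fit, alpha = 0.01) {
  tab <- if (inherits(fit, "chrono_anova")) fit$table else fit
  sig <- cbind(T = tab$p_time <= alpha,
               D = tab$p_drug <= alpha,
               I = tab$p_interaction <= alpha)
  lab <- apply(sig, 1, function(s)
    if (!any(s)) "ns" else paste(colnames(sig)[s], collapse = "&"))
  names(lab) <- tab$gene
  lab
}
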