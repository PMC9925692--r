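#' Vehicle-shape by drug-shape grid for interaction genes
#'
#' Genes whose time-by-drug interaction is significant change shape under
#' treatment, so their vehicle and drug time profiles are matched to the
#' template library independently and tabulated on a shape x shape grid
#' (rows: vehicle shape; columns: drug shape). Cells holding more genes
#' than `flag_threshold` (strictly) are flagged as patterns of interest.
#'
#' @param fit A `"chrono_anova"` object.
#' @param lib A [build_template_library()] over the fit's timepoints.
#' @param alpha Interaction-term threshold selecting the gene set
#'   (`p_interaction <= alpha`), default 0.01.
#' @param r_min Assignment threshold passed to [assign_template()].
#' @param flag_threshold Cells with count strictly greater than this are
#'   flagged; default 100.
#' @return Object of class `"interaction_grid"`: a list with `counts`
#'   (shape x shape integer matrix), `members` (named list of gene ids per
#'   non-empty cell, names `"veh|drug"`), `assignments` (per-gene
#'   data.frame with both shapes and correlations), `unassigned` (genes
#'   unassigned in either condition), `flagged` (data.frame of flagged
#'   cells) and `flag_threshold`.
#' @export
build_interaction_grid <- function(fit, lib, alpha = 0.01, r_min = 0.85,
                                   flag_threshold = 100) {
  stopifnot(inherits(fit, "chrono_anova"), inherits(lib, "template_library"))
  sel <- fit$table$p_interaction <= alpha
  if (!any(sel))
    stop("no interaction-significant genes at alpha = ", alpha)
  genes <- fit$table$gene[sel]
  Tn <- length(fit$timepoints)
  idx <- matrix(seq_len(2 * Tn), nrow = 2)
  Pv <- fit$cell_means[sel, idx[1, ], drop = FALSE]
  Pd <- fit$cell_means[sel, idx[2, ], drop = FALSE]
  rownames(Pv) <- rownames(Pd) <- genes
  av <- assign_template(Pv, lib, r_min = r_min)
  ad <- assign_template(Pd, lib, r_min = r_min)
  asg <- data.frame(gene = genes,
                    veh_shape = av$shape, veh_r = av$r,
                    drug_shape = ad$shape, drug_r = ad$r,
                    stringsAsFactors = FALSE)
  both <- !is.na(asg$veh_shape) & !is.na(asg$drug_shape)
  counts <- table(factor(asg$veh_shape[both], levels = lib$codes),
                  factor(asg$drug_shape[both], levels = lib$codes))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("vehicle", "drug")
  key <- paste(asg$veh_shape[both], asg$drug_shape[both], sep = "|")
  members <- split(asg$gene[both], key)
  fl <- which(counts > flag_threshold, arr.ind = TRUE)
  flagged <- data.frame(veh_shape = rownames(counts)[fl[, 1]],
                        drug_shape = colnames(counts)[fl[, 2]],
                        count = counts[fl],
                        stringsAsFactors = FALSE)
  flagged <- flagged[order(-flagged$count), , drop = FALSE]
  structure(list(counts = counts, members = members, assignments = asg,
                 unassigned = asg$gene[!both], flagged = flagged,
                 flag_threshold = flag_threshold),
            class = "interaction_grid")
}

#' @export
print.interaction_grid <- function(x, ...) {
  cat("interaction_grid: ", sum(x$counts), " genes assigned in both ",
      "conditions (", length(x$unassigned), " unassigned), ",
      nrow(x$flagged), " cell(s) > ", x$flag_threshold, " genes\n", sep = "")
  if (nrow(x$flagged)) {
    cat("  flagged cells:\n")
    for (i in seq_len(nrow(x$flagged)))
      cat("    ", x$flagged$veh_shape[i], " | ", x$flagged$drug_shape[i],
          ": ", x$flagged$count[i], "\n", sep = "")
  }
  invisible(x)
}

#' Per-timepoint drug-vs-vehicle comparison by protected LSD
#'
#' Fisher's protected least-significant-difference comparison of the drug
#' and vehicle cell means at each timepoint, using the pooled ANOVA
#' residual mean square: `t = (mean_drug - mean_veh) / sqrt(MSE * 2/r)`
#' with the ANOVA error degrees of freedom. Protection means the test is
#' only available for genes that passed the omnibus gate (any ANOVA
#' p-value at or below `gate_alpha`); requesting other genes is an error.
#'
#' The reported fold change is `log2((drug + offset)/(vehicle + offset))`
#' computed on abundance-scale cell means when an abundance matrix is
#' supplied, with a `+ offset` guard against zeros; otherwise it falls
#' back to the difference of log2-scale cell means. A message reports how
#' many fold changes the guard shifted by more than 1%.
#'
#' @param fit A `"chrono_anova"` object.
#' @param genes Genes to test; default all genes passing the omnibus gate.
#' @param abundance Optional [expr_set()] on a linear scale (same samples)
#'   providing abundance-scale cell means for the fold change.
#' @param alpha Per-comparison threshold, default 0.05.
#' @param gate_alpha Omnibus protection threshold, default 0.01.
#' @param offset Fold-change guard, default 1.
#' @return data.frame: `gene`, `timepoint`, `log2fc`, `t`, `p`, `class`
#'   (`"up"`, `"down"` or `"ns"`), one row per gene x timepoint.
#' @export
timepoint_lsd <- function(fit, genes = NULL, abundance = NULL,
                          alpha = 0.05, gate_alpha = 0.01, offset = 1) {
  stopifnot(inherits(fit, "chrono_anova"))
  tab <- fit$table
  minp <- pmin(tab$p_time, tab$p_drug, tab$p_interaction)
  gated <- tab$gene[minp <= gate_alpha]
  if (is.null(genes)) genes <- gated
  if (length(genes) == 0) stop("no genes to test")
  bad <- setdiff(genes, gated)
  if (length(bad))
    stop("protected LSD requires a significant omnibus test; gene(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " did not pass the gate at alpha = ", gate_alpha)
  ix <- match(genes, tab$gene)
  Tn <- length(fit$timepoints)
  idx <- matrix(seq_len(2 * Tn), nrow = 2)
  Mv <- fit$cell_means[ix, idx[1, ], drop = FALSE]
  Md <- fit$cell_means[ix, idx[2, ], drop = FALSE]
  se <- sqrt(tab$mse[ix] * 2 / fit$n_rep)
  diffs <- Md - Mv
  tstat <- diffs / se
  tstat[diffs == 0] <- 0  # covers 0/0 when MSE = 0
  pval <- 2 * stats::pt(abs(tstat), fit$df["error"], lower.tail = FALSE)

  if (!is.null(abundance)) {
    stopifnot(inherits(abundance, "expr_set"))
    if (abundance$scale == "log2")
      stop("`abundance` must be on a linear scale")
    des <- abundance$design
    keep <- des$timepoint %in% fit$timepoints
    A <- abundance$values[genes, keep, drop = FALSE]
    des <- des[keep, , drop = FALSE]
    cellmean <- function(cond, tp)
      rowMeans(A[, des$condition == cond & des$timepoint == tp,
                 drop = FALSE])
    Av <- sapply(fit$timepoints, function(tp) cellmean("vehicle", tp))
    Ad <- sapply(fit$timepoints, function(tp) cellmean("drug", tp))
    if (is.null(dim(Av))) { Av <- matrix(Av, 1); Ad <- matrix(Ad, 1) }
    lfc <- log2((Ad + offset) / (Av + offset))
    raw <- log2(Ad / Av)
    moved <- is.finite(raw) & raw != 0 & abs(lfc / raw - 1) > 0.01
    if (any(moved))
      message("timepoint_lsd: +", offset, " guard shifted ", sum(moved),
              " fold change(s) by > 1%")
  } else {
    lfc <- diffs
  }
  cls <- matrix("ns", nrow(lfc), ncol(lfc))
  cls[pval <= alpha & lfc > 0] <- "up"
  cls[pval <= alpha & lfc < 0] <- "down"
  data.frame(gene = rep(genes, times = Tn),
             timepoint = rep(fit$timepoints, each = length(genes)),
             log2fc = as.vector(lfc), t = as.vector(tstat),
             p = as.vector(pval), class = as.vector(cls),
             stringsAsFactors = FALSE)
}
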