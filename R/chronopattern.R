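#' Fit the full temporal-pattern analysis to a time-course experiment
#'
#' The one-stop fitting function: normalizes (when given counts), filters,
#' log-transforms, runs the per-gene two-way ANOVA gate, classifies Euler
#' sectors, assigns Time/Drug-sector DEGs to the 63-pattern template
#' library, tests templates for over-assignment, builds the interaction
#' shape-grid with per-timepoint protected-LSD calls, and (optionally)
#' runs overrepresentation analysis of flagged pattern memberships.
#'
#' @param x An [expr_set()] on any scale; counts require `lengths`.
#' @param lengths Named gene lengths in bases, for TPM normalization of
#'   counts.
#' @param symbols Optional gene-id to symbol map used by [filter_genes()].
#' @param genesets Optional named list of gene sets (e.g. [read_gmt()])
#'   for overrepresentation analysis of flagged patterns.
#' @param alpha ANOVA gate threshold (inclusive), default 0.01.
#' @param r_min Template-assignment correlation threshold, default 0.85.
#' @param lsd_alpha Per-timepoint LSD threshold, default 0.05.
#' @param flag_threshold Interaction-grid flag threshold (exclusive),
#'   default 100.
#' @param min_expressed_frac,min_mean Gene-filter settings (see
#'   [filter_genes()]); `filter = FALSE` skips filtering.
#' @param filter Apply [filter_genes()] before analysis? Default `TRUE`
#'   for linear-scale input.
#' @param log_offset Offset of the log2 transform, default 1.
#' @param timepoints Hours entering the ANOVA; default all but hour 0.
#' @return Object of class `"chronopattern"`; see Details.
#' @details The returned object is a list with components `anova`
#'   (`"chrono_anova"`), `sectors`, `library`, `assignments`,
#'   `enrichment`, `grid` (`"interaction_grid"` or `NULL`), `lsd`
#'   (per-timepoint comparisons for interaction genes, or `NULL`), `ora`
#'   (named list of ORA tables or `NULL`), `data` (the analyzed
#'   linear-scale [expr_set()]) and `params`. Methods: `print`,
#'   `summary`, `plot`.
#' @examples
#' sim <- simulate_timecourse(synth_config(n_genes = 300, seed = 7))
#' fit <- chronopattern(sim$data, filter = FALSE)
#' summary(fit)
#' @export
chronopattern <- function(x, lengths = NULL, symbols = NULL,
                          genesets = NULL, alpha = 0.01, r_min = 0.85,
                          lsd_alpha = 0.05, flag_threshold = 100,
                          min_expressed_frac = 0.5, min_mean = 1,
                          filter = TRUE, log_offset = 1,
                          timepoints = NULL) {
  stopifnot(inherits(x, "expr_set"))
  cl <- match.call()
  if (x$scale == "counts") {
    if (is.null(lengths))
      stop("count input requires gene `lengths` for TPM normalization")
    x <- compute_tpm(x, lengths)
  }
  if (x$scale == "log2") {
    abundance <- NULL
  } else {
    if (isTRUE(filter))
      x <- filter_genes(x, symbols = symbols,
                        min_expressed_frac = min_expressed_frac,
                        min_mean = min_mean)
    abundance <- x
  }
  lx <- log_transform(x, offset = log_offset)
  fit <- fit_twoway_anova(lx, timepoints = timepoints)
  sectors <- classify_euler_sector(fit, alpha = alpha)
  lib <- build_template_library(fit$timepoints)

  assignments <- NULL
  enrichment <- NULL
  if (any(sectors %in% c("T", "D", "T&D"))) {
    assignments <- assign_patterns(fit, lib, sectors = sectors,
                                   alpha = alpha, r_min = r_min)
    if (any(!is.na(assignments$pattern)))
      enrichment <- template_enrichment(assignments, lib, alpha = alpha)
  }

  grid <- NULL
  lsd <- NULL
  if (any(fit$table$p_interaction <= alpha)) {
    grid <- build_interaction_grid(fit, lib, alpha = alpha, r_min = r_min,
                                   flag_threshold = flag_threshold)
    igenes <- fit$table$gene[fit$table$p_interaction <= alpha]
    lsd <- timepoint_lsd(fit, genes = igenes, abundance = abundance,
                         alpha = lsd_alpha, gate_alpha = alpha,
                         offset = log_offset)
  }

  ora <- NULL
  if (!is.null(genesets)) {
    queries <- list()
    if (!is.null(enrichment) && any(enrichment$flagged)) {
      for (p in enrichment$pattern[enrichment$flagged])
        queries[[p]] <- assignments$gene[!is.na(assignments$pattern) &
                                           assignments$pattern == p]
    }
    if (!is.null(grid) && nrow(grid$flagged)) {
      for (i in seq_len(nrow(grid$flagged))) {
        key <- paste(grid$flagged$veh_shape[i], grid$flagged$drug_shape[i],
                     sep = "|")
        queries[[paste0("I:", key)]] <- grid$members[[key]]
      }
    }
    # background: analyzed genes annotated to at least one set
    universe <- intersect(fit$table$gene,
                          unique(unlist(genesets, use.names = FALSE)))
    ora <- lapply(queries, function(q)
      tryCatch(run_ora(q, genesets, universe = universe),
               error = function(e) NULL))
    ora <- ora[!vapply(ora, is.null, logical(1))]
    if (length(ora) == 0) ora <- NULL
  }

  structure(list(anova = fit, sectors = sectors, library = lib,
                 assignments = assignments, enrichment = enrichment,
                 grid = grid, lsd = lsd, ora = ora, data = x,
                 params = list(alpha = alpha, r_min = r_min,
                               lsd_alpha = lsd_alpha,
                               flag_threshold = flag_threshold,
                               log_offset = log_offset),
                 call = cl),
            class = "chronopattern")
}

#' @export
print.chronopattern <- function(x, ...) {
  tab <- x$anova$table
  ndeg <- sum(x$sectors != "ns")
  cat("chronopattern fit: ", nrow(tab), " genes, ",
      length(x$anova$timepoints), " timepoints, alpha = ",
      x$params$alpha, "\n", sep = "")
  cat("  DEGs: ", ndeg, " (", round(100 * ndeg / nrow(tab), 1),
      "% of genes)\n", sep = "")
  if (!is.null(x$assignments)) {
    asg <- sum(!is.na(x$assignments$pattern))
    cat("  T/D/T&D genes assigned to a template: ", asg, "/",
        nrow(x$assignments), "\n", sep = "")
  }
  if (!is.null(x$grid))
    cat("  interaction genes: ", nrow(x$grid$assignments), ", flagged grid",
        " cells: ", nrow(x$grid$flagged), "\n", sep = "")
  invisible(x)
}

#' Summarize a chronopattern fit
#'
#' @param object A `"chronopattern"` object.
#' @param ... Unused.
#' @return A `"summary.chronopattern"` list: `n_genes`, `n_deg`,
#'   `sector_counts`, `n_assigned`, `pct_assigned`, `flagged_patterns`
#'   (with their combined share of assigned DEGs), `flagged_cells`,
#'   `params`.
#' @export
summary.chronopattern <- function(object, ...) {
  secs <- c("T", "D", "I", "T&D", "T&I", "D&I", "T&D&I", "ns")
  counts <- table(factor(object$sectors, levels = secs))
  n_deg <- sum(object$sectors != "ns")
  n_try <- if (is.null(object$assignments)) 0L else nrow(object$assignments)
  n_asg <- if (is.null(object$assignments)) 0L else
    sum(!is.na(object$assignments$pattern))
  fp <- if (is.null(object$enrichment)) character(0) else
    object$enrichment$pattern[object$enrichment$flagged]
  share <- if (n_asg == 0 || length(fp) == 0) 0 else
    sum(object$enrichment$observed[object$enrichment$flagged]) / n_asg
  structure(list(n_genes = nrow(object$anova$table), n_deg = n_deg,
                 sector_counts = counts, n_assigned = n_asg,
                 pct_assigned = if (n_try) 100 * n_asg / n_try else NA_real_,
                 flagged_patterns = fp, flagged_share = share,
                 flagged_cells = if (is.null(object$grid))
                   data.frame() else object$grid$flagged,
                 params = object$params),
            class = "summary.chronopattern")
}

#' @export
print.summary.chronopattern <- function(x, ...) {
  cat("Temporal-pattern analysis summary\n")
  cat("  genes analyzed: ", x$n_genes, "; DEGs (any term p <= ",
      x$params$alpha, "): ", x$n_deg, "\n", sep = "")
  cat("  Euler sectors:\n")
  for (s in names(x$sector_counts))
    if (x$sector_counts[s] > 0)
      cat(sprintf("    %-6s %d\n", s, x$sector_counts[s]))
  if (x$n_assigned > 0)
    cat(sprintf("  template-assigned T/D/T&D DEGs: %d (%.1f%%)\n",
                x$n_assigned, x$pct_assigned))
  if (length(x$flagged_patterns))
    cat(sprintf("  over-assigned patterns: %s (%.0f%% of assigned DEGs)\n",
                paste(x$flagged_patterns, collapse = ", "),
                100 * x$flagged_share))
  if (nrow(x$flagged_cells))
    cat("  flagged interaction cells: ",
        paste(paste0(x$flagged_cells$veh_shape, "|",
                     x$flagged_cells$drug_shape,
                     " (", x$flagged_cells$count, ")"), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Plot a chronopattern fit
#'
#' Draws a barplot of per-pattern DEG counts (patterns with at least one
#' assigned gene) and, when an interaction grid exists, an image of the
#' vehicle-by-drug shape grid.
#'
#' @param x A `"chronopattern"` object.
#' @param which `"patterns"`, `"grid"` or both (default).
#' @param ... Passed to the underlying graphics calls.
#' @export
plot.chronopattern <- function(x, which = c("patterns", "grid"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if ("patterns" %in% which && !is.null(x$enrichment)) {
    e <- x$enrichment[x$enrichment$observed > 0, ]
    e <- utils::head(e[order(-e$observed), ], 20)
    graphics::barplot(e$observed, names.arg = e$pattern, las = 2,
                      col = ifelse(e$flagged, "firebrick", "grey70"),
                      ylab = "assigned DEGs",
                      main = "Temporal patterns (flagged in red)", ...)
    graphics::abline(h = e$expected[1], lty = 2)
  }
  if ("grid" %in% which && !is.null(x$grid)) {
    cnt <- x$grid$counts
    graphics::image(seq_len(nrow(cnt)), seq_len(ncol(cnt)),
                    log1p(cnt), axes = FALSE,
                    xlab = "vehicle shape", ylab = "drug shape",
                    main = "Interaction shape grid (log1p counts)", ...)
    graphics::axis(1, seq_len(nrow(cnt)), rownames(cnt), las = 2,
                   cex.axis = 0.6)
    graphics::axis(2, seq_len(ncol(cnt)), colnames(cnt), las = 2,
                   cex.axis = 0.6)
  }
  invisible(x)
}
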