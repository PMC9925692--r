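#' Trapezoid area under a lifespan viability curve
#'
#' Chronological-lifespan assays record percent viability per day; the
#' summary statistic per replicate culture is the trapezoid area under
#' that curve over the measured days (units: percent x days). No
#' extrapolation beyond the measured range is performed.
#'
#' @param day Strictly increasing numeric vector of days (>= 2 points).
#' @param viability Non-negative percent viability at each day.
#' @return The trapezoid area.
#' @examples
#' survival_auc(0:10, rep(100, 11))          # 1000
#' survival_auc(c(3, 5, 8), c(100, 50, 10))  # 240
#' @export
survival_auc <- function(day, viability) {
  if (length(day) != length(viability))
    stop("day and viability lengths differ")
  if (length(day) < 2) stop("need at least 2 measured days")
  if (any(diff(day) <= 0)) stop("days must be strictly increasing")
  if (any(viability < 0)) stop("viability must be non-negative")
  pracma::trapz(day, viability)
}

#' Per-replicate AUCs of grouped lifespan curves
#'
#' @param curves data.frame with columns `group`, `replicate`, `day`,
#'   `viability` (long format, one row per measurement).
#' @return data.frame with one row per (group, replicate) and its `auc`.
#' @export
cls_auc <- function(curves) {
  req <- c("group", "replicate", "day", "viability")
  miss <- setdiff(req, names(curves))
  if (length(miss)) stop("curves missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- interaction(curves$group, curves$replicate, drop = TRUE)
  rows <- lapply(split(curves, key), function(d) {
    d <- d[order(d$day), ]
    data.frame(group = d$group[1], replicate = d$replicate[1],
               auc = survival_auc(d$day, d$viability),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$replicate), ]
}

#' Two-sample comparison of lifespan AUCs
#'
#' Two-tailed pooled-variance (Student) t-test of per-replicate AUCs
#' between two groups, with a confidence interval for the difference of
#' means (group A minus group B). Welch's unequal-variance form is
#' available via `var_equal = FALSE`. When the pooled variance is exactly
#' zero the result is flagged degenerate: the interval collapses to the
#' observed difference, and p is 1 for a zero difference.
#'
#' @param auc_a,auc_b Numeric vectors of replicate AUCs (>= 2 each).
#' @param conf Confidence level, default 0.95.
#' @param var_equal Pooled-variance t when `TRUE` (default), Welch
#'   otherwise.
#' @return Object of class `"auc_test"`: list with `mean_a`, `mean_b`,
#'   `difference`, `conf_int`, `t`, `df`, `p_value`, `n`, `conf_level`,
#'   `degenerate`, `method`.
#' @export
auc_difference_test <- function(auc_a, auc_b, conf = 0.95,
                                var_equal = TRUE) {
  if (length(auc_a) < 2 || length(auc_b) < 2)
    stop("each group needs >= 2 replicate AUCs")
  d <- mean(auc_a) - mean(auc_b)
  if (stats::var(auc_a) == 0 && stats::var(auc_b) == 0) {
    res <- list(mean_a = mean(auc_a), mean_b = mean(auc_b),
                difference = d, conf_int = c(d, d),
                t = NA_real_, df = NA_real_,
                p_value = if (d == 0) 1 else NA_real_,
                n = c(length(auc_a), length(auc_b)),
                conf_level = conf, degenerate = TRUE,
                method = "degenerate (zero within-group variance)")
    return(structure(res, class = "auc_test"))
  }
  tt <- stats::t.test(auc_a, auc_b, var.equal = var_equal,
                      conf.level = conf)
  structure(list(mean_a = mean(auc_a), mean_b = mean(auc_b),
                 difference = d, conf_int = as.numeric(tt$conf.int),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 n = c(length(auc_a), length(auc_b)),
                 conf_level = conf, degenerate = FALSE,
                 method = tt$method),
            class = "auc_test")
}

#' @export
print.auc_test <- function(x, ...) {
  cat("Lifespan AUC comparison (", x$method, ")\n", sep = "")
  cat(sprintf("  mean AUC: A = %.3f (n=%d), B = %.3f (n=%d)\n",
              x$mean_a, x$n[1], x$mean_b, x$n[2]))
  cat(sprintf("  difference A-B = %.3f, %d%% CI [%.3f, %.3f], p = %.4g\n",
              x$difference, round(100 * x$conf_level),
              x$conf_int[1], x$conf_int[2], x$p_value))
  invisible(x)
}

#' Compare two lifespan groups from a long-format curve table
#'
#' Convenience wrapper: computes per-replicate AUCs with [cls_auc()] and
#' runs [auc_difference_test()] between two named groups.
#'
#' @param curves Long-format data.frame (see [cls_auc()]).
#' @param group_a,group_b Group labels to compare.
#' @param ... Passed to [auc_difference_test()].
#' @return An `"auc_test"` object.
#' @export
cls_test <- function(curves, group_a, group_b, ...) {
  aucs <- cls_auc(curves)
  a <- aucs$auc[aucs$group == group_a]
  b <- aucs$auc[aucs$group == group_b]
  if (length(a) == 0) stop("no curves for group '", group_a, "'")
  if (length(b) == 0) stop("no curves for group '", group_b, "'")
  auc_difference_test(a, b, ...)
}
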