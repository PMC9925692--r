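#' Expression matrix with sample design
#'
#' Light container pairing a gene-by-sample abundance matrix with its sample
#' design (condition, timepoint in hours, replicate) and a scale tag. This is
#' the object every analysis stage consumes and returns.
#'
#' @param values Numeric matrix, genes in rows (unique rownames required),
#'   samples in columns. Values must be non-negative unless `scale = "log2"`.
#' @param design Data frame with one row per column of `values` and columns
#'   `sample_id`, `condition` (`"vehicle"` or `"drug"`), `timepoint` (hours,
#'   numeric) and `replicate`.
#' @param scale One of `"counts"`, `"tpm"`, `"abundance"` (linear TPM-like
#'   values that need not sum to one million) or `"log2"`.
#' @return An object of class `"expr_set"`: a list with elements `values`,
#'   `design` and `scale`.
#' @examples
#' d <- data.frame(sample_id = c("s1", "s2"),
#'                 condition = c("vehicle", "drug"),
#'                 timepoint = c(1, 1), replicate = c(1, 1))
#' m <- matrix(1:4, 2, dimnames = list(c("gA", "gB"), d$sample_id))
#' expr_set(m, d, scale = "counts")
#' @export
expr_set <- function(values, design,
                     scale = c("counts", "tpm", "abundance", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must have gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("gene ids must be unique")
  if (scale != "log2" && any(values < 0, na.rm = TRUE))
    stop("negative abundance values are not allowed on scale '", scale, "'")
  design <- as.data.frame(design)
  req <- c("sample_id", "condition", "timepoint", "replicate")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(design) != ncol(values))
    stop("design has ", nrow(design), " rows but matrix has ",
         ncol(values), " columns")
  if (any(is.na(design[req])))
    stop("design fields must be complete (no NA)")
  bad <- setdiff(unique(design$condition), c("vehicle", "drug"))
  if (length(bad))
    stop("condition must be 'vehicle' or 'drug'; found: ",
         paste(bad, collapse = ", "))
  design$timepoint <- as.numeric(design$timepoint)
  if (is.null(colnames(values))) colnames(values) <- design$sample_id
  if (scale == "tpm") {
    cs <- colSums(values)
    off <- abs(cs - 1e6) / 1e6
    if (any(off > 1e-6))
      stop("scale 'tpm' requires column sums of 1e6; worst relative ",
           "deviation ", format(max(off)))
  }
  structure(list(values = values, design = design, scale = scale),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$scale, "]\n", sep = "")
  cat("  conditions: ", paste(sort(unique(x$design$condition)), collapse = ", "),
      "; timepoints (h): ", paste(sort(unique(x$design$timepoint)), collapse = ", "),
      "; replicates: ", length(unique(x$design$replicate)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Read an expression matrix and sample sheet from TSV
#'
#' The matrix file has gene ids in the first column and sample ids in the
#' header; the sample sheet has columns `sample_id`, `condition`,
#' `timepoint` (or `timepoint_h`) and `replicate`.
#'
#' @param matrix_file Path to the gene x sample TSV.
#' @param samples_file Path to the sample sheet TSV.
#' @param scale Scale tag of the stored values (see [expr_set()]).
#' @return An [expr_set()].
#' @export
read_expr_set <- function(matrix_file, samples_file, scale = "counts") {
  tab <- utils::read.delim(matrix_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  design <- utils::read.delim(samples_file, stringsAsFactors = FALSE)
  if ("timepoint_h" %in% names(design) && !"timepoint" %in% names(design))
    names(design)[names(design) == "timepoint_h"] <- "timepoint"
  m <- m[, design$sample_id, drop = FALSE]
  expr_set(m, design, scale = scale)
}

#' Write an expression matrix and sample sheet as TSV
#'
#' @param x An [expr_set()].
#' @param matrix_file,samples_file Output paths.
#' @return Invisibly, `x`.
#' @export
write_expr_set <- function(x, matrix_file, samples_file) {
  stopifnot(inherits(x, "expr_set"))
  tab <- data.frame(gene = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- x$design
  names(out)[names(out) == "timepoint"] <- "timepoint_h"
  utils::write.table(out, samples_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' TPM normalization of a count matrix
#'
#' Per sample, each gene's count is first converted to a length-normalized
#' rate, `count / (length/1000)`, and rates are rescaled to sum to one
#' million: `TPM_g = rate_g / sum(rates) * 1e6`. Column sums of the result
#' are exactly one million up to floating point.
#'
#' @param x An [expr_set()] on the `"counts"` scale.
#' @param lengths Named numeric vector of effective gene lengths in bases
#'   (> 0); names must cover every gene in `x`.
#' @return An [expr_set()] on the `"tpm"` scale.
#' @examples
#' d <- data.frame(sample_id = "s1", condition = "vehicle",
#'                 timepoint = 1, replicate = 1)
#' m <- matrix(c(10, 90), 2, dimnames = list(c("gA", "gB"), "s1"))
#' tpm <- compute_tpm(expr_set(m, d), c(gA = 1000, gB = 3000))
#' tpm$values  # 250000 and 750000
#' @export
compute_tpm <- function(x, lengths) {
  stopifnot(inherits(x, "expr_set"))
  if (x$scale != "counts")
    stop("compute_tpm expects counts; got scale '", x$scale, "'")
  genes <- rownames(x$values)
  miss <- setdiff(genes, names(lengths))
  if (length(miss))
    stop("no length for gene(s): ", paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ..." else "")
  len <- lengths[genes]
  if (any(len <= 0)) stop("gene lengths must be positive")
  rate <- x$values / (len / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    bad <- colnames(x$values)[tot == 0][1]
    stop("sample '", bad, "' has zero total rate; TPM undefined")
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  expr_set(tpm, x$design, scale = "tpm")
}

#' Filter genes on annotation and expression
#'
#' Retains genes that (a) carry a unique symbol annotation, when a symbol
#' map is supplied, and (b) are non-zero in at least `min_expressed_frac`
#' of samples and have mean abundance at least `min_mean`. Genes whose
#' symbol is shared with another gene are dropped on both sides (strict
#' uniqueness). A per-criterion removal report is attached as attribute
#' `"filter_report"` and emitted as a message.
#'
#' @param x An [expr_set()].
#' @param symbols Optional named character vector mapping gene id to symbol;
#'   genes absent from the map (or with `NA`/empty symbols) count as
#'   unannotated. `NULL` skips the annotation criterion.
#' @param min_expressed_frac Minimum fraction of samples with non-zero
#'   abundance (default 0.5).
#' @param min_mean Minimum mean abundance (default 1, TPM units).
#' @return The filtered [expr_set()], with attribute `"filter_report"`.
#' @export
filter_genes <- function(x, symbols = NULL, min_expressed_frac = 0.5,
                         min_mean = 1) {
  stopifnot(inherits(x, "expr_set"))
  if (nrow(x$values) == 0) stop("empty expression matrix")
  genes <- rownames(x$values)
  n <- ncol(x$values)
  keep_ann <- rep(TRUE, length(genes))
  if (!is.null(symbols)) {
    sym <- symbols[genes]
    has <- !is.na(sym) & nzchar(sym)
    dup_sym <- sym %in% sym[duplicated(sym) & !is.na(sym)]
    keep_ann <- has & !dup_sym
  }
  frac_nz <- rowMeans(x$values != 0)
  mu <- rowMeans(x$values)
  keep_expr <- frac_nz >= min_expressed_frac & mu >= min_mean
  keep <- keep_ann & keep_expr
  report <- c(n_in = length(genes),
              removed_annotation = sum(!keep_ann),
              removed_expression = sum(keep_ann & !keep_expr),
              n_out = sum(keep))
  if (!any(keep))
    stop("filter removed every gene; relax min_expressed_frac/min_mean")
  message("filter_genes: kept ", report["n_out"], "/", report["n_in"],
          " (", report["removed_annotation"], " failed annotation, ",
          report["removed_expression"], " failed expression)")
  out <- expr_set(x$values[keep, , drop = FALSE], x$design, scale = x$scale)
  attr(out, "filter_report") <- report
  out
}

#' Log2 transform of an abundance matrix
#'
#' @param x An [expr_set()] on a linear scale.
#' @param offset Pseudo-value added before taking logs (default 1,
#'   guarding zeros).
#' @return An [expr_set()] on the `"log2"` scale.
#' @export
log_transform <- function(x, offset = 1) {
  stopifnot(inherits(x, "expr_set"))
  if (x$scale == "log2") return(x)
  expr_set(log2(x$values + offset), x$design, scale = "log2")
}
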