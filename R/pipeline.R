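#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Recognized keys:
#' paths `matrix`, `samples`, `lengths`, `gmt`, `out_dir`; `scale`
#' (`counts`/`tpm`/`abundance`); numeric thresholds `alpha`, `r_min`,
#' `lsd_alpha`, `flag_threshold`, `min_expressed_frac`, `min_mean`,
#' `log_offset`; `timepoints` (comma-separated hours); `filter`
#' (true/false); `seed`.
#'
#' @param path Path to the config file.
#' @return Named list with numerics coerced.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 2L))
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  cfg <- as.list(vals)
  names(cfg) <- keys
  for (k in intersect(names(cfg),
                      c("alpha", "r_min", "lsd_alpha", "flag_threshold",
                        "min_expressed_frac", "min_mean", "log_offset",
                        "seed")))
    cfg[[k]] <- as.numeric(cfg[[k]])
  if ("timepoints" %in% names(cfg))
    cfg$timepoints <- as.numeric(strsplit(cfg$timepoints, ",")[[1]])
  if ("filter" %in% names(cfg))
    cfg$filter <- tolower(cfg$filter) %in% c("true", "1", "yes")
  cfg
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline from files to files
#'
#' Executes normalize, filter, ANOVA, Euler sectors, template assignment,
#' template enrichment, interaction grid + per-timepoint LSD, and ORA,
#' writing each stage's table as TSV into `out_dir` together with a
#' machine-readable JSON run summary. Identical inputs and config yield
#' byte-identical outputs. A failing stage aborts with the stage name and
#' cause.
#'
#' @param config Path to a flat key=value config file (see
#'   [read_run_config()]) or an equivalent named list.
#' @return Invisibly, the run summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  getd <- function(k, d) if (!is.null(config[[k]])) config[[k]] else d
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  out_dir <- getd("out_dir", ".")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  x <- stage("read", {
    if (is.null(config$matrix) || is.null(config$samples))
      stop("config must provide 'matrix' and 'samples' paths")
    read_expr_set(config$matrix, config$samples,
                  scale = getd("scale", "counts"))
  })
  lengths <- NULL
  if (!is.null(config$lengths))
    lengths <- stage("read", {
      lt <- utils::read.delim(config$lengths, stringsAsFactors = FALSE)
      stats::setNames(lt[[2]], lt[[1]])
    })
  genesets <- NULL
  if (!is.null(config$gmt))
    genesets <- stage("read", read_gmt(config$gmt))

  fit <- stage("analysis", chronopattern(
    x, lengths = lengths, genesets = genesets,
    alpha = getd("alpha", 0.01), r_min = getd("r_min", 0.85),
    lsd_alpha = getd("lsd_alpha", 0.05),
    flag_threshold = getd("flag_threshold", 100),
    min_expressed_frac = getd("min_expressed_frac", 0.5),
    min_mean = getd("min_mean", 1), filter = getd("filter", TRUE),
    log_offset = getd("log_offset", 1),
    timepoints = getd("timepoints", NULL)))

  stage("write", {
    write_expr_set(fit$data, file.path(out_dir, "matrix_analyzed.tsv"),
                   file.path(out_dir, "samples.tsv"))
    atab <- fit$anova$table
    atab$sector <- unname(fit$sectors[atab$gene])
    .write_tsv(atab[, c("gene", "p_time", "p_drug", "p_interaction",
                        "F_time", "F_drug", "F_interaction", "sector")],
               file.path(out_dir, "anova.tsv"))
    if (!is.null(fit$assignments))
      .write_tsv(fit$assignments, file.path(out_dir, "assignments.tsv"))
    if (!is.null(fit$enrichment))
      .write_tsv(fit$enrichment, file.path(out_dir, "template_enrichment.tsv"))
    if (!is.null(fit$grid)) {
      g <- data.frame(vehicle_shape = rownames(fit$grid$counts),
                      fit$grid$counts, check.names = FALSE)
      .write_tsv(g, file.path(out_dir, "interaction_grid.tsv"))
      mem <- data.frame(
        cell = rep(names(fit$grid$members), lengths(fit$grid$members)),
        gene = unlist(fit$grid$members, use.names = FALSE))
      .write_tsv(mem, file.path(out_dir, "interaction_members.tsv"))
    }
    if (!is.null(fit$lsd))
      .write_tsv(fit$lsd, file.path(out_dir, "timepoint_lsd.tsv"))
    if (!is.null(fit$ora))
      for (nm in names(fit$ora))
        .write_tsv(fit$ora[[nm]],
                   file.path(out_dir, paste0(
                     "ora_", gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv")))
  })

  s <- summary(fit)
  summary_list <- list(
    n_genes = s$n_genes, n_deg = s$n_deg,
    sector_counts = as.list(s$sector_counts),
    n_assigned = s$n_assigned, pct_assigned = s$pct_assigned,
    flagged_patterns = as.list(s$flagged_patterns),
    flagged_grid_cells = if (nrow(s$flagged_cells))
      paste0(s$flagged_cells$veh_shape, "|", s$flagged_cells$drug_shape)
    else list(),
    params = s$params)
  stage("write", jsonlite::write_json(
    summary_list, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA))
  invisible(summary_list)
}
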