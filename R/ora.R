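#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated — set name, description,
#' then member gene ids.
#'
#' @param file Path to a GMT file.
#' @return Named list of character vectors; descriptions kept as the
#'   `"description"` attribute.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT line(s): ", paste(utils::head(bad, 5), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param file Output path.
#' @param description Per-set description column; recycled (default `"na"`).
#' @export
write_gmt <- function(sets, file, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), description, sets)
  writeLines(lines, file)
  invisible(file)
}

#' Sig/Exp enrichment ratio
#'
#' @param sig Observed overlap count.
#' @param expected Expected overlap under the hypergeometric null.
#' @return `sig / expected` (0 when both are 0).
#' @export
ora_ratio <- function(sig, expected) {
  ifelse(expected == 0, ifelse(sig == 0, 0, Inf), sig / expected)
}

#' Hypergeometric overrepresentation analysis
#'
#' Tests a query gene list against each set of a collection for
#' overrepresentation. With universe size N, set size Tot and query size
#' n, the p-value is the exact upper hypergeometric tail
#' P(X >= Sig); expected overlap is `Exp = n * Tot / N` and the reported
#' ratio is `Sig / Exp`. BH correction is applied across tested sets.
#'
#' The universe defaults to the genes annotated to at least one set; a
#' user-supplied background (`universe`) is used as-is, with sets and
#' query restricted to it. Query genes outside the universe are dropped
#' with a message.
#'
#' @param query Character vector of gene ids.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Optional background gene ids (e.g. all filtered genes).
#' @param min_set,max_set Size bounds (after universe restriction) for a
#'   set to be tested; defaults 10 and 2000.
#' @return data.frame sorted by `p`: `set`, `tot`, `sig`, `exp`, `ratio`,
#'   `p`, `fdr`.
#' @export
run_ora <- function(query, sets, universe = NULL,
                    min_set = 10, max_set = 2000) {
  if (length(sets) == 0) stop("empty gene-set collection")
  uni <- if (is.null(universe))
    unique(unlist(sets, use.names = FALSE)) else unique(universe)
  if (length(uni) == 0) stop("empty universe after restriction")
  sets <- lapply(sets, intersect, uni)
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_set & sizes <= max_set]
  if (length(sets) == 0)
    stop("no gene set within size bounds [", min_set, ", ", max_set, "]")
  q0 <- unique(query)
  q <- intersect(q0, uni)
  dropped <- length(q0) - length(q)
  if (dropped > 0)
    message("run_ora: dropped ", dropped, " query gene(s) outside the universe")
  if (length(q) == 0) stop("empty query after restriction to the universe")
  N <- length(uni)
  n <- length(q)
  tot <- lengths(sets)
  sig <- vapply(sets, function(s) length(intersect(s, q)), integer(1))
  expd <- n * tot / N
  pv <- stats::phyper(sig - 1, tot, N - tot, n, lower.tail = FALSE)
  out <- data.frame(set = names(sets), tot = unname(tot),
                    sig = unname(sig), exp = unname(expd),
                    ratio = unname(ora_ratio(sig, expd)),
                    p = unname(pv), fdr = bh_adjust(unname(pv)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$set), ]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#' Thin validated front end over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (q-values), same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
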