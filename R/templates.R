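#' Build the canonical temporal template library
#'
#' Constructs the library of canonical temporal shapes over an ordered set
#' of timepoints and crosses them with the three drug-effect classes
#' (`up`, `down`, `nc`). For the default 6-timepoint design this yields 21
#' shapes — the flat shape `00` plus ten base shapes each in two vertical
#' reflections (`a` and `b = -a`) — and hence 63 patterns:
#' \itemize{
#'   \item `01`: change confined to the first timepoint;
#'   \item `02`–`04`: plateaus reached at successive intermediate
#'     timepoints, rising through a half-step onset (the soft onset keeps
#'     all shapes pairwise distinguishable under Pearson correlation);
#'   \item `05`: change confined to the last timepoint;
#'   \item `06`–`09`: single-timepoint spikes at the interior timepoints;
#'   \item `10`: linear change with time.
#' }
#' For general T (>= 3) the same families are generated: one first-point
#' and one last-point shape, T-3 plateaus, T-2 interior spikes and one
#' linear shape, i.e. 4T-3 shapes and 3(4T-3) patterns. Pearson matching
#' is invariant to affine rescaling of these vectors, so only their shape
#' matters.
#'
#' @param timepoints Ordered vector of timepoint labels (hours); default
#'   `1:6`. Only its length and order are used.
#' @return Object of class `"template_library"`: a list with
#'   `shapes` (shape-code x T matrix of template vectors), `codes`,
#'   `base_codes` (the non-flat base codes, `a` orientation),
#'   `classes` (`c("up","down","nc")`), `patterns` (data.frame of all
#'   shape x class combinations with a `pattern` id such as `"04a(up)"`)
#'   and `timepoints`.
#' @examples
#' lib <- build_template_library(1:6)
#' nrow(lib$shapes)      # 21 shapes
#' nrow(lib$patterns)    # 63 patterns
#' @export
build_template_library <- function(timepoints = 1:6) {
  Tn <- length(timepoints)
  if (Tn < 3)
    stop("at least 3 timepoints are required to define temporal shapes")
  spike <- function(i) {v <- numeric(Tn); v[i] <- 1; v}
  # plateau reached at position j+2 with a half-step onset at j+1; the
  # soft onset keeps every shape pairwise non-collinear under Pearson
  # (a hard step after position 1 would be the exact complement of the
  # first-point spike and thus indistinguishable from its reflection)
  plateau <- function(j) c(numeric(j), 0.5, rep(1, Tn - j - 1))
  base <- list(spike(1))                      # 01: first point
  if (Tn > 3) for (j in seq_len(Tn - 3)) base <- c(base, list(plateau(j)))
  base <- c(base, list(spike(Tn)))            # last point
  for (i in seq(2, Tn - 1)) base <- c(base, list(spike(i)))  # interior spikes
  base <- c(base, list(seq(0, Tn - 1) / (Tn - 1)))           # linear
  base_codes <- sprintf("%02d", seq_along(base))
  shapes <- matrix(0, nrow = 1 + 2 * length(base), ncol = Tn)
  codes <- character(nrow(shapes))
  codes[1] <- "00"
  k <- 1
  for (i in seq_along(base)) {
    shapes[k + 1, ] <- base[[i]];  codes[k + 1] <- paste0(base_codes[i], "a")
    shapes[k + 2, ] <- -base[[i]]; codes[k + 2] <- paste0(base_codes[i], "b")
    k <- k + 2
  }
  rownames(shapes) <- codes
  colnames(shapes) <- as.character(timepoints)
  classes <- c("up", "down", "nc")
  patterns <- expand.grid(shape = codes, class = classes,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  patterns$pattern <- paste0(patterns$shape, "(", patterns$class, ")")
  structure(list(shapes = shapes, codes = codes, base_codes = base_codes,
                 classes = classes, patterns = patterns,
                 timepoints = timepoints),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat("template_library: ", nrow(x$shapes), " temporal shapes x ",
      length(x$classes), " drug classes = ", nrow(x$patterns),
      " patterns over ", length(x$timepoints), " timepoints\n", sep = "")
  invisible(x)
}

# z-standardize rows of a profile matrix; zero-variance rows -> NA rows
.standardize_rows <- function(P) {
  mu <- rowMeans(P)
  sdv <- apply(P, 1, stats::sd)
  Z <- (P - mu) / sdv
  Z[sdv == 0, ] <- NA_real_
  list(z = Z, flat = sdv == 0)
}

#' Assign temporal profiles to their best-fitting template
#'
#' Computes the Pearson correlation of each standardized timepoint-mean
#' profile against every non-flat template of the library and assigns the
#' shape with the highest correlation, provided it exceeds `r_min`
#' (strictly). Reflected (`b`) shapes are the negated `a` vectors, so
#' their correlation is the negated `a` correlation. Ties are broken by
#' the lexicographically lowest shape code. Profiles with zero variance
#' are routed to the flat shape `00` directly (Pearson correlation with a
#' constant is undefined); their `r` is reported as `NA`.
#'
#' @param profiles Numeric matrix (genes x timepoints) of timepoint means,
#'   or a single profile vector. Standardization is internal, so any
#'   affine scaling of a profile gives the same assignment.
#' @param lib A [build_template_library()] object.
#' @param r_min Correlation threshold, default 0.85; assignments require
#'   `r > r_min`.
#' @return data.frame with columns `gene`, `shape` (`NA` when unassigned)
#'   and `r` (the best correlation over all non-flat shapes; `NA` for
#'   flat profiles).
#' @export
assign_template <- function(profiles, lib, r_min = 0.85) {
  stopifnot(inherits(lib, "template_library"))
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, nrow = 1,
                       dimnames = list("profile", NULL))
  Tn <- ncol(lib$shapes)
  if (ncol(profiles) != Tn)
    stop("profiles have ", ncol(profiles), " timepoints; library has ", Tn)
  if (any(!is.finite(profiles)))
    stop("profiles must be finite")
  a_codes <- grep("a$", rownames(lib$shapes), value = TRUE)
  A <- lib$shapes[a_codes, , drop = FALSE]
  Az <- t(apply(A, 1, function(v) (v - mean(v)) / stats::sd(v)))
  st <- .standardize_rows(profiles)
  # Pearson r = sum(z_x * z_y) / (T - 1)
  R <- st$z %*% t(Az) / (Tn - 1)
  # full candidate matrix in code order: 01a, 01b, 02a, 02b, ...
  cand_codes <- as.vector(rbind(a_codes, sub("a$", "b", a_codes)))
  Rfull <- matrix(NA_real_, nrow(profiles), length(cand_codes),
                  dimnames = list(rownames(profiles), cand_codes))
  Rfull[, a_codes] <- R
  Rfull[, sub("a$", "b", a_codes)] <- -R
  Rfull <- Rfull[, sort(cand_codes), drop = FALSE]  # lowest-code tie-break
  best_j <- apply(Rfull, 1, function(z) if (all(is.na(z))) NA_integer_
                  else which.max(z))
  best_r <- Rfull[cbind(seq_len(nrow(Rfull)), best_j)]
  shape <- colnames(Rfull)[best_j]
  shape[!is.na(best_r) & best_r <= r_min] <- NA_character_
  shape[st$flat] <- "00"
  best_r[st$flat] <- NA_real_
  data.frame(gene = rownames(profiles), shape = shape, r = best_r,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify each gene's overall drug effect
#'
#' A gene is `"nc"` (not changed by the drug) when its drug main-effect
#' p-value exceeds `alpha`; otherwise `"up"` or `"down"` according to
#' whether the drug-condition grand mean exceeds the vehicle grand mean.
#' The degenerate case of a significant drug term with exactly equal
#' grand means resolves to `"nc"` with a warning.
#'
#' @param fit A `"chrono_anova"` object.
#' @param alpha Threshold on the drug main-effect p-value, default 0.01.
#' @return Character vector (`"up"`, `"down"`, `"nc"`), named by gene.
#' @export
classify_drug_effect <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "chrono_anova"))
  M <- fit$cell_means
  Tn <- length(fit$timepoints)
  idx <- matrix(seq_len(2 * Tn), nrow = 2)  # row 1 vehicle, row 2 drug
  mv <- rowMeans(M[, idx[1, ], drop = FALSE])
  md <- rowMeans(M[, idx[2, ], drop = FALSE])
  cls <- ifelse(fit$table$p_drug > alpha, "nc",
                ifelse(md > mv, "up", ifelse(md < mv, "down", "nc")))
  tie <- fit$table$p_drug <= alpha & md == mv
  if (any(tie))
    warning(sum(tie), " gene(s) significant for drug with exactly equal ",
            "grand means; classified 'nc'")
  names(cls) <- fit$table$gene
  cls
}

#' Binomial test for over-assigned templates
#'
#' Under a uniform null each assigned gene falls into any of the library's
#' patterns with probability 1/63 (1 over the number of patterns). For
#' each pattern the observed count is compared to Binomial(n_assigned,
#' 1/n_patterns) with a one-sided upper-tail test; patterns with
#' `p <= alpha` are flagged as containing more genes than expected by
#' chance.
#'
#' @param assignments data.frame with a `pattern` column (`NA` for
#'   unassigned genes), as returned by [assign_patterns()].
#' @param lib A [build_template_library()] object.
#' @param alpha Flagging threshold, default 0.01.
#' @return data.frame with one row per library pattern: `pattern`,
#'   `observed`, `expected`, `p` and `flagged`, sorted by `p`.
#' @export
template_enrichment <- function(assignments, lib, alpha = 0.01) {
  stopifnot(inherits(lib, "template_library"))
  assigned <- assignments$pattern[!is.na(assignments$pattern)]
  n <- length(assigned)
  if (n == 0) stop("no assigned genes; enrichment undefined")
  pats <- lib$patterns$pattern
  obs <- table(factor(assigned, levels = pats))
  p0 <- 1 / length(pats)
  pv <- stats::pbinom(as.integer(obs) - 1L, n, p0, lower.tail = FALSE)
  out <- data.frame(pattern = pats, observed = as.integer(obs),
                    expected = n * p0, p = pv,
                    flagged = pv <= alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, -out$observed, out$pattern), ]
}

#' Assign DEGs to temporal patterns (shape x drug class)
#'
#' The pattern-assignment stage for genes significant by Time, Drug or
#' both (interaction-significant genes are handled by the pattern grid
#' instead, see [build_interaction_grid()]). Each gene's profile is its
#' per-timepoint mean over replicates and both conditions, z-standardized,
#' matched to the template library; genes in the Drug-only sector carry no
#' temporal signal by construction and are routed to shape `00`. The drug
#' class comes from [classify_drug_effect()].
#'
#' @param fit A `"chrono_anova"` object.
#' @param lib A [build_template_library()] over the fit's timepoints.
#' @param sectors Sector labels from [classify_euler_sector()]; computed
#'   at `alpha` when missing.
#' @param alpha Gate threshold, default 0.01.
#' @param r_min Assignment threshold passed to [assign_template()].
#' @param include Sectors whose genes enter assignment; default the
#'   Time/Drug sectors excluding any interaction-significant gene.
#' @return data.frame: `gene`, `sector`, `shape`, `r`, `class`, `pattern`
#'   (`NA` pattern when the shape is unassigned).
#' @export
assign_patterns <- function(fit, lib, sectors = NULL, alpha = 0.01,
                            r_min = 0.85,
                            include = c("T", "D", "T&D")) {
  stopifnot(inherits(fit, "chrono_anova"), inherits(lib, "template_library"))
  if (is.null(sectors)) sectors <- classify_euler_sector(fit, alpha)
  sel <- sectors %in% include
  if (!any(sel)) stop("no genes in sectors ", paste(include, collapse = ", "))
  genes <- fit$table$gene[sel]
  M <- fit$cell_means[sel, , drop = FALSE]
  Tn <- length(fit$timepoints)
  idx <- matrix(seq_len(2 * Tn), nrow = 2)
  # pooled profile: mean of vehicle and drug cell means per timepoint
  P <- (M[, idx[1, ], drop = FALSE] + M[, idx[2, ], drop = FALSE]) / 2
  rownames(P) <- genes
  asg <- assign_template(P, lib, r_min = r_min)
  # drug-only genes: no temporal term -> flat shape by definition
  d_only <- sectors[sel] == "D"
  asg$shape[d_only] <- "00"
  asg$r[d_only] <- NA_real_
  cls <- classify_drug_effect(fit, alpha)[sel]
  out <- data.frame(gene = genes, sector = unname(sectors[sel]),
                    shape = asg$shape, r = asg$r, class = unname(cls),
                    stringsAsFactors = FALSE)
  out$pattern <- ifelse(is.na(out$shape), NA_character_,
                        paste0(out$shape, "(", out$class, ")"))
  out
}
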