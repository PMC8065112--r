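#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value under the probability-mass convention: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table. A table
#' with a zero margin carries no information; p = 1 is returned with a
#' warning.
#'
#' @param table 2x2 matrix (or coercible) of non-negative integer counts.
#' @return List with `p_value`, `odds_ratio` (conditional MLE) and `table`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(77, 188, 100, 435), 2, byrow = TRUE))$p_value
fisher_exact_2x2 <- function(table) {
  tab <- matrix(as.numeric(table), 2, 2)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: Fisher test uninformative, p = 1")
    return(list(p_value = 1, odds_ratio = NA_real_, table = tab))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(
    p_value = ft$p.value,
    odds_ratio = unname(ft$estimate),
    table = tab
  )
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected by default: the Yates continuity correction is off unless
#' requested, matching the group-wise convention used for the clinical
#' association tables.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param continuity_correction Apply the Yates correction.
#' @return List with `statistic` (X-squared, 1 df) and `p_value`.
#' @export
#' @examples
#' chi2_2x2(matrix(c(3, 38, 8, 24), 2, byrow = TRUE))
chi2_2x2 <- function(table, continuity_correction = FALSE) {
  tab <- matrix(as.numeric(table), 2, 2)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: chi-squared test undefined")
  }
  ct <- suppressWarnings(
    stats::chisq.test(tab, correct = continuity_correction)
  )
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order preserved, `NA`s
#' passed through.
#'
#' @param p_values Numeric vector of p-values in [0,1].
#' @return q-values in the same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must be in [0,1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

.presence_matrix <- function(cohort, pathogenic_only = TRUE) {
  v <- cohort$variants
  if (pathogenic_only) {
    if (is.null(v$pathogenic)) stop("run classify_pathogenic() first")
    v <- v[v$pathogenic, , drop = FALSE]
  }
  pats <- cohort$clinical$patient_id
  genes <- sort(unique(v$gene))
  m <- matrix(FALSE, length(pats), length(genes),
    dimnames = list(pats, genes)
  )
  if (nrow(v)) {
    idx <- cbind(match(v$patient_id, pats), match(v$gene, genes))
    m[idx] <- TRUE
  }
  m
}

#' Pairwise co-occurrence / mutual-exclusivity matrix
#'
#' Tests every unordered pair of qualifying genes (altered in at least
#' `min_incidence` of patients) for co-occurrence or mutual exclusivity of
#' pathogenic alterations with a two-sided Fisher test, BH-corrected across
#' all pairs. Direction is taken from the odds ratio: above 1 co-occurrent,
#' below 1 mutually exclusive.
#'
#' @param cohort A [ctdna_cohort()] with pathogenicity annotated.
#' @param min_incidence Minimum alteration incidence (fraction of cohort)
#'   for a gene to enter the matrix.
#' @return data.frame (gene_a, gene_b, a, b, c, d, odds_ratio, p_value,
#'   q_value, direction) where `a` counts patients altered in both genes,
#'   `b`/`c` one gene only, `d` neither.
#' @export
cooccurrence_matrix <- function(cohort, min_incidence = 0.05) {
  m <- .presence_matrix(cohort)
  inc <- colMeans(m)
  genes <- names(inc)[inc >= min_incidence]
  if (length(genes) < 2) {
    stop("fewer than 2 genes pass the incidence threshold")
  }
  pairs <- utils::combn(genes, 2)
  res <- apply(pairs, 2, function(gp) {
    x <- m[, gp[1]]
    y <- m[, gp[2]]
    tab <- matrix(
      c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)), 2,
      byrow = TRUE
    )
    ft <- fisher_exact_2x2(tab)
    data.frame(
      gene_a = gp[1], gene_b = gp[2],
      a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
      odds_ratio = ft$odds_ratio, p_value = ft$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out$direction <- ifelse(
    is.na(out$odds_ratio) | out$odds_ratio == 1, "none",
    ifelse(out$odds_ratio > 1, "co-occurrent", "mutually exclusive")
  )
  out
}

#' Association of a gene's alterations with a clinical grouping
#'
#' Cross-tabulates pathogenic alteration in `gene` against a categorical
#' clinical covariate. With more than two levels, a group-wise uncorrected
#' chi-squared test is reported alongside pairwise two-sided Fisher tests
#' between levels (BH-corrected within this analysis family); with two
#' levels the Fisher test alone. Levels with zero patients are dropped with
#' a warning.
#'
#' @param cohort A [ctdna_cohort()] with pathogenicity annotated.
#' @param gene Gene symbol.
#' @param grouping Name of a clinical column (e.g. `"subtype"`), or a vector
#'   of group labels aligned with the clinical table.
#' @return List with `counts` (data.frame level, altered, unaltered),
#'   `groupwise` (chi-squared statistic + p over all levels, NA with two
#'   levels' Fisher only), and `pairwise` (data.frame level_a, level_b, a,
#'   b, c, d, p_value, q_value).
#' @export
group_association <- function(cohort, gene, grouping) {
  m <- .presence_matrix(cohort)
  if (!gene %in% colnames(m)) {
    stop("gene ", gene, " has no pathogenic alterations in the cohort")
  }
  altered <- m[, gene]
  g <- if (is.character(grouping) && length(grouping) == 1) {
    if (!grouping %in% names(cohort$clinical)) {
      stop("clinical covariate not found: ", grouping)
    }
    cohort$clinical[[grouping]]
  } else {
    grouping
  }
  g <- as.character(g)
  keep <- !is.na(g)
  g <- g[keep]
  altered <- altered[keep]
  lv <- names(which(table(g) > 0))
  if (length(lv) < 2) stop("fewer than 2 non-empty levels")
  counts <- data.frame(
    level = lv,
    altered = vapply(lv, function(l) sum(altered[g == l]), numeric(1)),
    unaltered = vapply(lv, function(l) sum(!altered[g == l]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(counts) <- NULL
  groupwise <- if (length(lv) > 2) {
    tab <- t(as.matrix(counts[, c("altered", "unaltered")]))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p_value = ct$p.value)
  } else {
    list(statistic = NA_real_, p_value = NA_real_)
  }
  pw <- utils::combn(lv, 2)
  pairwise <- apply(pw, 2, function(lp) {
    tab <- as.matrix(counts[match(lp, counts$level), c("altered", "unaltered")])
    ft <- fisher_exact_2x2(tab)
    data.frame(
      level_a = lp[1], level_b = lp[2],
      a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
      p_value = ft$p_value, stringsAsFactors = FALSE
    )
  })
  pairwise <- do.call(rbind, pairwise)
  pairwise$q_value <- bh_adjust(pairwise$p_value)
  list(counts = counts, groupwise = groupwise, pairwise = pairwise)
}

#' Write association results as a long-format TSV
#'
#' @param results data.frame of association rows (e.g. from
#'   [cooccurrence_matrix()]).
#' @param path Output path.
#' @param family Analysis-family label recorded in the first column.
#' @param metadata Optional `#`-header metadata.
#' @return Invisibly, `path`.
#' @export
write_associations <- function(results, path, family = "associations",
                               metadata = NULL) {
  out <- cbind(family = family, results)
  .write_tsv_meta(out, path, metadata)
  invisible(path)
}
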