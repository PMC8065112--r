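#' Maximum somatic VAF per patient
#'
#' The maximum variant allele frequency (mVAF) across a patient's retained
#' somatic calls, used as a proxy of ctDNA purity: under the assumption that
#' the top-VAF mutation is truncal (present in every cancer cell), it anchors
#' the cancer-fraction scale. Copy-number calls never enter the mVAF.
#'
#' @param cohort A [ctdna_cohort()], already germline-filtered.
#' @param pathogenic_only If `TRUE`, restrict to pathogenic calls. Default
#'   uses all retained somatic calls.
#' @return data.frame (patient_id, mvaf_pct); mvaf_pct is `NA` for patients
#'   with no (qualifying) variants.
#' @export
compute_mvaf <- function(cohort, pathogenic_only = FALSE) {
  v <- cohort$variants
  if (pathogenic_only) {
    if (is.null(v$pathogenic)) {
      stop("pathogenic_only = TRUE requires classify_pathogenic() first")
    }
    v <- v[v$pathogenic, , drop = FALSE]
  }
  mv <- tapply(v$vaf_pct, v$patient_id, max)
  out <- data.frame(
    patient_id = cohort$clinical$patient_id,
    mvaf_pct = as.numeric(mv[cohort$clinical$patient_id]),
    stringsAsFactors = FALSE
  )
  out
}

#' Annotate cancer fraction and clonal dominance
#'
#' For each variant, the cancer fraction (CF) is its VAF divided by the
#' patient's mVAF — a proxy for the fraction of tumour cells carrying the
#' mutation. Mutations with CF >= 0.5 are clonally dominant, CF < 0.5
#' subclonal. Patients with a single retained variant are not assessable:
#' with only one call the truncal anchor cannot be distinguished from a
#' subclone, so their annotations are `not_assessable` with CF `NA`.
#'
#' @param cohort A germline-filtered [ctdna_cohort()].
#' @param pathogenic_only Passed to [compute_mvaf()] for the mVAF anchor.
#' @return The cohort with variant columns `mvaf_pct`, `cancer_fraction` and
#'   `dominance` (`"dominant"`, `"subclonal"` or `"not_assessable"`) added.
#' @export
annotate_clonality <- function(cohort, pathogenic_only = FALSE) {
  v <- cohort$variants
  mv <- compute_mvaf(cohort, pathogenic_only = pathogenic_only)
  mvaf <- mv$mvaf_pct[match(v$patient_id, mv$patient_id)]
  n_per_pat <- table(v$patient_id)
  nvar <- as.integer(n_per_pat[v$patient_id])
  if (any(!is.na(mvaf) & mvaf == 0 & nvar > 0)) {
    stop("mVAF is 0 for a patient with variants present: inconsistent input")
  }
  cf <- ifelse(nvar >= 2, v$vaf_pct / mvaf, NA_real_)
  dominance <- rep("not_assessable", nrow(v))
  dominance[!is.na(cf) & cf >= 0.5] <- "dominant"
  dominance[!is.na(cf) & cf < 0.5] <- "subclonal"
  v$mvaf_pct <- mvaf
  v$cancer_fraction <- cf
  v$dominance <- dominance
  cohort$variants <- v
  cohort
}

.assessable <- function(cohort, pathogenic_only = TRUE) {
  v <- cohort$variants
  if (is.null(v$cancer_fraction)) {
    stop("run annotate_clonality() first")
  }
  if (pathogenic_only) {
    if (is.null(v$pathogenic)) stop("run classify_pathogenic() first")
    v <- v[v$pathogenic, , drop = FALSE]
  }
  v[!is.na(v$cancer_fraction), , drop = FALSE]
}

#' Gene-level clonal-dominance tests
#'
#' Compares each gene's cancer-fraction distribution against the cancer
#' fractions of all other genes with a two-sided rank-sum (Mann-Whitney)
#' test, with Benjamini-Hochberg correction across the tested genes. Each
#' mutation enters separately; no per-patient consensus is taken.
#'
#' @param cohort An annotated [ctdna_cohort()].
#' @param genes Genes to test; default all genes with at least `min_n`
#'   assessable mutations.
#' @param min_n Minimum assessable mutations for a gene to be tested.
#' @param pathogenic_only Restrict to pathogenic mutations (default).
#' @return data.frame (gene, n, mean_cf, n_dominant, n_subclonal, direction,
#'   p_value, q_value), ordered by mean_cf decreasing.
#' @export
gene_dominance_test <- function(cohort, genes = NULL, min_n = 1,
                                pathogenic_only = TRUE) {
  v <- .assessable(cohort, pathogenic_only)
  if (is.null(genes)) {
    tab <- table(v$gene)
    genes <- names(tab)[tab >= min_n]
  } else {
    missing_g <- setdiff(genes, v$gene)
    if (length(missing_g)) {
      stop(
        "gene(s) absent from cohort (no assessable mutations): ",
        paste(missing_g, collapse = ", ")
      )
    }
  }
  if (!length(genes)) stop("no genes to test")
  res <- lapply(genes, function(g) {
    in_g <- v$cancer_fraction[v$gene == g]
    rest <- v$cancer_fraction[v$gene != g]
    p <- if (length(rest)) {
      suppressWarnings(
        stats::wilcox.test(in_g, rest, alternative = "two.sided")$p.value
      )
    } else {
      NA_real_
    }
    data.frame(
      gene = g, n = length(in_g), mean_cf = mean(in_g),
      n_dominant = sum(in_g >= 0.5), n_subclonal = sum(in_g < 0.5),
      direction = if (!length(rest) || mean(in_g) >= mean(rest)) {
        "more dominant"
      } else {
        "more subclonal"
      },
      p_value = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out[order(-out$mean_cf), ]
}

#' Polyclonality summary per gene
#'
#' For each gene, counts carriers with exactly one versus two or more
#' pathogenic mutations in the gene, and compares the single/multiple split
#' against the aggregate of the remaining genes with a two-sided Fisher
#' test; BH correction across genes. Polyclonal (multiple) mutations in a
#' driver gene indicate independently evolved resistant clones.
#'
#' @param cohort A [ctdna_cohort()] with pathogenicity annotated.
#' @param genes Genes to summarise; default all genes with >= 1 carrier.
#' @param min_carriers Minimum carriers for a gene to be tested.
#' @return data.frame (gene, n_single, n_multiple, fraction_multiple,
#'   p_value, q_value).
#' @export
polyclonality_summary <- function(cohort, genes = NULL, min_carriers = 1) {
  v <- cohort$variants
  if (is.null(v$pathogenic)) stop("run classify_pathogenic() first")
  v <- v[v$pathogenic, , drop = FALSE]
  counts <- table(v$gene, v$patient_id)
  per_gene <- function(g) {
    x <- counts[g, ]
    c(single = sum(x == 1), multiple = sum(x >= 2))
  }
  all_genes <- rownames(counts)
  if (is.null(genes)) {
    carriers <- rowSums(counts > 0)
    genes <- all_genes[carriers >= min_carriers]
  }
  mat <- vapply(all_genes, per_gene, c(single = 0, multiple = 0))
  res <- lapply(genes, function(g) {
    rest <- rowSums(mat[, setdiff(all_genes, g), drop = FALSE])
    tab <- rbind(mat[, g], rest)
    p <- fisher_exact_2x2(tab)$p_value
    data.frame(
      gene = g, n_single = mat["single", g], n_multiple = mat["multiple", g],
      fraction_multiple = mat["multiple", g] / sum(mat[, g]),
      p_value = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Cancer-fraction variation across hotspots of a gene
#'
#' Within one gene, collects per-hotspot cancer-fraction distributions and
#' tests for variation across hotspots with a Kruskal-Wallis test. SNV
#' hotspots are included when they carry at least `min_count` mutations in
#' the data set; indels are always included.
#'
#' @param cohort An annotated [ctdna_cohort()].
#' @param gene Gene symbol.
#' @param min_count Minimum mutation count for SNV hotspot inclusion.
#' @param pathogenic_only Restrict to pathogenic mutations (default).
#' @return List with `cf_by_hotspot` (named list of CF vectors), `summary`
#'   (data.frame hotspot, n, mean_cf, is_indel) and `kruskal_p`.
#' @export
hotspot_cf_variation <- function(cohort, gene, min_count = 3,
                                 pathogenic_only = TRUE) {
  v <- .assessable(cohort, pathogenic_only)
  v <- v[v$gene == gene & v$protein_change != "", , drop = FALSE]
  if (!nrow(v)) stop("no assessable mutations for gene ", gene)
  is_indel <- nchar(v$ref) != nchar(v$alt) | v$ref == "-" | v$alt == "-" |
    v$variant_class %in% c("frameshift", "in-frame indel")
  tab <- table(v$protein_change)
  indel_hs <- unique(v$protein_change[is_indel])
  keep_hs <- union(names(tab)[tab >= min_count], indel_hs)
  v <- v[v$protein_change %in% keep_hs, , drop = FALSE]
  if (length(keep_hs) < 2) {
    stop("fewer than 2 included hotspots: variation test undefined")
  }
  cf_by <- split(v$cancer_fraction, v$protein_change)
  kw <- stats::kruskal.test(v$cancer_fraction, factor(v$protein_change))
  summ <- data.frame(
    hotspot = names(cf_by),
    n = vapply(cf_by, length, integer(1)),
    mean_cf = vapply(cf_by, mean, numeric(1)),
    is_indel = names(cf_by) %in% indel_hs,
    stringsAsFactors = FALSE
  )
  rownames(summ) <- NULL
  list(
    cf_by_hotspot = cf_by,
    summary = summ[order(-summ$mean_cf), ],
    kruskal_p = kw$p.value
  )
}

#' Cancer-fraction linkage of dual mutations in one gene
#'
#' Restricting to patients who carry a given anchor mutation plus at least
#' one other pathogenic mutation in the same gene, pairs the anchor's cancer
#' fraction with the co-occurring mutation's cancer fraction in each patient
#' and compares the two CF samples with a two-sided rank-sum test. When a
#' patient carries several partner mutations, each contributes one pair.
#'
#' @param cohort An annotated [ctdna_cohort()].
#' @param gene Gene symbol.
#' @param anchor_change Protein change of the anchor mutation (e.g.
#'   `"H1047R"`).
#' @return List with `pairs` (data.frame patient_id, anchor_cf, partner_cf,
#'   partner_change) and `p_value` (NA when no qualifying patients).
#' @export
dual_mutation_linkage <- function(cohort, gene, anchor_change) {
  v <- .assessable(cohort, pathogenic_only = TRUE)
  v <- v[v$gene == gene, , drop = FALSE]
  anchors <- v[v$protein_change == anchor_change, , drop = FALSE]
  pairs <- list()
  for (i in seq_len(nrow(anchors))) {
    pid <- anchors$patient_id[i]
    partners <- v[v$patient_id == pid & v$protein_change != anchor_change, ,
      drop = FALSE
    ]
    if (!nrow(partners)) next
    pairs[[pid]] <- data.frame(
      patient_id = pid,
      anchor_cf = anchors$cancer_fraction[i],
      partner_cf = partners$cancer_fraction,
      partner_change = partners$protein_change,
      stringsAsFactors = FALSE
    )
  }
  if (!length(pairs)) {
    return(list(
      pairs = data.frame(
        patient_id = character(0), anchor_cf = numeric(0),
        partner_cf = numeric(0), partner_change = character(0)
      ),
      p_value = NA_real_
    ))
  }
  pr <- do.call(rbind, pairs)
  rownames(pr) <- NULL
  p <- suppressWarnings(
    stats::wilcox.test(pr$anchor_cf, pr$partner_cf,
      alternative = "two.sided"
    )$p.value
  )
  if (is.na(p)) p <- 1 # complete ties: no evidence of asymmetry
  list(pairs = pr, p_value = p)
}

#' Write the per-variant clonality table
#'
#' @param cohort An annotated [ctdna_cohort()].
#' @param path Output TSV path.
#' @param metadata Optional `#`-header metadata (named character vector).
#' @return Invisibly, `path`.
#' @export
write_clonality <- function(cohort, path, metadata = NULL) {
  v <- cohort$variants
  if (is.null(v$cancer_fraction)) stop("run annotate_clonality() first")
  cols <- c(
    "patient_id", "gene", "protein_change", "vaf_pct", "mvaf_pct",
    "cancer_fraction", "dominance"
  )
  .write_tsv_meta(v[, cols], path, metadata)
  invisible(path)
}
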