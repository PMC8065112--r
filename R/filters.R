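#' Remove likely-germline variant calls
#'
#' ctDNA panels without matched germline sequencing report germline
#' polymorphisms alongside somatic calls. A call is treated as likely
#' germline, and removed, when both conditions hold: its VAF lies within
#' `vaf_halfwidth` percentage points of `vaf_center` (heterozygous-germline
#' band, default 50 +/- 2%), and its population allele frequency exceeds
#' `pop_af_threshold` percent (gnomAD-style AF > 0.001%). A call with no
#' population-AF annotation is never removed (absent AF is treated as 0).
#'
#' The operation partitions the input exactly and is idempotent.
#'
#' @param cohort A [ctdna_cohort()].
#' @param vaf_center,vaf_halfwidth Germline VAF band, in percent.
#' @param pop_af_threshold Population-AF cut-off, in percent.
#' @return List with `cohort` (filtered) and `removed` (the full records of
#'   removed calls).
#' @export
filter_germline <- function(cohort, vaf_center = 50, vaf_halfwidth = 2,
                            pop_af_threshold = 0.001) {
  v <- cohort$variants
  pop <- v$pop_af_pct
  pop[is.na(pop)] <- 0
  drop <- abs(v$vaf_pct - vaf_center) <= vaf_halfwidth & pop > pop_af_threshold
  out <- cohort
  out$variants <- v[!drop, , drop = FALSE]
  rownames(out$variants) <- NULL
  removed <- v[drop, , drop = FALSE]
  rownames(removed) <- NULL
  list(cohort = out, removed = removed)
}

#' Classify variant pathogenicity
#'
#' A variant is called pathogenic when any of three branches fires:
#' \describe{
#'   \item{hotspot}{its (gene, protein_change) pair is in the hotspot or
#'     oncogenic annotation set;}
#'   \item{recurrent-key-gene}{its gene is a key breast-cancer gene and the
#'     (gene, protein_change) recurrence count is at least `recurrence_min`;}
#'   \item{splice}{its variant class is splice.}
#' }
#' Otherwise it is non-pathogenic. The reason code records the first branch
#' that fired (in the order above).
#'
#' @param variants data.frame of variant calls (or a `ctdna_cohort`, whose
#'   variant table is annotated in place).
#' @param resources An [annotation_resources()] object.
#' @param recurrence_min Minimum recurrence count for the key-gene branch.
#' @return The input with added columns `pathogenic` (logical) and
#'   `pathogenic_reason` (`"hotspot"`, `"recurrent-key-gene"`, `"splice"` or
#'   `NA`).
#' @export
classify_pathogenic <- function(variants, resources, recurrence_min = 3) {
  if (inherits(variants, "ctdna_cohort")) {
    variants$variants <- classify_pathogenic(
      variants$variants, resources, recurrence_min
    )
    return(variants)
  }
  stopifnot(inherits(resources, "annotation_resources"))
  key <- paste(toupper(variants$gene), variants$protein_change, sep = "|")
  in_hotspot <- key %in% c(resources$hotspot_set, resources$oncogenic_set)
  rec <- resources$recurrence_counts[key]
  rec[is.na(rec)] <- 0L
  in_recurrent <- toupper(variants$gene) %in% resources$key_breast_genes &
    rec >= recurrence_min
  in_splice <- variants$variant_class == "splice"
  reason <- rep(NA_character_, nrow(variants))
  reason[in_splice] <- "splice"
  reason[in_recurrent] <- "recurrent-key-gene"
  reason[in_hotspot] <- "hotspot"
  variants$pathogenic <- in_hotspot | in_recurrent | in_splice
  variants$pathogenic_reason <- reason
  variants
}

.mapk_mutation_genes <- c(
  "EGFR", "HRAS", "KRAS", "NRAS", "ARAF", "BRAF", "RAF1", "MAP2K1",
  "MAP2K2", "MAPK1", "MAPK3", "FGFR1", "FGFR2", "FGFR3"
)
.mapk_fusion_genes <- c("FGFR2", "FGFR3")
.mapk_cn_genes <- c("BRAF", "EGFR", "FGFR1", "FGFR2", "KRAS")

#' Is an alteration a MAPK-pathway alteration?
#'
#' MAPK-pathway alterations comprise pathogenic mutations in the RAS-RAF-MEK-
#' ERK / FGFR axis genes (EGFR, HRAS, KRAS, NRAS, ARAF, BRAF, RAF1, MAP2K1,
#' MAP2K2, MAPK1, MAPK3, FGFR1, FGFR2, FGFR3), fusions of FGFR2/FGFR3, and
#' plasma copy number strictly greater than 3 in BRAF, EGFR, FGFR1, FGFR2 or
#' KRAS.
#'
#' @param gene Gene symbol (vectorised).
#' @param type Alteration type: `"mutation"`, `"fusion"` or `"copy_number"`.
#' @param pathogenic For mutations, whether the call is pathogenic; only
#'   pathogenic mutations count.
#' @param copy_number For copy-number calls, the observed plasma copy number.
#' @return Logical vector.
#' @export
#' @examples
#' is_mapk_alteration("KRAS", "mutation", pathogenic = TRUE)
#' is_mapk_alteration("BRAF", "copy_number", copy_number = 3.5)
#' is_mapk_alteration("BRAF", "copy_number", copy_number = 3.0)  # FALSE
is_mapk_alteration <- function(gene,
                               type = c("mutation", "fusion", "copy_number"),
                               pathogenic = TRUE, copy_number = NA_real_) {
  type <- match.arg(type)
  gene <- toupper(gene)
  switch(type,
    mutation = gene %in% .mapk_mutation_genes & pathogenic,
    fusion = gene %in% .mapk_fusion_genes,
    copy_number = gene %in% .mapk_cn_genes & !is.na(copy_number) &
      copy_number > 3
  )
}

#' Flag MAPK-pathway alterations across a cohort
#'
#' Applies [is_mapk_alteration()] to every pathogenic variant call and every
#' copy-number call in a cohort and reports, per patient, whether any
#' MAPK-pathway alteration is present.
#'
#' @param cohort A [ctdna_cohort()] with pathogenicity annotated.
#' @return data.frame (patient_id, mapk_altered).
#' @export
patient_mapk_status <- function(cohort) {
  v <- cohort$variants
  if (is.null(v$pathogenic)) {
    stop("run classify_pathogenic() before patient_mapk_status()")
  }
  mut_pat <- unique(v$patient_id[
    is_mapk_alteration(v$gene, "mutation", pathogenic = v$pathogenic)
  ])
  cn_pat <- if (nrow(cohort$cn)) {
    unique(cohort$cn$patient_id[is_mapk_alteration(
      cohort$cn$gene, "copy_number",
      copy_number = cohort$cn$observed_pcn
    )])
  } else {
    character(0)
  }
  data.frame(
    patient_id = cohort$clinical$patient_id,
    mapk_altered = cohort$clinical$patient_id %in% c(mut_pat, cn_pat),
    stringsAsFactors = FALSE
  )
}

#' Cohort-level alteration rate
#'
#' Fraction of patients with at least one variant call, computed on reported
#' calls (`stage = "reported"`) or on calls surviving the germline filter
#' (`stage = "filtered"`). Both denominators include clinical-table patients
#' with zero calls.
#'
#' @param cohort A [ctdna_cohort()].
#' @param stage `"reported"` or `"filtered"`.
#' @param ... Passed to [filter_germline()] when `stage = "filtered"`.
#' @return Percentage in [0,100].
#' @export
alteration_rate <- function(cohort, stage = c("reported", "filtered"), ...) {
  stage <- match.arg(stage)
  v <- if (stage == "filtered") {
    filter_germline(cohort, ...)$cohort$variants
  } else {
    cohort$variants
  }
  100 * length(unique(v$patient_id)) / n_patients(cohort)
}
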