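#' @keywords internal
"_PACKAGE"

.variant_cols <- c(
  "patient_id", "gene", "chrom", "pos", "ref", "alt", "protein_change",
  "variant_class", "vaf_pct", "pop_af_pct", "context3"
)

.variant_classes <- c(
  "missense", "nonsense", "frameshift", "in-frame indel", "splice",
  "synonymous", "other"
)

.subtypes <- c("HR+HER2-", "HR+HER2+", "HR-HER2+", "TNBC", "unknown")

#' Construct a ctDNA cohort
#'
#' A cohort bundles three tables keyed by `patient_id`: per-variant calls,
#' per-patient clinical covariates, and per-gene plasma copy-number calls.
#' Patients present in the clinical table with no variant calls are retained:
#' they form the denominator for "no ctDNA alteration" rates.
#'
#' Coordinates are 1-based fully-closed (MAF convention, GRCh37). VAF and
#' population allele frequency are both stored in percent.
#'
#' @param variants data.frame with columns `patient_id`, `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `protein_change`, `variant_class`, `vaf_pct`,
#'   `pop_af_pct` (NA when unknown), `context3` (NA for indels or when the
#'   reference context is unavailable).
#' @param clinical data.frame with columns `patient_id`, `subtype`,
#'   `lines_of_treatment`, `disease_sites` (comma-separated within the cell),
#'   `tissue_her2_status`.
#' @param cn Optional data.frame with columns `patient_id`, `gene`,
#'   `observed_pcn` (and, once computed, `adjusted_pcn`).
#' @return An object of class `ctdna_cohort`.
#' @export
ctdna_cohort <- function(variants, clinical, cn = NULL) {
  variants <- as.data.frame(variants)
  clinical <- as.data.frame(clinical)
  missing_cols <- setdiff(.variant_cols, names(variants))
  if (length(missing_cols)) {
    stop("variant table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(c("patient_id", "subtype") %in% names(clinical))) {
    stop("clinical table must have patient_id and subtype columns")
  }
  if (anyDuplicated(clinical$patient_id)) {
    stop("duplicate patient_id in clinical table")
  }
  bad_vaf <- !is.finite(variants$vaf_pct) | variants$vaf_pct < 0 |
    variants$vaf_pct > 100
  if (any(bad_vaf)) {
    stop(
      "malformed VAF (must be percent in [0,100]) at variant row(s): ",
      paste(utils::head(which(bad_vaf), 5), collapse = ", ")
    )
  }
  unknown <- setdiff(unique(variants$patient_id), clinical$patient_id)
  if (length(unknown)) {
    stop(
      "variant table references patient_id absent from clinical table: ",
      paste(unknown, collapse = ", ")
    )
  }
  if (is.null(cn)) {
    cn <- data.frame(
      patient_id = character(0), gene = character(0),
      observed_pcn = numeric(0), stringsAsFactors = FALSE
    )
  }
  cn <- as.data.frame(cn)
  if (nrow(cn) && any(cn$observed_pcn < 0)) {
    stop("observed_pcn must be >= 0")
  }
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref != "-" & variants$alt != "-"
  has_ctx <- is_snv & !is.na(variants$context3) & variants$context3 != ""
  if (any(has_ctx)) {
    bad_ctx <- has_ctx & (nchar(variants$context3) != 3L |
      substr(variants$context3, 2, 2) != variants$ref)
    if (any(bad_ctx)) {
      stop(
        "context3 must be a 3-mer centred on ref; offending row(s): ",
        paste(utils::head(which(bad_ctx), 5), collapse = ", ")
      )
    }
  }
  structure(
    list(variants = variants, clinical = clinical, cn = cn),
    class = "ctdna_cohort"
  )
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat(
    "ctdna_cohort:", nrow(x$clinical), "patients,",
    nrow(x$variants), "variant calls,", nrow(x$cn), "copy-number calls\n"
  )
  alt_pat <- length(unique(x$variants$patient_id))
  cat(sprintf(
    "  %d/%d patients (%.1f%%) with >=1 reported call\n",
    alt_pat, nrow(x$clinical), 100 * alt_pat / max(1, nrow(x$clinical))
  ))
  invisible(x)
}

#' Number of patients in a cohort
#' @param x A `ctdna_cohort`.
#' @return Integer patient count.
#' @export
n_patients <- function(x) nrow(x$clinical)

#' Read a cohort from tab-separated tables
#'
#' Reads the native variant table (header: patient_id, gene, chrom, pos, ref,
#' alt, protein_change, variant_class, vaf_pct, pop_af_pct, context3), the
#' clinical covariate table and, optionally, a copy-number table. Lines
#' starting with `#` are metadata and are skipped. Allele frequencies stored
#' as fractions in [0,1] can be converted with `vaf_scale = "fraction"`; the
#' scale is never guessed.
#'
#' A VCF may be supplied instead of the native variant table (extension
#' `.vcf`); per-sample VAF is taken from the FORMAT field named by
#' `vcf_vaf_field` and sample names are used as patient ids. Requires the
#' VariantAnnotation package.
#'
#' @param variant_path Path to variant table (TSV or VCF).
#' @param clinical_path Path to clinical TSV keyed by patient_id.
#' @param cn_path Optional path to copy-number TSV (patient_id, gene,
#'   observed_pcn).
#' @param vaf_scale `"percent"` (default) or `"fraction"`; applies to both
#'   vaf_pct and pop_af_pct columns of a TSV input.
#' @param vcf_vaf_field FORMAT field carrying the VAF when reading a VCF.
#' @return A [ctdna_cohort()].
#' @export
read_cohort <- function(variant_path, clinical_path, cn_path = NULL,
                        vaf_scale = c("percent", "fraction"),
                        vcf_vaf_field = "AF") {
  vaf_scale <- match.arg(vaf_scale)
  clinical <- utils::read.delim(
    clinical_path, stringsAsFactors = FALSE, comment.char = "#"
  )
  if (grepl("\\.vcf$", variant_path, ignore.case = TRUE)) {
    variants <- .read_vcf_variants(variant_path, vcf_vaf_field)
  } else {
    variants <- utils::read.delim(
      variant_path, stringsAsFactors = FALSE, comment.char = "#",
      colClasses = c(context3 = "character")
    )
    vaf_num <- suppressWarnings(as.numeric(variants$vaf_pct))
    bad <- is.na(vaf_num)
    if (any(bad)) {
      stop(
        "malformed VAF in variant table, line(s) ",
        paste(which(bad) + 1L, collapse = ", ") # +1 for the header line
      )
    }
    variants$vaf_pct <- vaf_num
    variants$pop_af_pct <- suppressWarnings(as.numeric(variants$pop_af_pct))
    if (vaf_scale == "fraction") {
      variants$vaf_pct <- 100 * variants$vaf_pct
      variants$pop_af_pct <- 100 * variants$pop_af_pct
    }
  }
  cn <- if (!is.null(cn_path)) {
    utils::read.delim(cn_path, stringsAsFactors = FALSE, comment.char = "#")
  }
  ctdna_cohort(variants, clinical, cn)
}

.read_vcf_variants <- function(path, vaf_field) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF input requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  if (!vaf_field %in% names(geno)) {
    stop("FORMAT field '", vaf_field, "' not present in VCF")
  }
  af <- geno[[vaf_field]]
  info <- VariantAnnotation::info(vcf)
  samples <- colnames(af)
  rows <- list()
  for (s in samples) {
    v <- af[, s]
    if (is.list(v)) v <- vapply(v, function(z) as.numeric(z)[1], numeric(1))
    keep <- !is.na(v)
    if (!any(keep)) next
    alt <- as.character(unlist(VariantAnnotation::alt(vcf)[keep]))
    rows[[s]] <- data.frame(
      patient_id = s,
      gene = if ("GENE" %in% names(info)) as.character(info$GENE[keep]) else NA_character_,
      chrom = as.character(GenomicRanges::seqnames(rr))[keep],
      pos = GenomicRanges::start(rr)[keep],
      ref = as.character(VariantAnnotation::ref(vcf))[keep],
      alt = alt,
      protein_change = if ("PCHANGE" %in% names(info)) {
        as.character(info$PCHANGE[keep])
      } else "",
      variant_class = "other",
      vaf_pct = 100 * as.numeric(v[keep]),
      pop_af_pct = NA_real_,
      context3 = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Write a cohort to tab-separated tables
#'
#' Writes `variants.tsv`, `clinical.tsv` and `cn.tsv` under `dir`, each with
#' an optional `#`-prefixed metadata header. Reading them back with
#' [read_cohort()] reproduces all fields.
#'
#' @param cohort A `ctdna_cohort`.
#' @param dir Output directory (created if absent).
#' @param metadata Optional named character vector written as `# key: value`
#'   header lines on every table.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, metadata = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("variants.tsv", "clinical.tsv", "cn.tsv"))
  tabs <- list(cohort$variants, cohort$clinical, cohort$cn)
  for (i in seq_along(paths)) {
    .write_tsv_meta(tabs[[i]], paths[i], metadata)
  }
  invisible(paths)
}

.write_tsv_meta <- function(df, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(metadata)) {
    writeLines(sprintf("# %s: %s", names(metadata), metadata), con)
  }
  utils::write.table(
    df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
}

#' Assemble annotation resources for pathogenicity calls
#'
#' The resources mirror the plain-table exports a user derives from hotspot
#' and oncogenicity databases (e.g. CancerHotspots, OncoKB) and a recurrence
#' count table (e.g. from COSMIC); they are inputs, never bundled. Gene
#' symbols and protein changes are case-normalised (genes upper-case).
#'
#' @param hotspots data.frame with columns `gene`, `protein_change`.
#' @param oncogenic data.frame with columns `gene`, `protein_change`.
#' @param recurrence data.frame with columns `gene`, `protein_change`,
#'   `count`.
#' @param key_breast_genes Character vector of genes in which recurrent
#'   mutations alone are considered pathogenic.
#' @return An `annotation_resources` object.
#' @export
annotation_resources <- function(hotspots = NULL, oncogenic = NULL,
                                 recurrence = NULL,
                                 key_breast_genes = c(
                                   "ESR1", "HER2", "PIK3CA", "EGFR", "RB1",
                                   "FGFR2"
                                 )) {
  norm_pairs <- function(df) {
    if (is.null(df) || !nrow(df)) return(character(0))
    paste(toupper(df$gene), df$protein_change, sep = "|")
  }
  if (!length(key_breast_genes)) stop("key_breast_genes must be non-empty")
  rec <- integer(0)
  if (!is.null(recurrence) && nrow(recurrence)) {
    rec <- as.integer(recurrence$count)
    names(rec) <- paste(toupper(recurrence$gene), recurrence$protein_change,
      sep = "|"
    )
  }
  structure(
    list(
      hotspot_set = norm_pairs(hotspots),
      oncogenic_set = norm_pairs(oncogenic),
      recurrence_counts = rec,
      key_breast_genes = toupper(key_breast_genes)
    ),
    class = "annotation_resources"
  )
}

#' Read annotation resources from three TSV files
#'
#' @param hotspot_path,oncogenic_path TSVs with columns gene, protein_change.
#' @param recurrence_path TSV with columns gene, protein_change, count.
#' @param key_breast_genes Passed to [annotation_resources()].
#' @return An `annotation_resources` object.
#' @export
read_annotation_resources <- function(hotspot_path, oncogenic_path,
                                      recurrence_path,
                                      key_breast_genes = c(
                                        "ESR1", "HER2", "PIK3CA", "EGFR",
                                        "RB1", "FGFR2"
                                      )) {
  rd <- function(p) {
    if (is.null(p)) NULL else {
      utils::read.delim(p, stringsAsFactors = FALSE, comment.char = "#")
    }
  }
  annotation_resources(
    rd(hotspot_path), rd(oncogenic_path), rd(recurrence_path),
    key_breast_genes
  )
}
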