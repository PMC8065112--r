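#' Run the full ctDNA analysis pipeline
#'
#' Executes the stages in order — germline filter, pathogenicity
#' classification, clonality annotation, copy-number adjustment, gene-level
#' association statistics, and (when a signature matrix is available)
#' clonal-versus-subclonal signature comparison — and writes one TSV per
#' stage under `out_dir`. Every output carries `#`-prefixed metadata header
#' lines recording the package version, the seed and a parameter hash, so a
#' run can be reproduced from its outputs. Inputs are never modified.
#'
#' @param config Either a named list or a path to a YAML file with entries:
#'   `variant_path`, `clinical_path` (required), `cn_path`,
#'   `hotspot_path`, `oncogenic_path`, `recurrence_path`,
#'   `signature_path`, `out_dir` (default `"plasmaclone_out"`), `seed`
#'   (default 1), plus optional overrides `vaf_center`, `vaf_halfwidth`,
#'   `pop_af_threshold`, `recurrence_min`, `min_incidence`,
#'   `operating_threshold`, `n_boot`, `sample_frac`, `signature_subtype`.
#' @param log Function used for progress messages (default [message]); use
#'   `function(...) {}` to silence.
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config, log = message) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    cn_path = NULL, hotspot_path = NULL, oncogenic_path = NULL,
    recurrence_path = NULL, signature_path = NULL,
    out_dir = "plasmaclone_out", seed = 1,
    vaf_center = 50, vaf_halfwidth = 2, pop_af_threshold = 0.001,
    recurrence_min = 3, min_incidence = 0.05, operating_threshold = 2.0,
    n_boot = 200, sample_frac = 0.9, signature_subtype = NULL
  )
  config <- utils::modifyList(defaults, config)
  for (p in c("variant_path", "clinical_path")) {
    if (is.null(config[[p]])) stop("config is missing required path: ", p)
  }
  for (p in c(
    "variant_path", "clinical_path", "cn_path", "hotspot_path",
    "oncogenic_path", "recurrence_path", "signature_path"
  )) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("stage input does not exist: ", p, " = ", config[[p]])
    }
  }
  ver <- as.character(utils::packageVersion("plasmaclone"))
  meta <- c(
    tool = paste0("plasmaclone ", ver),
    seed = as.character(config$seed),
    # out_dir is where results land, not an analysis parameter: two runs
    # into different directories must hash (and so diff) identically
    parameter_hash = .config_hash(config[setdiff(names(config), "out_dir")])
  )
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  paths <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE)
    })
  }

  log("reading cohort")
  cohort <- stage("read", read_cohort(
    config$variant_path, config$clinical_path, config$cn_path
  ))

  log("filtering likely-germline calls")
  filt <- stage("germline_filter", filter_germline(
    cohort, config$vaf_center, config$vaf_halfwidth, config$pop_af_threshold
  ))
  cohort <- filt$cohort
  .write_tsv_meta(filt$removed, outp("removed_germline.tsv"), meta)
  paths$removed_germline <- outp("removed_germline.tsv")

  if (!is.null(config$hotspot_path) || !is.null(config$oncogenic_path) ||
    !is.null(config$recurrence_path)) {
    log("classifying pathogenicity")
    res <- stage("pathogenicity", read_annotation_resources(
      config$hotspot_path, config$oncogenic_path, config$recurrence_path
    ))
    cohort <- classify_pathogenic(cohort, res, config$recurrence_min)
  } else {
    cohort$variants$pathogenic <- TRUE
    cohort$variants$pathogenic_reason <- NA_character_
  }

  log("annotating clonality")
  cohort <- stage("clonality", annotate_clonality(cohort))
  stage("clonality", write_clonality(cohort, outp("clonality.tsv"), meta))
  paths$clonality <- outp("clonality.tsv")

  if (nrow(cohort$cn)) {
    log("adjusting plasma copy number")
    cohort <- stage("copy_number",
      adjust_cohort_pcn(cohort, config$operating_threshold))
    .write_tsv_meta(cohort$cn, outp("copy_number.tsv"), meta)
    paths$copy_number <- outp("copy_number.tsv")
  }

  log("association statistics")
  assoc <- stage("associations", tryCatch(
    cooccurrence_matrix(cohort, config$min_incidence),
    error = function(e) NULL
  ))
  if (!is.null(assoc)) {
    write_associations(assoc, outp("cooccurrence.tsv"),
      family = "cooccurrence", metadata = meta)
    paths$cooccurrence <- outp("cooccurrence.tsv")
  }
  dom <- stage("associations", gene_dominance_test(cohort, min_n = 3))
  .write_tsv_meta(dom, outp("gene_dominance.tsv"), meta)
  paths$gene_dominance <- outp("gene_dominance.tsv")

  if (!is.null(config$signature_path)) {
    log("signature analysis")
    sig <- stage("signatures", read_signature_matrix(config$signature_path))
    sets <- stage("signatures",
      aggregate_clonal_subclonal(cohort, config$signature_subtype))
    if (nrow(sets$clonal$mutations) >= 10 &&
      nrow(sets$subclonal$mutations) >= 10) {
      ba <- bootstrap_exposures(sets$clonal$mutations, sig,
        n_iter = config$n_boot, sample_frac = config$sample_frac,
        seed = config$seed)
      bb <- bootstrap_exposures(sets$subclonal$mutations, sig,
        n_iter = config$n_boot, sample_frac = config$sample_frac,
        seed = config$seed + 1)
      cmp <- compare_conditions(ba, bb)
      names(cmp)[names(cmp) == "median_a"] <- "median_clonal"
      names(cmp)[names(cmp) == "median_b"] <- "median_subclonal"
      .write_tsv_meta(cmp, outp("signature_comparison.tsv"), meta)
      paths$signature_comparison <- outp("signature_comparison.tsv")
    } else {
      log("signature analysis skipped: too few assessable SNVs")
    }
  }
  log("pipeline complete")
  invisible(paths)
}

.config_hash <- function(config) {
  txt <- paste(
    names(config),
    vapply(config, function(x) paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";"
  )
  # small rolling hash; stable across sessions, no external dependency
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
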