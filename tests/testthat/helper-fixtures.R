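# Shared fixture builders and independent oracles.

# Build a variant-call row with sensible defaults; pos auto-increments so
# every call gets a unique site unless one is given.
.pos_counter <- local({
  i <- 0L
  function() {
    i <<- i + 3L
    i
  }
})

vrow <- function(patient_id, gene = "TP53", vaf = 10, pos = .pos_counter(),
                 protein_change = paste0("X", pos, "Y"), chrom = "1",
                 ref = "C", alt = "T", context3 = "ACA",
                 variant_class = "missense", pop_af = NA_real_) {
  data.frame(
    patient_id = patient_id, gene = gene, chrom = chrom, pos = pos,
    ref = ref, alt = alt, protein_change = protein_change,
    variant_class = variant_class, vaf_pct = vaf, pop_af_pct = pop_af,
    context3 = context3, stringsAsFactors = FALSE
  )
}

make_cohort <- function(variants, subtype = "HR+HER2-", cn = NULL,
                        extra_patients = character(0),
                        clinical_extra = NULL) {
  pats <- unique(c(variants$patient_id, extra_patients))
  clinical <- data.frame(
    patient_id = pats,
    subtype = rep_len(subtype, length(pats)),
    lines_of_treatment = 1L,
    disease_sites = "bone",
    tissue_her2_status = "negative",
    stringsAsFactors = FALSE
  )
  if (!is.null(clinical_extra)) {
    for (nm in names(clinical_extra)) {
      val <- clinical_extra[[nm]]
      clinical[[nm]] <- if (!is.null(names(val))) {
        unname(val[clinical$patient_id]) # keyed by patient, order-safe
      } else {
        rep_len(val, nrow(clinical))
      }
    }
  }
  ctdna_cohort(variants, clinical, cn)
}

# A cohort where every gene's cancer fractions are chosen exactly: one
# anchor variant at vaf = mvaf plus variants at cf * mvaf.
cf_cohort <- function(gene_cfs, mvaf = 20, subtype = "HR+HER2-") {
  rows <- list()
  pid <- 0L
  for (g in names(gene_cfs)) {
    for (cf in gene_cfs[[g]]) {
      pid <- pid + 1L
      p <- sprintf("Q%03d", pid)
      rows[[length(rows) + 1L]] <- vrow(p, gene = "ANCHOR", vaf = mvaf)
      rows[[length(rows) + 1L]] <- vrow(p, gene = g, vaf = cf * mvaf)
    }
  }
  make_cohort(do.call(rbind, rows), subtype = subtype)
}

mark_all_pathogenic <- function(cohort) {
  cohort$variants$pathogenic <- TRUE
  cohort$variants$pathogenic_reason <- "hotspot"
  cohort
}

# Independent two-sided Fisher oracle: exhaustive hypergeometric
# enumeration over all tables with the observed margins, probability-mass
# convention with the customary 1e-7 relative tolerance.
fisher_oracle <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  x <- max(0, r1 + c1 - n):min(r1, c1)
  p <- stats::dhyper(x, c1, n - c1, r1)
  pobs <- stats::dhyper(a, c1, n - c1, r1)
  sum(p[p <= pobs * (1 + 1e-7)])
}

# Independent step-up BH oracle.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(n)
  out[o] <- q
  out
}

expect_data_frame_equal <- function(a, b) {
  testthat::expect_equal(nrow(a), nrow(b))
  testthat::expect_identical(names(a), names(b))
  for (col in names(a)) testthat::expect_equal(a[[col]], b[[col]])
}
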