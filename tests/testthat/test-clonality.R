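test_that("mVAF is the per-patient maximum over retained calls", {
  v <- rbind(
    vrow("P1", vaf = 4.0), vrow("P1", vaf = 12.5), vrow("P1", vaf = 0.3),
    vrow("P2", vaf = 7.0)
  )
  co <- make_cohort(v, extra_patients = "P3")
  mv <- compute_mvaf(co)
  expect_equal(mv$mvaf_pct[mv$patient_id == "P1"], 12.5)
  expect_equal(mv$mvaf_pct[mv$patient_id == "P2"], 7.0)
  expect_true(is.na(mv$mvaf_pct[mv$patient_id == "P3"]))
})

test_that("cancer fractions follow the VAF ratio and the 0.5 dominance rule", {
  v <- rbind(
    vrow("P1", vaf = 20), vrow("P1", vaf = 5), vrow("P1", vaf = 10),
    vrow("P2", vaf = 9) # single alteration: not assessable
  )
  co <- annotate_clonality(make_cohort(v))
  p1 <- co$variants[co$variants$patient_id == "P1", ]
  expect_equal(sort(p1$cancer_fraction), c(0.25, 0.5, 1.0))
  expect_equal(
    p1$dominance[order(p1$cancer_fraction)],
    c("subclonal", "dominant", "dominant") # CF = 0.5 counts as dominant
  )
  p2 <- co$variants[co$variants$patient_id == "P2", ]
  expect_true(is.na(p2$cancer_fraction))
  expect_equal(p2$dominance, "not_assessable")
})

test_that("every assessable profile has a CF-1 variant and CFs are scale-free", {
  sim <- generate_cohort(cohort_config(n_patients = 150, seed = 9))
  co <- annotate_clonality(filter_germline(sim$cohort)$cohort)
  v <- co$variants[!is.na(co$variants$cancer_fraction), ]
  top <- tapply(v$cancer_fraction, v$patient_id, max)
  expect_true(all(abs(top - 1) < 1e-12))
  # scale invariance: halving every VAF in a profile leaves CFs unchanged
  co2 <- co
  co2$variants$vaf_pct <- co2$variants$vaf_pct / 2
  co2 <- annotate_clonality(co2)
  expect_equal(co2$variants$cancer_fraction, co$variants$cancer_fraction)
  expect_identical(co2$variants$dominance, co$variants$dominance)
})

test_that("gene dominance testing separates constructed extremes", {
  co <- cf_cohort(list(
    AKT1 = rep(1.0, 6), OTHER1 = rep(0.2, 6), OTHER2 = rep(0.25, 6)
  ))
  co <- mark_all_pathogenic(annotate_clonality(co))
  co$variants$pathogenic[co$variants$gene == "ANCHOR"] <- FALSE
  res <- gene_dominance_test(co, genes = c("AKT1", "OTHER1", "OTHER2"))
  akt <- res[res$gene == "AKT1", ]
  expect_equal(akt$direction, "more dominant")
  expect_lt(akt$p_value, 0.05)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_equal(akt$n_dominant, 6)
  expect_error(gene_dominance_test(co, genes = "ABSENT"), "ABSENT")
})

test_that("a gene drawn from the background is rarely called different", {
  set.seed(21)
  reject <- 0L
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    cfs <- round(runif(18, 0.05, 0.95), 3)
    co <- cf_cohort(list(
      GENEA = cfs[1:6], BG1 = cfs[7:12], BG2 = cfs[13:18]
    ))
    co <- mark_all_pathogenic(annotate_clonality(co))
    co$variants$pathogenic[co$variants$gene == "ANCHOR"] <- FALSE
    res <- gene_dominance_test(co, genes = "GENEA")
    if (res$p_value < 0.05) reject <- reject + 1L
  }
  expect_lte(reject / n_rep, 0.10)
})

test_that("degenerate single-observation dominance test still runs", {
  co <- cf_cohort(list(SOLO = 0.4, BG = round(runif(20, 0.1, 0.9), 2)))
  co <- mark_all_pathogenic(annotate_clonality(co))
  co$variants$pathogenic[co$variants$gene == "ANCHOR"] <- FALSE
  res <- gene_dominance_test(co, genes = "SOLO")
  expect_true(is.finite(res$p_value))
  expect_gt(res$p_value, 0.05)
})

test_that("polyclonality counts single versus multiple carriers", {
  v <- rbind(
    vrow("P1", gene = "ESR1", protein_change = "D538G", vaf = 10),
    vrow("P1", gene = "ESR1", protein_change = "Y537S", vaf = 4),
    vrow("P2", gene = "ESR1", protein_change = "D538G", vaf = 8),
    vrow("P1", gene = "AKT1", protein_change = "E17K", vaf = 6),
    vrow("P2", gene = "AKT1", protein_change = "E17K", vaf = 2),
    vrow("P3", gene = "AKT1", protein_change = "E17K", vaf = 2)
  )
  co <- mark_all_pathogenic(make_cohort(v))
  res <- polyclonality_summary(co)
  esr1 <- res[res$gene == "ESR1", ]
  expect_equal(c(esr1$n_single, esr1$n_multiple), c(1, 1))
  expect_equal(esr1$fraction_multiple, 0.5)
  akt1 <- res[res$gene == "AKT1", ]
  expect_equal(akt1$fraction_multiple, 0)
})

test_that("the polyclonality Fisher test equals the hypergeometric oracle", {
  tab <- matrix(c(10, 10, 90, 10), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab)$p_value, fisher_oracle(tab))
})

test_that("hotspot CF variation applies the count and indel inclusion rules", {
  rows <- list()
  add <- function(pid, change, cf, class = "missense", ref = "C", alt = "T") {
    rows[[length(rows) + 1]] <<- vrow(pid,
      gene = "ANCHOR", vaf = 20
    )
    rows[[length(rows) + 1]] <<- vrow(pid,
      gene = "PIK3CA", protein_change = change, vaf = cf * 20,
      variant_class = class, ref = ref, alt = alt,
      context3 = if (class == "missense") "ACA" else NA_character_
    )
  }
  for (i in 1:3) add(paste0("H", i), "H1047R", 0.9)
  for (i in 4:6) add(paste0("H", i), "E545K", 0.1)
  add("H7", "E726K", 0.5) # SNV seen twice: excluded
  add("H8", "E726K", 0.6)
  add("H9", "V105fs", 0.3, class = "frameshift", ref = "CT", alt = "C")
  co <- mark_all_pathogenic(annotate_clonality(
    make_cohort(do.call(rbind, rows))
  ))
  res <- hotspot_cf_variation(co, "PIK3CA", min_count = 3)
  expect_setequal(names(res$cf_by_hotspot), c("H1047R", "E545K", "V105fs"))
  expect_true(res$summary$is_indel[res$summary$hotspot == "V105fs"])
  expect_lt(res$kruskal_p, 0.05)
  # with only one hotspot left the test is undefined
  solo <- co
  solo$variants <- solo$variants[
    solo$variants$protein_change %in% c("H1047R", "") |
      solo$variants$gene == "ANCHOR", ]
  expect_error(hotspot_cf_variation(solo, "PIK3CA"), "fewer than 2")
})

test_that("dual-mutation linkage pairs anchors with partners only", {
  rows <- list()
  mk <- function(pid, anchor_cf, partner_cf = NULL) {
    rows[[length(rows) + 1]] <<- vrow(pid, gene = "ANCHOR", vaf = 20)
    rows[[length(rows) + 1]] <<- vrow(pid,
      gene = "PIK3CA", protein_change = "H1047R", vaf = anchor_cf * 20
    )
    if (!is.null(partner_cf)) {
      rows[[length(rows) + 1]] <<- vrow(pid,
        gene = "PIK3CA", protein_change = "E726K", vaf = partner_cf * 20
      )
    }
  }
  anchor_cfs <- c(0.9, 0.8, 0.95, 0.85, 0.9, 0.8, 0.92, 0.88)
  partner_cfs <- c(0.1, 0.2, 0.15, 0.12, 0.18, 0.1, 0.2, 0.16)
  for (i in seq_along(anchor_cfs)) {
    mk(sprintf("L%02d", i), anchor_cfs[i], partner_cfs[i])
  }
  mk("L99", 0.9) # anchor only: excluded from pairs
  co <- mark_all_pathogenic(annotate_clonality(
    make_cohort(do.call(rbind, rows))
  ))
  res <- dual_mutation_linkage(co, "PIK3CA", "H1047R")
  expect_equal(nrow(res$pairs), 8)
  expect_false("L99" %in% res$pairs$patient_id)
  expect_lt(res$p_value, 0.05)
  expect_true(all(res$pairs$anchor_cf > res$pairs$partner_cf))
})

test_that("identical anchor and partner CFs give a null linkage test", {
  rows <- list()
  for (i in 1:5) {
    pid <- paste0("E", i)
    rows[[length(rows) + 1]] <- vrow(pid, gene = "ANCHOR", vaf = 20)
    rows[[length(rows) + 1]] <- vrow(pid,
      gene = "PIK3CA", protein_change = "H1047R", vaf = 8
    )
    rows[[length(rows) + 1]] <- vrow(pid,
      gene = "PIK3CA", protein_change = "E726K", vaf = 8
    )
  }
  co <- mark_all_pathogenic(annotate_clonality(
    make_cohort(do.call(rbind, rows))
  ))
  res <- dual_mutation_linkage(co, "PIK3CA", "H1047R")
  expect_equal(res$p_value, 1)
  none <- dual_mutation_linkage(co, "PIK3CA", "G1049R")
  expect_equal(nrow(none$pairs), 0)
  expect_true(is.na(none$p_value))
})
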