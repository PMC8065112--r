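test_that("degenerate contingency tables are handled as contracts", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_warning(
    p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$p_value,
    "zero margin"
  )
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "zero margin")
  even <- chi2_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
})

test_that("the chi-squared statistic matches the hand formula", {
  # n(ad - bc)^2 / (r1 r2 c1 c2) = 73 * 232^2 / (41*32*11*62) = 4.391
  res <- chi2_2x2(matrix(c(3, 38, 8, 24), 2, byrow = TRUE))
  expect_equal(res$statistic, 73 * (3 * 24 - 38 * 8)^2 / (41 * 32 * 11 * 62),
    tolerance = 1e-12)
  expect_equal(res$statistic, 4.39, tolerance = 1e-2)
  # Yates correction is opt-in and changes the answer materially
  yates <- chi2_2x2(matrix(c(3, 38, 8, 24), 2, byrow = TRUE),
    continuity_correction = TRUE)
  expect_gt(yates$p_value, 0.07)
})

test_that("Fisher p matches exhaustive enumeration on small tables", {
  for (n in c(8, 14, 21, 30)) {
    for (r1 in 0:n) {
      for (c1 in 0:n) {
        for (a in max(0, r1 + c1 - n):min(r1, c1)) {
          tab <- matrix(c(a, r1 - a, c1 - a, n - r1 - c1 + a), 2, byrow = TRUE)
          if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
          expect_equal(fisher_exact_2x2(tab)$p_value, fisher_oracle(tab),
            tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("Fisher p is invariant to transposition and row/column swaps", {
  set.seed(17)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(fisher_exact_2x2(t(tab))$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, ])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[, 2:1])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p_value, p, tolerance = 1e-12)
    # the enumeration oracle shares the invariance
    expect_equal(fisher_oracle(t(tab)), fisher_oracle(tab), tolerance = 1e-12)
    expect_equal(fisher_oracle(tab[2:1, ]), fisher_oracle(tab),
      tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces hand step-up computations", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.04)), c(0.01, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")
  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # sorted input gives monotone q; all-significant leaves p unchanged
  p <- sort(runif(10))
  expect_true(all(diff(bh_adjust(p)) >= -1e-12))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
})

test_that("co-occurrence testing applies the 5% incidence rule", {
  # 100 patients: GENE_HI in 10, GENE_LO in 4 (4.9-like, below 5%)
  rows <- list()
  for (i in 1:10) rows[[length(rows) + 1]] <- vrow(sprintf("C%03d", i), gene = "GENE_HI")
  for (i in 1:4) rows[[length(rows) + 1]] <- vrow(sprintf("C%03d", i + 20), gene = "GENE_LO")
  for (i in 1:30) rows[[length(rows) + 1]] <- vrow(sprintf("C%03d", i + 40), gene = "GENE_BG")
  co <- mark_all_pathogenic(make_cohort(
    do.call(rbind, rows),
    extra_patients = sprintf("C%03d", 1:100)
  ))
  res <- cooccurrence_matrix(co, min_incidence = 0.05)
  expect_false(any(res$gene_a == "GENE_LO" | res$gene_b == "GENE_LO"))
  expect_true(any(res$gene_a == "GENE_HI" | res$gene_b == "GENE_HI"))
  expect_error(cooccurrence_matrix(co, min_incidence = 0.5), "fewer than 2")
})

test_that("constructed mutual exclusivity is detected with FDR control", {
  # 400 patients; A and B each in 60, never together; C independent
  set.seed(23)
  pats <- sprintf("M%03d", 1:400)
  rows <- list()
  for (i in 1:60) rows[[length(rows) + 1]] <- vrow(pats[i], gene = "GENE_A")
  for (i in 61:120) rows[[length(rows) + 1]] <- vrow(pats[i], gene = "GENE_B")
  for (i in sample(400, 60)) rows[[length(rows) + 1]] <- vrow(pats[i], gene = "GENE_C")
  co <- mark_all_pathogenic(make_cohort(
    do.call(rbind, rows), extra_patients = pats
  ))
  res <- cooccurrence_matrix(co)
  ab <- res[res$gene_a == "GENE_A" & res$gene_b == "GENE_B", ]
  expect_equal(ab$direction, "mutually exclusive")
  expect_lt(ab$q_value, 0.05)
  expect_equal(ab$a, 0) # no co-carriers
})

test_that("independent genes are rarely flagged across permuted cohorts", {
  set.seed(29)
  n_pat <- 150
  pats <- sprintf("N%03d", seq_len(n_pat))
  n_flag <- 0L
  n_pair <- 0L
  for (s in 1:200) {
    rows <- list()
    for (g in c("G1", "G2", "G3", "G4")) {
      for (p in pats[sample(n_pat, 25)]) {
        rows[[length(rows) + 1]] <- vrow(p, gene = g)
      }
    }
    co <- mark_all_pathogenic(make_cohort(
      do.call(rbind, rows), extra_patients = pats
    ))
    res <- cooccurrence_matrix(co)
    n_flag <- n_flag + sum(res$q_value < 0.05)
    n_pair <- n_pair + nrow(res)
  }
  expect_lte(n_flag / n_pair, 0.05)
})

test_that("group association recovers a constructed organotropism", {
  set.seed(31)
  n <- 500
  pats <- sprintf("O%03d", seq_len(n))
  site <- rep(c("bone", "visceral"), length.out = n)
  altered <- runif(n) < ifelse(site == "bone", 0.4, 0.1)
  rows <- lapply(pats[altered], vrow, gene = "BONEG")
  rows <- c(rows, lapply(pats[1:10], vrow, gene = "FILLER"))
  co <- mark_all_pathogenic(make_cohort(
    do.call(rbind, rows), extra_patients = pats,
    clinical_extra = list(disease_sites = setNames(site, pats))
  ))
  res <- group_association(co, "BONEG", "disease_sites")
  expect_lt(res$pairwise$q_value[1], 0.05)
  bone_rate <- with(
    res$counts, altered[level == "bone"] /
      (altered[level == "bone"] + unaltered[level == "bone"])
  )
  expect_gt(bone_rate, 0.3)
})

test_that("equal alteration rates across levels yield null associations", {
  pats <- sprintf("E%03d", 1:120)
  grp <- rep(c("a", "b", "c"), each = 40)
  altered <- rep(c(TRUE, FALSE), length.out = 120) # identical rate per level
  rows <- lapply(pats[altered], vrow, gene = "FLATG")
  co <- mark_all_pathogenic(make_cohort(
    do.call(rbind, rows), extra_patients = pats,
    clinical_extra = list(grp = setNames(grp, pats))
  ))
  res <- group_association(co, "FLATG", "grp")
  expect_true(all(res$pairwise$q_value > 0.9))
  expect_gt(res$groupwise$p_value, 0.9)
  expect_error(group_association(co, "FLATG", rep("one", 120)), "2 non-empty")
})
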