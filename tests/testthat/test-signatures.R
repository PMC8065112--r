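test_that("the synthetic signature set is a valid COSMIC-layout matrix", {
  sig <- synthetic_signature_matrix()
  expect_equal(dim(sig), c(96, 5))
  expect_identical(rownames(sig), sbs96_channels())
  expect_true(all(abs(colSums(sig) - 1) < 1e-12))
  expect_true(all(sig >= 0))
})

test_that("signature matrices round-trip through the COSMIC table layout", {
  sig <- synthetic_signature_matrix()
  d <- withr::local_tempdir()
  path <- file.path(d, "signatures.tsv")
  df <- data.frame(
    `Substitution Type` = substr(rownames(sig), 3, 5),
    Trinucleotide = paste0(
      substr(rownames(sig), 1, 1), substr(rownames(sig), 3, 3),
      substr(rownames(sig), 7, 7)
    ),
    `Somatic Mutation Type` = rownames(sig),
    check.names = FALSE
  )
  df <- cbind(df, as.data.frame(sig))
  # shuffled row order must be restored on read
  df <- df[sample(96), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sig2 <- read_signature_matrix(path)
  expect_equal(unname(sig2), unname(sig), tolerance = 1e-12)
  # a non-stochastic column is rejected
  bad <- df
  bad[["Signature 1"]] <- bad[["Signature 1"]] * 2
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_matrix(path), "sum to 1")
})

test_that("clonal/subclonal aggregation deduplicates sites per set", {
  v <- rbind(
    # site 100: dominant in P1 AND P2 -> one clonal count
    vrow("P1", gene = "TP53", vaf = 20, pos = 100),
    vrow("P2", gene = "TP53", vaf = 18, pos = 100),
    # site 200: dominant in P1, subclonal in P2 -> one count in each set
    vrow("P1", gene = "ESR1", vaf = 19, pos = 200, ref = "C", alt = "G",
      context3 = "TCT"),
    vrow("P2", gene = "ESR1", vaf = 2, pos = 200, ref = "C", alt = "G",
      context3 = "TCT"),
    # single-variant patient: not assessable, contributes nowhere
    vrow("P3", gene = "TP53", vaf = 30, pos = 300)
  )
  co <- annotate_clonality(make_cohort(v))
  sets <- aggregate_clonal_subclonal(co)
  expect_equal(nrow(sets$clonal$mutations), 2) # sites 100 and 200
  expect_equal(nrow(sets$subclonal$mutations), 1) # site 200
  expect_equal(sum(sets$clonal$catalogue), 2)
  expect_equal(sum(sets$subclonal$catalogue), 1)
  expect_equal(sets$subclonal$mutations$pos, 200)
})

test_that("exposure fitting recovers an exact single-signature catalogue", {
  sig <- synthetic_signature_matrix()
  catalogue <- round(sig[, "Signature 1"] * 1e6)
  fit <- fit_exposures(catalogue, sig)
  expect_gte(fit$weights["Signature 1"], 0.99)
  expect_equal(sum(fit$weights > 0), 1)
  expect_lt(fit$reconstruction_error, 1e-6)
  expect_error(fit_exposures(rep(0, 96), sig), "empty")
})

test_that("sub-threshold contamination is discarded, not reported", {
  sig <- synthetic_signature_matrix()
  mix <- generate_signature_mixture(
    sig, c("Signature 1" = 0.97, "Signature 13" = 0.03), 5000, seed = 41
  )
  fit <- fit_exposures(mix$catalogue, sig)
  expect_equal(unname(fit$weights["Signature 13"]), 0)
  expect_gt(fit$weights["Signature 1"], 0.9)
})

test_that("reconstruction error does not increase as tol tightens", {
  sig <- synthetic_signature_matrix()
  mix <- generate_signature_mixture(
    sig, c("Signature 1" = 0.5, "Signature 5" = 0.4), 2000, seed = 43
  )
  errs <- vapply(c(1e-1, 1e-2, 1e-3, 1e-4), function(tol) {
    fit_exposures(mix$catalogue, sig, tol = tol)$reconstruction_error
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("exposures of absent signatures vanish with catalogue size", {
  sig <- synthetic_signature_matrix()
  for (n in c(200, 2000)) {
    mix <- generate_signature_mixture(
      sig, c("Signature 1" = 0.6, "Signature 5" = 0.4), n, seed = 47
    )
    fit <- fit_exposures(mix$catalogue, sig)
    expect_equal(unname(fit$weights["Signature 3"]), 0)
    expect_equal(unname(fit$weights["Signature 13"]), 0)
  }
})

test_that("bootstrap subsampling is deterministic and degenerates sanely", {
  sig <- synthetic_signature_matrix()
  mix <- generate_signature_mixture(sig, c("Signature 2" = 1), 300, seed = 53)
  b1 <- bootstrap_exposures(mix$mutations, sig, n_iter = 25, seed = 7)
  b2 <- bootstrap_exposures(mix$mutations, sig, n_iter = 25, seed = 7)
  expect_identical(b1$exposures, b2$exposures)
  # a pure single-signature set keeps that signature on top every iteration
  top <- apply(b1$exposures, 1, which.max)
  expect_true(all(colnames(b1$exposures)[top] == "Signature 2"))
  expect_lt(max(b1$q75 - b1$q25), 0.1)
  one <- bootstrap_exposures(mix$mutations, sig, n_iter = 1, seed = 7)
  expect_equal(nrow(one$exposures), 1)
  expect_equal(one$q75 - one$q25, setNames(rep(0, 5), colnames(sig)))
  expect_error(
    bootstrap_exposures(mix$mutations[1:5, ], sig, seed = 1),
    "too small"
  )
  # bootstrap medians approach the full-data fit as the fraction grows
  b99 <- bootstrap_exposures(mix$mutations, sig, n_iter = 25, seed = 7,
    sample_frac = 0.99)
  expect_lt(
    max(abs(b99$median - b99$full_fit$weights)),
    max(abs(b1$median - b1$full_fit$weights)) + 0.02
  )
})

test_that("condition comparison flags only separated exposure distributions", {
  sig <- synthetic_signature_matrix()
  mix <- generate_signature_mixture(sig, c("Signature 1" = 1), 300, seed = 59)
  b1 <- bootstrap_exposures(mix$mutations, sig, n_iter = 40, seed = 7)
  cmp_same <- compare_conditions(b1, b1)
  expect_true(all(!cmp_same$highlighted))
  expect_true(all(cmp_same$p_value[cmp_same$median_a == 0 &
    cmp_same$median_b == 0] == 1))
  mix2 <- generate_signature_mixture(sig, c("Signature 13" = 1), 300, seed = 61)
  b2 <- bootstrap_exposures(mix2$mutations, sig, n_iter = 40, seed = 8)
  cmp <- compare_conditions(b1, b2)
  s13 <- cmp[cmp$signature == "Signature 13", ]
  expect_true(s13$highlighted)
  expect_equal(s13$direction, "higher in B")
  b3 <- b2
  colnames(b3$exposures) <- rev(colnames(b3$exposures))
  expect_error(compare_conditions(b1, b3), "different signature sets")
})

test_that("APOBEC dominance contingency equals the enumeration oracle", {
  rows <- list()
  for (i in 1:10) { # dominant, all non-APOBEC
    pid <- sprintf("A%02d", i)
    rows[[length(rows) + 1]] <- vrow(pid, gene = "PIK3CA", vaf = 20,
      ref = "C", alt = "T", context3 = "ACA")
    rows[[length(rows) + 1]] <- vrow(pid, gene = "PIK3CA", vaf = 2,
      ref = "C", alt = "G", context3 = "TCT") # subclonal, APOBEC
  }
  co <- mark_all_pathogenic(annotate_clonality(make_cohort(
    do.call(rbind, rows)
  )))
  res <- apobec_dominance_analysis(co, "PIK3CA")
  expect_equal(res$table["dominant", "apobec"], 0)
  expect_equal(res$table["subclonal", "apobec"], 10)
  expect_equal(res$prop_apobec_dominant, 0)
  expect_equal(res$prop_apobec_subclonal, 1)
  expect_equal(
    res$p_value,
    fisher_oracle(matrix(c(0, 10, 10, 0), 2, byrow = TRUE))
  )
})

test_that("uniform APOBEC status yields a null dominance comparison", {
  rows <- list()
  for (i in 1:6) {
    pid <- sprintf("B%02d", i)
    rows[[length(rows) + 1]] <- vrow(pid, gene = "PIK3CA", vaf = 20,
      ref = "C", alt = "G", context3 = "TCA")
    rows[[length(rows) + 1]] <- vrow(pid, gene = "PIK3CA", vaf = 3,
      ref = "C", alt = "A", context3 = "TCC")
  }
  co <- mark_all_pathogenic(annotate_clonality(make_cohort(
    do.call(rbind, rows)
  )))
  res <- apobec_dominance_analysis(co, "PIK3CA")
  expect_equal(res$prop_apobec_dominant, 1)
  expect_equal(res$prop_apobec_subclonal, 1)
  expect_equal(res$p_value, 1)
  empty <- apobec_dominance_analysis(co, "NOSUCH")
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$p_value))
})
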