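#' Read a COSMIC-layout signature matrix
#'
#' Expects the COSMIC v2 probabilities-table layout: one row per trinucleotide
#' channel with label columns (`Substitution Type` + `Trinucleotide`, or a
#' `Somatic Mutation Type` column holding labels like `A[C>A]A`) followed by
#' one numeric column per signature. Rows are reordered to the canonical
#' [sbs96_channels()] order and each signature column is checked to sum to 1.
#'
#' @param path TSV path.
#' @return Numeric 96 x K matrix, rownames the channel labels, colnames the
#'   signature names.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lbl_col <- which(vapply(df, function(col) {
    is.character(col) && all(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", col))
  }, logical(1)))
  if (length(lbl_col)) {
    labels <- df[[lbl_col[1]]]
  } else {
    st <- names(df)[tolower(names(df)) %in%
      c("substitution type", "substitution.type")]
    tn <- names(df)[tolower(names(df)) %in% c("trinucleotide")]
    if (!length(st) || !length(tn)) {
      stop("cannot locate channel labels in signature file")
    }
    labels <- paste0(
      substr(df[[tn[1]]], 1, 1), "[", df[[st[1]]], "]",
      substr(df[[tn[1]]], 3, 3)
    )
  }
  num <- vapply(df, is.numeric, logical(1))
  sig <- as.matrix(df[, num, drop = FALSE])
  rownames(sig) <- labels
  sig <- sig[sbs96_channels(), , drop = FALSE]
  csums <- colSums(sig)
  if (any(abs(csums - 1) > 1e-6)) {
    stop("signature column(s) do not sum to 1: ",
      paste(colnames(sig)[abs(csums - 1) > 1e-6], collapse = ", "))
  }
  sig
}

#' A synthetic reference signature set
#'
#' A small set of synthetic mutational signatures in COSMIC v2 layout and
#' naming, built in code for testing and simulation; these are NOT the COSMIC
#' signatures (which are not redistributable) but caricatures of the same
#' processes, sharp enough for exposure-recovery work:
#' \describe{
#'   \item{Signature 1}{ageing-like, C>T concentrated at NpCpG;}
#'   \item{Signature 2}{APOBEC-like C>T at TpCpN;}
#'   \item{Signature 3}{broad with a T>A / T>G transversion skew (HRD-like
#'     breadth, kept distinguishable from the flat profile);}
#'   \item{Signature 5}{flat with mild T>C preference;}
#'   \item{Signature 13}{APOBEC-like C>G at TpCpN, strongest at TCT/TCA.}
#' }
#'
#' @return 96 x 5 column-stochastic matrix.
#' @export
synthetic_signature_matrix <- function() {
  ch <- sbs96_channels()
  sub <- substr(ch, 3, 5)
  p5 <- substr(ch, 1, 1)
  p3 <- substr(ch, 7, 7)
  floor_w <- 0.1 / 96
  s1 <- rep(floor_w, 96)
  s1[sub == "C>T" & p3 == "G"] <- 1
  s2 <- rep(floor_w, 96)
  s2[sub == "C>T" & p5 == "T"] <- 1
  s3 <- rep(1, 96)
  s3[sub %in% c("T>A", "T>G")] <- 3 # transversion-skewed broad profile
  s5 <- rep(1, 96)
  s5[sub == "T>C"] <- 2.5
  s13 <- rep(floor_w, 96)
  s13[sub == "C>G" & p5 == "T"] <- 0.5
  s13[sub == "C>G" & p5 == "T" & p3 %in% c("T", "A")] <- 1
  sig <- cbind(
    "Signature 1" = s1, "Signature 2" = s2, "Signature 3" = s3,
    "Signature 5" = s5, "Signature 13" = s13
  )
  rownames(sig) <- ch
  sweep(sig, 2, colSums(sig), "/")
}

#' Aggregate clonal and subclonal mutation sets
#'
#' Splits a cohort's SNVs (all calls with a trinucleotide context,
#' regardless of pathogenicity) into clonally dominant and subclonal sets by
#' the annotated dominance call, optionally within one subtype. Each unique
#' mutation site (chrom, pos, ref, alt) is counted once per set; a site that
#' is dominant in one patient and subclonal in another contributes once to
#' each set. Not-assessable variants contribute to neither.
#'
#' @param cohort An annotated [ctdna_cohort()].
#' @param subtype Optional subtype label to restrict patients.
#' @return List with `clonal` and `subclonal`, each a list of `mutations`
#'   (deduplicated data.frame with chrom, pos, ref, alt, context3, channel)
#'   and `catalogue` (96-vector).
#' @export
aggregate_clonal_subclonal <- function(cohort, subtype = NULL) {
  v <- cohort$variants
  if (is.null(v$dominance)) stop("run annotate_clonality() first")
  if (!is.null(subtype)) {
    pats <- cohort$clinical$patient_id[cohort$clinical$subtype == subtype]
    v <- v[v$patient_id %in% pats, , drop = FALSE]
  }
  v <- v[!is.na(v$context3) & v$context3 != "" &
    nchar(v$ref) == 1L & nchar(v$alt) == 1L &
    v$ref != "-" & v$alt != "-", , drop = FALSE]
  one_set <- function(dom) {
    s <- v[v$dominance == dom, , drop = FALSE]
    key <- paste(s$chrom, s$pos, s$ref, s$alt, sep = ":")
    s <- s[!duplicated(key), c("chrom", "pos", "ref", "alt", "context3"),
      drop = FALSE
    ]
    rownames(s) <- NULL
    if (nrow(s)) s$channel <- snv_channel(s$ref, s$alt, s$context3)
    list(
      mutations = s,
      catalogue = build_catalogue(channels = if (nrow(s)) s$channel else character(0))
    )
  }
  list(clonal = one_set("dominant"), subclonal = one_set("subclonal"))
}

.gss_min <- function(f, lower = 0, upper = 1, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower
  b <- upper
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- f(c1)
  f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2
      c2 <- c1
      f2 <- f1
      c1 <- b - gr * (b - a)
      f1 <- f(c1)
    } else {
      a <- c1
      c1 <- c2
      f1 <- f2
      c2 <- a + gr * (b - a)
      f2 <- f(c2)
    }
  }
  x <- (a + b) / 2
  list(minimum = x, objective = f(x))
}

#' Fit non-negative signature exposures to a catalogue
#'
#' Greedy forward-selection refitting in the style of iterative signature
#' deconvolution: starting from an empty exposure vector, each round finds
#' the single signature whose best weight addition (golden-section line
#' search on [0, 1]) most reduces the squared error between the normalised
#' catalogue and the exposure-weighted signature mix, renormalising the
#' exposure vector to sum at most 1; rounds stop when the relative error
#' improvement falls below `tol`. Weights below `discard_threshold` are then
#' zeroed and the remaining signatures re-fitted.
#'
#' @param catalogue 96-vector of channel counts (total >= 1).
#' @param signatures 96 x K column-stochastic signature matrix.
#' @param discard_threshold Exposures below this are set to 0 before the
#'   final re-fit.
#' @param tol Relative squared-error improvement below which rounds stop.
#' @return List of class `exposure_estimate`: `weights` (named K-vector,
#'   sum <= 1), `residual` (1 - sum of weights), `reconstruction_error`
#'   (residual sum of squares against the normalised catalogue).
#' @export
fit_exposures <- function(catalogue, signatures, discard_threshold = 0.06,
                          tol = 1e-3) {
  if (sum(catalogue) < 1) stop("catalogue is empty: nothing to fit")
  if (length(catalogue) != nrow(signatures)) {
    stop("catalogue and signature matrix dimensions disagree")
  }
  m <- catalogue / sum(catalogue)
  K <- ncol(signatures)
  StS <- crossprod(signatures)
  Stm <- as.numeric(crossprod(signatures, m))
  mm <- sum(m * m)
  sse <- function(w) {
    mm - 2 * sum(w * Stm) + sum(w * (StS %*% w))
  }
  greedy <- function(active) {
    w <- numeric(K)
    Sw <- numeric(K) # StS %*% w
    qv <- 0 # <w, Stm>
    r <- 0 # w' StS w
    err <- mm
    repeat {
      s <- sum(w)
      best <- NULL
      for (j in active) {
        T_ <- Stm[j]
        W_ <- Sw[j]
        H_ <- StS[j, j]
        # sse along w + a*e_j, renormalised to sum <= 1, in scalar form
        f <- function(a) {
          if (s + a <= 1) {
            err - 2 * a * (T_ - W_) + a * a * H_
          } else {
            u <- s + a
            mm - 2 * (qv + a * T_) / u + (r + 2 * a * W_ + a * a * H_) / u^2
          }
        }
        cand <- .gss_min(f)
        if (is.null(best) || cand$objective < best$objective) {
          best <- list(j = j, alpha = cand$minimum, objective = cand$objective)
        }
      }
      if (is.null(best) || err <= 0) break
      improvement <- (err - best$objective) / err
      if (!is.finite(improvement) || improvement < tol) break
      w[best$j] <- w[best$j] + best$alpha
      if (sum(w) > 1) w <- w / sum(w)
      Sw <- as.numeric(StS %*% w)
      qv <- sum(w * Stm)
      r <- sum(w * Sw)
      err <- mm - 2 * qv + r
    }
    list(w = w, err = err)
  }
  fit <- greedy(seq_len(K))
  w <- fit$w
  repeat {
    drop_idx <- which(w > 0 & w < discard_threshold)
    if (!length(drop_idx)) break
    active <- which(w >= discard_threshold)
    if (!length(active)) {
      w <- numeric(K)
      fit <- list(w = w, err = sse(w))
      break
    }
    fit <- greedy(active)
    w <- fit$w
  }
  names(w) <- colnames(signatures)
  structure(
    list(
      weights = w, residual = 1 - sum(w),
      reconstruction_error = fit$err
    ),
    class = "exposure_estimate"
  )
}

#' @export
print.exposure_estimate <- function(x, ...) {
  nz <- x$weights[x$weights > 0]
  cat("exposure_estimate:",
    if (length(nz)) {
      paste(sprintf("%s = %.3f", names(nz), nz), collapse = ", ")
    } else "(all zero)",
    sprintf("| residual %.3f, RSS %.2e\n", x$residual, x$reconstruction_error)
  )
  invisible(x)
}

#' Bootstrap signature exposures by subsampling mutations
#'
#' Re-fits exposures on repeated subsamples of a mutation set: each
#' iteration draws `floor(sample_frac * n)` mutations (without replacement
#' by default — fractional subsampling; classical with-replacement
#' resampling behind `replace = TRUE`), rebuilds the 96-channel catalogue
#' and calls [fit_exposures()]. Deterministic for a fixed seed.
#'
#' @param mutation_set data.frame of SNVs with a `channel` column (or
#'   `ref`/`alt`/`context3` columns from which channels are derived), e.g.
#'   one set from [aggregate_clonal_subclonal()]; at least 10 rows.
#' @param signatures 96 x K signature matrix.
#' @param n_iter Number of iterations (default 200).
#' @param sample_frac Fraction of mutations drawn per iteration (default
#'   0.9).
#' @param seed Integer seed.
#' @param replace Draw with replacement instead of subsampling.
#' @param ... Passed to [fit_exposures()].
#' @return List of class `bootstrap_result`: `exposures` (n_iter x K
#'   matrix), `median`, `q25`, `q75` (named K-vectors), `n_mutations`,
#'   `full_fit` (exposures on the complete set).
#' @export
bootstrap_exposures <- function(mutation_set, signatures, n_iter = 200,
                                sample_frac = 0.9, seed = 1,
                                replace = FALSE, ...) {
  ch <- if (!is.null(mutation_set$channel)) {
    mutation_set$channel
  } else {
    snv_channel(mutation_set$ref, mutation_set$alt, mutation_set$context3)
  }
  n <- length(ch)
  if (n < 10) stop("mutation set too small to subsample (< 10 mutations)")
  k <- max(1L, floor(sample_frac * n))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expo <- matrix(NA_real_, n_iter, ncol(signatures),
    dimnames = list(NULL, colnames(signatures))
  )
  idx_ch <- match(ch, sbs96_channels())
  if (anyNA(idx_ch)) stop("mutation set contains unknown channel labels")
  for (i in seq_len(n_iter)) {
    idx <- sample.int(n, k, replace = replace)
    cat_i <- tabulate(idx_ch[idx], nbins = 96L)
    expo[i, ] <- fit_exposures(cat_i, signatures, ...)$weights
  }
  structure(
    list(
      exposures = expo,
      median = apply(expo, 2, stats::median),
      q25 = apply(expo, 2, stats::quantile, 0.25, names = FALSE),
      q75 = apply(expo, 2, stats::quantile, 0.75, names = FALSE),
      n_mutations = n,
      full_fit = fit_exposures(build_catalogue(channels = ch), signatures, ...)
    ),
    class = "bootstrap_result"
  )
}

#' Compare bootstrap exposure distributions between two conditions
#'
#' Per signature, compares the two bootstrap exposure vectors with a
#' two-sided Mann-Whitney U-test and flags whether the interquartile ranges
#' are disjoint. A signature is highlighted as differing between conditions
#' only when p < 0.05 AND the IQRs do not overlap — the bootstrap vectors
#' are strongly autocorrelated with the point estimate, so the rank test
#' alone overstates certainty.
#'
#' @param boot_a,boot_b `bootstrap_result` objects over the same signature
#'   set (e.g. clonal and subclonal).
#' @param alpha Rank-test significance level for highlighting.
#' @return data.frame (signature, median_a, median_b, direction, p_value,
#'   iqr_disjoint, highlighted).
#' @export
compare_conditions <- function(boot_a, boot_b, alpha = 0.05) {
  if (!identical(colnames(boot_a$exposures), colnames(boot_b$exposures))) {
    stop("bootstrap results cover different signature sets")
  }
  sigs <- colnames(boot_a$exposures)
  res <- lapply(sigs, function(s) {
    xa <- boot_a$exposures[, s]
    xb <- boot_b$exposures[, s]
    p <- if (all(xa == xa[1]) && all(xb == xb[1]) && xa[1] == xb[1]) {
      1
    } else {
      suppressWarnings(
        stats::wilcox.test(xa, xb, alternative = "two.sided")$p.value
      )
    }
    disjoint <- boot_a$q75[s] < boot_b$q25[s] || boot_b$q75[s] < boot_a$q25[s]
    data.frame(
      signature = s,
      median_a = unname(boot_a$median[s]), median_b = unname(boot_b$median[s]),
      direction = if (boot_a$median[s] == boot_b$median[s]) {
        "none"
      } else if (boot_b$median[s] > boot_a$median[s]) {
        "higher in B"
      } else {
        "higher in A"
      },
      p_value = p, iqr_disjoint = disjoint,
      highlighted = !is.na(p) && p < alpha && disjoint,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' APOBEC consensus-site enrichment by clonal dominance
#'
#' Cross-tabulates a gene's assessable SNVs by dominance (dominant vs
#' subclonal) and APOBEC consensus-site status, with a two-sided Fisher
#' test. Used to ask whether subclonal mutations in a driver gene arise
#' preferentially from APOBEC mutagenesis.
#'
#' @param cohort An annotated [ctdna_cohort()].
#' @param gene Gene symbol.
#' @param subtype Optional subtype restriction.
#' @param pathogenic_only Restrict to pathogenic mutations (default).
#' @return List with `table` (2x2: rows dominant/subclonal, cols
#'   apobec/other), `prop_apobec_dominant`, `prop_apobec_subclonal`,
#'   `p_value`, `n`. All-`NA` result when no assessable SNVs qualify.
#' @export
apobec_dominance_analysis <- function(cohort, gene, subtype = NULL,
                                      pathogenic_only = TRUE) {
  v <- .assessable(cohort, pathogenic_only)
  if (!is.null(subtype)) {
    pats <- cohort$clinical$patient_id[cohort$clinical$subtype == subtype]
    v <- v[v$patient_id %in% pats, , drop = FALSE]
  }
  v <- v[v$gene == gene & !is.na(v$context3) & v$context3 != "" &
    nchar(v$ref) == 1 & nchar(v$alt) == 1 &
    v$ref != "-" & v$alt != "-", , drop = FALSE]
  if (!nrow(v)) {
    return(list(
      table = NULL, prop_apobec_dominant = NA_real_,
      prop_apobec_subclonal = NA_real_, p_value = NA_real_, n = 0L
    ))
  }
  apo <- is_apobec_site(v$ref, v$alt, v$context3)
  dom <- v$dominance == "dominant"
  tab <- matrix(
    c(sum(dom & apo), sum(dom & !apo), sum(!dom & apo), sum(!dom & !apo)),
    2, 2,
    byrow = TRUE,
    dimnames = list(c("dominant", "subclonal"), c("apobec", "other"))
  )
  p <- suppressWarnings(fisher_exact_2x2(tab)$p_value)
  list(
    table = tab,
    prop_apobec_dominant = if (sum(dom)) mean(apo[dom]) else NA_real_,
    prop_apobec_subclonal = if (sum(!dom)) mean(apo[!dom]) else NA_real_,
    p_value = p, n = nrow(v)
  )
}

#' Write a 96-channel catalogue as TSV
#'
#' @param catalogue Named 96-vector.
#' @param path Output path.
#' @param metadata Optional `#`-header metadata.
#' @return Invisibly, `path`.
#' @export
write_catalogue <- function(catalogue, path, metadata = NULL) {
  df <- data.frame(
    channel = names(catalogue), count = as.integer(catalogue),
    stringsAsFactors = FALSE
  )
  .write_tsv_meta(df, path, metadata)
  invisible(path)
}
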