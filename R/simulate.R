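#' Configuration for the synthetic ctDNA cohort generator
#'
#' Defaults emulate a large advanced-breast-cancer liquid-biopsy cohort:
#' 800 patients with the published subtype mix, per-gene pathogenic
#' mutation prevalences matching the printed gene frequencies plus a long
#' tail of lower-frequency panel genes, truncal mVAF log-normally
#' distributed (median 10%, sdlog 1, truncated to (0.1, 80)%), subclonal
#' cancer fractions Beta(1.2, 2.5), additive truncated-Gaussian VAF noise
#' of 0.25 percentage points, near-50%-VAF germline contaminants with
#' population allele frequencies above the filter cut-off, multi-hit
#' hotspot spectra for ESR1 and PIK3CA, APOBEC trinucleotide-context
#' enrichment of subclonal mutations in HR+ disease, and HER2 plasma copy
#' number generated from the purity mixing model.
#'
#' @param n_patients Cohort size.
#' @param subtype_props Named proportions over HR+HER2-, HR+HER2+,
#'   HR-HER2+, TNBC, unknown (must sum to 1).
#' @param gene_prevalence Named vector of per-gene carrier probabilities.
#' @param subtype_multipliers Named list: per gene, named multipliers on the
#'   prevalence for specific subtypes.
#' @param hotspot_spectra Named list: per gene, named weights over hotspot
#'   protein changes; remaining probability `novel_frac` goes to unique
#'   novel changes.
#' @param novel_frac Fraction of a gene's mutations that are novel
#'   (non-hotspot) changes.
#' @param multi_hit Named vector of per-extra-mutation probabilities for
#'   multi-hit genes (each carrier draws `1 + rbinom(2, p)` mutations).
#' @param mvaf_meanlog,mvaf_sdlog,mvaf_range Truncal mVAF distribution
#'   (log-normal, percent).
#' @param cf_shape1,cf_shape2 Beta parameters of subclonal cancer fractions.
#' @param vaf_noise_sd Additive VAF measurement noise, percentage points.
#' @param passenger_rate Poisson mean of extra non-pathogenic passenger
#'   SNVs per patient.
#' @param germline_rate Probability a patient carries one near-50%-VAF
#'   germline contaminant call.
#' @param germline_vaf_sd SD of the contaminant VAF around 50%.
#' @param germline_popaf_medlog Median (log scale) of the contaminant
#'   population AF in percent.
#' @param apobec_enrichment Named list per subtype with elements `dominant`
#'   and `subclonal`: probability that a novel SNV draws an
#'   APOBEC-consensus context.
#' @param her2_amp_cn True HER2 copy number in tissue-amplified patients.
#' @param cn_noise_sd SD of the observed plasma copy-number noise.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    n_patients = 800,
    subtype_props = c(
      "HR+HER2-" = 0.644, "HR+HER2+" = 0.046, "HR-HER2+" = 0.045,
      "TNBC" = 0.173, "unknown" = 0.092
    ),
    gene_prevalence = c(
      TP53 = 0.441, PIK3CA = 0.349, ESR1 = 0.331, GATA3 = 0.110,
      ARID1A = 0.078, PTEN = 0.069, CDH1 = 0.06, ATM = 0.06, AKT1 = 0.05,
      RB1 = 0.05, NF1 = 0.05, MAP3K1 = 0.05, APC = 0.05, BRCA1 = 0.05,
      BRCA2 = 0.05, NOTCH1 = 0.05, HER2 = 0.04, KRAS = 0.04, KIT = 0.04,
      MET = 0.04, STK11 = 0.04, CDKN2A = 0.04, SMAD4 = 0.03, FGFR1 = 0.03,
      ALK = 0.03, BRAF = 0.02, EGFR = 0.02, FGFR2 = 0.02
    ),
    subtype_multipliers = list(
      ESR1 = c("HR+HER2-" = 1.2, "HR+HER2+" = 0.8, "HR-HER2+" = 0.2,
        TNBC = 0.05),
      GATA3 = c(TNBC = 0.1),
      TP53 = c(TNBC = 1.8),
      PIK3CA = c(TNBC = 0.5),
      HER2 = c("HR+HER2+" = 3, "HR-HER2+" = 3)
    ),
    hotspot_spectra = list(
      ESR1 = c(D538G = 0.35, Y537S = 0.2, Y537N = 0.1, Y537C = 0.05,
        E380Q = 0.15, L536R = 0.05),
      PIK3CA = c(H1047R = 0.3, E545K = 0.2, E542K = 0.12, N345K = 0.08,
        H1047L = 0.06, E726K = 0.06, G1049R = 0.04, C420R = 0.04),
      AKT1 = c(E17K = 0.9),
      KRAS = c(G12D = 0.4, G12V = 0.3, G13D = 0.2),
      BRAF = c(V600E = 0.8),
      TP53 = c(R175H = 0.1, R248Q = 0.1, R273H = 0.1, R273C = 0.06,
        R282W = 0.05, Y220C = 0.05)
    ),
    novel_frac = 0.2,
    multi_hit = c(ESR1 = 0.3, PIK3CA = 0.12),
    mvaf_meanlog = log(10), mvaf_sdlog = 1, mvaf_range = c(0.1, 80),
    cf_shape1 = 1.2, cf_shape2 = 2.5,
    vaf_noise_sd = 0.25,
    passenger_rate = 2,
    germline_rate = 0.1,
    germline_vaf_sd = 1,
    germline_popaf_medlog = log(0.05),
    apobec_enrichment = list(
      "HR+HER2-" = c(dominant = 0.10, subclonal = 0.40),
      "HR+HER2+" = c(dominant = 0.10, subclonal = 0.25),
      "HR-HER2+" = c(dominant = 0.05, subclonal = 0.15),
      "TNBC" = c(dominant = 0.10, subclonal = 0.20),
      "unknown" = c(dominant = 0.05, subclonal = 0.15)
    ),
    her2_amp_cn = 10,
    cn_noise_sd = 0.5,
    seed = 1) {
  if (abs(sum(subtype_props) - 1) > 1e-8) {
    stop("subtype_props must sum to 1")
  }
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (vaf_noise_sd < 0 || cn_noise_sd < 0) stop("noise sd must be >= 0")
  structure(as.list(environment()), class = "cohort_config")
}

# channel distributions used by the generator: APOBEC-like draws follow a
# Signature 13 / Signature 2 blend, background a Signature 1 / Signature 5
# blend, taken from the synthetic reference set
.generator_channel_dists <- function() {
  sig <- synthetic_signature_matrix()
  list(
    apobec = as.numeric(0.75 * sig[, "Signature 13"] + 0.25 * sig[, "Signature 2"]),
    background = as.numeric(0.5 * sig[, "Signature 1"] + 0.5 * sig[, "Signature 5"])
  )
}

.channel_to_snv <- function(channel) {
  data.frame(
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5),
    context3 = paste0(
      substr(channel, 1, 1), substr(channel, 3, 3), substr(channel, 7, 7)
    ),
    stringsAsFactors = FALSE
  )
}

.rtrunc_lnorm <- function(n, meanlog, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * n, meanlog, sdlog)
    out <- c(out, x[x > range[1] & x < range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic ctDNA cohort with ground truth
#'
#' Each patient draws a subtype, a latent tumour purity (truncal mVAF), and
#' per-gene pathogenic mutations; one somatic mutation per mutated patient
#' is truncal (cancer fraction 1, setting the mVAF) and the rest carry
#' Beta-distributed cancer fractions, so VAF = CF x mVAF before additive
#' truncated-Gaussian noise. Hotspot mutations occupy fixed synthetic
#' coordinates shared across patients; novel and passenger mutations get
#' unique coordinates and draw their trinucleotide context from an
#' APOBEC/background channel mixture whose APOBEC weight depends on subtype
#' and dominance class. Germline contaminants are added at VAF ~ N(50, 1)
#' with population AF above the filter cut-off. Observed HER2 plasma copy
#' number follows the purity mixing model 2(1 - t) + t x CN_true + noise.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (a [ctdna_cohort()]), `truth` (list of
#'   `variants` and `patients` ground-truth data.frames) and `resources`
#'   (an [annotation_resources()] covering the generated hotspots).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  dists <- .generator_channel_dists()
  channels <- sbs96_channels()
  genes <- names(config$gene_prevalence)

  # hotspot registry: fixed synthetic coordinates and contexts per hotspot
  registry <- list()
  for (g in names(config$hotspot_spectra)) {
    hs <- names(config$hotspot_spectra[[g]])
    ch <- sample(channels, length(hs), replace = TRUE,
      prob = dists$background)
    snv <- .channel_to_snv(ch)
    registry[[g]] <- data.frame(
      gene = g, protein_change = hs,
      chrom = paste0("SIM_", g),
      pos = 1000L + 3L * seq_along(hs),
      snv, stringsAsFactors = FALSE
    )
  }

  pid <- sprintf("P%04d", seq_len(config$n_patients))
  subtype <- sample(names(config$subtype_props), config$n_patients,
    replace = TRUE, prob = config$subtype_props)
  mvaf_true <- .rtrunc_lnorm(config$n_patients, config$mvaf_meanlog,
    config$mvaf_sdlog, config$mvaf_range)
  lines_tx <- sample(0:6, config$n_patients, replace = TRUE,
    prob = c(0.15, 0.2, 0.2, 0.15, 0.12, 0.1, 0.08))
  sites <- c("bone", "liver", "lymph node", "soft tissue", "visceral")
  disease_sites <- vapply(seq_len(config$n_patients), function(i) {
    paste(sample(sites, 1 + stats::rbinom(1, 3, 0.4)), collapse = ",")
  }, character(1))
  her2_pos <- subtype %in% c("HR+HER2+", "HR-HER2+")

  # per-subtype prevalence with gene-specific multipliers
  st_levels <- names(config$subtype_props)
  prev_mat <- vapply(genes, function(g) {
    p <- rep(config$gene_prevalence[[g]], length(st_levels))
    m <- config$subtype_multipliers[[g]]
    if (!is.null(m)) {
      hit <- match(names(m), st_levels)
      p[hit[!is.na(hit)]] <- p[hit[!is.na(hit)]] * m[!is.na(hit)]
    }
    pmin(p, 0.95)
  }, numeric(length(st_levels)))
  rownames(prev_mat) <- st_levels

  np <- config$n_patients
  ng <- length(genes)
  st_idx <- match(subtype, st_levels)
  carrier <- matrix(stats::runif(np * ng), np, ng) <
    prev_mat[st_idx, , drop = FALSE]
  counts <- carrier * 1L
  for (g in names(config$multi_hit)) {
    j <- match(g, genes)
    counts[, j] <- counts[, j] +
      carrier[, j] * stats::rbinom(np, 2L, config$multi_hit[[g]])
  }
  # passengers only where a tumour is shedding detectable ctDNA:
  # patients with no driver call yield no calls at all
  n_pass <- stats::rpois(np, config$passenger_rate) * (rowSums(counts) > 0)

  pat_i <- c(
    rep(rep(seq_len(np), ng), as.vector(counts)),
    rep(seq_len(np), n_pass)
  )
  gene_row <- c(
    rep(rep(genes, each = np), as.vector(counts)),
    sample(genes, sum(n_pass), replace = TRUE)
  )
  vclass <- c(
    rep("missense", sum(counts)), rep("synonymous", sum(n_pass))
  )
  nr <- length(pat_i)
  has_spec <- gene_row %in% names(config$hotspot_spectra) &
    vclass == "missense"
  is_hotspot <- has_spec & stats::runif(nr) >= config$novel_frac
  change <- sprintf("X%dY", seq_len(nr))
  pos <- 100000L + 3L * seq_len(nr)
  for (g in names(config$hotspot_spectra)) {
    rows_g <- which(is_hotspot & gene_row == g)
    if (!length(rows_g)) next
    spec <- config$hotspot_spectra[[g]]
    # distinct hotspot changes within a patient: sample without replacement
    by_pat <- split(rows_g, pat_i[rows_g])
    for (ix in by_pat) {
      k <- min(length(ix), length(spec))
      hs <- sample(names(spec), k, prob = spec)
      change[ix[seq_len(k)]] <- hs
      if (length(ix) > k) is_hotspot[ix[-seq_len(k)]] <- FALSE
    }
    reg_m <- match(change[rows_g], registry[[g]]$protein_change)
    ok <- !is.na(reg_m)
    pos[rows_g[ok]] <- registry[[g]]$pos[reg_m[ok]]
  }
  som <- data.frame(
    gene = gene_row, hotspot = is_hotspot, protein_change = change,
    chrom = paste0("SIM_", gene_row), pos = pos, variant_class = vclass,
    patient_id = pid[pat_i], stringsAsFactors = FALSE
  )
  # one truncal mutation per mutated patient anchors the mVAF; the rest
  # draw subclonal cancer fractions
  cf <- pmax(stats::rbeta(nr, config$cf_shape1, config$cf_shape2), 0.02)
  truncal <- vapply(
    split(seq_len(nr), pat_i), function(ix) ix[sample.int(length(ix), 1L)],
    integer(1)
  )
  cf[truncal] <- 1
  som$true_cf <- cf
  som$true_dominant <- som$true_cf >= 0.5
  som$mvaf_true <- mvaf_true[match(som$patient_id, pid)]
  som$vaf_true <- som$true_cf * som$mvaf_true
  som$subtype <- subtype[match(som$patient_id, pid)]

  # contexts: hotspots from the registry; novel/passenger draws depend on
  # subtype and dominance class through the APOBEC enrichment
  som$ref <- som$alt <- som$context3 <- NA_character_
  hs_idx <- which(som$hotspot)
  if (length(hs_idx)) {
    reg_all <- do.call(rbind, registry)
    m <- match(
      paste(som$gene[hs_idx], som$protein_change[hs_idx]),
      paste(reg_all$gene, reg_all$protein_change)
    )
    som$ref[hs_idx] <- reg_all$ref[m]
    som$alt[hs_idx] <- reg_all$alt[m]
    som$context3[hs_idx] <- reg_all$context3[m]
  }
  nov_idx <- which(!som$hotspot)
  if (length(nov_idx)) {
    p_apo <- vapply(nov_idx, function(j) {
      e <- config$apobec_enrichment[[som$subtype[j]]]
      if (is.null(e)) e <- c(dominant = 0.05, subclonal = 0.05)
      unname(e[[if (som$true_dominant[j]) "dominant" else "subclonal"]])
    }, numeric(1))
    is_apo <- stats::runif(length(nov_idx)) < p_apo
    ch <- character(length(nov_idx))
    if (any(is_apo)) {
      ch[is_apo] <- sample(channels, sum(is_apo), replace = TRUE,
        prob = dists$apobec)
    }
    if (any(!is_apo)) {
      ch[!is_apo] <- sample(channels, sum(!is_apo), replace = TRUE,
        prob = dists$background)
    }
    snv <- .channel_to_snv(ch)
    som$ref[nov_idx] <- snv$ref
    som$alt[nov_idx] <- snv$alt
    som$context3[nov_idx] <- snv$context3
  }
  som$vaf_obs <- pmin(pmax(
    som$vaf_true + stats::rnorm(nrow(som), 0, config$vaf_noise_sd), 0.01
  ), 100)
  som$germline <- FALSE
  som$pop_af_pct <- NA_real_

  # near-heterozygous germline contaminants with population AF support
  germ_pat <- which(stats::runif(config$n_patients) < config$germline_rate)
  if (length(germ_pat)) {
    ch <- sample(channels, length(germ_pat), replace = TRUE,
      prob = dists$background)
    snv <- .channel_to_snv(ch)
    germ <- data.frame(
      gene = sample(genes, length(germ_pat), replace = TRUE),
      hotspot = FALSE,
      protein_change = sprintf("G%dR", seq_along(germ_pat)),
      chrom = "SIM_GERMLINE",
      pos = 500000L + 3L * seq_along(germ_pat),
      variant_class = "missense",
      patient_id = pid[germ_pat],
      true_cf = NA_real_, true_dominant = NA,
      mvaf_true = mvaf_true[germ_pat],
      vaf_true = NA_real_,
      subtype = subtype[germ_pat],
      snv,
      vaf_obs = pmin(pmax(
        stats::rnorm(length(germ_pat), 50, config$germline_vaf_sd), 0.01
      ), 100),
      germline = TRUE,
      pop_af_pct = stats::rlnorm(length(germ_pat),
        config$germline_popaf_medlog, 1),
      stringsAsFactors = FALSE
    )
    som <- rbind(som, germ)
  }

  variants <- data.frame(
    patient_id = som$patient_id, gene = som$gene, chrom = som$chrom,
    pos = som$pos, ref = som$ref, alt = som$alt,
    protein_change = som$protein_change, variant_class = som$variant_class,
    vaf_pct = som$vaf_obs, pop_af_pct = som$pop_af_pct,
    context3 = som$context3, stringsAsFactors = FALSE
  )
  clinical <- data.frame(
    patient_id = pid, subtype = subtype, lines_of_treatment = lines_tx,
    disease_sites = disease_sites,
    tissue_her2_status = ifelse(her2_pos, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  t_true <- pmin(1, 2 * mvaf_true / 100)
  her2_cn_true <- ifelse(her2_pos, config$her2_amp_cn, 2)
  cn <- data.frame(
    patient_id = pid, gene = "ERBB2",
    observed_pcn = pmax(0,
      2 * (1 - t_true) + t_true * her2_cn_true +
        stats::rnorm(config$n_patients, 0, config$cn_noise_sd)),
    stringsAsFactors = FALSE
  )
  truth_variants <- data.frame(
    patient_id = som$patient_id, gene = som$gene, chrom = som$chrom,
    pos = som$pos, ref = som$ref, alt = som$alt,
    protein_change = som$protein_change,
    true_cf = som$true_cf,
    true_dominance = ifelse(is.na(som$true_dominant), NA_character_,
      ifelse(som$true_dominant, "dominant", "subclonal")),
    true_apobec = ifelse(is.na(som$context3), NA,
      is_apobec_site(som$ref, som$alt, som$context3)),
    germline = som$germline,
    vaf_true = som$vaf_true,
    stringsAsFactors = FALSE
  )
  truth_patients <- data.frame(
    patient_id = pid, mvaf_true = mvaf_true, t_true = t_true,
    her2_cn_true = her2_cn_true,
    tissue_her2_positive = her2_pos,
    stringsAsFactors = FALSE
  )
  hs_tab <- do.call(rbind, registry)
  resources <- annotation_resources(
    hotspots = hs_tab[, c("gene", "protein_change")],
    key_breast_genes = c("ESR1", "HER2", "PIK3CA", "EGFR", "RB1", "FGFR2")
  )
  list(
    cohort = ctdna_cohort(variants, clinical, cn),
    truth = list(variants = truth_variants, patients = truth_patients),
    resources = resources
  )
}

#' Sample a mutation list from a signature mixture
#'
#' Draws `n_mutations` channels i.i.d. from the exposure-weighted signature
#' mixture (any residual exposure mass is assigned to a uniform channel
#' distribution) and emits both a synthetic mutation list and its
#' 96-channel catalogue. The independent oracle for exposure-recovery
#' testing.
#'
#' @param signatures 96 x K signature matrix.
#' @param exposures Named (or K-long) non-negative vector, sum <= 1.
#' @param n_mutations Number of mutations to draw (>= 1).
#' @param seed Integer seed.
#' @return List with `mutations` (data.frame chrom, pos, ref, alt,
#'   context3, channel) and `catalogue`.
#' @export
generate_signature_mixture <- function(signatures, exposures, n_mutations,
                                       seed = 1) {
  if (n_mutations < 1) stop("n_mutations must be >= 1")
  if (any(exposures < 0) || sum(exposures) > 1 + 1e-8) {
    stop("exposures must be non-negative with sum <= 1")
  }
  w <- numeric(ncol(signatures))
  names(w) <- colnames(signatures)
  if (!is.null(names(exposures))) {
    w[names(exposures)] <- exposures
  } else {
    w[seq_along(exposures)] <- exposures
  }
  mix <- as.numeric(signatures %*% w) + (1 - sum(w)) / nrow(signatures)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ch <- sample(sbs96_channels(), n_mutations, replace = TRUE, prob = mix)
  snv <- .channel_to_snv(ch)
  mut <- data.frame(
    chrom = "SIM_SIG", pos = 3L * seq_len(n_mutations), snv, channel = ch,
    stringsAsFactors = FALSE
  )
  list(mutations = mut, catalogue = build_catalogue(channels = ch))
}
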