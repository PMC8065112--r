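#' The 96 trinucleotide substitution channels
#'
#' Channel labels follow the strand-collapsed convention used by the COSMIC
#' signature catalogues: six pyrimidine substitution classes (C>A, C>G, C>T,
#' T>A, T>C, T>G), each crossed with the 16 flanking-base combinations, in
#' alphabetical order within each class block. A substitution observed on a
#' purine reference base is reverse-complemented into this frame before
#' indexing.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`, in the canonical
#'   order.
#' @export
#' @examples
#' head(sbs96_channels())
sbs96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p5, p3) {
      paste0(p5, "[", s, "]", p3)
    })))
  }), use.names = FALSE)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of upper-case DNA strings (A/C/G/T only).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(b) {
    paste(rev(b), collapse = "")
  }, character(1)))
}

.check_snv_context <- function(ref, alt, context3) {
  ok_base <- function(b) b %in% c("A", "C", "G", "T")
  if (!all(nchar(ref) == 1L & nchar(alt) == 1L)) {
    stop("ref and alt must be single bases (SNVs only)")
  }
  if (!all(ok_base(ref)) || !all(ok_base(alt))) {
    stop("ref/alt contain bases outside A/C/G/T")
  }
  if (any(ref == alt)) {
    stop("ref and alt must differ")
  }
  if (!all(nchar(context3) == 3L)) {
    stop("context3 must be a 3-mer")
  }
  ctx_bases <- unlist(strsplit(context3, NULL))
  if (!all(ok_base(ctx_bases))) {
    stop("context3 contains bases outside A/C/G/T")
  }
  if (!all(substr(context3, 2, 2) == ref)) {
    stop("middle base of context3 must equal ref")
  }
  invisible(TRUE)
}

#' Map an SNV to its 96-channel label
#'
#' Purine-reference substitutions (ref G or A) are reverse-complemented into
#' the pyrimidine frame, so `G>A` in `CGT` and `C>T` in `ACG` land in the same
#' channel.
#'
#' @param ref,alt Single reference/alternate bases (vectorised).
#' @param context3 Reference trinucleotide centred on the variant position;
#'   its middle base must equal `ref`.
#' @return Character vector of channel labels as in [sbs96_channels()].
#' @export
#' @examples
#' snv_channel("C", "T", "ACG")
#' snv_channel("G", "A", "CGT")  # same channel, opposite strand
snv_channel <- function(ref, alt, context3) {
  n <- max(length(ref), length(alt), length(context3))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context3 <- rep_len(toupper(context3), n)
  .check_snv_context(ref, alt, context3)
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    context3[flip] <- revcomp(context3[flip])
  }
  paste0(
    substr(context3, 1, 1), "[", ref, ">", alt, "]", substr(context3, 3, 3)
  )
}

#' Classify an SNV as an APOBEC consensus site
#'
#' APOBEC cytidine deaminases preferentially mutate cytosine in a TpC
#' dinucleotide. The consensus set used here is T(C>G)T, T(C>G)A and T(C>A)N,
#' evaluated on either strand (purine-reference calls are mapped to the
#' pyrimidine frame first).
#'
#' @inheritParams snv_channel
#' @return Logical vector.
#' @export
#' @examples
#' is_apobec_site("C", "G", "TCT")   # TRUE
#' is_apobec_site("G", "C", "AGA")   # TRUE (reverse strand of the above)
#' is_apobec_site("C", "T", "TCA")   # FALSE (C>T not in the consensus set)
is_apobec_site <- function(ref, alt, context3) {
  ch <- snv_channel(ref, alt, context3)
  sub <- substr(ch, 3, 5)
  p5 <- substr(ch, 1, 1)
  p3 <- substr(ch, 7, 7)
  (sub == "C>G" & p5 == "T" & p3 %in% c("T", "A")) |
    (sub == "C>A" & p5 == "T")
}

#' Build a 96-channel mutation catalogue
#'
#' Counts SNVs into the 96 strand-collapsed trinucleotide channels. The sum
#' of the catalogue equals the number of input SNVs.
#'
#' @param ref,alt,context3 Parallel vectors describing SNVs (see
#'   [snv_channel()]), or alternatively `channels` directly.
#' @param channels Optional character vector of precomputed channel labels;
#'   if supplied, `ref`/`alt`/`context3` are ignored.
#' @return Named integer vector of length 96 in [sbs96_channels()] order.
#' @export
build_catalogue <- function(ref = NULL, alt = NULL, context3 = NULL,
                            channels = NULL) {
  if (is.null(channels)) {
    if (length(ref) == 0L) {
      channels <- character(0)
    } else {
      channels <- snv_channel(ref, alt, context3)
    }
  }
  all_ch <- sbs96_channels()
  bad <- setdiff(channels, all_ch)
  if (length(bad)) {
    stop("unknown channel label(s): ", paste(utils::head(bad, 3), collapse = ", "))
  }
  counts <- table(factor(channels, levels = all_ch))
  out <- as.integer(counts)
  names(out) <- all_ch
  out
}
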