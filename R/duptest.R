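# -- duplication vs somatic-mutation test --------------------------------------
#
# When a normally single-copy Y-STR shows two alleles, a constitutive
# duplication carries double the DNA dose (the two alleles' read depths sum to
# about twice the expected locus/reference ratio), while a somatic mutant
# splits a single dose (the summed ratio stays in the single-dose range). The
# expected ratio range comes from donor samples with single alleles at both
# the query locus and a similar-size reference locus in the same multiplex.

#' Empirical expected read-depth ratio range
#'
#' Per-donor ratio depth(locus)/depth(reference_locus) over donors carrying a
#' single allele at both loci; returns Tukey fences (Q1 - 1.5 IQR, Q3 +
#' 1.5 IQR) clipped to the observed minimum/maximum.
#'
#' @param depth_tab Data frame with sample, locus, depth (one row per called
#'   allele; stutter-adjusted depths recommended).
#' @param locus,reference_locus Locus names.
#' @param exclude Samples excluded from the donor set (usually the query).
#' @param min_donors Minimum usable donors (default 10).
#' @return Numeric `c(low, high)` with attribute `ratios`.
#' @export
expected_ratio_range <- function(depth_tab, locus, reference_locus,
                                 exclude = character(), min_donors = 10L) {
  ratios <- donor_ratios(depth_tab, locus, reference_locus, exclude)
  if (length(ratios) < min_donors)
    stop("insufficient data: only ", length(ratios), " usable donor samples ",
         "for ", locus, " vs ", reference_locus)
  q <- stats::quantile(ratios, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  low <- max(q[1] - 1.5 * iqr, min(ratios))
  high <- min(q[2] + 1.5 * iqr, max(ratios))
  structure(c(low = low, high = high), ratios = ratios)
}

donor_ratios <- function(depth_tab, locus, reference_locus, exclude) {
  keep <- !(depth_tab$sample %in% exclude)
  dt <- depth_tab[keep & depth_tab$locus %in% c(locus, reference_locus), ,
                  drop = FALSE]
  ratios <- c()
  for (s in unique(dt$sample)) {
    a <- dt$depth[dt$sample == s & dt$locus == locus]
    b <- dt$depth[dt$sample == s & dt$locus == reference_locus]
    if (length(a) == 1L && length(b) == 1L && b > 0)
      ratios[s] <- a / b
  }
  ratios
}

#' Classify an extra allele as duplication or somatic mutant
#'
#' The query sample must carry exactly two alleles at `locus` and one at the
#' reference locus. Verdict: `duplication` when the summed ratio exceeds the
#' expected range's upper fence and is at least `guard` (default 1.5) times
#' its midpoint; `somatic` when the summed ratio lies inside the range;
#' otherwise `ambiguous`.
#'
#' @param depth_tab Data frame with sample, locus, depth.
#' @param sample Query sample id.
#' @param locus Locus showing two alleles.
#' @param reference_locus Reference locus; chosen automatically by nearest
#'   amplicon size when `NULL`.
#' @param range Optional precomputed `c(low, high)`; computed from the other
#'   samples in `depth_tab` when `NULL`.
#' @param guard Duplication guard multiple of the range midpoint.
#' @param catalog A `locus_catalog` (for automatic reference choice).
#' @param min_donors Passed to [expected_ratio_range()].
#' @return A `ratio_test_result` list (sample, locus, reference_locus,
#'   expected range, per-allele ratios, summed ratio, verdict).
#' @export
classify_extra_allele <- function(depth_tab, sample, locus,
                                  reference_locus = NULL, range = NULL,
                                  guard = 1.5, catalog = default_catalog(),
                                  min_donors = 10L) {
  a <- depth_tab$depth[depth_tab$sample == sample & depth_tab$locus == locus]
  if (length(a) != 2L)
    stop("input error: query must carry exactly 2 alleles at ", locus,
         " (found ", length(a), ")")
  if (is.null(reference_locus))
    reference_locus <- choose_reference_locus(depth_tab, sample, locus, catalog)
  b <- depth_tab$depth[depth_tab$sample == sample &
                       depth_tab$locus == reference_locus]
  if (length(b) != 1L)
    stop("input error: query must carry exactly 1 allele at reference locus ",
         reference_locus)
  if (is.null(range))
    range <- expected_ratio_range(depth_tab, locus, reference_locus,
                                  exclude = sample, min_donors = min_donors)
  per_allele <- a / b
  summed <- sum(per_allele)
  mid <- mean(range[1:2])
  verdict <- if (summed > range[2] && summed >= guard * mid) "duplication"
             else if (summed >= range[1] && summed <= range[2]) "somatic"
             else "ambiguous"
  structure(
    list(sample = sample, locus = locus, reference_locus = reference_locus,
         expected_ratio_low = unname(range[1]),
         expected_ratio_high = unname(range[2]),
         per_allele_ratios = unname(per_allele),
         summed_ratio = unname(summed), verdict = verdict),
    class = "ratio_test_result")
}

#' @export
print.ratio_test_result <- function(x, ...) {
  cat(sprintf(
    "<ratio_test_result> %s @ %s (ref %s): sum ratio %.2f vs [%.2f, %.2f] -> %s\n",
    x$sample, x$locus, x$reference_locus, x$summed_ratio,
    x$expected_ratio_low, x$expected_ratio_high, x$verdict))
  invisible(x)
}

# nearest-amplicon-size single-copy locus also present with one allele in the
# query sample
choose_reference_locus <- function(depth_tab, sample, locus,
                                   catalog = default_catalog()) {
  sizes <- amplicon_sizes(catalog)
  cand <- names(sizes)[names(sizes) != locus]
  cand <- cand[vapply(cand, function(l) catalog[[l]]$copies == 1L, logical(1))]
  ok <- vapply(cand, function(l)
    sum(depth_tab$sample == sample & depth_tab$locus == l) == 1L, logical(1))
  cand <- cand[ok]
  if (!length(cand)) stop("no usable reference locus for ", locus)
  cand[which.min(abs(sizes[cand] - sizes[locus]))]
}

#' Approximate amplicon sizes of the catalogue loci
#'
#' Reference array length plus both flank windows; used to pick a
#' similar-size reference marker from the same multiplex.
#'
#' @param catalog A `locus_catalog`.
#' @return Named numeric vector of sizes in nt.
#' @export
amplicon_sizes <- function(catalog = default_catalog()) {
  vapply(catalog, function(def)
    reference_array_length(def) + 2 * def$flank_window, numeric(1))
}

#' Run the ratio test across a profile
#'
#' Applies [classify_extra_allele()] to every (sample, locus) showing two
#' called alleles at a normally single-copy locus.
#'
#' @param depth_tab Data frame with sample, locus, depth.
#' @param catalog A `locus_catalog`.
#' @param ... Passed to [classify_extra_allele()].
#' @return Data frame of verdicts.
#' @export
ratio_test_profile <- function(depth_tab, catalog = default_catalog(), ...) {
  multi <- unique(depth_tab[, c("sample", "locus")])
  counts <- table(paste(depth_tab$sample, depth_tab$locus, sep = "\r"))
  out <- list()
  for (i in seq_len(nrow(multi))) {
    s <- multi$sample[i]; l <- multi$locus[i]
    if (catalog[[l]]$copies != 1L) next
    if (counts[[paste(s, l, sep = "\r")]] != 2L) next
    res <- classify_extra_allele(depth_tab, s, l, catalog = catalog, ...)
    out[[length(out) + 1L]] <- data.frame(
      sample = s, locus = l, reference_locus = res$reference_locus,
      summed_ratio = res$summed_ratio,
      low = res$expected_ratio_low, high = res$expected_ratio_high,
      verdict = res$verdict, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(
    sample = character(), locus = character(), reference_locus = character(),
    summed_ratio = numeric(), low = numeric(), high = numeric(),
    verdict = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
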