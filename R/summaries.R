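# -- diversity, isometric-group, novelty and headline summaries ----------------

#' Per-locus allele diversity table
#'
#' Counts distinct length-based alleles (as CE would see them) and distinct
#' sequence-based alleles per locus, with the percentage increase, plus a
#' totals row. DYS385a,b is one row (both copies pooled).
#'
#' @param profile Data frame with locus, length_name and mps_name columns
#'   (one row per called allele).
#' @param known Optional known-variant catalogue (see [novelty_filter()]);
#'   when given, a per-locus novel count column is added.
#' @return Data frame (locus, n_length_alleles, n_sequence_alleles,
#'   pct_increase, n_novel) ordered by decreasing pct_increase with a "Total"
#'   row appended; the integer-rounded overall increase is in
#'   `attr(, "headline_pct")`.
#' @export
diversity_table <- function(profile, known = NULL) {
  loci <- unique(profile$locus)
  rows <- lapply(loci, function(l) {
    sub <- profile[profile$locus == l, , drop = FALSE]
    n_len <- length(unique(sub$length_name))
    n_seq <- length(unique(sub$mps_name))
    data.frame(locus = l, n_length_alleles = n_len, n_sequence_alleles = n_seq,
               pct_increase = if (n_len > 0)
                 round(100 * (n_seq - n_len) / n_len, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(known)) {
    nov <- novelty_filter(profile, known)
    out$n_novel <- vapply(out$locus, function(l)
      sum(nov$locus == l), integer(1))
  }
  out <- out[order(-out$pct_increase, out$locus), ]
  tot_len <- sum(out$n_length_alleles)
  tot_seq <- sum(out$n_sequence_alleles)
  total <- data.frame(locus = "Total", n_length_alleles = tot_len,
                      n_sequence_alleles = tot_seq,
                      pct_increase = round(100 * (tot_seq - tot_len) / tot_len,
                                           1),
                      stringsAsFactors = FALSE)
  if (!is.null(known)) total$n_novel <- sum(out$n_novel)
  out <- rbind(out, total)
  rownames(out) <- NULL
  attr(out, "headline_pct") <- round(100 * (tot_seq - tot_len) / tot_len)
  out
}

#' Isometric allele group tally
#'
#' Isometric groups are sets of >= 2 distinct sequence alleles sharing locus
#' and fragment length (length-based name).
#'
#' @param profile Data frame with locus, length_name, mps_name.
#' @return List with `groups` (locus, length_name, size), `histogram` (table
#'   of group sizes) and `n_loci` (loci exhibiting any group).
#' @export
isometric_groups <- function(profile) {
  key <- paste(profile$locus, profile$length_name, sep = "\r")
  sizes <- tapply(profile$mps_name, key, function(x) length(unique(x)))
  grp <- sizes[sizes >= 2]
  if (!length(grp)) {
    return(list(groups = data.frame(locus = character(),
                                    length_name = character(),
                                    size = integer()),
                histogram = table(integer()), n_loci = 0L))
  }
  parts <- strsplit(names(grp), "\r", fixed = TRUE)
  groups <- data.frame(
    locus = vapply(parts, `[`, character(1), 1),
    length_name = vapply(parts, `[`, character(1), 2),
    size = as.integer(grp), stringsAsFactors = FALSE)
  groups <- groups[order(groups$locus, groups$length_name), ]
  rownames(groups) <- NULL
  list(groups = groups, histogram = table(groups$size),
       n_loci = length(unique(groups$locus)))
}

#' Filter allele designations against a known-variant catalogue
#'
#' "Novel" means the full in-phase designation (repeat array plus flanking
#' variants) is absent from the catalogue: an allele whose array matches a
#' known entry but whose flanking variant is new is retained. Catalogue
#' entries ending in `"_*"` are flank-agnostic wildcards matching any
#' designation with the same unit list.
#'
#' @param profile Data frame with locus and mps_name columns (or an allele
#'   designation table with those columns).
#' @param known Data frame with locus and mps_name columns, or a TSV path.
#' @return Data frame of distinct novel (locus, mps_name) pairs.
#' @export
novelty_filter <- function(profile, known) {
  if (is.character(known)) known <- read_known_catalog(known)
  stopifnot(all(c("locus", "mps_name") %in% names(known)))
  alleles <- unique(profile[, c("locus", "mps_name")])
  # unit part: designation with the CE prefix and flank descriptors stripped
  unit_part <- function(name)
    sub("_.*$", "", sub("^CE[0-9.]+_", "", name))
  exact <- paste(known$locus, known$mps_name, sep = "\r")
  wild <- grepl("_\\*$", known$mps_name)
  wild_keys <- paste(known$locus[wild],
                     unit_part(sub("_\\*$", "", known$mps_name[wild])),
                     sep = "\r")
  hit_exact <- paste(alleles$locus, alleles$mps_name, sep = "\r") %in% exact
  hit_wild <- paste(alleles$locus, unit_part(alleles$mps_name), sep = "\r") %in%
    wild_keys
  novel <- alleles[!(hit_exact | hit_wild), , drop = FALSE]
  rownames(novel) <- NULL
  novel[order(novel$locus, novel$mps_name), ]
}

#' Read a known-variant catalogue TSV
#'
#' @param path TSV with columns locus, mps_name.
#' @return Data frame.
#' @export
read_known_catalog <- function(path) {
  known <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("known-variant catalogue load error: ",
                             conditionMessage(e)))
  need <- c("locus", "mps_name")
  if (!all(need %in% names(known)))
    stop("known-variant catalogue load error: needs columns ",
         paste(need, collapse = ", "))
  bad <- which(!nzchar(known$locus) | !nzchar(known$mps_name) |
               is.na(known$locus) | is.na(known$mps_name))
  if (length(bad))
    stop("known-variant catalogue load error at line ", bad[1] + 1L)
  known
}

#' Headline profile counts
#'
#' @param profile Allele-level profile (one row per called allele, DYS385a,b
#'   contributing two rows per sample) with a status column
#'   (primary/duplication/somatic or primary/additional).
#' @param variants Optional [extract_variants()] table for the SNP/indel and
#'   RPV tallies.
#' @return List of headline counts.
#' @export
headline_counts <- function(profile, variants = NULL) {
  out <- list(
    n_samples = length(unique(profile$sample)),
    total_alleles = nrow(profile),
    n_additional = sum(profile$status %in%
                       c("additional", "duplication", "somatic")),
    n_duplication = sum(profile$status == "duplication"),
    n_somatic = sum(profile$status == "somatic"))
  if (!is.null(variants)) {
    si <- variants[variants$kind %in% c("SNP", "indel"), , drop = FALSE]
    carriers <- unique(unlist(strsplit(si$carriers, ";", fixed = TRUE)))
    out$n_snp_indel_variants <- nrow(si)
    out$n_snp_indel_alleles <-
      length(unique(unlist(strsplit(si$designations, ";", fixed = TRUE))))
    out$n_snp_indel_loci <- length(unique(si$locus))
    out$n_snp_indel_samples <- length(carriers)
    rpv <- variants[variants$kind == "RPV", , drop = FALSE]
    out$n_rpv_alleles <-
      length(unique(unlist(strsplit(rpv$designations, ";", fixed = TRUE))))
  }
  out
}
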