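# -- per-sample allele calling -------------------------------------------------
#
# Reads (or read groups with counts) for one sample x locus are collapsed by
# identical decomposition; groups below the analytical threshold (20x by
# default) are dropped, the deepest group is the primary allele, and further
# groups are reported as candidate extra alleles only when they do not sit at
# the -1 stutter position (one full repeat unit shorter in CE length) of a
# deeper co-occurring group. DYS385a,b reports two alleles, doubled when
# homoallelic.

#' Call alleles from reads at one locus of one sample
#'
#' @param reads Character vector of read sequences, or a data.frame with
#'   columns `sequence` and `count` (pre-aggregated read groups).
#' @param locus A `locus_definition` or locus name.
#' @param sample Sample identifier carried through to the output.
#' @param threshold Analytical depth threshold (default 20).
#' @param stutter_ratio Maximum fraction of the deeper group's depth at which
#'   a -1 group at a multi-copy locus (DYS385a,b) is treated as stutter
#'   rather than a second allele (default 1/3).
#' @param catalog A `locus_catalog`.
#' @return A data.frame of calls (sample, locus, ce_name, mps_name,
#'   length_name, depth, depth_adjusted, status, ab_unresolved), with the
#'   underlying decompositions in `attr(, "decompositions")`. Zero rows when
#'   no group reaches the threshold.
#' @export
call_alleles <- function(reads, locus, sample = "sample1", threshold = 20L,
                         stutter_ratio = 1 / 3,
                         catalog = default_catalog()) {
  def <- catalog_locus(locus, catalog)
  if (is.character(reads)) {
    tab <- as.data.frame(table(sequence = reads), stringsAsFactors = FALSE)
    names(tab)[2] <- "count"
  } else {
    stopifnot(all(c("sequence", "count") %in% names(reads)))
    tab <- stats::aggregate(count ~ sequence, data = reads, FUN = sum)
  }
  if (!nrow(tab)) stop("no reads supplied for ", def$name)
  decs <- lapply(tab$sequence, decompose, locus = def, catalog = catalog)
  keys <- vapply(decs, decomposition_key, character(1))
  groups <- split(seq_len(nrow(tab)), keys)
  depth <- vapply(groups, function(ix) sum(tab$count[ix]), numeric(1))
  rep_dec <- lapply(groups, function(ix) decs[[ix[1]]])
  lens <- vapply(rep_dec, function(d) d$array_length, integer(1))

  ord <- order(-depth)
  depth <- depth[ord]; rep_dec <- rep_dec[ord]; lens <- lens[ord]

  keep <- depth >= threshold
  # -1 stutter masking: one period shorter in CE length than a deeper group.
  # At single-copy loci the mask is strictly positional (extra alleles in the
  # -1 position are never called, to avoid confusion with stutter products);
  # at DYS385a,b a genuine second allele may sit one repeat below the first,
  # so only groups within a plausible stutter fraction of the deeper group
  # are masked.
  stutter_of <- rep(NA_integer_, length(depth))
  for (i in seq_along(depth)) {
    deeper <- which(depth > depth[i] & lens - lens[i] == def$period)
    if (def$copies >= 2L)
      deeper <- deeper[depth[i] < stutter_ratio * depth[deeper]]
    if (length(deeper)) stutter_of[i] <- deeper[which.max(depth[deeper])]
  }
  reportable <- which(keep & is.na(stutter_of))
  if (!length(reportable)) return(empty_calls())

  n_report <- if (def$copies >= 2L) min(2L, length(reportable))
              else length(reportable)
  reportable <- reportable[seq_len(n_report)]

  adj <- vapply(reportable, function(i)
    depth[i] + sum(depth[which(stutter_of == i)]), numeric(1))

  out <- data.frame(
    sample = sample, locus = def$name,
    ce_name = vapply(rep_dec[reportable], ce_name, character(1),
                     catalog = catalog),
    mps_name = vapply(rep_dec[reportable], mps_name, character(1),
                      catalog = catalog),
    length_name = vapply(rep_dec[reportable], length_based_name, character(1),
                         catalog = catalog),
    depth = depth[reportable], depth_adjusted = adj,
    status = c("primary", rep("additional", length(reportable) - 1L)),
    ab_unresolved = def$copies >= 2L,
    stringsAsFactors = FALSE)
  if (def$copies >= 2L) {
    out$status <- "primary"
    if (nrow(out) == 1L) {  # homoallelic: both copies assumed present
      out <- out[c(1L, 1L), ]
      out$depth <- out$depth / 2
      out$depth_adjusted <- out$depth_adjusted / 2
      rownames(out) <- NULL
    }
  }
  attr(out, "decompositions") <- rep_dec[reportable]
  out
}

empty_calls <- function() {
  data.frame(sample = character(), locus = character(), ce_name = character(),
             mps_name = character(), length_name = character(),
             depth = numeric(), depth_adjusted = numeric(),
             status = character(), ab_unresolved = logical(),
             stringsAsFactors = FALSE)
}

#' Call alleles for a whole read table
#'
#' @param read_table Data frame with columns sample, locus, sequence, count.
#' @param threshold Analytical depth threshold.
#' @param catalog A `locus_catalog`.
#' @return Combined call data.frame (see [call_alleles()]).
#' @export
call_profile <- function(read_table, threshold = 20L,
                         catalog = default_catalog()) {
  stopifnot(all(c("sample", "locus", "sequence", "count") %in%
                names(read_table)))
  pieces <- list()
  for (key in split(seq_len(nrow(read_table)),
                    paste(read_table$sample, read_table$locus, sep = "\r"))) {
    sub <- read_table[key, , drop = FALSE]
    pieces[[length(pieces) + 1L]] <-
      call_alleles(sub[, c("sequence", "count")], locus = sub$locus[1],
                   sample = sub$sample[1], threshold = threshold,
                   catalog = catalog)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$sample, out$locus), ]
}

# rs ids whose flanking SNPs are known to shift CE fragment mobility
MOBILITY_SHIFT_RS <- c("rs368663163")

#' CE/MPS concordance report
#'
#' Compares the sequence-derived length-based names of an MPS profile with a
#' CE profile, allele by allele, and suggests a resolution category for each
#' discordance: a flanking indel changes the measured fragment length; a
#' known mobility-shift flanking SNP (e.g. rs368663163 at DYS481) changes
#' migration without changing length; otherwise a difference in proprietary
#' primer placement is the default explanation.
#'
#' @param mps_profile Data frame with sample, locus, length_name, and
#'   optionally flank_types (";"-joined types) and flank_ids columns.
#' @param ce_profile Data frame with sample, locus, ce_name.
#' @return List with `total`, `discordant`, `pct` (2 dp) and a `details`
#'   data.frame with one row per discordance.
#' @export
concordance <- function(mps_profile, ce_profile) {
  key <- function(p) paste(p$sample, p$locus, sep = "\r")
  mk <- sort(key(mps_profile)); ck <- sort(key(ce_profile))
  if (!identical(mk, ck))
    stop("input error: MPS and CE profiles cover different (sample, locus) ",
         "allele sets")
  # align allele slots within each (sample, locus) by sorted name
  m <- mps_profile[order(mps_profile$sample, mps_profile$locus,
                         suppressWarnings(as.numeric(mps_profile$length_name)),
                         mps_profile$length_name), , drop = FALSE]
  ce <- ce_profile[order(ce_profile$sample, ce_profile$locus,
                         suppressWarnings(as.numeric(ce_profile$ce_name)),
                         ce_profile$ce_name), , drop = FALSE]
  mismatch <- m$length_name != ce$ce_name
  details <- data.frame(sample = m$sample[mismatch], locus = m$locus[mismatch],
                        mps = m$length_name[mismatch],
                        ce = ce$ce_name[mismatch],
                        category = rep(NA_character_, sum(mismatch)),
                        stringsAsFactors = FALSE)
  if (nrow(details)) {
    ft <- if ("flank_types" %in% names(m)) m$flank_types[mismatch]
          else rep("", nrow(details))
    fi <- if ("flank_ids" %in% names(m)) m$flank_ids[mismatch]
          else rep("", nrow(details))
    ft[is.na(ft)] <- ""; fi[is.na(fi)] <- ""
    details$category <- ifelse(
      grepl("ins|del", ft), "flanking-indel",
      ifelse(vapply(fi, function(x)
               any(MOBILITY_SHIFT_RS %in% strsplit(x, ";")[[1]]), logical(1)),
             "mobility-shift-SNP",
             ifelse(ft == "", "primer-difference", "unknown")))
  }
  total <- nrow(m)
  list(total = total, discordant = nrow(details),
       pct = round(100 * nrow(details) / total, 2), details = details)
}
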