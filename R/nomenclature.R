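# -- allele nomenclature -------------------------------------------------------
#
# Two names per allele. The CE-compatible name counts repeat units the way
# capillary electrophoresis bins fragment lengths: counted blocks (plus
# period-length variant units) are summed, uncounted blocks (DYS19 ccta,
# DYS385 AAGG, DYS390 trailing taga, DYS481 leading CTG) are excluded but
# their deviation from the canonical copy number shifts the name, preserving
# back-compatibility (e.g. DYS19 with the ccta spacer absent is named a+b-1).
# The full MPS designation is "CE<name>_<bracketed units>[_<flank variants>]".

#' CE-compatible allele name
#'
#' @param d A `decomposition`.
#' @param catalog A `locus_catalog`.
#' @return Decimal string `"k"` or `"k.r"`.
#' @export
ce_name <- function(d, catalog = default_catalog()) {
  def <- catalog_locus(d$locus, catalog)
  counted <- 0L
  partial_len <- 0L
  # observed totals per uncounted block (variant units add to their block)
  uncounted_obs <- integer(length(def$blocks))
  seen_uncounted <- logical(length(def$blocks))
  for (u in d$units) {
    if (u$role == "spacer") next
    if (u$role == "partial") { partial_len <- partial_len + nchar(u$motif); next }
    b <- def$blocks[[u$block]]
    if (b$counted) {
      counted <- counted + u$count
    } else {
      uncounted_obs[u$block] <- uncounted_obs[u$block] + u$count
      seen_uncounted[u$block] <- TRUE
    }
  }
  shift <- 0L
  for (i in seq_along(def$blocks)) {
    b <- def$blocks[[i]]
    if (!b$counted && !b$fixed_spacer)
      shift <- shift + uncounted_obs[i] - b$canonical
  }
  k <- counted + shift
  if (k <= 0L) stop("naming error at ", def$name, ": non-positive CE name")
  r <- partial_len %% def$period
  if (r > 0L) sprintf("%d.%d", k, r) else as.character(k)
}

#' Full MPS sequence designation
#'
#' `"CE<k[.r]>_<bracketed units>[_<flank descriptors>]"`, deterministic, with
#' flank descriptors ordered upstream to downstream and ASCII signs.
#'
#' @param d A `decomposition`.
#' @param catalog A `locus_catalog`.
#' @return A designation string, e.g. `"CE11_CTTTT[11]_-7A>G"`.
#' @export
mps_name <- function(d, catalog = default_catalog()) {
  paste(c(paste0("CE", ce_name(d, catalog), "_", units_string(d)),
          flank_descriptors(d$flank_variants)), collapse = "_")
}

#' Length-based (CE electrophoresis) allele name
#'
#' The name CE would report for this allele: purely a function of the repeat
#' array length relative to the canonical reference. Isometric alleles
#' (distinct sequences, equal length) collide on this name by design.
#'
#' @param d A `decomposition`.
#' @param catalog A `locus_catalog`.
#' @return Decimal string `"k"` or `"k.r"`.
#' @export
length_based_name <- function(d, catalog = default_catalog()) {
  def <- catalog_locus(d$locus, catalog)
  ref_ce <- sum(vapply(def$blocks, function(b)
    if (b$counted) b$canonical else 0L, integer(1)))
  delta <- d$array_length - reference_array_length(def)
  k <- ref_ce + delta %/% def$period
  r <- delta %% def$period
  if (k <= 0L) stop("naming error at ", def$name, ": non-positive length name")
  if (r > 0L) sprintf("%d.%d", k, r) else as.character(k)
}

#' Parse an MPS designation back to a decomposition
#'
#' Inverse of [mps_name()]: the designation's unit list and flank descriptors
#' are rendered to a full-length sequence against the catalogue and re-parsed,
#' so the result is guaranteed to be in canonical parsed form.
#'
#' @param name Designation string, e.g. `"CE15_AAGG[5]GAAA[16]"`.
#' @param locus Locus name or `locus_definition`.
#' @param catalog A `locus_catalog`.
#' @return A `decomposition`.
#' @export
parse_mps_name <- function(name, locus, catalog = default_catalog()) {
  def <- catalog_locus(locus, catalog)
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) < 2L || !grepl("^CE[0-9]+(\\.[0-9]+)?$", parts[1]))
    stop("malformed designation: ", name)
  seq <- designation_sequence(def, parts[2],
                              if (length(parts) > 2L) parts[-(1:2)]
                              else character())
  decompose(seq, def, catalog)
}

# render a full-length sequence from a bracketed unit string plus flank
# descriptor strings (fixture/designation plumbing)
designation_sequence <- function(def, units_str, flank_strs = character()) {
  m <- gregexpr("([ACGT]+|N)\\[([0-9]+)\\]", units_str)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(units_str))
    stop("malformed unit string: ", units_str)
  toks <- regmatches(units_str, gregexpr("([ACGT]+|N)\\[([0-9]+)\\]",
                                         units_str))[[1]]
  spacers <- Filter(function(b) b$fixed_spacer, def$blocks)
  array <- paste(vapply(toks, function(tk) {
    motif <- sub("\\[.*", "", tk)
    count <- as.integer(sub(".*\\[([0-9]+)\\]", "\\1", tk))
    if (motif == "N") {
      len <- count
      hit <- Filter(function(b) nchar(b$motif) == len, spacers)
      if (!length(hit)) stop("no fixed spacer of length ", len, " at ", def$name)
      hit[[1]]$motif
    } else strrep_motif(motif, count)
  }, character(1)), collapse = "")
  fv <- parse_flank_descriptors(flank_strs)
  paste0(render_flank(def, "upstream", fv), array,
         render_flank(def, "downstream", fv))
}

parse_flank_descriptors <- function(strs) {
  if (!length(strs)) return(empty_flank_variants())
  rows <- lapply(strs, function(s) {
    if (grepl("^[+-][0-9]+\\.1->[ACGT]+$", s)) {
      off <- as.integer(sub("\\.1->.*", "", s))
      data.frame(offset = off, type = "ins", ref = "-",
                 alt = sub(".*->", "", s), genomic_position = NA_integer_,
                 id = NA_character_, stringsAsFactors = FALSE)
    } else if (grepl("^[+-][0-9]+[ACGT]+>-$", s)) {
      off <- as.integer(sub("^([+-][0-9]+).*", "\\1", s))
      data.frame(offset = off, type = "del",
                 ref = sub("^[+-][0-9]+([ACGT]+)>-$", "\\1", s), alt = "-",
                 genomic_position = NA_integer_, id = NA_character_,
                 stringsAsFactors = FALSE)
    } else if (grepl("^[+-][0-9]+[ACGT]>[ACGT]$", s)) {
      off <- as.integer(sub("^([+-][0-9]+).*", "\\1", s))
      data.frame(offset = off, type = "SNP",
                 ref = sub("^[+-][0-9]+([ACGT])>.*", "\\1", s),
                 alt = sub(".*>([ACGT])$", "\\1", s),
                 genomic_position = NA_integer_, id = NA_character_,
                 stringsAsFactors = FALSE)
    } else stop("malformed flank descriptor: ", s)
  })
  do.call(rbind, rows)
}

#' Write an allele-profile TSV
#'
#' @param profile Data frame with at least sample, locus, ce_name, mps_name
#'   and depth columns.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
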