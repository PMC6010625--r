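# -- locus catalogue -----------------------------------------------------------
#
# A locus definition is the grammar of one Y-STR: an ordered list of repeat-block
# specifications (5'->3' on the reporting strand), reference flanking sequences,
# and the naming rule linking structural repeat counts to the CE-compatible
# allele name. The packaged catalogue covers the 23 PowerPlex Y23 markers in 22
# definitions (DYS385a and DYS385b share one definition: commercial kits do not
# distinguish the two copies, and both are reported on the b-copy/forward-strand
# convention).

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Create a repeat-block specification
#'
#' @param motif Uppercase DNA motif (3-6 nt) for repeat blocks, or the literal
#'   spacer content for fixed spacers.
#' @param min_repeats,max_repeats Allowed copy-number range.
#' @param counted Does the block contribute to the CE allele name?
#' @param fixed_spacer Is this a fixed intervening sequence (e.g. the 42-nt
#'   spacer of DYS448), present in exactly one copy and never counted?
#' @param canonical Canonical (reference) copy number; for uncounted blocks the
#'   deviation from this value shifts the CE name.
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(motif, min_repeats, max_repeats, counted = TRUE,
                       fixed_spacer = FALSE, canonical = min_repeats) {
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif))
    stop("block motif must be a non-empty string over {A,C,G,T}: ", motif)
  if (fixed_spacer && counted)
    stop("fixed_spacer blocks must have counted = FALSE")
  if (min_repeats < 0 || max_repeats < min_repeats)
    stop("invalid repeat range [", min_repeats, ",", max_repeats, "]")
  structure(
    list(motif = motif, min_repeats = as.integer(min_repeats),
         max_repeats = as.integer(max_repeats), counted = isTRUE(counted),
         fixed_spacer = isTRUE(fixed_spacer), canonical = as.integer(canonical)),
    class = "block_spec")
}

#' Create a locus definition
#'
#' @param name Locus identifier (e.g. `"DYS390"`).
#' @param blocks Ordered list of [block_spec()] objects, 5'->3' on the
#'   reporting strand.
#' @param period CE repeat-unit length in nt (3-6).
#' @param upstream_flank,downstream_flank Reference flanking sequences
#'   (>= 30 nt each).
#' @param anchor 1-based GRCh38 chrY coordinate of the first array base.
#' @param strand Reporting strand, `"+"` or `"-"`.
#' @param copies Number of amplified copies (2 for DYS385a,b).
#' @param flank_window Number of flanking nt compared when calling flank
#'   variants (default 50).
#' @param known_flank_variants Optional data.frame (offset, ref, alt, id) of
#'   previously described flanking variants used for rs-id annotation.
#' @param note Free-text reporting note.
#' @return An object of class `locus_definition`.
#' @export
locus_definition <- function(name, blocks, period, upstream_flank,
                             downstream_flank, anchor = NA_integer_,
                             strand = "+", copies = 1L, flank_window = 50L,
                             known_flank_variants = NULL, note = "") {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  blocks <- lapply(blocks, function(b) {
    if (!inherits(b, "block_spec")) do.call(block_spec, b) else b
  })
  def <- structure(
    list(name = name, blocks = blocks, period = as.integer(period),
         upstream_flank = toupper(upstream_flank),
         downstream_flank = toupper(downstream_flank),
         anchor = as.integer(anchor), strand = strand,
         copies = as.integer(copies), flank_window = as.integer(flank_window),
         known_flank_variants = known_flank_variants, note = note),
    class = "locus_definition")
  validate_locus_definition(def)
  def
}

validate_locus_definition <- function(def) {
  name <- def$name
  if (!def$period %in% 3:6)
    stop("locus ", name, ": period must be in 3..6, got ", def$period)
  counted <- vapply(def$blocks, function(b) b$counted, logical(1))
  spacer <- vapply(def$blocks, function(b) b$fixed_spacer, logical(1))
  if (!any(counted))
    stop("locus ", name, ": needs at least one counted block")
  motif_len <- vapply(def$blocks, function(b) nchar(b$motif), integer(1))
  if (any(motif_len[counted] != def$period))
    stop("locus ", name, ": counted blocks must all have motif length equal ",
         "to the locus period (", def$period, ")")
  bad <- !spacer & (motif_len < 3 | motif_len > 6)
  if (any(bad))
    stop("locus ", name, ": repeat motifs must be 3-6 nt")
  for (fl in c("upstream_flank", "downstream_flank")) {
    s <- def[[fl]]
    if (nchar(s) < 30)
      stop("locus ", name, ": ", fl, " must be at least 30 nt")
    if (grepl("[^ACGT]", s))
      stop("locus ", name, ": ", fl, " must be DNA over {A,C,G,T}")
  }
  # unambiguous array boundaries: no repeat motif of this locus may sit
  # immediately adjacent to the array inside a flank
  motifs <- unique(vapply(def$blocks[!spacer], function(b) b$motif, character(1)))
  up_tail <- substring(def$upstream_flank,
                       nchar(def$upstream_flank) - def$period + 1)
  down_head <- substring(def$downstream_flank, 1, def$period)
  for (m in motifs) {
    if (substring(up_tail, nchar(up_tail) - nchar(m) + 1) == m)
      stop("locus ", name, ": upstream flank ends with repeat motif ", m)
    if (substring(down_head, 1, nchar(m)) == m)
      stop("locus ", name, ": downstream flank starts with repeat motif ", m)
  }
  invisible(def)
}

#' @export
print.locus_definition <- function(x, ...) {
  fmt <- vapply(x$blocks, function(b) {
    if (b$fixed_spacer) sprintf("N[%d]", nchar(b$motif))
    else sprintf("%s[%d-%d]%s", if (b$counted) b$motif else tolower(b$motif),
                 b$min_repeats, b$max_repeats, if (b$counted) "" else "*")
  }, character(1))
  cat(sprintf("<locus_definition> %s (period %d, %d copies)\n  %s\n",
              x$name, x$period, x$copies, paste(fmt, collapse = " ")))
  invisible(x)
}

#' Load a locus catalogue from a JSON config
#'
#' Reads and validates a catalogue of Y-STR locus definitions. The packaged
#' default (`default_catalog()`) encodes the 23 PowerPlex Y23 markers in 22
#' definitions; its repeat structures and naming rules follow the published
#' sequence-based nomenclature for these loci, while its reference flanking
#' sequences are synthetic stand-ins (see the packaged file's name and the
#' methods vignette).
#'
#' @param path Path to a catalogue JSON file.
#' @return A named list of `locus_definition` objects, with attributes
#'   `n_markers` (23 for the default catalogue) and `source`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$loci)) stop("catalogue config error: missing 'loci' array")
  defs <- list()
  for (entry in raw$loci) {
    nm <- entry$name
    if (is.null(nm)) stop("catalogue config error: locus without a name")
    if (nm %in% names(defs)) stop("catalogue config error: duplicate locus ", nm)
    blocks <- lapply(entry$blocks, function(b) {
      block_spec(motif = b$motif, min_repeats = b$min, max_repeats = b$max,
                 counted = isTRUE(b$counted), fixed_spacer = isTRUE(b$spacer),
                 canonical = if (is.null(b$canonical)) b$min else b$canonical)
    })
    kfv <- NULL
    if (length(entry$known_flank_variants)) {
      kfv <- do.call(rbind, lapply(entry$known_flank_variants, function(v)
        data.frame(offset = v$offset, ref = v$ref, alt = v$alt,
                   id = if (is.null(v$id)) NA_character_ else v$id,
                   stringsAsFactors = FALSE)))
    }
    defs[[nm]] <- locus_definition(
      name = nm, blocks = blocks, period = entry$period,
      upstream_flank = entry$upstream_flank,
      downstream_flank = entry$downstream_flank,
      anchor = if (is.null(entry$anchor)) NA_integer_ else entry$anchor,
      strand = if (is.null(entry$strand)) "+" else entry$strand,
      copies = if (is.null(entry$copies)) 1L else entry$copies,
      flank_window = if (is.null(entry$flank_window)) 50L else entry$flank_window,
      known_flank_variants = kfv,
      note = if (is.null(entry$note)) "" else entry$note)
  }
  attr(defs, "n_markers") <- sum(vapply(defs, function(d) d$copies, integer(1)))
  attr(defs, "source") <- path
  class(defs) <- "locus_catalog"
  defs
}

#' @export
print.locus_catalog <- function(x, ...) {
  cat(sprintf("<locus_catalog> %d definitions covering %d markers\n",
              length(x), attr(x, "n_markers")))
  invisible(x)
}

.catalog_cache <- new.env(parent = emptyenv())

#' The packaged PPY23 catalogue
#'
#' @return The default `locus_catalog` (cached after first load).
#' @export
default_catalog <- function() {
  if (is.null(.catalog_cache$default)) {
    path <- system.file("extdata", "ppy23_catalogue_synthetic_flanks.json",
                        package = "ystrseq", mustWork = TRUE)
    .catalog_cache$default <- load_catalog(path)
  }
  .catalog_cache$default
}

catalog_locus <- function(locus, catalog = default_catalog()) {
  if (inherits(locus, "locus_definition")) return(locus)
  def <- catalog[[locus]]
  if (is.null(def)) stop("unknown locus: ", locus)
  def
}

#' Canonical (reference) decomposition of a locus
#'
#' Returns the decomposition of the GRCh38-canonical allele: every block at its
#' canonical copy number, no variant units, no flanking variants.
#'
#' @param locus A `locus_definition` or a locus name resolved against
#'   `catalog`.
#' @param catalog A `locus_catalog`.
#' @return A `decomposition` object.
#' @export
reference_allele <- function(locus, catalog = default_catalog()) {
  def <- catalog_locus(locus, catalog)
  counts <- vapply(def$blocks, function(b) {
    if (b$fixed_spacer) 1L else b$canonical
  }, integer(1))
  decomposition_from_counts(def, counts)
}

# build a decomposition straight from per-block copy numbers (no parsing)
decomposition_from_counts <- function(def, counts) {
  stopifnot(length(counts) == length(def$blocks))
  units <- list()
  for (i in seq_along(def$blocks)) {
    b <- def$blocks[[i]]
    if (b$fixed_spacer) {
      units[[length(units) + 1L]] <-
        list(motif = b$motif, count = 1L, role = "spacer", block = i)
    } else if (counts[i] > 0L || !b$counted) {
      units[[length(units) + 1L]] <-
        list(motif = b$motif, count = as.integer(counts[i]),
             role = if (b$counted) "counted" else "uncounted", block = i)
    }
  }
  new_decomposition(def$name, units, flank_variants = empty_flank_variants())
}
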