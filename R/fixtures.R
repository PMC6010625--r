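# -- packaged in-study fixtures ------------------------------------------------
#
# Golden worked examples: the 60 published novel sequence designations, a
# complementary set of previously reported ("known") alleles chosen so the
# per-locus distinct length-based and sequence-based allele counts match the
# published diversity table, a 100-sample haplogroup-labelled tree with the
# published carrier patterns (15-sample superhaplogroup-P DYS635 RPV,
# 14-sample E DYS389II CAGA[6], 9-sample B2 DYS391 flanking SNP, ...), and a
# 2311-allele profile with 11 extra alleles and 4 planted CE/MPS
# discordances.

bra <- function(motif, n) sprintf("%s[%d]", motif, n)

#' The 60 novel sequence designations
#'
#' One row per novel in-phase sequence variant, with the locus, structural
#' CE-compatible name, bracketed unit list, flanking descriptor and observed
#' carrier count.
#'
#' @return Data frame (locus, ce, units, flank, obs, novel = TRUE).
#' @export
novel_designations <- function() {
  rows <- c(
    "DYS19|12|TCTA[13]CCTA[0]||1",
    "DYS385ab|9|AAGG[5]GAAA[10]||1",
    "DYS385ab|13|AAGG[5]GAAA[14]||1",
    "DYS385ab|15|AAGG[5]GAAA[16]||1",
    "DYS385ab|15|AAGG[8]GAAA[13]||1",
    "DYS385ab|16|AAGG[8]GAAA[14]||1",
    "DYS385ab|17|AAGG[5]GAAA[18]||1",
    "DYS385ab|18|AAGG[7]GAAA[17]||2",
    "DYS389II|30|TAGA[11]CAGA[2]N[48]TAGA[13]CAGA[4]||1",
    "DYS389II|30|TAGA[9]CAGA[3]N[48]TAGA[12]CAGA[6]||2",
    "DYS389II|31|TAGA[10]CAGA[3]N[48]TAGA[11]CAGA[1]TAGA[1]CAGA[5]||1",
    "DYS389II|34|TAGA[10]CAGA[3]N[48]TAGA[15]CAGA[6]||1",
    "DYS390|22|TAGA[14]CAGA[8]TAGA[2]TAGA[0]||1",
    "DYS390|23|TAGA[5]CAGA[1]TAGA[9]CAGA[8]TAGA[2]||1",
    "DYS390|24|TAGA[4]CAGA[1]TAGA[10]CAGA[10]TAGA[1]||1",
    "DYS390|24|TAGA[4]CAGA[1]TAGA[11]CAGA[7]TAGA[3]||1",
    "DYS390|24|TAGA[4]CAGA[1]TAGA[11]CAGA[8]TAGA[1]GAGA[1]||1",
    "DYS390|26|TAGA[4]CAGA[1]TAGA[12]CAGA[9]TAGA[2]||2",
    "DYS391|8|TCTA[8]|+50C>A|2",
    "DYS391|9|TCTA[9]|+50C>A|2",
    "DYS391|10|TCTA[10]|+50C>A|2",
    "DYS391|11|TCTA[11]|+50C>A|2",
    "DYS391|11|TCTG[1]TCTA[10]||1",
    "DYS391|12|TCTA[12]|+50C>A|1",
    "DYS437|15|TCTG[1]TCTA[8]TCTG[2]TCTA[4]||1",
    "DYS437|16|TCTA[6]TCTG[1]TCTA[3]TCTG[2]TCTA[4]||1",
    "DYS438|8|TTTTC[8]|+21T>C|1",
    "DYS438|11|TTTTC[11]|+7A>C|1",
    "DYS439|11|GATA[11]|+3A>T|1",
    "DYS448|13|AGAGAT[5]N[42]AGAGAT[8]||1",
    "DYS448|19|AGAGAT[13]N[42]AGAGAT[6]||1",
    "DYS448|20.4|AGAGAT[3]AGAT[1]AGAGAT[9]N[42]AGAGAT[8]||1",
    "DYS448|23|AGAGAT[14]N[42]AGAGAT[9]||1",
    "DYS448|23|AGAGAT[15]N[42]AGAGAT[8]||1",
    "DYS458|14|GAAA[13]GGAA[1]||1",
    "DYS458|15|GAAA[14]GGAA[1]||1",
    "DYS458|16|GAAA[15]GGAA[1]||1",
    "DYS458|17|GAAA[17]|+32T>C|1",
    "DYS458|17.2|GAAA[15]AA[1]GAAA[2]||1",
    "DYS458|19|GAAA[19]|+32T>C|1",
    "DYS458|19|GAAG[1]GAAA[18]||1",
    "DYS458|19.2|GAAA[17]AA[1]GAAA[2]||1",
    "DYS458|20|GAAA[19]GGAA[1]||1",
    "DYS481|26|CTG[0]CTT[27]||1",
    "DYS481|27|CTG[0]CTT[28]||2",
    "DYS481|28|CTG[1]CTT[3]CCT[1]CTT[24]||1",
    "DYS533|11|TATC[11]|-48.1->CTCTTCTAACTAT|1",
    "DYS533|15|TATC[15]||1",
    "DYS570|16|TTTC[16]|+4T>G|1",
    "DYS570|17|TTCC[1]TTTC[16]||1",
    "DYS570|17|TTTC[15]CTTC[1]TTTC[1]||1",
    "DYS570|19|TTTC[5]TCTC[1]TTTC[13]||1",
    "DYS576|18|AAAG[18]|+3AAA>-|1",
    "DYS635|18|TAGA[8]TACA[2]TAGA[2]TACA[2]TAGA[4]||3",
    "DYS635|20|TAGA[8]CAGA[1]TAGA[1]TACA[2]TAGA[2]TACA[2]TAGA[4]||1",
    "DYS635|21|TAGA[9]CAGA[1]TAGA[1]TACA[2]TAGA[2]TACA[2]TAGA[4]||1",
    "DYS635|25|TAGA[14]TACA[3]TAGA[2]TACA[2]TAGA[4]||1",
    "DYS643|11|CTTTT[11]|-7A>G|1",
    "DYS643|15|CTTTT[15]||1",
    "Y-GATA-H4|13|TCTA[13]|+36A>G|1")
  parts <- strsplit(rows, "|", fixed = TRUE)
  out <- data.frame(
    locus = vapply(parts, `[`, character(1), 1),
    ce = vapply(parts, `[`, character(1), 2),
    units = vapply(parts, `[`, character(1), 3),
    flank = vapply(parts, function(p) if (length(p) >= 4) p[4] else "",
                   character(1)),
    obs = as.integer(vapply(parts, function(p) p[length(p)], character(1))),
    stringsAsFactors = FALSE)
  out$novel <- TRUE
  out
}

# previously reported ("known") alleles completing the reference survey's per-locus
# distinct length/sequence allele counts
known_designations <- function() {
  simple <- function(locus, motif, counts, flank = "") {
    data.frame(locus = locus, units = vapply(counts, function(n)
      bra(motif, n), character(1)), flank = flank, stringsAsFactors = FALSE)
  }
  d19 <- data.frame(locus = "DYS19", units = c(
    "TCTA[10]CCTA[1]TCTA[3]", "TCTA[11]CCTA[1]TCTA[3]",
    "TCTA[12]CCTA[1]TCTA[3]", "TCTA[13]CCTA[1]TCTA[3]",
    "TCTA[14]CCTA[1]TCTA[3]", "TCTA[12]CCTA[1]TCTA[2]"),
    flank = "", stringsAsFactors = FALSE)
  d385 <- data.frame(locus = "DYS385ab", units = c(
    sprintf("AAGG[6]GAAA[%d]", c(10, 11, 12, 14, 19, 20, 21, 22,
                                 9, 13, 15, 16, 17, 18)),
    "AAGG[7]GAAA[9]"), flank = "", stringsAsFactors = FALSE)
  d389i <- data.frame(locus = "DYS389I", units = c(
    sprintf("TAGA[%d]CAGA[4]", 8:12), "TAGA[10]CAGA[3]"),
    flank = "", stringsAsFactors = FALSE)
  v389ii <- rbind(
    # final CAGA block at 4 repeats (T/O/N-associated, plus sporadic)
    c(10, 3, 11, 4), c(10, 3, 12, 4), c(10, 3, 13, 4), c(11, 3, 13, 4),
    c(10, 3, 15, 4), c(11, 3, 15, 4), c(9, 3, 12, 4),
    # final CAGA block at 6 repeats (E-associated)
    c(10, 3, 12, 6),
    # majority background at 5 repeats
    c(10, 3, 10, 5), c(10, 3, 11, 5), c(10, 3, 12, 5), c(10, 3, 13, 5),
    c(10, 3, 14, 5), c(10, 3, 15, 5), c(10, 3, 16, 5), c(9, 3, 12, 5),
    c(11, 3, 12, 5), c(10, 2, 12, 5), c(10, 4, 12, 5), c(9, 3, 13, 5),
    c(11, 3, 13, 5), c(9, 3, 14, 5), c(11, 3, 14, 5), c(9, 3, 15, 5),
    c(12, 3, 13, 5), c(12, 3, 14, 5), c(8, 3, 12, 5), c(12, 3, 12, 5))
  d389ii <- data.frame(locus = "DYS389II", units = apply(v389ii, 1, function(v)
    paste0(bra("TAGA", v[1]), bra("CAGA", v[2]), "N[48]",
           bra("TAGA", v[3]), bra("CAGA", v[4]))),
    flank = "", stringsAsFactors = FALSE)
  v390 <- rbind(
    c(4, 1, 7, 8), c(4, 1, 8, 8), c(4, 1, 12, 8), c(4, 1, 14, 8),
    c(4, 1, 9, 8), c(4, 1, 10, 8), c(4, 1, 11, 8), c(5, 1, 10, 8),
    c(4, 2, 10, 8), c(4, 1, 11, 9), c(5, 1, 12, 8), c(5, 1, 11, 8),
    c(4, 2, 11, 8))
  d390 <- data.frame(locus = "DYS390", units = apply(v390, 1, function(v)
    paste0(bra("TAGA", v[1]), bra("CAGA", v[2]), bra("TAGA", v[3]),
           bra("CAGA", v[4]), "TAGA[2]")), flank = "",
    stringsAsFactors = FALSE)
  d391 <- simple("DYS391", "TCTA", 8:11)
  d392 <- simple("DYS392", "TAT", 10:17)
  d393 <- rbind(simple("DYS393", "AGAT", 11:16),
                data.frame(locus = "DYS393", units = "CGAT[1]AGAT[12]",
                           flank = "", stringsAsFactors = FALSE))
  v437 <- rbind(c(7, 2, 4), c(8, 2, 4), c(11, 2, 4), c(9, 2, 4), c(10, 2, 4),
                c(8, 3, 4), c(9, 3, 4))
  d437 <- data.frame(locus = "DYS437", units = apply(v437, 1, function(v)
    paste0(bra("TCTA", v[1]), bra("TCTG", v[2]), bra("TCTA", v[3]))),
    flank = "", stringsAsFactors = FALSE)
  d438 <- rbind(simple("DYS438", "TTTTC", c(9, 10, 12, 13, 14, 8, 11)),
                simple("DYS438", "TTTTC", 10, flank = "+7A>C"))
  d439 <- simple("DYS439", "GATA", c(10, 12, 13, 14, 11))
  v448 <- rbind(c(9, 8), c(10, 8), c(12, 8), c(13, 8), c(14, 8),
                c(11, 8), c(12, 7), c(11, 9), c(13, 9), c(12, 9),
                c(10, 7), c(11, 7), c(12, 10), c(16, 7))
  d448 <- data.frame(locus = "DYS448", units = apply(v448, 1, function(v)
    paste0(bra("AGAGAT", v[1]), "N[42]", bra("AGAGAT", v[2]))),
    flank = "", stringsAsFactors = FALSE)
  d456 <- simple("DYS456", "AGAT", 13:17)
  d458 <- simple("DYS458", "GAAA", c(13, 18, 14, 15, 16, 17, 19))
  d481 <- rbind(
    data.frame(locus = "DYS481", units = sprintf("CTG[1]CTT[%d]",
                                                 c(18:25, 29)),
               flank = "", stringsAsFactors = FALSE),
    data.frame(locus = "DYS481", units = sprintf("CTG[2]CTT[%d]",
                                                 c(17, 18, 19, 21, 22, 23, 24)),
               flank = "", stringsAsFactors = FALSE),
    data.frame(locus = "DYS481", units = "CTG[2]CTT[20]", flank = "",
               stringsAsFactors = FALSE),
    data.frame(locus = "DYS481", units = "CTG[1]CTT[22]", flank = "-30C>T",
               stringsAsFactors = FALSE))
  d533 <- simple("DYS533", "TATC", c(9, 10, 12, 13, 14, 16, 11))
  d549 <- simple("DYS549", "GATA", 10:15)
  d570 <- simple("DYS570", "TTTC", c(14, 15, 18, 20, 21, 16, 17, 19))
  d576 <- simple("DYS576", "AAAG", c(13, 14, 15, 16, 17, 19, 20, 21))
  v635 <- rbind(c(6, 2, 2, 2, 4), c(7, 2, 2, 2, 4), c(9, 2, 2, 2, 4),
                c(12, 2, 2, 2, 4), c(14, 2, 2, 2, 4), c(16, 2, 2, 2, 4),
                c(9, 2, 2, 2, 3), c(13, 2, 2, 2, 4), c(10, 2, 2, 2, 4),
                c(11, 2, 2, 2, 4), c(15, 2, 2, 2, 4), c(8, 2, 2, 2, 5))
  d635 <- rbind(
    data.frame(locus = "DYS635",
               units = paste0("TAGA[11]TACA[2]TAGA[2]TACA[2]TAGA[2]",
                              "TACA[2]TAGA[2]"),
               flank = "", stringsAsFactors = FALSE),
    data.frame(locus = "DYS635", units = apply(v635, 1, function(v)
      paste0(bra("TAGA", v[1]), bra("TACA", v[2]), bra("TAGA", v[3]),
             bra("TACA", v[4]), bra("TAGA", v[5]))), flank = "",
      stringsAsFactors = FALSE))
  d643 <- simple("DYS643", "CTTTT", c(8, 9, 10, 12, 13, 14, 16, 11))
  dh4 <- simple("Y-GATA-H4", "TCTA", c(10, 11, 12, 14, 15, 13))
  out <- rbind(d19, d385, d389i, d389ii, d390, d391, d392, d393, d437, d438,
               d439, d448, d456, d458, d481, d533, d549, d570, d576, d635,
               d643, dh4)
  out$obs <- NA_integer_
  out$ce <- NA_character_
  out$novel <- FALSE
  out[, c("locus", "ce", "units", "flank", "obs", "novel")]
}

#' All fixture allele designations
#'
#' The union of the 60 novel designations and the complementary known
#' alleles, with decompositions, names and rendered sequences computed
#' against the catalogue.
#'
#' @param catalog A `locus_catalog`.
#' @return Data frame with locus, units, flank, novel, expected ce
#'   (structural, novel rows only), designation (computed mps_name), ce_name,
#'   length_name, sequence; decompositions in `attr(, "decompositions")`.
#' @export
fixture_designations <- function(catalog = default_catalog()) {
  spec <- rbind(novel_designations(), known_designations())
  decs <- vector("list", nrow(spec))
  seqs <- character(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    def <- catalog_locus(spec$locus[i], catalog)
    fl <- if (nzchar(spec$flank[i])) strsplit(spec$flank[i], ";")[[1]]
          else character()
    seqs[i] <- designation_sequence(def, spec$units[i], fl)
    decs[[i]] <- decompose(seqs[i], def, catalog)
  }
  spec$designation <- vapply(decs, mps_name, character(1), catalog = catalog)
  spec$ce_name <- vapply(decs, ce_name, character(1), catalog = catalog)
  spec$length_name <- vapply(decs, length_based_name, character(1),
                             catalog = catalog)
  spec$sequence <- seqs
  attr(spec, "decompositions") <- decs
  spec
}

# haplogroup layout of the 100-sample fixture tree (sizes sum to 100; the
# superhaplogroup-P clade Q1a+Q+R1a+R1b+R2 holds 15 samples)
fixture_haplogroup_sizes <- function() {
  c(A = 4, B2 = 9, B2b = 3, D = 6, C1a = 2, E = 14, G2a = 3, H = 6, I = 6,
    J1 = 4, J2 = 3, L = 2, T = 5, N = 4, O = 5, K = 4, F = 5, Q1a = 3,
    Q = 4, R1a = 4, R1b = 3, R2 = 1)
}

fixture_samples <- function() {
  sizes <- fixture_haplogroup_sizes()
  hg <- rep(names(sizes), sizes)
  ids <- sprintf("s%03d", seq_along(hg))
  names(hg) <- ids
  hg
}

#' The 100-sample fixture tree
#'
#' Haplogroup-labelled rooted tree mirroring the reference survey's sampling: every
#' haplogroup is a clade (multifurcating over its samples), superhaplogroup P
#' (Q1a, Q, R1a, R1b, R2; 15 samples) is a single clade, and T, O and N do
#' not form one clade.
#'
#' @return A `sample_tree`.
#' @export
fixture_tree <- function() {
  hg <- fixture_samples()
  grp <- function(name) {
    ids <- names(hg)[hg == name]
    if (length(ids) == 1L) ids else paste0("(", paste(ids, collapse = ","), ")")
  }
  p_clade <- sprintf("((%s,%s),((%s,%s),%s))",
                     grp("Q1a"), grp("Q"), grp("R1a"), grp("R1b"), grp("R2"))
  nwk <- sprintf(
    "((%s,(%s,%s)),((%s,%s),(%s,((%s,%s),((%s,(%s,%s)),((%s,%s),((%s,%s),((%s,%s),%s))))))));",
    grp("A"), grp("B2"), grp("B2b"), grp("D"), grp("C1a"), grp("E"),
    grp("G2a"), grp("H"), grp("I"), grp("J1"), grp("J2"), grp("L"), grp("T"),
    grp("N"), grp("O"), grp("K"), grp("F"), p_clade)
  sample_tree(nwk, hg)
}

# deterministic allele-to-sample assignment for one locus: named special
# assignments first, every remaining designation gets a sample, remaining
# samples cycle over `cycle_over` (defaults to all designations)
assign_alleles <- function(samples, designations, special = character(),
                           cycle_over = NULL) {
  out <- character(length(samples))
  names(out) <- samples
  out[names(special)] <- special
  left <- setdiff(samples, names(special))
  unused <- setdiff(designations, unname(special))
  k <- min(length(unused), length(left))
  if (k > 0) {
    out[left[seq_len(k)]] <- unused[seq_len(k)]
    left <- left[-seq_len(k)]
  }
  if (length(left)) {
    # keep haplogroup-restricted (special) alleles out of the filler pool
    pool <- if (!is.null(cycle_over)) cycle_over
            else if (length(unused)) unused
            else designations
    out[left] <- rep(pool, length.out = length(left))
  }
  out
}

#' The packaged 2311-allele fixture profile
#'
#' One row per called allele over the 100 fixture samples: 23 constitutive
#' alleles per sample (DYS385a,b contributing two) plus 5 duplication and 6
#' somatic extras. Carrier patterns of the featured variants follow the
#' fixture tree's haplogroups.
#'
#' @param catalog A `locus_catalog`.
#' @return Data frame (sample, locus, ce_name, mps_name, length_name, depth,
#'   status, flank_types, flank_ids) with decompositions attached;
#'   `attr(, "designations")` holds the [fixture_designations()] table.
#' @export
fixture_profile <- function(catalog = default_catalog()) {
  des <- fixture_designations(catalog)
  decs <- attr(des, "decompositions")
  hg <- fixture_samples()
  samples <- names(hg)
  des_key <- paste(des$locus, des$units, des$flank, sep = "|")
  lookup <- function(locus, units, flank = "")
    which(des_key == paste(locus, units, flank, sep = "|"))[1]

  sel <- function(name) names(hg)[hg == name]
  rows <- list(); row_dec <- list()
  add_row <- function(sample, ix, status = "primary", depth = NA_real_) {
    d <- decs[[ix]]
    fv <- d$flank_variants
    rows[[length(rows) + 1L]] <<- data.frame(
      sample = sample, locus = des$locus[ix], ce_name = des$ce_name[ix],
      mps_name = des$designation[ix], length_name = des$length_name[ix],
      depth = depth, status = status,
      flank_types = paste(fv$type, collapse = ";"),
      flank_ids = paste(fv$id[!is.na(fv$id)], collapse = ";"),
      stringsAsFactors = FALSE)
    row_dec[[length(row_dec) + 1L]] <<- d
  }

  loci <- unique(des$locus)
  base_depth <- function(sample, locus)
    600 + 37 * (utf8ToInt(substr(locus, 4, 4)) %% 7) +
      13 * (as.integer(sub("s", "", sample)) %% 11)

  # ---- special, haplogroup-linked assignments
  special <- list()
  spx <- function(locus, sample, units, flank = "")
    special[[locus]] <<- c(special[[locus]],
                           stats::setNames(lookup(locus, units, flank), sample))
  # DYS391: B2 clade carries the +50C>A flanking SNP
  b2 <- sel("B2")
  for (i in seq_along(b2)) {
    ceu <- c(8, 8, 9, 9, 10, 10, 11, 11, 12)[i]
    spx("DYS391", b2[i], sprintf("TCTA[%d]", ceu), "+50C>A")
  }
  spx("DYS391", sel("H")[1], "TCTG[1]TCTA[10]")
  # DYS635: all 15 superhaplogroup-P samples share the canonical 7-block RPV
  p_samples <- names(hg)[hg %in% c("Q1a", "Q", "R1a", "R1b", "R2")]
  for (s in p_samples)
    spx("DYS635", s,
        "TAGA[11]TACA[2]TAGA[2]TACA[2]TAGA[2]TACA[2]TAGA[2]")
  e <- sel("E")
  for (s in e[1:3])
    spx("DYS635", s, "TAGA[8]TACA[2]TAGA[2]TACA[2]TAGA[4]")
  spx("DYS635", e[4], "TAGA[8]CAGA[1]TAGA[1]TACA[2]TAGA[2]TACA[2]TAGA[4]")
  spx("DYS635", e[5], "TAGA[9]CAGA[1]TAGA[1]TACA[2]TAGA[2]TACA[2]TAGA[4]")
  spx("DYS635", e[6], "TAGA[14]TACA[3]TAGA[2]TACA[2]TAGA[4]")
  # DYS389II: E clade exclusive for final CAGA[6]; CAGA[4] in T,O,N + 3 more
  spx("DYS389II", e[1], "TAGA[9]CAGA[3]N[48]TAGA[12]CAGA[6]")
  spx("DYS389II", e[2], "TAGA[9]CAGA[3]N[48]TAGA[12]CAGA[6]")
  spx("DYS389II", e[3], "TAGA[10]CAGA[3]N[48]TAGA[11]CAGA[1]TAGA[1]CAGA[5]")
  spx("DYS389II", e[4], "TAGA[10]CAGA[3]N[48]TAGA[15]CAGA[6]")
  for (s in e[5:14]) spx("DYS389II", s, "TAGA[10]CAGA[3]N[48]TAGA[12]CAGA[6]")
  d4_units <- c("TAGA[11]CAGA[2]N[48]TAGA[13]CAGA[4]",
                apply(rbind(c(10, 3, 11, 4), c(10, 3, 12, 4), c(10, 3, 13, 4),
                            c(11, 3, 13, 4), c(10, 3, 15, 4), c(11, 3, 15, 4),
                            c(9, 3, 12, 4)), 1, function(v)
                  paste0(bra("TAGA", v[1]), bra("CAGA", v[2]), "N[48]",
                         bra("TAGA", v[3]), bra("CAGA", v[4]))))
  ton_plus <- c(sel("T"), sel("O"), sel("N"), sel("A")[1], sel("I")[1],
                sel("K")[1])
  for (i in seq_along(ton_plus))
    spx("DYS389II", ton_plus[i], d4_units[(i - 1L) %% length(d4_units) + 1L])
  # DYS481: CTG[0] confined to the B2b clade; CTG[2]+CTT[20] to G2a;
  # the mobility-shift flanking SNP in the single R2 sample
  b2b <- sel("B2b")
  spx("DYS481", b2b[1], "CTG[0]CTT[27]")
  spx("DYS481", b2b[2], "CTG[0]CTT[28]")
  spx("DYS481", b2b[3], "CTG[0]CTT[28]")
  for (s in sel("G2a")) spx("DYS481", s, "CTG[2]CTT[20]")
  spx("DYS481", sel("R2"), "CTG[1]CTT[22]", "-30C>T")
  spx("DYS481", sel("H")[2], "CTG[1]CTT[3]CCT[1]CTT[24]")
  ctg2 <- sprintf("CTG[2]CTT[%d]", c(17, 18, 19, 21, 22, 23, 24))
  dsel <- c(sel("D"), sel("C1a")[1])
  for (i in seq_along(ctg2)) spx("DYS481", dsel[i], ctg2[i])
  # DYS393: the internal first-unit SNP in all four R1a samples
  for (s in sel("R1a")) spx("DYS393", s, "CGAT[1]AGAT[12]")
  # DYS458: intermediate .2 alleles in J1
  j1 <- sel("J1")
  spx("DYS458", j1[1], "GAAA[15]AA[1]GAAA[2]")
  spx("DYS458", j1[2], "GAAA[17]AA[1]GAAA[2]")
  # discordance cells (flanking indel / mobility handled above at DYS481)
  spx("DYS533", e[7], "TATC[11]", "-48.1->CTCTTCTAACTAT")
  spx("DYS576", e[13], "AAAG[18]", "+3AAA>-")
  spx("DYS456", j1[4], "AGAT[15]")
  spx("DYS549", sel("K")[3], "GATA[12]")
  # primaries of the extra-allele cells
  spx("DYS643", sel("C1a")[1], "CTTTT[11]")
  spx("DYS439", b2[6], "GATA[12]")
  spx("DYS456", sel("E")[6], "AGAT[15]")
  spx("DYS549", j1[2], "GATA[12]")
  spx("DYS570", sel("N")[3], "TTTC[17]")
  spx("DYS392", sel("F")[5], "TAT[13]")
  spx("DYS19", b2[8], "TCTA[11]CCTA[1]TCTA[3]")
  spx("DYS458", sel("G2a")[2], "GAAA[16]")
  spx("DYS533", sel("T")[4], "TATC[12]")
  spx("DYS576", sel("K")[2], "AAAG[16]")
  spx("DYS391", sel("R1a")[3], "TCTA[10]")

  # ---- per-locus assignment
  for (locus in loci) {
    ix_all <- which(des$locus == locus)
    def <- catalog_locus(locus, catalog)
    sp <- special[[locus]]
    if (is.null(sp)) sp <- integer()
    if (def$copies == 2L) {
      # two alleles per sample; novels and knowns spread over the a/b slots
      a_slot <- assign_alleles(samples, ix_all, special = sp)
      b_slot <- assign_alleles(samples, rev(ix_all))
      for (s in samples) {
        dep <- base_depth(s, locus)
        add_row(s, as.integer(a_slot[s]), depth = dep)
        add_row(s, as.integer(b_slot[s]), depth = dep)
      }
    } else {
      slot <- assign_alleles(samples, ix_all, special = sp)
      for (s in samples)
        add_row(s, as.integer(slot[s]), depth = base_depth(s, locus))
    }
  }

  # ---- 11 extra alleles: 5 duplications, 6 somatic mutants
  extras <- list(
    list(sample = sel("C1a")[1], locus = "DYS643", units = "CTTTT[11]",
         flank = "-7A>G", status = "somatic"),
    list(sample = b2[6], locus = "DYS439", units = "GATA[13]",
         status = "somatic"),
    list(sample = sel("E")[6], locus = "DYS456", units = "AGAT[16]",
         status = "somatic"),
    list(sample = j1[2], locus = "DYS549", units = "GATA[13]",
         status = "somatic"),
    list(sample = sel("N")[3], locus = "DYS570", units = "TTTC[18]",
         status = "somatic"),
    list(sample = sel("F")[5], locus = "DYS392", units = "TAT[14]",
         status = "somatic"),
    list(sample = b2[8], locus = "DYS19", units = "TCTA[12]CCTA[1]TCTA[3]",
         status = "duplication"),
    list(sample = sel("G2a")[2], locus = "DYS458", units = "GAAA[17]",
         status = "duplication"),
    list(sample = sel("T")[4], locus = "DYS533", units = "TATC[13]",
         status = "duplication"),
    list(sample = sel("K")[2], locus = "DYS576", units = "AAAG[17]",
         status = "duplication"),
    list(sample = sel("R1a")[3], locus = "DYS391", units = "TCTA[11]",
         status = "duplication"))
  for (ex in extras) {
    ix <- lookup(ex$locus, ex$units, if (is.null(ex$flank)) "" else ex$flank)
    dep <- base_depth(ex$sample, ex$locus)
    add_row(ex$sample, ix, status = ex$status,
            depth = if (ex$status == "duplication") dep else 0.45 * dep)
  }

  out <- do.call(rbind, rows)
  attr(out, "decompositions") <- row_dec
  attr(out, "designations") <- des
  out
}

#' Matching CE profile with the four planted discordances
#'
#' CE names equal the length-based names everywhere except four alleles: the
#' DYS533 carrier of the 13-bp flanking insertion (CE reads 14.1), the
#' DYS481 carrier of the mobility-shift flanking SNP (CE reads 22.1), and
#' two primer-placement differences (DYS456 and DYS549, one unit off).
#'
#' @param profile A [fixture_profile()].
#' @return Data frame (sample, locus, ce_name).
#' @export
fixture_ce_profile <- function(profile) {
  ce <- data.frame(sample = profile$sample, locus = profile$locus,
                   ce_name = profile$length_name, stringsAsFactors = FALSE)
  hg <- fixture_samples()
  sel <- function(name) names(hg)[hg == name]
  e <- sel("E"); j1 <- sel("J1")
  bump <- function(sample, locus, value) {
    i <- which(ce$sample == sample & ce$locus == locus)
    stopifnot(length(i) == 1L)
    ce$ce_name[i] <<- value
  }
  bump(e[7], "DYS533", "14.1")              # 13-bp flanking insertion
  bump(sel("R2"), "DYS481", "22.1")         # rs368663163 mobility shift
  bump(j1[4], "DYS456", "16")               # primer-placement difference
  bump(sel("K")[3], "DYS549", "11")         # primer-placement difference
  ce
}

#' Known-variant catalogue for the fixture panel
#'
#' All fixture designations except the 60 novel ones.
#'
#' @param catalog A `locus_catalog`.
#' @return Data frame (locus, mps_name).
#' @export
fixture_known_catalog <- function(catalog = default_catalog()) {
  des <- fixture_designations(catalog)
  data.frame(locus = des$locus[!des$novel],
             mps_name = des$designation[!des$novel], stringsAsFactors = FALSE)
}

#' Write the fixture bundle to a directory
#'
#' Golden designation table, 100-sample tree (newick + haplogroup TSV),
#' allele profile, CE profile and known-variant catalogue, all as plain text.
#'
#' @param dir Output directory (created if needed).
#' @param catalog A `locus_catalog`.
#' @return Invisibly, the list of written paths.
#' @export
write_fixture_bundle <- function(dir = tempfile("fixtures"),
                                   catalog = default_catalog()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  des <- fixture_designations(catalog)
  profile <- fixture_profile(catalog)
  tree <- fixture_tree()
  paths <- c(
    designations = file.path(dir, "designations.tsv"),
    profile = file.path(dir, "profile.tsv"),
    ce_profile = file.path(dir, "ce_profile.tsv"),
    known = file.path(dir, "known_variants.tsv"),
    tree = file.path(dir, "tree.nwk"),
    haplogroups = file.path(dir, "haplogroups.tsv"))
  utils::write.table(des[, setdiff(names(des), "sequence")],
                     paths["designations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(profile, paths["profile"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fixture_ce_profile(profile), paths["ce_profile"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture_known_catalog(catalog), paths["known"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(tree$phy, paths["tree"])
  utils::write.table(
    data.frame(sample = names(tree$haplogroups),
               haplogroup = unname(tree$haplogroups)),
    paths["haplogroups"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
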