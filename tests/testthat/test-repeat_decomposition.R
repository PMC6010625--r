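test_that("locate_array finds the array between the flank anchors", {
  def <- default_catalog()[["DYS391"]]
  seq <- paste0(def$upstream_flank, strrep("TCTA", 9), def$downstream_flank)
  span <- locate_array(seq, "DYS391")
  expect_identical(unname(span[2] - span[1]), 36L)
  expect_identical(substring(seq, span[1], span[2] - 1L), strrep("TCTA", 9))
  # missing downstream flank is a locate error naming the side
  expect_error(locate_array(paste0(def$upstream_flank, strrep("TCTA", 9)),
                            "DYS391"), "downstream anchor")
  expect_error(locate_array(paste0(strrep("TCTA", 9), def$downstream_flank),
                            "DYS391"), "upstream anchor")
  # a 13-nt insertion deeper in the upstream flank does not break locating
  seq_ins <- make_seq("DYS533", "TATC[11]", "-48.1->CTCTTCTAACTAT")
  expect_silent(locate_array(seq_ins, "DYS533"))
})

test_that("greedy decomposition handles variant units, partials and spacers", {
  cases <- list(
    # internal SNP as a period-length variant unit
    list("DYS458", "GAAA[13]GGAA[1]"),
    # internal indel as a sub-period partial unit
    list("DYS458", "GAAA[15]AA[1]GAAA[2]"),
    # uncounted leading block present/absent
    list("DYS481", "CTG[1]CTT[22]"),
    list("DYS481", "CTG[0]CTT[28]"),
    # variant unit at the array start
    list("DYS391", "TCTG[1]TCTA[10]"),
    # variant units inside a later block plus block re-entry
    list("DYS437", "TCTA[6]TCTG[1]TCTA[3]TCTG[2]TCTA[4]"),
    # fixed spacer with a partial unit in the first block
    list("DYS448", "AGAGAT[3]AGAT[1]AGAGAT[9]N[42]AGAGAT[8]"),
    # compound array with an extra alternation absorbed as a variant unit
    list("DYS389II", "TAGA[10]CAGA[3]N[48]TAGA[11]CAGA[1]TAGA[1]CAGA[5]"))
  for (cs in cases) {
    d <- decompose(make_seq(cs[[1]], cs[[2]]), cs[[1]])
    expect_identical(ystrseq:::units_string(d), cs[[2]], info = cs[[2]])
  }
  # roles: every variant unit is one substitution from a catalogue motif;
  # partial units are shorter than the period
  d <- decompose(make_seq("DYS448", "AGAGAT[3]AGAT[1]AGAGAT[9]N[42]AGAGAT[8]"),
                 "DYS448")
  roles <- vapply(d$units, `[[`, character(1), "role")
  expect_identical(roles,
                   c("counted", "partial", "counted", "spacer", "counted"))
  expect_lt(nchar(d$units[[2]]$motif), 6L)
  # unparseable residue reports position and context
  def <- default_catalog()[["DYS392"]]
  bad <- paste0(def$upstream_flank, strrep("TAT", 8), "GGGGGG",
                strrep("TAT", 3), def$downstream_flank)
  expect_error(decompose(bad, "DYS392"), "unparseable")
})

test_that("render-decompose round-trip holds over random legal alleles", {
  cat <- default_catalog()
  set.seed(402)
  n_checked <- 0L
  for (rep in seq_len(10L)) {
    for (nm in names(cat)) {
      def <- cat[[nm]]
      d0 <- random_legal_decomposition(def)
      seq <- render_decomposition(d0, with_flanks = TRUE)
      d1 <- decompose(seq, nm)
      expect_identical(render_decomposition(d1), seq, info = nm)
      expect_identical(ystrseq:::block_count_vector(d1, def),
                       ystrseq:::block_count_vector(d0, def), info = nm)
      expect_identical(nrow(d1$flank_variants), 0L, info = nm)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("decompose is deterministic", {
  seq <- make_seq("DYS389II", "TAGA[9]CAGA[3]N[48]TAGA[12]CAGA[6]")
  a <- decompose(seq, "DYS389II")
  b <- decompose(seq, "DYS389II")
  expect_identical(ystrseq:::decomposition_key(a),
                   ystrseq:::decomposition_key(b))
})

test_that("flank variants are called with the +/- offset convention", {
  # single downstream substitution with rs annotation
  d <- decompose(make_seq("DYS391", "TCTA[11]", "+50C>A"), "DYS391")
  fv <- d$flank_variants
  expect_identical(nrow(fv), 1L)
  expect_identical(fv$offset, 50L)
  expect_identical(fv$ref, "C")
  expect_identical(fv$alt, "A")
  expect_identical(fv$id, "rs112815242")
  expect_identical(fv$genomic_position, 11982182L)
  # reference flanks give an empty list
  d0 <- decompose(make_seq("DYS391", "TCTA[11]"), "DYS391")
  expect_identical(nrow(d0$flank_variants), 0L)
  # 3-nt deletion right next to the array
  d2 <- decompose(make_seq("DYS576", "AAAG[18]", "+3AAA>-"), "DYS576")
  expect_identical(ystrseq:::flank_descriptors(d2$flank_variants), "+3AAA>-")
  expect_identical(d2$flank_variants$genomic_position, 7185388L)
  # 13-nt insertion upstream
  d3 <- decompose(make_seq("DYS533", "TATC[11]", "-48.1->CTCTTCTAACTAT"),
                  "DYS533")
  expect_identical(ystrseq:::flank_descriptors(d3$flank_variants),
                   "-48.1->CTCTTCTAACTAT")
  # near-edge upstream substitution (inside the anchor window)
  d4 <- decompose(make_seq("DYS643", "CTTTT[11]", "-7A>G"), "DYS643")
  expect_identical(ystrseq:::flank_descriptors(d4$flank_variants), "-7A>G")
})
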