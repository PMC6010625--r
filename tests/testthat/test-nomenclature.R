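name_of <- function(locus, units, flank = character()) {
  d <- decompose(make_seq(locus, units, flank), locus)
  list(ce = ce_name(d), mps = mps_name(d), len = length_based_name(d), d = d)
}

test_that("uncounted-block rules shift the CE name as published", {
  # DYS385 AAGG deviation from the canonical 6 copies: n-1 / +1 / +2
  expect_identical(name_of("DYS385ab", "AAGG[5]GAAA[16]")$ce, "15")
  expect_identical(name_of("DYS385ab", "AAGG[6]GAAA[14]")$ce, "14")
  expect_identical(name_of("DYS385ab", "AAGG[7]GAAA[17]")$ce, "18")
  expect_identical(name_of("DYS385ab", "AAGG[8]GAAA[13]")$ce, "15")
  # DYS481 leading CTG: 0 -> n-1, 2 -> n+1
  expect_identical(name_of("DYS481", "CTG[0]CTT[28]")$ce, "27")
  expect_identical(name_of("DYS481", "CTG[1]CTT[23]")$ce, "23")
  expect_identical(name_of("DYS481", "CTG[2]CTT[20]")$ce, "21")
  # DYS390 trailing taga: 1 -> -1, 3 -> +1 around the canonical 2
  expect_identical(name_of("DYS390", "TAGA[4]CAGA[1]TAGA[10]CAGA[10]TAGA[1]")$ce,
                   "24")
  expect_identical(name_of("DYS390", "TAGA[4]CAGA[1]TAGA[11]CAGA[8]TAGA[2]")$ce,
                   "24")
  expect_identical(name_of("DYS390", "TAGA[4]CAGA[1]TAGA[11]CAGA[7]TAGA[3]")$ce,
                   "24")
  # DYS19: with the ccta spacer absent the name is a + b - 1
  expect_identical(name_of("DYS19", "TCTA[13]CCTA[0]")$ce, "12")
  expect_identical(name_of("DYS19", "TCTA[11]CCTA[1]TCTA[3]")$ce, "14")
})

test_that("intermediate alleles carry the .r suffix", {
  expect_identical(
    name_of("DYS448", "AGAGAT[3]AGAT[1]AGAGAT[9]N[42]AGAGAT[8]")$ce, "20.4")
  expect_identical(name_of("DYS458", "GAAA[15]AA[1]GAAA[2]")$ce, "17.2")
  expect_identical(name_of("DYS458", "GAAA[17]AA[1]GAAA[2]")$ce, "19.2")
})

test_that("mps_name renders designation strings with flank descriptors", {
  expect_identical(name_of("DYS643", "CTTTT[11]", "-7A>G")$mps,
                   "CE11_CTTTT[11]_-7A>G")
  expect_identical(name_of("DYS481", "CTG[1]CTT[23]")$mps,
                   "CE23_CTG[1]CTT[23]")
  expect_identical(
    name_of("DYS448", "AGAGAT[3]AGAT[1]AGAGAT[9]N[42]AGAGAT[8]")$mps,
    "CE20.4_AGAGAT[3]AGAT[1]AGAGAT[9]N[42]AGAGAT[8]")
})

test_that("mps_name parses back to the same decomposition", {
  cat <- default_catalog()
  set.seed(913)
  for (rep in seq_len(5L)) {
    for (nm in names(cat)) {
      d0 <- random_legal_decomposition(cat[[nm]])
      d0 <- decompose(render_decomposition(d0), nm)  # canonical form
      nm1 <- mps_name(d0)
      d1 <- parse_mps_name(nm1, nm)
      expect_identical(mps_name(d1), nm1, info = nm)
      expect_identical(ystrseq:::decomposition_key(d1),
                       ystrseq:::decomposition_key(d0), info = nm)
    }
  }
  # with flank descriptors
  for (cs in list(c("DYS391", "TCTA[9]", "+50C>A"),
                  c("DYS533", "TATC[11]", "-48.1->CTCTTCTAACTAT"),
                  c("DYS576", "AAAG[18]", "+3AAA>-"))) {
    d0 <- decompose(make_seq(cs[1], cs[2], cs[3]), cs[1])
    d1 <- parse_mps_name(mps_name(d0), cs[1])
    expect_identical(mps_name(d1), mps_name(d0), info = cs[1])
  }
})

test_that("length-based names depend only on array length and collide for
           isometric alleles", {
  # the CE instrument reads fragment length: the structural GAAA count of
  # this DYS385 allele is 17 but its length-based name is 18
  r <- name_of("DYS385ab", "AAGG[7]GAAA[17]")
  expect_identical(r$len, "18")
  expect_identical(r$ce, r$len)
  # isometric DYS635 alleles: same length name, distinct designations
  a <- name_of("DYS635", "TAGA[8]TACA[2]TAGA[2]TACA[2]TAGA[4]")
  b <- name_of("DYS635", "TAGA[6]TACA[2]TAGA[4]TACA[2]TAGA[4]")
  expect_identical(a$len, b$len)
  expect_false(a$mps == b$mps)
  # ce_name equals length_based_name on random catalogue-legal alleles
  cat <- default_catalog()
  set.seed(914)
  for (rep in seq_len(5L)) {
    for (nm in names(cat)) {
      d <- decompose(render_decomposition(
        random_legal_decomposition(cat[[nm]])), nm)
      expect_identical(ce_name(d), length_based_name(d), info = nm)
    }
  }
})
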