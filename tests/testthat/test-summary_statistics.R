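test_that("diversity table reproduces the per-locus and total counts", {
  profile <- get_fixture_profile()
  div <- diversity_table(profile, known = fixture_known_catalog())
  total <- div[div$locus == "Total", ]
  expect_identical(total$n_length_alleles, 169L)
  expect_identical(total$n_sequence_alleles, 267L)
  expect_identical(total$pct_increase, 58.0)
  expect_identical(total$n_novel, 60L)
  expect_identical(attr(div, "headline_pct"), 58)
  row <- function(l) div[div$locus == l, ]
  expect_identical(row("DYS389II")$n_length_alleles, 7L)
  expect_identical(row("DYS389II")$n_sequence_alleles, 32L)
  expect_identical(row("DYS389II")$pct_increase, 357.1)
  expect_identical(row("DYS385ab")$pct_increase, 57.1)
  expect_identical(row("DYS392")$pct_increase, 0)
  # conservation: totals equal column sums
  body <- div[div$locus != "Total", ]
  expect_identical(sum(body$n_length_alleles), total$n_length_alleles)
  expect_identical(sum(body$n_sequence_alleles), total$n_sequence_alleles)
  expect_identical(sum(body$n_novel), total$n_novel)
})

test_that("diversity increase is zero for single-allele-per-locus profiles", {
  p <- data.frame(locus = c("DYS391", "DYS392"),
                  length_name = c("11", "13"),
                  mps_name = c("CE11_TCTA[11]", "CE13_TAT[13]"))
  div <- diversity_table(p)
  expect_true(all(div$pct_increase == 0))
})

test_that("isometric groups tally by locus and fragment length", {
  p <- data.frame(
    locus = c("DYS635", "DYS635", "DYS635", "DYS390", "DYS390", "DYS391"),
    length_name = c("18", "18", "19", "24", "24", "11"),
    mps_name = c("A", "B", "C", "D", "E", "F"))
  iso <- isometric_groups(p)
  expect_identical(nrow(iso$groups), 2L)
  expect_identical(unname(iso$histogram["2"]), 2L)
  expect_identical(iso$n_loci, 2L)
  # no sequence variation: empty tally
  p0 <- p[c(1, 3, 6), ]
  expect_identical(nrow(isometric_groups(p0)$groups), 0L)
  # planted sizes {2,2,3} give histogram {2: 2, 3: 1}
  p2 <- data.frame(
    locus = rep("DYS635", 7),
    length_name = c("18", "18", "19", "19", "20", "20", "20"),
    mps_name = letters[1:7])
  h <- isometric_groups(p2)$histogram
  expect_identical(unname(h["2"]), 2L)
  expect_identical(unname(h["3"]), 1L)
  # union of groups + singletons covers all distinct sequence alleles
  profile <- get_fixture_profile()
  iso_all <- isometric_groups(profile)
  n_in_groups <- sum(iso_all$groups$size)
  n_seq <- length(unique(paste(profile$locus, profile$mps_name)))
  n_len <- length(unique(paste(profile$locus, profile$length_name)))
  singles <- n_len - nrow(iso_all$groups)
  expect_identical(n_in_groups + singles, n_seq)
})

test_that("novelty filtering is keyed on the full in-phase designation", {
  profile <- get_fixture_profile()
  known <- fixture_known_catalog()
  nov <- novelty_filter(profile, known)
  expect_identical(nrow(nov), 60L)
  # an allele in the catalogue is filtered out; one whose array matches a
  # known entry but whose flanking SNP is new is retained
  expect_false("CE11_TCTA[11]" %in% nov$mps_name[nov$locus == "DYS391"])
  expect_true("CE11_TCTA[11]_+50C>A" %in% nov$mps_name[nov$locus == "DYS391"])
  # self and empty catalogues
  all_alleles <- unique(profile[, c("locus", "mps_name")])
  expect_identical(nrow(novelty_filter(profile, all_alleles)), 0L)
  empty <- data.frame(locus = character(), mps_name = character())
  expect_identical(nrow(novelty_filter(profile, empty)), nrow(all_alleles))
  # wildcard rows match flank-agnostically
  wild <- data.frame(locus = "DYS391", mps_name = "CE11_TCTA[11]_*")
  nov_w <- novelty_filter(profile, wild)
  expect_false("CE11_TCTA[11]_+50C>A" %in% nov_w$mps_name)
  # malformed catalogue rows are a load error with the line number
  path <- tempfile(fileext = ".tsv")
  writeLines(c("locus\tmps_name", "DYS391\tCE11_TCTA[11]", "DYS392\t"), path)
  expect_error(read_known_catalog(path), "line 3")
})

test_that("headline counts match the reference survey totals on the fixture profile", {
  profile <- get_fixture_profile()
  v <- extract_variants(profile)
  hc <- headline_counts(profile, v)
  expect_identical(hc$total_alleles, 2311L)
  expect_identical(hc$n_samples, 100L)
  expect_identical(hc$n_duplication, 5L)
  expect_identical(hc$n_somatic, 6L)
  # one sample, no extras: 23 alleles (DYS385a,b doubled)
  one <- profile[profile$sample == "s033" & profile$status == "primary", ]
  expect_identical(nrow(one), 23L)
  # planted SNP/indel recovery on a small constructed profile
  des <- get_fixture_designations()
  decs <- attr(des, "decompositions")
  pick <- c(which(des$locus == "DYS391" & des$flank == "+50C>A")[1:3],
            which(des$locus == "DYS458" & grepl("GGAA", des$units))[1:2])
  p <- data.frame(sample = sprintf("x%d", seq_along(pick)),
                  locus = des$locus[pick], mps_name = des$designation[pick],
                  length_name = des$length_name[pick], status = "primary")
  attr(p, "decompositions") <- decs[pick]
  v2 <- extract_variants(p)
  si <- v2[v2$kind %in% c("SNP", "indel"), ]
  expect_identical(nrow(si), 2L)   # one flank SNP + one variant unit
  hc2 <- headline_counts(p, v2)
  expect_identical(hc2$n_snp_indel_alleles, 5L)
  expect_identical(hc2$n_snp_indel_samples, 5L)
})
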