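reads_for <- function(locus, units, count, flank = character()) {
  data.frame(sequence = make_seq(locus, units, flank), count = count,
             stringsAsFactors = FALSE)
}

test_that("stutter and threshold rules gate reported alleles", {
  # a -1 group below the primary is suppressed as stutter
  rd <- rbind(reads_for("DYS458", "GAAA[17]", 500),
              reads_for("DYS458", "GAAA[16]", 40))
  calls <- call_alleles(rd, "DYS458", sample = "s1")
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$ce_name, "17")
  expect_identical(calls$depth, 500)
  expect_identical(calls$depth_adjusted, 540)   # stutter reads re-attributed
  # a +1 group is a candidate extra allele
  rd2 <- rbind(reads_for("DYS458", "GAAA[17]", 500),
               reads_for("DYS458", "GAAA[18]", 60))
  calls2 <- call_alleles(rd2, "DYS458", sample = "s1")
  expect_identical(calls2$status, c("primary", "additional"))
  expect_identical(calls2$ce_name, c("17", "18"))
  # groups below the 20x analytical threshold are dropped
  rd3 <- rbind(reads_for("DYS458", "GAAA[17]", 500),
               reads_for("DYS458", "GAAA[18]", 19))
  expect_identical(nrow(call_alleles(rd3, "DYS458")), 1L)
  expect_identical(nrow(call_alleles(reads_for("DYS458", "GAAA[17]", 12),
                                     "DYS458")), 0L)
})

test_that("raising the threshold never adds a call and depths conserve", {
  set.seed(71)
  rd <- rbind(reads_for("DYS570", "TTTC[17]", 310),
              reads_for("DYS570", "TTTC[16]", 35),
              reads_for("DYS570", "TTTC[19]", 150),
              reads_for("DYS570", "TTTC[12]", 28))
  prev <- Inf
  for (thr in c(20, 30, 100, 200)) {
    calls <- call_alleles(rd, "DYS570", threshold = thr)
    expect_lte(nrow(calls), prev)
    expect_lte(sum(calls$depth), sum(rd$count))
    prev <- nrow(calls)
  }
})

test_that("DYS385a,b reports two alleles, doubled when homoallelic", {
  rd <- rbind(reads_for("DYS385ab", "AAGG[6]GAAA[14]", 400),
              reads_for("DYS385ab", "AAGG[6]GAAA[11]", 380))
  calls <- call_alleles(rd, "DYS385ab")
  expect_identical(nrow(calls), 2L)
  expect_setequal(calls$ce_name, c("14", "11"))
  expect_true(all(calls$ab_unresolved))
  # heteroallelic one repeat apart: the deep -1 group is a real allele
  rd2 <- rbind(reads_for("DYS385ab", "AAGG[6]GAAA[14]", 400),
               reads_for("DYS385ab", "AAGG[6]GAAA[13]", 350))
  expect_setequal(call_alleles(rd2, "DYS385ab")$ce_name, c("13", "14"))
  # ... but a shallow -1 group is still stutter
  rd3 <- rbind(reads_for("DYS385ab", "AAGG[6]GAAA[14]", 400),
               reads_for("DYS385ab", "AAGG[6]GAAA[13]", 45))
  calls3 <- call_alleles(rd3, "DYS385ab")
  expect_identical(nrow(calls3), 2L)
  expect_identical(unique(calls3$ce_name), "14")
})

test_that("calls equal simulated truth on stutter-free noise-free reads", {
  panel <- get_noisefree_panel()
  calls <- panel$calls
  key <- function(df) sort(paste(df$sample, df$locus, df$mps_name))
  expect_identical(key(calls), key(panel$profile))
})

test_that("concordance reports discordances with resolution categories", {
  profile <- get_fixture_profile()
  ce <- fixture_ce_profile(profile)
  rep <- concordance(profile, ce)
  expect_identical(rep$total, 2311L)
  expect_identical(rep$discordant, 4L)
  expect_identical(rep$pct, 0.17)
  expect_setequal(rep$details$category,
                  c("flanking-indel", "mobility-shift-SNP",
                    "primer-difference"))
  expect_identical(sum(rep$details$category == "primer-difference"), 2L)
  # the mobility-shift call is driven by the known rs368663163 flank SNP
  expect_identical(
    rep$details$locus[rep$details$category == "mobility-shift-SNP"], "DYS481")
  # identical profiles: zero discordance
  same <- data.frame(sample = profile$sample, locus = profile$locus,
                     ce_name = profile$length_name)
  rep0 <- concordance(profile, same)
  expect_identical(rep0$discordant, 0L)
  expect_identical(rep0$pct, 0)
  # mismatched key sets are an input error
  expect_error(concordance(profile, ce[-1, ]), "input error")
})
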