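make_depth_tab <- function(ratios, ref_depth = 1000) {
  rows <- list()
  for (i in seq_along(ratios)) {
    s <- sprintf("d%02d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s, locus = c("DYS391", "DYS439"),
      depth = c(ratios[i] * ref_depth, ref_depth), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("expected ratio range from donors uses clipped Tukey fences", {
  # all donors at exactly 1.0
  tab <- make_depth_tab(rep(1, 12))
  rng <- expected_ratio_range(tab, "DYS391", "DYS439")
  expect_equal(unname(rng[1:2]), c(1, 1))
  # uniform ratios: fences clipped to observed extremes cover the bulk
  set.seed(5)
  ratios <- runif(99, 0.8, 1.2)
  rng2 <- expected_ratio_range(make_depth_tab(ratios), "DYS391", "DYS439")
  expect_lte(rng2[1], 0.85)
  expect_gte(rng2[2], 1.15)
  expect_gte(rng2[1], min(ratios))
  expect_lte(rng2[2], max(ratios))
  # donors lacking the reference locus are skipped, decrementing the count
  small <- make_depth_tab(rep(1, 10))
  small <- small[!(small$sample == "d01" & small$locus == "DYS439"), ]
  expect_error(expected_ratio_range(small, "DYS391", "DYS439"),
               "insufficient data")
  rng3 <- expected_ratio_range(small, "DYS391", "DYS439", min_donors = 9)
  expect_length(attr(rng3, "ratios"), 9L)
  expect_false("d01" %in% names(attr(rng3, "ratios")))
})

test_that("summed ratios separate duplication from somatic mutation", {
  tab <- make_depth_tab(runif(30, 0.95, 1.05))
  # duplicated: two alleles each near full dose
  q_dup <- data.frame(sample = "q", locus = c("DYS391", "DYS391", "DYS439"),
                      depth = c(980, 1010, 1000))
  res <- classify_extra_allele(rbind(tab, q_dup), "q", "DYS391", "DYS439")
  expect_identical(res$verdict, "duplication")
  expect_equal(res$summed_ratio, 1.99, tolerance = 0.01)
  # somatic: a single dose split between the two sequences
  q_som <- data.frame(sample = "q", locus = c("DYS391", "DYS391", "DYS439"),
                      depth = c(700, 300, 1000))
  res2 <- classify_extra_allele(rbind(tab, q_som), "q", "DYS391", "DYS439")
  expect_identical(res2$verdict, "somatic")
  # between the fences and the doubling guard: ambiguous
  q_mid <- data.frame(sample = "q", locus = c("DYS391", "DYS391", "DYS439"),
                      depth = c(900, 500, 1000))
  res3 <- classify_extra_allele(rbind(tab, q_mid), "q", "DYS391", "DYS439")
  expect_identical(res3$verdict, "ambiguous")
  # preconditions
  expect_error(classify_extra_allele(tab, "d01", "DYS391", "DYS439"),
               "exactly 2 alleles")
})

test_that("verdicts are scale invariant and deterministic", {
  set.seed(9)
  tab <- make_depth_tab(runif(25, 0.9, 1.1))
  q <- data.frame(sample = "q", locus = c("DYS391", "DYS391", "DYS439"),
                  depth = c(950, 990, 1000))
  v1 <- classify_extra_allele(rbind(tab, q), "q", "DYS391", "DYS439")$verdict
  tab10 <- tab; tab10$depth <- tab10$depth * 10
  q10 <- q; q10$depth <- q10$depth * 10
  v2 <- classify_extra_allele(rbind(tab10, q10), "q", "DYS391", "DYS439")$verdict
  v3 <- classify_extra_allele(rbind(tab, q), "q", "DYS391", "DYS439")$verdict
  expect_identical(v1, v2)
  expect_identical(v1, v3)
  expect_identical(v1, "duplication")
})

test_that("reference locus defaults to the nearest amplicon size", {
  sizes <- amplicon_sizes()
  expect_true(all(sizes > 100))
  tab <- make_depth_tab(rep(1, 15))
  q <- data.frame(sample = "q", locus = c("DYS391", "DYS391"),
                  depth = c(900, 950))
  # add single-allele depths for every locus in the query sample
  others <- data.frame(sample = "q", locus = setdiff(names(sizes), "DYS391"),
                       depth = 1000)
  res <- classify_extra_allele(rbind(tab, q, others), "q", "DYS391",
                               min_donors = 10)
  expect_identical(res$reference_locus,
                   names(which.min(abs(sizes[setdiff(names(sizes),
                     c("DYS391", "DYS385ab"))] - sizes["DYS391"]))))
})

test_that("the seeded 100-sample panel recovers 5 duplications and 6
           somatic mutants", {
  panel <- get_default_panel()
  calls <- panel$calls
  depth_tab <- data.frame(sample = calls$sample, locus = calls$locus,
                          depth = calls$depth_adjusted)
  verdicts <- ratio_test_profile(depth_tab)
  expect_identical(sum(verdicts$verdict == "duplication"), 5L)
  expect_identical(sum(verdicts$verdict == "somatic"), 6L)
  # the tested cells are the injected cells, and nearly all verdicts match
  # the injected kind (with 15% depth CV the single- and double-dose summed
  # ratios overlap slightly, so an occasional swap is expected)
  truth_extra <- panel$truth[panel$truth$kind %in%
                               c("duplication", "somatic"), ]
  expect_setequal(paste(verdicts$sample, verdicts$locus),
                  paste(truth_extra$carriers, truth_extra$locus))
  m <- merge(verdicts, truth_extra, by.x = c("sample", "locus"),
             by.y = c("carriers", "locus"))
  expect_gte(sum(m$verdict == m$kind), 9L)
})
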