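test_that("simulated trees are reproducible, binary and labelled", {
  cfg <- sim_config(n_samples = 100, seed = 1)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(t1$phy), ape::write.tree(t2$phy))
  expect_length(t1$phy$tip.label, 100L)
  expect_identical(t1$phy$Nnode, 99L)   # binary rooted
  expect_gte(length(unique(t1$haplogroups)), 8L)
  # n = 2: a single cherry
  t3 <- simulate_tree(sim_config(n_samples = 2, seed = 3))
  expect_setequal(t3$phy$tip.label, c("s001", "s002"))
  expect_identical(t3$phy$Nnode, 1L)
})

test_that("mutation placement respects the tree and the truth ledger", {
  panel <- get_noisefree_panel()
  truth <- panel$truth
  phy <- panel$tree$phy
  si <- truth[truth$kind %in% c("SNP", "indel"), ]
  # each event's carriers are exactly the leaves under its branch
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  clade <- function(node) {
    if (node <= length(phy$tip.label)) return(phy$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], clade))
  }
  for (i in seq_len(nrow(si)))
    expect_setequal(strsplit(si$carriers[i], ";")[[1]],
                    clade(si$branch[i]))
  # zero rates give reference alleles everywhere
  quiet <- place_mutations(panel$tree, config = sim_config(
    seed = 5, slippage_rate = 0, snp_indel_events = 0))
  expect_null(quiet$truth)
  refs <- vapply(names(default_catalog()), function(nm)
    ystrseq:::units_string(reference_allele(nm)), character(1))
  prof <- quiet$profile
  decs <- attr(prof, "decompositions")
  for (i in seq_len(nrow(prof)))
    expect_identical(ystrseq:::units_string(decs[[i]]), refs[[prof$locus[i]]])
})

test_that("read emission follows the depth and stutter models", {
  # degenerate depth model: every allele at exactly the median
  cfg <- sim_config(n_samples = 6, seed = 21, depth_cv = 0,
                    depth_median = 500, stutter_rate = 0,
                    slippage_rate = 0, snp_indel_events = 0,
                    n_duplications = 0, n_somatic = 0)
  panel <- simulate_panel(cfg)
  per_allele <- aggregate(count ~ sample + locus, panel$reads, sum)
  expect_true(all(per_allele$count %in% c(500, 1000)))  # DYS385: two copies
  # stutter fraction is binomial around the configured rate
  cfg2 <- sim_config(n_samples = 20, seed = 22, depth_cv = 0,
                     depth_median = 1000, stutter_rate = 0.1,
                     slippage_rate = 0, snp_indel_events = 0,
                     n_duplications = 0, n_somatic = 0)
  panel2 <- simulate_panel(cfg2)
  rd <- panel2$reads[panel2$reads$locus == "DYS458", ]
  main <- rd$count[rd$count > 500]
  stut <- rd$count[rd$count <= 500]
  expect_equal(mean(stut / 1000), 0.1, tolerance = 0.03)
  expect_true(all(main + stut == 1000))
  # full determinism under seed
  panel3 <- simulate_panel(cfg2)
  expect_identical(panel2$reads, panel3$reads)
  expect_identical(panel2$profile$mps_name, panel3$profile$mps_name)
})

test_that("injected duplications carry full dose and somatic mutants split", {
  panel <- get_noisefree_panel()   # depth_cv = 0, median 500
  rd <- panel$reads
  truth <- panel$truth
  dup <- truth[truth$kind == "duplication", ]
  for (i in seq_len(nrow(dup))) {
    counts <- rd$count[rd$sample == dup$carriers[i] &
                       rd$locus == dup$locus[i]]
    expect_identical(sort(counts), c(500L, 500L))
  }
  som <- truth[truth$kind == "somatic", ]
  for (i in seq_len(nrow(som))) {
    counts <- rd$count[rd$sample == som$carriers[i] &
                       rd$locus == som$locus[i]]
    expect_identical(sum(counts), 500L)
    expect_true(min(counts) >= 0.25 * 500 && max(counts) > 250)
  }
})

test_that("noise-free end-to-end run reproduces the truth ledger", {
  panel <- get_noisefree_panel()
  calls <- panel$calls
  key <- function(df) sort(paste(df$sample, df$locus, df$mps_name))
  expect_identical(key(calls), key(panel$profile))
  # verdicts
  depth_tab <- data.frame(sample = calls$sample, locus = calls$locus,
                          depth = calls$depth_adjusted)
  verdicts <- ratio_test_profile(depth_tab)
  truth_extra <- panel$truth[panel$truth$kind %in%
                               c("duplication", "somatic"), ]
  expect_setequal(paste(verdicts$sample, verdicts$locus, verdicts$verdict),
                  paste(truth_extra$carriers, truth_extra$locus,
                        truth_extra$kind))
  # variant carriers recovered exactly
  decs <- lapply(seq_len(nrow(calls)), function(i)
    parse_mps_name(calls$mps_name[i], calls$locus[i]))
  attr(calls, "decompositions") <- decs
  v <- extract_variants(calls)
  si <- panel$truth[panel$truth$kind %in% c("SNP", "indel"), ]
  for (i in seq_len(nrow(si))) {
    id <- paste0(si$locus[i], ":", si$payload[i])
    hit <- v[v$id == id, ]
    expect_identical(nrow(hit), 1L, info = id)
    expect_setequal(strsplit(hit$carriers, ";")[[1]],
                    strsplit(si$carriers[i], ";")[[1]])
  }
})
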