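test_that("origin counts match the exhaustive parsimony oracle", {
  set.seed(201)
  n_cases <- 0L
  for (rep in seq_len(60L)) {
    n <- sample(4:12, 1)
    phy <- ape::rtree(n, rooted = TRUE)
    phy$tip.label <- sprintf("t%02d", seq_len(n))
    tree <- sample_tree(phy)
    for (j in seq_len(9L)) {
      k <- sample(seq_len(n), 1)
      carriers <- sample(phy$tip.label, k)
      expect_identical(count_origins(carriers, tree),
                       brute_force_origins(carriers, phy))
      n_cases <- n_cases + 1L
    }
  }
  expect_gte(n_cases, 500L)
})

test_that("origin counts are invariant to re-rooting", {
  set.seed(202)
  for (rep in seq_len(20L)) {
    phy <- ape::rtree(8, rooted = TRUE)
    phy$tip.label <- sprintf("t%02d", 1:8)
    carriers <- sample(phy$tip.label, sample(2:6, 1))
    base <- count_origins(carriers, sample_tree(phy))
    for (node in c(3L, 6L)) {
      re <- ape::root(phy, outgroup = phy$tip.label[node],
                      resolve.root = TRUE)
      expect_identical(count_origins(carriers, sample_tree(re)), base)
    }
  }
})

test_that("monophyly means exactly one clade of carriers", {
  tree <- sample_tree("((a,b),(c,(d,e)));")
  expect_true(is_monophyletic(c("a", "b"), tree))
  expect_true(is_monophyletic(c("c", "d", "e"), tree))
  expect_true(is_monophyletic("d", tree))                       # single leaf
  expect_true(is_monophyletic(c("a", "b", "c", "d", "e"), tree)) # root clade
  expect_false(is_monophyletic(c("a", "c"), tree))
  expect_false(is_monophyletic(c("c", "d"), tree))  # mrca also spans e
  expect_error(is_monophyletic("zz", tree), "unknown sample")
  # single-branch placement implies a single origin
  expect_identical(count_origins(c("d", "e"), tree), 1L)
  expect_identical(count_origins(c("a", "b"), tree), 1L)
})

test_that("variants placed once on a branch classify monophyletic", {
  panel <- get_noisefree_panel()
  tr <- panel$tree
  si <- panel$truth[panel$truth$kind %in% c("SNP", "indel"), ]
  expect_gt(nrow(si), 0L)
  for (i in seq_len(nrow(si))) {
    carriers <- strsplit(si$carriers[i], ";", fixed = TRUE)[[1]]
    expect_true(is_monophyletic(carriers, tr), info = si$event[i])
    expect_identical(count_origins(carriers, tr), 1L, info = si$event[i])
  }
})

test_that("fixture carrier patterns reproduce the published associations", {
  profile <- get_fixture_profile()
  tr <- get_fixture_tree()
  v <- classify_variants(extract_variants(profile), tr)
  # DYS635: canonical 7-block RPV exclusive to the 15 superhaplogroup-P
  # samples, single origin
  rpv <- v[v$locus == "DYS635" & v$kind == "RPV" &
             grepl("11-2-2-2-2-2-2", v$id), ]
  expect_identical(nrow(rpv), 1L)
  expect_identical(rpv$n_carriers, 15L)
  expect_true(rpv$monophyletic)
  expect_identical(rpv$origins, 1L)
  expect_true(rpv$exclusive)
  expect_setequal(strsplit(rpv$haplogroups, ";")[[1]],
                  c("Q1a", "Q", "R1a", "R1b", "R2"))
  # DYS391 flanking SNP: all nine B2 samples, exclusively
  snp <- v[v$id == "DYS391:flank:+50C>A", ]
  expect_identical(snp$n_carriers, 9L)
  expect_true(snp$monophyletic)
  expect_identical(snp$haplogroups, "B2")
  expect_true(snp$exclusive)
  # DYS389II short block: 6-repeat monophyletic (haplogroup E), 4-repeat
  # polyphyletic (T, O, N plus sporadic carriers)
  c6 <- carriers_with_block_count(profile, "DYS389II", 5, 6)
  c4 <- carriers_with_block_count(profile, "DYS389II", 5, 4)
  expect_identical(length(c6), 14L)
  expect_true(is_monophyletic(c6, tr))
  expect_false(is_monophyletic(c4, tr))
  expect_gt(count_origins(c4, tr), 1L)
  hg4 <- associate_haplogroups(c4, tr)
  expect_true(all(c("T", "O", "N") %in% hg4$haplogroups))
  # DYS481: CTG absence monophyletic within B2b; CTG[2]+CTT[20] confined to
  # G2a while CTG[2] overall is polyphyletic
  c0 <- carriers_with_block_count(profile, "DYS481", 1, 0)
  expect_true(is_monophyletic(c0, tr))
  expect_identical(associate_haplogroups(c0, tr)$haplogroups, "B2b")
  g <- v[v$id == "DYS481:rpv:2-20", ]
  expect_identical(g$haplogroups, "G2a")
  expect_true(g$exclusive)
  c2 <- carriers_with_block_count(profile, "DYS481", 1, 2)
  expect_false(is_monophyletic(c2, tr))
  # DYS393 internal SNP: all four R1a samples
  r1a <- v[v$id == "DYS393:unit:CGAT", ]
  expect_identical(r1a$n_carriers, 4L)
  expect_identical(r1a$haplogroups, "R1a")
  expect_true(r1a$exclusive)
  # singleton flag for single-carrier variants
  expect_true(all(v$singleton == (v$n_carriers == 1L)))
})

test_that("extract_variants on an empty profile returns no records", {
  p <- data.frame(sample = character(), locus = character(),
                  length_name = character())
  attr(p, "decompositions") <- list()
  expect_identical(nrow(extract_variants(p)), 0L)
})
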