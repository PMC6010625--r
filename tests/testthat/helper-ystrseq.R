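# shared helpers: cached fixtures, legal-allele sampling, brute-force
# parsimony oracle

.cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.cache[[key]])) .cache[[key]] <- fn()
  .cache[[key]]
}

get_fixture_profile <- function() memo("profile", fixture_profile)
get_fixture_designations <- function() memo("designations", fixture_designations)
get_fixture_tree <- function() memo("tree", fixture_tree)
get_noisefree_panel <- function() memo("panel0", function() {
  panel <- simulate_panel(sim_config(seed = 11, stutter_rate = 0,
                                     depth_cv = 0, depth_median = 500))
  panel$calls <- call_profile(panel$reads, threshold = 20)
  panel
})
get_default_panel <- function() memo("panel1", function() {
  panel <- simulate_panel(sim_config(seed = 1))
  panel$calls <- call_profile(panel$reads, threshold = 20)
  panel
})

# full-length sequence for a bracketed designation
make_seq <- function(locus, units, flank = character()) {
  def <- default_catalog()[[locus]]
  ystrseq:::designation_sequence(def, units, flank)
}

# uniform catalogue-legal block counts that the greedy parser reproduces
# verbatim: every block at >= 1 copy, except a leading uncounted block
# (DYS481 ctg) which may take its legal 0
sample_legal_counts <- function(def) {
  vapply(seq_along(def$blocks), function(i) {
    b <- def$blocks[[i]]
    if (b$fixed_spacer) return(1L)
    lo <- max(b$min_repeats, 1L)
    if (i == 1L && !b$counted && b$min_repeats == 0L) lo <- 0L
    sample(seq.int(lo, b$max_repeats), 1L)
  }, integer(1))
}

random_legal_decomposition <- function(def) {
  ystrseq:::decomposition_from_counts(def, sample_legal_counts(def))
}

# exhaustive minimum-change count for a binary character on a rooted tree:
# brute force over all ancestral state assignments, root state free
brute_force_origins <- function(carriers, phy) {
  n_tip <- length(phy$tip.label)
  n_int <- phy$Nnode
  tip_state <- as.integer(phy$tip.label %in% carriers)
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    states <- c(tip_state, as.integer(intToBits(mask)[seq_len(n_int)]))
    changes <- sum(states[phy$edge[, 1]] != states[phy$edge[, 2]])
    if (changes < best) best <- changes
  }
  # a variant present in any sample has at least one origin
  if (length(carriers)) max(best, 1L) else as.integer(best)
}
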