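# -- phylogenetically structured synthetic panels ------------------------------
#
# The simulator emulates the reference survey's design end-to-end: a rooted sample
# phylogeny, slow branch-placed SNP/indel mutation (single origin per event),
# fast block-wise slippage (recurrent +/-1 repeat changes), per-allele read
# depths with -1 stutter, plus injected constitutive duplications and somatic
# mutants. Every event is recorded in a truth ledger so recovery can be
# checked exactly.

#' Simulation configuration
#'
#' Defaults mirror the reference survey's conditions: 100 samples, 5 duplications and 6
#' somatic mutants, a 20x analytical threshold downstream, per-allele depths
#' spanning roughly 251-11600x, and depth noise with 15% CV.
#'
#' @param n_samples Number of samples (>= 2).
#' @param snp_indel_events Number of branch-placed SNP/indel events (about
#'   one order of 10^-8 per base per generation in nature; here a per-study
#'   event count, default 34 distinct events).
#' @param slippage_rate Per-block per-branch probability of a +/-1 repeat
#'   slippage (the repeat-array process is ~5 orders of magnitude faster than
#'   SNPs; branches compress many generations, default 0.05).
#' @param depth_median,depth_cv Lognormal per-allele depth model (median,
#'   coefficient of variation), truncated to `depth_range`.
#' @param depth_range Truncation bounds for per-allele depth.
#' @param stutter_rate Fraction of an allele's reads emitted at the -1 repeat
#'   position of its longest counted block.
#' @param n_duplications,n_somatic Injected extra-allele events.
#' @param n_haplogroups Number of haplogroup labels cut from the tree.
#' @param seed Integer seed fixing all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 100L, snp_indel_events = 34L,
                       slippage_rate = 0.05, depth_median = 1500,
                       depth_cv = 0.15, depth_range = c(251, 11600),
                       stutter_rate = 0.1, n_duplications = 5L,
                       n_somatic = 6L, n_haplogroups = 10L, seed = 1L) {
  stopifnot(n_samples >= 2, slippage_rate >= 0, slippage_rate <= 1,
            stutter_rate >= 0, stutter_rate <= 1, depth_median > 0,
            depth_cv >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 snp_indel_events = as.integer(snp_indel_events),
                 slippage_rate = slippage_rate, depth_median = depth_median,
                 depth_cv = depth_cv, depth_range = depth_range,
                 stutter_rate = stutter_rate,
                 n_duplications = as.integer(n_duplications),
                 n_somatic = as.integer(n_somatic),
                 n_haplogroups = as.integer(n_haplogroups),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a rooted sample tree with haplogroup labels
#'
#' Random-coalescent-shape topology (random pairwise joins) over
#' `config$n_samples` leaves; haplogroup labels are assigned by cutting the
#' tree into `config$n_haplogroups` clades from the root down.
#'
#' @param config A [sim_config()].
#' @return A `sample_tree`.
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("s%03d", seq_len(n))
  frags <- as.list(ids)
  while (length(frags) > 1L) {
    pick <- sample.int(length(frags), 2L)
    frags[[pick[1]]] <- paste0("(", frags[[pick[1]]], ",",
                               frags[[pick[2]]], ")")
    frags[[pick[2]]] <- NULL
  }
  phy <- ape::read.tree(text = paste0(frags[[1]], ";"))
  hg <- cut_haplogroups(phy, config$n_haplogroups)
  sample_tree(phy, hg)
}

# assign haplogroup labels by repeatedly splitting the largest clade
cut_haplogroups <- function(phy, k) {
  n_tip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  clade_tips <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(kids[[as.character(node)]], clade_tips))
  }
  groups <- list(n_tip + 1L)  # root
  repeat {
    sizes <- vapply(groups, function(g) length(clade_tips(g)), integer(1))
    splittable <- which(vapply(groups, function(g) g > n_tip, logical(1)))
    if (length(groups) >= k || !length(splittable)) break
    big <- splittable[which.max(sizes[splittable])]
    repl <- kids[[as.character(groups[[big]])]]
    groups <- c(groups[-big], as.list(repl))
  }
  hg <- character(n_tip)
  for (i in seq_along(groups))
    hg[clade_tips(groups[[i]])] <- sprintf("HG%02d", i)
  names(hg) <- phy$tip.label
  hg
}

#' Place mutations on the tree
#'
#' Block-wise slippage (independent +/-1 events per branch, recurrence
#' allowed) plus `snp_indel_events` unique branch-placed SNP/indel events
#' (internal variant units, internal partial units, flanking SNPs and
#' flanking indels), each verified to be recoverable by the parser. Returns
#' the per-sample decompositions and a truth ledger.
#'
#' @param tree A `sample_tree`.
#' @param catalog A `locus_catalog`.
#' @param config A [sim_config()].
#' @return List with `profile` (data.frame + decompositions attribute),
#'   `truth` (event ledger) and `alleles` (per sample x marker decomposition
#'   list).
#' @export
place_mutations <- function(tree, catalog = default_catalog(), config) {
  set.seed(config$seed + 1L)
  phy <- as_phylo_tree(tree)
  n_tip <- length(phy$tip.label)
  eo <- ape::reorder.phylo(phy, "postorder")
  edges <- eo$edge
  kids <- split(edges[, 2], edges[, 1])
  clade_tips <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(kids[[as.character(node)]], clade_tips))
  }
  # markers: DYS385a,b simulated as two independent copies sharing one locus
  markers <- list()
  for (nm in names(catalog)) {
    def <- catalog[[nm]]
    for (cp in seq_len(def$copies))
      markers[[length(markers) + 1L]] <-
        list(locus = nm, copy = cp, def = def)
  }
  truth <- list()
  log_event <- function(...) truth[[length(truth) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  # ---- slippage: per-marker per-variable-block random walk down the tree
  counts <- list()   # [[marker]][leaf, block]
  preorder <- rev(seq_len(nrow(edges)))
  for (mi in seq_along(markers)) {
    def <- markers[[mi]]$def
    nb <- length(def$blocks)
    node_counts <- matrix(NA_integer_, nrow = n_tip + phy$Nnode, ncol = nb)
    root <- n_tip + 1L
    node_counts[root, ] <- vapply(def$blocks, function(b)
      if (b$fixed_spacer) 1L else b$canonical, integer(1))
    variable <- which(vapply(def$blocks, function(b)
      !b$fixed_spacer && b$max_repeats > b$min_repeats, logical(1)))
    for (ei in preorder) {
      par <- edges[ei, 1]; ch <- edges[ei, 2]
      cc <- node_counts[par, ]
      for (bi in variable) {
        if (stats::runif(1) < config$slippage_rate) {
          dir <- sample(c(-1L, 1L), 1L)
          b <- def$blocks[[bi]]
          if (cc[bi] + dir < b$min_repeats || cc[bi] + dir > b$max_repeats)
            dir <- -dir
          if (cc[bi] + dir >= b$min_repeats && cc[bi] + dir <= b$max_repeats) {
            cc[bi] <- cc[bi] + dir
            log_event(event = sprintf("slip%03d", length(truth) + 1L),
                      kind = "slippage", location = "internal",
                      locus = markers[[mi]]$locus, copy = markers[[mi]]$copy,
                      branch = ch, block = bi, delta = dir,
                      carriers = paste(phy$tip.label[clade_tips(ch)],
                                       collapse = ";"),
                      payload = "")
          }
        }
      }
      node_counts[ch, ] <- cc
    }
    counts[[mi]] <- node_counts[seq_len(n_tip), , drop = FALSE]
  }

  # ---- branch-placed SNP/indel events, verified recoverable
  events <- list()   # per marker: list of event descriptors
  for (mi in seq_along(markers)) events[[mi]] <- list()
  placed <- 0L
  used_ids <- character()
  tries <- 0L
  while (placed < config$snp_indel_events && tries < 4000L) {
    tries <- tries + 1L
    mi <- sample.int(length(markers), 1L)
    def <- markers[[mi]]$def
    ei <- sample.int(nrow(edges), 1L)
    ch <- edges[ei, 2]
    kind_pick <- sample(c("unit_snp", "partial", "flank_snp", "flank_indel"),
                        1L, prob = c(0.35, 0.15, 0.35, 0.15))
    ev <- make_event(def, kind_pick)
    if (is.null(ev)) next
    id <- paste(markers[[mi]]$locus, ev$key, sep = ":")
    if (id %in% used_ids) next
    # one internal event per block, one flank event per offset, per marker
    clash <- any(vapply(events[[mi]], function(e) e$key == ev$key ||
        (e$type %in% c("unit_snp", "partial") &&
         ev$type %in% c("unit_snp", "partial") && e$block == ev$block) ||
        (e$type %in% c("flank_snp", "flank_indel") &&
         ev$type %in% c("flank_snp", "flank_indel") &&
         abs(e$offset - ev$offset) < 4), logical(1)))
    if (clash) next
    carrier_tips <- clade_tips(ch)
    # verify recoverability on one carrier's current counts
    test_leaf <- carrier_tips[1]
    dec <- materialize_allele(def, counts[[mi]][test_leaf, ], list(ev),
                              catalog)
    if (is.null(dec)) next
    ev$branch <- ch
    ev$carriers <- carrier_tips
    events[[mi]][[length(events[[mi]]) + 1L]] <- ev
    used_ids <- c(used_ids, id)
    placed <- placed + 1L
    log_event(event = id, kind = ev$kind, location = ev$location,
              locus = markers[[mi]]$locus, copy = markers[[mi]]$copy,
              branch = ch, block = if (is.null(ev$block)) NA_integer_
                                   else ev$block,
              delta = NA_integer_,
              carriers = paste(phy$tip.label[carrier_tips], collapse = ";"),
              payload = ev$key)
  }
  if (placed < config$snp_indel_events)
    warning("placed only ", placed, " of ", config$snp_indel_events,
            " SNP/indel events")

  # ---- materialize decompositions per sample x marker
  alleles <- vector("list", length(markers))
  for (mi in seq_along(markers)) {
    def <- markers[[mi]]$def
    alleles[[mi]] <- vector("list", n_tip)
    for (leaf in seq_len(n_tip)) {
      evs <- Filter(function(e) leaf %in% e$carriers, events[[mi]])
      dec <- materialize_allele(def, counts[[mi]][leaf, ], evs, catalog,
                                strict = FALSE)
      if (is.null(dec))  # event clash with slipped counts: drop events
        dec <- materialize_allele(def, counts[[mi]][leaf, ], list(), catalog,
                                  strict = FALSE)
      alleles[[mi]][[leaf]] <- dec
    }
  }

  profile <- build_sim_profile(markers, alleles, phy$tip.label, catalog)
  truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
  list(profile = profile, truth = truth_df, alleles = alleles,
       markers = markers)
}

# construct one candidate SNP/indel event for a marker; NULL when no legal
# event exists for the drawn kind
make_event <- function(def, type) {
  variable <- which(vapply(def$blocks, function(b)
    !b$fixed_spacer && b$counted, logical(1)))
  all_motifs <- vapply(Filter(function(b) !b$fixed_spacer, def$blocks),
                       function(b) b$motif, character(1))
  if (type == "unit_snp") {
    bi <- if (length(variable) > 1L) sample(variable, 1L) else variable
    m <- def$blocks[[bi]]$motif
    for (i in seq_len(20L)) {
      p <- sample.int(nchar(m), 1L)
      alt <- sample(setdiff(DNA_ALPHABET, substring(m, p, p)), 1L)
      cand <- paste0(substring(m, 1, p - 1L), alt,
                     substring(m, p + 1L, nchar(m)))
      if (!cand %in% all_motifs)
        return(list(type = type, kind = "SNP", location = "internal",
                    block = bi, motif = cand,
                    key = sprintf("unit:%s", cand)))
    }
    return(NULL)
  }
  if (type == "partial") {
    bi <- if (length(variable) > 1L) sample(variable, 1L) else variable
    m <- def$blocks[[bi]]$motif
    L <- sample.int(def$period - 1L, 1L)
    frag <- substring(m, 1L, L)
    return(list(type = type, kind = "indel", location = "internal",
                block = bi, motif = frag,
                key = sprintf("partial:%s", frag)))
  }
  side <- sample(c(-1L, 1L), 1L)
  flank <- if (side < 0) def$upstream_flank else def$downstream_flank
  # keep clear of the 10-nt locate anchors adjacent to the array
  off <- sample(seq.int(12L, def$flank_window - 2L), 1L)
  base_at <- function(o) {
    if (side < 0) substring(flank, nchar(flank) - o + 1L,
                            nchar(flank) - o + 1L)
    else substring(flank, o, o)
  }
  if (type == "flank_snp") {
    ref <- base_at(off)
    alt <- sample(setdiff(DNA_ALPHABET, ref), 1L)
    return(list(type = type, kind = "SNP", location = "flanking",
                offset = side * off, ref = ref, alt = alt,
                key = sprintf("flank:%+d%s>%s", side * off, ref, alt)))
  }
  # flank_indel: short deletion of 1-3 nt
  L <- sample.int(3L, 1L)
  ref <- paste(vapply(seq.int(off, off + L - 1L), base_at, character(1)),
               collapse = "")
  # avoid ambiguous deletions (next base equal to first deleted base)
  if (base_at(off + L) == substring(ref, 1, 1)) return(NULL)
  list(type = type, kind = "indel", location = "flanking",
       offset = side * off, ref = ref, alt = "-",
       key = sprintf("flank:%+d%s>-", side * off, ref))
}

# build a decomposition for given block counts plus events; the rendered
# sequence is re-parsed so the result is in canonical parsed form. With
# strict = TRUE the parse must reproduce the intended designation exactly
# (used to verify that a candidate mutation event is recoverable); with
# strict = FALSE an equivalent canonical re-interpretation is accepted.
materialize_allele <- function(def, block_counts, events, catalog,
                               strict = TRUE) {
  units <- list()
  fv <- empty_flank_variants()
  for (i in seq_along(def$blocks)) {
    b <- def$blocks[[i]]
    if (b$fixed_spacer) {
      units[[length(units) + 1L]] <- list(motif = b$motif, count = 1L,
                                          role = "spacer", block = i)
      next
    }
    cnt <- block_counts[i]
    ev <- Filter(function(e) e$location == "internal" &&
                   !is.null(e$block) && e$block == i, events)
    if (length(ev)) {
      e <- ev[[1]]
      if (e$type == "unit_snp" && cnt >= 1L) {
        # one repeat unit of the block carries the substitution
        if (cnt > 1L)
          units[[length(units) + 1L]] <- list(motif = b$motif,
                                              count = cnt - 1L,
                                              role = if (b$counted) "counted"
                                                     else "uncounted",
                                              block = i)
        units[[length(units) + 1L]] <- list(motif = e$motif, count = 1L,
                                            role = "variant", block = i)
        next
      }
      if (e$type == "partial" && cnt >= 2L) {
        units[[length(units) + 1L]] <- list(motif = b$motif, count = cnt - 1L,
                                            role = if (b$counted) "counted"
                                                   else "uncounted", block = i)
        units[[length(units) + 1L]] <- list(motif = e$motif, count = 1L,
                                            role = "partial", block = i)
        units[[length(units) + 1L]] <- list(motif = b$motif, count = 1L,
                                            role = if (b$counted) "counted"
                                                   else "uncounted", block = i)
        next
      }
    }
    if (cnt > 0L || !b$counted)
      units[[length(units) + 1L]] <- list(motif = b$motif, count = cnt,
                                          role = if (b$counted) "counted"
                                                 else "uncounted", block = i)
  }
  for (e in events) {
    if (e$location != "flanking") next
    fv <- rbind(fv, data.frame(
      offset = e$offset, type = if (e$kind == "SNP") "SNP" else "del",
      ref = e$ref, alt = e$alt, genomic_position = NA_integer_,
      id = NA_character_, stringsAsFactors = FALSE))
  }
  cand <- new_decomposition(def$name, units, fv)
  seq <- render_decomposition(cand, catalog)
  parsed <- tryCatch(decompose(seq, def, catalog), error = function(e) NULL)
  if (is.null(parsed)) return(NULL)
  if (strict &&
      decomposition_key(stripped(parsed)) != decomposition_key(stripped(cand)))
    return(NULL)
  parsed
}

# drop annotation columns that legitimately differ pre/post parsing
stripped <- function(d) {
  d$flank_variants <- d$flank_variants[, c("offset", "type", "ref", "alt")]
  d
}

build_sim_profile <- function(markers, alleles, tip_labels, catalog) {
  rows <- list(); decs <- list()
  for (mi in seq_along(markers)) {
    for (leaf in seq_along(tip_labels)) {
      d <- alleles[[mi]][[leaf]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = tip_labels[leaf], locus = markers[[mi]]$locus,
        copy = markers[[mi]]$copy, ce_name = ce_name(d, catalog),
        mps_name = mps_name(d, catalog),
        length_name = length_based_name(d, catalog), status = "primary",
        stringsAsFactors = FALSE)
      decs[[length(decs) + 1L]] <- d
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "decompositions") <- decs
  out
}

#' Inject duplications and somatic mutants
#'
#' Adds `n_duplications` + `n_somatic` extra alleles at distinct
#' (sample, single-copy locus) cells. Extra alleles sit at +1 (somatic) or +2
#' (duplication) repeats of the largest counted block, never at the -1
#' stutter position of the primary allele.
#'
#' @param sim Output of [place_mutations()].
#' @param config A [sim_config()].
#' @param catalog A `locus_catalog`.
#' @return `sim` with extra rows appended to `profile` and events appended to
#'   `truth`.
#' @export
inject_extras <- function(sim, config, catalog = default_catalog()) {
  set.seed(config$seed + 2L)
  profile <- sim$profile
  decs <- attr(profile, "decompositions")
  single <- which(vapply(sim$markers, function(m) m$def$copies == 1L,
                         logical(1)))
  samples <- unique(profile$sample)
  n_extra <- config$n_duplications + config$n_somatic
  cells <- list()
  guard <- 0L
  while (length(cells) < n_extra && guard < 1000L) {
    guard <- guard + 1L
    cand <- list(sample = sample(samples, 1L),
                 marker = sample(single, 1L))
    key <- paste(cand$sample, cand$marker)
    if (key %in% vapply(cells, function(x) paste(x$sample, x$marker),
                        character(1))) next
    cells[[length(cells) + 1L]] <- cand
  }
  kinds <- c(rep("duplication", config$n_duplications),
             rep("somatic", config$n_somatic))
  extra_rows <- list(); extra_decs <- list(); truth_rows <- list()
  for (i in seq_along(cells)) {
    cand <- cells[[i]]
    def <- sim$markers[[cand$marker]]$def
    row_ix <- which(profile$sample == cand$sample &
                    profile$locus == def$name & profile$copy == 1L)
    base <- decs[[row_ix]]
    delta <- if (kinds[i] == "duplication") 2L else 1L
    extra <- shift_largest_block(base, def, delta, catalog)
    if (is.null(extra)) extra <- shift_largest_block(base, def, -2L, catalog)
    if (is.null(extra)) next
    extra_rows[[length(extra_rows) + 1L]] <- data.frame(
      sample = cand$sample, locus = def$name, copy = 1L,
      ce_name = ce_name(extra, catalog), mps_name = mps_name(extra, catalog),
      length_name = length_based_name(extra, catalog), status = kinds[i],
      stringsAsFactors = FALSE)
    extra_decs[[length(extra_decs) + 1L]] <- extra
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      event = sprintf("extra%02d", i), kind = kinds[i], location = "internal",
      locus = def$name, copy = 1L, branch = NA_integer_, block = NA_integer_,
      delta = delta, carriers = cand$sample,
      payload = mps_name(extra, catalog), stringsAsFactors = FALSE)
  }
  profile <- rbind(profile, do.call(rbind, extra_rows))
  attr(profile, "decompositions") <- c(decs, extra_decs)
  sim$profile <- profile
  sim$truth <- rbind(sim$truth, do.call(rbind, truth_rows))
  sim
}

# new decomposition with the largest counted block shifted by delta repeats
shift_largest_block <- function(d, def, delta, catalog) {
  counted <- which(vapply(def$blocks, function(b)
    b$counted && !b$fixed_spacer && b$max_repeats > b$min_repeats, logical(1)))
  if (!length(counted)) return(NULL)
  vec <- block_count_vector(d, def)
  bi <- counted[which.max(vec[counted])]
  b <- def$blocks[[bi]]
  if (vec[bi] + delta < b$min_repeats || vec[bi] + delta > b$max_repeats)
    return(NULL)
  counts <- vec
  counts[bi] <- counts[bi] + delta
  decomposition_from_counts(def, counts)
}

#' Emit a read table from a simulated profile
#'
#' Per allele, depth is drawn from the truncated lognormal depth model;
#' `stutter_rate` of those reads are emitted with one repeat fewer in the
#' allele's longest counted block. Duplicated alleles receive a full
#' independent dose each; somatic pairs split a single dose (the primary
#' keeping 55-75%).
#'
#' @param sim Output of [place_mutations()]/[inject_extras()].
#' @param config A [sim_config()].
#' @param catalog A `locus_catalog`.
#' @return Data frame (sample, locus, sequence, count); reads of the two
#'   DYS385 copies are pooled under the shared locus name.
#' @export
emit_reads <- function(sim, config, catalog = default_catalog()) {
  set.seed(config$seed + 3L)
  profile <- sim$profile
  decs <- attr(profile, "decompositions")
  sdlog <- sqrt(log(1 + config$depth_cv^2))
  draw_depth <- function() {
    for (i in seq_len(50L)) {
      d <- stats::rlnorm(1, meanlog = log(config$depth_median), sdlog = sdlog)
      if (d >= config$depth_range[1] && d <= config$depth_range[2])
        return(round(d))
    }
    round(min(max(d, config$depth_range[1]), config$depth_range[2]))
  }
  rows <- list()
  push <- function(sample, locus, seq, count) {
    count <- as.integer(round(count))
    if (count > 0L)
      rows[[length(rows) + 1L]] <<- data.frame(
        sample = sample, locus = locus, sequence = seq, count = count,
        stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(profile))) {
    st <- profile$status[i]
    if (st == "somatic") next  # handled with its primary below
    def <- catalog_locus(profile$locus[i], catalog)
    d <- decs[[i]]
    depth <- draw_depth()
    som_ix <- which(profile$sample == profile$sample[i] &
                    profile$locus == profile$locus[i] &
                    profile$status == "somatic")
    if (st == "primary" && length(som_ix)) {
      f <- stats::runif(1, 0.55, 0.75)
      emit_allele(push, profile$sample[i], def, d, round(f * depth),
                  config, catalog)
      emit_allele(push, profile$sample[i], def, decs[[som_ix[1]]],
                  depth - round(f * depth), config, catalog)
    } else {
      emit_allele(push, profile$sample[i], def, d, depth, config, catalog)
    }
  }
  out <- do.call(rbind, rows)
  # merge identical (sample, locus, sequence) rows (e.g. homoallelic DYS385)
  agg <- stats::aggregate(count ~ sample + locus + sequence, data = out,
                          FUN = sum)
  agg[order(agg$sample, agg$locus), ]
}

emit_allele <- function(push, sample, def, d, depth, config, catalog) {
  seq <- render_decomposition(d, catalog)
  stutter <- 0L
  if (config$stutter_rate > 0) {
    st_dec <- stutter_decomposition(d)
    if (!is.null(st_dec)) {
      stutter <- stats::rbinom(1, depth, config$stutter_rate)
      if (stutter > 0L)
        push(sample, def$name, render_decomposition(st_dec, catalog), stutter)
    }
  }
  push(sample, def$name, seq, depth - stutter)
}

# -1 stutter product: one repeat fewer in the longest counted unit, variant
# and partial units retained (slippage copies the template otherwise intact)
stutter_decomposition <- function(d) {
  counted <- which(vapply(d$units, function(u) u$role == "counted", logical(1)))
  if (!length(counted)) return(NULL)
  sizes <- vapply(d$units[counted], function(u) u$count, integer(1))
  i <- counted[which.max(sizes)]
  if (d$units[[i]]$count < 2L) return(NULL)
  d$units[[i]]$count <- d$units[[i]]$count - 1L
  new_decomposition(d$locus, d$units, d$flank_variants)
}

#' Simulate a complete panel
#'
#' Tree, mutations, duplications/somatic mutants and reads in one call.
#'
#' @param config A [sim_config()].
#' @param catalog A `locus_catalog`.
#' @return List with tree, profile, truth, reads.
#' @export
simulate_panel <- function(config = sim_config(),
                           catalog = default_catalog()) {
  tree <- simulate_tree(config)
  sim <- place_mutations(tree, catalog, config)
  sim <- inject_extras(sim, config, catalog)
  reads <- emit_reads(sim, config, catalog)
  list(tree = tree, profile = sim$profile, truth = sim$truth, reads = reads,
       config = config)
}
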