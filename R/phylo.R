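# -- phylogenetic classification of variants -----------------------------------
#
# Variants (flanking SNPs/indels, internal variant units and partial units,
# and repeat-pattern variants) are mapped onto a rooted sample phylogeny as
# binary presence/absence characters. The minimum number of state changes
# (gains and losses both allowed, root state free) is computed by unweighted
# parsimony generalized to polytomies; a variant is monophyletic when its
# carriers are exactly the leaf set of one node.

#' Construct a sample tree
#'
#' @param phy An `ape::phylo` rooted tree whose tip labels are sample ids, or
#'   a newick string/path accepted by [ape::read.tree()].
#' @param haplogroups Named character vector mapping sample id to haplogroup
#'   shorthand (e.g. "R1a"); optional.
#' @return An object of class `sample_tree`.
#' @export
sample_tree <- function(phy, haplogroups = NULL) {
  if (is.character(phy)) {
    phy <- if (file.exists(phy)) ape::read.tree(phy)
           else ape::read.tree(text = phy)
  }
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label))
    stop("sample tree has duplicated leaf ids")
  if (!is.null(haplogroups)) {
    missing <- setdiff(phy$tip.label, names(haplogroups))
    if (length(missing))
      stop("haplogroup labels missing for: ",
           paste(utils::head(missing, 5), collapse = ", "))
    haplogroups <- haplogroups[phy$tip.label]
  }
  structure(list(phy = phy, haplogroups = haplogroups), class = "sample_tree")
}

#' @export
print.sample_tree <- function(x, ...) {
  cat(sprintf("<sample_tree> %d samples%s\n", length(x$phy$tip.label),
              if (!is.null(x$haplogroups))
                sprintf(", %d haplogroups",
                        length(unique(x$haplogroups))) else ""))
  invisible(x)
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "sample_tree")) tree$phy
  else if (inherits(tree, "phylo")) tree
  else stop("expected a sample_tree or phylo object")
}

#' Minimum origin count of a carrier set under parsimony
#'
#' Minimum number of presence/absence state changes on the tree explaining
#' the carrier set, allowing both gains and losses, with free root state
#' (unit-cost parsimony; handles polytomies).
#'
#' @param carriers Character vector of carrier sample ids.
#' @param tree A `sample_tree` or `phylo`.
#' @return Integer count of state changes (>= 1 for non-empty, non-universal
#'   carrier sets; 0 when all or no leaves carry the variant).
#' @export
count_origins <- function(carriers, tree) {
  phy <- as_phylo_tree(tree)
  tips <- phy$tip.label
  unknown <- setdiff(carriers, tips)
  if (length(unknown))
    stop("input error: unknown sample id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  n_tip <- length(tips)
  n_node <- n_tip + phy$Nnode
  state <- tips %in% carriers
  INF <- n_node + 1  # exceeds any attainable change count
  cost0 <- c(ifelse(state, INF, 0), rep(0, phy$Nnode))
  cost1 <- c(ifelse(state, 0, INF), rep(0, phy$Nnode))
  # postorder over edges: accumulate child costs into parents
  eo <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1]; ch <- eo$edge[i, 2]
    cost0[par] <- cost0[par] + min(cost0[ch], cost1[ch] + 1)
    cost1[par] <- cost1[par] + min(cost1[ch], cost0[ch] + 1)
  }
  root <- n_tip + 1L
  changes <- as.integer(min(cost0[root], cost1[root]))
  # a variant carried by every sample still arose at least once
  if (length(carriers)) max(changes, 1L) else changes
}

#' Is a carrier set monophyletic?
#'
#' TRUE iff the carriers are exactly the leaf set of a single node (a clade),
#' including the single-leaf and all-leaves cases.
#'
#' @inheritParams count_origins
#' @return Logical flag.
#' @export
is_monophyletic <- function(carriers, tree) {
  phy <- as_phylo_tree(tree)
  tips <- phy$tip.label
  unknown <- setdiff(carriers, tips)
  if (length(unknown))
    stop("input error: unknown sample id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  carriers <- unique(carriers)
  if (!length(carriers)) return(FALSE)
  if (length(carriers) == 1L || length(carriers) == length(tips)) return(TRUE)
  node <- ape::getMRCA(phy, carriers)
  clade <- ape::extract.clade(phy, node)$tip.label
  setequal(clade, carriers)
}

#' Haplogroup association of a carrier set
#'
#' @param carriers Character vector of carrier sample ids.
#' @param tree A `sample_tree` with haplogroup labels.
#' @return List with `haplogroups` (label set among carriers) and `exclusive`
#'   (TRUE when no non-carrier shares any of those labels).
#' @export
associate_haplogroups <- function(carriers, tree) {
  stopifnot(inherits(tree, "sample_tree"), !is.null(tree$haplogroups))
  hg <- tree$haplogroups
  labels <- sort(unique(unname(hg[carriers])))
  others <- hg[setdiff(names(hg), carriers)]
  list(haplogroups = labels, exclusive = !any(others %in% labels))
}

#' Extract variant records from a decomposed profile
#'
#' One record per distinct flanking variant, per distinct internal variant
#' unit or partial unit, and per distinct repeat-pattern (block-count vector)
#' of alleles belonging to isometric groups, with carrier sample sets.
#'
#' @param profile A profile data frame (sample, locus, length_name columns)
#'   whose `attr(, "decompositions")` holds the per-row `decomposition`
#'   objects (as built by [fixture_profile()] or [call_profile()] row-binding
#'   helpers).
#' @param catalog A `locus_catalog`.
#' @return Data frame with variant id, locus, kind (SNP/indel/RPV), location
#'   (internal/flanking), carriers (";"-joined), n_carriers and the distinct
#'   allele designations bearing the variant.
#' @export
extract_variants <- function(profile, catalog = default_catalog()) {
  decs <- attr(profile, "decompositions")
  if (is.null(decs) || length(decs) != nrow(profile))
    stop("profile must carry one decomposition per row ",
         "(attr 'decompositions')")
  if (!nrow(profile)) return(empty_variant_records())
  recs <- new.env(parent = emptyenv())
  add <- function(id, locus, kind, location, sample, designation) {
    cur <- recs[[id]]
    if (is.null(cur))
      cur <- list(id = id, locus = locus, kind = kind, location = location,
                  carriers = character(), designations = character())
    cur$carriers <- union(cur$carriers, sample)
    cur$designations <- union(cur$designations, designation)
    recs[[id]] <- cur
  }
  # isometric groups: (locus, length name) classes with >= 2 distinct keys
  keys <- vapply(decs, decomposition_key, character(1))
  cls <- paste(profile$locus, profile$length_name, sep = "\r")
  n_keys_in_class <- tapply(keys, cls, function(k) length(unique(k)))
  for (i in seq_len(nrow(profile))) {
    d <- decs[[i]]
    s <- profile$sample[i]
    designation <- mps_name(d, catalog)
    fv <- d$flank_variants
    if (nrow(fv)) for (j in seq_len(nrow(fv))) {
      v <- fv[j, ]
      add(sprintf("%s:flank:%+d%s>%s", d$locus, v$offset, v$ref, v$alt),
          d$locus, if (v$type == "SNP") "SNP" else "indel", "flanking",
          s, designation)
    }
    for (u in d$units) {
      if (u$role == "variant")
        add(sprintf("%s:unit:%s", d$locus, u$motif), d$locus, "SNP",
            "internal", s, designation)
      if (u$role == "partial")
        add(sprintf("%s:partial:%s", d$locus, u$motif), d$locus, "indel",
            "internal", s, designation)
    }
    # RPV records for multi-block loci, restricted to isometric-group members
    def <- catalog_locus(d$locus, catalog)
    n_var_blocks <- sum(vapply(def$blocks, function(b)
      !b$fixed_spacer && b$max_repeats > b$min_repeats, logical(1)))
    if (n_var_blocks >= 2L && n_keys_in_class[[cls[i]]] >= 2L) {
      vec <- block_count_vector(d, def)
      add(sprintf("%s:rpv:%s", d$locus, paste(vec, collapse = "-")),
          d$locus, "RPV", "internal", s, designation)
    }
  }
  ids <- ls(recs)
  out <- do.call(rbind, lapply(ids, function(id) {
    r <- recs[[id]]
    data.frame(id = r$id, locus = r$locus, kind = r$kind,
               location = r$location,
               carriers = paste(sort(r$carriers), collapse = ";"),
               n_carriers = length(r$carriers),
               designations = paste(sort(r$designations), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$locus, out$kind, out$id), ]
}

empty_variant_records <- function() {
  data.frame(id = character(), locus = character(), kind = character(),
             location = character(), carriers = character(),
             n_carriers = integer(), designations = character(),
             stringsAsFactors = FALSE)
}

# per-catalogue-block totals of plain repeat units (variant/partial units
# excluded: they are SNP/indel records, not repeat-pattern state)
block_count_vector <- function(d, def) {
  vec <- integer(length(def$blocks))
  for (u in d$units)
    if (u$role %in% c("counted", "uncounted"))
      vec[u$block] <- vec[u$block] + u$count
  vec
}

#' Classify variant records on a tree
#'
#' Adds origin counts, monophyly flags, haplogroup associations and a
#' singleton flag to an [extract_variants()] table.
#'
#' @param variants Output of [extract_variants()].
#' @param tree A `sample_tree`.
#' @return The input with origins, monophyletic, haplogroups, exclusive and
#'   singleton columns added.
#' @export
classify_variants <- function(variants, tree) {
  if (!nrow(variants)) {
    variants$origins <- integer()
    variants$monophyletic <- logical()
    variants$haplogroups <- character()
    variants$exclusive <- logical()
    variants$singleton <- logical()
    return(variants)
  }
  carriers <- strsplit(variants$carriers, ";", fixed = TRUE)
  variants$origins <- vapply(carriers, count_origins, integer(1), tree = tree)
  variants$monophyletic <- vapply(carriers, is_monophyletic, logical(1),
                                  tree = tree)
  if (!is.null(tree$haplogroups)) {
    assoc <- lapply(carriers, associate_haplogroups, tree = tree)
    variants$haplogroups <- vapply(assoc, function(a)
      paste(a$haplogroups, collapse = ";"), character(1))
    variants$exclusive <- vapply(assoc, function(a) a$exclusive, logical(1))
  }
  variants$singleton <- variants$n_carriers == 1L
  variants
}

#' Samples whose allele has a given repeat count in one block
#'
#' Convenience selector for interrogating repeat-pattern families (e.g. all
#' samples whose DYS389II final CAGA block has 4 repeats).
#'
#' @param profile Profile with decompositions attribute.
#' @param locus Locus name.
#' @param block Catalogue block index.
#' @param count Repeat count to match.
#' @param catalog A `locus_catalog`.
#' @return Character vector of sample ids.
#' @export
carriers_with_block_count <- function(profile, locus, block, count,
                                      catalog = default_catalog()) {
  decs <- attr(profile, "decompositions")
  def <- catalog_locus(locus, catalog)
  hit <- vapply(seq_len(nrow(profile)), function(i) {
    if (profile$locus[i] != def$name) return(FALSE)
    block_count_vector(decs[[i]], def)[block] == count
  }, logical(1))
  sort(unique(profile$sample[hit]))
}
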