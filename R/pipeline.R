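# -- pipeline orchestration ----------------------------------------------------

#' Run configuration
#'
#' @param out_dir Output directory.
#' @param catalogue Path to a catalogue JSON (`NULL` = packaged default).
#' @param reads Path to a read-table TSV (sample, locus, sequence, count), or
#'   `NULL`.
#' @param sequences Path to a per-allele sequence TSV (sample, locus,
#'   sequence), or `NULL`.
#' @param profile Path to a precomputed profile TSV, or `NULL`.
#' @param tree Path to a newick tree, or `NULL` (skips classification).
#' @param haplogroups Path to a sample-to-haplogroup TSV, or `NULL`.
#' @param ce_profile Path to a CE profile TSV, or `NULL` (skips concordance).
#' @param known_variants Path to a known-variant TSV, or `NULL` (skips
#'   novelty filtering).
#' @param min_depth Analytical depth threshold.
#' @param seed Seed for any stochastic steps.
#' @param log_level "info" or "quiet".
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, catalogue = NULL, reads = NULL,
                       sequences = NULL, profile = NULL, tree = NULL,
                       haplogroups = NULL, ce_profile = NULL,
                       known_variants = NULL, min_depth = 20L, seed = 1L,
                       log_level = "info") {
  cfg <- list(out_dir = out_dir, catalogue = catalogue, reads = reads,
              sequences = sequences, profile = profile, tree = tree,
              haplogroups = haplogroups, ce_profile = ce_profile,
              known_variants = known_variants,
              min_depth = as.integer(min_depth), seed = as.integer(seed),
              log_level = log_level)
  if (cfg$min_depth <= 0L) stop("configuration error: min_depth must be > 0")
  inputs <- c("catalogue", "reads", "sequences", "profile", "tree",
              "haplogroups", "ce_profile", "known_variants")
  for (f in inputs)
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configuration error: ", f, " file not found: ", cfg[[f]])
  if (sum(!vapply(cfg[c("reads", "sequences", "profile")], is.null,
                  logical(1))) != 1L)
    stop("configuration error: exactly one of reads/sequences/profile ",
         "must be given")
  structure(cfg, class = "run_config")
}

pipe_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message("[ystrseq] ", ...)
}

#' Validate pipeline inputs
#'
#' Schema checks on all configured inputs; report-only (never throws for
#' content findings).
#'
#' @param config A [run_config()].
#' @return Data frame of findings (file, line, finding); zero rows when all
#'   inputs are well-formed.
#' @export
validate_inputs <- function(config) {
  findings <- list()
  note <- function(file, line, finding)
    findings[[length(findings) + 1L]] <<- data.frame(
      file = file, line = line, finding = finding, stringsAsFactors = FALSE)
  check_tsv <- function(path, need) {
    if (is.null(path)) return(NULL)
    lines <- readLines(path, warn = FALSE)
    if (!length(lines)) { note(path, 0L, "empty file"); return(NULL) }
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    miss <- setdiff(need, header)
    if (length(miss)) {
      note(path, 1L, paste("missing column(s):", paste(miss, collapse = ", ")))
      return(NULL)
    }
    nf <- lengths(strsplit(lines[-1], "\t", fixed = TRUE))
    bad <- which(nf != length(header))
    for (b in bad) note(path, b + 1L, "truncated or ragged row")
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  reads <- check_tsv(config$reads, c("sample", "locus", "sequence", "count"))
  seqs <- check_tsv(config$sequences, c("sample", "locus", "sequence"))
  prof <- check_tsv(config$profile, c("sample", "locus", "mps_name"))
  check_tsv(config$ce_profile, c("sample", "locus", "ce_name"))
  check_tsv(config$known_variants, c("locus", "mps_name"))
  if (!is.null(config$tree)) {
    phy <- tryCatch(ape::read.tree(config$tree), error = function(e) NULL)
    if (is.null(phy)) note(config$tree, 0L, "unreadable newick")
    else {
      tab <- if (!is.null(reads)) reads else if (!is.null(seqs)) seqs else prof
      if (!is.null(tab)) {
        extra <- setdiff(phy$tip.label, unique(tab$sample))
        for (s in extra)
          note(config$tree, 0L, paste("tree leaf absent from profile:", s))
      }
    }
  }
  if (!length(findings))
    return(data.frame(file = character(), line = integer(),
                      finding = character(), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Run the full pipeline
#'
#' decompose -> name -> call -> duplication test -> phylogenetic
#' classification -> summaries, writing TSV outputs under
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the in-memory stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  catalog <- if (is.null(config$catalogue)) default_catalog()
             else load_catalog(config$catalogue)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  emit <- function(obj, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs[[name]] <<- path
  }

  # ---- stage: calling / decomposition
  if (!is.null(config$reads)) {
    pipe_log(config, "calling alleles from reads")
    reads <- utils::read.delim(config$reads, stringsAsFactors = FALSE)
    profile <- call_profile(reads, threshold = config$min_depth,
                            catalog = catalog)
    decs <- list()
    for (i in seq_len(nrow(profile)))
      decs[[i]] <- parse_mps_name(profile$mps_name[i], profile$locus[i],
                                  catalog)
    attr(profile, "decompositions") <- decs
  } else if (!is.null(config$sequences)) {
    pipe_log(config, "decomposing per-allele sequences")
    seqs <- utils::read.delim(config$sequences, stringsAsFactors = FALSE)
    decs <- vector("list", nrow(seqs))
    rows <- vector("list", nrow(seqs))
    for (i in seq_len(nrow(seqs))) {
      d <- decompose(seqs$sequence[i], seqs$locus[i], catalog)
      decs[[i]] <- d
      rows[[i]] <- data.frame(
        sample = seqs$sample[i], locus = seqs$locus[i],
        ce_name = ce_name(d, catalog), mps_name = mps_name(d, catalog),
        length_name = length_based_name(d, catalog),
        depth = if ("depth" %in% names(seqs)) seqs$depth[i] else NA_real_,
        status = "primary", stringsAsFactors = FALSE)
    }
    profile <- do.call(rbind, rows)
    attr(profile, "decompositions") <- decs
  } else {
    pipe_log(config, "profile input: calling and duplication stages skipped")
    profile <- utils::read.delim(config$profile, stringsAsFactors = FALSE)
    decs <- list()
    for (i in seq_len(nrow(profile)))
      decs[[i]] <- parse_mps_name(profile$mps_name[i], profile$locus[i],
                                  catalog)
    attr(profile, "decompositions") <- decs
    if (!"length_name" %in% names(profile))
      profile$length_name <- vapply(decs, length_based_name, character(1),
                                    catalog = catalog)
    if (!"status" %in% names(profile)) profile$status <- "primary"
  }
  emit(profile, "profile")

  # ---- stage: duplication vs somatic test
  if (!is.null(config$reads) && "depth_adjusted" %in% names(profile)) {
    pipe_log(config, "read-depth ratio test")
    depth_tab <- data.frame(sample = profile$sample, locus = profile$locus,
                            depth = profile$depth_adjusted,
                            stringsAsFactors = FALSE)
    verdicts <- ratio_test_profile(depth_tab, catalog = catalog)
    if (nrow(verdicts)) {
      for (i in seq_len(nrow(verdicts))) {
        hit <- which(profile$sample == verdicts$sample[i] &
                     profile$locus == verdicts$locus[i] &
                     profile$status == "additional")
        profile$status[hit] <- verdicts$verdict[i]
      }
    }
    emit(verdicts, "ratio_test")
    emit(profile, "profile")
  }

  # ---- stage: concordance
  if (!is.null(config$ce_profile)) {
    pipe_log(config, "CE/MPS concordance")
    cep <- utils::read.delim(config$ce_profile, stringsAsFactors = FALSE)
    conc <- concordance(profile, cep)
    emit(data.frame(total = conc$total, discordant = conc$discordant,
                    pct = conc$pct), "concordance_summary")
    emit(conc$details, "concordance_details")
  }

  # ---- stage: phylogenetic classification
  variants <- extract_variants(profile, catalog)
  if (!is.null(config$tree)) {
    pipe_log(config, "phylogenetic classification")
    hgs <- NULL
    if (!is.null(config$haplogroups)) {
      h <- utils::read.delim(config$haplogroups, stringsAsFactors = FALSE)
      hgs <- stats::setNames(h$haplogroup, h$sample)
    }
    tree <- sample_tree(config$tree, hgs)
    variants <- classify_variants(variants, tree)
  }
  emit(variants, "variants")

  # ---- stage: summaries
  pipe_log(config, "summaries")
  known <- if (!is.null(config$known_variants))
    read_known_catalog(config$known_variants) else NULL
  div <- diversity_table(profile, known = known)
  emit(div, "diversity")
  iso <- isometric_groups(profile)
  emit(iso$groups, "isometric_groups")
  if (!is.null(known)) emit(novelty_filter(profile, known), "novel_alleles")
  head_counts <- headline_counts(profile, variants)
  emit(data.frame(metric = names(head_counts),
                  value = unlist(lapply(head_counts, as.character))),
       "headline_counts")
  invisible(list(profile = profile, variants = variants, diversity = div,
                 isometric = iso, headline = head_counts, outputs = outputs))
}
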