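# -- repeat-array decomposition ------------------------------------------------
#
# A decomposition is an allele sequence parsed into an ordered list of repeat
# units relative to a locus definition: counted and uncounted repeat blocks,
# fixed spacers, period-length variant units (internal SNPs, e.g. GGAA inside
# GAAA[n]), and at most one sub-period partial unit (internal indel, producing
# intermediate ".r" alleles), plus any flanking-region SNPs/indels.

new_decomposition <- function(locus, units, flank_variants) {
  array_length <- sum(vapply(units, function(u) nchar(u$motif) * u$count,
                             numeric(1)))
  structure(
    list(locus = locus, units = units, array_length = as.integer(array_length),
         flank_variants = flank_variants),
    class = "decomposition")
}

empty_flank_variants <- function() {
  data.frame(offset = integer(), type = character(), ref = character(),
             alt = character(), genomic_position = integer(),
             id = character(), stringsAsFactors = FALSE)
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %s  %s  (%d nt array)\n", x$locus,
              units_string(x), x$array_length))
  if (nrow(x$flank_variants))
    cat("  flank:", paste(flank_descriptors(x$flank_variants), collapse = " "),
        "\n")
  invisible(x)
}

#' @export
format.decomposition <- function(x, ...) decomposition_key(x)

# bracketed unit string, spacers shown as N[len]
units_string <- function(d) {
  paste(vapply(d$units, function(u) {
    if (u$role == "spacer") sprintf("N[%d]", nchar(u$motif))
    else sprintf("%s[%d]", u$motif, u$count)
  }, character(1)), collapse = "")
}

# canonical identity key: array structure plus phased flank variants
decomposition_key <- function(d) {
  fv <- flank_descriptors(d$flank_variants)
  paste(c(units_string(d), fv), collapse = "_")
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

strrep_motif <- function(motif, n) paste(rep(motif, n), collapse = "")

#' Locate the repeat array within a full-length sequence
#'
#' Finds the half-open interval spanned by the repeat array, using the
#' innermost `anchor_length` nt of each reference flank as unique anchors.
#' When a flanking variant sits inside one anchor (e.g. a SNP at +3) that
#' side's boundary is inferred instead by maximal exact motif extension from
#' the located side; the variant itself is then recovered by
#' [call_flank_variants()].
#'
#' @param sequence Full-length allele sequence (upstream flank + array +
#'   downstream flank).
#' @param locus A `locus_definition` or locus name.
#' @param catalog A `locus_catalog`.
#' @param anchor_length Anchor length in nt (default 10).
#' @return Integer vector `c(array_start, array_end)`, 1-based half-open
#'   (the array is `substring(sequence, array_start, array_end - 1)`).
#' @export
locate_array <- function(sequence, locus, catalog = default_catalog(),
                         anchor_length = 10L) {
  def <- catalog_locus(locus, catalog)
  sequence <- toupper(sequence)
  up <- def$upstream_flank
  up_anchor <- substring(up, nchar(up) - anchor_length + 1L, nchar(up))
  down_anchor <- substring(def$downstream_flank, 1L, anchor_length)
  find1 <- function(anchor, side) {
    hits <- gregexpr(anchor, sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NA_integer_)
    if (length(hits) > 1L)
      stop("locate error at ", def$name, ": ", side, " anchor not unique")
    hits[1]
  }
  up_hit <- find1(up_anchor, "upstream")
  down_hit <- find1(down_anchor, "downstream")
  if (is.na(up_hit) && is.na(down_hit))
    stop("locate error at ", def$name, ": upstream anchor not found")
  start <- if (!is.na(up_hit)) up_hit + anchor_length else NA_integer_
  end <- down_hit
  motifs <- unique(vapply(def$blocks, function(b) b$motif, character(1)))
  if (is.na(end)) {
    # near-edge downstream variant: extend exact motif/spacer matches
    pos <- start
    n <- nchar(sequence)
    repeat {
      hit <- FALSE
      for (m in motifs) {
        lm <- nchar(m)
        if (pos + lm - 1L <= n && substring(sequence, pos, pos + lm - 1L) == m) {
          pos <- pos + lm; hit <- TRUE; break
        }
      }
      if (!hit) break
    }
    end <- pos
    if (n - end + 1L < anchor_length)
      stop("locate error at ", def$name, ": downstream anchor not found")
  }
  if (is.na(start)) {
    # near-edge upstream variant: extend backwards from the downstream side
    pos <- end
    repeat {
      hit <- FALSE
      for (m in motifs) {
        lm <- nchar(m)
        if (pos - lm >= 1L && substring(sequence, pos - lm, pos - 1L) == m) {
          pos <- pos - lm; hit <- TRUE; break
        }
      }
      if (!hit) break
    }
    start <- pos
    if (start - 1L < anchor_length)
      stop("locate error at ", def$name, ": upstream anchor not found")
  }
  if (end < start)
    stop("locate error at ", def$name, ": anchors out of order")
  c(array_start = start, array_end = end)
}

#' Decompose an allele sequence into repeat units
#'
#' Greedy left-to-right maximal-extension parse of the repeat array against the
#' locus's ordered block grammar. At a mismatch the parser tries, in order:
#' the next block's motif (or fixed spacer), a single period-length variant
#' unit differing from the local motif by one substitution (internal SNP),
#' and a sub-period partial unit (internal indel; at most one per allele).
#' Flanking variants are called by outward comparison against the reference
#' flanks (see [call_flank_variants()]).
#'
#' @param sequence Full-length allele sequence, reporting-strand orientation.
#' @param locus A `locus_definition` or locus name.
#' @param catalog A `locus_catalog`.
#' @param with_flanks If `FALSE`, `sequence` is taken to be the bare array.
#' @return A `decomposition` object.
#' @export
decompose <- function(sequence, locus, catalog = default_catalog(),
                      with_flanks = TRUE) {
  def <- catalog_locus(locus, catalog)
  sequence <- toupper(sequence)
  if (with_flanks) {
    span <- locate_array(sequence, def)
    array <- substring(sequence, span[1], span[2] - 1L)
    fv <- call_flank_variants(sequence, def, span = span)
  } else {
    array <- sequence
    fv <- empty_flank_variants()
  }
  units <- parse_array(array, def)
  new_decomposition(def$name, units, fv)
}

parse_array <- function(array, def) {
  n <- nchar(array)
  blocks <- def$blocks
  nb <- length(blocks)
  period <- def$period
  pos <- 1L
  bi <- 1L
  partial_used <- FALSE
  units <- list()

  peek <- function(len) substring(array, pos, pos + len - 1L)
  emit <- function(motif, count, role, block) {
    k <- length(units)
    if (k > 0L && role == "variant" && units[[k]]$role == "variant" &&
        units[[k]]$motif == motif) {
      units[[k]]$count <<- units[[k]]$count + count
    } else {
      units[[k + 1L]] <<- list(motif = motif, count = as.integer(count),
                               role = role, block = as.integer(block))
    }
  }
  # maximal extension of `motif` at pos; returns copy count
  extend <- function(motif) {
    len <- nchar(motif)
    c0 <- 0L
    while (pos + (c0 + 1L) * len - 1L <= n &&
           substring(array, pos + c0 * len, pos + (c0 + 1L) * len - 1L) == motif)
      c0 <- c0 + 1L
    c0
  }
  block_role <- function(b) if (b$counted) "counted" else "uncounted"

  while (pos <= n) {
    b <- if (bi <= nb) blocks[[bi]] else NULL
    # continue current block
    if (!is.null(b) && !b$fixed_spacer) {
      cnt <- extend(b$motif)
      if (cnt > 0L) {
        emit(b$motif, cnt, block_role(b), bi)
        pos <- pos + cnt * nchar(b$motif)
        next
      }
    }
    if (!is.null(b) && b$fixed_spacer) {
      if (peek(nchar(b$motif)) == b$motif) {
        emit(b$motif, 1L, "spacer", bi)
        pos <- pos + nchar(b$motif)
        bi <- bi + 1L
        next
      }
      stop("decomposition error at ", def$name, " position ", pos,
           ": expected fixed spacer; context ", peek(10L))
    }
    # (i) next block's motif or spacer
    advanced <- FALSE
    if (bi < nb) {
      for (j in seq.int(bi + 1L, nb)) {
        bj <- blocks[[j]]
        hit <- if (bj$fixed_spacer) peek(nchar(bj$motif)) == bj$motif
               else extend(bj$motif) > 0L
        if (hit) {
          # blocks skipped over: record uncounted absences explicitly
          for (s in seq.int(bi, j - 1L)) {
            bs <- blocks[[s]]
            if (bs$fixed_spacer)
              stop("decomposition error at ", def$name, " position ", pos,
                   ": fixed spacer absent")
            if (!bs$counted && !any(vapply(units, function(u)
                  u$block == s, logical(1))))
              emit(bs$motif, 0L, "uncounted", s)
          }
          bi <- j
          advanced <- TRUE
          break
        }
      }
    }
    if (advanced) next
    # (ii) single-substitution variant unit in the local motif context
    w <- peek(period)
    if (nchar(w) == period) {
      local_motifs <- unique(c(
        if (!is.null(b) && !b$fixed_spacer) b$motif,
        if (bi > 1L && !blocks[[bi - 1L]]$fixed_spacer) blocks[[bi - 1L]]$motif,
        if (bi < nb && !blocks[[bi + 1L]]$fixed_spacer) blocks[[bi + 1L]]$motif))
      if (any(vapply(local_motifs, function(m) hamming(w, m) == 1, logical(1)))) {
        bctx <- if (!is.null(b)) bi else nb
        emit(w, 1L, "variant", bctx)
        pos <- pos + period
        next
      }
    }
    # (iii) one sub-period partial unit (internal indel -> intermediate allele)
    if (!partial_used) {
      resume_motifs <- c(
        if (!is.null(b) && !b$fixed_spacer) b$motif,
        if (bi < nb && !blocks[[bi + 1L]]$fixed_spacer) blocks[[bi + 1L]]$motif)
      found_L <- 0L
      for (L in seq.int(period - 1L, 1L)) {
        if (pos + L - 1L > n) next
        after <- pos + L
        ok <- after > n ||  # trailing partial
          any(vapply(resume_motifs, function(m)
            substring(array, after, after + nchar(m) - 1L) == m, logical(1)))
        if (ok) { found_L <- L; break }
      }
      if (found_L > 0L) {
        emit(peek(found_L), 1L, "partial", if (!is.null(b)) bi else nb)
        pos <- pos + found_L
        partial_used <- TRUE
        next
      }
    }
    stop("decomposition error at ", def$name, " position ", pos,
         ": unparseable residue; context ", peek(10L))
  }
  # trailing absent uncounted blocks are reported with count 0
  if (bi <= nb) {
    for (s in seq.int(bi, nb)) {
      bs <- blocks[[s]]
      if (bs$fixed_spacer)
        stop("decomposition error at ", def$name, ": fixed spacer absent")
      if (!bs$counted && !any(vapply(units, function(u) u$block == s,
                                     logical(1))))
        units[[length(units) + 1L]] <- list(motif = bs$motif, count = 0L,
                                            role = "uncounted",
                                            block = as.integer(s))
    }
  }
  units
}

#' Render a decomposition back to sequence
#'
#' @param d A `decomposition`.
#' @param catalog A `locus_catalog`.
#' @param with_flanks Include the reference flanks with the decomposition's
#'   flanking variants applied (default `TRUE`).
#' @return A DNA string.
#' @export
render_decomposition <- function(d, catalog = default_catalog(),
                                 with_flanks = TRUE) {
  def <- catalog_locus(d$locus, catalog)
  array <- paste(vapply(d$units, function(u) strrep_motif(u$motif, u$count),
                        character(1)), collapse = "")
  if (!with_flanks) return(array)
  paste0(render_flank(def, "upstream", d$flank_variants), array,
         render_flank(def, "downstream", d$flank_variants))
}

# apply flanking variants to a reference flank; works in array-outward
# orientation (upstream flank reversed) so offsets index directly
render_flank <- function(def, side, fv) {
  ref <- if (side == "upstream") def$upstream_flank else def$downstream_flank
  rel <- fv[if (side == "upstream") fv$offset < 0 else fv$offset > 0, ,
            drop = FALSE]
  if (!nrow(rel)) return(ref)
  chars <- strsplit(ref, "")[[1]]
  if (side == "upstream") chars <- rev(chars)
  rel$k <- abs(rel$offset)
  rel <- rel[order(-rel$k), , drop = FALSE]  # apply outermost first
  for (i in seq_len(nrow(rel))) {
    v <- rel[i, ]
    alt_out <- strsplit(v$alt, "")[[1]]
    ref_out <- strsplit(v$ref, "")[[1]]
    if (side == "upstream") { alt_out <- rev(alt_out); ref_out <- rev(ref_out) }
    if (v$type == "SNP") {
      chars[v$k] <- v$alt
    } else if (v$type == "del") {
      chars <- chars[-seq.int(v$k, v$k + nchar(v$ref) - 1L)]
    } else if (v$type == "ins") {
      # insertion outward of position k (between k and k+1)
      chars <- append(chars, alt_out, after = v$k)
    }
  }
  if (side == "upstream") chars <- rev(chars)
  paste(chars, collapse = "")
}

#' Call flanking-region SNPs and indels
#'
#' Ungapped outward comparison of the observed flanks against the reference
#' flanks from each array edge; a mismatch is resolved as a single
#' substitution if the remainder realigns, otherwise as an indel by anchored
#' realignment within `max_indel` nt. Offsets follow the +/- convention
#' (+ = downstream of the array, - = upstream; `+50C>A`).
#'
#' @param sequence Full-length allele sequence.
#' @param locus A `locus_definition` or locus name.
#' @param catalog A `locus_catalog`.
#' @param span Optional precomputed [locate_array()] interval.
#' @param max_indel Indel realignment band in nt (default 15).
#' @return A data.frame of flanking variants (offset, type, ref, alt,
#'   genomic_position, id).
#' @export
call_flank_variants <- function(sequence, locus, catalog = default_catalog(),
                                span = NULL, max_indel = 15L) {
  def <- catalog_locus(locus, catalog)
  sequence <- toupper(sequence)
  if (is.null(span)) span <- locate_array(sequence, def)
  obs_up <- substring(sequence, 1L, span[1] - 1L)
  obs_down <- substring(sequence, span[2], nchar(sequence))
  ref_len <- reference_array_length(def)
  out <- rbind(
    scan_flank(obs_up, def$upstream_flank, sign = -1L, def = def,
               max_indel = max_indel),
    scan_flank(obs_down, def$downstream_flank, sign = +1L, def = def,
               max_indel = max_indel))
  if (nrow(out)) {
    out$genomic_position <- as.integer(ifelse(
      out$offset < 0, def$anchor + out$offset,
      def$anchor + ref_len + out$offset - 1L))
    out$id <- annotate_rs(out, def)
    out <- out[order(out$offset), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

reference_array_length <- function(def) {
  sum(vapply(def$blocks, function(b)
    nchar(b$motif) * (if (b$fixed_spacer) 1L else b$canonical), numeric(1)))
}

annotate_rs <- function(fv, def) {
  ids <- rep(NA_character_, nrow(fv))
  kfv <- def$known_flank_variants
  if (!is.null(kfv) && nrow(kfv)) {
    for (i in seq_len(nrow(fv))) {
      hit <- which(kfv$offset == fv$offset[i] & kfv$ref == fv$ref[i] &
                   kfv$alt == fv$alt[i])
      if (length(hit)) ids[i] <- kfv$id[hit[1]]
    }
  }
  ids
}

# outward comparison of one flank; `obs`/`ref` in genome orientation, sign -1
# for upstream (offsets negative). Returns flank-variant rows.
scan_flank <- function(obs, ref, sign, def, max_indel = 15L) {
  window <- def$flank_window
  # array-outward orientation
  o <- strsplit(obs, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  if (sign < 0) { o <- rev(o); r <- rev(r) }
  vars <- list()
  io <- 1L; ir <- 1L
  match_ahead <- function(io2, ir2, need = 10L, min_evidence = 0L) {
    k <- min(need, length(o) - io2 + 1L, length(r) - ir2 + 1L)
    if (k <= 0L) return(TRUE)
    if (k < min_evidence) return(FALSE)
    all(o[seq.int(io2, io2 + k - 1L)] == r[seq.int(ir2, ir2 + k - 1L)])
  }
  out_seq <- function(chars) {
    if (sign < 0) chars <- rev(chars)
    paste(chars, collapse = "")
  }
  while (io <= length(o) && ir <= min(length(r), window)) {
    if (o[io] == r[ir]) { io <- io + 1L; ir <- ir + 1L; next }
    if (match_ahead(io + 1L, ir + 1L)) {
      vars[[length(vars) + 1L]] <- data.frame(
        offset = sign * ir, type = "SNP", ref = r[ir], alt = o[io],
        genomic_position = NA_integer_, id = NA_character_,
        stringsAsFactors = FALSE)
      io <- io + 1L; ir <- ir + 1L; next
    }
    done <- FALSE
    take_del <- function(d) {
      vars[[length(vars) + 1L]] <<- data.frame(
        offset = sign * ir, type = "del",
        ref = out_seq(r[seq.int(ir, ir + d - 1L)]), alt = "-",
        genomic_position = NA_integer_, id = NA_character_,
        stringsAsFactors = FALSE)
      ir <<- ir + d
    }
    take_ins <- function(d) {
      vars[[length(vars) + 1L]] <<- data.frame(
        offset = sign * (ir - 1L), type = "ins", ref = "-",
        alt = out_seq(o[seq.int(io, io + d - 1L)]),
        genomic_position = NA_integer_, id = NA_character_,
        stringsAsFactors = FALSE)
      io <<- io + d
    }
    # prefer the indel size/type implied by the flank length difference
    ldiff <- (length(o) - io) - (length(r) - ir)
    if (ldiff < 0 && -ldiff <= max_indel && match_ahead(io, ir - ldiff)) {
      take_del(-ldiff); done <- TRUE
    } else if (ldiff > 0 && ldiff <= max_indel &&
               match_ahead(io + ldiff, ir)) {
      take_ins(ldiff); done <- TRUE
    }
    if (!done) for (d in seq_len(max_indel)) {
      if (match_ahead(io, ir + d, min_evidence = 4L)) {
        take_del(d); done <- TRUE; break
      }
      if (match_ahead(io + d, ir, min_evidence = 4L)) {
        take_ins(d); done <- TRUE; break
      }
    }
    if (!done)
      stop("unresolvable flank at ", def$name, ", ",
           if (sign < 0) "upstream" else "downstream", " offset ", sign * ir)
  }
  if (!length(vars)) return(empty_flank_variants())
  do.call(rbind, vars)
}

# human-readable +/- descriptors: "+50C>A", "+3AAA>-", "-48.1->CTCTTCTAACTAT"
flank_descriptors <- function(fv) {
  if (is.null(fv) || !nrow(fv)) return(character())
  fv <- fv[order(fv$offset), , drop = FALSE]
  vapply(seq_len(nrow(fv)), function(i) {
    v <- fv[i, ]
    if (v$type == "ins") sprintf("%+d.1->%s", v$offset, v$alt)
    else sprintf("%+d%s>%s", v$offset, v$ref, v$alt)
  }, character(1))
}
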