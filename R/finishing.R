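# Finishing: reference-collinear ordering of assembly products into a
# pseudomolecule (one N per gap), pipeline reiteration, gap primer design,
# gap closure with long finishing reads, and inverted-repeat reconstruction.

# ---------------------------------------------------------------------------
# Anchor machinery: maximal runs of shared k-mers unique in both sequences,
# chained collinearly by longest increasing subsequence.

# Shared k-mers unique in both sequences -> data.table(pa, pb), 1-based.
shared_unique_kmers <- function(a, b, k) {
  ka <- kmer_positions(a, k)
  ka <- ka[, if (.N == 1L) .SD, by = "kmer"]
  kb <- kmer_positions(b, k)
  kb <- kb[, if (.N == 1L) .SD, by = "kmer"]
  m <- merge(ka, kb, by = "kmer", suffixes = c("_a", "_b"))
  if (!nrow(m)) {
    return(data.table::data.table(pa = integer(0), pb = integer(0)))
  }
  data.table::data.table(pa = m$pos_a, pb = m$pos_b)[order(pa)]
}

# Merge shared k-mer matches lying on the same diagonal into maximal blocks.
merge_diagonal_runs <- function(pa, pb, k) {
  if (!length(pa)) {
    return(data.frame(astart = integer(0), aend = integer(0),
                      bstart = integer(0), bend = integer(0),
                      len = integer(0)))
  }
  ord <- order(pb - pa, pa)
  pa <- pa[ord]; pb <- pb[ord]
  diag <- pb - pa
  newrun <- c(TRUE, diff(pa) != 1L | diff(diag) != 0L)
  run <- cumsum(newrun)
  astart <- tapply(pa, run, min)
  aend <- tapply(pa, run, max) + k - 1L
  bstart <- tapply(pb, run, min)
  bend <- tapply(pb, run, max) + k - 1L
  out <- data.frame(astart = as.integer(astart), aend = as.integer(aend),
                    bstart = as.integer(bstart), bend = as.integer(bend))
  out$len <- out$aend - out$astart + 1L
  out[order(out$astart), , drop = FALSE]
}

# Chain blocks collinearly: sort by astart, take the longest increasing
# subsequence on bstart, then trim residual overlaps between neighbours
# (blocks are exact diagonal matches, so trimming shifts both coordinates).
chain_blocks <- function(blocks) {
  if (!nrow(blocks)) return(blocks)
  blocks <- blocks[order(blocks$astart, blocks$bstart), , drop = FALSE]
  keep <- lis_indices(blocks$bstart)
  as_ <- blocks$astart[keep]; ae <- blocks$aend[keep]
  bs <- blocks$bstart[keep]; be <- blocks$bend[keep]
  n <- length(as_)
  ok <- logical(n)
  prev_a <- 0L; prev_b <- 0L
  for (i in seq_len(n)) {
    shift <- max(prev_a + 1L - as_[i], prev_b + 1L - bs[i], 0L)
    as_[i] <- as_[i] + shift
    bs[i] <- bs[i] + shift
    if (as_[i] > ae[i] || bs[i] > be[i]) next
    ok[i] <- TRUE
    prev_a <- ae[i]; prev_b <- be[i]
  }
  data.frame(astart = as_[ok], aend = ae[ok], bstart = bs[ok],
             bend = be[ok], len = ae[ok] - as_[ok] + 1L)
}

# Anchor a query against a reference on both strands. Returns the chained
# blocks of the better strand with query coordinates on the forward query,
# plus strand, total anchored length and the reference midpoint.
anchor_query <- function(query, reference, k = 31) {
  qlen <- nchar(query)
  res <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    sh <- shared_unique_kmers(q, reference, k)
    bl <- chain_blocks(merge_diagonal_runs(sh$pa, sh$pb, k))
    res[[strand]] <- list(blocks = bl, anchored = sum(bl$len))
  }
  strand <- if (res[["+"]]$anchored >= res[["-"]]$anchored) "+" else "-"
  bl <- res[[strand]]$blocks
  if (!nrow(bl)) {
    return(list(strand = strand, blocks = bl, anchored = 0L,
                ref_mid = NA_real_))
  }
  list(strand = strand, blocks = bl, anchored = sum(bl$len),
       ref_mid = stats::weighted.mean((bl$bstart + bl$bend) / 2, bl$len),
       other_anchored = res[[setdiff(c("+", "-"), strand)]]$anchored)
}

# ---------------------------------------------------------------------------
# Pseudomolecule

new_pseudomolecule <- function(sequence, provenance, unplaced = character(0)) {
  gaps <- which(strsplit(sequence, "", fixed = TRUE)[[1]] == "N")
  structure(list(sequence = sequence, provenance = provenance,
                 gaps = gaps, unplaced = unplaced),
            class = "Pseudomolecule")
}

#' @export
print.Pseudomolecule <- function(x, ...) {
  cat(sprintf("Pseudomolecule: %d nt, %d gap(s), %d placed contig(s), %d unplaced\n",
              nchar(x$sequence), length(x$gaps), nrow(x$provenance),
              length(x$unplaced)))
  invisible(x)
}

#' Order assembly products into a reference-collinear pseudomolecule
#'
#' Anchors every contig to the reference by maximal unique k-mer matches
#' (default 31-mers) chained collinearly. Scaffolds whose consecutive
#' contigs are not collinear with the reference (strand flip or a reference
#' jump above `max_jump`) are split at the gap between the offending
#' contigs; all resulting pieces, plus anchored singleton contigs, are
#' ordered and oriented by their reference midpoints and concatenated with
#' exactly one N between neighbours. Contigs without a reliable anchor
#' (fewer than `min_anchor` anchored bases) stay inside their scaffold
#' piece when they have one, and are otherwise reported as unplaced rather
#' than guessed.
#'
#' @param scaffolds a `ScaffoldSet` from [scaffold_contigs()].
#' @param contigs the contig table the scaffolds refer to.
#' @param reference reference sequence to order against (e.g. the
#'   single-copy core LSC+IRa+SSC of a related plastome).
#' @param anchor_k anchor k-mer length (default 31).
#' @param min_anchor minimum anchored bases for a confident placement.
#' @param max_jump reference jump (nt) between neighbouring contigs above
#'   which a scaffold is considered chimeric and split at the gap.
#' @return a `Pseudomolecule`: sequence with one N per remaining gap,
#'   provenance table (contig, orientation, start, end), gap positions and
#'   unplaced contig ids.
#' @export
order_against_reference <- function(scaffolds, contigs, reference,
                                    anchor_k = 31, min_anchor = 62,
                                    max_jump = 5000) {
  stopifnot(nrow(contigs) > 0)
  anch <- lapply(contigs$seq, anchor_query, reference = reference,
                 k = anchor_k)
  names(anch) <- contigs$id
  placed_ok <- vapply(anch, function(a) a$anchored >= min_anchor, TRUE)
  if (!any(placed_ok)) {
    stop("no contig anchors to the reference: wrong or missing reference?")
  }

  # split chimeric scaffolds at gaps between non-collinear contigs
  pieces <- list()
  for (sc in scaffolds) {
    ori_strand <- function(i) {
      a <- anch[[sc$contig[i]]]
      if (!placed_ok[[sc$contig[i]]]) return(NA_character_)
      # contig strand vs reference, corrected for in-scaffold orientation
      if (sc$orientation[i] == "+") a$strand else
        setdiff(c("+", "-"), a$strand)
    }
    mids <- vapply(seq_len(nrow(sc)), function(i) {
      if (placed_ok[[sc$contig[i]]]) anch[[sc$contig[i]]]$ref_mid
      else NA_real_
    }, 0)
    strands <- vapply(seq_len(nrow(sc)), function(i) ori_strand(i), "")
    cut_after <- rep(FALSE, nrow(sc))
    last_known <- NA_integer_
    for (i in seq_len(nrow(sc))) {
      if (is.na(mids[i])) next
      if (!is.na(last_known)) {
        jump <- abs(mids[i] - mids[last_known])
        flip <- !is.na(strands[i]) && !is.na(strands[last_known]) &&
          strands[i] != strands[last_known]
        if (jump > max_jump || flip) cut_after[last_known] <- TRUE
      }
      last_known <- i
    }
    piece_id <- cumsum(c(1L, utils::head(cut_after, -1L)))
    for (p in unique(piece_id)) {
      pieces[[length(pieces) + 1L]] <- sc[piece_id == p, , drop = FALSE]
    }
  }

  # place each piece by the anchored midpoint of its contigs
  place <- lapply(pieces, function(pc) {
    mids <- c(); strands <- c(); w <- c()
    for (i in seq_len(nrow(pc))) {
      cid <- pc$contig[i]
      if (!placed_ok[[cid]]) next
      a <- anch[[cid]]
      s <- if (pc$orientation[i] == "+") a$strand else
        setdiff(c("+", "-"), a$strand)
      mids <- c(mids, a$ref_mid); strands <- c(strands, s)
      w <- c(w, a$anchored)
    }
    if (!length(mids)) return(NULL)
    strand <- if (sum(w[strands == "+"]) >= sum(w[strands == "-"])) "+"
              else "-"
    list(piece = pc, mid = stats::weighted.mean(mids, w), strand = strand)
  })
  unplaced <- unlist(lapply(pieces[vapply(place, is.null, TRUE)],
                            function(pc) pc$contig))
  place <- place[!vapply(place, is.null, TRUE)]
  if (!length(place)) {
    stop("no contig anchors to the reference: wrong or missing reference?")
  }
  place <- place[order(vapply(place, `[[`, 0, "mid"))]

  seq_of <- stats::setNames(contigs$seq, contigs$id)
  parts <- character(0)
  prov <- list()
  at <- 0L
  for (j in seq_along(place)) {
    pc <- place[[j]]$piece
    if (place[[j]]$strand == "-") {
      pc <- pc[rev(seq_len(nrow(pc))), , drop = FALSE]
      pc$orientation <- ifelse(pc$orientation == "+", "-", "+")
    }
    if (j > 1L) { parts <- c(parts, "N"); at <- at + 1L }
    for (i in seq_len(nrow(pc))) {
      s <- seq_of[[pc$contig[i]]]
      if (pc$orientation[i] == "-") s <- revcomp(s)
      if (i > 1L) { parts <- c(parts, "N"); at <- at + 1L }
      prov[[length(prov) + 1L]] <- data.frame(
        contig = pc$contig[i], orientation = pc$orientation[i],
        start = at + 1L, end = at + nchar(s), stringsAsFactors = FALSE
      )
      parts <- c(parts, s)
      at <- at + nchar(s)
    }
  }
  new_pseudomolecule(paste(parts, collapse = ""), do.call(rbind, prov),
                     unplaced = unique(unplaced))
}

#' Reiterate selection, assembly and ordering against a pseudomolecule
#'
#' Uses the first-pass pseudomolecule as the new bait reference so that
#' reads diverging from the original reference are recaptured, reassembles
#' the selected reads and reorders the products against the ordering
#' reference.
#'
#' @param library the full quality-filtered `MatePairLibrary`.
#' @param pseudomolecule first-pass `Pseudomolecule`.
#' @param reference ordering reference (as in [order_against_reference()]).
#' @param params an `AssemblyParams`.
#' @param mapper a `MapperParams`.
#' @return list with `library` (reselected pairs), `report`, `contigs`,
#'   `scaffolds` and `pseudomolecule` (the new one).
#' @export
reiterate <- function(library, pseudomolecule, reference,
                      params = assembly_params(), mapper = mapper_params()) {
  stopifnot(inherits(pseudomolecule, "Pseudomolecule"))
  sel <- select_anchored_pairs(library, pseudomolecule$sequence, mapper)
  contigs <- build_contigs(c(sel$library$tagF, sel$library$tagR), params)
  scaffolds <- scaffold_contigs(contigs, sel$library, params, mapper)
  pm <- order_against_reference(scaffolds, contigs, reference)
  list(library = sel$library, report = sel$report, contigs = contigs,
       scaffolds = scaffolds, pseudomolecule = pm)
}

# ---------------------------------------------------------------------------
# Primer design

#' Melting temperature by the Wallace rule
#'
#' Tm = 2(A+T) + 4(G+C), the classic approximation for short
#' oligonucleotides.
#'
#' @param seq primer sequence(s).
#' @return numeric Tm in degrees Celsius.
#' @export
wallace_tm <- function(seq) {
  at <- nchar(gsub("[^AT]", "", seq))
  gc <- nchar(gsub("[^GC]", "", seq))
  2 * at + 4 * gc
}

has_long_run <- function(seq, max_run = 4L) {
  grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", max_run + 1L, max_run + 1L,
                max_run + 1L, max_run + 1L), seq)
}

# Scan one flank for an acceptable primer window. `near` is the flank end
# adjacent to the gap ("right" for the left/forward flank).
scan_primer <- function(flank, len_bounds, tm_bounds, near = c("right", "left")) {
  near <- match.arg(near)
  fl <- nchar(flank)
  for (delta in 0:(fl - len_bounds[1])) {
    for (plen in len_bounds[1]:len_bounds[2]) {
      if (plen + delta > fl) next
      win <- if (near == "right") {
        substr(flank, fl - delta - plen + 1L, fl - delta)
      } else {
        substr(flank, delta + 1L, delta + plen)
      }
      if (grepl("[^ACGT]", win)) next
      if (has_long_run(win)) next
      tm <- wallace_tm(win)
      if (tm >= tm_bounds[1] && tm <= tm_bounds[2]) {
        off <- if (near == "right") fl - delta - plen + 1L else delta + 1L
        return(list(seq = win, offset = off))
      }
    }
  }
  NULL
}

#' Design PCR primer pairs flanking pseudomolecule gaps
#'
#' For every gap (single N) the flanks are scanned for primer windows
#' satisfying length and melting-temperature bounds (Wallace rule
#' 2(A+T)+4(G+C)) without mononucleotide runs of five or more. The forward
#' primer sits on the left flank; the reverse primer is the reverse
#' complement of a right-flank window, so the pair faces each other across
#' the gap. Gaps too close to a molecule end, or with no acceptable window,
#' are flagged undesignable.
#'
#' @param pseudomolecule a `Pseudomolecule` (or plain sequence with N gaps).
#' @param flank_len flank length scanned on each side (nt).
#' @param primer_len integer bounds c(min, max) on primer length.
#' @param tm_bounds numeric bounds c(min, max) on Tm (degrees C).
#' @return data.frame: gap_pos, status, fwd, rev, fwd_start, rev_end,
#'   tm_fwd, tm_rev, product_span.
#' @export
design_gap_primers <- function(pseudomolecule, flank_len = 500,
                               primer_len = c(18L, 24L),
                               tm_bounds = c(52, 60)) {
  seq <- if (inherits(pseudomolecule, "Pseudomolecule"))
    pseudomolecule$sequence else pseudomolecule
  gaps <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "N")
  rows <- lapply(gaps, function(g) {
    base <- data.frame(gap_pos = g, status = "undesignable",
                       fwd = NA_character_, rev = NA_character_,
                       fwd_start = NA_integer_, rev_end = NA_integer_,
                       tm_fwd = NA_real_, tm_rev = NA_real_,
                       product_span = NA_integer_, stringsAsFactors = FALSE)
    if (g - flank_len < 1L || g + flank_len > nchar(seq)) {
      base$status <- "too_close_to_end"
      return(base)
    }
    left <- substr(seq, g - flank_len, g - 1L)
    right <- substr(seq, g + 1L, g + flank_len)
    fw <- scan_primer(left, primer_len, tm_bounds, near = "right")
    rv <- scan_primer(right, primer_len, tm_bounds, near = "left")
    if (is.null(fw) || is.null(rv)) return(base)
    fwd_start <- g - flank_len + fw$offset - 1L
    rev_end <- g + rv$offset + nchar(rv$seq) - 1L
    data.frame(gap_pos = g, status = "designed", fwd = fw$seq,
               rev = revcomp(rv$seq), fwd_start = fwd_start,
               rev_end = rev_end, tm_fwd = wallace_tm(fw$seq),
               tm_rev = wallace_tm(rv$seq),
               product_span = rev_end - fwd_start + 1L,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(gap_pos = integer(0), status = character(0),
                      fwd = character(0), rev = character(0),
                      fwd_start = integer(0), rev_end = integer(0),
                      tm_fwd = numeric(0), tm_rev = numeric(0),
                      product_span = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Gap closure with long finishing reads

# Ungapped anchoring of a flank within a set of reads via exact k-mer seeds
# and offset voting. Returns per-read candidate offsets.
flank_read_offsets <- function(flank, read_index, k) {
  fk <- kmer_positions(flank, k)
  if (!nrow(fk)) return(NULL)
  hits <- read_index[fk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(NULL)
  hits[, offset := rpos - pos]
  hits[, list(votes = .N), by = c("read_i", "offset")]
}

#' Close pseudomolecule gaps with long finishing reads
#'
#' Each finishing read (tried in both orientations) is anchored to the two
#' flanks of a gap by exact k-mer seeds with offset voting; the anchoring is
#' ungapped and verified over the full available overlap, which must reach
#' `min_overlap` columns on each flank with a mismatch rate at most
#' `max_mismatch_rate`. The gap's single N is then replaced by the read
#' segment spanning it (possibly empty). All overlap columns between
#' accepted reads and the short-read consensus are tallied into a
#' `DiscrepancyReport`; reads containing indels relative to the consensus
#' fail the ungapped verification and are counted as excluded. Gaps no read
#' spans on both flanks stay open as single Ns.
#'
#' @param pseudomolecule a `Pseudomolecule` or plain sequence with N gaps.
#' @param finishing_reads named character vector of long reads.
#' @param min_overlap minimum verified overlap per flank (nt).
#' @param seed_k exact seed length for anchoring.
#' @param max_mismatch_rate maximum mismatch fraction in a verified overlap.
#' @return list with `sequence` (gaps replaced), `gaps` (per-gap status
#'   table) and `report` (`DiscrepancyReport`: overlap_length, mismatches,
#'   rate, excluded_reads).
#' @export
close_gaps <- function(pseudomolecule, finishing_reads, min_overlap = 100,
                       seed_k = 21, max_mismatch_rate = 0.02) {
  seq <- if (inherits(pseudomolecule, "Pseudomolecule"))
    pseudomolecule$sequence else pseudomolecule
  reads <- c(finishing_reads, revcomp(finishing_reads))
  names(reads) <- c(names(finishing_reads),
                    paste0(names(finishing_reads), "_rc"))
  idx <- data.table::rbindlist(lapply(seq_along(reads), function(i) {
    kp <- kmer_positions(reads[[i]], seed_k)
    if (!nrow(kp)) return(NULL)
    data.table::data.table(kmer = kp$kmer, read_i = i, rpos = kp$pos)
  }))
  if (nrow(idx)) data.table::setkey(idx, kmer)

  total_overlap <- 0L
  total_mismatch <- 0L
  excluded <- 0L
  gap_rows <- list()

  # verified ungapped overlap of a flank [fs, fe] (pm coords) against read i
  # at offset off (read_pos = pm_pos - fs + 1 + off within the flank window)
  verify <- function(read, flank, off) {
    fl <- nchar(flank); rl <- nchar(read)
    i1 <- max(1L, 1L - off)          # flank coords covered by the read
    i2 <- min(fl, rl - off)
    if (i2 - i1 + 1L < min_overlap) return(NULL)
    fseg <- substr(flank, i1, i2)
    rseg <- substr(read, i1 + off, i2 + off)
    mm <- hamming_mismatches(fseg, rseg)
    if (mm / nchar(fseg) > max_mismatch_rate) return(NULL)
    list(overlap = nchar(fseg), mm = mm)
  }

  gaps <- rev(which(strsplit(seq, "", fixed = TRUE)[[1]] == "N"))
  for (g in gaps) {
    # flanks bounded by molecule ends and neighbouring gaps
    left_lim <- max(c(0L, which(strsplit(substr(seq, 1, g - 1L), "",
                                         fixed = TRUE)[[1]] == "N")))
    ls <- max(left_lim + 1L, g - 1000L)
    right_chars <- strsplit(substr(seq, g + 1L, nchar(seq)), "",
                            fixed = TRUE)[[1]]
    right_lim <- which(right_chars == "N")
    re <- if (length(right_lim)) g + right_lim[1L] - 1L
          else min(nchar(seq), g + 1000L)
    left <- substr(seq, ls, g - 1L)
    right <- substr(seq, g + 1L, re)
    status <- "open"
    if (nchar(left) >= min_overlap && nchar(right) >= min_overlap &&
        nrow(idx)) {
      offL <- flank_read_offsets(left, idx, seed_k)
      offR <- flank_read_offsets(right, idx, seed_k)
      best <- NULL
      if (!is.null(offL) && !is.null(offR)) {
        cand <- merge(offL, offR, by = "read_i", suffixes = c("L", "R"),
                      allow.cartesian = TRUE)
        if (nrow(cand)) {
          data.table::setorder(cand, -votesL, -votesR)
          cand <- utils::head(cand, 50L)
          for (ci in seq_len(nrow(cand))) {
            ri <- cand$read_i[ci]
            vL <- verify(reads[[ri]], left, cand$offsetL[ci])
            if (is.null(vL)) { excluded <- excluded + 1L; next }
            vR <- verify(reads[[ri]], right, cand$offsetR[ci])
            if (is.null(vR)) { excluded <- excluded + 1L; next }
            # read coords of the bases flanking the gap
            rl_end <- (g - 1L) - ls + 1L + cand$offsetL[ci]
            rr_start <- 1L + cand$offsetR[ci]
            # rr_start <= rl_end means the two flanks overlap in the read
            # (neighbouring contigs sharing junction sequence); the overlap
            # is trimmed from the right flank on closure
            if (rl_end + 1L - rr_start > nchar(right)) next
            score <- vL$overlap + vR$overlap
            if (is.null(best) || score > best$score) {
              best <- list(ri = ri, rl_end = rl_end, rr_start = rr_start,
                           vL = vL, vR = vR, score = score)
            }
          }
        }
      }
      if (!is.null(best)) {
        if (best$rr_start > best$rl_end) {
          insert <- substr(reads[[best$ri]], best$rl_end + 1L,
                           best$rr_start - 1L)
          trim <- 0L
        } else {
          insert <- ""
          trim <- best$rl_end + 1L - best$rr_start
        }
        seq <- paste0(substr(seq, 1L, g - 1L), insert,
                      substring(seq, g + 1L + trim))
        total_overlap <- total_overlap + best$vL$overlap + best$vR$overlap
        total_mismatch <- total_mismatch + best$vL$mm + best$vR$mm
        status <- "closed"
        gap_rows[[length(gap_rows) + 1L]] <- data.frame(
          gap_pos = g, status = status, read = names(reads)[best$ri],
          inserted_length = nchar(insert), stringsAsFactors = FALSE
        )
        next
      }
    }
    gap_rows[[length(gap_rows) + 1L]] <- data.frame(
      gap_pos = g, status = status, read = NA_character_,
      inserted_length = NA_integer_, stringsAsFactors = FALSE
    )
  }
  gap_tab <- if (length(gap_rows)) do.call(rbind, rev(gap_rows)) else
    data.frame(gap_pos = integer(0), status = character(0),
               read = character(0), inserted_length = integer(0),
               stringsAsFactors = FALSE)
  report <- structure(list(
    overlap_length = total_overlap,
    mismatches = total_mismatch,
    rate = if (total_overlap > 0L) total_mismatch / total_overlap else 0,
    excluded_reads = excluded
  ), class = "DiscrepancyReport")
  list(sequence = seq, gaps = gap_tab, report = report)
}

#' @export
print.DiscrepancyReport <- function(x, ...) {
  cat(sprintf("DiscrepancyReport: %d overlap columns, %d mismatches (%.4f%%), %d read overlaps excluded\n",
              x$overlap_length, x$mismatches, 100 * x$rate,
              x$excluded_reads))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Inverted repeat reconstruction and detection

# Project reference positions onto an assembled sequence: coarse placement
# by collinearity anchor blocks, refined by a windowed global alignment
# around the coarse estimate so the projection is exact up to local
# alignment ambiguity.
project_ref_positions <- function(sequence, ref_core, rpos, anchor_k = 31,
                                  window = 300) {
  sh <- shared_unique_kmers(sequence, ref_core, anchor_k)
  bl <- chain_blocks(merge_diagonal_runs(sh$pa, sh$pb, anchor_k))
  if (!nrow(bl)) {
    stop("no collinearity anchors between assembly and reference")
  }
  coarse <- vapply(rpos, function(r) {
    covering <- which(bl$bstart <= r & bl$bend >= r)
    if (length(covering)) {
      b <- covering[1L]
      return(bl$astart[b] + (r - bl$bstart[b]))
    }
    nearest <- which.min(pmin(abs(bl$bstart - r), abs(bl$bend - r)))
    bl$astart[nearest] + (r - bl$bstart[nearest])
  }, 0)
  mat <- nucleotide_matrix(1, -1)
  vapply(seq_along(rpos), function(i) {
    r <- rpos[i]
    q <- coarse[i]
    rw <- c(max(1L, r - window), min(nchar(ref_core), r + window))
    qw <- c(max(1L, round(q) - window - 50L),
            min(nchar(sequence), round(q) + window + 50L))
    rseg <- substr(ref_core, rw[1], rw[2])
    qseg <- substr(sequence, qw[1], qw[2])
    if (!nchar(rseg) || !nchar(qseg)) return(max(1, min(nchar(sequence), q)))
    aln <- Biostrings::pairwiseAlignment(
      qseg, rseg, type = "global", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 0.25
    )
    qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "",
                   fixed = TRUE)[[1]]
    ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "",
                   fixed = TRUE)[[1]]
    rcount <- cumsum(ra != "-")
    qcount <- cumsum(qa != "-")
    # a terminal base can pair with a chance-matching stray column, so the
    # boundary is read off the nearest solid run of aligned columns and
    # extrapolated collinearly from there
    aligned <- which(qa != "-" & ra != "-")
    if (!length(aligned)) return(max(1, min(nchar(sequence), q)))
    grp <- cumsum(c(1L, diff(aligned) != 1L))
    runlen <- ave(aligned, grp, FUN = length)
    t_ref <- r - rw[1] + 1L
    exact <- aligned[rcount[aligned] == t_ref]
    qproj <- if (length(exact) && runlen[match(exact[1L], aligned)] >= 5L) {
      # the target column itself lies in a solid aligned run: trust it
      qw[1] + qcount[exact[1L]] - 1L
    } else {
      # isolated (chance) terminal pairing or unaligned boundary: read the
      # mapping off the nearest solid run and extrapolate collinearly
      solid <- aligned[runlen >= 10L]
      if (!length(solid)) solid <- aligned[runlen == max(runlen)]
      cstar <- solid[which.min(abs(rcount[solid] - t_ref))]
      qw[1] + (qcount[cstar] - 1L) + (t_ref - rcount[cstar])
    }
    max(1, min(nchar(sequence), qproj))
  }, 0)
}

#' Append the second inverted-repeat copy to a single-copy assembly
#'
#' Takes a finished LSC+IRa+SSC sequence and appends IRb as the reverse
#' complement of IRa, yielding the full circular quadripartite genome. IRa
#' boundaries are taken from `ir_range` when known, or projected from an
#' annotated reference via collinearity anchors refined by windowed
#' alignment. With a reference, the assembly is also trimmed to the
#' projected core boundaries first: contigs assembled from a circular
#' molecule legitimately run past the canonical core ends into IRb, and
#' that overhang would otherwise be duplicated when IRb is appended.
#'
#' @param sequence finished single-copy sequence (LSC+IRa+SSC).
#' @param ir_range integer c(start, end) of IRa on `sequence`, if known.
#' @param reference a `PlastomeModel` (or list with `core` sequence and
#'   `ira` range) used to project the core and IRa boundaries when
#'   `ir_range` is missing.
#' @param anchor_k anchor k-mer length for boundary projection.
#' @return list with `sequence` (full circular genome), `ira` and `irb`
#'   ranges on it, junction coordinates, the trim applied to each end of
#'   the input, and `circular = TRUE`.
#' @export
add_inverted_repeat <- function(sequence, ir_range = NULL, reference = NULL,
                                anchor_k = 31) {
  trim <- c(start = 0L, end = 0L)
  if (is.null(ir_range)) {
    if (is.null(reference)) {
      stop("IRa not detectable: supply ir_range or an annotated reference")
    }
    if (inherits(reference, "PlastomeModel")) {
      ref_core <- plastome_core(reference)
      reg <- plastome_regions(reference)
      ref_ira <- c(reg$start[reg$region == "IRa"],
                   reg$end[reg$region == "IRa"])
    } else {
      ref_core <- reference$core
      ref_ira <- reference$ira
    }
    qpos <- project_ref_positions(sequence, ref_core,
                                  c(1L, ref_ira[1], ref_ira[2],
                                    nchar(ref_core)), anchor_k)
    n <- nchar(sequence)
    q1 <- max(1L, round(qpos[2]))
    q2 <- min(n, round(qpos[3]))
    ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    # terminal overhangs: contigs from a circular molecule run past the
    # canonical core ends into IRb, so a start overhang of length t must
    # equal revcomp(IRa[1..t]) and an end overhang revcomp of the IRa
    # tail. The reference projection centres the search; the junction
    # identity itself fixes the exact cut.
    find_overhang <- function(center, bound, check) {
      lo <- max(4L, center - 25L)
      hi <- min(center + 25L, bound, 400L)
      if (hi >= lo) {
        for (t in seq(hi, lo)) {
          mm <- check(t)
          if (mm <= (if (t >= 8L) 1L else 0L)) return(t)
        }
      }
      max(min(center, 3L), 0L)
    }
    t0_center <- max(round(qpos[1]) - 1L, 0L)
    t0 <- find_overhang(t0_center, q1 - 1L, function(t) {
      sum(ch[seq_len(t)] != comp[ch[q1 + t - seq_len(t)]])
    })
    t1_center <- max(n - round(qpos[4]), 0L)
    t1 <- find_overhang(t1_center, n - q2, function(t) {
      j <- seq_len(t)
      sum(ch[n - t + j] != comp[ch[q2 - j + 1L]])
    })
    trim <- c(start = t0, end = t1)
    sequence <- substr(sequence, t0 + 1L, n - t1)
    ir_range <- c(q1 - t0, q2 - t0)
    ir_range[1] <- max(1L, ir_range[1])
    ir_range[2] <- min(nchar(sequence), ir_range[2])
  }
  stopifnot(length(ir_range) == 2L, ir_range[1] >= 1,
            ir_range[2] <= nchar(sequence), ir_range[1] < ir_range[2])
  ira <- substr(sequence, ir_range[1], ir_range[2])
  full <- paste0(sequence, revcomp(ira))
  list(sequence = full,
       ira = as.integer(ir_range),
       irb = c(nchar(sequence) + 1L, nchar(full)),
       junctions = c(LSC_IRa = ir_range[1] - 1L,
                     IRa_SSC = ir_range[2],
                     SSC_IRb = nchar(sequence)),
       trim = trim,
       circular = TRUE)
}

#' Detect the inverted repeat pair in a complete plastome
#'
#' Finds the longest reverse-complement repeat by matching k-mers between
#' the genome and its reverse complement and merging antidiagonal runs. The
#' earlier copy is reported as IRa, the later as IRb.
#'
#' @param sequence complete genome sequence.
#' @param k match k-mer length.
#' @param min_ir_len minimum repeat length to accept (nt).
#' @return list with integer ranges `ira` and `irb`.
#' @export
detect_inverted_repeat <- function(sequence, k = 31, min_ir_len = 1000) {
  n <- nchar(sequence)
  rc <- revcomp(sequence)
  sh <- shared_unique_kmers(sequence, rc, k)
  bl <- merge_diagonal_runs(sh$pa, sh$pb, k)
  if (nrow(bl)) {
    # convert the rc-coordinate side to forward coordinates of the partner
    bl$pstart <- n - bl$bend + 1L
    bl$pend <- n - bl$bstart + 1L
    # drop self-overlapping (palindromic) matches and keep ordered pairs
    bl <- bl[bl$pstart > bl$aend, , drop = FALSE]
  }
  if (!nrow(bl) || max(bl$len) < min_ir_len) {
    stop("no inverted repeat of at least ", min_ir_len, " nt found")
  }
  best <- bl[which.max(bl$len), ]
  list(ira = c(best$astart, best$aend), irb = c(best$pstart, best$pend))
}
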