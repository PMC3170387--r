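# Comparative analysis: anchored global pairwise genome alignment,
# substitution classification (transitions si = A<->G plus C<->T,
# transversions sv = the four purine/pyrimidine exchanges), substitution
# rate, R = si/sv, and INDEL statistics, with the second inverted-repeat
# copy excluded upstream.

# Scoring matrix over A/C/G/T/N: match/mismatch on bases, 0 against N so
# ambiguous positions neither reward nor penalise.
nucleotide_matrix <- function(match = 1, mismatch = -1) {
  letters <- c(DNA_BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

# Align a batch of inter-anchor segment pairs. Segments that are empty on
# one side become pure gap runs; equal-length pairs whose direct stacking
# has at most floor(gap_open + gap_ext) mismatches are stacked as-is (any
# gapped alternative pays two gap runs, at least 2*(gap_open + gap_ext), so
# stacking is provably optimal there); the rest go through one batched
# affine-gap global DP call.
align_segments <- function(segA, segB, mat, gap_open, gap_ext, max_dp) {
  n <- length(segA)
  outA <- character(n)
  outB <- character(n)
  la <- nchar(segA)
  lb <- nchar(segB)
  if (any(la > max_dp | lb > max_dp)) {
    stop("inter-anchor segment of ", max(c(la, lb)),
         " nt exceeds the quadratic-DP bound (", max_dp,
         "); use smaller inputs or looser anchors")
  }
  outA[la == 0L] <- strrep("-", lb[la == 0L])
  outB[la == 0L] <- segB[la == 0L]
  outA[lb == 0L] <- segA[lb == 0L]
  outB[lb == 0L] <- strrep("-", la[lb == 0L])
  todo <- which(la > 0L & lb > 0L)
  if (length(todo)) {
    eqlen <- todo[la[todo] == lb[todo]]
    if (length(eqlen)) {
      mm <- hamming_mismatches(segA[eqlen], segB[eqlen])
      direct <- eqlen[mm <= floor(gap_open + gap_ext)]
      outA[direct] <- segA[direct]
      outB[direct] <- segB[direct]
      todo <- setdiff(todo, direct)
    }
    if (length(todo)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(segA[todo]),
        Biostrings::DNAStringSet(segB[todo]),
        type = "global", substitutionMatrix = mat,
        gapOpening = gap_open, gapExtension = gap_ext
      )
      outA[todo] <- as.character(Biostrings::alignedPattern(aln))
      outB[todo] <- as.character(Biostrings::alignedSubject(aln))
    }
  }
  list(A = outA, B = outB)
}

#' Anchored global pairwise genome alignment
#'
#' Aligns two collinear genome sequences by finding k-mers unique in both
#' (default 15-mers), merging them into maximal exact blocks, chaining the
#' blocks collinearly (longest increasing subsequence on the second
#' genome's coordinates), and closing the inter-anchor segments with
#' affine-gap global dynamic programming (match +1, mismatch -1, gap open
#' -2, gap extend -0.25). The mild gap penalties keep nearby
#' insertion/deletion events from being absorbed into mismatch runs, which
#' would otherwise bias divergence statistics at plastome-level divergence.
#' Chained blocks are shrunk by a small margin so block boundaries are
#' re-optimised by the DP. The concatenation of anchor
#' blocks and aligned segments is a full-length global alignment.
#'
#' @param a,b sequences to align (character strings, same strand).
#' @param anchor_k anchor k-mer length.
#' @param max_dp maximum inter-anchor segment length submitted to the
#'   quadratic DP; longer unanchored stretches raise an error.
#' @param match,mismatch,gap_open,gap_ext scoring scheme (costs positive
#'   for gaps).
#' @param block_margin bases trimmed from each end of every chained block.
#' @return a `pw_alignment`: list with `a_aligned`, `b_aligned` (equal
#'   length gapped strings) and `score`.
#' @export
pairwise_genome_align <- function(a, b, anchor_k = 15, max_dp = 20000,
                                  match = 1, mismatch = -1, gap_open = 2,
                                  gap_ext = 0.25, block_margin = 5) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  mat <- nucleotide_matrix(match, mismatch)
  sh <- shared_unique_kmers(a, b, anchor_k)
  bl <- chain_blocks(merge_diagonal_runs(sh$pa, sh$pb, anchor_k))
  if (nrow(bl) && block_margin > 0) {
    bl$astart <- bl$astart + block_margin
    bl$bstart <- bl$bstart + block_margin
    bl$aend <- bl$aend - block_margin
    bl$bend <- bl$bend - block_margin
    bl <- bl[bl$astart <= bl$aend, , drop = FALSE]
  }
  # segment boundaries between (and around) the chained anchor blocks
  segA_start <- c(1L, bl$aend + 1L)
  segA_end <- c(bl$astart - 1L, nchar(a))
  segB_start <- c(1L, bl$bend + 1L)
  segB_end <- c(bl$bstart - 1L, nchar(b))
  segA <- substring(a, segA_start, segA_end)
  segB <- substring(b, segB_start, segB_end)
  seg <- align_segments(segA, segB, mat, gap_open, gap_ext, max_dp)
  blocks <- substring(a, bl$astart, bl$aend)
  nseg <- length(segA)
  partsA <- character(2L * nseg - 1L)
  partsB <- character(2L * nseg - 1L)
  partsA[seq(1L, 2L * nseg - 1L, by = 2L)] <- seg$A
  partsB[seq(1L, 2L * nseg - 1L, by = 2L)] <- seg$B
  if (nseg > 1L) {
    partsA[seq(2L, 2L * nseg - 2L, by = 2L)] <- blocks
    partsB[seq(2L, 2L * nseg - 2L, by = 2L)] <- blocks
  }
  A <- paste(partsA, collapse = "")
  B <- paste(partsB, collapse = "")
  structure(list(a_aligned = A, b_aligned = B,
                 score = alignment_score(A, B, match, mismatch, gap_open,
                                         gap_ext)),
            class = "pw_alignment")
}

#' Score of a gapped pairwise alignment
#'
#' Recomputes the affine-gap score of an existing alignment: matches and
#' mismatches per column plus `gap_open + gap_ext * length` per gap run.
#'
#' @param A,B equal-length gapped strings.
#' @param match,mismatch,gap_open,gap_ext scoring scheme.
#' @return numeric score.
#' @export
alignment_score <- function(A, B, match = 1, mismatch = -1, gap_open = 2,
                            gap_ext = 0.25) {
  ca <- strsplit(A, "", fixed = TRUE)[[1]]
  cb <- strsplit(B, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  gapA <- ca == "-"
  gapB <- cb == "-"
  aligned <- !gapA & !gapB
  n_match <- sum(aligned & ca == cb)
  n_mis <- sum(aligned & ca != cb)
  gap_cost <- function(g) {
    r <- rle(g)
    runs <- sum(r$values)
    runlen <- sum(r$lengths[r$values])
    gap_open * runs + gap_ext * runlen
  }
  match * n_match + mismatch * n_mis - gap_cost(gapA) - gap_cost(gapB)
}

#' @export
print.pw_alignment <- function(x, ...) {
  cat(sprintf("pw_alignment: %d columns, score %g\n",
              nchar(x$a_aligned), x$score))
  invisible(x)
}

#' Pairwise divergence summary from component counts
#'
#' Builds the divergence summary of a pairwise alignment from its component
#' counts, computing the derived quantities: substitution rate =
#' substitutions / alignment length; R = si/sv (transitions over
#' transversions); INDEL ratio = total gap characters / alignment length.
#' Unrounded values are retained; the `report` element carries values
#' rounded to the conventional reporting precision (rate 2 decimals, R 1,
#' ratio 3).
#'
#' @param alignment_length total alignment columns (gaps included).
#' @param si,sv transition and transversion counts (may be NA when only
#'   INDEL statistics are of interest).
#' @param substitutions total substitutions; defaults to `si + sv`.
#' @param indels_length total gap characters summed over both rows.
#' @param rounding named vector with decimals for `rate`, `R`, `ratio`.
#' @return a `PairwiseDivergence` list.
#' @export
pairwise_divergence <- function(alignment_length, si = NA_integer_,
                                sv = NA_integer_, substitutions = NULL,
                                indels_length = 0L,
                                rounding = c(rate = 2, R = 1, ratio = 3)) {
  stopifnot(alignment_length > 0)
  if (is.null(substitutions)) {
    substitutions <- if (is.na(si) || is.na(sv)) NA_integer_ else si + sv
  }
  R <- if (is.na(si) || is.na(sv)) NA_real_
       else if (sv > 0L) si / sv
       else if (si > 0L) Inf
       else NA_real_
  rate <- substitutions / alignment_length
  ratio <- indels_length / alignment_length
  structure(list(
    alignment_length = alignment_length,
    substitutions = substitutions,
    si = si, sv = sv, R = R,
    substitution_rate = rate,
    indels_length = indels_length,
    indel_ratio = ratio,
    report = list(
      substitution_rate = round(rate, rounding[["rate"]]),
      R = round(R, rounding[["R"]]),
      indel_ratio = round(ratio, rounding[["ratio"]])
    )
  ), class = "PairwiseDivergence")
}

#' Divergence statistics of a pairwise alignment
#'
#' Classifies every alignment column: gap columns count toward the INDEL
#' length; columns where either base is N (or any non-ACGT code, treated as
#' N) are excluded from substitution counts but included in the alignment
#' length; substitutions are counted as unordered base pairs — A:G and C:T
#' are transitions (si), the four others transversions (sv).
#'
#' @param alignment a `pw_alignment`, or any list with gapped strings `A`
#'   and `B` (or `a_aligned`/`b_aligned`).
#' @param rounding report rounding, see [pairwise_divergence()].
#' @return a `PairwiseDivergence`.
#' @export
divergence_stats <- function(alignment,
                             rounding = c(rate = 2, R = 1, ratio = 3)) {
  A <- alignment$a_aligned %||% alignment$A
  B <- alignment$b_aligned %||% alignment$B
  ca <- strsplit(A, "", fixed = TRUE)[[1]]
  cb <- strsplit(B, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("aligned rows differ in length")
  gapA <- ca == "-"
  gapB <- cb == "-"
  valid <- !gapA & !gapB & ca %in% DNA_BASES & cb %in% DNA_BASES
  sub <- valid & ca != cb
  pair <- paste0(pmin(ca[sub], cb[sub]), pmax(ca[sub], cb[sub]))
  si <- sum(pair %in% c("AG", "CT"))
  sv <- sum(sub) - si
  pairwise_divergence(
    alignment_length = length(ca), si = si, sv = sv,
    indels_length = sum(gapA) + sum(gapB), rounding = rounding
  )
}

#' @export
print.PairwiseDivergence <- function(x, ...) {
  cat(sprintf(
    "PairwiseDivergence: %d columns | substitutions %s (rate %s) | si %s, sv %s, R %s | INDELs %d (ratio %s)\n",
    x$alignment_length,
    format(x$substitutions), format(x$report$substitution_rate),
    format(x$si), format(x$sv), format(x$report$R),
    x$indels_length, format(x$report$indel_ratio)))
  invisible(x)
}

#' Exclude the IRb copy from a plastome sequence
#'
#' Returns the LSC+IRa+SSC portion. For a `PlastomeModel` the IRb location
#' is known from the model; for a plain sequence it is taken from an
#' annotation range or detected as the later copy of the longest
#' reverse-complement repeat.
#'
#' @param genome a `PlastomeModel` or a plain sequence.
#' @param annotation integer c(start, end) of IRb on the sequence, if known.
#' @param min_ir_len minimum repeat length for detection.
#' @return the trimmed sequence (character string).
#' @export
exclude_irb <- function(genome, annotation = NULL, min_ir_len = 1000) {
  if (inherits(genome, "PlastomeModel")) return(plastome_core(genome))
  stopifnot(is.character(genome), length(genome) == 1L)
  irb <- if (!is.null(annotation)) as.integer(annotation)
         else detect_inverted_repeat(genome, min_ir_len = min_ir_len)$irb
  paste0(substr(genome, 1L, irb[1] - 1L), substring(genome, irb[2] + 1L))
}

#' Concatenate protein-coding gene sequences
#'
#' Extracts features of kind `gene` in genome order, reverse-complements
#' minus-strand genes, and concatenates them into one molecule — the input
#' used for coding-region divergence comparisons.
#'
#' @param genome a `PlastomeModel`, or a plain sequence (then `features`
#'   must be given).
#' @param features feature data.frame (name, start, end, strand, kind);
#'   defaults to the model's features.
#' @return list with `sequence`, `n_genes` and `total_length`.
#' @export
concatenate_coding <- function(genome, features = NULL) {
  if (inherits(genome, "PlastomeModel")) {
    if (is.null(features)) features <- genome$features
    genome <- plastome_sequence(genome)
  }
  stopifnot(!is.null(features))
  genes <- features[features$kind == "gene", , drop = FALSE]
  genes <- genes[order(genes$start), , drop = FALSE]
  if (nrow(genes) > 1L &&
      any(genes$start[-1L] <= utils::head(genes$end, -1L))) {
    warning("overlapping gene features; both extracted as annotated")
  }
  segs <- substring(genome, genes$start, genes$end)
  minus <- genes$strand == "-"
  segs[minus] <- revcomp(segs[minus])
  list(sequence = paste(segs, collapse = ""), n_genes = nrow(genes),
       total_length = sum(nchar(segs)))
}

#' Per-window identity along an alignment
#'
#' Plain-text stand-in for a rendered conservation plot: fraction of
#' identical columns (gaps count as differences) per fixed-size window of
#' alignment columns.
#'
#' @param alignment a `pw_alignment` (or list with `A`/`B`).
#' @param window window size in columns.
#' @return data.frame with window_start, window_end, identity.
#' @export
identity_windows <- function(alignment, window = 1000) {
  A <- alignment$a_aligned %||% alignment$A
  B <- alignment$b_aligned %||% alignment$B
  ca <- strsplit(A, "", fixed = TRUE)[[1]]
  cb <- strsplit(B, "", fixed = TRUE)[[1]]
  n <- length(ca)
  starts <- seq(1L, n, by = window)
  ends <- pmin(starts + window - 1L, n)
  ident <- vapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    mean(ca[idx] == cb[idx] & ca[idx] != "-")
  }, 0)
  data.frame(window_start = starts, window_end = ends, identity = ident)
}

#' Write divergence summaries as a TSV table
#'
#' One row per pair with the conventional columns: pair, alignment length,
#' substitution rate, R, INDEL length, INDEL ratio (report rounding).
#'
#' @param divergences named list of `PairwiseDivergence` objects.
#' @param path output TSV.
#' @export
write_divergence_tsv <- function(divergences, path) {
  rows <- lapply(names(divergences), function(nm) {
    d <- divergences[[nm]]
    data.frame(pair = nm, alignment_length = d$alignment_length,
               substitution_rate = d$report$substitution_rate,
               R = d$report$R, indels_length = d$indels_length,
               indel_ratio = d$report$indel_ratio,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
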