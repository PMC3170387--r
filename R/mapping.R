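# Seed-and-extend short-read mapper and reference-anchored pair selection.
#
# The mapper reports every end-to-end placement of a tag (or its reverse
# complement) with at most floor(max_mismatch_frac * length) mismatches.
# Seeding partitions the tag into (max_mismatches + 1) non-overlapping exact
# seeds of length min(seed_k, floor(L / (max_mismatches + 1))); by the
# pigeonhole principle at least one seed is exact in any admissible
# placement, so with seeds of at least 8 nt the search is complete and
# agrees with a brute-force scan of every offset and strand.

#' Mapper parameters
#'
#' @param seed_k maximum exact-seed length for the k-mer index (>= 8).
#' @param max_mismatch_frac maximum mismatch fraction per end-to-end
#'   alignment (in `[0, 0.5)`).
#' @param min_anchor_len minimum alignment length; `NULL` means the full tag.
#' @return a `MapperParams` list.
#' @export
mapper_params <- function(seed_k = 13, max_mismatch_frac = 0.1,
                          min_anchor_len = NULL) {
  stopifnot(seed_k >= 8, max_mismatch_frac >= 0, max_mismatch_frac < 0.5)
  structure(list(seed_k = as.integer(seed_k),
                 max_mismatch_frac = max_mismatch_frac,
                 min_anchor_len = min_anchor_len),
            class = "MapperParams")
}

# Batch mapper over tags of arbitrary (grouped) lengths.
# Returns data.table(read, pos, strand, mismatches, length); `pos` is the
# 1-based position of the alignment start on the forward reference strand.
map_tags <- function(tags, reference, params = mapper_params(),
                     circular = FALSE) {
  reflen <- nchar(reference)
  res <- list()
  lens <- nchar(tags)
  for (L in unique(lens)) {
    idx_tags <- which(lens == L)
    if (L < params$seed_k) {
      stop("tag shorter than seed_k (", params$seed_k, "): unusable read")
    }
    max_mm <- floor(params$max_mismatch_frac * L)
    k_eff <- max(min(params$seed_k, L %/% (max_mm + 1L)), 8L)
    k_eff <- min(k_eff, L)
    n_seeds <- min(max_mm + 1L, L %/% k_eff)
    offs <- (seq_len(n_seeds) - 1L) * k_eff + 1L
    refU <- if (circular) paste0(reference, substr(reference, 1L, L - 1L))
            else reference
    index <- kmer_positions(refU, k_eff)
    if (!nrow(index)) next
    max_start <- if (circular) reflen else reflen - L + 1L
    for (strand in c("+", "-")) {
      otags <- if (strand == "+") tags[idx_tags] else revcomp(tags[idx_tags])
      cand <- list()
      for (j in seq_along(offs)) {
        o <- offs[j]
        km <- substring(otags, o, o + k_eff - 1L)
        dt <- data.table::data.table(kmer = km, ti = seq_along(otags))
        hit <- index[dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
        if (!nrow(hit)) next
        hit[, start := pos - o + 1L]
        cand[[j]] <- hit[start >= 1L & start <= max_start,
                         list(ti, start)]
      }
      if (!length(cand)) next
      cand <- unique(data.table::rbindlist(cand))
      if (!nrow(cand)) next
      refsub <- substring(refU, cand$start, cand$start + L - 1L)
      mm <- hamming_mismatches(otags[cand$ti], refsub)
      ok <- mm <= max_mm
      if (!any(ok)) next
      res[[length(res) + 1L]] <- data.table::data.table(
        read = idx_tags[cand$ti[ok]], pos = cand$start[ok], strand = strand,
        mismatches = mm[ok], length = L
      )
    }
  }
  if (!length(res)) {
    return(data.table::data.table(read = integer(0), pos = integer(0),
                                  strand = character(0),
                                  mismatches = integer(0),
                                  length = integer(0)))
  }
  out <- data.table::rbindlist(res)
  data.table::setorder(out, read, pos, strand)
  out
}

#' Map one sequencing tag against a reference
#'
#' Seed-and-extend mapping of a single tag. All end-to-end placements of the
#' tag or its reverse complement with at most
#' `floor(max_mismatch_frac * length)` mismatches are returned.
#'
#' @param tag tag sequence (character string).
#' @param reference reference sequence.
#' @param params a `MapperParams`.
#' @param circular unroll the reference so alignments may wrap its origin.
#' @return data.frame of hits: `pos` (1-based start on the forward strand),
#'   `strand` (`"+"` if the tag matches forward, `"-"` if its reverse
#'   complement does), `mismatches`, `length`. Zero rows if the tag does not
#'   map.
#' @export
map_read <- function(tag, reference, params = mapper_params(),
                     circular = FALSE) {
  if (nchar(tag) < params$seed_k) {
    stop("tag shorter than seed_k (", params$seed_k, "): unusable read")
  }
  hits <- map_tags(tag, reference, params, circular = circular)
  as.data.frame(hits[, list(pos, strand, mismatches, length)])
}

#' Select read pairs anchored to a chloroplast reference
#'
#' Maps both tags of every pair against the reference and retains a pair if
#' at least one tag maps (the one-end-anchored criterion used to bait
#' chloroplast-derived fragments out of a total-DNA library).
#'
#' @param library a quality-filtered `MatePairLibrary`.
#' @param reference reference sequence (character string), e.g. the
#'   single-copy core of a chloroplast genome.
#' @param params a `MapperParams`.
#' @param circular treat the reference as circular.
#' @return list with `library` (retained pairs), `report` (a
#'   `SelectionReport`: counts, retained fraction and, when hidden origins
#'   exist, per-compartment recall and the precision for chloroplast reads)
#'   and `hits` (list `F`/`R` of mapping tables for the *input* library).
#' @export
select_anchored_pairs <- function(library, reference,
                                  params = mapper_params(),
                                  circular = FALSE) {
  stopifnot(inherits(library, "MatePairLibrary"))
  n <- length(library)
  if (n == 0L) {
    report <- structure(list(input_pairs = 0L, retained_pairs = 0L,
                             retained_fraction = NaN),
                        class = "SelectionReport")
    return(list(library = library, report = report, hits = NULL))
  }
  hitsF <- map_tags(library$tagF, reference, params, circular = circular)
  hitsR <- map_tags(library$tagR, reference, params, circular = circular)
  anchored <- rep(FALSE, n)
  anchored[unique(hitsF$read)] <- TRUE
  anchored[unique(hitsR$read)] <- TRUE
  report <- list(input_pairs = n, retained_pairs = sum(anchored),
                 retained_fraction = mean(anchored))
  if (!is.null(library$origin)) {
    tab <- table(library$origin)
    recall <- vapply(names(tab), function(o) {
      mean(anchored[library$origin == o])
    }, 0)
    report$recall_by_origin <- recall
    report$precision_chloroplast <-
      if (any(anchored)) mean(library$origin[anchored] == "chloroplast")
      else NaN
  }
  report <- structure(report, class = "SelectionReport")
  list(library = library[anchored], report = report,
       hits = list(F = hitsF, R = hitsR))
}

#' @export
print.SelectionReport <- function(x, ...) {
  cat(sprintf("SelectionReport: %d pairs in, %d retained (%.1f%%)\n",
              x$input_pairs, x$retained_pairs, 100 * x$retained_fraction))
  if (!is.null(x$recall_by_origin)) {
    cat("  recall by origin:",
        paste(names(x$recall_by_origin),
              sprintf("%.3f", x$recall_by_origin), sep = "=",
              collapse = ", "), "\n")
    cat(sprintf("  chloroplast precision: %.3f\n", x$precision_chloroplast))
  }
  invisible(x)
}

#' Per-base coverage profile from mapping hits
#'
#' Computes depth of coverage along reference coordinates. Reads with
#' several equally valid placements (e.g. within the two inverted repeats)
#' are assigned one placement uniformly at random under the given seed, so
#' total read placements are conserved while repeat copies share the
#' coverage.
#'
#' @param hits mapping table as returned by [map_tags()]/[map_read()]
#'   (columns read, pos, length; extra columns ignored).
#' @param reference_length reference length (nt).
#' @param one_per_read resolve multi-mapping reads to a single random
#'   placement before counting.
#' @param circular alignments extending past the end wrap to the start.
#' @param seed RNG seed for the random placement choice.
#' @return list with `depth` (integer vector of length `reference_length`)
#'   and `mean_depth`.
#' @export
coverage_profile <- function(hits, reference_length, one_per_read = TRUE,
                             circular = FALSE, seed = 1) {
  hits <- data.table::as.data.table(hits)
  if (!nrow(hits)) {
    return(list(depth = integer(reference_length), mean_depth = 0))
  }
  if (one_per_read) {
    hits <- with_seed(seed, {
      hits[, .SD[sample.int(.N, 1L)], by = "read"]
    })
  }
  starts <- hits$pos
  ends <- hits$pos + hits$length - 1L
  if (circular) {
    wrap <- ends > reference_length
    if (any(wrap)) {
      starts <- c(starts, rep(1L, sum(wrap)))
      ends2 <- ends
      ends2[wrap] <- reference_length
      ends <- c(ends2, ends[wrap] - reference_length)
    }
  } else {
    ends <- pmin(ends, reference_length)
  }
  keep <- starts <= reference_length & ends >= starts
  starts <- starts[keep]; ends <- ends[keep]
  inc <- tabulate(starts, nbins = reference_length + 1L)
  dec <- tabulate(ends + 1L, nbins = reference_length + 1L)
  depth <- cumsum(inc - dec)[seq_len(reference_length)]
  list(depth = depth, mean_depth = mean(depth))
}

#' Write a per-base depth table (BED-graph style)
#' @param depth integer depth vector.
#' @param path output TSV.
#' @param seqname sequence name for the first column.
#' @export
write_depth_tsv <- function(depth, path, seqname = "genome") {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  utils::write.table(
    data.frame(seq = seqname, start = starts, end = ends, depth = r$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
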