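# Synthetic-data module: quadripartite plastome models, controlled genome
# evolution with an exact mutation event log, and total-DNA mate-pair read
# libraries emulating an unfractionated short-read run.

# Largest k-mer used anywhere in the pipeline (collinearity anchors); a
# simulated segment must be at least 4x this long to be assemblable.
MAX_KMER <- 31L

# ---------------------------------------------------------------------------
# PlastomeModel

new_plastome <- function(lsc, ira, ssc, features, circular = TRUE) {
  structure(
    list(lsc = lsc, ira = ira, ssc = ssc, features = features,
         circular = circular),
    class = "PlastomeModel"
  )
}

#' Full circular plastome sequence (LSC + IRa + SSC + IRb)
#'
#' IRb is derived as the reverse complement of IRa, so the quadripartite
#' identity holds by construction.
#'
#' @param model a `PlastomeModel`.
#' @return single character string.
#' @export
plastome_sequence <- function(model) {
  paste0(model$lsc, model$ira, model$ssc, revcomp(model$ira))
}

#' Single-copy core of a plastome (LSC + IRa + SSC, IRb excluded)
#' @param model a `PlastomeModel`.
#' @return single character string.
#' @export
plastome_core <- function(model) {
  paste0(model$lsc, model$ira, model$ssc)
}

#' Region table of a plastome model
#'
#' @param model a `PlastomeModel`.
#' @return data.frame with columns region, start, end (1-based, on the full
#'   circular sequence laid out as LSC, IRa, SSC, IRb).
#' @export
plastome_regions <- function(model) {
  l <- nchar(model$lsc); i <- nchar(model$ira); s <- nchar(model$ssc)
  data.frame(
    region = c("LSC", "IRa", "SSC", "IRb"),
    start = c(1L, l + 1L, l + i + 1L, l + i + s + 1L),
    end = c(l, l + i, l + i + s, l + 2L * i + s),
    stringsAsFactors = FALSE
  )
}

#' @export
print.PlastomeModel <- function(x, ...) {
  r <- plastome_regions(x)
  cat(sprintf("PlastomeModel: %d nt circular (LSC %d, IRa %d, SSC %d, IRb %d), %d features\n",
              max(r$end), nchar(x$lsc), nchar(x$ira), nchar(x$ssc),
              nchar(x$ira), nrow(x$features)))
  invisible(x)
}

#' Simulate a quadripartite plastome
#'
#' Draws a random circular plastome with the canonical architecture of
#' flowering-plant chloroplast genomes: a large single-copy region (LSC),
#' an inverted repeat (IRa), a small single-copy region (SSC) and a second
#' inverted-repeat copy (IRb) that is the reverse complement of IRa. At
#' `size_factor = 1` the segments are 90 kb / 31 kb / 10 kb / 31 kb, the
#' proportions observed in duckweed plastomes; all segments scale linearly
#' with `size_factor`. Non-overlapping gene features are placed across the
#' LSC, IRa and SSC.
#'
#' @param size_factor positive scaling of all segment lengths.
#' @param gene_count number of gene features to place (>= 0).
#' @param seed integer RNG seed; the model is deterministic per seed.
#' @return a `PlastomeModel`.
#' @export
simulate_plastome <- function(size_factor = 1, gene_count = 60, seed = 1) {
  stopifnot(size_factor > 0, gene_count >= 0)
  seg <- round(c(lsc = 90000, ira = 31000, ssc = 10000) * size_factor)
  if (min(seg) < 4L * MAX_KMER) {
    stop("size_factor too small: a segment would be < 4x the largest k-mer (",
         4L * MAX_KMER, " nt)")
  }
  with_seed(seed, {
    lsc <- random_dna(seg[["lsc"]])
    ira <- random_dna(seg[["ira"]])
    ssc <- random_dna(seg[["ssc"]])
    regions <- data.frame(
      start = c(1L, seg[["lsc"]] + 1L, seg[["lsc"]] + seg[["ira"]] + 1L),
      end = cumsum(seg)
    )
    features <- place_genes(regions, gene_count)
    new_plastome(lsc, ira, ssc, features)
  })
}

# Greedy non-overlapping placement of gene features across regions,
# proportional to region length. Uses the current RNG stream.
place_genes <- function(regions, gene_count) {
  empty <- data.frame(name = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      kind = character(0), stringsAsFactors = FALSE)
  if (gene_count == 0L) return(empty)
  rlen <- regions$end - regions$start + 1L
  region_of <- sample(nrow(regions), gene_count, replace = TRUE,
                      prob = rlen)
  lens <- sample(c(300L, 450L, 600L, 900L, 1200L), gene_count,
                 replace = TRUE, prob = c(0.3, 0.25, 0.2, 0.15, 0.1))
  placed <- vector("list", gene_count)
  occupied <- lapply(seq_len(nrow(regions)), function(i) empty)
  n_ok <- 0L
  for (g in seq_len(gene_count)) {
    ri <- region_of[g]
    lo <- regions$start[ri]; hi <- regions$end[ri] - lens[g] + 1L
    if (hi < lo) next
    occ <- occupied[[ri]]
    for (try in seq_len(50L)) {
      s <- sample(lo:hi, 1L)
      e <- s + lens[g] - 1L
      if (!nrow(occ) || all(e < occ$start - 50L | s > occ$end + 50L)) {
        n_ok <- n_ok + 1L
        row <- data.frame(name = sprintf("gene%03d", n_ok), start = s,
                          end = e, strand = sample(c("+", "-"), 1L),
                          kind = "gene", stringsAsFactors = FALSE)
        placed[[g]] <- row
        occupied[[ri]] <- rbind(occ, row[, c("name", "start", "end",
                                             "strand", "kind")])
        break
      }
    }
  }
  out <- do.call(rbind, placed[!vapply(placed, is.null, TRUE)])
  if (is.null(out)) return(empty)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# EvolutionParams and genome evolution

#' Parameters controlling simulated genome evolution
#'
#' @param substitution_rate expected substitutions per aligned site.
#' @param R_target target transition/transversion ratio si/sv; each
#'   substitution is a transition with probability `R_target / (1 + R_target)`.
#' @param indel_rate expected INDEL events per ancestral site (split evenly
#'   between insertions and deletions).
#' @param indel_length_distribution list with numeric `lengths` and `probs`
#'   describing the discrete INDEL length distribution (positive support).
#' @param coding_rate_multiplier factor in (0, 1] thinning substitutions
#'   inside features of kind `gene`.
#' @param seed integer RNG seed.
#' @return an `EvolutionParams` list.
#' @export
evolution_params <- function(substitution_rate = 0.05, R_target = 0.7,
                             indel_rate = 0,
                             indel_length_distribution = indel_length_geometric(),
                             coding_rate_multiplier = 1, seed = 1) {
  stopifnot(substitution_rate >= 0, R_target > 0, indel_rate >= 0,
            coding_rate_multiplier > 0, coding_rate_multiplier <= 1)
  d <- indel_length_distribution
  if (!is.list(d) || is.null(d$lengths) || is.null(d$probs) ||
      length(d$lengths) != length(d$probs) || any(d$lengths < 1) ||
      any(d$probs < 0) || sum(d$probs) <= 0) {
    stop("indel_length_distribution must give positive lengths with a valid probability vector")
  }
  structure(list(substitution_rate = substitution_rate, R_target = R_target,
                 indel_rate = indel_rate, indel_length_distribution = d,
                 coding_rate_multiplier = coding_rate_multiplier,
                 seed = as.integer(seed)),
            class = "EvolutionParams")
}

#' Geometric INDEL length distribution
#'
#' Truncated geometric distribution of INDEL lengths. The default mean of
#' 5 nt reflects the predominance of short intergenic indels in plastomes.
#'
#' @param mean_length mean of the (untruncated) geometric distribution.
#' @param max_length truncation point.
#' @return list with `lengths` and `probs`.
#' @export
indel_length_geometric <- function(mean_length = 5, max_length = 500) {
  stopifnot(mean_length >= 1)
  p <- 1 / mean_length
  lengths <- seq_len(max_length)
  probs <- stats::dgeom(lengths - 1L, prob = p)
  list(lengths = lengths, probs = probs / sum(probs))
}

indel_dist_moments <- function(d) {
  p <- d$probs / sum(d$probs)
  m1 <- sum(d$lengths * p)
  m2 <- sum(d$lengths^2 * p)
  c(mean = m1, second = m2)
}

#' Back-solve the INDEL event rate for a target INDEL ratio
#'
#' The INDEL ratio of a pairwise alignment is total gap characters divided by
#' alignment columns. With events at rate r per ancestral site (half
#' insertions, half deletions) and mean length m, the expected ratio is
#' `r*m / (1 + r*m/2)`; this inverts that relation.
#'
#' @param target_ratio desired INDEL ratio (gap characters / columns).
#' @param distribution INDEL length distribution (see
#'   [indel_length_geometric()]).
#' @return event rate per ancestral site.
#' @export
indel_rate_for_ratio <- function(target_ratio,
                                 distribution = indel_length_geometric()) {
  stopifnot(target_ratio >= 0, target_ratio < 2)
  m <- indel_dist_moments(distribution)[["mean"]]
  rm <- target_ratio / (1 - target_ratio / 2)
  rm / m
}

#' Divergence presets mirroring observed duckweed plastome contrasts
#'
#' Named presets giving the whole-genome divergence regimes measured between
#' duckweed plastomes: an intra-tribe pair (substitution rate 0.05, R 0.7,
#' INDEL ratio 0.073, the Spirodela/Lemna level), a second intra-tribe pair
#' (0.04 / 0.6 / 0.061, the Wolffiella/Wolffia level) and an inter-tribe pair
#' (0.07 / 0.6 / 0.089).
#'
#' @param name one of `"intra-tribe"`, `"intra-tribe-wolffia"`,
#'   `"inter-tribe"`.
#' @param seed RNG seed stored in the returned parameters.
#' @return an `EvolutionParams`.
#' @export
evolution_preset <- function(name = c("intra-tribe", "intra-tribe-wolffia",
                                      "inter-tribe"), seed = 1) {
  name <- match.arg(name)
  p <- switch(name,
    "intra-tribe" = list(rate = 0.05, R = 0.7, ratio = 0.073),
    "intra-tribe-wolffia" = list(rate = 0.04, R = 0.6, ratio = 0.061),
    "inter-tribe" = list(rate = 0.07, R = 0.6, ratio = 0.089)
  )
  dist <- indel_length_geometric()
  evolution_params(
    substitution_rate = p$rate, R_target = p$R,
    indel_rate = indel_rate_for_ratio(p$ratio, dist),
    indel_length_distribution = dist, seed = seed
  )
}

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
transversion_partners <- list(A = c("C", "T"), G = c("C", "T"),
                              C = c("A", "G"), T = c("A", "G"))

#' Evolve a plastome under controlled substitution and INDEL regimes
#'
#' Mutates the single-copy core (LSC + IRa + SSC) of an ancestor plastome.
#' INDEL events are drawn per ancestral site at `indel_rate` (insertions and
#' deletions equally likely, lengths from the configured distribution) and
#' define a truth alignment between ancestor and derived sequence. The number
#' of substitutions is then drawn as Binomial(alignment columns,
#' `substitution_rate`) — realising the definition of the substitution rate
#' as expected substitutions per aligned site exactly — and substitutions are
#' placed on non-gap columns, thinned by `coding_rate_multiplier` inside gene
#' features. Each substitution is a transition with probability
#' `R_target/(1+R_target)`, so the expected si/sv ratio equals `R_target`.
#' Because the model stores only LSC/IRa/SSC and derives IRb as the reverse
#' complement of IRa, mutations in IRa are mirrored into IRb and the IR
#' identity is preserved.
#'
#' @param ancestor a `PlastomeModel`.
#' @param params an `EvolutionParams`.
#' @return list with `genome` (derived `PlastomeModel`), `log` (a
#'   `MutationEventLog` data.frame with columns pos, kind, ancestral,
#'   derived; positions are 1-based on the ancestor core, insertions placed
#'   after `pos`), and `alignment` (list `A`/`B`, the gapped truth alignment
#'   of ancestor vs derived core).
#' @export
evolve_genome <- function(ancestor, params) {
  stopifnot(inherits(ancestor, "PlastomeModel"),
            inherits(params, "EvolutionParams"))
  core <- plastome_core(ancestor)
  L <- nchar(core)
  if (L == 0L) stop("ancestor core is empty")
  with_seed(params$seed, {
    anc <- strsplit(core, "", fixed = TRUE)[[1]]

    # --- INDEL events ------------------------------------------------------
    dist <- params$indel_length_distribution
    ev_site <- which(stats::runif(L) < params$indel_rate)
    ins_events <- data.frame(pos = integer(0), seq = character(0))
    del <- rep(FALSE, L)
    del_events <- list()
    if (length(ev_site)) {
      is_ins <- stats::runif(length(ev_site)) < 0.5
      lens <- sample(dist$lengths, length(ev_site), replace = TRUE,
                     prob = dist$probs)
      ipos <- ev_site[is_ins]
      if (length(ipos)) {
        ins_events <- data.frame(
          pos = ipos - 1L,  # insertion after this ancestor position
          seq = vapply(lens[is_ins], random_dna, ""),
          stringsAsFactors = FALSE
        )
        # merge multiple insertions at the same point
        ins_events <- stats::aggregate(seq ~ pos, data = ins_events,
                                       FUN = paste, collapse = "")
        ins_events <- ins_events[order(ins_events$pos), , drop = FALSE]
      }
      dpos <- ev_site[!is_ins]
      dlen <- lens[!is_ins]
      for (j in seq_along(dpos)) {
        e <- min(dpos[j] + dlen[j] - 1L, L)
        del[dpos[j]:e] <- TRUE
      }
    }

    # insertions anchored strictly inside a deleted run are suppressed so
    # the event log is coordinate-wise unambiguous: replaying the events on
    # the ancestor by plain string surgery is then well defined
    if (nrow(ins_events)) {
      pos0 <- ins_events$pos
      inside <- pos0 >= 1L & pos0 < L & del[pmax(pos0, 1L)] &
        del[pmin(pos0 + 1L, L)]
      ins_events <- ins_events[!inside, , drop = FALSE]
    }

    # --- truth alignment columns ------------------------------------------
    aln <- build_indel_alignment(anc, del, ins_events)
    A <- aln$A; B <- aln$B; anc_pos <- aln$anc_pos

    # --- substitutions -----------------------------------------------------
    ncol_aln <- length(A)
    n_sub <- stats::rbinom(1L, ncol_aln, params$substitution_rate)
    match_cols <- which(A != "-" & B != "-")
    sub_log <- NULL
    if (n_sub > 0L && length(match_cols)) {
      w <- rep(1, length(match_cols))
      if (params$coding_rate_multiplier < 1 && nrow(ancestor$features)) {
        genes <- ancestor$features[ancestor$features$kind == "gene", ,
                                   drop = FALSE]
        if (nrow(genes)) {
          in_gene <- rep(FALSE, L)
          for (j in seq_len(nrow(genes))) {
            s <- genes$start[j]; e <- min(genes$end[j], L)
            if (s <= L) in_gene[s:e] <- TRUE
          }
          w[in_gene[anc_pos[match_cols]]] <- params$coding_rate_multiplier
        }
      }
      n_sub <- min(n_sub, length(match_cols))
      hit <- if (length(match_cols) == 1L) match_cols else
        sample(match_cols, n_sub, prob = w)
      old <- A[hit]
      is_ti <- stats::runif(n_sub) < params$R_target / (1 + params$R_target)
      new <- character(n_sub)
      new[is_ti] <- transition_partner[old[is_ti]]
      if (any(!is_ti)) {
        tv <- which(!is_ti)
        pick <- stats::runif(length(tv)) < 0.5
        new[tv] <- vapply(seq_along(tv), function(i) {
          transversion_partners[[old[tv[i]]]][if (pick[i]) 1L else 2L]
        }, "")
      }
      B[hit] <- new
      sub_log <- data.frame(pos = anc_pos[hit], kind = "substitution",
                            ancestral = old, derived = new,
                            stringsAsFactors = FALSE)
    }

    # --- event log ---------------------------------------------------------
    logs <- list(sub_log)
    if (any(del)) {
      r <- rle(del)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ds <- starts[r$values]; de <- ends[r$values]
      logs <- c(logs, list(data.frame(
        pos = ds, kind = "deletion",
        ancestral = substring(core, ds, de), derived = "",
        stringsAsFactors = FALSE
      )))
    }
    if (nrow(ins_events)) {
      logs <- c(logs, list(data.frame(
        pos = ins_events$pos, kind = "insertion", ancestral = "",
        derived = ins_events$seq, stringsAsFactors = FALSE
      )))
    }
    log <- do.call(rbind, logs[!vapply(logs, is.null, TRUE)])
    if (is.null(log)) {
      log <- data.frame(pos = integer(0), kind = character(0),
                        ancestral = character(0), derived = character(0),
                        stringsAsFactors = FALSE)
    } else {
      log <- log[order(log$pos, match(log$kind, c("substitution", "deletion",
                                                  "insertion"))), ,
                 drop = FALSE]
      rownames(log) <- NULL
    }

    # --- derived model -----------------------------------------------------
    keepB <- B != "-"
    derived_core <- paste(B[keepB], collapse = "")
    # map ancestor coordinate -> derived coordinate (last derived position at
    # or before the ancestor position)
    der_cum <- cumsum(keepB)
    col_of_anc <- match(seq_len(L), anc_pos)  # first column of each anc pos
    # columns are ordered; ancestor position p ends at the column before the
    # first column of p+1
    end_col <- c(col_of_anc[-1L] - 1L, length(A))
    map_end <- der_cum[end_col]               # derived pos after anc pos p
    lsc_len <- nchar(ancestor$lsc)
    ira_len <- nchar(ancestor$ira)
    b1 <- map_end[lsc_len]
    b2 <- map_end[lsc_len + ira_len]
    new_feats <- ancestor$features
    if (nrow(new_feats)) {
      map_start <- c(0L, map_end)[pmin(new_feats$start, L)] + 1L
      new_feats$start <- pmin(map_start, nchar(derived_core))
      new_feats$end <- map_end[pmin(new_feats$end, L)]
      new_feats <- new_feats[new_feats$end >= new_feats$start, , drop = FALSE]
      rownames(new_feats) <- NULL
    }
    derived <- new_plastome(
      lsc = substr(derived_core, 1L, b1),
      ira = substr(derived_core, b1 + 1L, b2),
      ssc = substr(derived_core, b2 + 1L, nchar(derived_core)),
      features = new_feats
    )
    list(genome = derived,
         log = log,
         alignment = list(A = paste(A, collapse = ""),
                          B = paste(B, collapse = "")))
  })
}

# Build gapped alignment columns from deletion mask and insertion table.
# Returns character vectors A (ancestor row), B (derived row) and anc_pos
# (ancestor coordinate of each column; insertions carry the position they
# follow).
build_indel_alignment <- function(anc, del, ins_events) {
  L <- length(anc)
  n_ins <- sum(nchar(ins_events$seq))
  A <- character(L + n_ins)
  B <- character(L + n_ins)
  anc_pos <- integer(L + n_ins)
  derived_anc <- anc
  derived_anc[del] <- "-"
  cuts <- c(0L, ins_events$pos, L)
  out_at <- 1L
  for (i in seq_len(length(cuts) - 1L)) {
    from <- cuts[i] + 1L; to <- cuts[i + 1L]
    if (from <= to) {
      idx <- out_at:(out_at + (to - from))
      A[idx] <- anc[from:to]
      B[idx] <- derived_anc[from:to]
      anc_pos[idx] <- from:to
      out_at <- out_at + (to - from) + 1L
    }
    if (i < length(cuts) - 1L) {
      ins_chars <- strsplit(ins_events$seq[i], "", fixed = TRUE)[[1]]
      idx <- out_at:(out_at + length(ins_chars) - 1L)
      A[idx] <- "-"
      B[idx] <- ins_chars
      anc_pos[idx] <- ins_events$pos[i]
      out_at <- out_at + length(ins_chars)
    }
  }
  list(A = A, B = B, anc_pos = anc_pos)
}

#' Replay a mutation event log on an ancestor sequence
#'
#' Applies the events of a `MutationEventLog` (sorted by ancestor position)
#' to the ancestor core sequence, reproducing the derived sequence exactly.
#'
#' @param ancestor a `PlastomeModel` or a plain core sequence string.
#' @param log event log as returned by [evolve_genome()].
#' @return the derived core sequence (character string).
#' @export
replay_event_log <- function(ancestor, log) {
  core <- if (inherits(ancestor, "PlastomeModel")) plastome_core(ancestor)
          else ancestor
  anc <- strsplit(core, "", fixed = TRUE)[[1]]
  L <- length(anc)
  del <- rep(FALSE, L)
  derived <- anc
  ins <- rep("", L + 1L)  # ins[p+1] inserted after ancestor position p
  for (i in seq_len(nrow(log))) {
    kind <- log$kind[i]; p <- log$pos[i]
    if (kind == "substitution") {
      if (derived[p] != log$ancestral[i])
        stop("log/ancestor mismatch at position ", p)
      derived[p] <- log$derived[i]
    } else if (kind == "deletion") {
      e <- p + nchar(log$ancestral[i]) - 1L
      del[p:e] <- TRUE
    } else if (kind == "insertion") {
      ins[p + 1L] <- paste0(ins[p + 1L], log$derived[i])
    } else stop("unknown event kind: ", kind)
  }
  derived[del] <- ""
  pieces <- c(rbind(ins[seq_len(L)], derived))
  paste0(paste(pieces, collapse = ""), ins[L + 1L])
}

# ---------------------------------------------------------------------------
# MatePairLibrary

new_mate_pair_library <- function(tagF, tagR, qualF, qualR, id = NULL,
                                  origin = NULL, truth = NULL,
                                  tag_length = NA_integer_,
                                  insert_mean = 1500, insert_sd = 150,
                                  orientation = "outward") {
  if (is.null(id)) id <- sprintf("pair%07d", seq_along(tagF))
  structure(
    list(id = id, tagF = tagF, tagR = tagR, qualF = qualF, qualR = qualR,
         origin = origin, truth = truth, tag_length = tag_length,
         insert_mean = insert_mean, insert_sd = insert_sd,
         orientation = orientation),
    class = "MatePairLibrary"
  )
}

#' @export
length.MatePairLibrary <- function(x) length(x$tagF)

#' @export
`[.MatePairLibrary` <- function(x, i) {
  new_mate_pair_library(
    tagF = x$tagF[i], tagR = x$tagR[i], qualF = x$qualF[i],
    qualR = x$qualR[i], id = x$id[i],
    origin = if (!is.null(x$origin)) x$origin[i] else NULL,
    truth = if (!is.null(x$truth)) x$truth[i, , drop = FALSE] else NULL,
    tag_length = x$tag_length, insert_mean = x$insert_mean,
    insert_sd = x$insert_sd, orientation = x$orientation
  )
}

#' @export
print.MatePairLibrary <- function(x, ...) {
  cat(sprintf("MatePairLibrary: %d pairs, %s-facing, tag %s nt, insert %g +/- %g nt\n",
              length(x), x$orientation, x$tag_length, x$insert_mean,
              x$insert_sd))
  if (!is.null(x$origin)) {
    tab <- table(x$origin)
    cat("  origins:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Tags re-oriented to the inward (innie) convention: tag1 maps forward at the
# fragment start, tag2 maps reverse at the fragment end. For outward-facing
# (SOLiD-style) libraries this reverse-complements both tags.
pair_tags_inward <- function(lib) {
  if (identical(lib$orientation, "outward")) {
    list(t1 = revcomp(lib$tagF), t2 = revcomp(lib$tagR))
  } else {
    list(t1 = lib$tagF, t2 = lib$tagR)
  }
}

# Sample mate-pair fragments from one source sequence. Positions are on the
# forward strand of the source; for circular sources fragments may wrap.
sample_fragments <- function(seq, n, tag_length, insert_mean, insert_sd,
                             circular = FALSE) {
  if (n == 0L) {
    return(list(frag = character(0), start = integer(0), insert = integer(0),
                strand = character(0)))
  }
  len <- nchar(seq)
  ins <- pmax(round(stats::rnorm(n, insert_mean, insert_sd)),
              2L * tag_length + 1L)
  if (circular) {
    ins <- pmin(ins, len)
    start <- sample.int(len, n, replace = TRUE)
    unrolled <- paste0(seq, substr(seq, 1L, min(len, max(ins))))
  } else {
    ins <- pmin(ins, len)
    start <- vapply(ins, function(il) sample.int(len - il + 1L, 1L), 0L)
    unrolled <- seq
  }
  frag <- substring(unrolled, start, start + ins - 1L)
  minus <- stats::runif(n) < 0.5
  frag[minus] <- revcomp(frag[minus])
  list(frag = frag, start = start, insert = ins,
       strand = ifelse(minus, "-", "+"))
}

# Per-base sequencing errors: uniform substitutions at `rate`.
add_read_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  L <- nchar(seqs[1])
  nerr <- stats::rbinom(length(seqs), L, rate)
  for (i in which(nerr > 0L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    at <- sample.int(L, nerr[i])
    ch[at] <- vapply(ch[at], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, "")
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Phred QV strings under the package QV model: per-base
# clamp(Normal(mu, sd), 2, 40), with a configurable fraction of bad reads
# drawn at bad_mu.
simulate_qv_strings <- function(n, len, qv_model) {
  mu <- ifelse(stats::runif(n) < qv_model$bad_frac, qv_model$bad_mu,
               qv_model$mu)
  m <- matrix(stats::rnorm(n * len, mean = rep(mu, each = len),
                           sd = qv_model$sd), nrow = len)
  m <- pmin(pmax(round(m), 2L), 40L)
  vapply(seq_len(n), function(i) intToUtf8(m[, i] + 33L), "")
}

#' Quality-value model specification
#'
#' @param mu mean QV of normal reads.
#' @param sd per-base QV standard deviation.
#' @param bad_frac fraction of reads drawn from the low-quality component.
#' @param bad_mu mean QV of low-quality reads.
#' @return a list used as `qv_model`.
#' @export
qv_model <- function(mu = 28, sd = 6, bad_frac = 0.05, bad_mu = 12) {
  list(mu = mu, sd = sd, bad_frac = bad_frac, bad_mu = bad_mu)
}

#' Simulate mate pairs from a single source sequence
#'
#' Lower-level sampler used by [simulate_total_dna_library()]; useful on its
#' own for assembler tests against a known source.
#'
#' @param sequence source sequence (character string).
#' @param n_pairs number of pairs.
#' @param tag_length tag (read) length in nt.
#' @param insert_mean,insert_sd insert size distribution (nt).
#' @param error_rate per-base substitution error rate.
#' @param qv QV model (see [qv_model()]).
#' @param orientation `"outward"` (SOLiD mate pairs) or `"inward"`.
#' @param circular treat the source as circular.
#' @param origin origin label stored for every pair.
#' @param seed integer RNG seed.
#' @return a `MatePairLibrary` with per-pair truth coordinates.
#' @export
simulate_mate_pairs <- function(sequence, n_pairs, tag_length = 50,
                                insert_mean = 1500, insert_sd = 150,
                                error_rate = 0, qv = qv_model(),
                                orientation = c("outward", "inward"),
                                circular = FALSE, origin = "chloroplast",
                                seed = 1) {
  orientation <- match.arg(orientation)
  stopifnot(n_pairs >= 0, insert_mean > 2 * tag_length,
            nchar(sequence) > insert_mean)
  with_seed(seed, {
    lib <- sample_pairs_from(list(sequence), rep(1L, max(n_pairs, 0L)),
                             c(origin), tag_length, insert_mean, insert_sd,
                             error_rate, qv, orientation,
                             circular = c(circular))
    lib
  })
}

# Shared fragment->tags machinery. `source_idx` assigns each pair to a
# compartment sequence; uses the current RNG stream.
sample_pairs_from <- function(sources, source_idx, origin_labels, tag_length,
                              insert_mean, insert_sd, error_rate, qv,
                              orientation, circular) {
  n <- length(source_idx)
  tagF <- tagR <- character(n)
  truth <- data.frame(origin = origin_labels[source_idx],
                      start = integer(n), insert = integer(n),
                      strand = character(n), stringsAsFactors = FALSE)
  for (si in unique(source_idx)) {
    idx <- which(source_idx == si)
    fr <- sample_fragments(sources[[si]], length(idx), tag_length,
                           insert_mean, insert_sd, circular = circular[si])
    left <- substr(fr$frag, 1L, tag_length)
    right <- substring(fr$frag, fr$insert - tag_length + 1L, fr$insert)
    if (orientation == "outward") {
      tagF[idx] <- revcomp(left)
      tagR[idx] <- right
    } else {
      tagF[idx] <- left
      tagR[idx] <- revcomp(right)
    }
    truth$start[idx] <- fr$start
    truth$insert[idx] <- fr$insert
    truth$strand[idx] <- fr$strand
  }
  tagF <- add_read_errors(tagF, error_rate)
  tagR <- add_read_errors(tagR, error_rate)
  new_mate_pair_library(
    tagF = tagF, tagR = tagR,
    qualF = simulate_qv_strings(n, tag_length, qv),
    qualR = simulate_qv_strings(n, tag_length, qv),
    origin = truth$origin, truth = truth, tag_length = tag_length,
    insert_mean = insert_mean, insert_sd = insert_sd,
    orientation = orientation
  )
}

#' Simulate a total-DNA mate-pair library
#'
#' Emulates an unfractionated total-DNA sequencing run: read pairs are drawn
#' from three compartments — the (circular) chloroplast genome, a nuclear
#' decoy and a mitochondrial decoy — with sampling probability proportional
#' to copy number times compartment length. The chloroplast is present at
#' `copy_ratio_chl_per_nuclear` copies per nuclear copy (around 100 in
#' duckweed leaf tissue). Tags are 50 nt and inserts ~1.5 kb by default,
#' outward-facing. Hidden origin labels and fragment coordinates are
#' recorded for every pair.
#'
#' @param plastome a `PlastomeModel` (the chloroplast compartment).
#' @param nuclear_size,mito_size decoy compartment lengths (nt).
#' @param copy_ratio_chl_per_nuclear chloroplast copies per nuclear copy.
#' @param mito_copies mitochondrial copies per nuclear copy.
#' @param n_pairs number of mate pairs to draw.
#' @param tag_length,insert_mean,insert_sd library geometry (nt).
#' @param error_rate per-base substitution error rate.
#' @param qv QV model (see [qv_model()]).
#' @param orientation `"outward"` or `"inward"`.
#' @param seed integer RNG seed; everything is deterministic per seed.
#' @return a `MatePairLibrary`; attribute `"compartments"` carries the decoy
#'   sequences.
#' @export
simulate_total_dna_library <- function(plastome, nuclear_size = 2e5,
                                       mito_size = 5e4,
                                       copy_ratio_chl_per_nuclear = 100,
                                       mito_copies = 10,
                                       n_pairs = 10000, tag_length = 50,
                                       insert_mean = 1500, insert_sd = 150,
                                       error_rate = 0.001, qv = qv_model(),
                                       orientation = c("outward", "inward"),
                                       seed = 1) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(plastome, "PlastomeModel"), n_pairs >= 0,
            insert_mean > 2 * tag_length)
  chl <- plastome_sequence(plastome)
  stopifnot(nchar(chl) > insert_mean, nuclear_size > insert_mean,
            mito_size > insert_mean)
  with_seed(seed, {
    nuc <- random_dna(nuclear_size)
    mito <- random_dna(mito_size)
    sources <- list(chl, nuc, mito)
    labels <- c("chloroplast", "nuclear", "mitochondrial")
    w <- c(copy_ratio_chl_per_nuclear * nchar(chl),
           1 * nuclear_size, mito_copies * mito_size)
    source_idx <- sample.int(3L, n_pairs, replace = TRUE, prob = w)
    lib <- sample_pairs_from(sources, source_idx, labels, tag_length,
                             insert_mean, insert_sd, error_rate, qv,
                             orientation,
                             circular = c(TRUE, FALSE, FALSE))
    attr(lib, "compartments") <- list(chloroplast = chl, nuclear = nuc,
                                      mitochondrial = mito)
    attr(lib, "copy_weights") <- stats::setNames(w, labels)
    lib
  })
}

#' Simulate long finishing reads from a genome
#'
#' Tiles the source with long reads (capillary-electrophoresis style) at a
#' fixed step so that every position — including the junctions flanking the
#' inverted repeat — is spanned; used for gap closure and assembly
#' validation.
#'
#' @param sequence source sequence.
#' @param read_length read length (nt).
#' @param step distance between consecutive read starts (nt).
#' @param error_rate per-base substitution error rate.
#' @param circular tile across the origin of a circular molecule.
#' @param seed RNG seed (used only when `error_rate > 0`).
#' @return named character vector of reads.
#' @export
simulate_finishing_reads <- function(sequence, read_length = 2000,
                                     step = 1000, error_rate = 0,
                                     circular = FALSE, seed = 1) {
  len <- nchar(sequence)
  src <- if (circular) paste0(sequence, substr(sequence, 1L, read_length))
         else sequence
  starts <- seq(1L, if (circular) len else max(len - read_length + 1L, 1L),
                by = step)
  reads <- substring(src, starts, pmin(starts + read_length - 1L, nchar(src)))
  names(reads) <- sprintf("finish%04d", seq_along(reads))
  if (error_rate > 0) {
    reads <- with_seed(seed, {
      out <- reads
      for (i in seq_along(out)) out[i] <- add_read_errors(out[i], error_rate)
      out
    })
  }
  reads
}
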