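# De novo assembly: de Bruijn graph contig building over canonical k-mers
# with a coverage cutoff, mate-pair scaffolding with a confirmation
# threshold, and assembly statistics.

#' Assembly parameters
#'
#' @param hash_length odd k-mer size for the de Bruijn graph (>= 11,
#'   default 19).
#' @param coverage_cutoff minimum k-mer multiplicity to enter the graph
#'   (default 11).
#' @param min_pair_count mate-pair confirmations required to join two
#'   contigs into a scaffold (default 120; scale down for small simulated
#'   libraries).
#' @param expected_coverage informational expected k-mer coverage; recorded
#'   but not used during contig construction.
#' @return an `AssemblyParams` list.
#' @export
assembly_params <- function(hash_length = 19, coverage_cutoff = 11,
                            min_pair_count = 120, expected_coverage = 150) {
  hash_length <- as.integer(hash_length)
  stopifnot(hash_length >= 11, hash_length %% 2L == 1L, coverage_cutoff >= 1,
            min_pair_count >= 1)
  structure(list(hash_length = hash_length,
                 coverage_cutoff = as.integer(coverage_cutoff),
                 min_pair_count = as.integer(min_pair_count),
                 expected_coverage = expected_coverage),
            class = "AssemblyParams")
}

#' Build contigs from short reads with a de Bruijn graph
#'
#' Counts canonical k-mers (lexicographic minimum of each k-mer and its
#' reverse complement, so both strands collapse; k is odd to exclude
#' palindromes), discards k-mers below the coverage cutoff, builds the
#' bidirected de Bruijn graph, clips dead-end tips shorter than 2k, pops
#' simple bubbles in favour of the higher-coverage path, and emits maximal
#' non-branching paths as contigs. Deterministic for a given read set.
#'
#' @param reads character vector of read sequences (uniform truncated tags).
#' @param params an `AssemblyParams`.
#' @return data.frame with columns id, seq, length, coverage (mean canonical
#'   k-mer multiplicity), ordered by decreasing length.
#' @export
build_contigs <- function(reads, params = assembly_params()) {
  k <- params$hash_length
  reads <- reads[nchar(reads) >= k]
  empty <- data.frame(id = character(0), seq = character(0),
                      length = integer(0), coverage = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(reads)) return(empty)
  km <- read_kmers(reads, k)
  km <- km[!grepl("[^ACGT]", km)]
  if (!length(km)) return(empty)
  cnt <- data.table::data.table(canon = canonical_kmers(km))[, .N,
                                                             by = "canon"]
  kept <- cnt[cnt$N >= params$coverage_cutoff]
  if (!nrow(kept)) {
    warning("no k-mer survives the coverage cutoff; empty assembly")
    return(empty)
  }
  g <- NULL
  for (round in 1:5) {
    g <- debruijn_unitigs(kept$canon, kept$N, k)
    if (!nrow(g$unitigs)) return(empty)
    drop <- character(0)
    # tip clipping: dead-end unitigs shorter than 2k hanging off a junction
    tips <- g$unitigs[g$unitigs$dead_start != g$unitigs$dead_end &
                        g$unitigs$length < 2L * k, , drop = FALSE]
    if (nrow(tips)) drop <- c(drop, unlist(g$members[tips$row]))
    # simple bubbles: parallel unitigs sharing both endpoint junctions;
    # keep the higher-coverage path. A unitig whose path runs from a node
    # to its own reverse complement coincides with its RC twin's endpoints
    # without being a bubble, so parallelism is judged between
    # RC-equivalence classes of the sequence, not raw paths.
    bub <- g$unitigs[!g$unitigs$dead_start & !g$unitigs$dead_end, ,
                     drop = FALSE]
    if (nrow(bub) > 1L) {
      key <- paste(bub$first_node, bub$last_node)
      rc <- revcomp(bub$seq)
      cls <- ifelse(bub$seq <= rc, bub$seq, rc)
      dupgrp <- split(seq_len(nrow(bub)), key)
      for (grp in dupgrp[lengths(dupgrp) > 1L]) {
        classes <- split(grp, cls[grp])
        if (length(classes) < 2L) next
        lens <- bub$length[vapply(classes, `[`, 0L, 1L)]
        if (max(lens) - min(lens) <= max(10L, round(0.1 * max(lens)))) {
          covs <- vapply(classes, function(ix) max(bub$coverage[ix]), 0)
          losers <- unlist(classes[-which.max(covs)])
          drop <- c(drop, unlist(g$members[bub$row[losers]]))
        }
      }
    }
    drop <- setdiff(unique(drop), g$junction_kmers)
    if (!length(drop)) break
    kept <- kept[!kept$canon %in% canonical_kmers(drop)]
    if (!nrow(kept)) return(empty)
    g <- NULL
  }
  if (is.null(g)) {
    g <- debruijn_unitigs(kept$canon, kept$N, k)
    if (!nrow(g$unitigs)) return(empty)
  }
  contigs <- g$unitigs
  # collapse reverse-complement duplicates
  cseq <- contigs$seq
  crc <- revcomp(cseq)
  canon_seq <- ifelse(cseq <= crc, cseq, crc)
  keep <- !duplicated(canon_seq)
  contigs <- contigs[keep, , drop = FALSE]
  contigs$seq <- canon_seq[keep]
  contigs <- contigs[order(-contigs$length, contigs$seq), , drop = FALSE]
  data.frame(id = sprintf("contig%04d", seq_len(nrow(contigs))),
             seq = contigs$seq, length = contigs$length,
             coverage = contigs$coverage, stringsAsFactors = FALSE)
}

# Core unitig extraction. `canon` are surviving canonical k-mers with counts
# `cov`. Builds the graph over both orientations and walks maximal
# non-branching paths. Returns the unitig table (with endpoint/dead-end
# bookkeeping), the k-mer membership of each unitig, and the junction k-mers
# (never removed during simplification).
debruijn_unitigs <- function(canon, cov, k) {
  nodes <- sort(unique(c(canon, revcomp(canon))))
  nn <- length(nodes)
  node_cov <- cov[match(canonical_kmers(nodes), canon)]
  suffix <- substr(nodes, 2L, k)
  succ <- matrix(NA_integer_, nn, 4L)
  for (b in 1:4) {
    succ[, b] <- match(paste0(suffix, DNA_BASES[b]), nodes)
  }
  outdeg <- rowSums(!is.na(succ))
  indeg <- tabulate(succ[!is.na(succ)], nbins = nn)
  through <- indeg == 1L & outdeg == 1L
  last_char <- substr(nodes, k, k)

  paths <- list()
  edge_used <- matrix(FALSE, nn, 4L)
  buf <- integer(nn + 1L)
  # maximal non-branching path out of junction/dead-start node u via edge b
  walk_linear <- function(u, b) {
    len <- 1L
    buf[1L] <<- u
    edge_used[u, b] <<- TRUE
    v <- succ[u, b]
    while (through[v]) {
      nb <- which(!is.na(succ[v, ]))[1L]
      if (edge_used[v, nb]) break
      len <- len + 1L
      buf[len] <<- v
      edge_used[v, nb] <<- TRUE
      v <- succ[v, nb]
    }
    len <- len + 1L
    buf[len] <<- v
    buf[seq_len(len)]
  }
  # isolated cycle of through-nodes containing u
  walk_cycle <- function(u) {
    len <- 1L
    buf[1L] <<- u
    nb <- which(!is.na(succ[u, ]))[1L]
    edge_used[u, nb] <<- TRUE
    v <- succ[u, nb]
    while (v != u) {
      len <- len + 1L
      buf[len] <<- v
      nb <- which(!is.na(succ[v, ]))[1L]
      edge_used[v, nb] <<- TRUE
      v <- succ[v, nb]
    }
    buf[seq_len(len)]
  }
  starts <- which(outdeg > 0L & !through)
  for (u in starts) {
    for (b in which(!is.na(succ[u, ]))) {
      if (edge_used[u, b]) next
      paths[[length(paths) + 1L]] <- walk_linear(u, b)
    }
  }
  for (u in which(through)) {
    nb <- which(!is.na(succ[u, ]))[1L]
    if (!edge_used[u, nb]) {
      paths[[length(paths) + 1L]] <- walk_cycle(u)
    }
  }
  # fully isolated nodes (no edges at all)
  iso <- which(outdeg == 0L & indeg == 0L)
  for (u in iso) paths[[length(paths) + 1L]] <- u

  if (!length(paths)) {
    return(list(unitigs = data.frame(), members = list(),
                junction_kmers = character(0)))
  }
  seqs <- vapply(paths, function(p) {
    if (length(p) == 1L) nodes[p[1L]]
    else paste0(nodes[p[1L]], paste(last_char[p[-1L]], collapse = ""))
  }, "")
  covs <- vapply(paths, function(p) mean(node_cov[p]), 0)
  first_node <- vapply(paths, function(p) p[1L], 0L)
  last_node <- vapply(paths, function(p) p[length(p)], 0L)
  unitigs <- data.frame(
    row = seq_along(paths),
    seq = seqs,
    length = nchar(seqs),
    coverage = covs,
    first_node = first_node,
    last_node = last_node,
    dead_start = indeg[first_node] == 0L,
    dead_end = outdeg[last_node] == 0L,
    stringsAsFactors = FALSE
  )
  members <- lapply(paths, function(p) nodes[p])
  junction <- nodes[indeg > 1L | outdeg > 1L]
  list(unitigs = unitigs, members = members, junction_kmers = junction)
}

#' Scaffold contigs with mate-pair evidence
#'
#' Maps each tag of every pair to the contig set; pairs whose tags map
#' uniquely to two different contigs vote for an oriented junction between
#' them. Junctions with at least `min_pair_count` votes are accepted, gap
#' lengths are estimated from the insert size minus the observed flanking
#' distances (floored at zero), conflicting junctions are resolved in favour
#' of the higher support (ties: smaller contig id) and cyclic joins are
#' broken at their weakest edge.
#'
#' @param contigs contig table from [build_contigs()].
#' @param library the (filtered, selected) `MatePairLibrary` used as
#'   evidence.
#' @param params an `AssemblyParams` (uses `min_pair_count`).
#' @param mapper a `MapperParams` for tag-to-contig mapping.
#' @return list of scaffolds; each scaffold is a data.frame with columns
#'   contig, orientation, gap_after, support_after (NA on the last row).
#'   Class `"ScaffoldSet"`.
#' @export
scaffold_contigs <- function(contigs, library, params = assembly_params(),
                             mapper = mapper_params()) {
  singletons <- function(ids) {
    lapply(ids, function(cid) {
      data.frame(contig = cid, orientation = "+", gap_after = NA_real_,
                 support_after = NA_real_, stringsAsFactors = FALSE)
    })
  }
  finish <- function(sc) structure(sc, class = "ScaffoldSet")
  if (!nrow(contigs)) return(finish(list()))
  if (nrow(contigs) == 1L || length(library) == 0L) {
    return(finish(singletons(contigs$id)))
  }

  spacer <- strrep("N", max(library$tag_length, 50L))
  cat_ref <- paste(contigs$seq, collapse = spacer)
  starts <- cumsum(c(1L, utils::head(nchar(contigs$seq), -1L) +
                       nchar(spacer)))
  ends <- starts + nchar(contigs$seq) - 1L

  tw <- pair_tags_inward(library)
  h1 <- map_tags(tw$t1, cat_ref, mapper)
  h2 <- map_tags(tw$t2, cat_ref, mapper)
  uniq <- function(h) h[, if (.N == 1L) .SD, by = "read"]
  h1 <- uniq(h1); h2 <- uniq(h2)
  locate <- function(h) {
    ci <- findInterval(h$pos, starts)
    ok <- ci >= 1L & h$pos + h$length - 1L <= ends[ci]
    data.table::data.table(read = h$read[ok], contig = ci[ok],
                           cpos = h$pos[ok] - starts[ci[ok]] + 1L,
                           strand = h$strand[ok], L = h$length[ok])
  }
  l1 <- locate(h1); l2 <- locate(h2)
  pairs <- merge(l1, l2, by = "read", suffixes = c("1", "2"))
  pairs <- pairs[pairs$contig1 != pairs$contig2, ]
  if (!nrow(pairs)) return(finish(singletons(contigs$id)))

  clen <- nchar(contigs$seq)
  A <- pairs$contig1; B <- pairs$contig2
  oA <- pairs$strand1
  # orient B so the second (fragment-end, reverse-mapping) tag reads reverse
  oB <- ifelse(pairs$strand2 == "-", "+", "-")
  flankA <- ifelse(oA == "+", clen[A] - pairs$cpos1 + 1L,
                   pairs$cpos1 + pairs$L1 - 1L)
  flankB <- ifelse(oB == "+", pairs$cpos2 + pairs$L2 - 1L,
                   clen[B] - pairs$cpos2 + 1L)
  gap <- library$insert_mean - flankA - flankB
  # canonicalise junction direction by contig index
  flip <- function(o) ifelse(o == "+", "-", "+")
  swap <- A > B
  jun <- data.table::data.table(
    A = ifelse(swap, B, A),
    oA = ifelse(swap, flip(oB), oA),
    B = ifelse(swap, A, B),
    oB = ifelse(swap, flip(oA), oB),
    gap = gap
  )
  votes <- jun[, list(n = .N, gap = stats::median(gap)),
               by = c("A", "oA", "B", "oB")]
  votes <- votes[votes$n >= params$min_pair_count, ]
  data.table::setorder(votes, -n, A, B)

  # greedy port assignment + union-find cycle breaking
  port_used <- matrix(FALSE, nrow(contigs), 2L,
                      dimnames = list(NULL, c("L", "R")))
  uf <- seq_len(nrow(contigs))
  find <- function(x) { while (uf[x] != x) x <- uf[x]; x }
  links <- list()
  for (i in seq_len(nrow(votes))) {
    v <- votes[i]
    pA <- ifelse(v$oA == "+", "R", "L")
    pB <- ifelse(v$oB == "+", "L", "R")
    if (port_used[v$A, pA] || port_used[v$B, pB]) next
    rA <- find(v$A); rB <- find(v$B)
    if (rA == rB) next  # would close a cycle; weakest by greedy order
    port_used[v$A, pA] <- TRUE
    port_used[v$B, pB] <- TRUE
    uf[rA] <- rB
    links[[length(links) + 1L]] <-
      list(A = v$A, pA = pA, B = v$B, pB = pB,
           gap = max(round(v$gap), 0), support = v$n)
  }

  # doubly linked ports -> chains
  link_of <- array(NA_integer_, dim = c(nrow(contigs), 2L),
                   dimnames = list(NULL, c("L", "R")))
  for (j in seq_along(links)) {
    link_of[links[[j]]$A, links[[j]]$pA] <- j
    link_of[links[[j]]$B, links[[j]]$pB] <- j
  }
  n_links <- rowSums(!is.na(link_of))
  visited <- rep(FALSE, nrow(contigs))
  scaffolds <- list()
  for (c0 in order(-clen)) {
    if (visited[c0] || n_links[c0] == 0L) next
    if (n_links[c0] == 2L) next  # interior; reached from a chain end
    enter <- if (is.na(link_of[c0, "L"])) "L" else "R"
    chain <- list()
    cur <- c0; p_in <- enter
    repeat {
      visited[cur] <- TRUE
      ori <- if (p_in == "L") "+" else "-"
      p_out <- if (p_in == "L") "R" else "L"
      lid <- link_of[cur, p_out]
      if (is.na(lid)) {
        chain[[length(chain) + 1L]] <-
          data.frame(contig = contigs$id[cur], orientation = ori,
                     gap_after = NA_real_, support_after = NA_real_,
                     stringsAsFactors = FALSE)
        break
      }
      lk <- links[[lid]]
      chain[[length(chain) + 1L]] <-
        data.frame(contig = contigs$id[cur], orientation = ori,
                   gap_after = lk$gap, support_after = lk$support,
                   stringsAsFactors = FALSE)
      nxt <- if (lk$A == cur) lk$B else lk$A
      p_in <- if (lk$A == cur) lk$pB else lk$pA
      cur <- nxt
    }
    scaffolds[[length(scaffolds) + 1L]] <- do.call(rbind, chain)
  }
  left <- which(!visited)
  scaffolds <- c(scaffolds, singletons(contigs$id[left]))
  finish(scaffolds)
}

#' Scaffold sequences with gap markers
#'
#' @param scaffolds a `ScaffoldSet` from [scaffold_contigs()].
#' @param contigs the contig table the scaffolds refer to.
#' @param gap_mode `"estimated"` writes a run of N of the estimated gap
#'   length (at least one); `"single"` writes exactly one N per junction.
#' @return named character vector of scaffold sequences.
#' @export
scaffold_sequences <- function(scaffolds, contigs,
                               gap_mode = c("estimated", "single")) {
  gap_mode <- match.arg(gap_mode)
  seq_of <- stats::setNames(contigs$seq, contigs$id)
  out <- vapply(scaffolds, function(sc) {
    pieces <- character(0)
    for (i in seq_len(nrow(sc))) {
      s <- seq_of[[sc$contig[i]]]
      if (sc$orientation[i] == "-") s <- revcomp(s)
      pieces <- c(pieces, s)
      if (i < nrow(sc)) {
        ng <- if (gap_mode == "single") 1L else max(1L, round(sc$gap_after[i]))
        pieces <- c(pieces, strrep("N", ng))
      }
    }
    paste(pieces, collapse = "")
  }, "")
  names(out) <- sprintf("scaffold%03d", seq_along(out))
  out
}

#' N50 of a set of sequence lengths
#'
#' Length of the shortest sequence in the smallest set of longest sequences
#' whose combined length covers at least half the total.
#'
#' @param lengths numeric vector of sequence lengths.
#' @return the N50 (0 for empty input).
#' @export
n50 <- function(lengths) {
  lengths <- lengths[lengths > 0]
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Assembly statistics
#'
#' Contig and scaffold counts, N50s and total contig length, the metrics
#' conventionally reported for a short-read organelle assembly.
#'
#' @param contigs contig table from [build_contigs()].
#' @param scaffolds optional `ScaffoldSet`; scaffold lengths include
#'   estimated gaps.
#' @return an `AssemblyStats` list.
#' @export
assembly_metrics <- function(contigs, scaffolds = NULL) {
  sc_lengths <- if (!is.null(scaffolds) && length(scaffolds)) {
    nchar(scaffold_sequences(scaffolds, contigs, gap_mode = "estimated"))
  } else numeric(0)
  structure(list(
    n_contigs = nrow(contigs),
    n_scaffolds = length(sc_lengths),
    N50_contig = n50(contigs$length),
    N50_scaffold = n50(sc_lengths),
    total_contig_length = sum(contigs$length)
  ), class = "AssemblyStats")
}

#' @export
print.AssemblyStats <- function(x, ...) {
  cat(sprintf("AssemblyStats: %d contigs (N50 %s bp, total %s bp), %d scaffolds (N50 %s bp)\n",
              x$n_contigs, format(x$N50_contig, big.mark = ","),
              format(x$total_contig_length, big.mark = ","),
              x$n_scaffolds, format(x$N50_scaffold, big.mark = ",")))
  invisible(x)
}

#' Write assembly statistics as TSV
#' @param stats an `AssemblyStats`.
#' @param path output file.
#' @export
write_assembly_stats <- function(stats, path) {
  utils::write.table(as.data.frame(unclass(stats)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
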