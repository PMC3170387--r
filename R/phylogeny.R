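# Maximum-parsimony phylogeny: Fitch scoring, exhaustive topology search,
# bootstrap bipartition support and outgroup rooting. Gap and N characters
# are treated as missing data (compatible with every base).

state_codes <- c(A = 1L, C = 2L, G = 4L, T = 8L)

#' Build an aligned character matrix
#'
#' Accepts a taxa-by-columns character matrix, a named character vector of
#' equal-length aligned sequences, or the path of an aligned FASTA file.
#'
#' @param x matrix, named character vector, or FASTA path.
#' @return character matrix with taxon rownames.
#' @export
character_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(!is.null(rownames(x)))
    return(x)
  }
  if (is.character(x)) {
    if (length(x) == 1L && file.exists(x)) x <- read_fasta(x)
    stopifnot(!is.null(names(x)))
    if (length(unique(nchar(x))) != 1L) {
      stop("aligned sequences must have equal length")
    }
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
    return(m)
  }
  stop("cannot interpret input as a character matrix")
}

# Bit-encode states; anything outside A/C/G/T (gap, N, ambiguity) becomes
# the full state set 15 (missing data).
encode_states <- function(m) {
  e <- matrix(15L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (b in names(state_codes)) e[m == b] <- state_codes[[b]]
  e
}

# Site-pattern compression: unique columns plus weights, and the pattern id
# of every original column (for fast bootstrap reweighting).
compress_patterns <- function(e) {
  key <- do.call(paste, c(lapply(seq_len(nrow(e)), function(i) e[i, ]),
                          sep = ","))
  first <- !duplicated(key)
  grp <- match(key, key[first])
  list(patterns = e[, first, drop = FALSE],
       weights = tabulate(grp, nbins = sum(first)),
       pattern_of_col = grp)
}

# Precompute the postorder traversal of a topology for repeated Fitch
# scoring: root the unrooted binary tree along the first tip's edge.
fitch_prep <- function(tree, taxa) {
  if (!setequal(tree$tip.label, taxa)) {
    stop("taxon mismatch between matrix and topology")
  }
  tr <- tree
  if (!ape::is.rooted(tr) || !ape::is.binary(tr)) {
    tr <- ape::root(ape::unroot(tr), outgroup = sort(taxa)[1L],
                    resolve.root = TRUE)
  }
  tr <- stats::reorder(tr, "postorder")
  list(edge = tr$edge, n_tip = length(tr$tip.label),
       n_node = tr$Nnode, tip_taxon = tr$tip.label)
}

# Vectorised Fitch pass over site patterns. Returns the weighted parsimony
# length.
fitch_score <- function(prep, patterns, weights) {
  np <- ncol(patterns)
  S <- matrix(0L, prep$n_tip + prep$n_node, np)
  S[seq_len(prep$n_tip), ] <- patterns[prep$tip_taxon, , drop = FALSE]
  set <- c(rep(TRUE, prep$n_tip), rep(FALSE, prep$n_node))
  changes <- integer(np)
  for (i in seq_len(nrow(prep$edge))) {
    p <- prep$edge[i, 1L]; ch <- prep$edge[i, 2L]
    if (!set[p]) {
      S[p, ] <- S[ch, ]
      set[p] <- TRUE
    } else {
      inter <- bitwAnd(S[p, ], S[ch, ])
      z <- inter == 0L
      changes <- changes + z
      S[p, ] <- ifelse(z, bitwOr(S[p, ], S[ch, ]), inter)
    }
  }
  sum(changes * weights)
}

#' Fitch parsimony length of a topology
#'
#' Minimum number of character changes the tree requires, summed over
#' columns (Fitch's dynamic program on the binary-rooted version of the
#' topology; the count is invariant to the rooting). Gap/N states are
#' missing data and never force a change.
#'
#' @param matrix input for [character_matrix()].
#' @param topology an `ape` `phylo` object or a Newick string over exactly
#'   the matrix's taxa.
#' @return integer parsimony length.
#' @export
fitch_length <- function(matrix, topology) {
  m <- character_matrix(matrix)
  tree <- if (is.character(topology)) ape::read.tree(text = topology)
          else topology
  cp <- compress_patterns(encode_states(m))
  fitch_score(fitch_prep(tree, rownames(m)), cp$patterns, cp$weights)
}

#' Exhaustive maximum-parsimony tree search
#'
#' Enumerates every unrooted binary topology over the matrix's taxa (15 for
#' five taxa), scores each with Fitch parsimony and returns the optimum.
#' Ties are returned as the co-optimal set together with their strict
#' consensus. Above `exhaustive_bound` taxa the enumeration is refused
#' (heuristic search is out of scope).
#'
#' @param matrix input for [character_matrix()]; at least 4 taxa.
#' @param exhaustive_bound largest taxon count accepted (default 9).
#' @return list with `tree` (a best topology), `length`, `co_optimal`
#'   (multiPhylo of all optima), `consensus` (strict consensus of the
#'   optima) and `n_topologies`.
#' @export
mp_search <- function(matrix, exhaustive_bound = 9) {
  m <- character_matrix(matrix)
  n <- nrow(m)
  if (n < 4L) stop("tree search needs at least 4 taxa")
  if (n > exhaustive_bound) {
    stop("more than ", exhaustive_bound,
         " taxa: exhaustive search refused; reduce the taxon set")
  }
  cp <- compress_patterns(encode_states(m))
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(m))
  preps <- lapply(trees, fitch_prep, taxa = rownames(m))
  scores <- vapply(preps, fitch_score, 0, patterns = cp$patterns,
                   weights = cp$weights)
  best <- which(scores == min(scores))
  co <- trees[best]
  class(co) <- "multiPhylo"
  consensus <- if (length(best) > 1L) ape::consensus(co, p = 1)
               else co[[1L]]
  list(tree = co[[1L]], length = min(scores), co_optimal = co,
       consensus = consensus, n_topologies = length(trees))
}

# Non-trivial bipartition keys of a topology; each key is the sorted tip
# set on the side not containing the alphabetically first taxon.
tree_bipartitions <- function(tree) {
  taxa <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  lab <- attr(parts, "labels")
  keys <- character(0)
  for (p in parts) {
    side <- lab[p]
    if (taxa[1L] %in% side) side <- setdiff(lab, side)
    if (length(side) < 2L || length(side) > length(lab) - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for the maximum-parsimony tree
#'
#' Resamples alignment columns with replacement, repeats the exhaustive
#' parsimony search per replicate, and records how often each internal
#' bipartition of the original best tree occurs in the replicate's optimum
#' (the strict consensus when a replicate has ties). Supports are mapped
#' onto the best tree's internal nodes as percentages. Deterministic per
#' seed.
#'
#' @param matrix input for [character_matrix()].
#' @param reps bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @param exhaustive_bound passed to [mp_search()].
#' @return list with `tree` (best tree, node labels = support), `support`
#'   (named vector, percent per bipartition), `length`, `reps`.
#' @export
bootstrap_support <- function(matrix, reps = 1000, seed = 1,
                              exhaustive_bound = 9) {
  m <- character_matrix(matrix)
  n <- nrow(m)
  if (n < 4L) stop("tree search needs at least 4 taxa")
  if (n > exhaustive_bound) {
    stop("more than ", exhaustive_bound, " taxa: exhaustive search refused")
  }
  cp <- compress_patterns(encode_states(m))
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(m))
  preps <- lapply(trees, fitch_prep, taxa = rownames(m))
  scores <- vapply(preps, fitch_score, 0, patterns = cp$patterns,
                   weights = cp$weights)
  best_idx <- which.min(scores)
  best_tree <- trees[[best_idx]]
  keys <- tree_bipartitions(best_tree)
  counts <- stats::setNames(numeric(length(keys)), keys)
  np <- ncol(cp$patterns)
  ncols <- ncol(m)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      cols <- sample.int(ncols, replace = TRUE)
      w <- tabulate(cp$pattern_of_col[cols], nbins = np)
      sc <- vapply(preps, fitch_score, 0, patterns = cp$patterns,
                   weights = w)
      opt <- which(sc == min(sc))
      rep_keys <- if (length(opt) == 1L) {
        tree_bipartitions(trees[[opt]])
      } else {
        co <- trees[opt]
        class(co) <- "multiPhylo"
        tree_bipartitions(ape::consensus(co, p = 1))
      }
      hit <- keys %in% rep_keys
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / reps
  # attach supports to internal nodes of the best tree
  parts <- ape::prop.part(best_tree)
  lab <- attr(parts, "labels")
  taxa <- sort(best_tree$tip.label)
  node_lab <- vapply(parts, function(p) {
    side <- lab[p]
    if (taxa[1L] %in% side) side <- setdiff(lab, side)
    if (length(side) < 2L || length(side) > length(lab) - 2L) return("")
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) sprintf("%g", support[[key]]) else ""
  }, "")
  best_tree$node.label <- node_lab
  list(tree = best_tree, support = support, length = scores[best_idx],
       reps = reps)
}

#' Root a tree with an outgroup
#'
#' Places the root on the outgroup's pendant edge and reports the ingroup
#' branching order from the most basal lineage to the terminal cherry.
#'
#' @param tree a `phylo` object.
#' @param outgroup outgroup taxon name (must be in the tree).
#' @return list with `tree` (rooted `phylo`) and `order` (list of character
#'   vectors: successive lineages split off along the ingroup spine, ending
#'   with the terminal group).
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("unknown outgroup taxon: ", outgroup)
  }
  rt <- ape::root(ape::unroot(tree), outgroup = outgroup,
                  resolve.root = TRUE)
  # walk the ingroup spine, splitting off the smaller side at each node
  tips_under <- function(node) {
    if (node <= length(rt$tip.label)) return(rt$tip.label[node])
    kids <- rt$edge[rt$edge[, 1L] == node, 2L]
    unlist(lapply(kids, tips_under))
  }
  root_node <- length(rt$tip.label) + 1L
  kids <- rt$edge[rt$edge[, 1L] == root_node, 2L]
  og_side <- vapply(kids, function(k) outgroup %in% tips_under(k), TRUE)
  node <- kids[!og_side][1L]
  order <- list()
  while (node > length(rt$tip.label)) {
    kids <- rt$edge[rt$edge[, 1L] == node, 2L]
    sizes <- vapply(kids, function(k) length(tips_under(k)), 0L)
    if (all(sizes == sizes[1L])) {
      order[[length(order) + 1L]] <- sort(unlist(lapply(kids, tips_under)))
      node <- 0L
      break
    }
    small <- kids[which.min(sizes)]
    order[[length(order) + 1L]] <- sort(tips_under(small))
    node <- kids[which.max(sizes)]
  }
  if (node > 0L) order[[length(order) + 1L]] <- rt$tip.label[node]
  list(tree = rt, order = order)
}

#' Project genomes onto a backbone to build an aligned matrix
#'
#' Aligns every genome pairwise to a chosen backbone and projects the
#' aligned bases onto the backbone's coordinates (insertions relative to
#' the backbone are dropped, deletions become gaps), producing the aligned
#' character matrix used for tree inference.
#'
#' @param genomes named character vector/list of genome sequences.
#' @param backbone name of the backbone genome (default: the first).
#' @param ... passed to [pairwise_genome_align()].
#' @return character matrix (taxa x backbone positions).
#' @export
project_to_backbone <- function(genomes, backbone = names(genomes)[1],
                                ...) {
  genomes <- as.list(genomes)
  stopifnot(backbone %in% names(genomes))
  bb <- genomes[[backbone]]
  rows <- list()
  rows[[backbone]] <- strsplit(bb, "", fixed = TRUE)[[1]]
  for (nm in setdiff(names(genomes), backbone)) {
    aln <- pairwise_genome_align(bb, genomes[[nm]], ...)
    ca <- strsplit(aln$a_aligned, "", fixed = TRUE)[[1]]
    cb <- strsplit(aln$b_aligned, "", fixed = TRUE)[[1]]
    rows[[nm]] <- cb[ca != "-"]
  }
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  m
}

#' Write a tree in Newick format
#' @param tree a `phylo` (node labels, e.g. bootstrap supports, are kept).
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a tree from a Newick file
#' @param path Newick file.
#' @return a `phylo`.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
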