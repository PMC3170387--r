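# Independent oracles and fixture builders used across the suite.

# Brute-force read mapper: every offset, both strands, mismatch count by
# direct character comparison. The reference implementation the seed-and-
# extend mapper must agree with.
brute_force_map <- function(tag, reference, max_mismatch_frac = 0.1) {
  L <- nchar(tag)
  max_mm <- floor(max_mismatch_frac * L)
  ref_chars <- strsplit(reference, "")[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    t_chars <- strsplit(if (strand == "+") tag else revcomp(tag), "")[[1]]
    for (pos in seq_len(nchar(reference) - L + 1L)) {
      mm <- sum(t_chars != ref_chars[pos:(pos + L - 1L)])
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(
          pos = pos, strand = strand, mismatches = mm, length = L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pos = integer(0), strand = character(0),
                      mismatches = integer(0), length = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$pos, res$strand), , drop = FALSE]
}

# Naive event-log replay by right-to-left string surgery, independent of
# the package's alignment-based construction.
naive_replay <- function(core, log) {
  if (!nrow(log)) return(core)
  # right-to-left surgery; an insertion after position p edits to the right
  # of p, so at equal positions it must be applied before a deletion at p
  key <- log$pos + 0.5 * (log$kind == "insertion")
  log <- log[order(-key), , drop = FALSE]
  for (i in seq_len(nrow(log))) {
    p <- log$pos[i]
    if (log$kind[i] == "substitution") {
      stopifnot(substr(core, p, p) == log$ancestral[i])
      substr(core, p, p) <- log$derived[i]
    } else if (log$kind[i] == "deletion") {
      e <- p + nchar(log$ancestral[i]) - 1L
      stopifnot(substr(core, p, e) == log$ancestral[i])
      core <- paste0(substr(core, 1L, p - 1L), substring(core, e + 1L))
    } else if (log$kind[i] == "insertion") {
      core <- paste0(substr(core, 1L, p), log$derived[i],
                     substring(core, p + 1L))
    }
  }
  core
}

# Exhaustive Fitch oracle: minimum over all internal-node labelings of the
# number of state changes along edges. Missing tips (encoded 15) match any
# state. Tree must be binary (rooted internally for enumeration; the
# minimum is rooting-invariant).
brute_force_fitch_column <- function(tree, states) {
  tr <- ape::reorder.phylo(
    ape::root(ape::unroot(tree), outgroup = sort(tree$tip.label)[1L],
              resolve.root = TRUE), "postorder")
  n_tip <- length(tr$tip.label)
  n_int <- tr$Nnode
  bases <- c(1L, 2L, 4L, 8L)
  grid <- as.matrix(expand.grid(rep(list(bases), n_int)))
  tip_state <- states[tr$tip.label]
  cost <- numeric(nrow(grid))
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L] - n_tip
    ch <- tr$edge[i, 2L]
    ps <- grid[, p]
    if (ch <= n_tip) {
      s <- tip_state[[ch]]
      if (s == 15L) next  # missing: compatible with anything
      cost <- cost + (bitwAnd(ps, s) == 0L)
    } else {
      cost <- cost + (ps != grid[, ch - n_tip])
    }
  }
  min(cost)
}

brute_force_fitch <- function(tree, m) {
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  enc <- matrix(15L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (b in names(code)) enc[m == b] <- code[[b]]
  sum(vapply(seq_len(ncol(enc)), function(j) {
    brute_force_fitch_column(tree, enc[, j])
  }, 0))
}

# Random aligned character matrix with optional missing data.
random_matrix <- function(n_taxa, n_cols, missing = 0.05) {
  m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_cols, TRUE),
              n_taxa, n_cols)
  if (missing > 0) {
    miss <- stats::runif(length(m)) < missing
    m[miss] <- sample(c("-", "N"), sum(miss), TRUE)
  }
  rownames(m) <- paste0("t", seq_len(n_taxa))
  m
}

# Manual mate-pair library builder for controlled QC/scaffolding fixtures.
make_library <- function(tagF, tagR, qvF, qvR, insert_mean = 1500,
                         insert_sd = 150, orientation = "inward",
                         origin = NULL) {
  qstr <- function(q) {
    vapply(q, function(v) intToUtf8(as.integer(v) + 33L), "")
  }
  plastomics:::new_mate_pair_library(
    tagF = tagF, tagR = tagR, qualF = qstr(qvF), qualR = qstr(qvR),
    origin = origin, tag_length = max(nchar(tagF)),
    insert_mean = insert_mean, insert_sd = insert_sd,
    orientation = orientation
  )
}

# Uniform-quality helper: one QV vector per tag at a constant value.
flat_qv <- function(n, len, qv) replicate(n, rep(qv, len), simplify = FALSE)

# Fraction of identical columns in a pairwise alignment of two sequences.
aligned_identity <- function(a, b, ...) {
  aln <- pairwise_genome_align(a, b, ...)
  ca <- strsplit(aln$a_aligned, "")[[1]]
  cb <- strsplit(aln$b_aligned, "")[[1]]
  mean(ca == cb & ca != "-")
}
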