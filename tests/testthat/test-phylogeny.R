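# Maximum-parsimony phylogeny: Fitch scoring against a brute-force oracle,
# exhaustive search, bootstrap support and outgroup rooting.

test_that("the A,A,G,G column scores 1 and 2 on the two 4-taxon topologies", {
  m <- matrix(c("A", "A", "G", "G"), 4, 1,
              dimnames = list(c("t1", "t2", "t3", "t4"), NULL))
  expect_equal(fitch_length(m, "((t1,t2),(t3,t4));"), 1)
  expect_equal(fitch_length(m, "((t1,t3),(t2,t4));"), 2)
  # invariant column contributes nothing; missing is compatible with anything
  mi <- matrix(c("C", "C", "C", "C"), 4, 1,
               dimnames = list(c("t1", "t2", "t3", "t4"), NULL))
  expect_equal(fitch_length(mi, "((t1,t2),(t3,t4));"), 0)
  mm <- matrix(c("A", "A", "-", "A"), 4, 1,
               dimnames = list(c("t1", "t2", "t3", "t4"), NULL))
  expect_equal(fitch_length(mm, "((t1,t3),(t2,t4));"), 0)
})

test_that("Fitch length equals the exhaustive labeling minimum on random matrices", {
  set.seed(110)
  for (i in 1:200) {
    n_taxa <- sample(4:6, 1)
    m <- random_matrix(n_taxa, sample(5:30, 1))
    tr <- ape::rtree(n_taxa, tip.label = sample(rownames(m)), br = NULL)
    expect_equal(fitch_length(m, tr), brute_force_fitch(tr, m))
  }
})

test_that("Fitch length agrees with an independent parsimony implementation", {
  set.seed(111)
  for (i in 1:10) {
    m <- random_matrix(5, 80)
    tr <- ape::rtree(5, tip.label = rownames(m), br = NULL)
    pd <- phangorn::phyDat(m, type = "DNA")
    expect_equal(fitch_length(m, tr),
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})

test_that("exhaustive search enumerates all topologies and finds the optimum", {
  set.seed(112)
  m4 <- random_matrix(4, 40, missing = 0)
  s4 <- mp_search(m4)
  expect_equal(s4$n_topologies, 3L)
  m5 <- random_matrix(5, 40, missing = 0)
  s5 <- mp_search(m5)
  expect_equal(s5$n_topologies, 15L)
  # the optimum really is minimal over the enumeration
  all5 <- phangorn::allTrees(5, rooted = FALSE, tip.label = rownames(m5))
  scores <- vapply(all5, function(t) fitch_length(m5, t), 0)
  expect_equal(s5$length, min(scores))

  # all-invariant matrix: every topology ties at length 0
  mi <- matrix("A", 5, 30, dimnames = list(paste0("t", 1:5), NULL))
  si <- mp_search(mi)
  expect_equal(si$length, 0)
  expect_equal(length(si$co_optimal), 15L)

  expect_error(mp_search(random_matrix(3, 10)), "at least 4")
  expect_error(mp_search(random_matrix(10, 10)), "exhaustive")
})

test_that("search recovers the generating topology and ignores taxon order", {
  set.seed(113)
  taxa <- c("S.pol", "L.min", "W.lin", "W.aus", "P.dac")
  base <- sample(c("A", "C", "G", "T"), 1500, TRUE)
  M <- matrix(rep(base, each = 5), 5, 1500, dimnames = list(taxa, NULL))
  mutate <- function(M, rows, n) {
    cols <- sample(ncol(M), n)
    for (cc in cols) M[rows, cc] <- sample(c("A", "C", "G", "T"), 1)
    M
  }
  M <- mutate(M, c("W.lin", "W.aus"), 90)
  M <- mutate(M, c("L.min", "W.lin", "W.aus"), 90)
  M <- mutate(M, "P.dac", 150)
  s <- mp_search(M)
  expect_equal(length(s$co_optimal), 1L)
  truth <- ape::read.tree(text = "(((W.lin,W.aus),L.min),S.pol,P.dac);")
  expect_equal(ape::dist.topo(ape::unroot(s$tree), ape::unroot(truth))[1], 0)
  # taxon input order does not change the result
  s2 <- mp_search(M[c(3, 5, 1, 4, 2), ])
  expect_equal(ape::dist.topo(ape::unroot(s2$tree), ape::unroot(s$tree))[1], 0)
})

test_that("bootstrap supports behave at the edges and are seed-deterministic", {
  set.seed(114)
  taxa <- paste0("t", 1:5)
  # overwhelming signal: every column consistent with one tree
  col_ab <- c("A", "A", "C", "C", "C"); col_de <- c("G", "G", "G", "T", "T")
  M <- cbind(matrix(rep(col_ab, 30), 5), matrix(rep(col_de, 30), 5))
  rownames(M) <- taxa
  bs <- bootstrap_support(M, reps = 50, seed = 7)
  expect_true(all(bs$support == 100))

  # a single replicate gives supports of exactly 0 or 100
  bs1 <- bootstrap_support(M, reps = 1, seed = 8)
  expect_true(all(bs1$support %in% c(0, 100)))

  M2 <- random_matrix(5, 120, missing = 0)
  a <- bootstrap_support(M2, reps = 40, seed = 9)
  b <- bootstrap_support(M2, reps = 40, seed = 9)
  expect_identical(a$support, b$support)
  expect_true(all(a$support >= 0 & a$support <= 100))
})

test_that("bootstrap support grows with signal strength", {
  set.seed(115)
  taxa <- c("A1", "A2", "B1", "B2", "OG")
  make_m <- function(n_signal) {
    ncols <- 400
    base <- matrix(rep(sample(c("A", "C", "G", "T"), ncols, TRUE),
                       each = 5), 5, ncols)
    rownames(base) <- taxa
    noise_cols <- sample(ncols, 60)
    for (cc in noise_cols) base[sample(5, 1), cc] <- sample(c("A","C","G","T"), 1)
    sig <- sample(setdiff(seq_len(ncols), noise_cols), n_signal)
    for (cc in sig) base[c("A1", "A2"), cc] <- "T"
    base
  }
  # bipartition keys are canonicalised to the side not containing the
  # alphabetically first taxon, so the A1+A2 split is keyed by its
  # complement
  key <- "B1|B2|OG"
  sup <- vapply(c(2, 6, 20), function(k) {
    bs <- bootstrap_support(make_m(k), reps = 60, seed = 10)
    if (key %in% names(bs$support)) bs$support[[key]] else 0
  }, 0)
  expect_true(sup[1] <= sup[2] && sup[2] <= sup[3])
  expect_gt(sup[3], 90)
})

test_that("outgroup rooting places the outgroup basally and is idempotent", {
  tr <- ape::read.tree(text = "(((W.lin,W.aus),L.min),S.pol,P.dac);")
  rt <- root_with_outgroup(tr, "P.dac")
  root_node <- length(rt$tree$tip.label) + 1L
  kids <- rt$tree$edge[rt$tree$edge[, 1] == root_node, 2]
  og_is_child <- any(vapply(kids, function(k) {
    k <= length(rt$tree$tip.label) &&
      rt$tree$tip.label[k] == "P.dac"
  }, TRUE))
  expect_true(og_is_child)
  # basal-to-derived ingroup listing: Spirodela first, Wolffia cherry last
  expect_equal(rt$order[[1]], "S.pol")
  expect_equal(rt$order[[2]], "L.min")
  expect_setequal(rt$order[[3]], c("W.aus", "W.lin"))
  rt2 <- root_with_outgroup(rt$tree, "P.dac")
  expect_true(ape::all.equal.phylo(rt$tree, rt2$tree, use.edge.length = FALSE))
  expect_error(root_with_outgroup(tr, "nope"), "unknown")
})

test_that("backbone projection yields an aligned matrix over backbone coordinates", {
  set.seed(116)
  bb <- random_dna(4000)
  g2 <- bb
  substr(g2, 2001, 2001) <- if (substr(bb, 2001, 2001) == "A") "G" else "A"
  g3 <- paste0(substr(bb, 1, 1000), substring(bb, 1051))  # 50 nt deletion
  m <- project_to_backbone(list(ref = bb, x = g2, y = g3))
  expect_equal(dim(m), c(3L, 4000L))
  expect_identical(paste(m["ref", ], collapse = ""), bb)
  expect_equal(sum(m["x", ] != m["ref", ]), 1L)
  expect_equal(sum(m["y", ] == "-"), 50L)
})

test_that("trees round-trip through Newick with support labels", {
  tr <- ape::read.tree(text = "((t1,t2)95,(t3,t4)87);")
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(back$tip.label, tr$tip.label)
  expect_equal(back$node.label, tr$node.label)
  unlink(f)
})
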