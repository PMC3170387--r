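# Finishing: reference-collinear ordering, reiteration, primer design, gap
# closure, and inverted-repeat reconstruction.

as_contig_table <- function(seqs) {
  data.frame(id = sprintf("contig%04d", seq_along(seqs)), seq = seqs,
             length = nchar(seqs), coverage = 50, stringsAsFactors = FALSE)
}

singleton_scaffolds <- function(ids) {
  structure(lapply(ids, function(i) {
    data.frame(contig = i, orientation = "+", gap_after = NA_real_,
               support_after = NA_real_, stringsAsFactors = FALSE)
  }), class = "ScaffoldSet")
}

test_that("shuffled flipped partition of a reference reorders to the reference", {
  set.seed(70)
  ref <- random_dna(12000)
  bounds <- c(1, sort(sample(2000:10000, 3)), 12001)
  pieces <- substring(ref, bounds[-5], bounds[-1] - 1)
  ord <- sample(4)
  flip <- c(TRUE, FALSE, TRUE, FALSE)
  ctg <- as_contig_table(ifelse(flip, revcomp(pieces[ord]), pieces[ord]))
  pm <- order_against_reference(singleton_scaffolds(ctg$id), ctg, ref)
  expect_identical(gsub("N", "", pm$sequence), ref)
  expect_equal(length(pm$gaps), 3L)   # one N per neighbour junction
  expect_equal(length(pm$unplaced), 0L)
  # provenance tiles the non-N sequence without overlap
  prov <- pm$provenance[order(pm$provenance$start), ]
  expect_true(all(prov$start[-1] > prov$end[-nrow(prov)]))
})

test_that("a single contig passes through without gap characters", {
  set.seed(71)
  ref <- random_dna(5000)
  ctg <- as_contig_table(substr(ref, 101, 4900))
  pm <- order_against_reference(singleton_scaffolds(ctg$id), ctg, ref)
  expect_identical(pm$sequence, ctg$seq[1])
  expect_equal(length(pm$gaps), 0L)
})

test_that("a chimeric scaffold is split at its gap and reordered", {
  set.seed(72)
  ref <- random_dna(90000)
  pieceA <- substr(ref, 9000, 12000)    # ~10 kb region
  pieceB <- substr(ref, 78000, 81000)   # ~80 kb region
  ctg <- as_contig_table(c(pieceA, pieceB))
  chimera <- structure(list(data.frame(
    contig = ctg$id, orientation = c("+", "+"),
    gap_after = c(10, NA), support_after = c(130, NA),
    stringsAsFactors = FALSE)), class = "ScaffoldSet")
  pm <- order_against_reference(chimera, ctg, ref)
  expect_equal(length(pm$gaps), 1L)
  expect_identical(gsub("N", "", pm$sequence), paste0(pieceA, pieceB))
})

test_that("unanchored contigs are reported, never silently placed", {
  set.seed(73)
  ref <- random_dna(6000)
  ctg <- as_contig_table(c(substr(ref, 1000, 3000), random_dna(800)))
  pm <- order_against_reference(singleton_scaffolds(ctg$id), ctg, ref)
  expect_identical(pm$unplaced, "contig0002")
  expect_false(grepl(ctg$seq[2], pm$sequence, fixed = TRUE))
  ctg_none <- as_contig_table(random_dna(900))
  expect_error(order_against_reference(singleton_scaffolds(ctg_none$id),
                                       ctg_none, ref), "reference")
})

test_that("reiteration is a fixed point at zero divergence and recaptures reads", {
  p <- simulate_plastome(0.1, 0, seed = 74)
  core <- plastome_core(p)
  lib <- simulate_mate_pairs(plastome_sequence(p), n_pairs = 18000,
                             circular = TRUE, seed = 75)
  fq <- filter_mate_pairs(lib)$library
  ap <- assembly_params(min_pair_count = 5)
  sel1 <- select_anchored_pairs(fq, core)
  ctg1 <- build_contigs(c(sel1$library$tagF, sel1$library$tagR), ap)
  sc1 <- scaffold_contigs(ctg1, sel1$library, ap)
  pm1 <- order_against_reference(sc1, ctg1, core)
  it <- reiterate(fq, pm1, core, ap)
  # pass-2 selection retains a superset of pass-1 retained pairs
  expect_true(all(sel1$library$id %in% it$library$id))
  expect_setequal(it$contigs$seq, ctg1$seq)  # fixed point: same contig set
  expect_lte(length(it$pseudomolecule$gaps), length(pm1$gaps))
})

test_that("primer design respects Tm bounds, orientation and run filters", {
  expect_equal(wallace_tm(paste0(strrep("G", 5), strrep("C", 5),
                                 strrep("AT", 5))), 4 * 10 + 2 * 10)
  set.seed(76)
  seq <- paste0(random_dna(600), "N", random_dna(600))
  pr <- design_gap_primers(seq, flank_len = 500)
  expect_equal(pr$status, "designed")
  expect_gte(pr$tm_fwd, 52); expect_lte(pr$tm_fwd, 60)
  expect_gte(pr$tm_rev, 52); expect_lte(pr$tm_rev, 60)
  # forward primer is a left-flank substring; reverse primer is the
  # reverse complement of a right-flank window (facing each other)
  expect_true(grepl(pr$fwd, substr(seq, 101, 600), fixed = TRUE))
  expect_true(grepl(revcomp(pr$rev), substring(seq, 602), fixed = TRUE))
  expect_gt(pr$product_span, 0)

  # mononucleotide-run flank is undesignable
  runseq <- paste0(strrep("A", 600), "N", strrep("T", 600))
  pr2 <- design_gap_primers(runseq, flank_len = 500)
  expect_equal(pr2$status, "undesignable")
  # gap too close to the molecule end is flagged
  edge <- paste0(random_dna(50), "N", random_dna(600))
  pr3 <- design_gap_primers(edge, flank_len = 500)
  expect_equal(pr3$status, "too_close_to_end")
})

test_that("gap closure recovers the truth and counts planted discrepancies", {
  set.seed(77)
  truth <- random_dna(2400)
  gap_at <- 1200
  pm <- paste0(substr(truth, 1, gap_at - 101), "N",
               substring(truth, gap_at))
  # identical spanning read: closes with zero discrepancy
  read <- substr(truth, 500, 1900)
  cl <- close_gaps(pm, c(fin1 = read), min_overlap = 100)
  expect_identical(cl$sequence, truth)
  expect_equal(cl$report$mismatches, 0L)
  expect_equal(cl$report$rate, 0)

  # overlap of 1000 columns with exactly one planted mismatch: rate 0.001
  truth2 <- random_dna(1001)
  pm2 <- paste0(substr(truth2, 1, 500), "N", substring(truth2, 502))
  read2 <- truth2
  at <- 200
  b <- substr(read2, at, at)
  substr(read2, at, at) <- setdiff(c("A", "C", "G", "T"), b)[1]
  cl2 <- close_gaps(pm2, c(fin1 = read2), min_overlap = 100,
                    seed_k = 21, max_mismatch_rate = 0.02)
  expect_equal(cl2$report$overlap_length, 1000L)
  expect_equal(cl2$report$mismatches, 1L)
  expect_equal(cl2$report$rate, 0.001)

  # non-gap columns are never modified (masking comparison)
  masked_in <- strsplit(pm2, "")[[1]]
  masked_out <- strsplit(cl2$sequence, "")[[1]]
  expect_identical(masked_out[-501], masked_in[-501])
})

test_that("a read anchoring only one flank leaves the gap open", {
  set.seed(78)
  truth <- random_dna(2000)
  pm <- paste0(substr(truth, 1, 999), "N", substring(truth, 1001))
  short_read <- substr(truth, 100, 980)  # left flank only
  cl <- close_gaps(pm, c(fin1 = short_read))
  expect_equal(cl$gaps$status, "open")
  expect_identical(cl$sequence, pm)
})

test_that("inverted-repeat reconstruction round-trips the simulated genome", {
  p <- simulate_plastome(0.1, 8, seed = 79)
  core <- plastome_core(p)
  reg <- plastome_regions(p)
  ira <- c(reg$start[2], reg$end[2])
  out <- add_inverted_repeat(core, ir_range = ira)
  expect_equal(nchar(out$sequence), nchar(core) + (ira[2] - ira[1] + 1))
  expect_identical(substring(out$sequence, out$irb[1]),
                   revcomp(substr(out$sequence, out$ira[1], out$ira[2])))
  expect_identical(out$sequence, plastome_sequence(p))
  expect_true(out$circular)
  # strip IRb -> add it back -> identical
  expect_identical(add_inverted_repeat(exclude_irb(p), ir_range = ira)$sequence,
                   plastome_sequence(p))
  expect_error(add_inverted_repeat(core), "IRa")
})

test_that("IR detection finds the annotated repeat pair", {
  p <- simulate_plastome(0.1, 0, seed = 80)
  det <- detect_inverted_repeat(plastome_sequence(p))
  reg <- plastome_regions(p)
  # the maximal repeat may extend a base or two past the annotated
  # boundary when a flanking base happens to complement its partner
  expect_lte(max(abs(det$ira - c(reg$start[2], reg$end[2]))), 2)
  expect_lte(max(abs(det$irb - c(reg$start[4], reg$end[4]))), 2)
  expect_error(detect_inverted_repeat(random_dna(5000)), "inverted repeat")
})
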