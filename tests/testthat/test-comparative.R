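# Comparative module: anchored pairwise alignment, substitution
# classification and divergence statistics.

test_that("self-alignment is the identity", {
  set.seed(90)
  a <- random_dna(3000)
  aln <- pairwise_genome_align(a, a)
  d <- divergence_stats(aln)
  expect_equal(d$alignment_length, 3000L)
  expect_equal(d$substitutions, 0L)
  expect_equal(d$indels_length, 0L)
  expect_true(is.na(d$R))
})

test_that("a deleted block reappears as exactly that many gap columns", {
  set.seed(91)
  a <- random_dna(4000)
  b <- paste0(substr(a, 1, 1800), substring(a, 1901))
  aln <- pairwise_genome_align(a, b)
  d <- divergence_stats(aln)
  expect_equal(d$indels_length, 100L)
  expect_equal(d$alignment_length, 4000L)
  expect_equal(d$substitutions, 0L)
})

test_that("anchored alignment attains the full quadratic DP score", {
  set.seed(92)
  for (i in 1:3) {
    a <- random_dna(1800)
    ch <- strsplit(a, "")[[1]]
    at <- sample(1800, 70)
    ch[at] <- vapply(ch[at],
                     function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    b <- paste(ch, collapse = "")
    b <- paste0(substr(b, 1, 700), substring(b, 726))       # 25 nt deletion
    b <- paste0(substr(b, 1, 1200), random_dna(40), substring(b, 1201))
    aln <- pairwise_genome_align(a, b)
    expect_identical(gsub("-", "", aln$a_aligned), a)
    expect_identical(gsub("-", "", aln$b_aligned), b)
    full <- Biostrings::pairwiseAlignment(
      a, b, type = "global",
      substitutionMatrix = plastomics:::nucleotide_matrix(1, -1),
      gapOpening = 2, gapExtension = 0.25)
    expect_equal(aln$score, Biostrings::score(full))
  }
})

test_that("hand-enumerated columns classify into si and sv correctly", {
  # ACGT vs GCTT: A<->G transition, G<->T transversion
  d <- divergence_stats(list(A = "ACGT", B = "GCTT"))
  expect_equal(d$substitutions, 2L)
  expect_equal(d$si, 1L)
  expect_equal(d$sv, 1L)
  expect_equal(d$R, 1)
  expect_equal(d$substitution_rate, 0.5)

  # gap and N columns never contribute to si/sv
  d2 <- divergence_stats(list(A = "A-GTNA", B = "AC-TCG"))
  expect_equal(d2$alignment_length, 6L)
  expect_equal(d2$indels_length, 2L)
  expect_equal(d2$si, 1L)   # the final A:G column; the N column is excluded
  expect_equal(d2$sv, 0L)
  d3 <- divergence_stats(list(A = "AAAA", B = "AAAA"))
  expect_true(is.na(d3$R))
  d4 <- divergence_stats(list(A = "AC", B = "GT"))  # A>G ti, C>T ti
  expect_equal(d4$si, 2L)
  expect_equal(d4$R, Inf)
})

test_that("published component counts reproduce the printed derived ratios", {
  expect_equal(pairwise_divergence(141014,
                                   indels_length = 10262)$report$indel_ratio,
               0.073)
  expect_equal(pairwise_divergence(115940,
                                   indels_length = 4365)$report$indel_ratio,
               0.038)
})

test_that("si + sv equals the substitution count on random alignments", {
  set.seed(93)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    A <- sample(c("A", "C", "G", "T", "-", "N"), n, TRUE,
                prob = c(.22, .22, .22, .22, .08, .04))
    B <- sample(c("A", "C", "G", "T", "-", "N"), n, TRUE,
                prob = c(.22, .22, .22, .22, .08, .04))
    # no double-gap columns
    both <- A == "-" & B == "-"
    B[both] <- "A"
    d <- divergence_stats(list(A = paste(A, collapse = ""),
                               B = paste(B, collapse = "")))
    expect_equal(d$si + d$sv, d$substitutions)
    expect_equal(d$indels_length, sum(A == "-") + sum(B == "-"))
    expect_gte(d$substitution_rate, 0); expect_lte(d$substitution_rate, 1)
    expect_gte(d$indel_ratio, 0)
  }
})

test_that("divergence estimates recover the generating parameters", {
  anc <- simulate_plastome(0.3, 0, seed = 94)  # ~39 kb core
  params <- evolution_params(substitution_rate = 0.05, R_target = 0.7,
                             indel_rate = indel_rate_for_ratio(0.073),
                             seed = 95)
  ev <- evolve_genome(anc, params)
  est <- divergence_stats(pairwise_genome_align(plastome_core(anc),
                                                plastome_core(ev$genome)))
  n <- est$alignment_length
  expect_lt(abs(est$substitution_rate - 0.05), 3 * sqrt(.05 * .95 / n))
  p_ti <- 0.7 / 1.7
  se_R <- sqrt(p_ti * (1 - p_ti) / est$substitutions) * (1 + 0.7)^2
  expect_lt(abs(est$R - 0.7), 3 * se_R)
})

test_that("IRb exclusion by detection agrees with annotation-based trimming", {
  p <- simulate_plastome(0.1, 10, seed = 96)
  full <- plastome_sequence(p)
  reg <- plastome_regions(p)
  by_annot <- exclude_irb(full, annotation = c(reg$start[4], reg$end[4]))
  by_detect <- exclude_irb(full)
  expect_identical(by_annot, plastome_core(p))
  expect_identical(exclude_irb(p), plastome_core(p))
  # detection may shift each junction by a base or two when flanking bases
  # happen to extend the repeat
  expect_lte(abs(nchar(by_detect) - nchar(by_annot)), 4)
  common <- min(nchar(by_detect), nchar(by_annot)) - 4L
  expect_identical(substr(by_detect, 1, common), substr(by_annot, 1, common))
})

test_that("coding concatenation respects order, strand and additivity", {
  set.seed(97)
  g <- random_dna(5000)
  feats <- data.frame(
    name = c("g1", "g2", "g3"),
    start = c(101, 1001, 3001), end = c(400, 1600, 3900),
    strand = c("+", "-", "+"), kind = "gene", stringsAsFactors = FALSE)
  cc <- concatenate_coding(g, feats)
  expect_equal(cc$n_genes, 3L)
  expect_equal(cc$total_length, 300 + 600 + 900)
  expect_identical(cc$sequence, paste0(substr(g, 101, 400),
                                       revcomp(substr(g, 1001, 1600)),
                                       substr(g, 3001, 3900)))
  # simulated annotation: extraction equals truth genes
  p <- simulate_plastome(0.1, 12, seed = 98)
  cc2 <- concatenate_coding(p)
  expect_equal(cc2$n_genes, nrow(p$features))
  expect_equal(cc2$total_length,
               sum(p$features$end - p$features$start + 1))
  over <- feats
  over$start[2] <- 350  # overlap with g1
  expect_warning(concatenate_coding(g, over), "overlap")
})

test_that("per-window identity flags the diverged window", {
  set.seed(99)
  a <- random_dna(3000)
  b <- a
  substr(b, 1501, 1600) <- paste(sample(c("A","C","G","T"), 100, TRUE),
                                 collapse = "")
  aln <- pairwise_genome_align(a, b)
  iw <- identity_windows(aln, window = 500)
  expect_equal(nrow(iw), ceiling(nchar(aln$a_aligned) / 500))
  worst <- which.min(iw$identity)
  # the diverged block (columns ~1501-1600) sits inside the worst window
  expect_lte(iw$window_start[worst], 1650)
  expect_gte(iw$window_end[worst], 1500)
  expect_lt(iw$identity[worst], 0.95)
  expect_true(all(iw$identity[-worst] > 0.9))
})
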