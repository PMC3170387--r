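# Synthetic-data module: plastome architecture, controlled evolution with
# an exact event log, and total-DNA mate-pair libraries.

test_that("simulated plastome has the quadripartite architecture and scales", {
  p <- simulate_plastome(size_factor = 1, gene_count = 0, seed = 3)
  full <- plastome_sequence(p)
  expect_equal(nchar(full), 90000 + 31000 + 10000 + 31000)
  # IRb is the base-by-base reverse complement of IRa
  expect_identical(substring(full, 131001), revcomp(substr(full, 90001, 121000)))

  p2 <- simulate_plastome(size_factor = 0.1, gene_count = 5, seed = 3)
  r <- plastome_regions(p2)
  expect_equal(r$end - r$start + 1L, c(9000L, 3100L, 1000L, 3100L))
  expect_error(simulate_plastome(size_factor = 0.005), "size_factor")
})

test_that("plastome simulation is deterministic per seed and features lie in bounds", {
  a <- simulate_plastome(0.1, gene_count = 25, seed = 11)
  b <- simulate_plastome(0.1, gene_count = 25, seed = 11)
  expect_identical(plastome_sequence(a), plastome_sequence(b))
  expect_identical(a$features, b$features)
  f <- a$features
  expect_true(all(f$start >= 1 & f$end <= nchar(plastome_sequence(a))))
  expect_true(all(f$end >= f$start))
  # non-overlapping placement
  f <- f[order(f$start), ]
  if (nrow(f) > 1) expect_true(all(f$start[-1] > f$end[-nrow(f)]))
})

test_that("zero-rate evolution is the identity with an empty log", {
  p <- simulate_plastome(0.1, 10, seed = 5)
  ev <- evolve_genome(p, evolution_params(substitution_rate = 0, R_target = 1,
                                          indel_rate = 0, seed = 2))
  expect_identical(plastome_core(ev$genome), plastome_core(p))
  expect_equal(nrow(ev$log), 0L)
})

test_that("replaying the event log reproduces the derived genome exactly", {
  p <- simulate_plastome(0.1, 10, seed = 6)
  for (seed in 1:3) {
    ev <- evolve_genome(p, evolution_preset("inter-tribe", seed = seed))
    expect_identical(naive_replay(plastome_core(p), ev$log),
                     plastome_core(ev$genome))
    expect_identical(replay_event_log(p, ev$log), plastome_core(ev$genome))
  }
})

test_that("column scan of the truth alignment matches the log's own counts", {
  # 10 kb ancestor, substitution_rate 0.05, R_target 0.7 at a fixed seed
  p <- simulate_plastome(0.08, 0, seed = 7)  # core 10480 nt
  ev <- evolve_genome(p, evolution_params(substitution_rate = 0.05,
                                          R_target = 0.7, seed = 9))
  ca <- strsplit(ev$alignment$A, "")[[1]]
  cb <- strsplit(ev$alignment$B, "")[[1]]
  expect_identical(paste(ca[ca != "-"], collapse = ""), plastome_core(p))
  expect_identical(paste(cb[cb != "-"], collapse = ""),
                   plastome_core(ev$genome))
  sub_cols <- which(ca != "-" & cb != "-" & ca != cb)
  pair <- paste0(pmin(ca[sub_cols], cb[sub_cols]),
                 pmax(ca[sub_cols], cb[sub_cols]))
  si_scan <- sum(pair %in% c("AG", "CT"))
  sv_scan <- sum(!pair %in% c("AG", "CT"))
  logs <- ev$log[ev$log$kind == "substitution", ]
  lpair <- paste0(pmin(logs$ancestral, logs$derived),
                  pmax(logs$ancestral, logs$derived))
  expect_equal(si_scan, sum(lpair %in% c("AG", "CT")))
  expect_equal(sv_scan, sum(!lpair %in% c("AG", "CT")))
})

test_that("realized si/sv ratio tracks R_target within 3 binomial SE", {
  p <- simulate_plastome(1, 0, seed = 8)  # core 131 kb
  r_target <- 0.7
  ev <- evolve_genome(p, evolution_params(substitution_rate = 0.08,
                                          R_target = r_target, seed = 10))
  logs <- ev$log[ev$log$kind == "substitution", ]
  expect_gt(nrow(logs), 10000)
  lpair <- paste0(pmin(logs$ancestral, logs$derived),
                  pmax(logs$ancestral, logs$derived))
  si <- sum(lpair %in% c("AG", "CT"))
  sv <- nrow(logs) - si
  p_ti <- r_target / (1 + r_target)
  se_R <- sqrt(p_ti * (1 - p_ti) / nrow(logs)) * (1 + r_target)^2
  expect_lt(abs(si / sv - r_target), 3 * se_R)
  # substitution events never have ancestral == derived
  expect_true(all(logs$ancestral != logs$derived))
})

test_that("INDEL rate back-solver inverts the expected-ratio relation", {
  d <- indel_length_geometric()
  m <- sum(d$lengths * d$probs)
  for (target in c(0.061, 0.073, 0.089)) {
    r <- indel_rate_for_ratio(target, d)
    expect_equal(r * m / (1 + r * m / 2), target, tolerance = 1e-10)
  }
  expect_error(evolution_params(indel_length_distribution =
                                  list(lengths = c(0, 1), probs = c(.5, .5))),
               "positive")
})

test_that("total-DNA library obeys geometry, determinism and origin labelling", {
  p <- simulate_plastome(0.1, 10, seed = 12)
  lib0 <- simulate_total_dna_library(p, n_pairs = 0, seed = 1)
  expect_equal(length(lib0), 0L)

  lib <- simulate_total_dna_library(p, nuclear_size = 1e5, mito_size = 3e4,
                                    n_pairs = 3000, seed = 13)
  expect_equal(length(lib), 3000L)
  expect_true(all(nchar(lib$tagF) == 50, nchar(lib$tagR) == 50))
  expect_true(all(nchar(lib$qualF) == nchar(lib$tagF)))
  expect_true(all(nchar(lib$qualR) == nchar(lib$tagR)))
  expect_gt(lib$insert_mean, 2 * lib$tag_length)
  expect_setequal(unique(lib$origin),
                  c("chloroplast", "nuclear", "mitochondrial"))
  lib2 <- simulate_total_dna_library(p, nuclear_size = 1e5, mito_size = 3e4,
                                     n_pairs = 3000, seed = 13)
  expect_identical(lib$tagF, lib2$tagF)
  expect_identical(lib$qualR, lib2$qualR)
})

test_that("compartment sampling follows copy x length proportions", {
  p <- simulate_plastome(0.1, 0, seed = 14)
  lib <- simulate_total_dna_library(p, nuclear_size = 2e5, mito_size = 5e4,
                                    copy_ratio_chl_per_nuclear = 100,
                                    mito_copies = 10, n_pairs = 8000,
                                    seed = 15)
  w <- attr(lib, "copy_weights")
  obs <- table(factor(lib$origin, levels = names(w)))
  chi <- suppressWarnings(stats::chisq.test(obs, p = w / sum(w)))
  expect_gt(chi$p.value, 0.01)
})

test_that("realized chloroplast/nuclear depth ratio matches the copy ratio", {
  p <- simulate_plastome(0.1, 0, seed = 16)
  lib <- simulate_total_dna_library(p, nuclear_size = 2e5, mito_size = 5e4,
                                    copy_ratio_chl_per_nuclear = 100,
                                    mito_copies = 10, n_pairs = 25000,
                                    seed = 17)
  # depth from the hidden origins: tag bases per compartment length
  chl_len <- nchar(plastome_sequence(p))
  tagbp <- 2 * lib$tag_length
  depth_chl <- sum(lib$origin == "chloroplast") * tagbp / chl_len
  depth_nuc <- sum(lib$origin == "nuclear") * tagbp / 2e5
  expect_lt(abs(depth_chl / depth_nuc - 100) / 100, 0.15)
})

test_that("FASTQ round trip preserves sequences and qualities", {
  p <- simulate_plastome(0.1, 0, seed = 18)
  lib <- simulate_total_dna_library(p, n_pairs = 200, seed = 19)
  tmp <- tempfile()
  write_mate_pairs(lib, tmp)
  back <- read_mate_pairs(paste0(tmp, "_1.fastq"), paste0(tmp, "_2.fastq"))
  expect_identical(back$tagF, unname(lib$tagF))
  expect_identical(back$tagR, unname(lib$tagR))
  expect_identical(back$qualF, unname(lib$qualF))
  unlink(paste0(tmp, c("_1.fastq", "_2.fastq")))
})

test_that("truth outputs round-trip through FASTA, GFF3 and the event log TSV", {
  p <- simulate_plastome(0.1, 15, seed = 20)
  fa <- tempfile(fileext = ".fasta")
  write_fasta(c(genome = plastome_sequence(p)), fa)
  expect_identical(unname(read_fasta(fa)[1]), plastome_sequence(p))
  gff <- tempfile(fileext = ".gff3")
  write_features_gff3(p, gff)
  f <- read_features_gff3(gff)
  expect_equal(f$start, p$features$start)
  expect_equal(f$end, p$features$end)
  expect_equal(f$strand, p$features$strand)
  ev <- evolve_genome(p, evolution_preset("intra-tribe", seed = 21))
  tsv <- tempfile(fileext = ".tsv")
  write_event_log(ev$log, tsv)
  back <- read_event_log(tsv)
  expect_identical(naive_replay(plastome_core(p), back),
                   plastome_core(ev$genome))
  unlink(c(fa, gff, tsv))
})

test_that("YAML-configured simulation writes the declared outputs", {
  cfg <- list(seed = 4,
              plastome = list(size_factor = 0.1, gene_count = 5),
              library = list(n_pairs = 100, nuclear_size = 50000,
                             mito_size = 40000))
  out <- tempfile()
  res <- simulate_from_config(cfg, out_dir = out)
  expect_s3_class(res$plastome, "PlastomeModel")
  expect_equal(length(res$library), 100L)
  expect_true(all(file.exists(file.path(out,
    c("reads_1.fastq", "reads_2.fastq", "truth.fasta", "truth.gff3",
      "pair_truth.tsv")))))
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  res2 <- simulate_from_config(yml)
  expect_identical(res2$library$tagF, res$library$tagF)
  unlink(out, recursive = TRUE); unlink(yml)
})
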