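# File format wrappers. FASTA/FASTQ through Biostrings, GFF3 through
# rtracklayer, plain tables through base R.

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences (uppercased).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a mate-pair library from two FASTQ files
#'
#' Reads the forward (F3) and reverse (R3) tag files of a mate-pair library.
#' Pairing is positional: record i of `fq1` is mated with record i of `fq2`.
#'
#' @param fq1,fq2 FASTQ paths for the two tag files.
#' @param insert_mean,insert_sd library insert-size parameters (nt); not
#'   derivable from FASTQ, so they must be supplied for scaffolding.
#' @param orientation `"outward"` (SOLiD-style mate pairs) or `"inward"`.
#' @return a `MatePairLibrary`.
#' @export
read_mate_pairs <- function(fq1, fq2, insert_mean = 1500, insert_sd = 150,
                            orientation = c("outward", "inward")) {
  orientation <- match.arg(orientation)
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) stop("FASTQ files have different record counts")
  new_mate_pair_library(
    tagF = unname(toupper(as.character(r1))),
    tagR = unname(toupper(as.character(r2))),
    qualF = unname(as.character(S4Vectors::mcols(r1)$qualities)),
    qualR = unname(as.character(S4Vectors::mcols(r2)$qualities)),
    id = sub("/[12]$", "", sub("\\s.*$", "", names(r1))),
    origin = NULL, truth = NULL,
    tag_length = max(nchar(as.character(r1)), 0L),
    insert_mean = insert_mean, insert_sd = insert_sd,
    orientation = orientation
  )
}

#' Write a mate-pair library as two FASTQ files
#'
#' @param lib a `MatePairLibrary`.
#' @param prefix output prefix; writes `<prefix>_1.fastq` and `<prefix>_2.fastq`.
#' @return the two paths, invisibly.
#' @export
write_mate_pairs <- function(lib, prefix) {
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  ids <- lib$id
  s1 <- Biostrings::DNAStringSet(lib$tagF)
  names(s1) <- paste0(ids, "/1")
  s2 <- Biostrings::DNAStringSet(lib$tagR)
  names(s2) <- paste0(ids, "/2")
  Biostrings::writeXStringSet(s1, p1, format = "fastq",
                              qualities = Biostrings::BStringSet(lib$qualF))
  Biostrings::writeXStringSet(s2, p2, format = "fastq",
                              qualities = Biostrings::BStringSet(lib$qualR))
  invisible(c(p1, p2))
}

#' Write plastome features as GFF3
#'
#' @param model a `PlastomeModel`.
#' @param path output GFF3 file.
#' @param seqname sequence name used in the GFF3 (default `"plastome"`).
#' @export
write_features_gff3 <- function(model, path, seqname = "plastome") {
  f <- model$features
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = f$strand
  )
  gr$type <- f$kind
  gr$ID <- f$name
  gr$Name <- f$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read features from a GFF3 file
#'
#' @param path GFF3 file.
#' @return data.frame with columns name, start, end, strand, kind.
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else
    if (!is.null(gr$ID)) as.character(gr$ID) else
      paste0("feature", seq_along(gr))
  data.frame(
    name = nm,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = as.character(gr$type),
    stringsAsFactors = FALSE
  )
}

#' Write a mutation event log as TSV
#'
#' @param log a `MutationEventLog` data.frame (pos, kind, ancestral, derived).
#' @param path output TSV file.
#' @export
write_event_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutation event log from TSV
#' @param path TSV written by [write_event_log()].
#' @return data.frame of events.
#' @export
read_event_log <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("integer", "character", "character",
                                        "character"))
  x$ancestral[is.na(x$ancestral)] <- ""
  x$derived[is.na(x$derived)] <- ""
  x
}

#' Run a total-DNA simulation from a YAML configuration
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [simulate_plastome()] and [simulate_total_dna_library()] (sections
#' `plastome:` and `library:`, plus a top-level `seed:`), simulates a
#' plastome and a total-DNA mate-pair library, and optionally writes the
#' FASTQ pair, the truth FASTA/GFF3 and the per-pair truth table to
#' `out_dir`.
#'
#' @param config path to a YAML file, or an equivalent nested list.
#' @param out_dir optional output directory; created if missing.
#' @return list with elements `plastome` and `library`.
#' @export
simulate_from_config <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- cfg$seed %||% 1L
  pargs <- cfg$plastome %||% list()
  pargs$seed <- pargs$seed %||% seed
  model <- do.call(simulate_plastome, pargs)
  largs <- cfg$library %||% list()
  largs$plastome <- model
  largs$seed <- largs$seed %||% (seed + 1L)
  lib <- do.call(simulate_total_dna_library, largs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mate_pairs(lib, file.path(out_dir, "reads"))
    write_fasta(c(plastome = plastome_sequence(model)),
                file.path(out_dir, "truth.fasta"))
    write_features_gff3(model, file.path(out_dir, "truth.gff3"))
    utils::write.table(lib$truth, file.path(out_dir, "pair_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(plastome = model, library = lib)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
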