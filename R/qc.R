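# Read QC: truncation, mean-quality filtering, intact-pair enforcement.

#' Quality-filter parameters
#'
#' Mate-pair preprocessing truncates every tag to a fixed prefix and keeps
#' only tags whose mean quality on that prefix strictly exceeds a threshold;
#' by default a pair survives only if both mates pass, because downstream
#' scaffolding needs intact pairs.
#'
#' @param truncate_to prefix length kept from each tag (nt, default 40).
#' @param min_mean_qv mean-QV threshold; survivors must *exceed* it
#'   (strictly greater than, default 20).
#' @param require_both_mates drop the whole pair unless both tags pass.
#' @return a `FilterParams` list.
#' @export
filter_params <- function(truncate_to = 40, min_mean_qv = 20,
                          require_both_mates = TRUE) {
  stopifnot(truncate_to > 0, min_mean_qv >= 0)
  structure(list(truncate_to = as.integer(truncate_to),
                 min_mean_qv = min_mean_qv,
                 require_both_mates = isTRUE(require_both_mates)),
            class = "FilterParams")
}

#' Quality-filter a mate-pair library
#'
#' Each tag is truncated to its `truncate_to` nt prefix (tags shorter than
#' that fail outright); the mean QV is computed on the truncated prefix and
#' must strictly exceed `min_mean_qv`. With `require_both_mates`, a pair is
#' kept only when both tags pass. The operation is idempotent: filtering an
#' already-filtered library changes nothing.
#'
#' @param library a `MatePairLibrary`.
#' @param params a `FilterParams` (see [filter_params()]).
#' @return list with `library` (the surviving pairs, tags truncated) and
#'   `report` (a `FilterReport` with input/kept/dropped counts by reason).
#' @export
filter_mate_pairs <- function(library, params = filter_params()) {
  stopifnot(inherits(library, "MatePairLibrary"))
  tl <- params$truncate_to
  n <- length(library)
  if (n == 0L) {
    report <- structure(list(input_pairs = 0L, kept_pairs = 0L,
                             dropped_pairs = 0L, tags_failed_short = 0L,
                             tags_failed_quality = 0L),
                        class = "FilterReport")
    out <- library
    out$tag_length <- tl
    return(list(library = out, report = report))
  }

  eval_tag <- function(seqs, quals) {
    long_enough <- nchar(seqs) >= tl & nchar(quals) >= tl
    mq <- rep(NA_real_, length(seqs))
    mq[long_enough] <- mean_qv(substr(quals[long_enough], 1L, tl))
    list(pass = long_enough & !is.na(mq) & mq > params$min_mean_qv,
         short = !long_enough,
         lowq = long_enough & (is.na(mq) | mq <= params$min_mean_qv))
  }
  f <- eval_tag(library$tagF, library$qualF)
  r <- eval_tag(library$tagR, library$qualR)
  keep <- if (params$require_both_mates) f$pass & r$pass else f$pass | r$pass

  out <- library[keep]
  out$tagF <- substr(out$tagF, 1L, tl)
  out$tagR <- substr(out$tagR, 1L, tl)
  out$qualF <- substr(out$qualF, 1L, tl)
  out$qualR <- substr(out$qualR, 1L, tl)
  out$tag_length <- tl

  report <- structure(list(
    input_pairs = n,
    kept_pairs = sum(keep),
    dropped_pairs = n - sum(keep),
    tags_failed_short = sum(f$short) + sum(r$short),
    tags_failed_quality = sum(f$lowq) + sum(r$lowq)
  ), class = "FilterReport")
  list(library = out, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport: %d pairs in, %d kept, %d dropped (%d short tags, %d low-quality tags)\n",
              x$input_pairs, x$kept_pairs, x$dropped_pairs,
              x$tags_failed_short, x$tags_failed_quality))
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `FilterReport`.
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(as.data.frame(unclass(report)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
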