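HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
HIT_NUMERIC <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                 "sstart", "send", "evalue", "bitscore", "qlen", "slen")

empty_hits <- function() {
  out <- data.frame(qseqid = character(), sseqid = character(),
                    pident = numeric(), length = integer(),
                    mismatch = integer(), gapopen = integer(),
                    qstart = integer(), qend = integer(),
                    sstart = integer(), send = integer(),
                    evalue = numeric(), bitscore = numeric(),
                    qlen = integer(), slen = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("sim_hits", "data.frame")
  out
}

as_sim_hits <- function(df) {
  for (cc in setdiff(c(HIT_COLS, "qlen", "slen"), names(df))) df[[cc]] <- NA
  df <- df[, c(HIT_COLS, "qlen", "slen"), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sim_hits", "data.frame")
  df
}

#' Parse a BLAST-style tabular hit file
#'
#' Accepts the standard 12-column tabular dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), optionally followed by `qlen` and `slen` columns
#' (the "std qlen slen" 14-column dialect). Sequence lengths are resolved
#' from the `qlen`/`slen` columns when present, otherwise from `lengths`.
#'
#' @param path path to a tab-separated hit file (or a connection).
#' @param lengths named integer vector mapping sequence id to length, used
#'   for rows lacking `qlen`/`slen` columns.
#' @return a `sim_hits` data frame with one row per hit and resolved
#'   `qlen`/`slen` columns.
#' @export
parse_hit_table <- function(path, lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(!ncols %in% c(12L, 14L))
  if (length(bad))
    stop("malformed hit table: line ", bad[1], " has ", ncols[bad[1]],
         " columns (expected 12 or 14)")
  n14 <- ncols == 14L
  mat <- t(vapply(fields, function(f) c(f, rep(NA_character_, 14L - length(f))),
                  character(14)))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- c(HIT_COLS, "qlen", "slen")
  for (cc in HIT_NUMERIC) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    newly_bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(newly_bad))
      stop("malformed hit table: non-numeric '", cc, "' at line ", newly_bad[1])
    df[[cc]] <- v
  }
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "qlen", "slen")
  for (cc in int_cols) df[[cc]] <- as.integer(round(df[[cc]]))
  # resolve lengths
  if (!is.null(lengths)) {
    miss_q <- is.na(df$qlen)
    df$qlen[miss_q] <- unname(lengths[df$qseqid[miss_q]])
    miss_s <- is.na(df$slen)
    df$slen[miss_s] <- unname(lengths[df$sseqid[miss_s]])
  }
  unresolved <- unique(c(df$qseqid[is.na(df$qlen)], df$sseqid[is.na(df$slen)]))
  if (length(unresolved))
    stop("cannot resolve lengths for id(s): ",
         paste(sort(unresolved), collapse = ", "))
  if (any(df$qend < df$qstart) || any(df$send < df$sstart))
    stop("malformed hit table: alignment end precedes start")
  if (any(df$length < 1L)) stop("malformed hit table: alignment length < 1")
  as_sim_hits(df)
}

#' Write hits in BLAST tabular format
#'
#' @param hits a `sim_hits` data frame.
#' @param path output path.
#' @param dialect `"12col"` (standard) or `"14col"` (standard plus
#'   `qlen`/`slen`).
#' @return invisibly, the path.
#' @export
write_hit_table <- function(hits, path, dialect = c("14col", "12col")) {
  dialect <- match.arg(dialect)
  cols <- if (dialect == "14col") c(HIT_COLS, "qlen", "slen") else HIT_COLS
  fmt <- vapply(seq_len(nrow(hits)), function(i) {
    row <- lapply(cols, function(cc) {
      v <- hits[[cc]][i]
      if (is.numeric(v) && !is.integer(v)) sprintf("%.10g", v) else as.character(v)
    })
    paste(unlist(row), collapse = "\t")
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}

#' Coverage-rescaled percent identity
#'
#' The identity measure used throughout the protocol: BLAST percent identity
#' multiplied by the hit coverage of the shorter of the two sequences
#' (alignment columns over the shorter sequence length, capped at 1). Full
#' coverage leaves the identity untouched; partial hits are penalized in
#' proportion to the uncovered fraction of the shorter sequence.
#'
#' @param pident percent identity in (0, 100].
#' @param aln_len alignment length in columns (including gap columns).
#' @param len_q,len_s lengths of the two sequences.
#' @return adjusted identity as a percent; vectorized.
#' @export
adjusted_identity <- function(pident, aln_len, len_q, len_s) {
  if (any(len_q <= 0) || any(len_s <= 0))
    stop("sequence lengths must be positive")
  cov_short <- pmin(aln_len / pmin(len_q, len_s), 1.0)
  pident * cov_short
}

#' Mutual alignment coverage
#'
#' Fraction of each sequence covered by the hit, computed from the 1-based
#' inclusive alignment coordinates. Used to enforce the rule that an edge
#' requires the match to span at least a given fraction of *both* sequences,
#' which keeps domain-sharing fragments from linking unrelated families.
#'
#' @param qstart,qend,sstart,send 1-based inclusive alignment coordinates.
#' @param len_q,len_s sequence lengths.
#' @return a list with components `cov_q` and `cov_s`, each in (0, 1].
#' @export
mutual_coverage <- function(qstart, qend, sstart, send, len_q, len_s) {
  if (any(len_q <= 0) || any(len_s <= 0))
    stop("sequence lengths must be positive")
  if (any(qend > len_q) || any(send > len_s))
    stop("alignment coordinates exceed declared sequence length")
  list(cov_q = (qend - qstart + 1) / len_q,
       cov_s = (send - sstart + 1) / len_s)
}

# Reduce hits to the single best hit per unordered pair: the better of the
# two directional hits, ranked by bitscore, then e-value, then a fixed
# lexicographic tie-break so results are reproducible.
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(hits) == 0) return(as_sim_hits(hits))
  key <- ifelse(hits$qseqid < hits$sseqid,
                paste(hits$qseqid, hits$sseqid, sep = "\r"),
                paste(hits$sseqid, hits$qseqid, sep = "\r"))
  ord <- order(key, -hits$bitscore, hits$evalue, hits$qseqid, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  as_sim_hits(hits[keep, , drop = FALSE])
}
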