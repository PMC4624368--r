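#' Default alignment scoring parameters
#'
#' BLOSUM62 with affine gap penalties (open 11, extend 1) for proteins; a
#' +2/-3 match/mismatch scheme with gap open 5, extend 2 for nucleotides.
#' The e-value surrogate for the built-in aligner uses a Karlin-Altschul
#' style transform `E = K * m * n * exp(-lambda * S)` with fixed parameters;
#' it is a rank-consistent stand-in, not a calibrated BLAST e-value.
#'
#' @param alphabet `"protein"` or `"dna"`.
#' @return a list with `matrix`, `gap_open`, `gap_extend`, `lambda`, `K`.
#' @export
align_scoring <- function(alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "protein") {
    list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
         lambda = 0.267, K = 0.041)
  } else {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
    list(matrix = m, gap_open = 5, gap_extend = 2, lambda = 0.625, K = 0.41)
  }
}

score_to_evalue <- function(score, m, n, scoring) {
  scoring$K * m * n * exp(-scoring$lambda * score)
}

score_to_bits <- function(score, scoring) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

# Vectorized extraction of hit rows from an element-wise PairwiseAlignments
# object (pattern i was aligned to subject i).
hits_from_pa <- function(pa, pat_ids, pat_lens, sub_ids, sub_lens, scoring,
                         min_score) {
  sc <- Biostrings::score(pa)
  keep <- which(sc >= min_score)
  if (length(keep) == 0) return(empty_hits())
  pa_nm <- Biostrings::nmatch(pa)[keep]
  pa_nmm <- Biostrings::nmismatch(pa)[keep]
  p_al <- Biostrings::pattern(pa)
  s_al <- Biostrings::subject(pa)
  p_start <- BiocGenerics::start(p_al)[keep]; p_end <- BiocGenerics::end(p_al)[keep]
  s_start <- BiocGenerics::start(s_al)[keep]; s_end <- BiocGenerics::end(s_al)[keep]
  # alignment columns = pattern span plus gap columns in the pattern
  ni <- Biostrings::nindel(pa)
  aln_len <- (p_end - p_start + 1) +
    Biostrings::deletion(ni)[keep, "WidthSum"]
  n_gapcols <- aln_len - pa_nm - pa_nmm
  sc <- sc[keep]
  df <- data.frame(
    qseqid = pat_ids[keep], sseqid = sub_ids[keep],
    pident = 100 * pa_nm / aln_len,
    length = as.integer(aln_len),
    mismatch = as.integer(pa_nmm),
    gapopen = as.integer(n_gapcols),  # gap columns (not openings) for the built-in aligner
    qstart = p_start, qend = p_end,
    sstart = s_start, send = s_end,
    evalue = score_to_evalue(sc, pat_lens[keep], sub_lens[keep], scoring),
    bitscore = score_to_bits(sc, scoring),
    qlen = pat_lens[keep], slen = sub_lens[keep],
    stringsAsFactors = FALSE
  )
  as_sim_hits(df)
}

#' Locally align two sequences
#'
#' Smith-Waterman local alignment with affine gaps (via
#' [Biostrings::pairwiseAlignment()]). Percent identity is identical columns
#' over aligned columns including gap columns, the same denominator BLAST
#' uses. Returns `NULL` when the best local score falls below `min_score`.
#'
#' @param a,b residue strings (or single-row `seq_set`s).
#' @param alphabet `"protein"` or `"dna"`; both sequences must share it.
#' @param scoring scoring list as from [align_scoring()].
#' @param min_score minimum raw alignment score to report a hit.
#' @param ids identifiers for the two sequences.
#' @return a one-row `sim_hits` data frame, or `NULL` if below `min_score`.
#' @export
local_align <- function(a, b, alphabet = "protein", scoring = NULL,
                        min_score = 25, ids = c("query", "subject")) {
  if (inherits(a, "seq_set")) { ids[1] <- a$id[1]; alphabet <- a$alphabet[1]; a <- a$residues[1] }
  if (inherits(b, "seq_set")) {
    if (b$alphabet[1] != alphabet) stop("alphabet mismatch between sequences")
    ids[2] <- b$id[1]; b <- b$residues[1]
  }
  alphabet <- match.arg(alphabet, c("protein", "dna"))
  scoring <- scoring %||% align_scoring(alphabet)
  xs <- if (alphabet == "protein") Biostrings::AAString else Biostrings::DNAString
  pa <- Biostrings::pairwiseAlignment(
    xs(a), xs(b), type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  out <- hits_from_pa(pa, ids[1], nchar(a), ids[2], nchar(b), scoring,
                      min_score)
  if (nrow(out) == 0) NULL else out
}

# Maximum number of pairs aligned in a single vectorized call; bounds the
# transient memory of the element-wise alignment.
ALIGN_CHUNK <- 5000L

#' All-against-all similarity search
#'
#' Computes (or accepts) pairwise hits for a sequence set and applies the
#' per-query hit cap: at most `max_hits_per_query` subjects per query,
#' ranked by bitscore, then e-value, then subject id. Self-hits are never
#' reported. With the built-in aligner each unordered pair is aligned once
#' and reported in both directions (the scoring scheme is symmetric).
#'
#' @param seqs a `seq_set`.
#' @param max_hits_per_query per-query subject cap (the protocol uses 5000
#'   for the all-against-all step and 500 for recruitment rounds).
#' @param min_score minimum raw score for the built-in aligner.
#' @param scoring scoring list as from [align_scoring()].
#' @return a `sim_hits` data frame.
#' @export
all_vs_all <- function(seqs, max_hits_per_query = 5000, min_score = 25,
                       scoring = NULL) {
  stopifnot(inherits(seqs, "seq_set"))
  if (length(unique(seqs$alphabet)) > 1) stop("alphabet mismatch in set")
  hits <- search_pairs(seqs, seqs, min_score = min_score, scoring = scoring,
                       triangular = TRUE)
  if (nrow(hits) == 0) return(hits)
  mirror <- hits
  mirror[, c("qseqid", "sseqid", "qstart", "qend", "sstart", "send",
             "qlen", "slen")] <-
    hits[, c("sseqid", "qseqid", "sstart", "send", "qstart", "qend",
             "slen", "qlen")]
  cap_hits_per_query(as_sim_hits(rbind(hits, mirror)), max_hits_per_query)
}

# Align every query in `queries` against every subject in `subjects` with
# the built-in aligner. With triangular = TRUE (queries identical to
# subjects) only the upper triangle is computed.
search_pairs <- function(queries, subjects, min_score = 25, scoring = NULL,
                         triangular = FALSE) {
  if (nrow(queries) == 0 || nrow(subjects) == 0) return(empty_hits())
  alphabet <- subjects$alphabet[1]
  if (queries$alphabet[1] != alphabet) stop("alphabet mismatch")
  scoring <- scoring %||% align_scoring(alphabet)
  xs_set <- if (alphabet == "protein") Biostrings::AAStringSet
            else Biostrings::DNAStringSet
  if (triangular) {
    n <- nrow(queries)
    if (n < 2) return(empty_hits())
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    qi <- ut[, 1]; sj <- ut[, 2]
  } else {
    grid <- expand.grid(q = seq_len(nrow(queries)),
                        s = seq_len(nrow(subjects)))
    qi <- grid$q; sj <- grid$s
  }
  qset <- xs_set(queries$residues)
  sset <- xs_set(subjects$residues)
  out <- list()
  for (chunk in split(seq_along(qi), (seq_along(qi) - 1) %/% ALIGN_CHUNK)) {
    pa <- Biostrings::pairwiseAlignment(
      qset[qi[chunk]], sset[sj[chunk]],
      type = "local", substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    out[[length(out) + 1L]] <-
      hits_from_pa(pa, queries$id[qi[chunk]], queries$length[qi[chunk]],
                   subjects$id[sj[chunk]], subjects$length[sj[chunk]],
                   scoring, min_score)
  }
  res <- do.call(rbind, c(list(empty_hits()), out))
  as_sim_hits(res[res$qseqid != res$sseqid, , drop = FALSE])
}

cap_hits_per_query <- function(hits, max_hits_per_query) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(hits)), hits$qseqid, FUN = seq_along)
  as_sim_hits(hits[rank <= max_hits_per_query, , drop = FALSE])
}
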