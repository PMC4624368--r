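#' Build a labeled sequence set
#'
#' A `seq_set` is the package's basic container: a data frame with one row
#' per sequence, carrying the residue string, alphabet, origin label
#' (Archaea, Bacteria, Eukaryote, MGE, Environment or Published) and an
#' optional sample identifier. Duplicate residue strings are flagged in the
#' `redundant` column so that redundant sequences can be filtered before
#' network construction.
#'
#' @param id character vector of unique sequence identifiers.
#' @param residues character vector of residue strings (no gaps).
#' @param alphabet either `"protein"` or `"dna"` (recycled).
#' @param origin origin label per sequence, one of `"Archaea"`, `"Bacteria"`,
#'   `"Eukaryote"`, `"MGE"`, `"Environment"`, `"Published"`.
#' @param sample_id sample label per sequence (may be `""`).
#'
#' @return a data frame of class `seq_set` with columns `id`, `residues`,
#'   `alphabet`, `origin`, `sample_id`, `length`, `redundant`.
#' @export
seq_set <- function(id, residues, alphabet = "protein",
                    origin = "Published", sample_id = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  n <- length(id)
  if (length(residues) != n)
    stop("'id' and 'residues' must have equal length")
  if (anyDuplicated(id))
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(residues)))
    stop("empty residue strings for: ",
         paste(id[!nzchar(residues)], collapse = ", "))
  alphabet <- rep_len(as.character(alphabet), n)
  if (!all(alphabet %in% c("protein", "dna")))
    stop("alphabet must be 'protein' or 'dna'")
  origin <- rep_len(as.character(origin), n)
  bad <- !origin %in% ORIGIN_LEVELS
  if (any(bad))
    stop("unknown origin label(s): ", paste(unique(origin[bad]), collapse = ", "))
  out <- data.frame(
    id = id,
    residues = residues,
    alphabet = alphabet,
    origin = origin,
    sample_id = rep_len(as.character(sample_id), n),
    length = nchar(residues),
    redundant = duplicated(residues) | duplicated(residues, fromLast = TRUE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Combine sequence sets
#'
#' @param ... `seq_set` objects.
#' @return a single `seq_set`; ids must remain unique.
#' @export
bind_seq_sets <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  df <- do.call(rbind, lapply(parts, as.data.frame))
  seq_set(df$id, df$residues, df$alphabet, df$origin, df$sample_id)
}

#' Read sequences from FASTA with a metadata table
#'
#' Reads a protein or nucleotide FASTA file and joins a tab-separated
#' metadata table with columns `id`, `origin`, `sample_id`. Sequences absent
#' from the metadata table default to origin `"Published"` and empty sample.
#'
#' @param fasta path to a FASTA file.
#' @param metadata optional path to a metadata TSV.
#' @param alphabet `"protein"` or `"dna"`.
#' @return a `seq_set`.
#' @export
read_seq_set <- function(fasta, metadata = NULL, alphabet = "protein") {
  alphabet <- match.arg(alphabet, c("protein", "dna"))
  xs <- if (alphabet == "protein") Biostrings::readAAStringSet(fasta)
        else Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(xs))
  origin <- rep("Published", length(ids))
  sample_id <- rep("", length(ids))
  if (!is.null(metadata)) {
    md <- read.delim(metadata, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("id", "origin") %in% names(md)))
      stop("metadata table must have columns 'id' and 'origin'")
    idx <- match(ids, md$id)
    hit <- !is.na(idx)
    origin[hit] <- md$origin[idx[hit]]
    if ("sample_id" %in% names(md)) sample_id[hit] <- md$sample_id[idx[hit]]
  }
  seq_set(ids, as.character(xs), alphabet, origin, sample_id)
}

#' Write a sequence set to FASTA plus a metadata table
#'
#' FASTA lines are wrapped at 60 columns. The metadata TSV has columns
#' `id`, `origin`, `sample_id`.
#'
#' @param seqs a `seq_set`.
#' @param fasta output FASTA path.
#' @param metadata optional output metadata TSV path.
#' @return invisibly, the FASTA path.
#' @export
write_seq_set <- function(seqs, fasta, metadata = NULL) {
  xs <- if (seqs$alphabet[1] == "protein")
    Biostrings::AAStringSet(setNames(seqs$residues, seqs$id))
  else Biostrings::DNAStringSet(setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(xs, fasta, width = 60L)
  if (!is.null(metadata)) {
    write.table(seqs[, c("id", "origin", "sample_id")], metadata,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

# Subset a seq_set by id, preserving class.
seq_subset <- function(seqs, ids) {
  out <- seqs[match(ids, seqs$id), , drop = FALSE]
  if (anyNA(out$id)) stop("unknown sequence ids requested")
  rownames(out) <- NULL
  out
}

# Named length lookup vector from a seq_set.
length_map <- function(seqs) setNames(seqs$length, seqs$id)
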