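#' Induced subgraph of highly divergent environmental sequences
#'
#' Restricts the exploratory network to environmental nodes whose identity
#' to the closest published relative falls below the divergence cutoff
#' (60% by default). Sequences without any published hit can optionally be
#' kept; by default they are excluded, since their divergence cannot be
#' quantified.
#'
#' @param net the exploratory `igraph` network.
#' @param cpr a `cpr_records` data frame.
#' @param config an [ssn_config()].
#' @param keep_no_cpr keep environmental nodes with no published hit.
#' @return an `igraph` induced subgraph.
#' @export
divergent_subgraph <- function(net, cpr, config = ssn_config(),
                               keep_no_cpr = FALSE) {
  idx <- match(igraph::V(net)$name, cpr$env_id)
  is_env <- igraph::V(net)$origin == "Environment"
  val <- cpr$cpr_identity[idx]
  no <- cpr$no_cpr[idx]
  keep <- is_env & !is.na(idx) &
    ((!no & val < config$cpr_divergence_cutoff) | (no & keep_no_cpr))
  igraph::induced_subgraph(net, which(keep))
}

#' Enumerate maximal cliques (Bron-Kerbosch with pivoting)
#'
#' Lists every maximal clique of at least `min_size` nodes. Output is
#' canonical: members sorted within each clique, cliques sorted
#' lexicographically by member vector, so enumeration order never depends
#' on internal recursion order. Overlapping maximal cliques are all
#' reported.
#'
#' @param graph an `igraph` object (simple, undirected).
#' @param min_size smallest clique to report.
#' @param max_nodes guard against pathological inputs: enumeration aborts
#'   if the graph has more nodes than this.
#' @return a list of character vectors of node ids.
#' @export
maximal_cliques <- function(graph, min_size = 3, max_nodes = 10000) {
  n <- igraph::vcount(graph)
  if (n > max_nodes)
    stop("graph has ", n, " nodes, above the clique-enumeration guard (",
         max_nodes, "); raise 'max_nodes' only if you know the input")
  if (n == 0) return(list())
  ids <- igraph::V(graph)$name %||% as.character(seq_len(n))
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"),
                function(v) sort(unique(as.integer(v))))
  # strip self-loops defensively
  adj <- lapply(seq_len(n), function(i) setdiff(adj[[i]], i))
  found <- new.env(parent = emptyenv())
  found$res <- vector("list", 64L); found$n <- 0L
  emit <- function(r) {
    found$n <- found$n + 1L
    if (found$n > length(found$res))
      found$res <- c(found$res, vector("list", length(found$res)))
    found$res[[found$n]] <- r
  }
  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      if (length(r) >= min_size) emit(r)
      return(invisible())
    }
    # pivot: vertex of P united X maximizing neighbours inside P
    cand <- c(p, x)
    deg <- vapply(cand, function(u) length(intersect(adj[[u]], p)), integer(1))
    u <- cand[which.max(deg)]
    for (v in setdiff(p, adj[[u]])) {
      nv <- adj[[v]]
      bk(c(r, v), intersect(p, nv), intersect(x, nv))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
    invisible()
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques <- lapply(found$res[seq_len(found$n)],
                    function(ix) sort(ids[ix]))
  keys <- vapply(cliques, paste, character(1), collapse = "\r")
  cliques[order(keys)]
}

#' Keep the largest maximal clique per connected component
#'
#' Companion to [maximal_cliques()] mirroring tools that report only the
#' largest maximal cliques: within each connected component of the graph,
#' only the largest clique is kept (ties broken by lexicographic member
#' order).
#'
#' @param graph the graph the cliques were enumerated on.
#' @param cliques output of [maximal_cliques()].
#' @return a filtered list of cliques.
#' @export
largest_clique_per_component <- function(graph, cliques) {
  if (length(cliques) == 0) return(cliques)
  comp <- connected_components(graph)
  cid <- vapply(cliques, function(cl) comp[[cl[1]]], integer(1))
  keep <- unlist(lapply(split(seq_along(cliques), cid), function(ix) {
    sizes <- lengths(cliques[ix])
    ix[sizes == max(sizes)][1]  # cliques already in lexicographic order
  }))
  cliques[sort(keep)]
}

#' Average residue identity of an aligned clique
#'
#' Mean over all unordered pairs of (identical columns / columns where both
#' sequences are non-gap) x 100. Pairs with no mutually non-gap column are
#' excluded with a warning; if every pair is excluded the average is
#' undefined (`NA`).
#'
#' @param alignment named character vector of equal-length aligned rows
#'   (gap character `-`).
#' @return mean pairwise identity in percent, or `NA` if undefined.
#' @export
clique_average_identity <- function(alignment) {
  stopifnot(length(alignment) >= 2)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  n <- nrow(mat)
  vals <- c()
  excluded <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok)) { excluded <- excluded + 1L; next }
    vals <- c(vals, 100 * sum(mat[i, ok] == mat[j, ok]) / sum(ok))
  }
  if (excluded > 0)
    warning(excluded, " pair(s) with no mutually non-gap column excluded")
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Count conserved alignment columns retained in blocks
#'
#' A simplified conserved-block filter in the spirit of alignment-trimming
#' tools: a column is conserved when it contains no gaps (up to
#' `max_gap_frac`) and its most frequent residue occurs in strictly more
#' than `conserved_frac` of the rows; only contiguous runs of at least
#' `min_block_len` conserved columns are retained. The returned count is
#' the number of retained columns; cliques whose alignments retain more
#' than 10 columns are considered alignable downstream.
#'
#' @param alignment named character vector of equal-length aligned rows.
#' @param conserved_frac minimum fraction (exclusive) of rows sharing the
#'   majority residue for a conserved column.
#' @param max_gap_frac maximum fraction of gap rows tolerated per column.
#' @param min_block_len minimum length of a retained run.
#' @return integer count of retained columns.
#' @export
conserved_block_count <- function(alignment, conserved_frac = 0.5,
                                  max_gap_frac = 0, min_block_len = 10) {
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  n <- nrow(mat)
  col_ok <- apply(mat, 2, function(col) {
    gaps <- sum(col == "-")
    if (gaps / n > max_gap_frac) return(FALSE)
    res <- col[col != "-"]
    max(table(res)) > conserved_frac * n
  })
  r <- rle(col_ok)
  sum(r$lengths[r$values & r$lengths >= min_block_len])
}

#' Characterize divergent cliques
#'
#' Builds the clique report: for each maximal clique of highly divergent
#' environmental sequences, its members, home component, average residue
#' identity, retained conserved-block columns, alignable flag, and (when
#' coding sequences are available) the average pairwise dN/dS.
#'
#' @param net the exploratory network (for component ids).
#' @param sub the divergent subgraph from [divergent_subgraph()].
#' @param seqs the `seq_set` holding the clique members' residues.
#' @param config an [ssn_config()].
#' @param cds optional named character vector of coding sequences for
#'   members (same ids as the proteins).
#' @param largest_only keep only the largest clique per component of the
#'   divergent subgraph.
#' @return a data frame of class `clique_report`, one row per clique,
#'   with a `members` list-column.
#' @export
clique_report <- function(net, sub, seqs, config = ssn_config(), cds = NULL,
                          largest_only = FALSE) {
  cliques <- maximal_cliques(sub, min_size = config$min_clique_size,
                             max_nodes = config$max_clique_nodes)
  if (largest_only) cliques <- largest_clique_per_component(sub, cliques)
  comp <- setNames(igraph::V(net)$component_id, igraph::V(net)$name)
  rows <- lapply(seq_along(cliques), function(k) {
    mem <- cliques[[k]]
    aln <- clique_alignment(seq_subset(seqs, mem))
    avg_id <- if (is.null(aln)) NA_real_ else
      suppressWarnings(clique_average_identity(aln))
    blocks <- if (is.null(aln)) NA_integer_ else
      conserved_block_count(aln, min_block_len = config$min_block_len)
    avg_omega <- NA_real_
    n_omega_excluded <- NA_integer_
    if (!is.null(cds) && all(mem %in% names(cds)) && !is.null(aln)) {
      cod <- backthread_codon_alignment(aln, cds[mem])
      dn <- clique_dnds(cod)
      avg_omega <- dn$avg_omega
      n_omega_excluded <- dn$n_excluded
    }
    data.frame(clique_id = k, size = length(mem),
               family_component_id = unname(comp[mem[1]]),
               avg_identity = avg_id,
               avg_omega = avg_omega, n_omega_excluded = n_omega_excluded,
               retained_block_columns = blocks,
               alignable = !is.na(blocks) & blocks > 10,
               members = I(list(mem)), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(clique_id = integer(), size = integer(),
               family_component_id = integer(), avg_identity = numeric(),
               avg_omega = numeric(), n_omega_excluded = integer(),
               retained_block_columns = integer(), alignable = logical(),
               members = I(list()))
  class(out) <- c("clique_report", "data.frame")
  out
}

# Gap-free fixture alignment: clique members from the generator share one
# length, so the "alignment" is the raw sequences. Unequal lengths would
# need an external aligner; return NULL in that case.
clique_alignment <- function(seqs) {
  if (length(unique(seqs$length)) != 1) return(NULL)
  setNames(seqs$residues, seqs$id)
}

#' Write the clique report as TSV
#'
#' @param report a `clique_report`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_clique_report <- function(report, path) {
  df <- report
  df$members <- vapply(df$members, paste, character(1), collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
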