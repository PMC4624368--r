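# Independent oracles and small fixture builders used across the suite.

# ---- graph fixtures -------------------------------------------------------

# Build an igraph network directly from an edge data frame and origin map,
# bypassing the similarity engine.
make_net <- function(edges, origins, sample_id = NULL) {
  ids <- sort(names(origins))
  vdf <- data.frame(name = ids, origin = unname(origins[ids]),
                    sample_id = if (is.null(sample_id)) ""
                                else unname(sample_id[ids]),
                    stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && is.null(edges$adjusted_identity))
    edges$adjusted_identity <- 50
  if (nrow(edges) > 0 && is.null(edges$evalue)) edges$evalue <- 1e-30
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vdf)
  igraph::V(g)$component_id <- connected_components(g)
  g
}

# A synthetic qualifying hit row (full-length, low e-value by default).
make_hit <- function(q, s, pident = 90, qlen = 100, slen = 100,
                     aln_len = min(qlen, slen),
                     qstart = 1, qend = aln_len,
                     sstart = 1, send = aln_len,
                     evalue = 1e-30, bitscore = 100) {
  df <- data.frame(qseqid = q, sseqid = s, pident = pident,
                   length = as.integer(aln_len), mismatch = 0L, gapopen = 0L,
                   qstart = as.integer(qstart), qend = as.integer(qend),
                   sstart = as.integer(sstart), send = as.integer(send),
                   evalue = evalue, bitscore = bitscore,
                   qlen = as.integer(qlen), slen = as.integer(slen),
                   stringsAsFactors = FALSE)
  ssnrecruit:::as_sim_hits(df)
}

bind_hits <- function(...) ssnrecruit:::as_sim_hits(do.call(rbind, list(...)))

# Random labeled graph for conductance / component checks.
random_labeled_graph <- function(n, p, domains = c("Archaea", "Bacteria",
                                                   "Eukaryote")) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  igraph::V(g)$origin <- sample(domains, n, replace = TRUE)
  igraph::V(g)$component_id <- connected_components(g)
  g
}

# ---- brute-force oracles --------------------------------------------------

# Conductance by explicit edge classification over the component's edges.
brute_conductance <- function(g, component, domain) {
  comp <- connected_components(g)
  members <- names(comp)[comp == component]
  el <- igraph::as_edgelist(g, names = TRUE)
  orig <- stats::setNames(igraph::V(g)$origin, igraph::V(g)$name)
  inside <- el[, 1] %in% members & el[, 2] %in% members
  el <- el[inside, , drop = FALSE]
  ext <- 0; int <- 0
  for (k in seq_len(nrow(el))) {
    d1 <- orig[el[k, 1]] == domain
    d2 <- orig[el[k, 2]] == domain
    if (d1 && d2) int <- int + 1
    else if (d1 || d2) ext <- ext + 1
  }
  ext / int
}

# Connected components by union-find over the edge list.
brute_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_len(nrow(edges)))
    parent[[find(edges[k, 1])]] <- find(edges[k, 2])
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# All maximal cliques by exhaustive subset enumeration (bitmask; n <= 16).
brute_cliques <- function(g, min_size) {
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  am <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  nbr <- vapply(seq_len(n), function(v)
    sum(bitwShiftL(1L, which(am[v, ] > 0) - 1L)), numeric(1))
  closed <- nbr + bitwShiftL(1L, seq_len(n) - 1L)  # N[v] plus v itself
  subsets <- seq_len(2^n - 1)
  is_clique <- function(s) {
    vs <- which(bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) > 0)
    all(vapply(vs, function(v) bitwAnd(s, closed[v]) == s, logical(1)))
  }
  cl <- Filter(is_clique, subsets)
  # maximal: no strict clique superset
  clset <- cl
  maximal <- Filter(function(s) {
    !any(vapply(clset, function(t) t != s && bitwAnd(s, t) == s, logical(1)))
  }, cl)
  out <- lapply(maximal, function(s)
    sort(ids[which(bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) > 0)]))
  out <- Filter(function(x) length(x) >= min_size, out)
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

# BFS distances from a source set over an adjacency list (explicit queue).
brute_bfs <- function(g, sources) {
  ids <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g, mode = "all"),
                function(v) ids[as.integer(v)])
  names(adj) <- ids
  dist <- stats::setNames(rep(Inf, length(ids)), ids)
  queue <- sources
  dist[sources] <- 0
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.infinite(dist[[w]])) {
      dist[[w]] <- dist[[v]] + 1
      queue <- c(queue, w)
    }
  }
  dist
}

# Smith-Waterman with affine gaps (gap of length L costs open + L * ext),
# plain dynamic programming; returns the optimal local score.
sw_score <- function(a, b, mat = NULL, open = 11, ext = 1) {
  if (is.null(mat)) {
    # scoring matrix is a shared input of engine and oracle; the oracle's
    # independence is in the DP itself
    mat <- get(data("BLOSUM62", package = "Biostrings",
                    envir = environment()))
  }
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- E <- F_ <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
    F_[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F_[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(0, H[i, j] + mat[x[i], y[j]],
                           E[i + 1, j + 1], F_[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

random_protein_str <- function(len) {
  paste(sample(ssnrecruit:::AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# NG86 per-codon site counts by direct enumeration of the nine mutations,
# written independently of the package's lookup tables.
brute_codon_sites <- function(codon, exclude_stops = TRUE) {
  code <- Biostrings::GENETIC_CODE
  chars <- strsplit(codon, "")[[1]]
  s <- n <- 0
  for (pos in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
    mut <- chars; mut[pos] <- alt
    mcd <- paste(mut, collapse = "")
    if (code[[mcd]] == "*") {
      if (!exclude_stops) n <- n + 1 / 3
      next
    }
    if (code[[mcd]] == code[[codon]]) s <- s + 1 / 3 else n <- n + 1 / 3
  }
  c(S = s, N = n)
}

# Random stop-free coding sequence of n codons.
random_cds <- function(n_codons) {
  ssnrecruit:::random_cds_for_protein(random_protein_str(n_codons))
}
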