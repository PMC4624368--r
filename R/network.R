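#' Build the filtered similarity network
#'
#' Nodes are sequences; an undirected edge joins two sequences when the
#' best hit between them (the better of the two directional hits) passes
#' the full filter triple: e-value below `max_evalue`, coverage-rescaled
#' identity at or above `min_adjusted_identity`, and alignment coverage of
#' at least `min_mutual_coverage` on *both* sequences. The coverage rule
#' prevents two sequences from being linked by the mere sharing of a
#' fragment such as a single domain.
#'
#' @param hits a `sim_hits` data frame (both directions or one).
#' @param seqs a `seq_set` supplying lengths and origin labels for every id
#'   appearing in `hits`.
#' @param config an [ssn_config()].
#' @param include_singletons if `TRUE`, sequences without a qualifying edge
#'   are kept as isolated nodes; by default only edge-incident nodes enter
#'   the network.
#' @return an `igraph` object with vertex attributes `origin`, `sample_id`,
#'   `length`, `component_id` and edge attributes `adjusted_identity`,
#'   `cov_q`, `cov_s`, `evalue`, `pident`.
#' @export
build_network <- function(hits, seqs, config = ssn_config(),
                          include_singletons = FALSE) {
  unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), seqs$id)
  if (length(unknown))
    stop("hits reference unknown sequence id(s): ",
         paste(sort(unknown), collapse = ", "))
  best <- best_hits(hits)
  if (nrow(best)) {
    lm <- length_map(seqs)
    lq <- unname(lm[best$qseqid]); ls_ <- unname(lm[best$sseqid])
    cov <- mutual_coverage(best$qstart, best$qend, best$sstart, best$send,
                           lq, ls_)
    adj <- adjusted_identity(best$pident, best$length, lq, ls_)
    ok <- best$evalue < config$max_evalue &
      adj >= config$min_adjusted_identity &
      cov$cov_q >= config$min_mutual_coverage &
      cov$cov_s >= config$min_mutual_coverage
    edges <- data.frame(
      from = pmin(best$qseqid, best$sseqid),
      to = pmax(best$qseqid, best$sseqid),
      adjusted_identity = adj, cov_q = cov$cov_q, cov_s = cov$cov_s,
      evalue = best$evalue, pident = best$pident,
      stringsAsFactors = FALSE)[ok, , drop = FALSE]
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  } else {
    edges <- data.frame(from = character(), to = character(),
                        adjusted_identity = numeric(), cov_q = numeric(),
                        cov_s = numeric(), evalue = numeric(),
                        pident = numeric(), stringsAsFactors = FALSE)
  }
  node_ids <- if (include_singletons) sort(seqs$id)
              else sort(unique(c(edges$from, edges$to)))
  vdf <- data.frame(name = node_ids, stringsAsFactors = FALSE)
  idx <- match(node_ids, seqs$id)
  vdf$origin <- seqs$origin[idx]
  vdf$sample_id <- seqs$sample_id[idx]
  vdf$length <- seqs$length[idx]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vdf)
  igraph::V(g)$component_id <- connected_components(g)
  g
}

#' Connected components with deterministic numbering
#'
#' Components are numbered 1, 2, ... in order of their lexicographically
#' smallest member id, so component ids are stable across runs.
#'
#' @param net an `igraph` network.
#' @return a named integer vector mapping node id to component id.
#' @export
connected_components <- function(net) {
  memb <- igraph::components(net)$membership
  ids <- igraph::V(net)$name
  if (length(ids) == 0) return(setNames(integer(0), character(0)))
  smallest <- vapply(split(ids, memb), min, character(1))
  new_num <- setNames(rank(smallest), names(smallest))
  setNames(as.integer(new_num[as.character(memb)]), ids)
}

#' Per-domain conductance of a component
#'
#' For a domain D within a connected component, conductance is the number
#' of component edges with exactly one endpoint labeled D (external edges)
#' divided by the number of edges with both endpoints labeled D (internal
#' edges). A low value means the domain forms a cohesive group with little
#' evidence of gene transfer out of it. When the domain has no internal
#' edge the ratio is `Inf` if external edges exist, and `NaN` (0/0) when
#' the domain is absent or edgeless; neither counts as below any threshold,
#' so single-domain or degenerate components can never qualify. When
#' external edges are absent but internal edges exist the conductance is 0.
#'
#' @param net an `igraph` network with `origin` vertex attributes.
#' @param component a component id from [connected_components()].
#' @param domain an origin label.
#' @return a non-negative number, possibly `Inf` or `NaN`.
#' @export
domain_conductance <- function(net, component, domain) {
  if (!domain %in% ORIGIN_LEVELS)
    stop("unknown domain label: ", domain)
  comp_map <- igraph::V(net)$component_id %||% connected_components(net)
  members <- igraph::V(net)$name[comp_map == component]
  if (length(members) == 0) stop("no such component: ", component)
  sub <- igraph::induced_subgraph(net, members)
  el <- igraph::as_edgelist(sub, names = TRUE)
  orig <- setNames(igraph::V(sub)$origin, igraph::V(sub)$name)
  a <- orig[el[, 1]] == domain
  b <- orig[el[, 2]] == domain
  internal <- sum(a & b)
  external <- sum(xor(a, b))
  external / internal
}

#' Select nucleus gene families by per-domain conductance
#'
#' A connected component passes when at least two of the configured domains
#' have conductance strictly below the threshold: the component then holds
#' at least two cohesive domain-specific groups with little sign of
#' inter-domain transfer, the signature of an ancient, rarely transferred
#' family.
#'
#' @param net an `igraph` network (typically built from published sequences
#'   only).
#' @param config an [ssn_config()].
#' @return a data frame of class `family_nuclei`, one row per component,
#'   sorted by component id, with per-domain conductance columns
#'   (`conductance_<domain>`), `size`, `passes`, and a `members`
#'   list-column.
#' @export
select_nuclei <- function(net, config = ssn_config()) {
  comp_map <- igraph::V(net)$component_id %||% connected_components(net)
  comp_ids <- sort(unique(comp_map))
  doms <- config$conductance_domains
  rows <- lapply(comp_ids, function(cid) {
    cond <- vapply(doms, function(d) domain_conductance(net, cid, d),
                   numeric(1))
    members <- sort(igraph::V(net)$name[comp_map == cid])
    below <- !is.na(cond) & cond < config$conductance_threshold
    out <- data.frame(component_id = cid, size = length(members),
                      passes = sum(below) >= 2, stringsAsFactors = FALSE)
    for (d in doms) out[[paste0("conductance_", d)]] <- cond[[d]]
    out$members <- I(list(members))
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("family_nuclei", "data.frame")
  res
}

#' Export a network to GraphML
#'
#' Writes the network with its vertex attributes (origin, component id,
#' plus any annotation columns supplied) and edge attributes so it can be
#' opened in standard graph tools.
#'
#' @param net an `igraph` network.
#' @param path output `.graphml` path.
#' @param annotations optional data frame with an `id` column; remaining
#'   columns are attached as vertex attributes.
#' @return invisibly, the path.
#' @export
export_graphml <- function(net, path, annotations = NULL) {
  if (!is.null(annotations)) {
    idx <- match(igraph::V(net)$name, annotations$id)
    for (cc in setdiff(names(annotations), "id")) {
      val <- annotations[[cc]][idx]
      if (is.numeric(val)) val[is.na(val)] <- -1 else val[is.na(val)] <- ""
      net <- igraph::set_vertex_attr(net, cc, value = val)
    }
  }
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write the network edge list as TSV
#'
#' Columns: the two node ids, coverage-rescaled identity and e-value,
#' sorted for reproducible output.
#'
#' @param net an `igraph` network.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(u = pmin(el[, 1], el[, 2]), v = pmax(el[, 1], el[, 2]),
                   adjusted_identity = igraph::E(net)$adjusted_identity,
                   evalue = igraph::E(net)$evalue,
                   stringsAsFactors = FALSE)
  df <- df[order(df$u, df$v), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the nuclei report as TSV
#'
#' @param nuclei output of [select_nuclei()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_nuclei_report <- function(nuclei, path) {
  df <- nuclei
  df$members <- vapply(df$members, paste, character(1), collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
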