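#' One round of environmental recruitment
#'
#' Searches every seed sequence against the environmental database and
#' recruits the subjects of qualifying hits. Recruitment applies only the
#' e-value cutoff and the per-seed hit cap — the identity/coverage edge
#' filter is deliberately *not* applied here; it is enforced later when the
#' exploratory network is rebuilt. This looser recruitment is what lets
#' indirectly connected ("class 2") sequences enter the dataset.
#'
#' @param seeds a `seq_set` of seed sequences.
#' @param env_db a `seq_set` of environmental sequences.
#' @param config an [ssn_config()].
#' @return a list with `recruits` (character vector of recruited env ids,
#'   sorted) and `hits` (the qualifying seed-to-environment hits).
#' @export
recruit_round <- function(seeds, env_db, config = ssn_config()) {
  if (nrow(env_db) == 0) {
    warning("empty environmental database; nothing recruited")
    return(list(recruits = character(0), hits = empty_hits()))
  }
  if (nrow(seeds) == 0)
    return(list(recruits = character(0), hits = empty_hits()))
  hits <- search_pairs(seeds, env_db, min_score = config$min_align_score)
  hits <- hits[hits$evalue < config$max_evalue, , drop = FALSE]
  hits <- cap_hits_per_query(as_sim_hits(hits), config$recruit_hit_cap)
  list(recruits = sort(unique(hits$sseqid)), hits = hits)
}

#' Expand nucleus families with environmental homologs
#'
#' Runs up to `recruitment_rounds` rounds of recruitment: nuclei sequences
#' seed round 1; the newly recruited environmental sequences seed round 2
#' against the same environmental database, gathering homologs of homologs
#' that are not directly detectable from the nuclei.
#'
#' @param nuclei_seqs a `seq_set` of nucleus-family member sequences.
#' @param env_db a `seq_set` of environmental sequences.
#' @param config an [ssn_config()].
#' @return a list with `seqs` (nuclei plus recruited sequences),
#'   `provenance` (data frame: `env_id`, `round`, `seed_id`, `evalue`), and
#'   `hits` (all recruitment hits).
#' @export
expand_families <- function(nuclei_seqs, env_db, config = ssn_config()) {
  recruited <- character(0)
  prov <- data.frame(env_id = character(), round = integer(),
                     seed_id = character(), evalue = numeric(),
                     stringsAsFactors = FALSE)
  all_hits <- empty_hits()
  seeds <- nuclei_seqs
  rounds <- config$recruitment_rounds
  for (r in seq_len(rounds)) {
    if (nrow(seeds) == 0 || nrow(env_db) == 0) break
    rr <- recruit_round(seeds, env_db, config)
    all_hits <- as_sim_hits(rbind(all_hits, rr$hits))
    new_ids <- setdiff(rr$recruits, recruited)
    if (length(new_ids)) {
      best <- rr$hits[rr$hits$sseqid %in% new_ids, , drop = FALSE]
      best <- best[order(best$sseqid, best$evalue, -best$bitscore,
                         best$qseqid), , drop = FALSE]
      best <- best[!duplicated(best$sseqid), , drop = FALSE]
      prov <- rbind(prov, data.frame(env_id = best$sseqid, round = r,
                                     seed_id = best$qseqid,
                                     evalue = best$evalue,
                                     stringsAsFactors = FALSE))
    }
    recruited <- union(recruited, new_ids)
    seeds <- seq_subset(env_db, new_ids)
  }
  prov <- prov[order(prov$round, prov$env_id), , drop = FALSE]
  rownames(prov) <- NULL
  expanded <- if (length(recruited))
    bind_seq_sets(nuclei_seqs, seq_subset(env_db, sort(recruited)))
  else nuclei_seqs
  list(seqs = expanded, provenance = prov, hits = all_hits)
}

#' Topological class labels from graph distance to the nucleus set
#'
#' Environmental sequences directly connected to a nucleus sequence are
#' class 1; sequences connected to a class-1 sequence but not to any
#' nucleus sequence are class 2 (breadth-first distance 2); anything
#' farther (including sequences disconnected from every nucleus) is
#' "distal". Nucleus members are labeled "nucleus".
#'
#' @param net the exploratory `igraph` network.
#' @param nucleus_ids character vector of nucleus node ids (must be a
#'   subset of the network's nodes).
#' @return a data frame `id`, `class`, `distance` (in edges; `Inf` for
#'   disconnected nodes), sorted by id.
#' @export
classify_nodes <- function(net, nucleus_ids) {
  ids <- igraph::V(net)$name
  missing_ids <- setdiff(nucleus_ids, ids)
  if (length(missing_ids))
    stop("nucleus id(s) absent from the network: ",
         paste(sort(missing_ids), collapse = ", "))
  if (length(nucleus_ids) == 0) {
    d <- rep(Inf, length(ids))
  } else {
    dm <- igraph::distances(net, v = ids, to = nucleus_ids)
    d <- apply(dm, 1, min)
  }
  cls <- ifelse(ids %in% nucleus_ids, "nucleus",
         ifelse(d == 1, "class1",
         ifelse(d == 2, "class2", "distal")))
  out <- data.frame(id = ids, class = cls, distance = unname(d),
                    stringsAsFactors = FALSE)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identity to the closest published relative (CPR)
#'
#' For each environmental sequence, searches the published database and
#' reports the maximum coverage-rescaled identity over all hits with
#' e-value below the cutoff, together with the best-matching published id.
#' Ties are broken by higher bitscore, then lexicographic published id.
#' Sequences without any qualifying hit are reported with `no_cpr = TRUE`
#' (never as identity 0).
#'
#' @param env_seqs a `seq_set` of environmental sequences.
#' @param published_db a `seq_set` of published (non-environmental)
#'   sequences.
#' @param config an [ssn_config()].
#' @param hits optional precomputed environment-vs-published `sim_hits`;
#'   when `NULL` the built-in aligner is used.
#' @return a data frame of class `cpr_records`: `env_id`,
#'   `best_published_id`, `cpr_identity`, `stratum` (the environmental
#'   sequence's sample label), `no_cpr`.
#' @export
cpr_identity <- function(env_seqs, published_db, config = ssn_config(),
                         hits = NULL) {
  if (is.null(hits)) {
    hits <- if (nrow(published_db)) {
      search_pairs(env_seqs, published_db,
                   min_score = config$min_align_score)
    } else empty_hits()
  }
  hits <- hits[hits$evalue < config$max_evalue &
                 hits$qseqid %in% env_seqs$id &
                 hits$sseqid %in% published_db$id, , drop = FALSE]
  if (nrow(hits)) {
    lm_q <- length_map(env_seqs); lm_s <- length_map(published_db)
    adj <- adjusted_identity(hits$pident, hits$length,
                             unname(lm_q[hits$qseqid]),
                             unname(lm_s[hits$sseqid]))
    ord <- order(hits$qseqid, -adj, -hits$bitscore, hits$sseqid)
    hits <- hits[ord, , drop = FALSE]; adj <- adj[ord]
    keep <- !duplicated(hits$qseqid)
    best <- data.frame(env_id = hits$qseqid[keep],
                       best_published_id = hits$sseqid[keep],
                       cpr_identity = adj[keep], stringsAsFactors = FALSE)
  } else {
    best <- data.frame(env_id = character(), best_published_id = character(),
                       cpr_identity = numeric(), stringsAsFactors = FALSE)
  }
  idx <- match(env_seqs$id, best$env_id)
  out <- data.frame(
    env_id = env_seqs$id,
    best_published_id = ifelse(is.na(idx), NA_character_,
                               best$best_published_id[idx]),
    cpr_identity = ifelse(is.na(idx), NA_real_, best$cpr_identity[idx]),
    stratum = env_seqs$sample_id,
    no_cpr = is.na(idx),
    stringsAsFactors = FALSE)
  out <- out[order(out$env_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpr_records", "data.frame")
  out
}

#' Histogram of CPR identity, stratified
#'
#' Bins the CPR identities into the given intervals (left-closed,
#' right-open, with the last bin closed at 100) and reports per-stratum
#' proportions that sum to 1 within each stratum. Sequences with no CPR are
#' excluded from the proportions but counted in the `n_no_cpr` column.
#'
#' @param cpr a `cpr_records` data frame.
#' @param breaks increasing numeric vector of bin edges spanning (0, 100],
#'   e.g. `c(0, 60, 95, 100)`.
#' @param stratum optional vector overriding the records' stratum labels
#'   (e.g. class labels instead of sample labels).
#' @return a data frame with one row per stratum x bin: `stratum`, `bin`,
#'   `count`, `proportion`, `n_no_cpr`.
#' @export
divergence_summary <- function(cpr, breaks = c(0, 60, 95, 100),
                               stratum = NULL) {
  stopifnot(all(diff(breaks) > 0), length(breaks) >= 2)
  strat <- stratum %||% cpr$stratum
  strat[!nzchar(strat)] <- "(unlabeled)"
  bins <- paste0("[", breaks[-length(breaks)], ",", breaks[-1],
                 c(rep(")", length(breaks) - 2), "]"))
  rows <- lapply(sort(unique(strat)), function(s) {
    sel <- strat == s
    vals <- cpr$cpr_identity[sel & !cpr$no_cpr]
    n_no <- sum(sel & cpr$no_cpr)
    if (length(vals) == 0) {
      warning("stratum '", s, "' has no CPR values")
      counts <- rep(0L, length(bins))
      props <- rep(0, length(bins))
    } else {
      bi <- findInterval(vals, breaks, rightmost.closed = TRUE)
      bi[bi == 0 | bi > length(bins)] <- NA
      counts <- tabulate(bi, nbins = length(bins))
      props <- counts / sum(counts)
    }
    data.frame(stratum = s, bin = bins, count = counts, proportion = props,
               n_no_cpr = n_no, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
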