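#' Pipeline configuration
#'
#' Collects every threshold the protocol applies. Defaults mirror the
#' published protocol: homology edges require e-value < 1e-5, at least 30%
#' coverage-rescaled identity and a match covering at least 80% of both
#' sequences; nucleus families need per-domain conductance below 0.4 for
#' two domains; environmental sequences below 60% identity to their closest
#' published relative count as highly divergent; recruitment runs two
#' rounds with a 500-hit cap per seed and the all-against-all step caps at
#' 5000 hits per query.
#'
#' @param max_evalue maximum e-value for a hit to qualify.
#' @param min_adjusted_identity minimum coverage-rescaled identity (%) for
#'   an edge.
#' @param min_mutual_coverage minimum alignment coverage of each of the two
#'   sequences for an edge.
#' @param conductance_threshold per-domain conductance below which a domain
#'   counts as a cohesive group.
#' @param conductance_domains domains that can qualify a component.
#' @param cpr_divergence_cutoff identity (%) to the closest published
#'   relative below which an environmental sequence is "highly divergent".
#' @param recruitment_rounds number of environmental recruitment rounds.
#' @param recruit_hit_cap per-seed subject cap during recruitment.
#' @param allvsall_hit_cap per-query subject cap for all-against-all.
#' @param min_clique_size smallest reported divergent clique.
#' @param min_align_score raw-score floor for the built-in aligner.
#' @param min_block_len minimum run of conserved gap-free columns retained
#'   by the conserved-block filter.
#' @param max_clique_nodes guard on the divergent subgraph size before
#'   clique enumeration.
#' @param rng_seed integer seed driving all randomness in a run.
#' @return a list of class `ssn_config`.
#' @export
ssn_config <- function(max_evalue = 1e-5,
                       min_adjusted_identity = 30,
                       min_mutual_coverage = 0.80,
                       conductance_threshold = 0.4,
                       conductance_domains = c("Archaea", "Bacteria"),
                       cpr_divergence_cutoff = 60,
                       recruitment_rounds = 2,
                       recruit_hit_cap = 500,
                       allvsall_hit_cap = 5000,
                       min_clique_size = 3,
                       min_align_score = 25,
                       min_block_len = 10,
                       max_clique_nodes = 10000,
                       rng_seed = 1L) {
  cfg <- list(max_evalue = max_evalue,
              min_adjusted_identity = min_adjusted_identity,
              min_mutual_coverage = min_mutual_coverage,
              conductance_threshold = conductance_threshold,
              conductance_domains = conductance_domains,
              cpr_divergence_cutoff = cpr_divergence_cutoff,
              recruitment_rounds = recruitment_rounds,
              recruit_hit_cap = recruit_hit_cap,
              allvsall_hit_cap = allvsall_hit_cap,
              min_clique_size = min_clique_size,
              min_align_score = min_align_score,
              min_block_len = min_block_len,
              max_clique_nodes = max_clique_nodes,
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  class(cfg) <- "ssn_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$max_evalue > 0,
            cfg$min_adjusted_identity >= 0, cfg$min_adjusted_identity <= 100,
            cfg$min_mutual_coverage >= 0, cfg$min_mutual_coverage <= 1,
            cfg$conductance_threshold >= 0,
            all(cfg$conductance_domains %in% ORIGIN_LEVELS),
            cfg$cpr_divergence_cutoff > 0, cfg$cpr_divergence_cutoff <= 100,
            cfg$recruitment_rounds >= 0,
            cfg$recruit_hit_cap >= 1, cfg$allvsall_hit_cap >= 1,
            cfg$min_clique_size >= 2,
            cfg$min_block_len >= 1)
  invisible(cfg)
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_ssn_config()` returns an `ssn_config`;
#'   `write_ssn_config()` invisibly returns the path.
#' @export
read_ssn_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(ssn_config))
  do.call(ssn_config, raw[intersect(names(raw), known)])
}

#' @rdname read_ssn_config
#' @param cfg an `ssn_config`.
#' @export
write_ssn_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
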