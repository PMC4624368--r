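#' Run the full discovery pipeline
#'
#' Executes the whole protocol: build the initial network over published
#' sequences, select nucleus families by per-domain conductance, recruit
#' environmental homologs in iterative rounds, rebuild the exploratory
#' network under the full edge filter, assign class labels by distance to
#' the nucleus set, score each environmental sequence against the published
#' database (closest published relative), extract maximal cliques of highly
#' divergent environmental sequences and characterize them (average
#' identity, conserved blocks, dN/dS where coding sequences exist), and
#' write every result as sorted TSV plus a GraphML export and a run
#' manifest. With the same configuration and seed, all tabular outputs are
#' byte-identical across runs.
#'
#' @param out_dir output directory (created if missing).
#' @param config an [ssn_config()].
#' @param sim a [sim_config()] used to generate the input dataset; ignored
#'   when `input` is given. Its seed defaults to the pipeline seed.
#' @param input optional list with `seqs` (a `seq_set`), and optionally
#'   `hits` (precomputed `sim_hits` for the initial published-vs-published
#'   search), `cds` (named character vector of coding sequences) and
#'   `truth`; supply this to run on real data instead of simulating.
#' @return invisibly, a list with all intermediate objects (`seqs`,
#'   `initial_net`, `nuclei`, `expansion`, `exploratory_net`, `classes`,
#'   `cpr`, `cliques`, `report`, `manifest`).
#' @export
run_pipeline <- function(out_dir, config = ssn_config(), sim = NULL,
                         input = NULL) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tick <- function(stage, start) {
    timings[stage] <<- round(as.numeric(Sys.time()) - as.numeric(start), 3)
  }

  # -- stage: data ----------------------------------------------------------
  st <- Sys.time()
  truth <- NULL; cds <- NULL; init_hits <- NULL
  if (is.null(input)) {
    sim <- sim %||% sim_config(rng_seed = config$rng_seed)
    ds <- simulate_dataset(sim)
    seqs <- ds$seqs; truth <- ds$truth; cds <- ds$cds
  } else {
    seqs <- input$seqs
    cds <- input$cds
    truth <- input$truth
    init_hits <- input$hits
  }
  write_seq_set(seqs, file.path(out_dir, "sequences.fasta"),
                file.path(out_dir, "metadata.tsv"))
  if (!is.null(truth)) write_truth_table(truth, file.path(out_dir, "truth.tsv"))
  if (length(cds)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds),
                                file.path(out_dir, "cds.fasta"), width = 60L)
  }
  published <- seqs[seqs$origin != "Environment", , drop = FALSE]
  env_db <- seqs[seqs$origin == "Environment", , drop = FALSE]
  tick("data", st)

  # -- stage: initial network and nucleus selection -------------------------
  st <- Sys.time()
  if (is.null(init_hits))
    init_hits <- all_vs_all(published, config$allvsall_hit_cap,
                            config$min_align_score)
  initial_net <- build_network(init_hits, published, config)
  nuclei <- select_nuclei(initial_net, config)
  write_nuclei_report(nuclei, file.path(out_dir, "nuclei.tsv"))
  nucleus_ids <- sort(unlist(nuclei$members[nuclei$passes]))
  tick("nuclei", st)

  # -- stage: recruitment ---------------------------------------------------
  st <- Sys.time()
  seed_seqs <- if (length(nucleus_ids)) seq_subset(seqs, nucleus_ids)
               else seqs[0, , drop = FALSE]
  expansion <- expand_families(seed_seqs, env_db, config)
  write.table(expansion$provenance, file.path(out_dir, "recruits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tick("recruit", st)

  # -- stage: exploratory network -------------------------------------------
  st <- Sys.time()
  expl_hits <- all_vs_all(expansion$seqs, config$allvsall_hit_cap,
                          config$min_align_score)
  exploratory_net <- build_network(expl_hits, expansion$seqs, config,
                                   include_singletons = TRUE)
  write_edge_list(exploratory_net, file.path(out_dir, "edges.tsv"))
  tick("network", st)

  # -- stage: classes -------------------------------------------------------
  st <- Sys.time()
  classes <- classify_nodes(exploratory_net, nucleus_ids)
  write.table(classes, file.path(out_dir, "classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tick("classes", st)

  # -- stage: closest published relatives -----------------------------------
  st <- Sys.time()
  env_recruited <- expansion$seqs[expansion$seqs$origin == "Environment", ,
                                  drop = FALSE]
  cpr <- cpr_identity(env_recruited, published, config)
  write.table(cpr, file.path(out_dir, "cpr.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hist_tab <- if (nrow(cpr)) divergence_summary(cpr) else NULL
  if (!is.null(hist_tab))
    write.table(hist_tab, file.path(out_dir, "cpr_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  report <- summary_report(cpr, classes, config)
  write.table(report, file.path(out_dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tick("cpr", st)

  # -- stage: divergent cliques ---------------------------------------------
  st <- Sys.time()
  sub <- divergent_subgraph(exploratory_net, cpr, config)
  cliques <- clique_report(exploratory_net, sub, expansion$seqs, config,
                           cds = cds)
  write_clique_report(cliques, file.path(out_dir, "cliques.tsv"))
  annot <- data.frame(id = classes$id, class = classes$class,
                      cpr_identity = cpr$cpr_identity[match(classes$id,
                                                            cpr$env_id)],
                      stringsAsFactors = FALSE)
  export_graphml(exploratory_net, file.path(out_dir, "network.graphml"),
                 annotations = annot)
  tick("cliques", st)

  # -- manifest -------------------------------------------------------------
  outputs <- sort(setdiff(list.files(out_dir), "manifest.yaml"))
  manifest <- list(
    version = as.character(utils::packageVersion("ssnrecruit")),
    config = unclass(config),
    sim_config = if (!is.null(sim)) lapply(unclass(sim), unclass) else NULL,
    outputs = outputs,
    digests = as.list(tools::md5sum(file.path(out_dir, outputs))),
    stage_seconds = as.list(timings),
    total_seconds = round(as.numeric(Sys.time()) - as.numeric(t0), 3))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(seqs = seqs, truth = truth, cds = cds,
                 initial_net = initial_net, nuclei = nuclei,
                 nucleus_ids = nucleus_ids, expansion = expansion,
                 exploratory_net = exploratory_net, classes = classes,
                 cpr = cpr, cliques = cliques, report = report,
                 manifest = manifest))
}

# Key-value report of the summary statistics the protocol prints:
# per-class counts, divergent fractions, the one-sided KS statistic
# comparing class-1 and class-2 divergence, and the gut/non-gut
# two-proportion comparison of highly divergent sequences.
summary_report <- function(cpr, classes, config) {
  kv <- list()
  cls <- classes$class[match(cpr$env_id, classes$id)]
  kv$n_env <- nrow(cpr)
  kv$n_class1 <- sum(cls == "class1", na.rm = TRUE)
  kv$n_class2 <- sum(cls == "class2", na.rm = TRUE)
  kv$n_distal <- sum(cls == "distal", na.rm = TRUE)
  kv$n_no_cpr <- sum(cpr$no_cpr)
  with_cpr <- !cpr$no_cpr
  kv$frac_divergent <- if (any(with_cpr))
    mean(cpr$cpr_identity[with_cpr] < config$cpr_divergence_cutoff)
  else NA_real_
  v1 <- cpr$cpr_identity[with_cpr & cls == "class1"]
  v2 <- cpr$cpr_identity[with_cpr & cls == "class2"]
  kv$ks_class2_below_class1 <- if (length(v1) && length(v2))
    ks_statistic(v2, v1, "a_below_b") else NA_real_
  strat <- cpr$stratum
  gut <- with_cpr & strat == "gut"
  nongut <- with_cpr & strat != "gut" & nzchar(strat)
  if (any(gut) && any(nongut)) {
    div50 <- cpr$cpr_identity < 50
    counts <- rbind(c(sum(div50[gut]), sum(gut) - sum(div50[gut])),
                    c(sum(div50[nongut]), sum(nongut) - sum(div50[nongut])))
    pr <- proportion_report(counts)
    kv$prop_divergent_gut <- pr$prop_1
    kv$prop_divergent_nongut <- pr$prop_2
    kv$prop_chisq <- pr$chisq
  } else {
    kv$prop_divergent_gut <- NA_real_
    kv$prop_divergent_nongut <- NA_real_
    kv$prop_chisq <- NA_real_
  }
  data.frame(metric = names(kv), value = unname(unlist(kv)),
             stringsAsFactors = FALSE)
}
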