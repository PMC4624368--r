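#' Simulate one gene family with planted structure
#'
#' Emits the sequences of a single family according to its type and the
#' identity targets in the configuration, together with a truth table
#' recording what the pipeline is expected to recover. Passing families
#' consist of two domain clades (Archaea, Bacteria) whose members sit well
#' below the edge threshold across domains, joined through a single
#' MGE-labeled linker lineage placed midway between the two domain
#' ancestors — the component is connected, yet each domain keeps many
#' internal and few external edges, which is the conductance signature of
#' an ancient, rarely transferred family. Passing families also carry a
#' class-1 environmental clade (direct neighbors of a nucleus member), a
#' class-2 clade reachable only through class 1, an off-network published
#' relative that gives the class-2 clade a measurable closest-published-
#' relative identity, and coverage-violating fragments.
#'
#' @param cfg a [sim_config()].
#' @param family_index 1-based family number (used for id prefixes).
#' @param type one of `"pass"`, `"fail_unbalanced"`, `"fail_single"`.
#' @return a list with `seqs` (a `seq_set`), `truth` (data frame) and
#'   `cds` (named character vector for environmental clade members).
#' @export
simulate_family <- function(cfg, family_index = 1,
                            type = c("pass", "fail_unbalanced",
                                     "fail_single")) {
  type <- match.arg(type)
  pre <- sprintf("F%02d", family_index)
  L <- cfg$protein_length
  ids <- character(0); seqs <- character(0); origins <- character(0)
  samples <- character(0); truth <- list(); cds_out <- character(0)
  add <- function(id, res, origin, sample, class, cpr_lo = NA, cpr_hi = NA,
                  omega = NA, clade = "") {
    ids <<- c(ids, id); seqs <<- c(seqs, res); origins <<- c(origins, origin)
    samples <<- c(samples, sample)
    truth[[length(truth) + 1L]] <<- data.frame(
      id = id, family = pre, family_type = type, clade = clade,
      intended_class = class, cpr_lo = cpr_lo, cpr_hi = cpr_hi,
      omega = omega, pass_expected = (type == "pass"),
      stringsAsFactors = FALSE)
  }
  nucleus_class <- if (type == "pass") "nucleus" else "published"

  if (type == "fail_single") {
    ancB <- random_protein(L)
    for (i in seq_len(cfg$clade_size))
      add(sprintf("%s_BAC%02d", pre, i),
          evolve_protein(ancB, 100 * cfg$m_domain), "Bacteria", "",
          nucleus_class, clade = "bacteria")
  } else {
    ancA <- random_protein(L)
    div <- make_divergence(ancA, 100 * cfg$anc_identity)
    ancB <- apply_divergence(ancA, div)
    linker <- apply_divergence(ancA, div, first_k = ceiling(length(div$pos) / 2))
    n_arch <- if (type == "pass") cfg$clade_size else cfg$small_clade_size
    for (i in seq_len(n_arch))
      add(sprintf("%s_ARC%02d", pre, i),
          evolve_protein(ancA, 100 * cfg$m_domain), "Archaea", "",
          nucleus_class, clade = "archaea")
    for (i in seq_len(cfg$clade_size))
      add(sprintf("%s_BAC%02d", pre, i),
          evolve_protein(ancB, 100 * cfg$m_domain), "Bacteria", "",
          nucleus_class, clade = "bacteria")
    add(sprintf("%s_LNK01", pre), linker, "MGE", "", nucleus_class,
        clade = "linker")
  }

  if (type == "pass") {
    parent <- seqs[ids == sprintf("%s_ARC01", pre)]
    e1 <- evolve_protein(parent, 100 * cfg$t_class1)
    e1_cds <- random_cds_for_protein(e1)
    c1_cds <- character(cfg$env_class1_size)
    for (i in seq_len(cfg$env_class1_size)) {
      c1_cds[i] <- evolve_cds_to_identity(e1_cds, cfg$omega,
                                          100 * cfg$m_env)
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(c1_cds[i])))
      id <- sprintf("%s_ENV1%02d", pre, i)
      add(id, prot, "Environment", "gut", "class1",
          cpr_lo = cfg$cpr_band_class1[1], cpr_hi = cfg$cpr_band_class1[2],
          omega = cfg$omega, clade = "env_class1")
      cds_out[id] <- c1_cds[i]
    }
    e2_cds <- evolve_cds_to_identity(c1_cds[1], cfg$omega,
                                     100 * cfg$u_class2)
    e2_prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(e2_cds)))
    for (i in seq_len(cfg$env_class2_size)) {
      ci <- evolve_cds_to_identity(e2_cds, cfg$omega, 100 * cfg$m_env)
      prot <- as.character(Biostrings::translate(Biostrings::DNAString(ci)))
      id <- sprintf("%s_ENV2%02d", pre, i)
      add(id, prot, "Environment", "nonGut", "class2",
          cpr_lo = cfg$cpr_band_class2[1], cpr_hi = cfg$cpr_band_class2[2],
          omega = cfg$omega, clade = "env_class2")
      cds_out[id] <- ci
    }
    cousin <- evolve_protein(e2_prot, 100 * cfg$v_cousin)
    add(sprintf("%s_CSN01", pre), cousin, "Published", "",
        "published_offnet", clade = "cousin")
    if (cfg$fragment_count > 0) {
      src <- seqs[ids == sprintf("%s_ARC02", pre)]
      flen <- round(L * cfg$fragment_length_fraction)
      for (i in seq_len(cfg$fragment_count)) {
        st <- sample.int(L - flen + 1, 1)
        add(sprintf("%s_FRG%02d", pre, i), substring(src, st, st + flen - 1),
            "Environment", "gut", "fragment", clade = "fragment")
      }
    }
  }

  list(seqs = seq_set(ids, seqs, "protein", origins, samples),
       truth = do.call(rbind, truth),
       cds = cds_out)
}

#' Simulate a full synthetic dataset
#'
#' Seeds the RNG from the configuration and emits all families, their truth
#' table and the environmental coding sequences. The same configuration
#' (including seed) always reproduces the dataset byte for byte.
#'
#' @param cfg a [sim_config()].
#' @return a list with `seqs`, `truth`, `cds` and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$rng_seed)
  fams <- lapply(seq_len(cfg$n_families), function(i)
    simulate_family(cfg, i, cfg$family_types[i]))
  seqs <- do.call(bind_seq_sets, lapply(fams, `[[`, "seqs"))
  truth <- do.call(rbind, lapply(fams, `[[`, "truth"))
  rownames(truth) <- NULL
  cds <- do.call(c, lapply(fams, `[[`, "cds"))
  list(seqs = seqs, truth = truth, cds = cds, config = cfg)
}

#' Write a truth table as TSV
#'
#' @param truth truth table from [simulate_dataset()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
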