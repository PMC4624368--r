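# Synthetic sequence families with planted network structure: two domain
# clades joined by a single inter-domain "linker" lineage (so that the
# component is connected while each domain keeps few external edges),
# environmental clades at controlled divergence bands attached at class-1
# or class-2 positions, coverage-violating fragments, and coding sequences
# evolved under a chosen dN/dS. All randomness flows through R's RNG; call
# sites seed it once per dataset.

#' Synthetic-dataset configuration
#'
#' Identity targets are percent identities the emitted sequences should
#' realize (within a few points); the generator derives per-branch
#' substitution counts from them, correcting for chance agreement under a
#' uniform replacement alphabet.
#'
#' @param n_families number of families to emit.
#' @param family_types character vector recycled over families; each is
#'   one of `"pass"` (two well-populated domain clades plus a linker;
#'   should pass the conductance test), `"fail_unbalanced"` (one domain
#'   too sparse to form a cohesive group) or `"fail_single"` (one domain
#'   only).
#' @param protein_length residues per ancestor protein.
#' @param clade_size sequences per domain clade.
#' @param small_clade_size size of the sparse domain in
#'   `"fail_unbalanced"` families.
#' @param intra_identity target mutual identity (%) between members of one
#'   domain clade.
#' @param inter_identity target identity (%) of the inter-domain linker to
#'   clade members; this is the detectable inter-domain signal. Members of
#'   different domains sit well below the edge threshold, which is what
#'   gives passing families their low conductance.
#' @param env_intra_identity target mutual identity (%) within an
#'   environmental clade.
#' @param env_class1_size,env_class2_size environmental clade sizes
#'   (class-1-like clades attach directly to a nucleus member; class-2-like
#'   clades attach to a class-1 member and stay below the edge threshold
#'   against every nucleus sequence).
#' @param cpr_band_class1,cpr_band_class2 target closest-published-relative
#'   identity bands (%, low/high) for the two environmental clades. The
#'   class-2 band is realized through an off-network published relative.
#' @param class2_attach_identity target identity (%) of class-2 members to
#'   their class-1 attachment sequence.
#' @param fragment_count coverage-violating fragments per passing family.
#' @param fragment_length_fraction fragment length as a fraction of the
#'   full protein.
#' @param omega dN/dS ratio for coding-sequence evolution within
#'   environmental clades.
#' @param edge_identity_threshold identity threshold (%) the downstream
#'   network filter is expected to use; only used to validate that the
#'   planted bands are not contradictory.
#' @param rng_seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_families = 3,
                       family_types = c("pass", "fail_unbalanced",
                                        "fail_single"),
                       protein_length = 200,
                       clade_size = 8,
                       small_clade_size = 2,
                       intra_identity = 75,
                       inter_identity = 56,
                       env_intra_identity = 72,
                       env_class1_size = 5,
                       env_class2_size = 4,
                       cpr_band_class1 = c(40, 55),
                       cpr_band_class2 = c(33, 45),
                       class2_attach_identity = 45,
                       fragment_count = 1,
                       fragment_length_fraction = 0.4,
                       omega = 0.2,
                       edge_identity_threshold = 30,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  cfg$family_types <- rep_len(family_types, n_families)
  stopifnot(protein_length >= 50, clade_size >= 2, small_clade_size >= 2,
            intra_identity > 0, intra_identity <= 100,
            inter_identity > 0, inter_identity < intra_identity,
            env_intra_identity > 50, env_intra_identity <= 100,
            all(cpr_band_class1 > 0), all(cpr_band_class1 <= 100),
            all(cpr_band_class2 > 0), all(cpr_band_class2 <= 100),
            fragment_length_fraction > 0, fragment_length_fraction < 0.8,
            omega >= 0)
  # derived branch parameters (survival = per-site probability of keeping
  # the parent residue along one branch)
  q <- 1 / 19  # chance agreement of two independently substituted residues
  raw <- function(p) (p - q) / (1 - q)
  sib <- function(p) {
    # survival m with sibling identity m^2 + (1-m)^2 * q = p
    a <- 1 + q; b <- -2 * q; cc <- q - p
    (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  }
  cfg$m_domain <- sib(intra_identity / 100)
  cfg$m_env <- sib(env_intra_identity / 100)
  h <- raw(inter_identity / 100) / cfg$m_domain  # linker-to-ancestor survival
  if (h >= 1 || h <= 0.5)
    stop("inter_identity incompatible with intra_identity: linker cannot ",
         "be placed between the domain ancestors")
  cfg$anc_identity <- 2 * h - 1  # domain ancestor-to-ancestor survival
  cfg$t_class1 <- raw(mean(cpr_band_class1) / 100) / cfg$m_env
  cfg$u_class2 <- raw(class2_attach_identity / 100) / cfg$m_env
  cfg$v_cousin <- raw(mean(cpr_band_class2) / 100) / cfg$m_env
  if (any(c(cfg$t_class1, cfg$u_class2, cfg$v_cousin) >= 1))
    stop("divergence bands too high for the environmental clade identity")
  # cross-domain members must stay clearly below the edge threshold
  cross <- cfg$m_domain^2 * cfg$anc_identity
  cross_realized <- 100 * (cross + (1 - cross) * q)
  if (cross_realized >= edge_identity_threshold - 2)
    stop("inter-domain member identity (", round(cross_realized, 1),
         "%) too close to the edge threshold; lower inter_identity")
  # class-2 members must stay clearly below the edge threshold vs nuclei
  c2nuc <- cfg$m_env^2 * cfg$u_class2 * cfg$m_env * cfg$t_class1
  c2nuc_realized <- 100 * (c2nuc + (1 - c2nuc) * q)
  if (c2nuc_realized >= edge_identity_threshold - 2)
    stop("class-2 band (", round(c2nuc_realized, 1),
         "% vs nuclei) overlaps the edge threshold; lower the bands")
  class(cfg) <- "sim_config"
  cfg
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Evolve a protein to a target identity
#'
#' Substitutes a fixed number of randomly chosen positions (each to a
#' random different residue) so that the descendant's identity to the
#' ancestor equals the target up to rounding; the realized identity is
#' always within 3 percentage points of the target for sequences of at
#' least 20 residues.
#'
#' @param ancestor residue string.
#' @param target_identity percent identity in (0, 100].
#' @return descendant residue string.
#' @export
evolve_protein <- function(ancestor, target_identity) {
  stopifnot(target_identity > 0, target_identity <= 100,
            nchar(ancestor) > 0)
  div <- make_divergence(ancestor, target_identity)
  apply_divergence(ancestor, div)
}

# Sample the substitution set carrying `ancestor` to the target identity.
make_divergence <- function(ancestor, target_identity) {
  len <- nchar(ancestor)
  d <- round(len * (1 - target_identity / 100))
  pos <- sample.int(len, d)
  chars <- strsplit(ancestor, "")[[1]]
  res <- vapply(pos, function(p) sample(setdiff(AA_ALPHABET, chars[p]), 1),
                character(1))
  list(pos = pos, res = res)
}

apply_divergence <- function(ancestor, div, first_k = length(div$pos)) {
  chars <- strsplit(ancestor, "")[[1]]
  k <- seq_len(first_k)
  chars[div$pos[k]] <- div$res[k]
  paste(chars, collapse = "")
}

#' Percent identity between two equal-length sequences
#'
#' Site-wise (Hamming) identity; the generator's ground-truth measure.
#'
#' @param a,b equal-length residue strings.
#' @return percent identity.
#' @export
protein_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  100 * sum(x == y) / length(x)
}

# ---- codon-level evolution ------------------------------------------------

.sim_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(.sim_env$code)) .sim_env$code <- Biostrings::GENETIC_CODE
  .sim_env$code
}

aa_codons <- function() {
  if (is.null(.sim_env$byaa))
    .sim_env$byaa <- split(names(genetic_code()), genetic_code())
  .sim_env$byaa
}

random_cds_for_protein <- function(protein) {
  byaa <- aa_codons()
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) {
    opts <- byaa[[a]]
    if (is.null(opts)) stop("no codon for residue: ", a)
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

# One accept/reject codon-evolution proposal sweep. Proposals pick a random
# nucleotide position and a random different base; changes creating stop
# codons are discarded, synonymous changes are always accepted and
# nonsynonymous ones accepted with probability omega.
propose_step <- function(chars, omega, code) {
  pos <- sample.int(length(chars), 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
  cstart <- pos - (pos - 1) %% 3
  old_cd <- paste(chars[cstart:(cstart + 2)], collapse = "")
  new <- chars; new[pos] <- alt
  new_cd <- paste(new[cstart:(cstart + 2)], collapse = "")
  new_aa <- code[[new_cd]]
  if (new_aa == "*") return(NULL)
  syn <- new_aa == code[[old_cd]]
  if (!syn && runif(1) >= omega) return(NULL)
  list(chars = new, syn = syn, codon_index = (cstart + 2) %/% 3,
       new_aa = new_aa)
}

#' Evolve coding sequences under a fixed dN/dS
#'
#' Descendants are generated from the ancestor coding sequence by repeated
#' single-nucleotide proposals: a random position and random different
#' base; proposals creating stop codons are discarded, synonymous changes
#' accepted, nonsynonymous changes accepted with probability `omega`
#' (`omega = 0` gives purely synonymous evolution). `branch_scale` sets the
#' expected number of proposals per nucleotide site on each descendant's
#' branch.
#'
#' @param ancestor_cds coding sequence (length divisible by 3, no internal
#'   stops).
#' @param n_descendants how many descendants to draw.
#' @param omega relative acceptance rate of nonsynonymous changes.
#' @param branch_scale proposals per nucleotide site per branch.
#' @return a list with `cds` (named character vector `d1..dn`) and
#'   `proteins` (their translations).
#' @export
simulate_codons <- function(ancestor_cds, n_descendants = 2, omega = 0.2,
                            branch_scale = 0.1) {
  stopifnot(omega >= 0, branch_scale > 0)
  code <- genetic_code()
  anc <- strsplit(toupper(ancestor_cds), "")[[1]]
  n_prop <- round(branch_scale * length(anc))
  cds <- vapply(seq_len(n_descendants), function(i) {
    chars <- anc
    for (k in seq_len(n_prop)) {
      st <- propose_step(chars, omega, code)
      if (!is.null(st)) chars <- st$chars
    }
    paste(chars, collapse = "")
  }, character(1))
  names(cds) <- paste0("d", seq_len(n_descendants))
  proteins <- vapply(cds, function(x)
    as.character(Biostrings::translate(Biostrings::DNAString(x))),
    character(1))
  list(cds = cds, proteins = proteins)
}

# Codon evolution until the translated protein reaches a target identity
# to the ancestor protein (used when the network-level identity band must
# be hit exactly while keeping codon-level omega control).
evolve_cds_to_identity <- function(ancestor_cds, omega, target_identity,
                                   max_proposals = NULL) {
  code <- genetic_code()
  chars <- strsplit(toupper(ancestor_cds), "")[[1]]
  anc_prot <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(ancestor_cds))), "")[[1]]
  np <- length(anc_prot)
  d_target <- round(np * (1 - target_identity / 100))
  max_proposals <- max_proposals %||% (500 * length(chars))
  cur_prot <- anc_prot
  d <- 0L
  for (k in seq_len(max_proposals)) {
    if (d >= d_target) break
    st <- propose_step(chars, omega, code)
    if (is.null(st)) next
    chars <- st$chars
    if (!st$syn) {
      i <- st$codon_index
      was_diff <- cur_prot[i] != anc_prot[i]
      cur_prot[i] <- st$new_aa
      d <- d + (cur_prot[i] != anc_prot[i]) - was_diff
    }
  }
  if (d < d_target)
    stop("identity band unreachable within proposal budget")
  paste(chars, collapse = "")
}
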