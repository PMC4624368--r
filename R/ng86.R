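# Nei-Gojobori (1986) pairwise dN/dS with fractional site counting,
# equal-weight averaging over minimal substitution paths, stop-codon
# exclusion and Jukes-Cantor correction. Lookup tables over the 64 codons
# are built once per session and cached.

.ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_env$tabs)) return(.ng86_env$tabs)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  nt <- c("A", "C", "G", "T")
  is_stop <- code == "*"
  # fractional synonymous/nonsynonymous sites per codon; mutations to stop
  # codons are excluded from the site opportunity (each position divides
  # by 3, so excluded mass shrinks the codon's total below 3)
  S <- N <- setNames(numeric(64), codons)
  for (cd in codons[!is_stop]) {
    chars <- strsplit(cd, "")[[1]]
    for (pos in 1:3) for (alt in setdiff(nt, chars[pos])) {
      mut <- chars; mut[pos] <- alt
      mcd <- paste(mut, collapse = "")
      if (is_stop[mcd]) next
      if (code[mcd] == code[cd]) S[cd] <- S[cd] + 1 / 3
      else N[cd] <- N[cd] + 1 / 3
    }
  }
  # per-pair synonymous/nonsynonymous difference counts, averaged over all
  # minimal substitution paths that avoid stop codons
  Sd <- Nd <- matrix(0, 64, 64, dimnames = list(codons, codons))
  valid <- matrix(TRUE, 64, 64, dimnames = list(codons, codons))
  for (i in seq_len(64)) for (j in seq_len(64)) {
    a <- codons[i]; b <- codons[j]
    if (a == b) next
    if (is_stop[a] || is_stop[b]) { valid[i, j] <- FALSE; next }
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    dpos <- which(ca != cb)
    perms <- permutations_of(dpos)
    sd_tot <- nd_tot <- 0; n_ok <- 0L
    for (ord in perms) {
      cur <- ca; sd <- nd <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- cb[pos]
        ncd <- paste(nxt, collapse = "")
        if (is_stop[ncd]) { ok <- FALSE; break }
        if (code[ncd] == code[paste(cur, collapse = "")]) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_ok <- n_ok + 1L }
    }
    if (n_ok == 0) valid[i, j] <- FALSE
    else { Sd[i, j] <- sd_tot / n_ok; Nd[i, j] <- nd_tot / n_ok }
  }
  .ng86_env$tabs <- list(S = S, N = N, Sd = Sd, Nd = Nd, valid = valid,
                         is_stop = is_stop)
  .ng86_env$tabs
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (k in seq_along(x))
    for (rest in permutations_of(x[-k]))
      out[[length(out) + 1L]] <- c(x[k], rest)
  out
}

#' Fractional synonymous/nonsynonymous site counts for one codon
#'
#' Each codon position contributes its fraction of synonymous single-
#' nucleotide changes. With `exclude_stops = TRUE` (the default used in the
#' pairwise estimator) mutations to stop codons are dropped from the site
#' opportunity, so S + N can fall below 3; with `exclude_stops = FALSE`
#' every one of the nine single-nucleotide mutations is classified and
#' S + N is exactly 3.
#'
#' @param codon a 3-letter codon string (ACGT alphabet).
#' @param exclude_stops drop mutations that create stop codons.
#' @return named numeric vector `c(S =, N =)`.
#' @export
ng86_codon_sites <- function(codon, exclude_stops = TRUE) {
  codon <- toupper(codon)
  code <- Biostrings::GENETIC_CODE
  if (!codon %in% names(code)) stop("not a codon: ", codon)
  if (code[codon] == "*") stop("stop codon has no site counts: ", codon)
  if (exclude_stops) {
    tabs <- ng86_tables()
    return(c(S = unname(tabs$S[codon]), N = unname(tabs$N[codon])))
  }
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
    mut <- chars; mut[pos] <- alt
    mcd <- paste(mut, collapse = "")
    if (code[mcd] != "*" && code[mcd] == code[codon]) s <- s + 1 / 3
  }
  c(S = s, N = 3 - s)
}

split_codons <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  if (n %% 3 != 0) stop("sequence length not a multiple of 3")
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

#' Pairwise NG86 dN/dS
#'
#' Nei-Gojobori fractional site counting over two aligned codon sequences.
#' Columns containing gaps, ambiguity characters or stop codons in either
#' sequence are skipped, as are columns whose every minimal substitution
#' path passes through a stop codon. Multi-substitution codons average
#' synonymous/nonsynonymous difference counts over all minimal paths with
#' equal weight. Proportions are corrected with the Jukes-Cantor formula
#' `d = -3/4 ln(1 - 4/3 p)`; `omega = dN/dS` is undefined (`NA`) when
#' `dS = 0`, when the pair is identical, or when either proportion is
#' saturated (p >= 3/4).
#'
#' @param codons_a,codons_b equal-length codon strings (length divisible
#'   by 3; gaps as `-`).
#' @return an object of class `ng86`: a list with `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `dS`, `dN`, `omega`, `n_codons`, `n_skipped`, `flags`,
#'   `method`.
#' @export
ng86_pair <- function(codons_a, codons_b) {
  ca <- split_codons(codons_a); cb <- split_codons(codons_b)
  if (length(ca) != length(cb)) stop("codon sequences differ in length")
  tabs <- ng86_tables()
  codons <- names(tabs$S)
  clean <- ca %in% codons & cb %in% codons &
    !tabs$is_stop[match(ca, codons)] & !tabs$is_stop[match(cb, codons)]
  clean[is.na(clean)] <- FALSE
  flags <- character(0)
  ia <- match(ca[clean], codons); ib <- match(cb[clean], codons)
  path_ok <- tabs$valid[cbind(ia, ib)] | (ia == ib)
  n_path_excluded <- sum(!path_ok)
  if (n_path_excluded > 0)
    flags <- c(flags, "codon_columns_without_stop-free_path_excluded")
  ia <- ia[path_ok]; ib <- ib[path_ok]
  n_used <- length(ia)
  n_skipped <- length(ca) - n_used
  if (n_used == 0) {
    return(structure(list(S = 0, N = 0, Sd = 0, Nd = 0, pS = NA_real_,
                          pN = NA_real_, dS = NA_real_, dN = NA_real_,
                          omega = NA_real_, n_codons = 0L,
                          n_skipped = n_skipped,
                          flags = c(flags, "no_comparable_codons"),
                          method = "NG86"), class = "ng86"))
  }
  S <- (sum(tabs$S[ia]) + sum(tabs$S[ib])) / 2
  N <- (sum(tabs$N[ia]) + sum(tabs$N[ib])) / 2
  Sd <- sum(tabs$Sd[cbind(ia, ib)])
  Nd <- sum(tabs$Nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS); dN <- jc(pN)
  if (!is.na(pS) && pS >= 3 / 4) flags <- c(flags, "pS_saturated")
  if (!is.na(pN) && pN >= 3 / 4) flags <- c(flags, "pN_saturated")
  omega <- NA_real_
  if (Sd == 0 && Nd == 0) {
    flags <- c(flags, "identical_sequences_omega_undefined")
  } else if (is.na(dS) || is.na(dN)) {
    flags <- c(flags, "omega_undefined_correction")
  } else if (dS == 0) {
    flags <- c(flags, "dS_zero_omega_undefined")
  } else {
    omega <- dN / dS
  }
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega, n_codons = n_used,
                 n_skipped = n_skipped, flags = flags, method = "NG86"),
            class = "ng86")
}

#' @export
print.ng86 <- function(x, ...) {
  cat("NG86 pairwise dN/dS over", x$n_codons, "codons\n")
  cat(sprintf("  S = %.2f  N = %.2f  Sd = %.2f  Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  dS = %s  dN = %s  omega = %s\n",
              format(x$dS), format(x$dN), format(x$omega)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Thread coding sequences onto a protein alignment
#'
#' Maps each protein alignment column to a codon triplet column: residues
#' take their codon from the coding sequence, protein gaps become `---`.
#' Each coding sequence must be exactly three times the ungapped protein
#' length (a trailing stop codon is stripped) and must translate to the
#' protein under the standard genetic code.
#'
#' @param protein_alignment named character vector of aligned protein rows.
#' @param cds named character vector of coding sequences (same names).
#' @return named character vector of codon-aligned nucleotide rows.
#' @export
backthread_codon_alignment <- function(protein_alignment, cds) {
  missing_cds <- setdiff(names(protein_alignment), names(cds))
  if (length(missing_cds))
    stop("no coding sequence for: ", paste(missing_cds, collapse = ", "))
  out <- vapply(names(protein_alignment), function(id) {
    prot_aln <- toupper(protein_alignment[[id]])
    prot <- gsub("-", "", prot_aln, fixed = TRUE)
    np <- nchar(prot)
    cd <- toupper(cds[[id]])
    if (nchar(cd) == 3 * (np + 1) &&
        substring(cd, nchar(cd) - 2) %in% c("TAA", "TAG", "TGA"))
      cd <- substring(cd, 1, nchar(cd) - 3)
    if (nchar(cd) != 3 * np)
      stop("coding sequence for '", id, "' has length ", nchar(cd),
           ", expected ", 3 * np)
    trans <- as.character(Biostrings::translate(
      Biostrings::DNAString(cd), if.fuzzy.codon = "X"))
    if (trans != prot) {
      bad <- which(strsplit(trans, "")[[1]] != strsplit(prot, "")[[1]])[1]
      stop("coding sequence for '", id, "' translates to '",
           substring(trans, bad, bad), "' but protein has '",
           substring(prot, bad, bad), "' at residue ", bad)
    }
    cod <- split_codons(cd)
    cols <- strsplit(prot_aln, "")[[1]]
    row <- character(length(cols))
    k <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") row[i] <- "---"
      else { k <- k + 1L; row[i] <- cod[k] }
    }
    paste(row, collapse = "")
  }, character(1))
  setNames(out, names(protein_alignment))
}

#' Average pairwise dN/dS over a clique alignment
#'
#' Runs [ng86_pair()] on every unordered pair of rows and averages the
#' defined omega values; pairs with undefined omega (identical sequences,
#' dS = 0, saturation) are excluded and counted.
#'
#' @param codon_alignment named character vector of codon-aligned rows.
#' @return a list with `avg_omega` (`NA` when no pair qualifies),
#'   `n_pairs`, `n_excluded` and `pairs` (per-pair data frame).
#' @export
clique_dnds <- function(codon_alignment) {
  ids <- names(codon_alignment)
  stopifnot(length(ids) >= 2)
  rows <- list()
  for (i in seq_len(length(ids) - 1)) for (j in seq(i + 1, length(ids))) {
    r <- ng86_pair(codon_alignment[[i]], codon_alignment[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = ids[i], id_b = ids[j], S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
      dS = r$dS, dN = r$dN, omega = r$omega,
      flags = paste(r$flags, collapse = ";"), stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  def <- !is.na(pairs$omega)
  list(avg_omega = if (any(def)) mean(pairs$omega[def]) else NA_real_,
       n_pairs = nrow(pairs), n_excluded = sum(!def), pairs = pairs)
}
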