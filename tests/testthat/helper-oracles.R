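# Shared fixtures and independent oracles. Everything here is deliberately
# written without the package's internal machinery: brute-force loops,
# Matrix::expm for matrix exponentials, seqinr for translation.

# a simple injected property scale (values unrelated to the packaged K0)
fixture_scale <- function() {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  aa_scale(setNames(seq(2, 40, by = 2), aas), name = "fixture")
}

# all 64 codons and their translation, independent of the package
oracle_codon_table <- function() {
  nucs <- c("A", "C", "G", "T")
  codons <- sort(apply(expand.grid(nucs, nucs, nucs,
                                   stringsAsFactors = FALSE),
                       1L, paste0, collapse = ""))
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]])
  }, character(1))
  data.frame(codon = codons, aa = aa, stringsAsFactors = FALSE)
}

# brute-force list of ordered single-step nonsynonymous substitutions
oracle_single_step_events <- function() {
  tab <- oracle_codon_table()
  sense <- tab[tab$aa != "*", ]
  out <- list()
  for (i in seq_len(nrow(sense))) {
    for (j in seq_len(nrow(sense))) {
      if (i == j) next
      ci <- sense$codon[i]; cj <- sense$codon[j]
      ndiff <- sum(strsplit(ci, "")[[1]] != strsplit(cj, "")[[1]])
      if (ndiff != 1) next
      if (sense$aa[i] == sense$aa[j]) next
      out[[length(out) + 1L]] <- c(ci, cj)
    }
  }
  do.call(rbind, out)
}

# independently coded Goldman-Yang rate matrix (same codon ordering as the
# package: alphabetical sense codons)
oracle_gy94_matrix <- function(kappa, omega, pi) {
  tab <- oracle_codon_table()
  sense <- tab[tab$aa != "*", ]
  codons <- sense$codon
  n <- length(codons)
  stopifnot(identical(names(pi), codons))
  is_ts <- function(a, b) {
    paste0(sort(c(a, b)), collapse = "") %in% c("AG", "CT")
  }
  Q <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      si <- strsplit(codons[i], "")[[1]]
      sj <- strsplit(codons[j], "")[[1]]
      diff <- which(si != sj)
      if (length(diff) != 1) next
      r <- pi[j]
      if (is_ts(si[diff], sj[diff])) r <- r * kappa
      if (sense$aa[i] != sense$aa[j]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

# transition matrix via Matrix::expm (independent of the package's
# eigendecomposition route)
oracle_pmat <- function(Q, t) {
  as.matrix(Matrix::expm(Q * t))
}

# brute-force phylogenetic likelihood by enumerating all internal-node
# state assignments. tip_states: ntip x nsites matrix of codon indices.
oracle_enum_loglik <- function(phy, pmats, pi, tip_states) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  nstate <- length(pi)
  combos <- as.matrix(expand.grid(rep(list(seq_len(nstate)), nnode)))
  root_col <- 1L   # node ntip+1 is column 1
  ll <- 0
  for (s in seq_len(ncol(tip_states))) {
    val <- pi[combos[, root_col]]
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      pstate <- combos[, p - ntip]
      cstate <- if (ch <= ntip) rep(tip_states[ch, s], nrow(combos))
                else combos[, ch - ntip]
      val <- val * pmats[[e]][cbind(pstate, cstate)]
    }
    ll <- ll + log(sum(val))
  }
  ll
}

# codon strings -> indices in the package's sense-codon order
codon_index <- function(mat) {
  codons <- names(sense_codons())
  matrix(match(mat, codons), nrow(mat), ncol(mat),
         dimnames = dimnames(mat))
}

# small alignment object from explicit codon strings per taxon
aln_from_codons <- function(...) {
  seqs <- vapply(list(...), paste0, character(1), collapse = "")
  codon_alignment(seqs)
}
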