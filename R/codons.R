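#' @importFrom stats setNames
NULL

NUCS <- c("A", "C", "G", "T")

# purine<->purine / pyrimidine<->pyrimidine pairs
.is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

#' Sense codons of a genetic code
#'
#' Returns the sense (non-stop) codons of a genetic code in alphabetical
#' order, together with the amino acid each encodes.
#'
#' @param numcode NCBI genetic code number (1 = standard nuclear code).
#' @return Named character vector: names are codons, values one-letter
#'   amino-acid codes. Stop codons are excluded.
#' @export
sense_codons <- function(numcode = 1) {
  all_codons <- apply(expand.grid(NUCS, NUCS, NUCS, stringsAsFactors = FALSE),
                      1L, paste0, collapse = "")
  all_codons <- sort(all_codons)
  aa <- vapply(all_codons, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]], numcode = numcode)
  }, character(1))
  keep <- aa != "*"
  if (sum(keep) < 60L) {
    stop("genetic code ", numcode, " yields fewer than 60 sense codons")
  }
  setNames(aa[keep], all_codons[keep])
}

# cached standard-code table (61 sense codons)
.std_code <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sense_codons(1)
    cache
  }
})

#' Empirical codon frequencies from an alignment
#'
#' Computes equilibrium codon frequencies over the 61 sense codons, either
#' from per-position nucleotide frequencies (F3X4) or from raw codon counts
#' (F61). Gaps and ambiguous codons are ignored. Frequencies are renormalised
#' over sense codons.
#'
#' @param aln A `codon_alignment` (see [read_codon_alignment()]).
#' @param model `"F3X4"` (default) or `"F61"`.
#' @param pseudocount Added to F61 counts so no sense codon has frequency 0.
#' @return Named numeric vector of length 61 summing to 1.
#' @export
codon_frequencies <- function(aln, model = c("F3X4", "F61"),
                              pseudocount = 0.5) {
  model <- match.arg(model)
  code <- .std_code()
  codons <- names(code)
  mat <- unclass(aln)
  obs <- mat[mat %in% codons]
  if (length(obs) == 0L) stop("alignment contains no unambiguous sense codons")
  if (model == "F61") {
    cnt <- table(factor(obs, levels = codons)) + pseudocount
    pi <- as.numeric(cnt) / sum(cnt)
  } else {
    pos_freq <- matrix(0, 3, 4, dimnames = list(NULL, NUCS))
    for (p in 1:3) {
      nt <- substr(obs, p, p)
      tab <- table(factor(nt, levels = NUCS))
      pos_freq[p, ] <- as.numeric(tab) / sum(tab)
    }
    pi <- vapply(codons, function(cd) {
      pos_freq[1, substr(cd, 1, 1)] *
        pos_freq[2, substr(cd, 2, 2)] *
        pos_freq[3, substr(cd, 3, 3)]
    }, numeric(1))
    pi <- pi / sum(pi)
  }
  setNames(pi, codons)
}

#' Uniform codon frequencies
#'
#' @return Named numeric vector, 1/61 for each sense codon.
#' @export
uniform_codon_frequencies <- function() {
  code <- .std_code()
  setNames(rep(1 / length(code), length(code)), names(code))
}

# validate a 61-codon frequency vector
.check_freqs <- function(freqs) {
  code <- .std_code()
  if (is.null(names(freqs)) || !setequal(names(freqs), names(code))) {
    stop("codon frequencies must be named by the 61 sense codons")
  }
  freqs <- freqs[names(code)]
  if (any(freqs < 0)) stop("codon frequencies must be nonnegative")
  if (abs(sum(freqs) - 1) > 1e-6) stop("codon frequencies must sum to 1")
  freqs / sum(freqs)
}
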