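#' Codon substitution rate matrix with a radical/conservative split
#'
#' Builds the 61x61 instantaneous rate matrix of the property-partitioned
#' codon model. Codon pairs differing at more than one nucleotide position
#' have rate 0. Single-step rates are `pi_j` (synonymous transversion),
#' `kappa*pi_j` (synonymous transition), and for nonsynonymous changes the
#' same expressions multiplied by `omega` (conservative pairs) or `gamma`
#' (radical pairs). With `gamma == omega` the matrix is the standard
#' Goldman-Yang codon model. The matrix is rescaled so the expected
#' substitution rate at stationarity is 1, making branch lengths expected
#' substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Conservative nonsynonymous/synonymous ratio (> 0).
#' @param gamma Radical nonsynonymous/synonymous ratio (> 0).
#' @param partition A [build_partition()] result classifying every
#'   single-step nonsynonymous pair.
#' @param freqs Codon frequencies over the 61 sense codons.
#' @param scaled If `FALSE`, skip the unit-rate rescaling.
#' @return 61x61 matrix with rows summing to 0, dimnames the sense codons.
#' @export
build_rate_matrix <- function(kappa, omega, gamma, partition, freqs,
                              scaled = TRUE) {
  stopifnot(kappa > 0, omega > 0, gamma > 0,
            inherits(partition, "radical_partition"))
  pi <- .check_freqs(freqs)
  codons <- names(.std_code())
  n <- length(codons)
  tpl <- .codon_template()
  cls <- .template_classes(partition)

  mult <- rep(1, nrow(tpl))
  mult[tpl$nonsyn] <- ifelse(cls[tpl$nonsyn] == "radical", gamma, omega)
  rates <- pi[tpl$j] * ifelse(tpl$transition, kappa, 1) * mult
  Q <- matrix(0, n, n, dimnames = list(codons, codons))
  Q[cbind(tpl$i, tpl$j)] <- rates
  diag(Q) <- -rowSums(Q)
  if (scaled) {
    mu <- -sum(pi * diag(Q))
    if (mu <= 0) stop("degenerate rate matrix (zero total rate)")
    Q <- Q / mu
  }
  Q
}

# Single-nucleotide-step structure of the standard code, computed once:
# one row per ordered sense-codon pair (i, j) differing at one position,
# with the transition/transversion flag, nonsynonymy, and the unordered
# pair key used by partitions.
.codon_template <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- .std_code()
    codons <- names(code)
    rows <- list()
    for (i in seq_along(codons)) {
      ci <- codons[i]
      for (pos in 1:3) {
        base <- substr(ci, pos, pos)
        for (nt in setdiff(NUCS, base)) {
          cj <- ci
          substr(cj, pos, pos) <- nt
          j <- match(cj, codons)
          if (is.na(j)) next   # stop codon
          rows[[length(rows) + 1L]] <- data.frame(
            i = i, j = j,
            transition = .is_transition(base, nt),
            nonsyn = code[[ci]] != code[[cj]],
            key = if (ci < cj) paste(ci, cj, sep = "|")
                  else paste(cj, ci, sep = "|"),
            stringsAsFactors = FALSE)
        }
      }
    }
    cache <<- do.call(rbind, rows)
    cache
  }
})

# radical/conservative class per template row (NA for synonymous), cached
# on the partition object's environment-free structure via attribute
.template_classes <- function(partition) {
  cls <- attr(partition, "template_classes")
  if (!is.null(cls)) return(cls)
  tpl <- .codon_template()
  cls <- rep(NA_character_, nrow(tpl))
  hit <- match(tpl$key[tpl$nonsyn], names(partition$lookup))
  if (anyNA(hit)) {
    stop("partition does not classify codon pair ",
         tpl$key[tpl$nonsyn][is.na(hit)][1])
  }
  cls[tpl$nonsyn] <- unname(partition$lookup[hit])
  cls
}

# Eigendecomposition of a reversible Q via the symmetric similarity
# transform S = D^{1/2} Q D^{-1/2}, D = diag(pi). Returns the pieces needed
# to form P(t) = A exp(L t) B cheaply for many t.
.decompose_q <- function(Q, freqs) {
  pi <- .check_freqs(freqs)
  sp <- sqrt(pi)
  S <- Q * (sp %o% (1 / sp))
  S <- (S + t(S)) / 2   # symmetrise against rounding
  es <- eigen(S, symmetric = TRUE)
  list(values = es$values,
       A = es$vectors / sp,          # diag(1/sp) %*% U
       B = t(es$vectors * sp))       # t(U) %*% diag(sp)
}

.pmat_from_decomp <- function(decomp, t) {
  P <- decomp$A %*% (exp(decomp$values * t) * decomp$B)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix
#'
#' Matrix exponential `P(t) = exp(Qt)` for a reversible codon rate matrix,
#' computed through the symmetric similarity transform implied by the
#' stationary frequencies.
#'
#' @param Q Rate matrix from [build_rate_matrix()].
#' @param t Branch length (>= 0), expected substitutions per codon.
#' @param freqs The stationary codon frequencies of `Q`.
#' @return Row-stochastic 61x61 matrix.
#' @export
transition_probabilities <- function(Q, t, freqs) {
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("branch length t must be a single finite value >= 0")
  }
  d <- .decompose_q(Q, freqs)
  P <- .pmat_from_decomp(d, t)
  dimnames(P) <- dimnames(Q)
  P
}
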