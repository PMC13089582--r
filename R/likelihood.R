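# ---- internal: alignment patterns and tree traversal structures ----

# site patterns: codon state index per taxon (NA = missing/ambiguous),
# collapsed to unique columns with weights
.aln_patterns <- function(aln) {
  code <- .std_code()
  mat <- unclass(aln)
  idx <- matrix(match(mat, names(code)), nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  key <- apply(idx, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- idx[, first, drop = FALSE]
  map <- match(key, key[first])
  list(states = pat, weights = as.numeric(table(map)[as.character(
    seq_len(sum(first)))]), site_map = map)
}

# postorder traversal plan for a tagged tree against alignment taxa
.tree_struct <- function(ttree, taxa) {
  stopifnot(inherits(ttree, "tagged_tree"))
  phy <- ttree$phylo
  if (!setequal(phy$tip.label, taxa)) {
    stop("alignment and tree taxa disagree; e.g. ",
         paste(utils::head(c(setdiff(taxa, phy$tip.label),
                             setdiff(phy$tip.label, taxa)), 3),
               collapse = ", "))
  }
  po <- ape::reorder.phylo(phy, "postorder")
  okey <- paste(phy$edge[, 1], phy$edge[, 2])
  pkey <- paste(po$edge[, 1], po$edge[, 2])
  perm <- match(pkey, okey)
  list(ntip = length(phy$tip.label),
       nnode = phy$Nnode,
       root = length(phy$tip.label) + 1L,
       edge = po$edge,
       lens = po$edge.length,
       tags = ttree$tags[perm],
       tip_row = function(aln_rows) match(phy$tip.label, aln_rows))
}

# Felsenstein pruning over precomputed per-edge transition matrices, with
# per-node column rescaling against underflow. pmats: list over postorder
# edges; tip_states: codon state index per tree tip x pattern (NA missing).
# Returns per-pattern log-likelihood.
.prune_scaled <- function(ts, pmats, tip_states, pi) {
  npat <- ncol(tip_states)
  nstate <- length(pi)
  partial <- vector("list", ts$ntip + ts$nnode)
  scalelog <- vector("list", ts$ntip + ts$nnode)
  tip_partial <- function(node) {
    L <- matrix(0, nstate, npat)
    s <- tip_states[node, ]
    miss <- is.na(s)
    if (any(miss)) L[, miss] <- 1
    if (any(!miss)) L[cbind(s[!miss], which(!miss))] <- 1
    L
  }
  for (e in seq_len(nrow(ts$edge))) {
    parent <- ts$edge[e, 1]
    child <- ts$edge[e, 2]
    if (child <= ts$ntip) {
      Lc <- tip_partial(child); sc <- 0
    } else {
      Lc <- partial[[child]]; sc <- scalelog[[child]]
    }
    contrib <- pmats[[e]] %*% Lc
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
      scalelog[[parent]] <- sc
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
      scalelog[[parent]] <- scalelog[[parent]] + sc
    }
    # rescale by the matrix maximum to guard against underflow (a scalar
    # factor keeps this cheap; pattern likelihood spreads at these tree
    # sizes stay far from the double-precision floor)
    cm <- max(partial[[parent]])
    if (cm > 0 && (cm < 1e-3 || cm > 1e3)) {
      partial[[parent]] <- partial[[parent]] / cm
      scalelog[[parent]] <- scalelog[[parent]] + log(cm)
    }
  }
  site <- as.numeric(pi %*% partial[[ts$root]])
  log(site) + scalelog[[ts$root]]
}

# per-edge transition matrices for one rate-matrix-per-tag setting
.edge_pmats <- function(ts, decomps_by_tag) {
  lapply(seq_len(nrow(ts$edge)), function(e) {
    .pmat_from_decomp(decomps_by_tag[[ts$tags[e]]], ts$lens[e])
  })
}

# ---- internal: single-class and mixture per-pattern log-likelihoods ----

# gamma_by_tag: named vector c(fg=, bg=) (may be equal)
.loglik_single <- function(pat, ts, kappa, omega, gamma_by_tag,
                           partition, freqs) {
  pi <- .check_freqs(freqs)
  tags_used <- unique(ts$tags)
  decomps <- lapply(setNames(tags_used, tags_used), function(tg) {
    Q <- build_rate_matrix(kappa, omega, gamma_by_tag[[tg]], partition, pi)
    .decompose_q(Q, pi)
  })
  pmats <- .edge_pmats(ts, decomps)
  tip_states <- pat$states[ts$tip_row(rownames(pat$states)), , drop = FALSE]
  .prune_scaled(ts, pmats, tip_states, pi)
}

# classes: data.frame(omega, gamma, prop); returns list(ll, class_ll)
.loglik_mixture <- function(pat, ts, kappa, classes, partition, freqs) {
  pi <- .check_freqs(freqs)
  tip_states <- pat$states[ts$tip_row(rownames(pat$states)), , drop = FALSE]
  class_ll <- matrix(NA_real_, nrow(classes), ncol(pat$states))
  for (c in seq_len(nrow(classes))) {
    Q <- build_rate_matrix(kappa, classes$omega[c], classes$gamma[c],
                           partition, pi)
    d <- .decompose_q(Q, pi)
    pmats <- lapply(seq_len(nrow(ts$edge)), function(e) {
      .pmat_from_decomp(d, ts$lens[e])
    })
    class_ll[c, ] <- .prune_scaled(ts, pmats, tip_states, pi)
  }
  # log sum_c p_c exp(ll_c), stably
  lp <- log(classes$prop) + class_ll
  m <- apply(lp, 2L, max)
  ll <- m + log(colSums(exp(sweep(lp, 2L, m))))
  list(ll = ll, class_ll = class_ll)
}

#' Phylogenetic log-likelihood under the property-partitioned codon model
#'
#' Computes the log-likelihood of a codon alignment on a tagged tree by
#' Felsenstein pruning. With `mixture = NULL` a single (omega, gamma) class
#' applies to all sites; `params$gamma` may be a single value or a named
#' pair `c(fg = , bg = )` giving foreground branches their own radical rate.
#' With a `mixture`, per-site likelihoods are proportion-weighted sums over
#' the site classes (no branch tags).
#'
#' @param aln A `codon_alignment`.
#' @param tree A [tagged_tree()] whose tips match the alignment taxa.
#' @param params List with `kappa`, `omega`, and `gamma` (scalar or
#'   `c(fg=, bg=)`).
#' @param partition A [build_partition()] result.
#' @param freqs Codon frequencies (default F3X4 from the alignment).
#' @param mixture Optional data frame with columns `omega`, `gamma`, `prop`
#'   (one row per site class, proportions summing to 1).
#' @return Total log-likelihood (numeric scalar) with attribute
#'   `"site_loglik"` giving the per-site values.
#' @export
log_likelihood <- function(aln, tree, params, partition,
                           freqs = codon_frequencies(aln), mixture = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (ncol(aln) == 0L) stop("empty alignment")
  pat <- .aln_patterns(aln)
  ts <- .tree_struct(tree, rownames(aln))
  if (is.null(mixture)) {
    g <- params$gamma
    gbt <- if (length(g) == 1L) c(fg = unname(g), bg = unname(g)) else {
      if (!all(c("fg", "bg") %in% names(g))) {
        stop("gamma must be scalar or named c(fg=, bg=)")
      }
      g
    }
    ll_pat <- .loglik_single(pat, ts, params$kappa, params$omega, gbt,
                             partition, freqs)
  } else {
    if (abs(sum(mixture$prop) - 1) > 1e-8) {
      stop("mixture proportions must sum to 1")
    }
    ll_pat <- .loglik_mixture(pat, ts, params$kappa, mixture, partition,
                              freqs)$ll
  }
  ll_site <- ll_pat[pat$site_map]
  structure(sum(ll_pat * pat$weights), site_loglik = ll_site)
}
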