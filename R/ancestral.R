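# ---- marginal ancestral reconstruction under the fitted codon model ----

# down (subtree) partials per node and per-edge contributions, single class.
# Returns list(partial=list of 61 x npat, contrib=list per postorder edge).
.down_pass <- function(ts, pmats, tip_states, nstate) {
  npat <- ncol(tip_states)
  partial <- vector("list", ts$ntip + ts$nnode)
  contrib <- vector("list", nrow(ts$edge))
  tip_partial <- function(node) {
    L <- matrix(0, nstate, npat)
    s <- tip_states[node, ]
    miss <- is.na(s)
    if (any(miss)) L[, miss] <- 1
    if (any(!miss)) L[cbind(s[!miss], which(!miss))] <- 1
    L
  }
  for (node in seq_len(ts$ntip)) partial[[node]] <- tip_partial(node)
  for (e in seq_len(nrow(ts$edge))) {
    parent <- ts$edge[e, 1]
    child <- ts$edge[e, 2]
    contrib[[e]] <- pmats[[e]] %*% partial[[child]]
    partial[[parent]] <- if (is.null(partial[[parent]])) contrib[[e]]
                         else partial[[parent]] * contrib[[e]]
    cm <- max(partial[[parent]])
    if (cm > 0 && (cm < 1e-3 || cm > 1e3)) {
      partial[[parent]] <- partial[[parent]] / cm
      # scale factors cancel in normalised posteriors; not tracked here
    }
  }
  list(partial = partial, contrib = contrib)
}

# outside partials G per node (root prior = pi); preorder over the
# postorder edge list reversed
.up_pass <- function(ts, pmats, down, pi) {
  npat <- ncol(down$partial[[ts$root]])
  G <- vector("list", ts$ntip + ts$nnode)
  G[[ts$root]] <- matrix(pi, length(pi), npat)
  edges_of <- split(seq_len(nrow(ts$edge)), ts$edge[, 1])
  for (e in rev(seq_len(nrow(ts$edge)))) {
    parent <- ts$edge[e, 1]
    child <- ts$edge[e, 2]
    sibs <- setdiff(edges_of[[as.character(parent)]], e)
    out <- G[[parent]]
    for (s in sibs) out <- out * down$contrib[[s]]
    Gc <- crossprod(pmats[[e]], out)   # t(P) %*% out
    cm <- max(Gc)
    if (cm > 0 && (cm < 1e-3 || cm > 1e3)) Gc <- Gc / cm
    G[[child]] <- Gc
  }
  G
}

# per-class posterior state matrices (61 x npat) at requested nodes
.node_posteriors_class <- function(ts, pmats, tip_states, pi, nodes) {
  down <- .down_pass(ts, pmats, tip_states, length(pi))
  G <- .up_pass(ts, pmats, down, pi)
  lapply(nodes, function(n) {
    num <- if (n == ts$root) pi * down$partial[[n]]
           else G[[n]] * down$partial[[n]]
    cs <- colSums(num)
    cs[cs == 0] <- 1
    sweep(num, 2L, cs, "/")
  })
}

#' Marginal ancestral codon posteriors
#'
#' Computes, for each requested node, the marginal posterior distribution
#' over the 61 sense codons at every site under the fitted (reversible)
#' property-partitioned model, by combining subtree ("down") and
#' rest-of-tree ("up") partial likelihoods. Under a site mixture the
#' posterior is the class-posterior-weighted average of the per-class
#' reconstructions. At a tip with an observed codon the posterior is a
#' point mass; at a missing entry it is prior/posterior weighted like any
#' internal node.
#'
#' @inheritParams log_likelihood
#' @param nodes Integer vector of ape node numbers (tips are
#'   `1..Ntip`, internal nodes `Ntip+1..`). Default: all internal nodes.
#' @return Named list (by node number) of `nsites x 61` matrices, each row
#'   summing to 1; class `node_posterior`.
#' @export
marginal_ancestral_states <- function(aln, tree, params, partition,
                                      freqs = codon_frequencies(aln),
                                      mixture = NULL, nodes = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  pat <- .aln_patterns(aln)
  ts <- .tree_struct(tree, rownames(aln))
  pi <- .check_freqs(freqs)
  codons <- names(pi)
  if (is.null(nodes)) nodes <- ts$root:(ts$ntip + ts$nnode)
  if (any(nodes < 1 | nodes > ts$ntip + ts$nnode)) {
    stop("node number(s) outside tree: ",
         paste(nodes[nodes < 1 | nodes > ts$ntip + ts$nnode], collapse = ", "))
  }
  tip_states <- pat$states[ts$tip_row(rownames(pat$states)), , drop = FALSE]

  if (is.null(mixture)) {
    g <- params$gamma
    gbt <- if (length(g) == 1L) c(fg = unname(g), bg = unname(g)) else g
    decomps <- lapply(c(fg = "fg", bg = "bg")[unique(ts$tags)],
                      function(tg) {
      Q <- build_rate_matrix(params$kappa, params$omega, gbt[[tg]],
                             partition, pi)
      .decompose_q(Q, pi)
    })
    pmats <- .edge_pmats(ts, decomps)
    post_pat <- .node_posteriors_class(ts, pmats, tip_states, pi, nodes)
  } else {
    # class posterior weights per pattern
    res <- .loglik_mixture(pat, ts, params$kappa, mixture, partition, pi)
    lp <- log(mixture$prop) + res$class_ll
    m <- apply(lp, 2L, max)
    w <- exp(sweep(lp, 2L, m))
    w <- sweep(w, 2L, colSums(w), "/")
    post_pat <- NULL
    for (c in seq_len(nrow(mixture))) {
      Q <- build_rate_matrix(params$kappa, mixture$omega[c],
                             mixture$gamma[c], partition, pi)
      d <- .decompose_q(Q, pi)
      pmats <- lapply(seq_len(nrow(ts$edge)), function(e) {
        .pmat_from_decomp(d, ts$lens[e])
      })
      pc <- .node_posteriors_class(ts, pmats, tip_states, pi, nodes)
      pc <- lapply(pc, function(mat) sweep(mat, 2L, w[c, ], "*"))
      post_pat <- if (is.null(post_pat)) pc
                  else Map(`+`, post_pat, pc)
    }
  }
  out <- lapply(post_pat, function(mat) {
    full <- t(mat[, pat$site_map, drop = FALSE])
    colnames(full) <- codons
    full
  })
  names(out) <- as.character(nodes)
  structure(out, class = "node_posterior")
}

#' Expected property value per site from a codon posterior
#'
#' `E[K0]_site = sum_codon P(codon) * K0(aa(codon))`.
#'
#' @param posterior One element of a [marginal_ancestral_states()] result
#'   (an `nsites x 61` matrix), or the whole `node_posterior` list (then a
#'   matrix with one column per node is returned).
#' @param scale An [aa_scale()].
#' @return Numeric vector of per-site expectations (or matrix for a list).
#' @export
expected_property <- function(posterior, scale) {
  stopifnot(inherits(scale, "aa_scale"))
  code <- .std_code()
  vals <- scale$values[code]
  if (inherits(posterior, "node_posterior")) {
    return(vapply(posterior, function(p) as.numeric(p %*% vals),
                  numeric(nrow(posterior[[1]]))))
  }
  stopifnot(is.matrix(posterior), ncol(posterior) == length(vals))
  as.numeric(posterior %*% vals)
}

#' Node number of the most recent common ancestor of a set of tips
#'
#' Convenience wrapper resolving clade specifications to ape node numbers.
#'
#' @param tree A [tagged_tree()] or `phylo`.
#' @param tips Character vector of tip labels (one tip returns its number).
#' @return Integer node number.
#' @export
mrca_node <- function(tree, tips) {
  phy <- if (inherits(tree, "tagged_tree")) tree$phylo else tree
  idx <- match(tips, phy$tip.label)
  if (anyNA(idx)) stop("tip not in tree: ", tips[is.na(idx)][1])
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(phy, idx)
}

#' Screen for convergent compressibility-decreasing substitutions
#'
#' For each specified lineage (a parent node and child node bounding a
#' branch of interest), flags sites that underwent an amino-acid
#' substitution (the most-probable parent and child amino acids differ) with
#' a decrease in the posterior-expected K0. Requiring an actual state change
#' keeps infinitesimal posterior-weighted drifts at conserved sites from
#' counting as decreases. The convergent set is the intersection of the
#' decreasing-substitution sites across all lineages; final candidates
#' additionally require a site-class posterior P(gamma1 classes) above
#' `posterior_threshold` (the probability that the site belongs to the
#' radical-rate-elevated mixture classes).
#'
#' @param posteriors A [marginal_ancestral_states()] result covering every
#'   node referenced by `lineages`.
#' @param lineages Named list; each element `list(parent =, child =)` with
#'   ape node numbers.
#' @param scale An [aa_scale()].
#' @param site_posterior Data frame from [fit_site_model()] (`$posterior`),
#'   with columns `site` and `p_gamma1`; or `NULL` to skip the site-class
#'   filter (equivalent to threshold 0).
#' @param posterior_threshold Threshold in (0, 1) on `p_gamma1`
#'   (default 0.95).
#' @param min_decrease Minimum magnitude of the expected K0 decrease for a
#'   site to count (default 0: any strict decrease).
#' @return List of class `convergence_screen`: `candidates` (data frame:
#'   site, per-lineage most-probable parent/child codons and amino acids,
#'   expected dK0, p_gamma1), `per_lineage` (data frames of all decreasing
#'   sites per lineage), `convergent_sites` (the intersection before the
#'   site-class filter).
#' @export
convergence_screen <- function(posteriors, lineages, scale,
                               site_posterior = NULL,
                               posterior_threshold = 0.95,
                               min_decrease = 0) {
  stopifnot(inherits(posteriors, "node_posterior"))
  if (length(lineages) < 1) stop("at least one lineage required")
  if (posterior_threshold <= 0 || posterior_threshold >= 1) {
    stop("posterior_threshold must be in (0, 1)")
  }
  code <- .std_code()
  per_lineage <- list()
  for (nm in names(lineages)) {
    ln <- lineages[[nm]]
    pp <- posteriors[[as.character(ln$parent)]]
    cp <- posteriors[[as.character(ln$child)]]
    if (is.null(pp) || is.null(cp)) {
      stop("posteriors missing for lineage ", nm)
    }
    ek_parent <- expected_property(pp, scale)
    ek_child <- expected_property(cp, scale)
    dk <- ek_child - ek_parent
    mp_p_all <- colnames(pp)[max.col(pp)]
    mp_c_all <- colnames(cp)[max.col(cp)]
    substituted <- code[mp_p_all] != code[mp_c_all]
    dec <- which(dk < -min_decrease & substituted)
    mp_parent <- mp_p_all[dec]
    mp_child <- mp_c_all[dec]
    per_lineage[[nm]] <- data.frame(
      lineage = rep(nm, length(dec)), site = dec,
      parent_codon = mp_parent, parent_aa = unname(code[mp_parent]),
      child_codon = mp_child, child_aa = unname(code[mp_child]),
      delta_K0 = dk[dec], stringsAsFactors = FALSE)
  }
  convergent <- Reduce(intersect, lapply(per_lineage, `[[`, "site"))
  if (!is.null(site_posterior)) {
    hi <- site_posterior$site[site_posterior$p_gamma1 > posterior_threshold]
    cand_sites <- intersect(convergent, hi)
  } else {
    cand_sites <- convergent
  }
  cand <- do.call(rbind, lapply(per_lineage, function(df) {
    df[df$site %in% cand_sites, , drop = FALSE]
  }))
  if (!is.null(site_posterior) && nrow(cand)) {
    cand$p_gamma1 <- site_posterior$p_gamma1[
      match(cand$site, site_posterior$site)]
  }
  rownames(cand) <- NULL
  structure(list(candidates = cand, per_lineage = per_lineage,
                 convergent_sites = sort(convergent),
                 posterior_threshold = posterior_threshold),
            class = "convergence_screen")
}

#' @export
print.convergence_screen <- function(x, ...) {
  cat("Convergence screen:",
      length(x$convergent_sites), "convergent decreasing site(s);",
      length(unique(x$candidates$site)), "candidate(s) after the",
      sprintf("P(gamma1) > %.2f filter\n", x$posterior_threshold))
  if (nrow(x$candidates)) print(x$candidates)
  invisible(x)
}
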