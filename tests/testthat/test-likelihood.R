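pi_u <- uniform_codon_frequencies()
part60 <- build_partition(k0_scale(), 60)
pars <- list(kappa = 3, omega = 0.5, gamma = 0.8)

test_that("zero-branch limit gives the stationary log-density of the
           observed codons", {
  aln <- aln_from_codons(A = c("ATG", "TGC", "GGG"),
                         B = c("ATG", "TGC", "GGG"))
  phy <- ape::read.tree(text = "(A:0,B:0);")
  ll <- log_likelihood(aln, tagged_tree(phy), pars, part60, freqs = pi_u)
  expect_equal(as.numeric(ll), sum(log(pi_u[c("ATG", "TGC", "GGG")])),
               tolerance = 1e-10)
})

test_that("pruning equals brute-force enumeration on small trees", {
  trees <- c("(A:0.2,B:0.35);",
             "(A:0.2,(B:0.1,C:0.3):0.15);",
             "((A:0.12,B:0.2):0.08,(C:0.3,D:0.05):0.11);")
  alns <- list(
    aln_from_codons(A = c("ATG", "TTT"), B = c("ACG", "TTC")),
    aln_from_codons(A = c("ATG", "CTT", "AAA"), B = c("ATA", "CTC", "AAG"),
                    C = c("ACG", "CTT", "AGA")),
    aln_from_codons(A = c("ATG", "GAT"), B = c("ATG", "GCT"),
                    C = c("CTG", "GAT"), D = c("ATC", "GAC")))
  Q <- build_rate_matrix(pars$kappa, pars$omega, pars$gamma, part60, pi_u)
  for (i in seq_along(trees)) {
    phy <- ape::read.tree(text = trees[i])
    aln <- alns[[i]]
    pmats <- lapply(phy$edge.length, function(t) oracle_pmat(Q, t))
    tips <- codon_index(unclass(aln))[phy$tip.label, , drop = FALSE]
    oracle <- oracle_enum_loglik(phy, pmats, pi_u, tips)
    got <- log_likelihood(aln, tagged_tree(phy), pars, part60, freqs = pi_u)
    expect_equal(as.numeric(got), oracle, tolerance = 1e-8)
  }
})

test_that("branch-tagged likelihood matches enumeration with per-branch
           matrices", {
  phy <- ape::read.tree(text = "(A:0.2,(B:0.1,C:0.3):0.15);")
  tags <- c("bg", "fg", "bg", "fg")[seq_len(nrow(phy$edge))]
  aln <- aln_from_codons(A = c("ATG", "CTT"), B = c("ATA", "CTC"),
                         C = c("ACG", "TTT"))
  g <- c(fg = 1.6, bg = 0.3)
  Qs <- lapply(g, function(gm) {
    build_rate_matrix(pars$kappa, pars$omega, gm, part60, pi_u)
  })
  pmats <- lapply(seq_len(nrow(phy$edge)), function(e) {
    oracle_pmat(Qs[[tags[e]]], phy$edge.length[e])
  })
  tips <- codon_index(unclass(aln))[phy$tip.label, , drop = FALSE]
  oracle <- oracle_enum_loglik(phy, pmats, pi_u, tips)
  got <- log_likelihood(aln, tagged_tree(phy, tags),
                        list(kappa = pars$kappa, omega = pars$omega,
                             gamma = g), part60, freqs = pi_u)
  expect_equal(as.numeric(got), oracle, tolerance = 1e-8)
})

test_that("mixture likelihood is the proportion-weighted site combination
           of its classes", {
  tt <- synthetic_cetacean_tree(fg_stems = FALSE)
  sim <- simulate_codon_alignment(tt, part60, 40, kappa = 3, omega = 0.4,
                                  gamma = 0.6, seed = 21)
  mix <- data.frame(omega = c(0.2, 0.9), gamma = c(0.4, 2.5),
                    prop = c(0.7, 0.3))
  ll_mix <- log_likelihood(sim$alignment, tt, list(kappa = 3), part60,
                           freqs = pi_u, mixture = mix)
  site_mix <- attr(ll_mix, "site_loglik")
  site_cls <- sapply(seq_len(nrow(mix)), function(c) {
    attr(log_likelihood(sim$alignment, tt,
                        list(kappa = 3, omega = mix$omega[c],
                             gamma = mix$gamma[c]),
                        part60, freqs = pi_u), "site_loglik")
  })
  manual <- log(exp(site_cls) %*% mix$prop)
  expect_equal(site_mix, as.numeric(manual), tolerance = 1e-9)
  # degenerate mixture = single class
  mix1 <- data.frame(omega = c(0.4, 0.4), gamma = c(0.6, 0.6),
                     prop = c(0.5, 0.5))
  ll1 <- log_likelihood(sim$alignment, tt, list(kappa = 3), part60,
                        freqs = pi_u, mixture = mix1)
  ll2 <- log_likelihood(sim$alignment, tt,
                        list(kappa = 3, omega = 0.4, gamma = 0.6),
                        part60, freqs = pi_u)
  expect_equal(as.numeric(ll1), as.numeric(ll2), tolerance = 1e-9)
})

test_that("likelihood is invariant to rerooting, taxon order, and site
           order", {
  phy <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.3):0.07);")
  set.seed(8)
  tt <- tagged_tree(phy)
  sim <- simulate_codon_alignment(tt, part60, 30, kappa = 3, omega = 0.4,
                                  gamma = 0.6, seed = 22)
  aln <- sim$alignment
  base <- as.numeric(log_likelihood(aln, tt, pars, part60, freqs = pi_u))
  # reroot: same unrooted metric, different rooted representation
  for (og in c("A", "C", "D")) {
    re <- ape::root(ape::unroot(phy), outgroup = og, resolve.root = TRUE)
    ll <- as.numeric(log_likelihood(aln, tagged_tree(re), pars, part60,
                                    freqs = pi_u))
    expect_equal(ll, base, tolerance = 1e-8)
  }
  # taxon order
  perm <- unclass(aln)[c("D", "B", "A", "C"), ]
  aln_perm <- structure(perm, class = "codon_alignment")
  expect_equal(as.numeric(log_likelihood(aln_perm, tt, pars, part60,
                                         freqs = pi_u)), base,
               tolerance = 1e-10)
  # site order
  set.seed(9)
  aln_shuf <- structure(unclass(aln)[, sample(ncol(aln))],
                        class = "codon_alignment")
  expect_equal(as.numeric(log_likelihood(aln_shuf, tt, pars, part60,
                                         freqs = pi_u)), base,
               tolerance = 1e-10)
})

test_that("gaps and ambiguity codes act as missing data", {
  phy <- ape::read.tree(text = "(A:0.1,(B:0.1,C:0.1):0.1);")
  tt <- tagged_tree(phy)
  aln <- aln_from_codons(A = c("ATG", "---"), B = c("ATG", "NNN"),
                         C = c("ATG", "CTT"))
  ll <- log_likelihood(aln, tt, pars, part60, freqs = pi_u)
  # site 2 carries information only through C; its site likelihood is the
  # stationary probability of the observed codon
  site_ll <- attr(ll, "site_loglik")
  expect_equal(site_ll[2], log(pi_u[["CTT"]]), tolerance = 1e-8)
})

test_that("input validation: taxon mismatch and empty alignment", {
  phy <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- aln_from_codons(A = "ATG", X = "ATG")
  expect_error(log_likelihood(aln, tagged_tree(phy), pars, part60,
                              freqs = pi_u), "disagree")
  empty <- structure(matrix(character(0), 2, 0,
                            dimnames = list(c("A", "B"), NULL)),
                     class = "codon_alignment")
  expect_error(log_likelihood(empty, tagged_tree(phy), pars, part60,
                              freqs = pi_u), "empty")
})
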