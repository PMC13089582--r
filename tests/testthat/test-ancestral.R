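pi_u <- uniform_codon_frequencies()
part60 <- build_partition(k0_scale(), 60)
pars <- list(kappa = 3, omega = 0.5, gamma = 0.8)

test_that("tip posteriors are point masses on observed codons and rows
           normalise", {
  phy <- ape::read.tree(text = "(A:0.2,(B:0.1,C:0.1):0.1);")
  tt <- tagged_tree(phy)
  aln <- aln_from_codons(A = c("ATG", "---"), B = c("ACG", "CTT"),
                         C = c("ATA", "CTC"))
  post <- marginal_ancestral_states(aln, tt, pars, part60, freqs = pi_u,
                                    nodes = c(1, 4, 5))
  pA <- post[["1"]]
  expect_equal(unname(pA[1, "ATG"]), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(post[["4"]]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(post[["5"]]) - 1) < 1e-9))
  # missing tip entry: a proper distribution, not a point mass
  expect_lt(max(pA[2, ]), 1)
  expect_equal(sum(pA[2, ]), 1, tolerance = 1e-9)
  expect_error(marginal_ancestral_states(aln, tt, pars, part60,
                                         freqs = pi_u, nodes = 99),
               "outside")
})

test_that("marginal posteriors match brute-force Bayes enumeration on a
           3-taxon tree", {
  phy <- ape::read.tree(text = "(A:0.2,(B:0.1,C:0.3):0.15);")
  tt <- tagged_tree(phy)
  aln <- aln_from_codons(A = c("ATG", "CTT"), B = c("ATA", "CTC"),
                         C = c("ACG", "TTT"))
  Q <- build_rate_matrix(pars$kappa, pars$omega, pars$gamma, part60, pi_u)
  pmats <- lapply(phy$edge.length, function(t) oracle_pmat(Q, t))
  tips <- codon_index(unclass(aln))[phy$tip.label, , drop = FALSE]
  got <- marginal_ancestral_states(aln, tt, pars, part60, freqs = pi_u,
                                   nodes = c(4, 5))
  # enumerate joint internal-state probabilities, then marginalise
  nstate <- 61
  for (s in 1:2) {
    joint <- matrix(0, nstate, nstate)  # node4 (root) x node5
    for (x in seq_len(nstate)) {
      for (y in seq_len(nstate)) {
        p <- pi_u[x]
        for (e in seq_len(nrow(phy$edge))) {
          from <- phy$edge[e, 1]; to <- phy$edge[e, 2]
          a <- if (from == 4) x else y
          b <- if (to <= 3) tips[to, s] else y
          p <- p * pmats[[e]][a, b]
        }
        joint[x, y] <- p
      }
    }
    expect_equal(unname(got[["4"]][s, ]),
                 unname(rowSums(joint) / sum(joint)), tolerance = 1e-8)
    expect_equal(unname(got[["5"]][s, ]),
                 unname(colSums(joint) / sum(joint)), tolerance = 1e-8)
  }
})

test_that("expected property integrates the codon posterior over the
           scale", {
  sc <- k0_scale()
  codons <- names(sense_codons())
  nsite <- 2
  post <- matrix(0, nsite, 61, dimnames = list(NULL, codons))
  post[1, "GCC"] <- 1                       # point mass on Ala
  post[2, c("TCC", "GCC")] <- 0.5           # half Ser, half Ala
  expect_equal(expected_property(post, sc),
               c(sc$values[["A"]],
                 mean(sc$values[c("S", "A")])), tolerance = 1e-12)
})

test_that("posterior-weighted ancestral states shift the expected property
           away from the point-state value", {
  # the same substitution event yields slightly different expected dK0 in
  # different lineages because ancestral states are probabilistic
  sc <- k0_scale()
  codons <- names(sense_codons())
  p1 <- matrix(0, 1, 61, dimnames = list(NULL, codons))
  p2 <- p1
  p1[1, "TCC"] <- 0.98; p1[1, "GCC"] <- 0.02
  p2[1, "TCC"] <- 0.90; p2[1, "GCC"] <- 0.10
  child <- p1; child[1, ] <- 0; child[1, "GCC"] <- 1
  d1 <- expected_property(child, sc) - expected_property(p1, sc)
  d2 <- expected_property(child, sc) - expected_property(p2, sc)
  expect_true(d1 < 0 && d2 < 0)
  expect_gt(abs(d1), abs(d2))
  expect_equal(d1, delta_property("S", "A", sc) * 0.98, tolerance = 1e-12)
})

test_that("convergence screen: set relations, lineage-order invariance,
           and reduction without the site filter", {
  sc <- k0_scale()
  codons <- names(sense_codons())
  point <- function(cods) {
    m <- matrix(0, length(cods), 61, dimnames = list(NULL, codons))
    m[cbind(seq_along(cods), match(cods, codons))] <- 1
    m
  }
  # 6 sites; parents/children chosen so that:
  #  site 1 decreases in both lineages (S->A), high p_gamma1
  #  site 2 decreases only in lineage 1 (L->P)
  #  site 3 decreases in both but low p_gamma1 (I->V)
  #  sites 4-6 unchanged
  par1 <- point(c("TCC", "CTG", "ATC", "AAA", "GGG", "TGG"))
  ch1 <- point(c("GCC", "CCG", "GTC", "AAA", "GGG", "TGG"))
  par2 <- point(c("TCC", "CTG", "ATC", "AAA", "GGG", "TGG"))
  ch2 <- point(c("GCC", "CTG", "GTC", "AAA", "GGG", "TGG"))
  posts <- structure(list(`10` = par1, `11` = ch1, `12` = par2, `13` = ch2),
                     class = "node_posterior")
  sp <- data.frame(site = 1:6,
                   p_gamma1 = c(0.99, 0.99, 0.10, 0.99, 0.99, 0.99))
  lins <- list(phys = list(parent = 10, child = 11),
               ziph = list(parent = 12, child = 13))
  scr <- convergence_screen(posts, lins, sc, site_posterior = sp)
  expect_equal(sort(unique(scr$candidates$site)), 1)
  expect_equal(scr$convergent_sites, c(1, 3))
  # candidates are a subset of each lineage's decreasing list
  for (pl in scr$per_lineage) {
    expect_true(all(unique(scr$candidates$site) %in% pl$site))
  }
  # lineage order does not matter
  scr2 <- convergence_screen(posts, rev(lins), sc, site_posterior = sp)
  expect_equal(sort(unique(scr2$candidates$site)),
               sort(unique(scr$candidates$site)))
  expect_equal(scr2$convergent_sites, scr$convergent_sites)
  # single lineage, no site filter: the plain decreasing list
  scr3 <- convergence_screen(posts, lins["phys"], sc, site_posterior = NULL)
  expect_equal(sort(unique(scr3$candidates$site)), c(1, 2, 3))
  # reported codon states are the most probable ones
  expect_equal(scr$candidates$parent_codon[scr$candidates$site == 1],
               c("TCC", "TCC"))
  expect_equal(scr$candidates$child_aa[scr$candidates$site == 1],
               c("A", "A"))
  # no decrease anywhere -> empty candidate set
  scr4 <- convergence_screen(structure(list(`10` = par1, `11` = par1),
                                       class = "node_posterior"),
                             list(l = list(parent = 10, child = 11)), sc,
                             site_posterior = NULL)
  expect_equal(nrow(scr4$candidates), 0)
  expect_error(convergence_screen(posts, lins, sc, sp,
                                  posterior_threshold = 1.5), "in \\(0, 1\\)")
})

test_that("planted convergent compressibility-decreasing site is recovered
           exactly", {
  sc <- k0_scale()
  tt <- synthetic_cetacean_tree()
  mix <- data.frame(omega = c(0.3, 0.3, 2, 2), gamma = c(0.3, 3, 0.3, 3),
                    prop = c(0.55, 0.18, 0.18, 0.09))
  sim <- simulate_codon_alignment(tt, part60, 150, kappa = 4,
                                  mixture = mix, seed = 41)
  aln <- unclass(sim$alignment)
  # plant an S -> A change on both deep-clade stems at a gamma1-class site:
  # ancestors serine, the two deep clades alanine
  gamma1_sites <- which(sim$site_class %in% c(2, 4))
  planted <- gamma1_sites[1]
  aln[, planted] <- "TCC"
  deep <- grep("^deep", rownames(aln))
  aln[deep, planted] <- "GCC"
  aln <- structure(aln, class = "codon_alignment")
  # truth-based site-class posterior (generator truth, not refit)
  sp <- data.frame(site = seq_len(ncol(aln)),
                   p_gamma1 = as.numeric(sim$site_class %in% c(2, 4)))
  phy <- tt$phylo
  lins <- list(
    deep1 = list(parent = phy$edge[tt$tags == "fg", 1][1],
                 child = mrca_node(tt, c("deep1_a", "deep1_b"))),
    deep2 = list(parent = phy$edge[tt$tags == "fg", 1][2],
                 child = mrca_node(tt, c("deep2_a", "deep2_b"))))
  nodes <- unique(unlist(lapply(lins, unlist)))
  post <- marginal_ancestral_states(aln, tt, list(kappa = 4), part60,
                                    freqs = codon_frequencies(aln),
                                    mixture = mix, nodes = nodes)
  scr <- convergence_screen(post, lins, sc, site_posterior = sp,
                            posterior_threshold = 0.95)
  expect_equal(unique(scr$candidates$site), planted)
  row <- scr$candidates[scr$candidates$lineage == "deep1", ]
  expect_equal(row$parent_aa, "S")
  expect_equal(row$child_aa, "A")
  expect_lt(row$delta_K0, 0)
})
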