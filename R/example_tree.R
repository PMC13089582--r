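#' Default synthetic study phylogeny
#'
#' A fixed 12-taxon tree mimicking, at reduced scale, the study layout: two
#' separate "deep-diving" clades whose stem branches are tagged foreground,
#' all other branches background. Branch lengths are in expected codon
#' substitutions and of realistic magnitude for a conserved vertebrate
#' gene.
#'
#' @param fg_stems Tag the two deep clades' stem branches as foreground
#'   (default `TRUE`; `FALSE` gives an all-background tree).
#' @return A [tagged_tree()].
#' @export
synthetic_cetacean_tree <- function(fg_stems = TRUE) {
  nwk <- paste0(
    "(((deep1_a:0.06,deep1_b:0.06):0.12,(bg_a:0.09,bg_b:0.09):0.09):0.05,",
    "(((deep2_a:0.05,deep2_b:0.05):0.14,(bg_c:0.08,bg_d:0.08):0.11):0.04,",
    "((bg_e:0.07,bg_f:0.07):0.06,(bg_g:0.10,bg_h:0.10):0.03):0.05):0.04);")
  phy <- ape::read.tree(text = nwk)
  tags <- rep("bg", nrow(phy$edge))
  if (fg_stems) {
    for (cl in list(c("deep1_a", "deep1_b"), c("deep2_a", "deep2_b"))) {
      stem <- which(phy$edge[, 2] == ape::getMRCA(phy, cl))
      tags[stem] <- "fg"
    }
  }
  tagged_tree(phy, tags)
}
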