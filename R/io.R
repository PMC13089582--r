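#' Codon alignment objects
#'
#' A codon alignment is stored as a character matrix of codon triplets
#' (taxa in rows, codon sites in columns, row names the taxon labels).
#' Gaps and ambiguity codes are retained as written and treated as missing
#' data by the likelihood machinery.
#'
#' @param seqs Named character vector of aligned nucleotide sequences, all
#'   the same length, lengths divisible by 3.
#' @param stop_policy What to do with internal stop codons: `"error"`
#'   (default) or `"missing"` (replace with `"---"` and warn). A terminal
#'   stop codon shared by all sequences is trimmed silently.
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs, stop_policy = c("error", "missing")) {
  stop_policy <- match.arg(stop_policy)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("sequences must be named by taxon")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate taxon labels: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs <- toupper(gsub("U", "T", toupper(seqs)))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences differ in length")
  if (lens[1] %% 3 != 0) {
    stop("sequence length ", lens[1], " not divisible by 3 (taxon ",
         names(seqs)[1], ")")
  }
  bad <- which(nchar(seqs) %% 3 != 0)
  if (length(bad)) stop("length not divisible by 3 for taxon ",
                        names(seqs)[bad[1]])
  nsite <- lens[1] %/% 3
  mat <- matrix("", length(seqs), nsite,
                dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    mat[i, ] <- substring(seqs[i], 3 * seq_len(nsite) - 2, 3 * seq_len(nsite))
  }
  code <- .std_code()
  is_stop <- matrix(!(mat %in% names(code)) &
                      mat %in% c("TAA", "TAG", "TGA"),
                    nrow(mat), ncol(mat))
  # trim a shared terminal stop
  if (nsite > 1 && all(is_stop[, nsite] | !grepl("^[ACGT]{3}$", mat[, nsite]))
      && any(is_stop[, nsite])) {
    mat <- mat[, -nsite, drop = FALSE]
    is_stop <- is_stop[, -nsite, drop = FALSE]
  }
  if (any(is_stop)) {
    w <- which(is_stop, arr.ind = TRUE)[1, ]
    msg <- sprintf("internal stop codon at site %d in taxon %s",
                   w[2], rownames(mat)[w[1]])
    if (stop_policy == "error") stop(msg) else {
      warning(msg, "; treated as missing data")
      mat[is_stop] <- "---"
    }
  }
  structure(mat, class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d taxa x %d codon sites\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file, codon-aligned (lengths divisible by 3).
#' @param stop_policy Passed to [codon_alignment()].
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path, stop_policy = c("error", "missing")) {
  if (!file.exists(path)) stop("file not found: ", path)
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                           seqtype = "DNA")
  seqs <- vapply(fa, function(s) as.character(s)[1], character(1))
  codon_alignment(setNames(seqs, names(fa)), stop_policy = stop_policy)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste0, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = rownames(aln), file.out = path)
  invisible(path)
}

#' Tagged phylogeny
#'
#' Couples an `ape` phylogeny with a foreground/background tag for every
#' branch. Tags drive the branch variant of the codon model: `fg` branches
#' get their own radical-rate parameter.
#'
#' @param phy An `ape::phylo` with branch lengths.
#' @param tags Character vector of `"fg"`/`"bg"`, one per edge of `phy`
#'   (row order of `phy$edge`), or `NULL` for all-background.
#' @return Object of class `tagged_tree`: list with `phylo` and `tags`.
#' @export
tagged_tree <- function(phy, tags = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  ne <- nrow(phy$edge)
  if (is.null(tags)) tags <- rep("bg", ne)
  if (length(tags) != ne || !all(tags %in% c("fg", "bg"))) {
    stop("tags must be one 'fg'/'bg' value per branch")
  }
  structure(list(phylo = phy, tags = tags), class = "tagged_tree")
}

#' @export
print.tagged_tree <- function(x, ...) {
  cat(sprintf("Tagged tree: %d tips, %d branches (%d fg, %d bg)\n",
              length(x$phylo$tip.label), nrow(x$phylo$edge),
              sum(x$tags == "fg"), sum(x$tags == "bg")))
  invisible(x)
}

# edge indices of the stem + internal branches of the clade spanned by tips
.clade_edges <- function(phy, tips, include_descendants = TRUE) {
  idx <- match(tips, phy$tip.label)
  if (anyNA(idx)) stop("clade tip not in tree: ", tips[is.na(idx)][1])
  if (length(idx) == 1L) {
    node <- idx
  } else {
    node <- ape::getMRCA(phy, idx)
  }
  stem <- which(phy$edge[, 2] == node)
  if (!include_descendants || length(idx) == 1L) return(stem)
  desc <- .descendant_nodes(phy, node)
  c(stem, which(phy$edge[, 1] %in% c(node, desc)))
}

.descendant_nodes <- function(phy, node) {
  out <- integer(0)
  stack <- phy$edge[phy$edge[, 1] == node, 2]
  while (length(stack)) {
    out <- c(out, stack)
    stack <- phy$edge[phy$edge[, 1] %in% stack, 2]
  }
  out
}

#' Read a Newick tree with foreground tags
#'
#' Two tagging dialects are supported and may be combined, in which case
#' they must agree: (1) `#1` suffixes on tip or internal-node labels mark
#' the branch leading to that node as foreground; (2) `fg_clades`, a list of
#' tip-label vectors, marks each clade's stem branch (and, with
#' `include_descendants = TRUE`, all branches inside the clade) as
#' foreground.
#'
#' @param path Newick file with branch lengths.
#' @param fg_clades Optional list of character vectors of tip labels.
#' @param include_descendants Whether clade tagging includes the branches
#'   within the clade (default `FALSE`: stem branch only, the usual
#'   foreground-lineage convention).
#' @return A [tagged_tree()].
#' @export
read_tagged_tree <- function(path, fg_clades = NULL,
                             include_descendants = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("could not parse Newick in ", path)
  ne <- nrow(phy$edge)
  ntip <- length(phy$tip.label)
  tag_nodes <- integer(0)
  has_tag <- grepl("#\\d+$", phy$tip.label)
  if (any(has_tag)) {
    tag_nodes <- c(tag_nodes, which(has_tag))
    phy$tip.label <- sub("\\s*#\\d+$", "", phy$tip.label)
  }
  if (!is.null(phy$node.label)) {
    has_ntag <- grepl("#\\d+$", phy$node.label)
    if (any(has_ntag)) {
      tag_nodes <- c(tag_nodes, ntip + which(has_ntag))
      phy$node.label <- sub("\\s*#\\d+$", "", phy$node.label)
    }
  }
  tags_inline <- rep("bg", ne)
  tags_inline[phy$edge[, 2] %in% tag_nodes] <- "fg"

  tags_clade <- NULL
  if (!is.null(fg_clades)) {
    tags_clade <- rep("bg", ne)
    for (cl in fg_clades) {
      tags_clade[.clade_edges(phy, cl, include_descendants)] <- "fg"
    }
  }
  if (length(tag_nodes) && !is.null(tags_clade)) {
    if (!identical(tags_inline, tags_clade)) {
      bad <- which(tags_inline != tags_clade)
      stop("inline #tags and fg_clades disagree on branch(es) ",
           paste(bad, collapse = ", "))
    }
  }
  tags <- if (!is.null(tags_clade) && !length(tag_nodes)) tags_clade
          else tags_inline
  tagged_tree(phy, tags)
}

# write a delimited table with '#' metadata header lines
.write_report <- function(df, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
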