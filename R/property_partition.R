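#' Amino-acid property scales
#'
#' An amino-acid property scale maps each of the 20 standard amino acids to a
#' numeric value. The scale used throughout this package is amino-acid
#' compressibility K0 (units m^3 mol^-1 Pa^-1 x 1e-15), stored as a
#' magnitude, so that a substitution lowering the value is one that reduces
#' the compressibility of the residue. Any other 20-value scale (volume,
#' hydrophobicity, ...) can be injected through the same constructor.
#'
#' @param values Named numeric vector: names are one-letter amino-acid codes,
#'   exactly the 20 standard residues, all finite.
#' @param name Text label for the scale.
#' @return An object of class `aa_scale`.
#' @export
aa_scale <- function(values, name = "custom") {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  if (is.null(names(values)) || !setequal(names(values), aas)) {
    missing <- setdiff(aas, names(values))
    stop("scale must cover exactly the 20 standard amino acids",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")))
  }
  values <- values[aas]
  if (!all(is.finite(values))) stop("scale values must all be finite")
  structure(list(values = values, name = name), class = "aa_scale")
}

#' @export
print.aa_scale <- function(x, ...) {
  cat("Amino-acid property scale:", x$name, "\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Read an amino-acid property scale from a delimited file
#'
#' Expects two columns (one-letter amino-acid code, value), whitespace- or
#' tab-delimited; a header line and `#` comment lines are allowed.
#'
#' @param path File path.
#' @param name Label for the scale; defaults to the file name.
#' @return An [aa_scale()] object.
#' @export
read_property_scale <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("scale file must have two columns: aa, value")
  # drop an optional header row
  if (is.na(suppressWarnings(as.numeric(tab[1, 2])))) tab <- tab[-1, ]
  vals <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(vals)) stop("non-numeric scale values in ", path)
  aa_scale(setNames(vals, toupper(tab[[1]])), name = name)
}

#' Packaged amino-acid compressibility scale
#'
#' The K0 magnitudes shipped with the package (see
#' `inst/extdata/k0_scale_synthetic.tsv`). This table is a synthetic
#' reconstruction: it preserves the pairwise K0 differences that the
#' rhodopsin analysis constrains and fills in the remaining residues with
#' plausible values; it is not a transcription of any published scale.
#'
#' @return An [aa_scale()] object named `"K0-synthetic"`.
#' @export
k0_scale <- function() {
  path <- system.file("extdata", "k0_scale_synthetic.tsv",
                      package = "rhodopress", mustWork = TRUE)
  read_property_scale(path, name = "K0-synthetic")
}

#' Enumerate single-step nonsynonymous codon substitutions
#'
#' Lists every ordered pair of sense codons that differ at exactly one
#' nucleotide position and encode different amino acids. Changes to or from
#' stop codons are excluded entirely.
#'
#' @param numcode NCBI genetic code number (default 1, standard code).
#' @return Data frame with columns `from_codon`, `to_codon`, `from_aa`,
#'   `to_aa`, `position` (1-3), `transition` (logical).
#' @export
single_step_nonsynonymous_pairs <- function(numcode = 1) {
  code <- if (numcode == 1) .std_code() else sense_codons(numcode)
  codons <- names(code)
  out <- vector("list", length(codons))
  for (i in seq_along(codons)) {
    ci <- codons[i]
    rows <- list()
    for (pos in 1:3) {
      base <- substr(ci, pos, pos)
      for (nt in setdiff(NUCS, base)) {
        cj <- ci
        substr(cj, pos, pos) <- nt
        if (!cj %in% codons) next            # stop codon
        if (code[[ci]] == code[[cj]]) next   # synonymous
        rows[[length(rows) + 1L]] <- data.frame(
          from_codon = ci, to_codon = cj,
          from_aa = code[[ci]], to_aa = code[[cj]],
          position = pos, transition = .is_transition(base, nt),
          stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signed property change of a substitution
#'
#' @param from_aa,to_aa One-letter amino-acid codes (vectorised).
#' @param scale An [aa_scale()].
#' @return `scale(to_aa) - scale(from_aa)`; antisymmetric under swapping the
#'   arguments.
#' @export
delta_property <- function(from_aa, to_aa, scale) {
  stopifnot(inherits(scale, "aa_scale"))
  bad <- setdiff(unique(c(from_aa, to_aa)), names(scale$values))
  if (length(bad)) {
    stop("amino acid(s) absent from scale: ", paste(bad, collapse = ", "))
  }
  unname(scale$values[to_aa] - scale$values[from_aa])
}

#' Radical/conservative partition of nonsynonymous substitutions
#'
#' Ranks the single-nucleotide-accessible nonsynonymous substitution events
#' by the absolute property change |dK0| and designates the top `P` percent
#' as radical, the remainder as conservative. Ranking is at the level of
#' unordered codon-pair events, so the classification is symmetric under
#' pair reversal. Ties at the boundary are resolved inclusively: every event
#' with |dK0| >= the cutoff value is radical.
#'
#' @param scale An [aa_scale()].
#' @param P Percent of events to call radical. The analysis grid is
#'   10, 20, ..., 90; other values in (0, 100) are accepted with a warning.
#' @param numcode Genetic code number.
#' @return An object of class `radical_partition`: a list with `P`,
#'   `threshold` (the |dK0| cutoff), `events` (unordered-pair table with
#'   columns `from_codon`, `to_codon`, `from_aa`, `to_aa`, `delta_K0`,
#'   `abs_delta_K0`, `class`), `scale_name`, and `lookup` (named character
#'   vector keyed by "codon1|codon2" with the two codons sorted).
#' @export
build_partition <- function(scale, P, numcode = 1) {
  stopifnot(inherits(scale, "aa_scale"))
  if (length(P) != 1L || !is.finite(P) || P <= 0 || P >= 100) {
    stop("P must be a single percent in (0, 100)")
  }
  if (!P %in% seq(10, 90, by = 10)) {
    warning("P = ", P, " is outside the standard grid 10, 20, ..., 90")
  }
  ev <- single_step_nonsynonymous_pairs(numcode)
  # collapse ordered events to unordered pairs
  key <- ifelse(ev$from_codon < ev$to_codon,
                paste(ev$from_codon, ev$to_codon, sep = "|"),
                paste(ev$to_codon, ev$from_codon, sep = "|"))
  ev <- ev[!duplicated(key), c("from_codon", "to_codon", "from_aa", "to_aa")]
  ev$delta_K0 <- delta_property(ev$from_aa, ev$to_aa, scale)
  ev$abs_delta_K0 <- abs(ev$delta_K0)
  ev <- ev[order(-ev$abs_delta_K0, ev$from_codon, ev$to_codon), ]
  rownames(ev) <- NULL
  n_rad <- floor(nrow(ev) * P / 100)
  if (n_rad < 1L) stop("P too small: no event would be radical")
  threshold <- ev$abs_delta_K0[n_rad]
  ev$class <- ifelse(ev$abs_delta_K0 >= threshold, "radical", "conservative")
  lk <- setNames(ev$class, ifelse(ev$from_codon < ev$to_codon,
                                  paste(ev$from_codon, ev$to_codon, sep = "|"),
                                  paste(ev$to_codon, ev$from_codon, sep = "|")))
  structure(list(P = P, threshold = threshold, events = ev,
                 scale_name = scale$name, lookup = lk),
            class = "radical_partition")
}

#' @export
print.radical_partition <- function(x, ...) {
  cat(sprintf("Radical/conservative partition (scale %s): P = %d%%\n",
              x$scale_name, x$P))
  cat(sprintf("  |dK0| threshold %.4g; %d radical / %d conservative pairs\n",
              x$threshold, sum(x$events$class == "radical"),
              sum(x$events$class == "conservative")))
  invisible(x)
}

# class of an unordered codon pair; error if not a single-step nonsyn pair
.pair_class <- function(partition, codon_i, codon_j) {
  key <- ifelse(codon_i < codon_j, paste(codon_i, codon_j, sep = "|"),
                paste(codon_j, codon_i, sep = "|"))
  cl <- partition$lookup[key]
  if (anyNA(cl)) stop("codon pair not in partition: ", key[is.na(cl)][1])
  cl
}

#' Write a partition report
#'
#' One row per unordered codon-pair event with its property change and
#' radical/conservative class, preceded by `#` metadata lines.
#'
#' @param partition A [build_partition()] result.
#' @param path Output file.
#' @export
write_partition_report <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rhodopress radical/conservative partition"),
    sprintf("# scale: %s  P: %d  threshold: %.6g",
            partition$scale_name, partition$P, partition$threshold)), con)
  utils::write.table(partition$events, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
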