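#' Write a trajectory as a multi-frame PDB
#'
#' One MODEL per frame, Calpha atoms only, residue numbers from the
#' trajectory object.
#'
#' @param traj A [coordinate_trajectory()].
#' @param path Output path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  traj <- .as_trajectory(traj)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(traj$coords)[1]
  n <- dim(traj$coords)[2]
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[f, , , drop = TRUE]
    if (n == 1L) xyz <- matrix(xyz, 1, 3)
    lines <- sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), traj$residue, xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-frame PDB as a coordinate trajectory
#'
#' Parses MODEL blocks through `bio3d` and returns the Calpha coordinates
#' per frame. Masses default to the carbon mass for every atom.
#'
#' @param path PDB file with one MODEL per frame.
#' @return A [coordinate_trajectory()].
#' @export
read_trajectory_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  n <- ncol(xyz) / 3
  coords <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  coordinate_trajectory(coords, residue = pdb$atom$resno[seq_len(n)])
}
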