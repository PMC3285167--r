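#' Resolve PDB-style atom selections to indices
#'
#' Collective variables may address atoms either by integer index or, when a
#' structure file is available, by a PDB-style selection `"RESNAME
#' RESNO ATOMNAME"` (for example `"GLU 22 HE2"`). Parsing uses bio3d's PDB
#' reader (first model only); this helper is the only place the package
#' touches structure files.
#'
#' @param pdb_file Path to a PDB file.
#' @param selections Character vector of `"resid resno elety"` selections,
#'   or a list mixing integers (passed through) and such strings.
#' @return Integer vector of 1-based atom indices.
#' @export
resolve_pdb_selection <- function(pdb_file, selections) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stopf("PDB selection resolution requires the bio3d package")
  pdb <- bio3d::read.pdb(pdb_file, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  one <- function(sel) {
    if (is.numeric(sel)) return(as.integer(sel))
    parts <- strsplit(trimws(sel), "[[:space:]]+")[[1]]
    if (length(parts) != 3)
      stopf("selection '%s' is not of the form 'RESNAME RESNO ATOMNAME'", sel)
    hit <- which(atoms$resid == toupper(parts[1]) &
                   atoms$resno == as.integer(parts[2]) &
                   atoms$elety == toupper(parts[3]))
    if (length(hit) == 0) stopf("selection '%s' matches no atom", sel)
    if (length(hit) > 1)
      stopf("selection '%s' is ambiguous (%d atoms)", sel, length(hit))
    hit
  }
  vapply(as.list(selections), one, integer(1))
}

#' Read coordinates of a PDB file as a frame
#'
#' Convenience: first-model coordinates as an n x 3 matrix usable with
#' [eval_lcod()].
#'
#' @param pdb_file Path to a PDB file.
#' @return n x 3 coordinate matrix (angstrom).
#' @export
pdb_frame <- function(pdb_file) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stopf("PDB reading requires the bio3d package")
  pdb <- bio3d::read.pdb(pdb_file, multi = FALSE, verbose = FALSE)
  m <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}
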