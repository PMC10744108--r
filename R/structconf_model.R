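read_model <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("cif", "mmcif")) bio3d::read.cif(file) else
    bio3d::read.pdb(file)
}

#' Per-residue confidence (pLDDT) track from a predicted model
#'
#' Predicted models store the per-residue confidence in the B-factor
#' column. One value per residue is extracted using the representative-atom
#' convention: the CA atom for polymer residues, the first atom otherwise.
#' Gaps in residue numbering within a chain are reported in the `gaps`
#' attribute, not filled.
#'
#' @param model path to a PDB or mmCIF file, or a `bio3d` pdb object
#' @return data frame with `chain`, `resno`, `plddt`; attribute `gaps`
#'   lists missing residue numbers per chain
#' @export
plddt_track <- function(model) {
  pdb <- if (is.character(model)) read_model(model) else model
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("model contains no atoms")
  key <- factor(paste(at$chain, at$resno),
                levels = unique(paste(at$chain, at$resno)))
  # representative atom: CA when present, else the residue's first atom
  pick <- vapply(split(seq_len(nrow(at)), key), function(rows) {
    ca <- rows[at$elety[rows] == "CA"]
    if (length(ca) > 0L) ca[1L] else rows[1L]
  }, integer(1))
  out <- data.frame(chain = at$chain[pick], resno = at$resno[pick],
                    plddt = at$b[pick], stringsAsFactors = FALSE)
  gaps <- lapply(split(out$resno, out$chain), function(rn) {
    setdiff(seq(min(rn), max(rn)), rn)
  })
  attr(out, "gaps") <- gaps[vapply(gaps, length, 1L) > 0L]
  out
}

#' Atom set for contact analysis
#'
#' A flat table of atoms (element symbol, coordinates in Angstrom, chain,
#' residue number and name, atom name) paired with a van der Waals radius
#' table. Every element must have a radius entry; coordinates must be
#' finite.
#'
#' @param atoms data frame with columns `elem`, `x`, `y`, `z`, `chain`,
#'   `resno`, and optionally `name` and `resid`
#' @param radii named numeric vector element -> radius (Angstrom);
#'   defaults to [vdw_radii()]
#' @return an object of class `atom_set`
#' @export
atom_set <- function(atoms, radii = vdw_radii()) {
  req <- c("elem", "x", "y", "z", "chain", "resno")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  missing <- setdiff(unique(atoms$elem), names(radii))
  if (length(missing) > 0L)
    stop("no van der Waals radius for element(s): ",
         paste(missing, collapse = ", "))
  if (is.null(atoms$name)) atoms$name <- atoms$elem
  if (is.null(atoms$resid)) atoms$resid <- NA_character_
  structure(list(atoms = atoms, radii = radii), class = "atom_set")
}

#' Build an atom set from a PDB/mmCIF model
#'
#' @param model path to a PDB or mmCIF file, or a `bio3d` pdb object
#' @param radii radius table, see [atom_set()]
#' @return an [atom_set()]
#' @export
as_atom_set <- function(model, radii = vdw_radii()) {
  pdb <- if (is.character(model)) read_model(model) else model
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- sub("^[0-9]*", "", at$elety)
    elem <- toupper(substr(elem, 1L, 1L))
  }
  elem <- sub("^\\s+|\\s+$", "", elem)
  elem <- paste0(toupper(substr(elem, 1L, 1L)),
                 tolower(substr(elem, 2L, nchar(elem))))
  atom_set(data.frame(elem = elem, x = at$x, y = at$y, z = at$z,
                      chain = at$chain, resno = at$resno,
                      name = at$elety, resid = at$resid,
                      stringsAsFactors = FALSE),
           radii = radii)
}

#' Van der Waals radius table
#'
#' Element radii in Angstrom from the Bondi (1964) compilation, shipped
#' with the package; override with a two-column CSV (`element`, `radius`).
#'
#' @param file optional CSV path replacing the packaged table
#' @return named numeric vector, element -> radius
#' @export
vdw_radii <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "vdw_radii_bondi1964.csv",
                        package = "fretab", mustWork = TRUE)
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  stats::setNames(tab$radius, tab$element)
}
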