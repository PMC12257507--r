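#' Atomic masses for common protein/ligand elements
#'
#' Named vector of standard atomic masses (unified atomic mass units) used
#' when loading structures. The pseudo-element `"X"` (mass 1) is used for
#' chemistry-free model particles such as nanoparticle atoms.
#'
#' @format Named numeric vector, names are element symbols.
#' @export
element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, B = 10.81, SI = 28.085, F = 18.998, CL = 35.45,
  BR = 79.904, I = 126.904, "NA" = 22.990, K = 39.098, MG = 24.305,
  CA = 40.078, MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
  CU = 63.546, ZN = 65.38, X = 1.0
)

#' Construct an atom cloud
#'
#' An `atomcloud` is the common currency of the structural pipeline: an
#' ordered set of atoms with Cartesian coordinates in nanometres plus
#' per-atom metadata. All structural observables ([rmsd()],
#' [radius_of_gyration()], [min_distance()]) operate on this container.
#'
#' @param coords Numeric matrix with one row per atom and columns x, y, z,
#'   in nm. Coordinates must be finite.
#' @param element Element symbols, recycled to the number of atoms. Used for
#'   mass lookup when `mass` is `NULL`.
#' @param mass Atomic masses (u). Defaults to a lookup in [element_masses].
#' @param chain,resno,resid Chain identifier, residue sequence number and
#'   residue name, recycled.
#' @param is_hetero Logical flag per atom (HETATM origin), recycled.
#' @param occupancy Occupancy in `[0, 1]`, recycled.
#' @param altloc Alternate-location label (`""` when absent), recycled.
#' @param source_label Free-text provenance string.
#' @return An object of class `atomcloud`: a list with elements `atoms`
#'   (data frame), `source_label` and `unit` (always `"nm"`).
#' @examples
#' cl <- atom_cloud(rbind(c(0, 0, 0), c(1, 0, 0)), element = "C")
#' n_atoms(cl)
#' @export
atom_cloud <- function(coords, element = "X", mass = NULL, chain = "A",
                       resno = 1L, resid = "UNK", is_hetero = FALSE,
                       occupancy = 1, altloc = "", source_label = "user") {
  coords <- as.matrix(coords)
  if (is.vector(coords)) coords <- matrix(coords, ncol = 3)
  if (ncol(coords) != 3) stop("coords must have 3 columns (x, y, z in nm)")
  if (nrow(coords) < 1) stop("an atom cloud needs at least one atom")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  element <- toupper(rep_len(as.character(element), n))
  if (is.null(mass)) {
    mass <- unname(element_masses[element])
    if (anyNA(mass)) {
      bad <- unique(element[is.na(mass)])
      stop("no mass known for element(s): ", paste(bad, collapse = ", "))
    }
  } else {
    mass <- rep_len(as.numeric(mass), n)
  }
  if (any(mass <= 0)) stop("atomic masses must be positive")
  occupancy <- rep_len(as.numeric(occupancy), n)
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancy must lie in [0, 1]")
  atoms <- data.frame(
    element = element,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    mass = mass,
    chain = rep_len(as.character(chain), n),
    resno = rep_len(as.integer(resno), n),
    resid = rep_len(as.character(resid), n),
    is_hetero = rep_len(as.logical(is_hetero), n),
    occupancy = occupancy,
    altloc = rep_len(as.character(altloc), n),
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, source_label = source_label, unit = "nm"),
            class = "atomcloud")
}

#' Number of atoms in a cloud
#' @param cloud An `atomcloud`.
#' @return Integer atom count.
#' @export
n_atoms <- function(cloud) {
  stopifnot(inherits(cloud, "atomcloud"))
  nrow(cloud$atoms)
}

#' Coordinate matrix of a cloud
#' @param cloud An `atomcloud`.
#' @return Numeric matrix (n x 3), nm.
#' @export
coords <- function(cloud) {
  stopifnot(inherits(cloud, "atomcloud"))
  as.matrix(cloud$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a cloud
#'
#' Returns a copy of `cloud` with new coordinates; all other per-atom
#' metadata, atom order and provenance are preserved.
#'
#' @param cloud An `atomcloud`.
#' @param xyz Numeric matrix (n x 3), nm.
#' @return An `atomcloud`.
#' @export
set_coords <- function(cloud, xyz) {
  stopifnot(inherits(cloud, "atomcloud"))
  xyz <- as.matrix(xyz)
  if (!identical(dim(xyz), c(n_atoms(cloud), 3L)) &&
      !(nrow(xyz) == n_atoms(cloud) && ncol(xyz) == 3)) {
    stop("replacement coordinates must be an n x 3 matrix")
  }
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  cloud$atoms$x <- xyz[, 1]
  cloud$atoms$y <- xyz[, 2]
  cloud$atoms$z <- xyz[, 3]
  cloud
}

#' Rigidly translate a cloud
#' @param cloud An `atomcloud`.
#' @param shift Numeric length-3 vector, nm.
#' @return Translated copy of the cloud.
#' @export
translate_cloud <- function(cloud, shift) {
  stopifnot(length(shift) == 3, all(is.finite(shift)))
  set_coords(cloud, sweep(coords(cloud), 2, as.numeric(shift), "+"))
}

#' Summarise an atom cloud
#'
#' @param cloud An `atomcloud`.
#' @return A list with `n_atoms`, `chains` (sorted unique chain ids),
#'   `bounding_box` (2 x 3 matrix of min/max per axis, nm) and
#'   `total_mass` (u).
#' @examples
#' describe(atom_cloud(diag(3)))
#' @export
describe <- function(cloud) {
  stopifnot(inherits(cloud, "atomcloud"))
  xyz <- coords(cloud)
  bb <- rbind(min = apply(xyz, 2, min), max = apply(xyz, 2, max))
  colnames(bb) <- c("x", "y", "z")
  list(
    n_atoms = n_atoms(cloud),
    chains = sort(unique(cloud$atoms$chain)),
    bounding_box = bb,
    total_mass = sum(cloud$atoms$mass)
  )
}

#' @export
print.atomcloud <- function(x, ...) {
  d <- describe(x)
  cat("<atomcloud> ", d$n_atoms, " atoms, chains: ",
      paste(d$chains, collapse = ","), "\n", sep = "")
  cat("  source: ", x$source_label, " (coordinates in nm)\n", sep = "")
  ext <- d$bounding_box["max", ] - d$bounding_box["min", ]
  cat(sprintf("  extent: %.3f x %.3f x %.3f nm, total mass %.1f u\n",
              ext[1], ext[2], ext[3], d$total_mass))
  invisible(x)
}
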