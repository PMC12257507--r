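#' Specification of a simplified nanoparticle model
#'
#' The nanoparticle is represented without chemistry: `n_atoms` point
#' atoms placed independently and uniformly inside a cube. The default
#' 20 nm box edge matches the modelled particle size; the atom count is a
#' free resolution parameter recorded in every report.
#'
#' @param n_atoms Number of atoms (>= 1). Default 1000.
#' @param box_edge Cube edge length, nm (> 0). Default 20.
#' @param seed RNG seed for reproducible generation.
#' @return A `np_spec` list.
#' @export
np_spec <- function(n_atoms = 1000L, box_edge = 20, seed = 1L) {
  n_atoms <- as.integer(n_atoms)
  if (is.na(n_atoms) || n_atoms < 1) stop("n_atoms must be >= 1")
  if (!is.finite(box_edge) || box_edge <= 0) stop("box_edge must be > 0")
  structure(list(n_atoms = n_atoms, box_edge = box_edge,
                 seed = as.integer(seed)),
            class = "np_spec")
}

#' Generate a random-atom nanoparticle cloud
#'
#' Draws `n_atoms` positions i.i.d. uniform on `[0, box_edge]^3`. The draw
#' order is fixed (atom-major, axis-minor: x, y, z for atom 1, then atom 2,
#' ...) so a given seed always yields the identical cloud. Atoms carry the
#' pseudo-element `"X"` with unit mass.
#'
#' @param spec A [np_spec()].
#' @return An [atom_cloud()] labelled with the generating spec.
#' @examples
#' np <- generate_np(np_spec(n_atoms = 100, seed = 7))
#' range(coords(np))
#' @export
generate_np <- function(spec = np_spec()) {
  stopifnot(inherits(spec, "np_spec"))
  set.seed(spec$seed)
  xyz <- matrix(stats::runif(3 * spec$n_atoms, 0, spec$box_edge),
                ncol = 3, byrow = TRUE)
  cl <- atom_cloud(xyz, element = "X", mass = 1, chain = "N",
                   is_hetero = TRUE, resid = "NPX",
                   source_label = sprintf("np(n=%d, edge=%g, seed=%d)",
                                          spec$n_atoms, spec$box_edge,
                                          spec$seed))
  cl
}

#' Relative placement of protein and nanoparticle
#'
#' @param mode `"gap"` (translate the protein along +x so the minimum
#'   protein-nanoparticle distance equals `gap` exactly), `"centered"`
#'   (protein centroid moved onto the nanoparticle centroid) or
#'   `"explicit-offset"` (protein centroid at nanoparticle centroid +
#'   `offset`).
#' @param gap Surface-to-surface separation along +x, nm (>= 0).
#' @param offset Length-3 translation, nm, used by `"explicit-offset"`.
#' @return A `placement_spec` list.
#' @export
placement_spec <- function(mode = c("gap", "centered", "explicit-offset"),
                           gap = 0.1, offset = c(0, 0, 0)) {
  mode <- match.arg(mode)
  if (mode == "gap" && (!is.finite(gap) || gap < 0)) {
    stop("gap must be >= 0")
  }
  if (length(offset) != 3 || !all(is.finite(offset))) {
    stop("offset must be a finite length-3 vector")
  }
  structure(list(mode = mode, gap = gap, offset = as.numeric(offset)),
            class = "placement_spec")
}

#' Compose a protein-nanoparticle scene
#'
#' Rigidly translates the protein into the stated placement; the
#' nanoparticle is never moved and neither input is modified. In `"gap"`
#' mode the protein's minimum-x atom is placed exactly `gap` nm along +x
#' from the nanoparticle's maximum-x atom with matched y and z; every
#' other cross pair is then at least `gap` apart, so the minimum
#' protein-nanoparticle distance equals `gap` by construction.
#'
#' @param protein,np `atomcloud` objects.
#' @param placement A [placement_spec()].
#' @return A `scene` list with elements `protein`, `np` and `placement`.
#' @examples
#' np <- generate_np(np_spec(n_atoms = 50, seed = 1))
#' prot <- atom_cloud(rbind(c(0, 0, 0), c(0.5, 0, 0)), element = "C")
#' sc <- compose_scene(prot, np, placement_spec("gap", gap = 1))
#' min_distance(sc$protein, sc$np)  # exactly 1
#' @export
compose_scene <- function(protein, np, placement = placement_spec()) {
  stopifnot(inherits(protein, "atomcloud"), inherits(np, "atomcloud"),
            inherits(placement, "placement_spec"))
  pxyz <- coords(protein)
  nxyz <- coords(np)
  shift <- switch(placement$mode,
    gap = {
      ip <- which.min(pxyz[, 1])[1]
      iq <- which.max(nxyz[, 1])[1]
      c(nxyz[iq, 1] + placement$gap - pxyz[ip, 1],
        nxyz[iq, 2] - pxyz[ip, 2],
        nxyz[iq, 3] - pxyz[ip, 3])
    },
    centered = colMeans(nxyz) - colMeans(pxyz),
    `explicit-offset` = colMeans(nxyz) + placement$offset - colMeans(pxyz)
  )
  structure(list(protein = translate_cloud(protein, shift),
                 np = np,
                 placement = placement,
                 shift = shift),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene> protein:", n_atoms(x$protein), "atoms | nanoparticle:",
      n_atoms(x$np), "atoms | placement:", x$placement$mode, "\n")
  invisible(x)
}
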