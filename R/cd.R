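#' Circular dichroism spectrum
#'
#' Mean-residue-ellipticity curve on an ascending wavelength grid inside
#' the far-UV window 190-240 nm.
#'
#' @param wavelengths Ascending wavelengths, nm, within `[190, 240]`,
#'   at least 10 points.
#' @param ellipticity Mean residue ellipticity per wavelength
#'   (deg cm^2 dmol^-1).
#' @return A `cd_spectrum` list.
#' @export
cd_spectrum <- function(wavelengths, ellipticity) {
  wavelengths <- as.numeric(wavelengths)
  ellipticity <- as.numeric(ellipticity)
  if (length(wavelengths) != length(ellipticity)) {
    stop("wavelengths and ellipticity must have equal length")
  }
  if (length(wavelengths) < 10) stop("a spectrum needs at least 10 points")
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly ascending")
  }
  if (min(wavelengths) < 190 || max(wavelengths) > 240) {
    stop("wavelength grid must lie within [190, 240] nm")
  }
  structure(list(wavelengths = wavelengths, ellipticity = ellipticity),
            class = "cd_spectrum")
}

#' Secondary-structure fractions
#'
#' Non-negative (alpha-helix, beta-sheet, random-coil) fractions summing
#' to one.
#'
#' @param alpha,beta,coil Fractions in `[0, 1]` summing to 1 (within
#'   1e-9).
#' @return A `ss_fractions` list.
#' @examples
#' ss_fractions(0.8759, 0.0048, 0.1193)
#' @export
ss_fractions <- function(alpha, beta, coil) {
  f <- c(alpha = alpha, beta = beta, coil = coil)
  if (any(!is.finite(f)) || any(f < -1e-12) || any(f > 1 + 1e-12)) {
    stop("fractions must lie in [0, 1]")
  }
  if (abs(sum(f) - 1) > 1e-9) stop("fractions must sum to 1 (within 1e-9)")
  structure(as.list(pmin(pmax(f, 0), 1)), class = "ss_fractions")
}

#' @export
print.ss_fractions <- function(x, ...) {
  cat(sprintf(
    "<ss_fractions> alpha %.2f%%  beta %.2f%%  coil %.2f%%\n",
    100 * x$alpha, 100 * x$beta, 100 * x$coil))
  invisible(x)
}

# sum of Gaussian bands: centers (nm), widths (nm, sd), amplitudes
.cd_bands <- function(wl, centers, widths, amps) {
  y <- numeric(length(wl))
  for (i in seq_along(centers)) {
    y <- y + amps[i] * exp(-0.5 * ((wl - centers[i]) / widths[i])^2)
  }
  y
}

#' Packaged three-component CD reference basis
#'
#' Idealised mean-residue-ellipticity curves for pure alpha-helix,
#' beta-sheet and random coil on a 1 nm grid from 190 to 240 nm, built
#' from sums of Gaussian bands with the hallmark features of each state:
#' the helix basis has a strong positive pi-pi* band near 192 nm and the
#' two negative bands near 209 and 222-223 nm; the sheet basis a positive
#' band near 196 nm and a single negative band near 218 nm; the coil
#' basis a deep negative band near 198 nm. Band parameters are versioned
#' in the source; a user basis can be supplied from CSV via
#' [read_basis_csv()].
#'
#' @return A `cd_basis`: list with `wavelengths` and the matrix `curves`
#'   (columns alpha, beta, coil) plus a `provenance` note.
#' @examples
#' b <- builtin_cd_basis()
#' b$wavelengths[which.min(b$curves[, "alpha"])]
#' @export
builtin_cd_basis <- function() {
  wl <- seq(190, 240, by = 1)
  alpha <- .cd_bands(wl, c(192, 208, 222), c(5.5, 4.5, 5),
                     c(70000, -32000, -35000))
  beta <- .cd_bands(wl, c(196, 218), c(5.5, 6.5), c(35000, -14000))
  coil <- .cd_bands(wl, c(198, 222), c(6.5, 10), c(-42000, 2500))
  new_cd_basis(wl, cbind(alpha = alpha, beta = beta, coil = coil),
               provenance = "npcorona builtin idealized basis v1")
}

#' Construct a CD basis
#'
#' @param wavelengths Common ascending grid, nm.
#' @param curves Numeric matrix with columns `alpha`, `beta`, `coil`.
#' @param provenance Free-text provenance note.
#' @return A `cd_basis` list.
#' @export
new_cd_basis <- function(wavelengths, curves, provenance = "user") {
  curves <- as.matrix(curves)
  if (nrow(curves) != length(wavelengths) || ncol(curves) != 3) {
    stop("curves must be a length(wavelengths) x 3 matrix")
  }
  colnames(curves) <- c("alpha", "beta", "coil")
  # coarse shape check: the helix component must show its two negative
  # bands (local minima) in the 209-210 and 222-225 nm windows
  a <- curves[, "alpha"]
  loc_min <- which(diff(sign(diff(a))) > 0) + 1
  wmin <- wavelengths[loc_min]
  if (!any(wmin >= 208 & wmin <= 211) || !any(wmin >= 221 & wmin <= 226)) {
    warning("alpha basis lacks the expected negative bands near ",
            "209-210 and 222-225 nm")
  }
  structure(list(wavelengths = as.numeric(wavelengths), curves = curves,
                 provenance = provenance),
            class = "cd_basis")
}

#' Synthesize a CD spectrum from fractions
#'
#' Pointwise linear combination of the basis curves weighted by the
#' secondary-structure fractions, plus optional i.i.d. Gaussian noise.
#'
#' @param fractions [ss_fractions()].
#' @param basis A `cd_basis`. Default [builtin_cd_basis()].
#' @param noise_sd Noise sd in ellipticity units. Default 0.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A [cd_spectrum()] on the basis grid.
#' @examples
#' sp <- synthesize_spectrum(ss_fractions(1, 0, 0))
#' @export
synthesize_spectrum <- function(fractions, basis = builtin_cd_basis(),
                                noise_sd = 0, seed = 1L) {
  stopifnot(inherits(fractions, "ss_fractions"), inherits(basis, "cd_basis"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  y <- drop(basis$curves %*% c(fractions$alpha, fractions$beta,
                               fractions$coil))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  cd_spectrum(basis$wavelengths, y)
}

# exact least squares on the 2-simplex by active-set enumeration: the
# optimum's support is one of the 7 non-empty subsets of {alpha, beta,
# coil}; on each support the equality-constrained (sum = 1) solution is a
# small KKT linear solve, and the feasible candidate with smallest
# residual is the global constrained optimum.
.simplex_ls <- function(A, y) {
  # rescale so the Gram block and the simplex-constraint row of the KKT
  # system are commensurate (raw ellipticities are O(1e4))
  sc <- max(abs(A), 1e-12)
  A <- A / sc
  y <- y / sc
  best <- NULL
  for (S in list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3)) {
    As <- A[, S, drop = FALSE]
    k <- length(S)
    KKT <- rbind(cbind(2 * crossprod(As), rep(1, k)),
                 c(rep(1, k), 0))
    rhs <- c(2 * crossprod(As, y), 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    fS <- sol[seq_len(k)]
    if (any(fS < -1e-10)) next
    r2 <- sum((drop(As %*% fS) - y)^2)
    if (is.null(best) || r2 < best$r2) {
      f <- numeric(3); f[S] <- fS
      best <- list(f = f, r2 = r2)
    }
  }
  if (is.null(best)) stop("simplex-constrained solve failed")
  f <- pmax(best$f, 0)
  list(f = f / sum(f), r2 = best$r2 * sc^2)
}

#' Estimate secondary-structure fractions from a CD spectrum
#'
#' Solves least squares over the 2-simplex (non-negative fractions
#' summing to one) against the reference basis — a transparent,
#' deterministic composition estimator. Spectra on a different grid are
#' linearly interpolated onto the basis grid; extrapolation beyond the
#' spectrum's own range is refused. A nearly collinear basis triggers a
#' conditioning warning but still returns the constrained optimum.
#'
#' @param spectrum A [cd_spectrum()].
#' @param basis A `cd_basis`. Default [builtin_cd_basis()].
#' @return A list with `fractions` ([ss_fractions()]), `residual` (root
#'   sum of squared residuals) and `n_points` used.
#' @examples
#' sp <- synthesize_spectrum(ss_fractions(0.8759, 0.0048, 0.1193))
#' deconvolve(sp)$fractions
#' @export
deconvolve <- function(spectrum, basis = builtin_cd_basis()) {
  stopifnot(inherits(spectrum, "cd_spectrum"), inherits(basis, "cd_basis"))
  keep <- basis$wavelengths >= min(spectrum$wavelengths) &
    basis$wavelengths <= max(spectrum$wavelengths)
  if (sum(keep) < 10) {
    stop("spectrum covers fewer than 10 basis grid points; ",
         "extrapolation is refused")
  }
  wl <- basis$wavelengths[keep]
  y <- stats::approx(spectrum$wavelengths, spectrum$ellipticity,
                     xout = wl, rule = 1)$y
  A <- basis$curves[keep, , drop = FALSE]
  sv <- svd(A)$d
  if (sv[3] / sv[1] < 1e-8) {
    warning("basis is near-collinear (condition ratio ",
            format(sv[3] / sv[1], digits = 2),
            "); fractions are poorly determined")
  }
  sol <- .simplex_ls(A, y)
  list(
    fractions = ss_fractions(sol$f[1], sol$f[2], sol$f[3]),
    residual = sqrt(sol$r2),
    n_points = length(y)
  )
}

#' Deconvolve a concentration series of CD spectra
#'
#' Applies [deconvolve()] to each spectrum of a titration series and
#' assembles a tidy table of composition versus nanoparticle
#' concentration.
#'
#' @param spectra List of [cd_spectrum()] objects.
#' @param concentrations Numeric concentration labels, mg/mL (`NA`
#'   allowed; rows are retained and flagged).
#' @param basis A `cd_basis`.
#' @return Data frame with columns `concentration`, `f_alpha`, `f_beta`,
#'   `f_coil`, `residual`, `missing_label`.
#' @export
titration_series <- function(spectra, concentrations = NULL,
                             basis = builtin_cd_basis()) {
  if (inherits(spectra, "cd_spectrum")) spectra <- list(spectra)
  if (length(spectra) < 1) stop("at least one spectrum is required")
  if (is.null(concentrations)) concentrations <- rep(NA_real_, length(spectra))
  if (length(concentrations) != length(spectra)) {
    stop("one concentration label per spectrum is required (NA allowed)")
  }
  rows <- lapply(seq_along(spectra), function(i) {
    d <- deconvolve(spectra[[i]], basis)
    data.frame(
      concentration = as.numeric(concentrations[i]),
      f_alpha = d$fractions$alpha,
      f_beta = d$fractions$beta,
      f_coil = d$fractions$coil,
      residual = d$residual,
      missing_label = is.na(concentrations[i])
    )
  })
  do.call(rbind, rows)
}

#' Read / write CD CSV formats
#'
#' Spectrum CSV columns: `wavelength_nm`, `ellipticity`. Basis CSV
#' columns: `wavelength_nm`, `alpha`, `beta`, `coil`.
#'
#' @param spectrum A [cd_spectrum()]; `path` a CSV file path.
#' @param path CSV file path.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelengths,
                              ellipticity = spectrum$ellipticity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "ellipticity") %in% names(df))) {
    stop("spectrum CSV must have columns wavelength_nm, ellipticity")
  }
  df <- df[order(df$wavelength_nm), ]
  cd_spectrum(df$wavelength_nm, df$ellipticity)
}

#' @rdname write_spectrum_csv
#' @export
read_basis_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "alpha", "beta", "coil")
  if (!all(need %in% names(df))) {
    stop("basis CSV must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[order(df$wavelength_nm), ]
  new_cd_basis(df$wavelength_nm,
               as.matrix(df[, c("alpha", "beta", "coil")]),
               provenance = basename(path))
}
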