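#' Generate geometric point clouds with known size statistics
#'
#' Seeded generators for validation fixtures whose radius of gyration is
#' known analytically:
#' * `"sphere-shell"` — points exactly at radius `size` from the origin
#'   (isotropic Gaussian directions, normalised); R_g = `size`.
#' * `"uniform-ball"` — uniform in the solid ball of radius `size` via
#'   radial inverse CDF (`r = size * U^(1/3)`) on isotropic directions;
#'   R_g converges to `size * sqrt(3/5)`.
#' * `"gaussian-blob"` — isotropic Gaussian with per-coordinate sd
#'   `size`.
#' * `"helix"` — deterministic ideal alpha-helix backbone trace
#'   (radius `size` nm, default 0.23; rise 0.15 nm and 100 degrees of
#'   twist per residue), a protein-like decoy shared by the structural
#'   and CD test suites.
#'
#' Draw order is fixed per kind (directions first, then radii), so equal
#' specs give bit-identical clouds.
#'
#' @param kind One of `"sphere-shell"`, `"uniform-ball"`,
#'   `"gaussian-blob"`, `"helix"`.
#' @param n_atoms Number of points (>= 1).
#' @param size Radius (nm) or, for `"helix"`, helical radius (nm).
#' @param seed RNG seed (ignored by the deterministic helix).
#' @return An [atom_cloud()].
#' @examples
#' radius_of_gyration(generate_cloud("sphere-shell", 500, size = 2))  # 2
#' @export
generate_cloud <- function(kind = c("sphere-shell", "uniform-ball",
                                    "gaussian-blob", "helix"),
                           n_atoms, size = 1, seed = 1L) {
  kind <- match.arg(kind)
  n_atoms <- as.integer(n_atoms)
  if (is.na(n_atoms) || n_atoms < 1) stop("n_atoms must be >= 1")
  if (!is.finite(size) || size <= 0) stop("size must be > 0")
  if (kind != "helix") set.seed(as.integer(seed))
  xyz <- switch(kind,
    "sphere-shell" = {
      g <- matrix(stats::rnorm(3 * n_atoms), ncol = 3, byrow = TRUE)
      size * g / sqrt(rowSums(g^2))
    },
    "uniform-ball" = {
      g <- matrix(stats::rnorm(3 * n_atoms), ncol = 3, byrow = TRUE)
      r <- size * stats::runif(n_atoms)^(1 / 3)
      r * g / sqrt(rowSums(g^2))
    },
    "gaussian-blob" = matrix(stats::rnorm(3 * n_atoms, 0, size),
                             ncol = 3, byrow = TRUE),
    "helix" = {
      i <- seq_len(n_atoms) - 1
      ang <- i * 100 * pi / 180
      cbind(size * cos(ang), size * sin(ang), i * 0.15)
    }
  )
  atom_cloud(xyz, element = if (kind == "helix") "C" else "X",
             mass = if (kind == "helix") NULL else 1,
             resno = if (kind == "helix") seq_len(n_atoms) else 1L,
             resid = if (kind == "helix") "ALA" else "SYN",
             source_label = sprintf("synthetic %s(n=%d, size=%g, seed=%d)",
                                    kind, n_atoms, size, as.integer(seed)))
}

#' Named ITC scenarios with the study's experimental design
#'
#' Ready-made (parameters, schedule) pairs for the two protein titrations:
#' 1.42 mL cell holding nanoparticles at 1.5 g/L, titrated at 310.15 K
#' with albumin (2.88 g/L) or insulin (1.99 g/L) from the syringe;
#' generating binding parameters are the corresponding one-site values
#' (albumin N = 0.246, K = 7.55e4, dH = -163.4 cal/g; insulin N = 0.262,
#' K = 2.87e4, dH = -9.706 cal/g). The injection program, unstated in the
#' experimental design, defaults to 28 x 10 uL and is recorded in the
#' schedule.
#'
#' @param protein `"albumin"` or `"insulin"`.
#' @param n_injections,injection_volume Injection program override.
#' @return List with `params` ([binding_parameters()]) and `schedule`
#'   ([titration_schedule()]).
#' @examples
#' sc <- itc_scenario("albumin")
#' sc$params$K
#' @export
itc_scenario <- function(protein = c("albumin", "insulin"),
                         n_injections = 28L, injection_volume = 10e-6) {
  protein <- match.arg(protein)
  p <- switch(protein,
    albumin = list(N = 0.246, K = 7.55e4, dH = -163.4, syr = 2.88),
    insulin = list(N = 0.262, K = 2.87e4, dH = -9.706, syr = 1.99)
  )
  schedule <- titration_schedule(
    injection_volumes = injection_volume, n_injections = n_injections,
    cell_volume = 1.42e-3, syringe_conc = p$syr, cell_conc0 = 1.5,
    temperature = 310.15
  )
  list(
    params = binding_parameters(N = p$N, K = p$K, dH = p$dH,
                                temperature = 310.15),
    schedule = schedule,
    label = protein
  )
}

#' Generate a synthetic thermogram with known ground truth
#'
#' Forward-models a one-site titration and adds Gaussian noise on the
#' normalized heats with sd equal to `noise_sd` times the maximum
#' absolute normalized heat; raw heats are recomputed so that the
#' normalization invariant holds. The generating parameters are returned
#' alongside so recovery tests never re-derive them.
#'
#' @param params [binding_parameters()] ground truth.
#' @param schedule [titration_schedule()].
#' @param noise_sd Relative noise level (fraction of max |normalized
#'   heat|, >= 0).
#' @param seed RNG seed.
#' @return List with `thermogram` and `truth`.
#' @examples
#' sc <- itc_scenario("albumin")
#' g <- generate_itc(sc$params, sc$schedule, noise_sd = 0.01, seed = 3)
#' @export
generate_itc <- function(params, schedule, noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  tg <- one_site_heats(params, schedule)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    s <- noise_sd * max(abs(tg$normalized))
    y <- tg$normalized + stats::rnorm(length(tg$normalized), 0, s)
    mass_inj <- schedule$syringe_conc * schedule$injection_volumes
    tg <- new_thermogram(y * mass_inj, schedule)
  }
  list(thermogram = tg, truth = params)
}

#' Generate a CD titration series with known compositions
#'
#' Emulates a protein + nanoparticle CD titration: secondary-structure
#' fractions are interpolated linearly (in fraction space) between the
#' free-protein composition and the composition at the highest
#' nanoparticle concentration across the concentration grid, and a
#' spectrum is synthesized at each point. Defaults reproduce the
#' HSA-like series: alpha 87.59% -> 40.9%, beta 0.48% -> 8.78%, coil
#' 11.93% -> 50.32% over 0.01-1.8 mg/mL.
#'
#' @param concentrations Ascending concentration grid, mg/mL.
#' @param start_fractions,end_fractions [ss_fractions()] at the first and
#'   last grid point.
#' @param basis A `cd_basis`.
#' @param noise_sd Spectral noise sd (ellipticity units).
#' @param seed Master seed; spectrum i uses `seed + i`.
#' @return List of entries, each with `concentration`, `spectrum` and
#'   `true_fractions`.
#' @export
generate_cd_series <- function(concentrations = seq(0.01, 1.8,
                                                    length.out = 7),
                               start_fractions = ss_fractions(0.8759,
                                                              0.0048,
                                                              0.1193),
                               end_fractions = ss_fractions(0.409, 0.0878,
                                                            0.5032),
                               basis = builtin_cd_basis(),
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(start_fractions, "ss_fractions"),
            inherits(end_fractions, "ss_fractions"))
  if (length(concentrations) < 1 || is.unsorted(concentrations)) {
    stop("concentrations must be a non-empty ascending grid")
  }
  n <- length(concentrations)
  t <- if (n == 1) 0 else (concentrations - concentrations[1]) /
    (concentrations[n] - concentrations[1])
  f0 <- unlist(start_fractions)
  f1 <- unlist(end_fractions)
  lapply(seq_len(n), function(i) {
    f <- (1 - t[i]) * f0 + t[i] * f1
    fr <- ss_fractions(f[["alpha"]], f[["beta"]], f[["coil"]])
    list(
      concentration = concentrations[i],
      spectrum = synthesize_spectrum(fr, basis, noise_sd = noise_sd,
                                     seed = as.integer(seed) + i),
      true_fractions = fr
    )
  })
}
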