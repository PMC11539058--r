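#' The packaged 49-condition formulation table
#'
#' Temperature (K), ionic strength (mM), pH, melting temperature (stored
#' as printed; the values are on the Celsius scale) and log aggregation
#' rate ln(v) for the 49 formulation conditions of the Fab aggregation
#' study, shipped as a plain-CSV fixture.
#'
#' @return `condition_table` data.frame with 49 rows.
#' @export
table1_fixture <- function() {
  read_condition_table(system.file("extdata", "condition_table.csv",
                                   package = "aggkin", mustWork = TRUE))
}

#' Specification of a synthetic trajectory
#'
#' Describes a toy polymer whose per-residue Gaussian fluctuation
#' amplitudes emulate the condition-dependent dynamics of a protein in
#' different formulations: frame t is the fixed base geometry plus
#' isotropic Gaussian displacement of standard deviation
#' `sigma[residue] * temperature_scale` per coordinate.
#'
#' Residues named ASP/GLU carry side-chain carboxylate oxygens
#' (OD1/OD2, OE1/OE2) and LYS/ARG carry side-chain nitrogens (NZ,
#' NH1/NH2), plus a backbone amide N and carbonyl O per residue, so the
#' salt-bridge and hydrogen-bond detectors can be exercised without real
#' chemistry.
#'
#' @param n_residues chain length.
#' @param atoms_per_residue number of carbon atoms per residue (>= 1; the
#'   first is the alpha carbon `CA`).
#' @param n_frames number of frames (>= 2).
#' @param base_geometry `"helix"` (regular spiral) or `"coil"` (seeded
#'   random walk).
#' @param sigma per-residue fluctuation amplitude, Angstrom (scalar
#'   recycled).
#' @param temperature_scale multiplier on sigma (models the temperature
#'   dependence of fluctuations).
#' @param residue_names optional 3-letter codes per residue (default
#'   `"ALA"`); ASP/GLU/LYS/ARG add charged side-chain pseudo-atoms.
#' @param polar_backbone add backbone N and O atoms per residue.
#' @param dt frame spacing, ns.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_residues = 20, atoms_per_residue = 1,
                            n_frames = 50,
                            base_geometry = c("helix", "coil"),
                            sigma = 0.3, temperature_scale = 1,
                            residue_names = NULL, polar_backbone = FALSE,
                            dt = 0.1, seed = 1) {
  base_geometry <- match.arg(base_geometry)
  sigma <- rep_len(sigma, n_residues)
  stopifnot(n_residues >= 1, atoms_per_residue >= 1, n_frames >= 2,
            all(sigma >= 0), temperature_scale >= 0)
  residue_names <- residue_names %||% rep("ALA", n_residues)
  stopifnot(length(residue_names) == n_residues)
  structure(list(n_residues = n_residues,
                 atoms_per_residue = atoms_per_residue,
                 n_frames = n_frames, base_geometry = base_geometry,
                 sigma = sigma, temperature_scale = temperature_scale,
                 residue_names = residue_names,
                 polar_backbone = polar_backbone, dt = dt, seed = seed),
            class = "trajectory_spec")
}

.sidechain_atoms <- list(
  ASP = data.frame(name = c("OD1", "OD2"), element = "O"),
  GLU = data.frame(name = c("OE1", "OE2"), element = "O"),
  LYS = data.frame(name = "NZ", element = "N"),
  ARG = data.frame(name = c("NH1", "NH2"), element = "N"))

# deterministic local offsets (Angstrom) for atoms within a residue
.atom_offsets <- matrix(c(0, 0, 0,  1.5, 0, 0,  0.75, 1.3, 0,
                          0.75, 0.43, 1.22,  -1.2, 0.8, 0.4,
                          -0.6, -1.3, 0.5, 0.4, -0.9, -1.1,
                          1.1, 1.1, -0.9), ncol = 3, byrow = TRUE)

#' Generate a synthetic trajectory
#'
#' @param spec a [trajectory_spec()].
#' @return a [trajectory()]; bit-identical for identical specs.
#' @export
synth_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  with_seed(spec$seed, {
    nres <- spec$n_residues
    centers <- if (spec$base_geometry == "helix") {
      i <- seq_len(nres)
      cbind(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180),
            1.5 * i)
    } else {
      steps <- matrix(stats::rnorm(3 * nres), ncol = 3)
      steps <- 3.8 * steps / sqrt(row_norms2(steps))
      apply(steps, 2, cumsum)
    }
    if (nres == 1) centers <- matrix(centers, ncol = 3)
    topo_rows <- list(); base <- list()
    for (r in seq_len(nres)) {
      rn <- spec$residue_names[r]
      at <- data.frame(name = c("CA", if (spec$atoms_per_residue > 1)
        paste0("CB", seq_len(spec$atoms_per_residue - 1)) else NULL),
        element = "C", stringsAsFactors = FALSE)
      if (spec$polar_backbone)
        at <- rbind(at, data.frame(name = c("N", "O"),
                                   element = c("N", "O")))
      sc <- .sidechain_atoms[[rn]]
      if (!is.null(sc)) at <- rbind(at, sc)
      k <- nrow(at)
      off <- .atom_offsets[rep_len(seq_len(nrow(.atom_offsets)), k), ,
                           drop = FALSE]
      base[[r]] <- sweep(off[seq_len(k), , drop = FALSE], 2, centers[r, ], `+`)
      topo_rows[[r]] <- data.frame(
        name = at$name, element = at$element, residue_name = rn,
        residue_index = r, stringsAsFactors = FALSE)
    }
    topo <- do.call(rbind, topo_rows)
    topo <- cbind(serial = seq_len(nrow(topo)), topo, chain_id = "A")
    xyz0 <- do.call(rbind, base)
    n <- nrow(xyz0)
    sig_atom <- spec$sigma[topo$residue_index] * spec$temperature_scale
    coords <- array(0, c(n, 3, spec$n_frames))
    for (f in seq_len(spec$n_frames)) {
      noise <- matrix(stats::rnorm(3 * n, sd = rep(sig_atom, 3)), ncol = 3)
      if (all(sig_atom == 0)) noise[] <- 0
      coords[, , f] <- xyz0 + noise
    }
    trajectory(topo, coords, times = spec$dt * (seq_len(spec$n_frames) - 1))
  })
}

#' Specification of a synthetic low-rank feature table
#'
#' Emulates the statistical structure the latent-variable regression
#' assumes: features X = F L' + E with `latent_rank` standard-normal
#' factors F, loadings L and Gaussian feature noise E; the response is
#' y = X beta + eps with planted coefficients beta and response noise
#' whose standard deviation is `response_noise_frac` times the standard
#' deviation of the noiseless signal X beta.
#'
#' @param n_rows number of conditions (default 49, matching the study).
#' @param features column names (default the 17 canonical descriptor
#'   codes).
#' @param latent_rank number of latent factors (<= number of features).
#' @param loadings optional p x rank matrix (default seeded N(0,1)).
#' @param beta optional planted coefficient vector over features
#'   (default seeded N(0,1)).
#' @param noise_sd feature noise standard deviation.
#' @param response_noise_frac response noise as a fraction of
#'   sd(X beta).
#' @param seed RNG seed.
#' @return list of class `feature_table_spec`.
#' @export
feature_table_spec <- function(n_rows = 49, features = canonical_features(),
                               latent_rank = 2, loadings = NULL,
                               beta = NULL, noise_sd = 0,
                               response_noise_frac = 0, seed = 1) {
  p <- length(features)
  stopifnot(latent_rank >= 1, latent_rank <= p, noise_sd >= 0,
            response_noise_frac >= 0, n_rows >= 3)
  structure(list(n_rows = n_rows, features = features,
                 latent_rank = latent_rank, loadings = loadings,
                 beta = beta, noise_sd = noise_sd,
                 response_noise_frac = response_noise_frac, seed = seed),
            class = "feature_table_spec")
}

#' Generate a synthetic feature table with planted structure
#'
#' @param spec a [feature_table_spec()].
#' @return list with `X` (data.frame of features), `y` (response),
#'   `beta_true`, `loadings`, `factors`, `signal_sd`; identical for
#'   identical specs.
#' @export
synth_feature_table <- function(spec) {
  stopifnot(inherits(spec, "feature_table_spec"))
  with_seed(spec$seed, {
    n <- spec$n_rows; p <- length(spec$features); r <- spec$latent_rank
    L <- spec$loadings %||% matrix(stats::rnorm(p * r), p, r)
    Fm <- matrix(stats::rnorm(n * r), n, r)
    E <- if (spec$noise_sd > 0)
      matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    else matrix(0, n, p)
    X <- Fm %*% t(L) + E
    colnames(X) <- spec$features
    beta <- spec$beta %||% stats::rnorm(p)
    signal <- drop(X %*% beta)
    ssd <- stats::sd(signal)
    eps <- if (spec$response_noise_frac > 0)
      stats::rnorm(n, sd = spec$response_noise_frac * ssd) else rep(0, n)
    list(X = as.data.frame(X), y = signal + eps,
         beta_true = stats::setNames(beta, spec$features),
         loadings = L, factors = Fm, signal_sd = ssd)
  })
}
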