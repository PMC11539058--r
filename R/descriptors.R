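#' Descriptor configuration
#'
#' Collects every geometric cutoff and windowing convention used by the
#' descriptor calculations.
#'
#' @param probe_radius solvent probe radius, Angstrom (water, 1.4).
#' @param sphere_points number of quasi-uniform mesh points per atom in the
#'   Shrake-Rupley SASA calculation.
#' @param hbond_da_cutoff donor-acceptor distance cutoff, Angstrom.
#' @param hbond_angle_cutoff H-donor-acceptor angle cutoff, degrees.
#' @param saltbridge_cutoff acidic-O to basic-N distance cutoff, Angstrom.
#' @param native_cutoff alpha-carbon contact cutoff, Angstrom.
#' @param last_window_fraction trailing fraction of frames over which
#'   time-averaged descriptors are evaluated (0.5 of a 100 ns run = the
#'   last 50 ns).
#' @param baseline_frames number of leading frames averaged as the
#'   delta-SASA baseline.
#' @param delta_sasa_baseline `"mean"` (average of the first
#'   `baseline_frames` frames, the default) or `"single"` (the single
#'   frame numbered `baseline_frames`).
#' @return list of class `descriptor_config`.
#' @export
descriptor_config <- function(probe_radius = 1.4, sphere_points = 960,
                              hbond_da_cutoff = 3.5, hbond_angle_cutoff = 30,
                              saltbridge_cutoff = 3.2, native_cutoff = 8.0,
                              last_window_fraction = 0.5,
                              baseline_frames = 20L,
                              delta_sasa_baseline = c("mean", "single")) {
  delta_sasa_baseline <- match.arg(delta_sasa_baseline)
  cfg <- list(probe_radius = probe_radius, sphere_points = sphere_points,
              hbond_da_cutoff = hbond_da_cutoff,
              hbond_angle_cutoff = hbond_angle_cutoff,
              saltbridge_cutoff = saltbridge_cutoff,
              native_cutoff = native_cutoff,
              last_window_fraction = last_window_fraction,
              baseline_frames = as.integer(baseline_frames),
              delta_sasa_baseline = delta_sasa_baseline)
  with(cfg, stopifnot(probe_radius > 0, sphere_points >= 8,
                      hbond_da_cutoff > 0, hbond_angle_cutoff > 0,
                      saltbridge_cutoff > 0, native_cutoff > 0,
                      last_window_fraction > 0, last_window_fraction < 1,
                      baseline_frames >= 1))
  structure(cfg, class = "descriptor_config")
}

#' The seven aggregation-prone regions of the Fab studied here
#'
#' Residue windows on the continuous 442-residue index (light chain 1-214,
#' heavy chain 215-442): 31-36, 47-51, 114-118, 129-139 on the light chain
#' and 261-265, 325-329, 387-402 on the heavy chain.
#'
#' @return data.frame with columns `code`, `start`, `end`.
#' @export
default_apr_regions <- function() {
  data.frame(
    code  = c("r_31_36", "r_47_51", "r_114_118", "r_129_139",
              "r_261_265", "r_325_329", "r_387_402"),
    start = c(31L, 47L, 114L, 129L, 261L, 325L, 387L),
    end   = c(36L, 51L, 118L, 139L, 265L, 329L, 402L),
    stringsAsFactors = FALSE)
}

#' Canonical descriptor column codes
#'
#' The seventeen descriptor columns of a feature table, in canonical
#' order: total and nonpolar SASA, delta-SASA of the seven
#' aggregation-prone regions and their sum, native-contact fraction,
#' last-window mean RMSF/RMSD/Rg, hydrogen-bond count, net charge and
#' salt-bridge occurrence average.
#'
#' @param aprs optional APR region table supplying the `r_*` codes.
#' @return character vector of column names.
#' @export
canonical_features <- function(aprs = default_apr_regions()) {
  c("total_sasa", "nonpolar_sasa", aprs$code, "sum_aprsasa",
    "native_contact", "mean_rmsf", "mean_rmsd", "mean_rg",
    "n_hbonds", "net_charge", "salt_bridge")
}

# ---- superposition and deviation measures ---------------------------------

#' Kabsch weighted rigid-body superposition
#'
#' Finds the proper rotation and translation minimising the weighted RMSD
#' between `mobile` and `reference`, via SVD of the weighted covariance
#' with a determinant correction that excludes reflections.
#'
#' @param mobile,reference N x 3 coordinate matrices, Angstrom.
#' @param weights optional per-atom weights (default uniform).
#' @return list with `coords` (superposed mobile), `rmsd` (weighted,
#'   Angstrom), `rotation` (3 x 3), `translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop_aggkin("mobile and reference must have identical dimensions")
  n <- nrow(mobile)
  if (n < 3) stop_aggkin("at least 3 points required")
  w <- weights %||% rep(1, n)
  if (length(w) != n || sum(w) <= 0)
    stop_aggkin("weights must be positive-sum and length N")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rot <- A %*% t(R)
  out <- sweep(rot, 2, cr, `+`)
  rmsd <- sqrt(sum(w * row_norms2(out - reference)))
  list(coords = out, rmsd = rmsd, rotation = R,
       translation = cr - as.numeric(R %*% cm))
}

select_atoms <- function(traj, names = NULL, elements = NULL,
                         residues = NULL, heavy = FALSE) {
  topo <- traj$topology
  keep <- rep(TRUE, nrow(topo))
  if (!is.null(names)) keep <- keep & topo$name %in% names
  if (!is.null(elements)) keep <- keep & topo$element %in% elements
  if (!is.null(residues)) keep <- keep & topo$residue_index %in% residues
  if (heavy) keep <- keep & topo$element != "H"
  which(keep)
}

#' All-atom RMSD time series relative to a reference frame
#'
#' Each frame is superposed (Kabsch) onto the reference over the selection
#' before the deviation is evaluated, so rigid-body motion never registers
#' as deviation. The reported scalar descriptor is the mean of this series
#' over the trailing window ([last_window_mean()]).
#'
#' @param traj a [trajectory()].
#' @param reference_frame_index frame used as the reference (first frame
#'   by convention).
#' @param selection atom indices; default all atoms.
#' @param superpose set `FALSE` to skip the fit (raw deviation).
#' @return numeric per-frame RMSD series, Angstrom.
#' @export
rmsd_series <- function(traj, reference_frame_index = 1, selection = NULL,
                        superpose = TRUE) {
  sel <- selection %||% seq_len(n_atoms(traj))
  if (!length(sel)) stop_aggkin("empty atom selection")
  ref <- frame_coords(traj, reference_frame_index)[sel, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)[sel, , drop = FALSE]
    if (superpose) kabsch_superpose(x, ref)$rmsd
    else sqrt(mean(row_norms2(x - ref)))
  }, numeric(1))
}

#' Per-residue RMSF over the trailing window
#'
#' Root-mean-square fluctuation of one selected atom per residue (alpha
#' carbons by default) about its time-average position. Frames in the
#' window are first superposed onto the first window frame, the mean
#' structure is computed, and frames are re-superposed onto that mean
#' (two-pass convention) before fluctuations are measured.
#'
#' @param traj a [trajectory()].
#' @param atom_name atom picked per residue (default `"CA"`).
#' @param config [descriptor_config()] supplying the window fraction.
#' @param superpose set `FALSE` to measure fluctuations in the fixed frame
#'   (useful for controlled tests).
#' @return named numeric vector, one RMSF (Angstrom) per residue index;
#'   the global descriptor is its unweighted mean.
#' @export
rmsf_per_residue <- function(traj, atom_name = "CA",
                             config = descriptor_config(),
                             superpose = TRUE) {
  if (n_frames(traj) < 2) stop_aggkin("RMSF requires at least 2 frames")
  sel <- select_atoms(traj, names = atom_name)
  res <- traj$topology$residue_index[sel]
  if (anyDuplicated(res) || !length(sel))
    stop_aggkin("selection must contain exactly one '%s' atom per residue",
                atom_name)
  win <- last_window_idx(n_frames(traj), config$last_window_fraction)
  if (length(win) < 2) win <- seq_len(n_frames(traj))
  X <- traj$coords[sel, , win, drop = FALSE]
  nt <- length(win)
  if (superpose) {
    ref <- X[, , 1]
    for (t in seq_len(nt)) X[, , t] <- kabsch_superpose(X[, , t], ref)$coords
    mref <- apply(X, c(1, 2), mean)
    for (t in seq_len(nt)) X[, , t] <- kabsch_superpose(X[, , t], mref)$coords
  }
  m <- apply(X, c(1, 2), mean)
  dev2 <- matrix(0, nrow(m), nt)
  for (t in seq_len(nt)) dev2[, t] <- row_norms2(X[, , t] - m)
  out <- sqrt(rowMeans(dev2))
  names(out) <- as.character(res)
  out
}

#' Mass-weighted radius of gyration series
#'
#' @param traj a [trajectory()].
#' @return per-frame Rg, Angstrom.
#' @export
radius_of_gyration <- function(traj) {
  m <- traj$topology$mass
  if (sum(m) <= 0) stop_aggkin("total mass must be positive")
  w <- m / sum(m)
  vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    com <- colSums(x * w)
    sqrt(sum(w * row_norms2(sweep(x, 2, com))))
  }, numeric(1))
}

# ---- solvent accessible surface area ---------------------------------------

# Quasi-uniform unit sphere mesh by the golden-spiral (Fibonacci) layout.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley per-atom solvent accessible surface area
#'
#' Rolls a spherical probe over each atom: the atom's expanded sphere of
#' radius (vdw + probe) is meshed with `sphere_points` golden-spiral
#' points and the accessible fraction is the share of points outside every
#' neighbouring atom's expanded sphere. Hydrogens take no part, neither as
#' surface atoms nor as occluders.
#'
#' @param traj a [trajectory()] (or anything [frame_coords()] accepts).
#' @param frame frame index.
#' @param subset atom indices whose areas are wanted (default: all heavy
#'   atoms). Occluders are always all heavy atoms.
#' @param config [descriptor_config()].
#' @return numeric vector of per-atom areas (Angstrom^2), named by atom
#'   serial, one entry per subset atom.
#' @export
shrake_rupley_sasa <- function(traj, frame = 1, subset = NULL,
                               config = descriptor_config()) {
  heavy <- select_atoms(traj, heavy = TRUE)
  subset <- subset %||% heavy
  subset <- intersect(subset, heavy)
  if (!length(subset)) return(numeric(0))
  xyz <- frame_coords(traj, frame)
  radii <- traj$topology$vdw_radius
  if (anyNA(radii[heavy])) stop_aggkin("missing vdw radius")
  probe <- config$probe_radius
  mesh <- golden_spiral_points(config$sphere_points)
  hx <- xyz[heavy, , drop = FALSE]
  hr <- radii[heavy] + probe
  out <- numeric(length(subset))
  for (k in seq_along(subset)) {
    i <- subset[k]
    ri <- radii[i] + probe
    ci <- xyz[i, ]
    d2 <- row_norms2(sweep(hx, 2, ci))
    nb <- which(d2 < (hr + ri)^2 & d2 > 1e-12)
    pts <- sweep(mesh * ri, 2, ci, `+`)
    if (length(nb)) {
      acc <- rep(TRUE, nrow(pts))
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- row_norms2(sweep(pts[acc, , drop = FALSE], 2, hx[j, ]))
        acc[acc] <- dj2 > hr[j]^2
      }
      frac <- mean(acc)
    } else frac <- 1
    out[k] <- 4 * pi * ri^2 * frac
  }
  names(out) <- traj$topology$serial[subset]
  out
}

#' Total heavy-atom SASA of a frame
#' @inheritParams shrake_rupley_sasa
#' @return scalar Angstrom^2.
#' @export
total_sasa <- function(traj, frame = 1, config = descriptor_config()) {
  sum(shrake_rupley_sasa(traj, frame, config = config))
}

#' Nonpolar SASA of a frame
#'
#' Solvent accessibility of the carbon atoms only (all heavy atoms still
#' occlude), the conventional hydrophobic-exposure measure.
#'
#' @inheritParams shrake_rupley_sasa
#' @return scalar Angstrom^2.
#' @export
nonpolar_sasa <- function(traj, frame = 1, config = descriptor_config()) {
  carbons <- select_atoms(traj, elements = "C", heavy = TRUE)
  sum(shrake_rupley_sasa(traj, frame, subset = carbons, config = config))
}

region_sasa_series <- function(traj, region, frames, config) {
  atoms <- select_atoms(traj, residues = seq.int(region$start, region$end),
                        heavy = TRUE)
  if (!length(atoms))
    stop_aggkin("region %s has no atoms in the topology", region$code)
  vapply(frames, function(f)
    sum(shrake_rupley_sasa(traj, f, subset = atoms, config = config)),
    numeric(1))
}

#' Delta-SASA of an aggregation-prone region
#'
#' Change in a region's solvent exposure over a run: the mean region SASA
#' across the trailing window minus an early baseline (by default the mean
#' of the first `baseline_frames` frames; a single-frame baseline is
#' available via the config). Averaged over replicate trajectories.
#'
#' @param replicates list of [trajectory()] objects (a single trajectory
#'   is accepted).
#' @param region one row of an APR table (`code`, `start`, `end`).
#' @param config [descriptor_config()].
#' @return scalar delta-SASA, Angstrom^2.
#' @export
delta_sasa_region <- function(replicates, region,
                              config = descriptor_config()) {
  if (inherits(replicates, "trajectory")) replicates <- list(replicates)
  vals <- vapply(replicates, function(traj) {
    nf <- n_frames(traj)
    if (nf < config$baseline_frames)
      stop_aggkin("trajectory has %d frames, fewer than the %d baseline frames",
                  nf, config$baseline_frames)
    win <- last_window_idx(nf, config$last_window_fraction)
    base_frames <- if (config$delta_sasa_baseline == "mean")
      seq_len(config$baseline_frames) else config$baseline_frames
    late <- mean(region_sasa_series(traj, region, win, config))
    base <- mean(region_sasa_series(traj, region, base_frames, config))
    late - base
  }, numeric(1))
  mean(vals)
}

# ---- hydrogen bonds and salt bridges ---------------------------------------

# map each hydrogen to its covalently bound heavy atom (nearest N/O within
# bond_cutoff in the given frame)
find_donors <- function(traj, frame, bond_cutoff = 1.25) {
  hy <- select_atoms(traj, elements = "H")
  no <- select_atoms(traj, elements = c("N", "O"))
  if (!length(hy) || !length(no)) return(NULL)
  xyz <- frame_coords(traj, frame)
  pairs <- lapply(hy, function(h) {
    d2 <- row_norms2(sweep(xyz[no, , drop = FALSE], 2, xyz[h, ]))
    j <- which.min(d2)
    if (d2[j] <= bond_cutoff^2) c(h = h, donor = no[j]) else NULL
  })
  do.call(rbind, pairs)
}

#' Hydrogen-bond count per frame
#'
#' A bond is counted when a donor (N/O carrying a covalently bound H) and
#' an acceptor (any other N/O) lie within the distance cutoff and the
#' H-donor-acceptor angle is within the angle cutoff. Structures without
#' hydrogens fall back to distance-only counting of N/O pairs, with a
#' warning.
#'
#' @param traj a [trajectory()].
#' @param config [descriptor_config()].
#' @param frames frame indices (default all).
#' @return integer per-frame counts.
#' @export
hydrogen_bond_count <- function(traj, config = descriptor_config(),
                                frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  no <- select_atoms(traj, elements = c("N", "O"))
  if (!length(no)) {
    warn_aggkin("no N/O atoms: hydrogen-bond count is 0")
    return(rep(0L, length(frames)))
  }
  has_h <- length(select_atoms(traj, elements = "H")) > 0
  if (!has_h)
    warn_aggkin("no hydrogens present: distance-only hydrogen-bond counting")
  cut2 <- config$hbond_da_cutoff^2
  cosang <- cos(config$hbond_angle_cutoff * pi / 180)
  vapply(frames, function(f) {
    xyz <- frame_coords(traj, f)
    if (!has_h) {
      d2 <- as.matrix(stats::dist(xyz[no, , drop = FALSE]))^2
      return(sum(d2[upper.tri(d2)] <= cut2))
    }
    dn <- find_donors(traj, f)
    if (is.null(dn)) return(0L)
    count <- 0L
    for (r in seq_len(nrow(dn))) {
      h <- dn[r, "h"]; d <- dn[r, "donor"]
      acc <- setdiff(no, d)
      if (!length(acc)) next
      v_da <- sweep(xyz[acc, , drop = FALSE], 2, xyz[d, ])
      d2 <- row_norms2(v_da)
      ok <- d2 <= cut2 & d2 > 1e-12
      if (!any(ok)) next
      v_dh <- xyz[h, ] - xyz[d, ]
      cosv <- (v_da[ok, , drop = FALSE] %*% v_dh) /
        (sqrt(d2[ok]) * sqrt(sum(v_dh^2)))
      count <- count + sum(cosv >= cosang)
    }
    as.integer(count)
  }, integer(1))
}

saltbridge_atoms <- function(traj) {
  topo <- traj$topology
  acid <- which(topo$residue_name %in% c("ASP", "GLU") &
                  topo$element == "O" &
                  grepl("^(OD|OE)", topo$name))
  base <- which(topo$residue_name %in% c("ARG", "LYS") &
                  topo$element == "N" &
                  grepl("^(NE|NH|NZ)", topo$name))
  list(acid = acid, base = base)
}

#' Salt-bridge occurrence table and average
#'
#' An acidic/basic residue pair (ASP/GLU side-chain O against ARG/LYS
#' side-chain N) enters the pair universe when its minimum O-N distance is
#' within the cutoff in at least one trailing-window frame; its occurrence
#' is the percentage of window frames satisfying the criterion. The scalar
#' descriptor is the mean occurrence over pairs, then over replicates.
#'
#' @param replicates list of [trajectory()] objects (or a single one).
#' @param config [descriptor_config()].
#' @return list with `pairs` (per-replicate occurrence tables) and
#'   `average` (scalar percent).
#' @export
salt_bridge_occurrence <- function(replicates,
                                   config = descriptor_config()) {
  if (inherits(replicates, "trajectory")) replicates <- list(replicates)
  per_rep <- lapply(replicates, function(traj) {
    sb <- saltbridge_atoms(traj)
    if (!length(sb$acid) || !length(sb$base)) return(NULL)
    topo <- traj$topology
    acid_res <- unique(topo$residue_index[sb$acid])
    base_res <- unique(topo$residue_index[sb$base])
    win <- last_window_idx(n_frames(traj), config$last_window_fraction)
    cut2 <- config$saltbridge_cutoff^2
    grid <- expand.grid(acid = acid_res, base = base_res)
    hits <- matrix(0L, nrow(grid), length(win))
    for (t in seq_along(win)) {
      xyz <- frame_coords(traj, win[t])
      for (g in seq_len(nrow(grid))) {
        oa <- sb$acid[topo$residue_index[sb$acid] == grid$acid[g]]
        nb <- sb$base[topo$residue_index[sb$base] == grid$base[g]]
        d2 <- outer(seq_along(oa), seq_along(nb), function(i, j)
          row_norms2(xyz[oa[i], , drop = FALSE] - xyz[nb[j], , drop = FALSE]))
        hits[g, t] <- as.integer(min(d2) <= cut2)
      }
    }
    occ <- 100 * rowMeans(hits)
    keep <- rowSums(hits) > 0
    if (!any(keep)) return(NULL)
    data.frame(acid_residue = grid$acid[keep], base_residue = grid$base[keep],
               occurrence = occ[keep])
  })
  nonempty <- !vapply(per_rep, is.null, logical(1))
  if (!any(nonempty)) {
    warn_aggkin("no salt-bridge pairs within cutoff: average is 0")
    return(list(pairs = per_rep, average = 0))
  }
  rep_means <- vapply(per_rep[nonempty],
                      function(p) mean(p$occurrence), numeric(1))
  list(pairs = per_rep, average = mean(rep_means))
}

# ---- native contacts -------------------------------------------------------

#' Fraction of native contacts Q per frame
#'
#' The native contact set holds all alpha-carbon pairs of distinct
#' residues within the cutoff in the reference frame; Q(t) is the fraction
#' of those pairs still within the cutoff at frame t. The scalar
#' descriptor is the mean Q over the trailing window, averaged across
#' replicates (see [native_contact_feature()]).
#'
#' @param traj a [trajectory()].
#' @param reference_frame_index reference frame (first frame by default).
#' @param config [descriptor_config()].
#' @return numeric per-frame Q series in [0, 1].
#' @export
native_contact_fraction <- function(traj, reference_frame_index = 1,
                                    config = descriptor_config()) {
  ca <- select_atoms(traj, names = "CA")
  if (length(ca) < 4) stop_aggkin("need at least 4 alpha-carbons")
  res <- traj$topology$residue_index[ca]
  ref <- frame_coords(traj, reference_frame_index)[ca, , drop = FALSE]
  dref <- as.matrix(stats::dist(ref))
  distinct <- outer(res, res, `!=`)
  contact <- dref <= config$native_cutoff & distinct & upper.tri(dref)
  idx <- which(contact, arr.ind = TRUE)
  if (!nrow(idx)) stop_aggkin("empty native contact set")
  vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)[ca, , drop = FALSE]
    d <- sqrt(row_norms2(x[idx[, 1], , drop = FALSE] -
                           x[idx[, 2], , drop = FALSE]))
    mean(d <= config$native_cutoff)
  }, numeric(1))
}

#' Replicate-averaged native-contact descriptor
#' @param replicates list of [trajectory()] objects (or one).
#' @inheritParams native_contact_fraction
#' @return scalar mean Q over the trailing window and replicates.
#' @export
native_contact_feature <- function(replicates, reference_frame_index = 1,
                                   config = descriptor_config()) {
  if (inherits(replicates, "trajectory")) replicates <- list(replicates)
  mean(vapply(replicates, function(tr) {
    q <- native_contact_fraction(tr, reference_frame_index, config)
    last_window_mean(q, config$last_window_fraction)
  }, numeric(1)))
}

# ---- net charge ------------------------------------------------------------

#' Henderson-Hasselbalch net charge from per-site pKa values
#'
#' Each basic site contributes +1/(1 + 10^(pH - pKa)) and each acidic site
#' contributes -1/(1 + 10^(pKa - pH)), so a site exactly at its pKa
#' carries half a charge. pKa values are consumed as input (from any
#' external predictor); no electrostatics is computed here.
#'
#' @param pka_sites data.frame with columns `residue_index`, `site_label`,
#'   `pka`, `site_class` (`"acid"` or `"base"`).
#' @param pH solution pH, in (0, 14).
#' @return net charge in elementary charges.
#' @export
net_charge <- function(pka_sites, pH) {
  stopifnot(pH > 0, pH < 14)
  if (is.null(pka_sites) || nrow(pka_sites) == 0) {
    warn_aggkin("empty pKa site list: net charge 0")
    return(0)
  }
  if (!all(pka_sites$site_class %in% c("acid", "base")))
    stop_aggkin("site_class must be 'acid' or 'base'")
  acid <- pka_sites$pka[pka_sites$site_class == "acid"]
  base <- pka_sites$pka[pka_sites$site_class == "base"]
  sum(1 / (1 + 10^(pH - base))) - sum(1 / (1 + 10^(acid - pH)))
}

# ---- feature table assembly ------------------------------------------------

#' Assemble the 17-descriptor feature table across conditions
#'
#' Runs every descriptor on each condition's replicate trajectories and
#' averages across replicates, producing one row per condition with the
#' canonical columns of [canonical_features()]. `sum_aprsasa` is the row
#' sum of the per-region delta-SASA columns by construction.
#'
#' @param replicate_sets named list (by condition id) of lists of
#'   [trajectory()] objects.
#' @param conditions a `condition_table` (supplies pH per condition).
#' @param pka_tables named list (by condition id) of pKa site tables for
#'   [net_charge()]; a single table is recycled to all conditions.
#' @param aprs APR region table; defaults to the seven Fab regions. For
#'   synthetic systems pass scaled-down regions with the same codes.
#' @param config [descriptor_config()].
#' @return data.frame of class `feature_table`, rows keyed by
#'   `condition_id`.
#' @export
build_feature_table <- function(replicate_sets, conditions,
                                pka_tables = NULL,
                                aprs = default_apr_regions(),
                                config = descriptor_config()) {
  ids <- names(replicate_sets)
  if (is.null(ids)) stop_aggkin("replicate_sets must be named by condition id")
  rows <- lapply(ids, function(id) {
    reps <- replicate_sets[[id]]
    if (inherits(reps, "trajectory")) reps <- list(reps)
    if (!length(reps)) stop_aggkin("condition %s has no replicates", id)
    frac <- config$last_window_fraction
    rep_mean <- function(fn) mean(vapply(reps, fn, numeric(1)))

    tot <- rep_mean(function(tr)
      mean(vapply(last_window_idx(n_frames(tr), frac), function(f)
        total_sasa(tr, f, config), numeric(1))))
    np <- rep_mean(function(tr)
      mean(vapply(last_window_idx(n_frames(tr), frac), function(f)
        nonpolar_sasa(tr, f, config), numeric(1))))
    dsasa <- vapply(seq_len(nrow(aprs)), function(r)
      delta_sasa_region(reps, aprs[r, ], config), numeric(1))
    names(dsasa) <- aprs$code
    q <- native_contact_feature(reps, config = config)
    rmsf <- rep_mean(function(tr)
      mean(rmsf_per_residue(tr, config = config)))
    rmsd <- rep_mean(function(tr)
      last_window_mean(rmsd_series(tr), frac))
    rg <- rep_mean(function(tr)
      last_window_mean(radius_of_gyration(tr), frac))
    hb <- rep_mean(function(tr) {
      win <- last_window_idx(n_frames(tr), frac)
      mean(hydrogen_bond_count(tr, config, frames = win))
    })
    sb <- salt_bridge_occurrence(reps, config)$average

    cond <- conditions[match(as.numeric(id), conditions$number), ]
    pka <- if (is.data.frame(pka_tables)) pka_tables else pka_tables[[id]]
    nc <- if (is.null(pka)) NA_real_ else net_charge(pka, cond$pH)

    out <- c(total_sasa = tot, nonpolar_sasa = np, dsasa,
             sum_aprsasa = sum(dsasa), native_contact = q,
             mean_rmsf = rmsf, mean_rmsd = rmsd, mean_rg = rg,
             n_hbonds = hb, net_charge = nc, salt_bridge = sb)
    out
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- tab[, canonical_features(aprs)]
  tab <- cbind(condition_id = as.numeric(ids), tab)
  class(tab) <- c("feature_table", "data.frame")
  tab
}
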