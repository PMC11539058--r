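test_that("Kabsch superposition recovers rigid motions and matches a
           grid-search oracle on an asymmetric set", {
  set.seed(42)
  ref <- matrix(rnorm(12), 4, 3)

  expect_equal(kabsch_superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)

  mob <- sweep(ref %*% t(rotation_about(c(0, 0, 1), 37 * pi / 180)),
               2, c(1, 2, 3), `+`)
  expect_lt(kabsch_superpose(mob, ref)$rmsd, 1e-9)

  pert <- ref + matrix(rnorm(12, sd = 0.3), 4, 3)
  got <- kabsch_superpose(pert, ref)$rmsd
  expect_equal(got, oracle_min_rmsd(pert, ref), tolerance = 1e-3)

  expect_error(kabsch_superpose(ref[1:3, ], ref), "dimensions")
  expect_error(kabsch_superpose(ref, ref, weights = rep(0, 4)), "weights")
})

test_that("RMSD series is zero for static and rigidly moved trajectories
           and matches the direct formula on a toy", {
  base <- matrix(rnorm(15), 5, 3)
  static <- make_traj(list(base, base, base))
  expect_equal(rmsd_series(static), rep(0, 3), tolerance = 1e-12)

  shifted <- make_traj(list(base, sweep(base, 2, c(1, 0, 0), `+`)))
  expect_lt(max(rmsd_series(shifted)), 1e-12)

  f2 <- base + matrix(rnorm(15, sd = 0.5), 5, 3)
  f3 <- base + matrix(rnorm(15, sd = 1.0), 5, 3)
  toy <- make_traj(list(base, f2, f3))
  series <- rmsd_series(toy)
  direct <- vapply(list(base, f2, f3), function(fr) {
    sup <- kabsch_superpose(fr, base)$coords
    sqrt(mean(rowSums((sup - base)^2)))
  }, numeric(1))
  expect_equal(series, direct, tolerance = 1e-10)
})

test_that("RMSF matches hand computation and is rigid-motion invariant", {
  # two frames, one atom displaced 2 A, superposition disabled:
  # mean position sits 1 A from both frames -> RMSF exactly 1
  base <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 10, 10, 0), 4, 3,
                 byrow = TRUE)
  f2 <- base; f2[2, 1] <- f2[2, 1] + 2
  tr <- make_traj(list(base, f2))
  rmsf <- rmsf_per_residue(tr, superpose = FALSE,
                           config = descriptor_config(
                             last_window_fraction = 0.99))
  expect_equal(unname(rmsf), c(0, 1, 0, 0), tolerance = 1e-12)

  # invariance of RMSD/RMSF under a global rigid motion of all frames
  sp <- trajectory_spec(n_residues = 6, n_frames = 12, sigma = 0.3,
                        seed = 4)
  tr <- synth_trajectory(sp)
  moved <- apply_rigid_motion(tr)
  expect_equal(rmsd_series(tr), rmsd_series(moved), tolerance = 1e-6)
  expect_equal(rmsf_per_residue(tr), rmsf_per_residue(moved),
               tolerance = 1e-6)
})

test_that("radius of gyration follows the mass-weighted formula", {
  one <- make_traj(list(matrix(c(1, 2, 3), 1)))
  expect_equal(radius_of_gyration(one), 0)

  two <- make_traj(list(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)))
  expect_equal(radius_of_gyration(two), 1.0)

  set.seed(7)
  xyz <- matrix(rnorm(30, sd = 4), 10, 3)
  tr <- make_traj(list(xyz))
  tr$topology$mass <- runif(10, 1, 30)
  m <- tr$topology$mass
  com <- colSums(xyz * m / sum(m))
  direct <- sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(tr), direct, tolerance = 1e-12)
})

test_that("Shrake-Rupley SASA matches the analytic sphere, full occlusion,
           a cap-formula two-sphere case, and converges with mesh density", {
  iso <- make_traj(list(matrix(0, 1, 3)), names = "C")
  a <- shrake_rupley_sasa(iso)
  expect_equal(unname(a), 4 * pi * 3.1^2, tolerance = 0.01 * 4 * pi * 3.1^2)

  # six octahedral neighbours at 2 A fully enclose the central atom
  shell <- rbind(c(0, 0, 0), 2 * rbind(diag(3), -diag(3)))
  enc <- make_traj(list(shell), names = rep("C", 7))
  expect_equal(unname(shrake_rupley_sasa(enc, subset = 1)), 0)

  # two identical spheres 2 A apart: high-density mesh oracle + analytic cap
  pair <- make_traj(list(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)),
                    names = c("C", "C"))
  got <- shrake_rupley_sasa(pair)
  dense <- shrake_rupley_sasa(pair, config = descriptor_config(
    sphere_points = 1e5))
  expect_equal(unname(got), unname(dense), tolerance = 0.005)
  r <- 3.1; h <- r - 1  # spherical-cap height at half the 2 A separation
  analytic <- 4 * pi * r^2 - 2 * pi * r * h
  expect_equal(unname(got[1]), analytic, tolerance = 0.005 * analytic)

  # doubling the mesh changes values by < 1%
  dbl <- shrake_rupley_sasa(pair, config = descriptor_config(
    sphere_points = 1920))
  expect_lt(max(abs(dbl - got) / got), 0.01)
})

test_that("nonpolar SASA sums per-carbon areas and total SASA is additive", {
  xyz <- matrix(c(0, 0, 0, 1.5, 0, 0, 3, 0.5, 0, 0, 1.4, 0.5, 2, 2, 1),
                5, 3, byrow = TRUE)
  toy <- make_traj(list(xyz), names = c("C", "N", "C", "O", "C"))
  per_atom <- shrake_rupley_sasa(toy)
  expect_equal(total_sasa(toy), sum(per_atom), tolerance = 1e-9)
  carbons <- which(toy$topology$element == "C")
  expect_equal(nonpolar_sasa(toy),
               sum(shrake_rupley_sasa(toy, subset = carbons)),
               tolerance = 1e-9)

  no_c <- make_traj(list(xyz[1:2, ]), names = c("N", "O"))
  expect_equal(nonpolar_sasa(no_c), 0)
  single_c <- make_traj(list(matrix(0, 1, 3)), names = "C")
  expect_equal(nonpolar_sasa(single_c), total_sasa(single_c))
})

test_that("region delta-SASA is zero for static runs and recovers a
           constructed step in exposure", {
  cfg <- descriptor_config(baseline_frames = 3, sphere_points = 480)
  base <- matrix(c(0, 0, 0, 3.4, 0, 0), 2, 3, byrow = TRUE)
  static <- make_traj(rep(list(base), 8), names = c("CA", "CA"))
  region <- data.frame(code = "r_1_1", start = 1L, end = 1L)
  expect_equal(delta_sasa_region(static, region, cfg), 0, tolerance = 1e-12)

  # neighbour retreats after the baseline -> exposure of residue 1 steps up
  far <- base; far[2, 1] <- 50
  step <- make_traj(c(rep(list(base), 4), rep(list(far), 4)),
                    names = c("CA", "CA"))
  early <- sum(shrake_rupley_sasa(make_traj(list(base)), subset = 1,
                                  config = cfg))
  late <- sum(shrake_rupley_sasa(make_traj(list(far),
                                           names = c("CA", "CA")),
                                 subset = 1, config = cfg))
  expect_equal(delta_sasa_region(step, region, cfg), late - early,
               tolerance = 1e-9)
  expect_gt(delta_sasa_region(step, region, cfg), 0)
})

test_that("hydrogen-bond geometry follows the distance and angle criteria", {
  mk <- function(o_pos, h_pos = c(1, 0, 0)) {
    make_traj(list(rbind(c(0, 0, 0), h_pos, o_pos)),
              names = c("N", "H", "O"))
  }
  expect_equal(hydrogen_bond_count(mk(c(2.9, 0, 0))), 1L)
  expect_equal(hydrogen_bond_count(mk(c(3.8, 0, 0))), 0L)
  # acceptor at 45 degrees off the N-H axis at 2.9 A -> angle fail
  ang <- 45 * pi / 180
  expect_equal(hydrogen_bond_count(mk(2.9 * c(cos(ang), sin(ang), 0))), 0L)
  # no hydrogens: distance-only fallback with a warning
  noh <- make_traj(list(rbind(c(0, 0, 0), c(2.9, 0, 0))),
                   names = c("N", "O"))
  expect_warning(cnt <- hydrogen_bond_count(noh), "distance-only")
  expect_equal(cnt, 1L)
})

test_that("salt-bridge occurrence counts window frames within cutoff", {
  near <- rbind(c(0, 0, 0), c(3.0, 0, 0))
  far <- rbind(c(0, 0, 0), c(6.0, 0, 0))
  mk <- function(frames) make_traj(frames,
    names = c("OD1", "NZ"), elements = c("O", "N"),
    residue_index = c(1, 2), residue_name = c("ASP", "LYS"))

  always <- mk(rep(list(near), 6))
  expect_equal(salt_bridge_occurrence(always)$average, 100)

  never <- mk(rep(list(far), 6))
  expect_warning(res <- salt_bridge_occurrence(never), "no salt-bridge")
  expect_equal(res$average, 0)

  # within cutoff in 5 of the 10 window frames -> 50%
  frames <- c(rep(list(far), 10), rep(list(near), 5), rep(list(far), 5))
  half <- mk(frames)
  expect_equal(salt_bridge_occurrence(half)$average, 50)
})

test_that("native-contact fraction is 1 at the reference, 0 when scattered,
           and matches hand enumeration on a 5-residue chain", {
  # chain with 5 A spacing: contacts = the four (i, i+1) pairs only
  chain <- cbind(5 * (0:4), 0, 0)
  ref <- make_traj(list(chain))
  expect_equal(native_contact_fraction(ref), 1)

  scattered <- chain; scattered[, 2] <- c(0, 60, 120, 180, 240)
  tr <- make_traj(list(chain, scattered))
  expect_equal(native_contact_fraction(tr), c(1, 0))

  broken <- chain; broken[5, 1] <- broken[5, 1] + 5  # breaks (4,5) only
  tr2 <- make_traj(list(chain, broken))
  expect_equal(native_contact_fraction(tr2)[2], 0.75)

  expect_true(all(native_contact_fraction(tr2) >= 0 &
                    native_contact_fraction(tr2) <= 1))
})

test_that("Henderson-Hasselbalch net charge: half-titration, limits,
           direct formula and pH monotonicity", {
  acid <- data.frame(residue_index = 1, site_label = "D1", pka = 7,
                     site_class = "acid")
  expect_equal(net_charge(acid, 7), -0.5)

  base <- data.frame(residue_index = 2, site_label = "K1", pka = 10,
                     site_class = "base")
  expect_equal(net_charge(base, 3), 1 / (1 + 10^(3 - 10)), tolerance = 1e-12)
  expect_gt(net_charge(base, 3), 0.999)

  mix <- data.frame(residue_index = 1:5, site_label = letters[1:5],
                    pka = c(4, 4, 4, 10, 10),
                    site_class = c(rep("acid", 3), rep("base", 2)))
  direct <- -3 / (1 + 10^(4 - 7)) + 2 / (1 + 10^(7 - 10))
  expect_equal(net_charge(mix, 7), direct, tolerance = 1e-12)
  expect_equal(round(direct, 3), -0.999)

  phs <- seq(1, 13, by = 0.25)
  z <- vapply(phs, function(p) net_charge(mix, p), numeric(1))
  expect_true(all(diff(z) <= 1e-12))

  expect_warning(z0 <- net_charge(mix[0, ], 7), "empty")
  expect_equal(z0, 0)
})

test_that("the feature table assembles all canonical columns with internal
           consistency and a planted temperature-RMSF trend", {
  aprs <- data.frame(code = c("r_1_2", "r_4_5"), start = c(1L, 4L),
                     end = c(2L, 5L))
  cfg <- descriptor_config(baseline_frames = 2, sphere_points = 240)
  conds <- data.frame(number = 1:2, temperature = c(277, 338),
                      ionic_strength = 0, pH = c(5, 7), tm = 70,
                      ln_v = c(-2, 5))
  mk <- function(tscale, seed) synth_trajectory(trajectory_spec(
    n_residues = 5, n_frames = 8, sigma = 0.25,
    temperature_scale = tscale, polar_backbone = TRUE,
    residue_names = c("ASP", "ALA", "LYS", "ALA", "GLU"), seed = seed))
  pka <- data.frame(residue_index = c(1, 3, 5),
                    site_label = c("D", "K", "E"), pka = c(3.9, 10.5, 4.3),
                    site_class = c("acid", "base", "acid"))
  ft <- suppressWarnings(build_feature_table(
    list(`1` = list(mk(0.5, 1)), `2` = list(mk(2, 2))),
    conds, pka_tables = pka, aprs = aprs, config = cfg))
  expect_equal(names(ft), c("condition_id", canonical_features(aprs)))
  expect_equal(ft$sum_aprsasa, ft$r_1_2 + ft$r_4_5, tolerance = 1e-6)
  expect_false(anyNA(ft))

  # static condition: zero RMSD and zero delta-SASA
  static <- synth_trajectory(trajectory_spec(n_residues = 5, n_frames = 8,
                                             sigma = 0, seed = 3))
  ft0 <- suppressWarnings(build_feature_table(
    list(`1` = list(static)), conds[1, ], pka_tables = pka,
    aprs = aprs, config = cfg))
  expect_equal(ft0$mean_rmsd, 0, tolerance = 1e-10)
  expect_equal(ft0$r_1_2, 0, tolerance = 1e-10)

  # planted sigma(T) profile: global RMSF increases with temperature scale
  scales <- c(0.25, 0.5, 1, 2)
  rmsf <- vapply(seq_along(scales), function(i)
    mean(rmsf_per_residue(mk(scales[i], 10 + i))), numeric(1))
  expect_true(all(diff(rmsf) > 0))
})
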