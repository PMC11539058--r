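# Builders for tiny in-code fixtures shared across test files.

# A hand-positioned trajectory from explicit coordinates.
# frames: list of n x 3 matrices. topo columns defaulted for quick toys.
make_traj <- function(frames, names = NULL, elements = NULL,
                      residue_index = NULL, residue_name = NULL) {
  n <- nrow(frames[[1]])
  names <- names %||% rep("CA", n)
  elements <- elements %||% aggkin:::infer_element(names)
  topo <- data.frame(
    serial = seq_len(n), name = names, element = elements,
    residue_name = residue_name %||% rep("ALA", n),
    residue_index = residue_index %||% seq_len(n),
    chain_id = "A", stringsAsFactors = FALSE)
  coords <- array(unlist(frames), c(n, 3, length(frames)))
  trajectory(topo, coords)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal multi-model PDB text
pdb_model_lines <- function(model, xyz, names = rep("CA", nrow(xyz)),
                            drop_atom = NULL) {
  rows <- seq_len(nrow(xyz))
  if (!is.null(drop_atom)) rows <- setdiff(rows, drop_atom)
  c(sprintf("MODEL     %4d", model),
    sprintf("ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            rows, names[rows], rows, xyz[rows, 1], xyz[rows, 2], xyz[rows, 3]),
    "ENDMDL")
}

write_toy_pdb <- function(path, n_models = 1, n_atoms = 3, drop_in = NULL) {
  xyz <- matrix(as.numeric(seq_len(3 * n_atoms)), ncol = 3)
  lines <- unlist(lapply(seq_len(n_models), function(m)
    pdb_model_lines(m, xyz + 0.1 * m,
                    drop_atom = if (identical(m, drop_in)) n_atoms else NULL)))
  writeLines(c(lines, "END"), path)
  path
}

# random rigid motion applied to every frame of a trajectory
apply_rigid_motion <- function(traj, angle = 0.7, axis = c(0, 0, 1),
                               shift = c(1, -2, 3)) {
  R <- rotation_about(axis, angle)
  for (f in seq_len(n_frames(traj)))
    traj$coords[, , f] <- sweep(traj$coords[, , f] %*% t(R), 2, shift, `+`)
  traj
}

rotation_about <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# seeded draw that restores the caller's RNG state
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
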