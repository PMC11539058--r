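#' @importFrom stats cor sd prcomp quantile
#' @importFrom utils read.csv write.csv head
NULL

# Built-in element table. Masses in Da, van der Waals radii in Angstrom.
# Radii follow the common Bondi-style convention used throughout the
# SASA calculations; both can be overridden per call where it matters.
.element_table <- data.frame(
  element = c("C", "N", "O", "S", "H", "P"),
  mass    = c(12.011, 14.007, 15.999, 32.06, 1.008, 30.974),
  vdw     = c(1.70, 1.55, 1.52, 1.80, 1.20, 1.80),
  stringsAsFactors = FALSE
)

element_property <- function(elements, what = c("mass", "vdw")) {
  what <- match.arg(what)
  i <- match(elements, .element_table$element)
  if (anyNA(i)) {
    stop_aggkin("unknown element(s): %s",
                paste(unique(elements[is.na(i)]), collapse = ", "))
  }
  .element_table[[what]][i]
}

# Infer the element from a PDB-style atom name: leading digits stripped,
# first character that matches a known element wins (handles "CA", "1HB",
# "OD1", "NZ", ...). Two-letter elements are not needed for proteins here.
infer_element <- function(atom_names) {
  x <- toupper(gsub("^[0-9']+", "", trimws(atom_names)))
  el <- substr(x, 1, 1)
  bad <- !(el %in% .element_table$element)
  if (any(bad)) {
    stop_aggkin("cannot infer element for atom name(s): %s",
                paste(unique(atom_names[bad]), collapse = ", "))
  }
  el
}

#' Construct a trajectory object
#'
#' A trajectory couples an atom topology (names, elements, residue and chain
#' assignment, masses and van der Waals radii) with one or more coordinate
#' frames in Angstrom and frame times in nanoseconds. Residue numbering is
#' continuous across chains (for the Fab studied here: light chain 1-214,
#' heavy chain 215-442), because the aggregation-prone-region windows are
#' defined on that continuous index.
#'
#' @param topology data.frame with columns `serial`, `name`, `element`,
#'   `residue_name`, `residue_index`, `chain_id`, and optionally `mass`,
#'   `vdw_radius` (filled from the built-in element table when absent).
#' @param coords numeric array of dimension `n_atoms x 3 x n_frames`
#'   (a single `n_atoms x 3` matrix is promoted to one frame), Angstrom.
#' @param times frame times in ns; defaults to 0.1 ns spacing.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL) {
  req <- c("serial", "name", "element", "residue_name", "residue_index",
           "chain_id")
  miss <- setdiff(req, names(topology))
  if (length(miss)) stop_aggkin("topology lacks column(s): %s",
                                paste(miss, collapse = ", "))
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3, 1))
  n <- nrow(topology)
  if (n < 1) stop_aggkin("topology must contain at least one atom")
  if (dim(coords)[1] != n || dim(coords)[2] != 3)
    stop_aggkin("coords must be %d x 3 x n_frames", n)
  nf <- dim(coords)[3]
  if (nf < 1) stop_aggkin("at least one frame required")
  if (is.null(times)) times <- 0.1 * (seq_len(nf) - 1)
  if (length(times) != nf || (nf > 1 && any(diff(times) <= 0)))
    stop_aggkin("frame times must match frame count and strictly increase")
  if (!("mass" %in% names(topology)))
    topology$mass <- element_property(topology$element, "mass")
  if (!("vdw_radius" %in% names(topology)))
    topology$vdw_radius <- element_property(topology$element, "vdw")
  if (any(topology$mass <= 0) || any(topology$vdw_radius <= 0))
    stop_aggkin("masses and vdw radii must be positive")
  if (any(topology$residue_index < 1))
    stop_aggkin("residue_index must be >= 1")
  structure(list(topology = topology, coords = coords, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms, %d residues, %d frames (%.1f-%.1f ns)\n",
              n_atoms(x), length(unique(x$topology$residue_index)),
              n_frames(x), x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

#' @export
n_atoms <- function(traj) nrow(traj$topology)

#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame as an n x 3 matrix (Angstrom)
#' @param traj trajectory.
#' @param i frame index.
#' @export
frame_coords <- function(traj, i = 1) {
  stopifnot(i >= 1, i <= n_frames(traj))
  m <- traj$coords[, , i]
  if (!is.matrix(m)) m <- matrix(m, ncol = 3)
  m
}

# ---- PDB / XYZ reading -----------------------------------------------------

# Count ATOM/HETATM records inside each MODEL block so a malformed
# multi-model file fails with the index of the offending model instead of
# an opaque parser error.
validate_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) < 2) return(invisible(length(model_starts)))
  model_ends <- which(trimws(rec) == "ENDMDL")
  if (length(model_ends) != length(model_starts))
    stop_aggkin("unbalanced MODEL/ENDMDL records in '%s'", path)
  counts <- mapply(function(a, b) sum(rec[a:b] %in% c("ATOM  ", "HETATM")),
                   model_starts, model_ends)
  if (length(unique(counts)) > 1) {
    ref <- counts[1]
    bad <- which(counts != ref)[1]
    stop_aggkin(
      "model %d has %d atoms but model 1 has %d: models must share one topology",
      bad, counts[bad], ref)
  }
  invisible(length(model_starts))
}

#' Read a structure or trajectory file
#'
#' Supports multi-model PDB (each MODEL is one frame; all models must share
#' the same atoms in the same order) and extended XYZ as written by
#' [write_trajectory()]. Elements missing from the file are inferred from
#' atom names; masses and van der Waals radii come from a built-in element
#' table. Frame times default to 0.1 ns spacing when the file carries none.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param chain_offsets optional named integer vector adding a per-chain
#'   offset to residue numbers, for mapping per-chain numbering onto the
#'   continuous index (e.g. `c(H = 214)` for a Fab heavy chain).
#' @return a [trajectory()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz"),
                           chain_offsets = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_aggkin("file not found: '%s'", path)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "xyz") return(read_xyz(path))

  validate_pdb_models(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  element <- trimws(at$elesy)
  if (all(is.na(element)) || any(!nzchar(element) | is.na(element)))
    element <- infer_element(at$elety)
  resno <- at$resno
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), " ", at$chain)
  if (!is.null(chain_offsets)) {
    for (ch in names(chain_offsets))
      resno[chain == ch] <- resno[chain == ch] + chain_offsets[[ch]]
  }
  topo <- data.frame(serial = at$eleno, name = trimws(at$elety),
                     element = element, residue_name = trimws(at$resid),
                     residue_index = resno, chain_id = chain,
                     stringsAsFactors = FALSE)
  nf <- nrow(pdb$xyz)
  n <- nrow(topo)
  coords <- array(NA_real_, c(n, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(topo, coords)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop_aggkin("empty XYZ file: '%s'", path)
  frames <- list(); times <- numeric(0); i <- 1; f <- 0
  elements <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop_aggkin("bad atom count at line %d", i)
    comment <- lines[i + 1]
    t <- suppressWarnings(as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1",
                                         comment)))
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    el <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    f <- f + 1
    if (f == 1) elements <- el
    else if (!identical(el, elements))
      stop_aggkin("frame %d atom order differs from frame 1", f)
    frames[[f]] <- xyz
    times[f] <- if (is.na(t)) NA_real_ else t
    i <- i + 2 + n
  }
  n <- nrow(frames[[1]])
  coords <- array(unlist(frames), c(n, 3, f))
  if (anyNA(times)) times <- NULL
  topo <- data.frame(serial = seq_len(n), name = elements,
                     element = elements, residue_name = "UNK",
                     residue_index = seq_len(n), chain_id = " ",
                     stringsAsFactors = FALSE)
  trajectory(topo, coords, times)
}

#' Write a trajectory to XYZ or multi-model PDB
#'
#' XYZ is written at 1e-6 Angstrom precision (the lossless interchange
#' format of this package; PDB's fixed columns carry only 1e-3). The XYZ
#' comment line records the frame time as `t= <ns>`.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format `"xyz"` or `"pdb"`.
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "xyz") {
    con <- file(path, "w"); on.exit(close(con))
    n <- n_atoms(traj)
    for (f in seq_len(n_frames(traj))) {
      xyz <- frame_coords(traj, f)
      writeLines(c(as.character(n), sprintf("t= %.6f ns", traj$times[f]),
                   sprintf("%-2s %14.6f %14.6f %14.6f", traj$topology$element,
                           xyz[, 1], xyz[, 2], xyz[, 3])), con)
    }
  } else {
    xyz <- t(apply(traj$coords, 3, function(m) as.numeric(t(m))))
    if (n_frames(traj) == 1) xyz <- matrix(traj$coords[, , 1],
                                           nrow = 1, byrow = FALSE)
    write_pdb_frames(traj, xyz, path, bfac = rep(0, n_atoms(traj)))
  }
  invisible(path)
}

write_pdb_frames <- function(traj, xyz_rows, path, bfac) {
  topo <- traj$topology
  bio3d::write.pdb(file = path, xyz = xyz_rows,
                   type = rep("ATOM", nrow(topo)),
                   eleno = topo$serial, elety = topo$name,
                   resid = topo$residue_name, resno = topo$residue_index,
                   chain = ifelse(topo$chain_id == " ", "", topo$chain_id),
                   b = bfac, elesy = topo$element)
  invisible(path)
}

# ---- condition table -------------------------------------------------------

#' Read a formulation-condition table
#'
#' The expected CSV carries one row per formulation condition with columns
#' `number`, `temperature` (K), `ionic_strength` (mM), `pH`, `tm`
#' (melting temperature, stored exactly as printed in the source table;
#' the values are on the Celsius scale) and `ln_v` (natural log of the
#' aggregation rate, v in percent per day). The packaged 49-condition
#' fixture is available via [table1_fixture()].
#'
#' @param path CSV file path.
#' @return validated data.frame of class `condition_table`.
#' @export
read_condition_table <- function(path) {
  if (!file.exists(path)) stop_aggkin("file not found: '%s'", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("number", "temperature", "ionic_strength", "pH", "tm", "ln_v")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop_aggkin("condition table lacks column(s): %s",
                                paste(miss, collapse = ", "))
  if (nrow(x) == 0) stop_aggkin("no data rows in '%s'", path)
  check <- function(ok, msg) {
    if (any(!ok)) stop_aggkin("condition table row %s: %s",
                              paste(which(!ok), collapse = ", "), msg)
  }
  check(x$number >= 1 & x$number == round(x$number), "bad condition number")
  check(x$ionic_strength >= 0, "ionic strength must be >= 0")
  check(x$pH >= 3.5 & x$pH <= 9.0, "pH outside the studied range 3.5-9")
  check(is.finite(x$temperature) & x$temperature > 0, "bad temperature")
  class(x) <- c("condition_table", "data.frame")
  x
}

# ---- B-factor map ----------------------------------------------------------

#' Write per-residue values into a PDB B-factor column
#'
#' Produces a single-model PDB of the given frame in which every atom
#' carries its residue's value in the B-factor column (two decimals,
#' clipped to [0, 99.99] with a warning). This is the mechanism used to
#' paint residue-level regression R-squared values onto the structure for
#' molecular-viewer rendering.
#'
#' @param traj a [trajectory()]; its frame `frame` supplies coordinates.
#' @param per_residue_values numeric vector named by residue index, one
#'   value per residue present in the topology.
#' @param path output PDB path.
#' @param frame frame index to write.
#' @export
write_bfactor_map <- function(traj, per_residue_values, path, frame = 1) {
  res <- unique(traj$topology$residue_index)
  nm <- names(per_residue_values)
  if (is.null(nm)) {
    if (length(per_residue_values) != length(res))
      stop_aggkin("expected %d per-residue values, got %d",
                  length(res), length(per_residue_values))
    names(per_residue_values) <- as.character(res)
    nm <- names(per_residue_values)
  }
  missing_res <- setdiff(as.character(res), nm)
  if (length(missing_res))
    stop_aggkin("no value for residue(s): %s",
                paste(missing_res, collapse = ", "))
  vals <- per_residue_values[as.character(traj$topology$residue_index)]
  if (any(vals < 0 | vals > 99.99, na.rm = TRUE)) {
    warn_aggkin("B-factor values clipped to [0, 99.99]")
    vals <- pmin(pmax(vals, 0), 99.99)
  }
  vals[is.na(vals)] <- 0
  xyz <- matrix(as.numeric(t(frame_coords(traj, frame))), nrow = 1)
  sub <- traj
  sub$coords <- traj$coords[, , frame, drop = FALSE]
  write_pdb_frames(sub, xyz, path, bfac = round(vals, 2))
}
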