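#' Frame dataset of CG coordinate/force pairs
#'
#' Container for the training data of force matching: per-system arrays of
#' bead coordinates (A) and matching forces (kcal/mol/A) at a stated
#' temperature.  Systems may have different bead counts.
#'
#' @param coords numeric array `[M, n, 3]` (A) or a named list of such arrays
#'   (one per system).
#' @param forces matching array or list of arrays (kcal/mol/A).
#' @param temperature temperature (K) the frames were sampled at.
#' @param system system tag used when `coords` is a single array.
#' @return Object of class `frame_dataset` with elements `systems` (named
#'   list of `list(coords, forces)`) and `temperature`.
#' @export
frame_dataset <- function(coords, forces, temperature, system = "system") {
  if (!is.list(coords)) {
    coords <- stats::setNames(list(coords), system)
    forces <- stats::setNames(list(forces), system)
  }
  stopifnot(length(coords) == length(forces))
  systems <- Map(function(x, f) {
    x <- as_frames_array(x)
    f <- as_frames_array(f)
    if (!identical(dim(x), dim(f)))
      stop("coordinates and forces must have identical shape", call. = FALSE)
    if (!all(is.finite(x)) || !all(is.finite(f)))
      stop("non-finite values in frames", call. = FALSE)
    list(coords = x, forces = f)
  }, coords, forces)
  structure(list(systems = systems, temperature = temperature),
            class = "frame_dataset")
}

as_frames_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(1, dim(x)))
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 3)
  x
}

#' @export
print.frame_dataset <- function(x, ...) {
  cat(sprintf("Frame dataset at %g K, %d system(s):\n", x$temperature,
              length(x$systems)))
  for (nm in names(x$systems))
    cat(sprintf("  %s: %d frames x %d beads\n", nm,
                dim(x$systems[[nm]]$coords)[1], dim(x$systems[[nm]]$coords)[2]))
  invisible(x)
}

#' Number of frames in a frame dataset
#' @param frames a [frame_dataset()].
#' @return Total frame count over all systems.
#' @export
n_frames <- function(frames) {
  sum(vapply(frames$systems, function(s) dim(s$coords)[1], numeric(1)))
}

#' Map all-atom frames to CG frames
#'
#' Applies the linear CG mapping: a pure row selection that retains the
#' coordinates and forces of the chosen alpha-carbon atoms (no averaging),
#' optionally thinning frames by a stride (every stride-th frame, starting
#' from the first).
#'
#' @param all_atom_coords array `[M, n_atoms, 3]` (A).
#' @param all_atom_forces matching array (kcal/mol/A).
#' @param ca_indices 1-based atom indices of the alpha carbons, one per
#'   residue.
#' @param stride keep every stride-th frame (default 1).
#' @param temperature temperature metadata (K).
#' @param system system tag.
#' @return A [frame_dataset()] with `ceiling(M / stride)` frames.
#' @export
map_frames <- function(all_atom_coords, all_atom_forces, ca_indices,
                       stride = 1L, temperature = 350, system = "system") {
  stopifnot(stride >= 1)
  if (!identical(dim(all_atom_coords), dim(all_atom_forces)))
    stop("coordinate and force arrays must have identical shape",
         call. = FALSE)
  stopifnot(length(dim(all_atom_coords)) == 3)
  if (any(ca_indices < 1 | ca_indices > dim(all_atom_coords)[2]))
    stop("ca_indices out of range", call. = FALSE)
  keep <- seq(1, dim(all_atom_coords)[1], by = stride)
  frame_dataset(all_atom_coords[keep, ca_indices, , drop = FALSE],
                all_atom_forces[keep, ca_indices, , drop = FALSE],
                temperature = temperature, system = system)
}

#' Read residue names and alpha-carbon indices from a PDB structure
#'
#' @param path PDB file path.
#' @return List with `residue_names`, `ca_indices` (1-based atom indices into
#'   the PDB atom table), and `ca_coords` (n x 3 matrix, A).
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  res_key <- paste(at$chain, at$resno, at$insert)
  res_ids <- unique(res_key)
  ca_indices <- integer(length(res_ids))
  residue_names <- character(length(res_ids))
  for (i in seq_along(res_ids)) {
    rows <- which(res_key == res_ids[i])
    ca <- rows[at$elety[rows] == "CA"]
    if (length(ca) == 0)
      stop(sprintf("residue %d (%s) has no CA atom", i,
                   at$resid[rows[1]]), call. = FALSE)
    ca_indices[i] <- ca[1]
    residue_names[i] <- at$resid[rows[1]]
  }
  list(residue_names = residue_names, ca_indices = ca_indices,
       ca_coords = as.matrix(at[ca_indices, c("x", "y", "z")]))
}

#' Write and read frame datasets
#'
#' Frame archives are stored as a versioned native array archive (RDS):
#' groups per system with `[M, n, 3]` coordinate and force arrays plus the
#' temperature attribute.  The round trip is exact.
#'
#' @param frames a [frame_dataset()].
#' @param path file path (conventionally `.rds`).
#' @return `read_frames` returns the [frame_dataset()].
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "frame_dataset"))
  saveRDS(list(format = "cgfold-frames", version = 1L,
               temperature = frames$temperature, systems = frames$systems),
          path)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "cgfold-frames"))
    stop("not a cgfold frame archive: ", path, call. = FALSE)
  structure(list(systems = x$systems, temperature = x$temperature),
            class = "frame_dataset")
}
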