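#' Build a CG topology from a residue sequence
#'
#' One bead per residue.  Bonds connect consecutive beads (i, i+1), dihedrals
#' are defined over every four consecutive beads (i..i+3), and default
#' repulsion exclusions are the bonded pairs.  Each bead carries its
#' residue's total mass; equilibrium distributions are mass-independent, so
#' any positive mass is thermodynamically valid.
#'
#' @param residue_names character vector of 3-letter residue codes
#'   (length >= 2).
#' @param vocabulary a [bead_vocabulary()].
#' @param chain chain label.
#' @param exclusion_offsets integer vector of neighbor offsets whose pairs
#'   are excluded from the repulsive prior; default `1` (bonded pairs only),
#'   set to e.g. `c(1, 2, 3)` to also exclude (i, i+2) and (i, i+3).
#' @return Object of class `cg_topology` with elements `n_beads`,
#'   `residue_names`, `type_ids` (0-based), `bonds`, `dihedrals`,
#'   `exclusion_pairs` (1-based index matrices), `masses`, `chain`.
#' @examples
#' top <- build_cg_topology(c("ALA", "GLY", "SER", "LEU"))
#' top$n_beads      # 4
#' nrow(top$bonds)  # 3
#' @export
build_cg_topology <- function(residue_names, vocabulary = bead_vocabulary(),
                              chain = "A", exclusion_offsets = 1L) {
  if (length(residue_names) < 2)
    stop("a CG topology needs at least two residues", call. = FALSE)
  n <- length(residue_names)
  type_ids <- assign_bead_types(residue_names, vocabulary)
  bonds <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  dihedrals <- if (n >= 4) {
    cbind(seq_len(n - 3), seq_len(n - 3) + 1L, seq_len(n - 3) + 2L,
          seq_len(n - 3) + 3L)
  } else {
    matrix(integer(0), ncol = 4)
  }
  excl <- do.call(rbind, lapply(as.integer(exclusion_offsets), function(o) {
    if (o < 1 || o >= n) return(NULL)
    cbind(seq_len(n - o), seq_len(n - o) + o)
  }))
  if (is.null(excl)) excl <- matrix(integer(0), ncol = 2)
  nm <- toupper(residue_names)
  aliases <- attr(vocabulary, "aliases")
  hit <- nm %in% names(aliases)
  nm[hit] <- aliases[nm[hit]]
  structure(list(n_beads = n, residue_names = toupper(residue_names),
                 type_ids = type_ids, bonds = bonds, dihedrals = dihedrals,
                 exclusion_pairs = excl, exclusion_offsets =
                   as.integer(exclusion_offsets),
                 masses = unname(residue_masses[nm]), chain = chain),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("CG topology '%s': %d beads, %d bonds, %d dihedrals, %d excluded pairs\n",
              x$chain, x$n_beads, nrow(x$bonds), nrow(x$dihedrals),
              nrow(x$exclusion_pairs)))
  invisible(x)
}

#' Non-excluded repulsion pairs of a topology
#'
#' All bead pairs (i < j) minus the topology's exclusion pairs; these are the
#' pairs the repulsive prior acts on.
#'
#' @param topology a [build_cg_topology()] object.
#' @return Two-column matrix of 1-based bead index pairs.
#' @export
repulsion_pairs <- function(topology) {
  n <- topology$n_beads
  all_pairs <- t(utils::combn(n, 2))
  if (nrow(topology$exclusion_pairs) > 0) {
    key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    all_pairs <- all_pairs[!(key(all_pairs) %in% key(topology$exclusion_pairs)), ,
                           drop = FALSE]
  }
  all_pairs
}

#' Write or read a CG topology as YAML
#'
#' @param topology a `cg_topology`.
#' @param path file path.
#' @return `read_topology` returns a `cg_topology`.
#' @export
write_topology <- function(topology, path) {
  yaml::write_yaml(list(residues = as.list(topology$residue_names),
                        chain = topology$chain,
                        exclusion_offsets =
                          as.list(topology$exclusion_offsets)), path)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  y <- yaml::read_yaml(path)
  build_cg_topology(unlist(y$residues), chain = y$chain %||% "A",
                    exclusion_offsets = unlist(y$exclusion_offsets) %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
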