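#' Bead-type vocabulary
#'
#' One CG bead per residue, one bead type per amino-acid identity: the 20
#' canonical amino acids plus norleucine (NLE), a non-standard residue that
#' occurs in the Villin headpiece, giving exactly 21 types.  Ids are assigned
#' alphabetically over the canonical 3-letter codes (0-based), with NLE last
#' (id 20), so embeddings are reproducible across runs.  Protonation-variant
#' residue names map to their parent amino acid; terminal residues are typed
#' identically to internal ones.
#'
#' @param extra_aliases optional named character vector of additional residue
#'   name aliases, e.g. `c(MSE = "MET")`.
#' @return An object of class `bead_vocabulary`: a named integer vector of
#'   type ids with the alias table stored as an attribute.
#' @examples
#' vocab <- bead_vocabulary()
#' length(vocab)          # 21
#' vocab[["NLE"]]         # 20
#' @export
bead_vocabulary <- function(extra_aliases = NULL) {
  canonical <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
  ids <- stats::setNames(seq_along(canonical) - 1L, canonical)
  ids <- c(ids, NLE = 20L)
  aliases <- c(HSD = "HIS", HSE = "HIS", HSP = "HIS", HID = "HIS",
               HIE = "HIS", HIP = "HIS", CYX = "CYS", CYM = "CYS",
               GLH = "GLU", ASH = "ASP", LYN = "LYS", NLN = "NLE")
  if (!is.null(extra_aliases)) {
    stopifnot(is.character(extra_aliases), !is.null(names(extra_aliases)))
    aliases[names(extra_aliases)] <- extra_aliases
  }
  structure(ids, aliases = aliases, class = "bead_vocabulary")
}

#' @export
print.bead_vocabulary <- function(x, ...) {
  cat("Bead-type vocabulary:", length(x), "types\n")
  print(unclass(x))
  invisible(x)
}

#' Assign bead type ids to a residue sequence
#'
#' Every residue name must be a canonical amino acid, a recognized
#' protonation variant, or NLE.  Terminal residues are not special-cased.
#'
#' @param residue_names character vector of 3-letter residue codes.
#' @param vocabulary a [bead_vocabulary()].
#' @return Integer vector of 0-based type ids, one per residue.
#' @export
assign_bead_types <- function(residue_names, vocabulary = bead_vocabulary()) {
  stopifnot(is.character(residue_names), length(residue_names) >= 1)
  nm <- toupper(residue_names)
  aliases <- attr(vocabulary, "aliases")
  hit <- nm %in% names(aliases)
  nm[hit] <- aliases[nm[hit]]
  unknown <- setdiff(unique(nm), names(vocabulary))
  if (length(unknown) > 0)
    stop("unknown residue name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unname(vocabulary[nm])
}

# per-residue masses (amu); bead carries its residue's total mass
residue_masses <- c(
  ALA = 71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09, CYS = 103.14,
  GLN = 128.13, GLU = 129.12, GLY = 57.05, HIS = 137.14, ILE = 113.16,
  LEU = 113.16, LYS = 128.17, MET = 131.19, PHE = 147.18, PRO = 97.12,
  SER = 87.08, THR = 101.10, TRP = 186.21, TYR = 163.18, VAL = 99.13,
  NLE = 113.16)
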