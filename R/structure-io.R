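#' Read per-residue metadata from a predicted structure
#'
#' Parses a PDB or mmCIF file with \pkg{bio3d} and returns one row per
#' polymer residue, in file order. For AlphaFold models the B-factor column
#' holds the per-residue pLDDT confidence score (0-100); the value reported
#' is taken from each residue's first atom. Hetero records (ligands,
#' waters) are skipped: residues are the nodes of the analysis.
#' Multi-chain files are supported by concatenating chains in file order,
#' which matches the joint PAE matrix emitted for multimer predictions.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format `"auto"` (by file extension), `"pdb"`, or `"cif"`.
#' @return A tibble with columns `index` (1-based position in the PAE
#'   matrix), `chain`, `resno` (author residue number), `ins` (insertion
#'   code, `""` if none), `label` (author number plus insertion code, e.g.
#'   `"52A"`), and `plddt` (B-factor of the residue's first atom).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(sprintf("structure file not found: '%s'", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
    ),
    error = function(e) {
      stop_format(sprintf("could not read '%s' as %s: %s", path, format,
                          conditionMessage(e)))
    }
  )
  atoms <- parsed$atom[parsed$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop_format(sprintf("no polymer residues found in '%s'", path))
  }
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  key <- paste(atoms$chain, atoms$resno, ins, sep = "\r")
  first <- !duplicated(key)
  tibble(
    index = seq_len(sum(first)),
    chain = as.character(atoms$chain[first]),
    resno = as.integer(atoms$resno[first]),
    ins = ins[first],
    label = paste0(atoms$resno[first], ins[first]),
    plddt = as.numeric(atoms$b[first])
  )
}

#' Check that a PAE matrix and a residue table describe the same protein
#'
#' @param pae A [pae_matrix].
#' @param residues A residue tibble from [read_structure()].
#' @return `residues`, unchanged, when the residue count matches the matrix
#'   dimension; otherwise a reconciliation error stating both lengths.
#' @export
reconcile_residues <- function(pae, residues) {
  stopifnot(inherits(pae, "pae_matrix"))
  if (nrow(residues) != pae$n) {
    stop_reconcile(sprintf(
      "PAE matrix has %d residues but the structure has %d",
      pae$n, nrow(residues)
    ))
  }
  residues
}

# Default residue table when no structure is supplied: single unnamed
# chain, residues numbered 1..n.
default_residues <- function(n) {
  tibble(
    index = seq_len(n),
    chain = rep("", n),
    resno = seq_len(n),
    ins = rep("", n),
    label = as.character(seq_len(n)),
    plddt = rep(NA_real_, n)
  )
}
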