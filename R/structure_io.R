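#' Read an atomic structure from PDB or mmCIF
#'
#' Parses a coordinate file into a `structure_model`: a flat, ordered atom
#' table (one row per atom, file order preserved) that all geometric
#' operations in the package consume. Only the first MODEL of multi-model
#' files is kept, and for alternate locations only altloc "A" or blank is
#' retained, so every model is a single deterministic conformer.
#'
#' @param path Path to a coordinate file.
#' @param format One of `"auto"` (default; decided from the file extension,
#'   `.cif`/`.mmcif` is mmCIF, anything else PDB), `"pdb"` or `"cif"`.
#' @return An object of class `structure_model`: a list with elements
#'   `identifier` (basename without extension), `atoms` (data.frame with
#'   columns `chain`, `resno`, `insert`, `resname`, `atom`, `element`,
#'   `x`, `y`, `z`, `occ`, `b`, `het`), and `provenance` (source path and
#'   format). Coordinates are in Angstrom; residue numbers are author
#'   numbering.
#' @examples
#' ring <- make_ring(n_spokes = 8, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_structure(ring$model, f)
#' m <- read_structure(f)
#' nrow(m$atoms)
#' @seealso [select_atoms()], [write_structure()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read structure file: '", path, "' does not exist", call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
      else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    ),
    error = function(e) {
      stop("failed to parse '", path, "' as ", format, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("structure '", path, "' contains no atoms", call. = FALSE)
  }
  atoms <- data.frame(
    chain   = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resno   = as.integer(at$resno),
    insert  = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resname = as.character(at$resid),
    atom    = as.character(at$elety),
    element = ifelse(is.na(at$elesy), guess_element(at$elety), as.character(at$elesy)),
    x       = as.numeric(at$x),
    y       = as.numeric(at$y),
    z       = as.numeric(at$z),
    occ     = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    b       = ifelse(is.na(at$b), 0, as.numeric(at$b)),
    het     = as.character(at$type) == "HETATM",
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    stop("structure '", path, "' has non-finite coordinates", call. = FALSE)
  }
  structure_model(atoms,
                  identifier = sub("\\.[^.]*$", "", basename(path)),
                  provenance = list(path = path, format = format))
}

#' Construct a structure model from an atom table
#'
#' Low-level constructor used by [read_structure()] and the synthetic-data
#' generators. Validates coordinates and occupancies and checks that
#' `(chain, resno, insert, atom)` is unique.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`, `occ`, `b`, `het`.
#' @param identifier Short name for the model.
#' @param provenance List recording where the atoms came from.
#' @return A `structure_model` object.
#' @export
structure_model <- function(atoms, identifier = "model", provenance = list()) {
  stopifnot(is.data.frame(atoms))
  needed <- c("chain", "resno", "insert", "resname", "atom",
              "element", "x", "y", "z", "occ", "b", "het")
  missing <- setdiff(needed, names(atoms))
  if (length(missing)) {
    stop("atom table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  if (any(atoms$occ < 0 | atoms$occ > 1)) {
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, insertion, atom) records in model",
         call. = FALSE)
  }
  rownames(atoms) <- NULL
  structure(list(identifier = identifier, atoms = atoms,
                 provenance = provenance),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model '", x$identifier, "': ",
      nrow(a), " atoms, ", length(unique(a$chain)), " chain(s) [",
      paste(utils::head(unique(a$chain), 8), collapse = " "),
      if (length(unique(a$chain)) > 8) " ..." else "", "]\n", sep = "")
  invisible(x)
}

# element from PDB atom name when the element column is absent
guess_element <- function(atom_name) {
  nm <- toupper(trimws(as.character(atom_name)))
  el <- substr(gsub("[^A-Z]", "", nm), 1, 1)
  el[substr(nm, 1, 2) %in% c("FE", "ZN", "MG", "MN", "SE")] <-
    substr(nm, 1, 2)[substr(nm, 1, 2) %in% c("FE", "ZN", "MG", "MN", "SE")]
  el
}

#' Define an atom selection
#'
#' A selection restricts by chain identifiers, an inclusive author-numbered
#' residue range, and atom names; any empty criterion matches everything.
#'
#' @param chains Character vector of chain ids, or `NULL` for all chains.
#' @param residues Inclusive residue range `c(start, end)` in author
#'   numbering (a single number selects that one residue), or `NULL`.
#' @param atoms Character vector of atom names (e.g. `"CA"`), or `NULL`.
#' @return An object of class `atom_selection`.
#' @examples
#' selection(chains = "A", residues = c(91, 308), atoms = "CA")
#' @export
selection <- function(chains = NULL, residues = NULL, atoms = NULL) {
  if (!is.null(residues)) {
    if (length(residues) == 1L) residues <- c(residues, residues)
    stopifnot(length(residues) == 2L)
    if (residues[1] > residues[2]) {
      stop("residue range start must be <= end", call. = FALSE)
    }
    residues <- as.integer(residues)
  }
  structure(list(chains = chains, residues = residues, atoms = atoms),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("selection:",
      if (is.null(x$chains)) "all chains" else
        paste0("chains {", paste(x$chains, collapse = ","), "}"),
      if (is.null(x$residues)) "all residues" else
        paste0("residues [", x$residues[1], ",", x$residues[2], "]"),
      if (is.null(x$atoms)) "all atoms" else
        paste0("atoms {", paste(x$atoms, collapse = ","), "}"), "\n")
  invisible(x)
}

#' Select atoms from a structure model
#'
#' Returns the rows of the atom table matching every non-empty criterion of
#' the selection, in model (file) order. By default hydrogens, waters and
#' HETATM records are excluded, since all geometric analyses in the package
#' operate on protein heavy atoms; set `include_het = TRUE` to keep them.
#'
#' @param model A `structure_model`.
#' @param sel An [selection()] object (default: select everything).
#' @param include_het Keep HETATM/water/hydrogen records (default `FALSE`).
#' @return data.frame of matching atom rows (possibly empty), model order.
#' @export
select_atoms <- function(model, sel = selection(), include_het = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model$atoms) == 0L) stop("model contains no atoms", call. = FALSE)
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!include_het) {
    keep <- keep & !a$het & a$element != "H" & a$element != "D" &
      a$resname != "HOH" & a$resname != "WAT"
  }
  if (!is.null(sel$chains)) keep <- keep & a$chain %in% sel$chains
  if (!is.null(sel$residues)) {
    keep <- keep & a$resno >= sel$residues[1] & a$resno <= sel$residues[2]
  }
  if (!is.null(sel$atoms)) keep <- keep & a$atom %in% sel$atoms
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a structure model as a PDB file
#'
#' Emits fixed-width ATOM/HETATM records (temperature factors with two
#' decimals, coordinates with three, i.e. standard PDB precision).
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty model", call. = FALSE)
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      type = ifelse(a$het, "HETATM", "ATOM"),
      eleno = seq_len(nrow(a)),
      elety = a$atom,
      resid = a$resname,
      chain = a$chain,
      resno = a$resno,
      insert = ifelse(a$insert == "", NA, a$insert),
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      o = a$occ,
      b = a$b,
      elesy = a$element
    )
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write PDB to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Copy per-residue values into the temperature-factor column
#'
#' Utility for exporting per-residue statistics (for instance relative
#' hydrogen exchange from [residue_consolidation()]) onto a structure for
#' visualisation: every atom of residue `i` receives `values[i]`; residues
#' without a value get `missing_value`.
#'
#' @param model A `structure_model`.
#' @param values Numeric vector indexed by residue number.
#' @param missing_value b-factor for residues with no value (default 0).
#' @return The model with the `b` column replaced.
#' @export
set_bfactor <- function(model, values, missing_value = 0) {
  stopifnot(inherits(model, "structure_model"))
  b <- values[model$atoms$resno]
  b[is.na(b)] <- missing_value
  model$atoms$b <- as.numeric(b)
  model
}
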