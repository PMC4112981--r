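#' Create a compound record
#'
#' A compound is a named 2D structure held as SMILES. Structures are parsed and
#' canonicalized with OpenBabel; `standardized = TRUE` marks a structure that
#' has been through [standardize_compound()] (single fragment, stereo stripped,
#' neutral protonation).
#'
#' @param smiles SMILES string.
#' @param name compound name, non-empty, unique within a panel.
#' @param validate check that the SMILES parses (default `TRUE`).
#' @return an object of class `xr_compound` with fields `name`, `smiles`
#'   (current structure), `source_smiles` (as supplied) and `standardized`.
#' @export
#' @examples
#' compound("CC(=O)Oc1ccccc1C(=O)O", "aspirin")
compound <- function(smiles, name, validate = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L,
            is.character(name), length(name) == 1L)
  if (!nzchar(trimws(name))) stop("compound name must be non-empty")
  smiles <- trimws(smiles)
  if (validate && !is_valid_smiles(smiles)) {
    stop("unparsable SMILES for '", name, "': ", smiles)
  }
  structure(list(name = name, smiles = smiles, source_smiles = smiles,
                 standardized = FALSE),
            class = "xr_compound")
}

#' @export
print.xr_compound <- function(x, ...) {
  cat(sprintf("<compound> %s%s\n  %s\n", x$name,
              if (x$standardized) " (standardized)" else "", x$smiles))
  invisible(x)
}

is_compound <- function(x) inherits(x, "xr_compound")

#' Read a SMILES line file
#'
#' Dialect: one record per line, `SMILES<whitespace>name`; the name is the
#' remainder of the line and may contain spaces. Blank lines and lines starting
#' with `#` are skipped. Input order is preserved.
#'
#' @param path path to a `.smi` file.
#' @return list of [compound()] objects (unstandardized).
#' @seealso [write_smiles_file()], [read_sdf_file()]
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) return(list())
  bad <- character(0)
  out <- vector("list", length(keep))
  nms <- character(length(keep))
  for (i in seq_along(keep)) {
    ln <- trimws(lines[keep[i]])
    m <- regmatches(ln, regexec("^(\\S+)\\s+(.+)$", ln))[[1]]
    if (length(m) != 3L) {
      bad <- c(bad, sprintf("line %d: expected 'SMILES name'", keep[i]))
      next
    }
    smi <- m[2]; nm <- trimws(m[3])
    if (!is_valid_smiles(smi)) {
      bad <- c(bad, sprintf("line %d: unparsable SMILES '%s'", keep[i], smi))
      next
    }
    out[[i]] <- compound(smi, nm, validate = FALSE)
    nms[i] <- nm
  }
  if (length(bad)) stop("errors reading ", path, ":\n  ",
                        paste(bad, collapse = "\n  "))
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) stop("duplicate compound names in ", path, ": ",
                        paste(dup, collapse = ", "))
  out
}

#' Write compounds to a SMILES line file
#'
#' @param compounds list of [compound()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(compounds, path) {
  stopifnot(all(vapply(compounds, is_compound, logical(1))))
  writeLines(vapply(compounds, function(x) paste(x$smiles, x$name), character(1)),
             path)
  invisible(path)
}

#' Read compounds from an SDF (V2000) file
#'
#' Structures are converted to SMILES with OpenBabel. The compound name is
#' taken from the molecule title line, falling back to a `NAME`/`name` data
#' field when the title is blank.
#'
#' @param path path to an SDF file.
#' @return list of [compound()] objects (unstandardized).
#' @export
read_sdf_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sdfs <- ChemmineR::read.SDFset(path)
  out <- vector("list", length(sdfs))
  for (i in seq_along(sdfs)) {
    sdf <- sdfs[[i]]
    nm <- trimws(ChemmineR::header(sdf)[["Molecule_Name"]])
    if (!nzchar(nm)) {
      db <- ChemmineR::datablock(sdf)
      hit <- which(tolower(names(db)) == "name")
      nm <- if (length(hit)) trimws(db[[hit[1]]]) else ""
    }
    if (!nzchar(nm)) stop("SDF record ", i, " has no name")
    smi <- as.character(ChemmineR::sdf2smiles(sdfs[i]))[1]
    smi <- strsplit(trimws(smi), "\\s+")[[1]][1]
    out[[i]] <- compound(smi, nm)
  }
  nms <- vapply(out, `[[`, character(1), "name")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) stop("duplicate compound names in ", path, ": ",
                        paste(dup, collapse = ", "))
  out
}

#' Standardize a compound structure
#'
#' Applies the preprocessing that 2D structural-key comparison assumes:
#' \enumerate{
#'   \item keep the largest covalent fragment (salt/counterion stripping);
#'     largest by heavy-atom count, ties broken by molecular weight;
#'   \item remove all stereo descriptors (structural keys cannot separate
#'     diastereomers or enantiomers, so stereo must not influence comparison);
#'   \item normalize protonation to the neutral form for common ionized groups
#'     (deprotonated oxyacids/thiols, protonated amines);
#'   \item canonicalize the SMILES.
#' }
#' The operation is idempotent.
#'
#' @param x an [compound()] object.
#' @return the standardized compound (`standardized = TRUE`).
#' @export
#' @examples
#' standardize_compound(compound("C[C@@H](O)[C@H](C)O.[Na+].[Cl-]", "demo"))
standardize_compound <- function(x) {
  stopifnot(is_compound(x))
  smi <- largest_fragment(x$smiles)
  smi <- strip_stereo_smiles(smi)
  smi <- neutralize_smiles(smi)
  can <- canonical_smiles(smi)
  if (!nzchar(can)) stop("empty structure after standardization of '", x$name, "'")
  if (grepl(".", can, fixed = TRUE)) {
    # largest-fragment selection must leave one connected component
    stop("structure of '", x$name, "' is still multi-fragment after stripping")
  }
  x$smiles <- can
  x$standardized <- TRUE
  x
}

#' @rdname standardize_compound
#' @param compounds list of compounds.
#' @export
standardize_compounds <- function(compounds) {
  lapply(compounds, standardize_compound)
}

# ---- internal structure helpers (OpenBabel-backed) --------------------------

canonical_smiles <- function(smiles) {
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  s <- strsplit(trimws(out), "\\s+")[[1]][1]
  if (is.na(s)) "" else s
}

is_valid_smiles <- function(smiles) {
  if (!nzchar(smiles)) return(FALSE)
  nzchar(canonical_smiles(smiles))
}

heavy_atom_count <- function(smiles) {
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  as.integer(ChemmineOB::smartsSearch_OB(mol, "[!#1]"))
}

molecular_weight <- function(smiles) {
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  as.numeric(ChemmineOB::prop_OB(mol)$MW)
}

# keep largest covalent fragment: heavy atoms, tie -> MW
largest_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) stop("empty structure")
  if (length(frags) == 1L) return(frags)
  ha <- vapply(frags, heavy_atom_count, integer(1))
  top <- which(ha == max(ha))
  if (length(top) > 1L) {
    mw <- vapply(frags[top], molecular_weight, numeric(1))
    top <- top[which.max(mw)]
  }
  frags[top[1]]
}

# drop tetrahedral marks and double-bond direction; bracket hydrogen counts
# ([C@@H] -> [CH]) are preserved, so constitution is unchanged
strip_stereo_smiles <- function(smiles) {
  gsub("@|/|\\\\", "", smiles)
}

# neutralize the common single-atom charges; quaternary centres are left alone
neutralize_smiles <- function(smiles) {
  s <- smiles
  s <- gsub("[O-]", "O", s, fixed = TRUE)
  s <- gsub("[S-]", "S", s, fixed = TRUE)
  s <- gsub("[N-]", "N", s, fixed = TRUE)
  s <- gsub("\\[NH([0-9]?)\\+\\]", "N", s)
  s
}
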