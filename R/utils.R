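#' @keywords internal
"_PACKAGE"

## Gas constant in kcal mol^-1 K^-1; used for every RT factor in the package.
GAS_CONSTANT_KCAL <- 1.987204e-3

#' Thermal energy RT in kcal/mol
#'
#' @param temperature Temperature in Kelvin. The default, 310 K, matches the
#'   simulation temperature used throughout the affinity calculations.
#' @return RT in kcal/mol.
#' @export
rt_kcal <- function(temperature = 310) {
  stopifnot(is.numeric(temperature), temperature > 0)
  GAS_CONSTANT_KCAL * temperature
}

## van der Waals radii (Angstrom) by element; unknown elements fall back to
## carbon-like 1.7 A. Configurable through ligsite_params().
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8)
VDW_DEFAULT <- 1.7

vdw_radius <- function(elements, table = VDW_RADII, default = VDW_DEFAULT) {
  r <- unname(table[toupper(elements)])
  r[is.na(r)] <- default
  r
}

## Residue names treated as solvent/ions, excluded from "protein" selections.
SOLVENT_RESNAMES <- c(
  "HOH", "WAT", "TIP", "TIP3", "SOL", "NA", "CL", "K", "MG", "CA", "ZN",
  "SO4", "PO4", "GOL", "EDO", "ACT", "DMS"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Infer element symbol from a PDB atom name when the element column is blank.
## PDB convention: columns 13-14 hold the element, so a name like " CA " is
## carbon while "CA  " starting in column 13 would be calcium; after
## whitespace-stripping we use the first alphabetic character, except for
## obvious two-letter halogens/metals in HETATM names.
infer_element <- function(atom_names) {
  nm <- toupper(trimws(atom_names))
  first <- substr(gsub("[^A-Z]", "", nm), 1, 1)
  ## hydrogens named like 1HB2 / HG11
  first[grepl("^[0-9]*H", nm)] <- "H"
  first
}

## Deterministic seed derivation: combine a base seed with a small stream id,
## staying well below .Machine$integer.max.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + stream) %% 2147483647)
}
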