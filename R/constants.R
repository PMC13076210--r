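#' Monoisotopic mass constants
#'
#' Standard monoisotopic masses (Da) used throughout the fragment-ion
#' calculus: elemental/small-molecule constants and the 20 amino-acid
#' residue masses, plus the two supported named modifications
#' (carbamidomethyl-Cys, fixed; oxidised Met, variable).
#'
#' @return A named list with elements `constants` (named numeric vector:
#'   `proton`, `H`, `H2O`, `NH3`, `CO`, `C13C12`), `residues` (named
#'   numeric vector of the 20 residue masses) and `modifications`
#'   (named numeric vector of mass deltas for `cam` and `ox`).
#' @examples
#' mass_constants()$constants[["proton"]]
#' @export
mass_constants <- function() {
  list(
    constants = c(
      proton = 1.0072765,
      H      = 1.0078250,
      H2O    = 18.0105646,
      NH3    = 17.0265491,
      CO     = 27.9949146,
      C13C12 = 1.0033548
    ),
    residues = c(
      G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
      V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
      I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
      K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
      F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
    ),
    modifications = c(cam = 57.021464, ox = 15.994915)
  )
}

# internal cached copies (constants never change at run time)
.mf <- mass_constants()
.RESIDUES <- .mf$residues
.CONST <- .mf$constants
.MODS <- .mf$modifications

# token-level masses: plain residues plus the named-mod tokens
.TOKEN_MASSES <- c(
  .RESIDUES,
  `C(cam)` = unname(.RESIDUES["C"] + .MODS["cam"]),
  `M(ox)`  = unname(.RESIDUES["M"] + .MODS["ox"])
)

#' Supported fragmentation methods
#' @return Character vector of the five supported dissociation methods.
#' @export
fragmentation_methods <- function() c("HCD", "ECD", "EID", "UVPD", "ETciD")

#' Ion series names in canonical (alphabet) order
#' @return Character vector of the ten backbone ion series labels.
#' @export
ion_series_names <- function() {
  c("a", "a+1", "b", "c-1", "c", "x", "x+1", "y", "z", "z+1")
}

# clash-resolution / dictionary priority: common series first
.SERIES_PRIORITY <- c("y", "b", "c", "z", "a", "x", "z+1", "a+1", "c-1", "x+1")

#' Tokenise a (possibly modified) peptide string
#'
#' Peptide strings use one upper-case letter per residue, with named
#' modifications attached in parentheses: `"C(cam)"` for
#' carbamidomethyl-Cys and `"M(ox)"` for oxidised Met, e.g.
#' `"PEPTM(ox)IDEC(cam)K"`.
#'
#' @param peptide Single peptide string.
#' @return Character vector of residue tokens (one per residue).
#' @examples
#' peptide_tokens("AC(cam)M(ox)K")
#' @export
peptide_tokens <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L, !is.na(peptide))
  tokens <- regmatches(
    peptide,
    gregexpr("[A-Z](\\([a-z0-9]+\\))?", peptide)
  )[[1]]
  if (nchar(peptide) == 0L || sum(nchar(tokens)) != nchar(peptide)) {
    stop("cannot tokenise peptide string: '", peptide, "'", call. = FALSE)
  }
  bad <- !tokens %in% names(.TOKEN_MASSES)
  if (any(bad)) {
    stop(
      "invalid residue token(s) at position(s) ",
      paste(which(bad), collapse = ", "), ": ",
      paste(unique(tokens[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  tokens
}

# residue-level masses for a token vector, plus optional positional deltas
residue_mass_vector <- function(tokens, modifications = NULL) {
  masses <- unname(.TOKEN_MASSES[tokens])
  if (!is.null(modifications) && length(modifications) > 0L) {
    pos <- as.integer(names(modifications))
    if (anyNA(pos) || any(pos < 1L) || any(pos > length(tokens))) {
      stop("modification positions must be 1..peptide length", call. = FALSE)
    }
    if (any(!is.finite(modifications))) {
      stop("modification mass deltas must be finite", call. = FALSE)
    }
    masses[pos] <- masses[pos] + as.numeric(modifications)
  }
  masses
}
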