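#' Ion series offset table
#'
#' Neutral-mass offsets (Da) of the ten backbone fragment-ion series
#' relative to the base series of their terminus: `b` for N-terminal
#' fragments (neutral mass = sum of prefix residues) and `y` for
#' C-terminal fragments (suffix residues + H2O). The z-series offsets
#' follow the radical "z-dot" convention common in the ECD literature
#' (z = y - NH3 + H, z+1 = z + H) and can be overridden.
#'
#' @param z_offset Neutral offset of the z series relative to y.
#' @param z1_offset Neutral offset of the z+1 series relative to y.
#' @return Tibble with columns `series`, `terminus` ("N"/"C") and
#'   `offset` (Da relative to b or y).
#' @export
ion_series_table <- function(z_offset = -.CONST[["NH3"]] + .CONST[["H"]],
                             z1_offset = z_offset + .CONST[["H"]]) {
  H <- .CONST[["H"]]; CO <- .CONST[["CO"]]; NH3 <- .CONST[["NH3"]]
  tibble::tibble(
    series = c("a", "a+1", "b", "c-1", "c", "x", "x+1", "y", "z", "z+1"),
    terminus = c(rep("N", 5L), rep("C", 5L)),
    offset = c(
      -CO,            # a  = b - CO
      -CO + H,        # a+1 = a + H (radical a plus one hydrogen)
      0,              # b
      NH3 - H,        # c-1 = c - H (radical)
      NH3,            # c  = b + NH3
      CO - 2 * H,     # x  = y + CO - H2
      CO - H,         # x+1 = x + H
      0,              # y
      z_offset,       # z (z-dot by default)
      z1_offset       # z+1 = z + H
    )
  )
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus any
#' positional mass deltas.
#'
#' @param peptide Peptide string (see [peptide_tokens()] for the
#'   modified-residue grammar).
#' @param modifications Optional named numeric vector of extra mass
#'   deltas, names = 1-based residue positions.
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("PEPTIDE")
#' @export
peptide_mass <- function(peptide, modifications = NULL) {
  tokens <- peptide_tokens(peptide)
  sum(residue_mass_vector(tokens, modifications)) + .CONST[["H2O"]]
}

#' Neutral mass of a backbone fragment
#'
#' @inheritParams peptide_mass
#' @param series Ion series name(s), one of
#'   `a, a+1, b, c-1, c, x, x+1, y, z, z+1` (recycled against `ordinal`).
#' @param ordinal Fragment length(s): number of residues counted from
#'   the N terminus for a/b/c-type ions and from the C terminus for
#'   x/y/z-type ions. Must satisfy `1 <= ordinal <= length - 1`.
#' @param series_table Offset table from [ion_series_table()].
#' @return Numeric vector of neutral fragment masses (Da).
#' @examples
#' fragment_mass("PEPTIDE", "b", 2)
#' fragment_mass("PEPTIDE", c("b", "y"), c(2, 1))
#' @export
fragment_mass <- function(peptide, series, ordinal, modifications = NULL,
                          series_table = ion_series_table()) {
  tokens <- peptide_tokens(peptide)
  n <- length(tokens)
  k <- max(length(series), length(ordinal))
  series <- rep_len(series, k)
  ordinal <- rep_len(as.integer(ordinal), k)
  if (any(ordinal < 1L) || any(ordinal >= n)) {
    stop("fragment ordinal out of range (must be 1..length-1 = 1..",
         n - 1L, ")", call. = FALSE)
  }
  idx <- match(series, series_table$series)
  if (anyNA(idx)) {
    stop("unknown ion series: ",
         paste(unique(series[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  masses <- residue_mass_vector(tokens, modifications)
  prefix <- cumsum(masses)
  suffix <- rev(cumsum(rev(masses)))
  base <- ifelse(
    series_table$terminus[idx] == "N",
    prefix[ordinal],
    suffix[n - ordinal + 1L] + .CONST[["H2O"]]
  )
  base + series_table$offset[idx]
}

#' m/z of an ion from its neutral mass and charge
#'
#' @param neutral Neutral mass(es), Da.
#' @param charge Positive integer charge(s).
#' @return `(neutral + charge * proton) / charge`.
#' @examples
#' ion_mz(799.3600, 2)
#' @export
ion_mz <- function(neutral, charge) {
  if (any(charge < 1L)) stop("charge must be >= 1", call. = FALSE)
  (neutral + charge * .CONST[["proton"]]) / charge
}

#' Enumerate the theoretical fragment ions of a peptide
#'
#' Full cross product of ion series, fragment ordinal (1 up to
#' `min(max_ordinal, length - 1)`) and fragment charge, in the
#' deterministic order (series as given, ordinal, charge).
#'
#' @inheritParams fragment_mass
#' @param series Character vector of ion series to enumerate.
#' @param max_ordinal Maximum fragment length (default 29).
#' @param charges Fragment charge states (default `1:3`).
#' @return Tibble with columns `series`, `ordinal`, `charge`,
#'   `neutral`, `mz` and `ion` (label `"<series>:<ordinal>:<charge>"`).
#' @examples
#' theoretical_ions("PEPTIDE", series = c("b", "y"))
#' @export
theoretical_ions <- function(peptide, series = ion_series_names(),
                             max_ordinal = 29L, charges = 1:3,
                             modifications = NULL,
                             series_table = ion_series_table()) {
  stopifnot(length(series) >= 1L)
  tokens <- peptide_tokens(peptide)
  n_ord <- min(max_ordinal, length(tokens) - 1L)
  if (n_ord < 1L) stop("peptide must have length >= 2", call. = FALSE)
  grid <- tidyr::expand_grid(
    series = series,
    ordinal = seq_len(n_ord),
    charge = as.integer(charges)
  )
  neutral <- fragment_mass(peptide, grid$series, grid$ordinal,
                           modifications = modifications,
                           series_table = series_table)
  tibble::tibble(
    series = grid$series,
    ordinal = grid$ordinal,
    charge = grid$charge,
    neutral = neutral,
    mz = ion_mz(neutral, grid$charge),
    ion = ion_label(grid$series, grid$ordinal, grid$charge)
  )
}

#' Compose / parse ion labels
#'
#' Labels follow the grammar `"<series>:<ordinal>:<charge>"`, e.g.
#' `"y:3:1"` or `"a+1:7:2"`.
#'
#' @param series,ordinal,charge Vectors composing the label.
#' @return `ion_label()`: character vector. `parse_ion_label()`: tibble
#'   with columns `series`, `ordinal`, `charge`.
#' @examples
#' ion_label("y", 3, 1)
#' parse_ion_label("a+1:7:2")
#' @export
ion_label <- function(series, ordinal, charge) {
  paste(series, ordinal, charge, sep = ":")
}

#' @rdname ion_label
#' @param label Character vector of ion labels.
#' @export
parse_ion_label <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("malformed ion label: ", paste(label[bad], collapse = ", "),
         call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  tibble::tibble(
    series = m[, 1L],
    ordinal = as.integer(m[, 2L]),
    charge = as.integer(m[, 3L])
  )
}

#' Precursor isotope peak positions
#'
#' The first `n_isotopes` isotopologue peaks of the intact precursor at
#' its own charge, plus the same neutral species recomputed at
#' `charge + 1`. These positions are excluded from fragment annotation.
#'
#' @param precursor_mz Precursor m/z.
#' @param charge Precursor charge (>= 1).
#' @param n_isotopes Number of isotope peaks per charge state.
#' @return Tibble with columns `charge`, `k` (isotope index, 0-based)
#'   and `mz`.
#' @export
precursor_isotope_mzs <- function(precursor_mz, charge, n_isotopes = 4L) {
  stopifnot(charge >= 1L, n_isotopes >= 1L)
  neutral <- (precursor_mz - .CONST[["proton"]]) * charge
  k <- seq_len(n_isotopes) - 1L
  purrr::map_dfr(c(charge, charge + 1L), function(z) {
    tibble::tibble(
      charge = as.integer(z),
      k = k,
      mz = ion_mz(neutral, z) + k * .CONST[["C13C12"]] / z
    )
  })
}
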