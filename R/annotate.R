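#' Annotation parameters
#'
#' Bundles the matching tolerances and per-method ion-series sets used
#' by [annotate_spectrum()].
#'
#' @param tol_ppm Matching tolerance in parts per million (default 10).
#' @param precursor_window_da Full width (Da) of the exclusion window
#'   centred on the precursor m/z (default 2.4).
#' @param n_isotope_peaks Number of precursor isotope peaks flagged per
#'   charge state (default 4; applied at the precursor charge and
#'   charge + 1).
#' @param peak_rule When several peaks fall within tolerance of one
#'   theoretical ion: `"nearest"` (smallest |ppm|, default) or
#'   `"intense"` (largest intensity).
#' @param series_sets Named list mapping each fragmentation method to
#'   its ion-series set (defaults from [default_series_sets()]).
#' @param frag_charges Fragment charge states considered (default 1:3).
#' @param max_ordinal Maximum fragment length (default 29).
#' @return List of class `annotation_params`.
#' @export
annotation_params <- function(tol_ppm = 10, precursor_window_da = 2.4,
                              n_isotope_peaks = 4L,
                              peak_rule = c("nearest", "intense"),
                              series_sets = default_series_sets(),
                              frag_charges = 1:3, max_ordinal = 29L) {
  stopifnot(tol_ppm > 0, precursor_window_da >= 0)
  structure(
    list(
      tol_ppm = tol_ppm,
      precursor_window_da = precursor_window_da,
      n_isotope_peaks = as.integer(n_isotope_peaks),
      peak_rule = match.arg(peak_rule),
      series_sets = series_sets,
      frag_charges = as.integer(frag_charges),
      max_ordinal = as.integer(max_ordinal)
    ),
    class = "annotation_params"
  )
}

#' Default ion-series set per fragmentation method
#'
#' ECD spectra are dominated by c/z-type fragments, HCD by a/b/y,
#' while EID and UVPD produce all ten main series; ETciD yields
#' b/c/y/z-type ions. Each set can be overridden through
#' [annotation_params()].
#'
#' @return Named list of character vectors.
#' @export
default_series_sets <- function() {
  list(
    HCD = c("a", "a+1", "b", "y"),
    ECD = c("c-1", "c", "z", "z+1", "y", "b"),
    EID = ion_series_names(),
    UVPD = ion_series_names(),
    ETciD = c("b", "c", "y", "z", "z+1")
  )
}

#' Ion-series set for a fragmentation method
#' @param method Fragmentation method name.
#' @param params [annotation_params()] object.
#' @return Character vector of series names.
#' @export
method_series <- function(method, params = annotation_params()) {
  set <- params$series_sets[[method]]
  if (is.null(set)) stop("unknown fragmentation method: ", method,
                         call. = FALSE)
  set
}

#' Annotate an MS2 spectrum against a peptide's theoretical ions
#'
#' Peaks inside the precursor exclusion window are removed first, then
#' peaks matching any of the precursor isotope positions (within
#' tolerance) are flagged, and only the remaining peaks are matched to
#' theoretical fragment ions within the ppm tolerance. Many-to-many
#' matches are resolved deterministically by [resolve_clashes()]; each
#' theoretical ion annotates at most one peak and vice versa.
#'
#' @param peaks Data frame with columns `mz` and `intensity`.
#' @param peptide Peptide string (modified-token grammar).
#' @param precursor_mz,precursor_charge Precursor m/z and charge.
#' @param method Fragmentation method (selects the ion-series set).
#' @param params [annotation_params()] object.
#' @param modifications Optional positional mass deltas (see
#'   [peptide_mass()]).
#' @return Tibble with one row per input peak (in m/z order):
#'   `peak` (index into the m/z-sorted peak list), `mz`, `intensity`,
#'   `status` (`"assigned"`, `"precursor_window"`,
#'   `"precursor_isotope"` or `"unassigned"`) and, for assigned peaks,
#'   `ion`, `series`, `ordinal`, `frag_charge`, `theo_mz`, `ppm`.
#'   The ppm sign convention is `(observed - theoretical) /
#'   theoretical * 1e6`.
#' @export
annotate_spectrum <- function(peaks, peptide, precursor_mz, precursor_charge,
                              method, params = annotation_params(),
                              modifications = NULL) {
  tokens <- peptide_tokens(peptide)
  if (length(tokens) < 2L) stop("peptide must have length >= 2",
                                call. = FALSE)
  series <- method_series(method, params)

  peaks <- tibble::as_tibble(peaks)[, c("mz", "intensity")]
  stopifnot(all(is.finite(peaks$mz)), all(peaks$intensity >= 0))
  peaks <- dplyr::arrange(peaks, .data$mz)
  n <- nrow(peaks)
  out <- tibble::tibble(
    peak = seq_len(n), mz = peaks$mz, intensity = peaks$intensity,
    status = rep("unassigned", n),
    ion = NA_character_, series = NA_character_,
    ordinal = NA_integer_, frag_charge = NA_integer_,
    theo_mz = NA_real_, ppm = NA_real_
  )
  if (n == 0L) return(out)

  # 1) precursor window exclusion (full width, centred on precursor m/z)
  half <- params$precursor_window_da / 2
  in_window <- abs(out$mz - precursor_mz) <= half
  out$status[in_window] <- "precursor_window"

  # 2) precursor isotope flagging at charge and charge + 1
  iso <- precursor_isotope_mzs(precursor_mz, precursor_charge,
                               params$n_isotope_peaks)
  eligible <- which(out$status == "unassigned")
  if (length(eligible) > 0L && nrow(iso) > 0L) {
    dppm <- abs(outer(out$mz[eligible], iso$mz, "-")) /
      rep(iso$mz, each = length(eligible)) * 1e6
    hit <- apply(dppm <= params$tol_ppm, 1L, any)
    out$status[eligible[hit]] <- "precursor_isotope"
  }

  # 3) fragment matching on the remaining peaks
  theo <- theoretical_ions(peptide, series = series,
                           max_ordinal = params$max_ordinal,
                           charges = params$frag_charges,
                           modifications = modifications)
  eligible <- which(out$status == "unassigned")
  if (length(eligible) == 0L) return(out)

  d <- outer(out$mz[eligible], theo$mz, "-") /
    rep(theo$mz, each = length(eligible)) * 1e6
  idx <- which(abs(d) <= params$tol_ppm, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)

  candidates <- tibble::tibble(
    peak = eligible[idx[, 1L]],
    series = theo$series[idx[, 2L]],
    ordinal = theo$ordinal[idx[, 2L]],
    charge = theo$charge[idx[, 2L]],
    theo_mz = theo$mz[idx[, 2L]],
    ppm = d[idx],
    intensity = out$intensity[eligible[idx[, 1L]]]
  )
  chosen <- resolve_clashes(candidates, peak_rule = params$peak_rule)
  if (nrow(chosen) > 0L) {
    out$status[chosen$peak] <- "assigned"
    out$ion[chosen$peak] <- ion_label(chosen$series, chosen$ordinal,
                                      chosen$charge)
    out$series[chosen$peak] <- chosen$series
    out$ordinal[chosen$peak] <- chosen$ordinal
    out$frag_charge[chosen$peak] <- chosen$charge
    out$theo_mz[chosen$peak] <- chosen$theo_mz
    out$ppm[chosen$peak] <- chosen$ppm
  }
  out
}

#' Resolve many-to-many peak/ion match candidates
#'
#' Greedy one-to-one assignment: candidates are taken in ascending
#' |ppm| (or descending intensity under the `"intense"` rule), with
#' ties broken by a fixed series priority
#' (y, b, c, z, a, x, z+1, a+1, c-1, x+1), then lower fragment charge,
#' then lower ordinal. Each peak and each theoretical ion is used at
#' most once; the procedure is stable and deterministic.
#'
#' @param candidates Tibble with columns `peak`, `series`, `ordinal`,
#'   `charge`, `ppm` and (for the `"intense"` rule) `intensity`;
#'   optional extra columns are carried through.
#' @param peak_rule `"nearest"` or `"intense"`.
#' @return Subset of `candidates` forming the unique assignment.
#' @export
resolve_clashes <- function(candidates, peak_rule = "nearest") {
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) == 0L) return(candidates)
  prio <- match(candidates$series, .SERIES_PRIORITY)
  if (anyNA(prio)) stop("unknown series in candidates", call. = FALSE)
  primary <- if (identical(peak_rule, "intense")) {
    -candidates$intensity
  } else {
    abs(candidates$ppm)
  }
  ord <- order(primary, prio, candidates$charge, candidates$ordinal,
               candidates$peak)
  used_peak <- integer(0)
  used_ion <- character(0)
  keep <- logical(nrow(candidates))
  labels <- ion_label(candidates$series, candidates$ordinal,
                      candidates$charge)
  for (i in ord) {
    if (candidates$peak[i] %in% used_peak) next
    if (labels[i] %in% used_ion) next
    keep[i] <- TRUE
    used_peak <- c(used_peak, candidates$peak[i])
    used_ion <- c(used_ion, labels[i])
  }
  candidates[keep, , drop = FALSE]
}

#' Annotate a table of PSMs against their spectra
#'
#' Joins a PSM table to a spectra table on (`raw_file`, `scan`) and
#' annotates each match. Returns the assigned peaks only, with PSM
#' identity carried along; non-assigned peak statuses are dropped (use
#' [annotate_spectrum()] for the full per-peak view).
#'
#' @param spectra Tibble with columns `raw_file`, `scan`,
#'   `precursor_mz`, `precursor_charge` and a `peaks` list-column of
#'   data frames (`mz`, `intensity`).
#' @param psms Tibble with columns `raw_file`, `scan`, `peptide`,
#'   `charge`, `method` (and optionally `hyperscore`, `is_decoy`).
#' @param params [annotation_params()] object.
#' @return Tibble of assignments, one row per annotated peak, with
#'   columns `psm` (row index into `psms`), `raw_file`, `scan`,
#'   `peptide`, `method`, `ion`, `series`, `ordinal`, `frag_charge`,
#'   `theo_mz`, `mz`, `ppm`, `intensity`.
#' @export
annotate_psms <- function(spectra, psms, params = annotation_params()) {
  key <- paste(spectra$raw_file, spectra$scan, sep = "\r")
  hit <- match(paste(psms$raw_file, psms$scan, sep = "\r"), key)
  if (anyNA(hit)) {
    stop("PSM(s) reference spectra absent from `spectra`: rows ",
         paste(utils::head(which(is.na(hit)), 5L), collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(psms)), function(i) {
    s <- hit[i]
    ann <- annotate_spectrum(
      spectra$peaks[[s]], psms$peptide[i],
      precursor_mz = spectra$precursor_mz[s],
      precursor_charge = spectra$precursor_charge[s],
      method = psms$method[i], params = params
    )
    ann <- dplyr::filter(ann, .data$status == "assigned")
    if (nrow(ann) == 0L) return(NULL)
    tibble::tibble(
      psm = i,
      raw_file = psms$raw_file[i], scan = psms$scan[i],
      peptide = psms$peptide[i], method = psms$method[i],
      ion = ann$ion, series = ann$series, ordinal = ann$ordinal,
      frag_charge = ann$frag_charge, theo_mz = ann$theo_mz,
      mz = ann$mz, ppm = ann$ppm, intensity = ann$intensity
    )
  })
}

#' Mean per-spectrum ion-series proportions by fragmentation method
#'
#' For every annotated spectrum the proportion of assigned peaks per
#' ion series is computed from counts (not intensities); proportions
#' are then averaged over the spectra of each method. Spectra with zero
#' assignments contribute nothing.
#'
#' @param assignments Assignment tibble from [annotate_psms()] (needs
#'   columns `psm` or (`raw_file`, `scan`, `peptide`), `method`,
#'   `series`).
#' @param series Series levels to report (default all ten);
#'   assignments outside this set are dropped before proportions are
#'   computed, so the reported proportions always sum to 1 per method.
#' @return Tibble `method` x `series` with column `proportion`; the
#'   proportions of each method sum to 1.
#' @export
annotation_proportions <- function(assignments,
                                   series = ion_series_names()) {
  stopifnot(nrow(assignments) > 0L)
  lvls <- series
  assignments <- assignments[assignments$series %in% lvls, , drop = FALSE]
  if (nrow(assignments) == 0L) {
    stop("no assignments in the requested series", call. = FALSE)
  }
  if (!"psm" %in% names(assignments)) {
    assignments$psm <- paste(assignments$raw_file, assignments$scan,
                             assignments$peptide, sep = "\r")
  }
  per_spectrum <- assignments |>
    dplyr::count(.data$method, .data$psm, .data$series) |>
    dplyr::group_by(.data$method, .data$psm) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  per_spectrum |>
    dplyr::group_by(.data$method, .data$psm) |>
    tidyr::complete(series = lvls, fill = list(proportion = 0)) |>
    dplyr::group_by(.data$method, .data$series) |>
    dplyr::summarise(proportion = mean(.data$proportion),
                     .groups = "drop") |>
    dplyr::mutate(series = factor(.data$series, levels = lvls)) |>
    dplyr::arrange(.data$method, .data$series)
}

#' Intensity ratio of a+1 over a ions in one annotated spectrum
#'
#' Sum of intensities assigned to the a+1 series divided by the sum
#' assigned to the a series. In electron- and photon-based spectra a
#' large ratio indicates radical a+1 ions formed by gas-phase
#' chemistry rather than 13C isotopes of a ions.
#'
#' @param assignments Assignment rows of a single spectrum (columns
#'   `series`, `intensity`).
#' @return Ratio, or `NA_real_` when no a-ion intensity is present
#'   (undefined, not zero).
#' @export
a1_over_a_ratio <- function(assignments) {
  a <- sum(assignments$intensity[assignments$series == "a"])
  a1 <- sum(assignments$intensity[assignments$series == "a+1"])
  if (a <= 0) return(NA_real_)
  a1 / a
}
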