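#' Read an MGF file of MS2 spectra
#'
#' Parses the Mascot generic format subset used for peptide MS2 data:
#' `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`, `CHARGE`,
#' `SCANS` and `RTINSECONDS` headers followed by `m/z intensity` peak
#' lines.
#'
#' @param path Path to an (uncompressed) MGF file.
#' @param raw_file Raw-file name recorded for each spectrum; defaults
#'   to the file's base name.
#' @return Tibble with columns `raw_file`, `scan`, `title`,
#'   `precursor_mz`, `precursor_charge`, `rt` and a `peaks`
#'   list-column of tibbles (`mz`, `intensity`, sorted by m/z).
#' @export
read_mgf <- function(path, raw_file = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  purrr::map2_dfr(begins, ends, function(b, e) {
    block <- lines[(b + 1L):(e - 1L)]
    is_header <- grepl("^[A-Z]+=", block)
    headers <- block[is_header]
    kv <- sub("=.*$", "", headers)
    vals <- sub("^[A-Z]+=", "", headers)
    get <- function(key) if (key %in% kv) vals[match(key, kv)] else NA_character_
    pep <- get("PEPMASS")
    charge <- get("CHARGE")
    title <- get("TITLE")
    scan <- get("SCANS")
    if (is.na(scan) && !is.na(title)) {
      m <- regmatches(title, regexpr("scan=([0-9]+)", title))
      scan <- if (length(m)) sub("scan=", "", m) else NA_character_
    }
    peak_lines <- block[!is_header & nzchar(block)]
    peaks <- if (length(peak_lines) > 0L) {
      m <- do.call(rbind, strsplit(trimws(peak_lines), "[ \t]+"))
      tibble::tibble(mz = as.numeric(m[, 1L]),
                     intensity = as.numeric(m[, 2L])) |>
        dplyr::arrange(.data$mz)
    } else {
      tibble::tibble(mz = numeric(0), intensity = numeric(0))
    }
    tibble::tibble(
      raw_file = raw_file,
      scan = as.integer(scan),
      title = title,
      precursor_mz = as.numeric(strsplit(pep, "[ \t]+")[[1L]][1L]),
      precursor_charge = as.integer(sub("\\+$", "", charge)),
      rt = as.numeric(get("RTINSECONDS")),
      peaks = list(peaks)
    )
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra Tibble as returned by [read_mgf()] (columns
#'   `scan`, `precursor_mz`, `precursor_charge`, `peaks`; optional
#'   `title`, `rt`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::map_chr(seq_len(nrow(spectra)), function(i) {
    p <- spectra$peaks[[i]]
    title <- if ("title" %in% names(spectra) && !is.na(spectra$title[i])) {
      spectra$title[i]
    } else {
      sprintf("%s scan=%d", spectra$raw_file[i], spectra$scan[i])
    }
    hdr <- c(
      "BEGIN IONS",
      paste0("TITLE=", title),
      sprintf("PEPMASS=%.6f", spectra$precursor_mz[i]),
      sprintf("CHARGE=%d+", spectra$precursor_charge[i]),
      sprintf("SCANS=%d", spectra$scan[i]),
      if ("rt" %in% names(spectra) && !is.na(spectra$rt[i])) {
        sprintf("RTINSECONDS=%.2f", spectra$rt[i])
      }
    )
    paste(c(hdr, sprintf("%.6f %.6g", p$mz, p$intensity), "END IONS"),
          collapse = "\n")
  })
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

# required columns of a PSM table
.PSM_COLS <- c("raw_file", "scan", "peptide", "modifications", "charge",
               "method", "hyperscore", "is_decoy")

#' Read / write a PSM table (TSV)
#'
#' The tab-separated PSM contract has columns `raw_file`, `scan`,
#' `peptide` (modified token grammar), `modifications`, `charge`,
#' `method`, `hyperscore`, `is_decoy`. Unknown extra columns are
#' accepted with a warning; missing required columns are an error.
#'
#' @param path Path to the TSV file.
#' @return Tibble of PSMs.
#' @export
read_psms <- function(path) {
  psms <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.PSM_COLS, names(psms))
  if (length(missing) > 0L) {
    stop("PSM table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(psms), .PSM_COLS)
  if (length(extra) > 0L) {
    warning("ignoring unknown PSM column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  psms$scan <- as.integer(psms$scan)
  psms$charge <- as.integer(psms$charge)
  psms$is_decoy <- as.logical(psms$is_decoy)
  psms
}

#' @rdname read_psms
#' @param psms PSM tibble.
#' @export
write_psms <- function(psms, path) {
  readr::write_tsv(psms, path, progress = FALSE)
  invisible(path)
}

#' Write annotated peaks to TSV
#'
#' One row per assignment: scan, ion label, ordinal, charge,
#' theoretical m/z, observed m/z, ppm error and intensity.
#'
#' @param assignments Assignment tibble from [annotate_psms()].
#' @param path Output path.
#' @export
write_annotations <- function(assignments, path) {
  cols <- c("raw_file", "scan", "peptide", "method", "ion", "ordinal",
            "frag_charge", "theo_mz", "mz", "ppm", "intensity")
  readr::write_tsv(assignments[, intersect(cols, names(assignments))],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("ion" %in% names(ann) && !"series" %in% names(ann)) {
    ann$series <- parse_ion_label(ann$ion)$series
  }
  ann
}
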