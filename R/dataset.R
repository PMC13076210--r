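#' Clean a PSM table for model training
#'
#' Removes decoy PSMs and PSMs with no identified annotations.
#'
#' @param psms PSM tibble (columns incl. `is_decoy`).
#' @param assignments Assignment tibble from [annotate_psms()] (its
#'   `psm` column indexes rows of `psms`).
#' @return Filtered PSM tibble with a `psm` column preserving the
#'   original row index (so `assignments$psm` still applies).
#' @export
clean_psms <- function(psms, assignments) {
  psms <- tibble::as_tibble(psms)
  psms$psm <- seq_len(nrow(psms))
  annotated <- unique(assignments$psm)
  out <- dplyr::filter(psms, !.data$is_decoy, .data$psm %in% annotated)
  n_decoy <- sum(psms$is_decoy)
  n_unann <- nrow(psms) - n_decoy - nrow(out)
  message(sprintf("clean_psms: removed %d decoys, %d without annotations; %d retained",
                  n_decoy, n_unann, nrow(out)))
  out
}

#' Deduplicate PSMs to unique (sequence, charge, method) spectra
#'
#' Retains the instance with the highest hyperscore per key; ties are
#' broken by lexicographic (`raw_file`, `scan`) order for determinism.
#'
#' @param psms PSM tibble with columns `peptide`, `charge`, `method`,
#'   `hyperscore`, `raw_file`, `scan`.
#' @return One row per unique key.
#' @export
deduplicate_psms <- function(psms) {
  psms |>
    dplyr::arrange(dplyr::desc(.data$hyperscore), .data$raw_file,
                   .data$scan) |>
    dplyr::distinct(.data$peptide, .data$charge, .data$method,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$peptide, .data$charge, .data$method)
}

#' Build the model's ion dictionary from an annotation corpus
#'
#' The dictionary is the model's unstructured output space: all ion
#' labels that occur at least `min_count` times in the corpus, in the
#' canonical order (series priority y, b, c, z, a, x, z+1, a+1, c-1,
#' x+1; then ordinal; then charge).
#'
#' @param assignments Assignment tibble (column `ion`, or `series` +
#'   `ordinal` + `frag_charge`).
#' @param min_count Minimum number of occurrences (default 100).
#' @return Tibble of class `ion_dictionary` with columns `ion`,
#'   `series`, `ordinal`, `charge`, `count`, `index` (1-based, dense);
#'   attribute `min_count`.
#' @export
build_ion_dictionary <- function(assignments, min_count = 100L) {
  if (nrow(assignments) == 0L) {
    dict <- tibble::tibble(ion = character(0), series = character(0),
                           ordinal = integer(0), charge = integer(0),
                           count = integer(0), index = integer(0))
    return(structure(dict, class = c("ion_dictionary", class(dict)),
                     min_count = as.integer(min_count)))
  }
  counts <- dplyr::count(assignments, .data$ion, name = "count")
  parsed <- parse_ion_label(counts$ion)
  dict <- dplyr::bind_cols(counts, parsed) |>
    dplyr::filter(.data$count >= min_count) |>
    dplyr::arrange(match(.data$series, .SERIES_PRIORITY), .data$ordinal,
                   .data$charge) |>
    dplyr::mutate(index = dplyr::row_number()) |>
    dplyr::select("ion", "series", "ordinal", "charge", "count", "index")
  structure(dict, class = c("ion_dictionary", class(dict)),
            min_count = as.integer(min_count))
}

# analytic mask: -1 iff ion ordinal >= peptide length (in residues)
# or ion charge > precursor charge
dictionary_mask <- function(dictionary, peptide_len, precursor_charge) {
  dictionary$ordinal >= peptide_len | dictionary$charge > precursor_charge
}

#' Build a masked, max-scaled intensity target vector
#'
#' Maps each annotated ion string of one PSM to its dictionary index.
#' Entries whose ion cannot occur for this peptide (ordinal at or
#' beyond the peptide length, or fragment charge above the precursor
#' charge) are set to -1 and masked out of training; all other
#' unannotated entries are 0. Non-negative entries are max-scaled by
#' the most intense ion so intensities fall in `[0, 1]` (an all-zero
#' vector stays all zero).
#'
#' @param ions Character vector of annotated ion labels.
#' @param intensities Numeric vector of matching intensities.
#' @param peptide Peptide string (its token count is the length used
#'   for masking).
#' @param charge Precursor charge.
#' @param dictionary [build_ion_dictionary()] result.
#' @return Numeric vector of length `nrow(dictionary)` with entries in
#'   `{-1} U [0, 1]`.
#' @export
vectorize_ions <- function(ions, intensities, peptide, charge, dictionary) {
  len <- length(peptide_tokens(peptide))
  if (len > 30L) stop("peptide exceeds the maximum model length of 30",
                      call. = FALSE)
  if (nrow(dictionary) == 0L) stop("empty ion dictionary", call. = FALSE)
  target <- numeric(nrow(dictionary))
  idx <- match(ions, dictionary$ion)
  hit <- !is.na(idx)
  if (any(hit)) {
    # several peaks can map to the same label only across PSMs, not
    # within one (annotation is one-to-one); keep max defensively
    for (j in which(hit)) {
      target[idx[j]] <- max(target[idx[j]], intensities[j])
    }
  }
  mask <- dictionary_mask(dictionary, len, charge)
  m <- max(target[!mask], 0)
  if (m > 0) target[!mask] <- target[!mask] / m
  target[mask] <- -1
  target
}

#' Turn annotated PSMs into model-ready training records
#'
#' @param psms Cleaned, deduplicated PSM tibble (with `psm` column
#'   from [clean_psms()], or plain row indexing).
#' @param assignments Assignment tibble whose `psm` column indexes the
#'   original PSM table.
#' @param dictionary Ion dictionary.
#' @return Tibble of training records: `raw_file`, `scan`, `peptide`,
#'   `charge`, `method`, list-columns `ions` and `intensities` (the
#'   annotated evidence), and `target` (masked, max-scaled vector).
#' @export
vectorize_psms <- function(psms, assignments, dictionary) {
  keys <- if ("psm" %in% names(psms)) psms$psm else seq_len(nrow(psms))
  ann_split <- split(assignments[, c("ion", "intensity")],
                     factor(assignments$psm, levels = keys))
  records <- tibble::tibble(
    raw_file = psms$raw_file, scan = psms$scan, peptide = psms$peptide,
    charge = psms$charge, method = psms$method,
    ions = purrr::map(ann_split, "ion"),
    intensities = purrr::map(ann_split, "intensity")
  )
  records$target <- purrr::pmap(
    list(records$ions, records$intensities, records$peptide,
         records$charge),
    vectorize_ions, dictionary = dictionary
  )
  records
}

#' Deterministic train/validation/test split
#'
#' Records are shuffled under `seed` and partitioned; validation and
#' test sizes are floor allocations and the remainder goes to train,
#' so a 0.8/0.1/0.1 split of 1,000 records yields exactly 800/100/100.
#'
#' @param records Training-record tibble.
#' @param fractions Length-3 numeric summing to 1 (train, validation,
#'   test).
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return `records` with an added `split` factor column.
#' @export
split_dataset <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 17L) {
  stopifnot(length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  n <- nrow(records)
  if (n < 10L) warning("fewer than 10 records; split is degenerate",
                       call. = FALSE)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_val <- floor(n * fractions[2L])
  n_test <- floor(n * fractions[3L])
  split <- rep("train", n)
  if (n_val > 0L) split[perm[seq_len(n_val)]] <- "validation"
  if (n_test > 0L) split[perm[n_val + seq_len(n_test)]] <- "test"
  records$split <- factor(split, levels = c("train", "validation", "test"))
  attr(records, "split_seed") <- as.integer(seed)
  attr(records, "split_fractions") <- fractions
  records
}

#' Write / read a columnar training dataset
#'
#' Datasets are written as Parquet files (train split sharded into
#' 8-12 similar-size files for parallel data loading; validation and
#' test as one file each) with columns `raw_file`, `scan`, `peptide`,
#' `charge`, `method`, `split` and the annotated `ions` /
#' `intensities` list-columns -- sufficient to map any example back to
#' its raw spectrum. The ion dictionary and split provenance are
#' stored in a JSON sidecar (`dataset.json`). Target vectors are
#' rebuilt from the evidence + dictionary on read.
#'
#' @param records Split training-record tibble ([split_dataset()]).
#' @param dir Output directory (created if needed).
#' @param dictionary Ion dictionary used for vectorization.
#' @param n_shards Number of train shards (default 8).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(records, dir, dictionary, n_shards = 8L) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the 'arrow' package is required for Parquet dataset IO",
         call. = FALSE)
  }
  stopifnot(n_shards >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("raw_file", "scan", "peptide", "charge", "method", "split",
            "ions", "intensities")
  records <- tibble::as_tibble(records)[, cols]
  train <- dplyr::filter(records, .data$split == "train")
  shard <- rep(seq_len(n_shards), length.out = nrow(train))
  for (s in seq_len(n_shards)) {
    arrow::write_parquet(train[shard == s, , drop = FALSE],
                         file.path(dir, sprintf("train-%02d.parquet", s)))
  }
  for (part in c("validation", "test")) {
    arrow::write_parquet(dplyr::filter(records, .data$split == part),
                         file.path(dir, paste0(part, ".parquet")))
  }
  jsonlite::write_json(
    list(
      dictionary = as.data.frame(dictionary),
      min_count = attr(dictionary, "min_count"),
      split_seed = attr(records, "split_seed"),
      n_shards = n_shards
    ),
    file.path(dir, "dataset.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_dataset
#' @return `read_dataset()`: list with `records` (targets rebuilt) and
#'   `dictionary`.
#' @export
read_dataset <- function(dir) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the 'arrow' package is required for Parquet dataset IO",
         call. = FALSE)
  }
  sidecar <- jsonlite::read_json(file.path(dir, "dataset.json"),
                                 simplifyVector = TRUE)
  dict <- tibble::as_tibble(sidecar$dictionary)
  dict <- structure(dict, class = c("ion_dictionary", class(dict)),
                    min_count = sidecar$min_count)
  files <- list.files(dir, pattern = "\\.parquet$", full.names = TRUE)
  records <- purrr::map_dfr(sort(files), function(f) {
    x <- tibble::as_tibble(arrow::read_parquet(f))
    required <- c("raw_file", "scan", "peptide", "charge", "method",
                  "ions", "intensities")
    missing <- setdiff(required, names(x))
    if (length(missing) > 0L) {
      stop("dataset file ", basename(f), " is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(x), c(required, "split"))
    if (length(extra) > 0L) {
      warning("ignoring unknown dataset column(s): ",
              paste(extra, collapse = ", "), call. = FALSE)
      x <- x[, c(required, intersect("split", names(x)))]
    }
    x
  })
  records$ions <- purrr::map(records$ions, as.character)
  records$intensities <- purrr::map(records$intensities, as.numeric)
  records$target <- purrr::pmap(
    list(records$ions, records$intensities, records$peptide,
         records$charge),
    vectorize_ions, dictionary = dict
  )
  list(records = records, dictionary = dict)
}
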