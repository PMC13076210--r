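#' Ratio of observed to theoretically possible fragment ions
#'
#' @param n_observed Number of annotated (assigned) fragment ions.
#' @param n_theoretical Number of theoretical ions for the method's
#'   series set (must be > 0).
#' @return `n_observed / n_theoretical`.
#' @export
observed_theoretical_ratio <- function(n_observed, n_theoretical) {
  if (any(n_theoretical <= 0)) {
    stop("theoretical ion set must be non-empty", call. = FALSE)
  }
  n_observed / n_theoretical
}

#' Ratio of predicted-and-observed ions to all predicted ions
#'
#' Restricted to non-masked dictionary entries: an ion counts as
#' predicted when its predicted intensity exceeds `floor` (default 0,
#' i.e. any positive prediction), and as observed when its target
#' intensity is positive.
#'
#' @param target Target vector (`{-1} U [0,1]`).
#' @param prediction Prediction vector over the same dictionary.
#' @param floor Predicted-intensity floor (default 0).
#' @return Ratio in `[0, 1]`, or `NA_real_` when no ion is predicted
#'   above the floor (undefined, flagged rather than zero).
#' @export
predicted_ion_ratio <- function(target, prediction, floor = 0) {
  stopifnot(length(target) == length(prediction))
  valid <- target != -1
  predicted <- valid & prediction > floor
  if (!any(predicted)) return(NA_real_)
  sum(predicted & target > 0) / sum(predicted)
}

#' Intensity-aware rescoring feature table
#'
#' One feature row per training record: spectral angle similarity
#' (1 - masked spectral distance between observed target and
#' prediction), per-spectrum Pearson, the observed/theoretical ion
#' ratio, the predicted-ion ratio, the matched-ion count and the
#' fraction of total spectrum intensity explained by assigned peaks
#' (when spectra are supplied).
#'
#' @param records Vectorized records with `target` list-column and
#'   columns `peptide`, `charge`, `method` (plus `raw_file`, `scan`).
#' @param model Fitted `intensity_model` (or `NULL` to skip
#'   prediction-based features).
#' @param predictions Optional precomputed prediction matrix (rows =
#'   records, columns = dictionary entries); overrides `model`.
#' @param spectra Optional spectra tibble (for the intensity-explained
#'   feature); matched on (`raw_file`, `scan`).
#' @param params [annotation_params()] (for the theoretical ion count
#'   of each method's series set).
#' @param floor Predicted-intensity floor for [predicted_ion_ratio()],
#'   applied after max-scaling each prediction to its base peak
#'   (default 0.05, i.e. an ion counts as predicted when it reaches 5
#'   percent of the predicted base peak — the model is a dense
#'   regressor whose LeakyReLU output is never exactly zero, so a
#'   strictly positive floor is what "predicted" means here).
#' @return `records` (minus the list-columns) with feature columns
#'   `spectral_angle`, `pearson`, `obs_theo_ratio`, `pred_ratio`,
#'   `matched_count`, `intensity_explained`.
#' @export
feature_table <- function(records, model = NULL, spectra = NULL,
                          params = annotation_params(), floor = 0.05,
                          predictions = NULL) {
  n <- nrow(records)
  target <- do.call(rbind, records$target)
  pred <- if (!is.null(predictions)) {
    if (!all(dim(predictions) == dim(target))) {
      stop("predictions do not match record targets", call. = FALSE)
    }
    predictions
  } else if (!is.null(model)) {
    if (model$config$dict_size != ncol(target)) {
      stop("model dictionary does not match record targets",
           call. = FALSE)
    }
    predict_matrix(model, records$peptide, records$charge, records$method)
  }
  len <- vapply(records$peptide,
                function(p) length(peptide_tokens(p)), integer(1))
  n_theo <- vapply(seq_len(n), function(i) {
    length(method_series(records$method[i], params)) *
      min(params$max_ordinal, len[i] - 1L) * length(params$frag_charges)
  }, numeric(1))
  matched <- lengths(records$ions)
  out <- dplyr::select(records, -dplyr::any_of(c("ions", "intensities",
                                                 "target", "prediction")))
  out$matched_count <- as.integer(matched)
  out$obs_theo_ratio <- observed_theoretical_ratio(matched, n_theo)
  if (!is.null(pred)) {
    out$spectral_angle <- 1 - masked_spectral_distance(pred, target,
                                                       reduce = FALSE)
    out$pearson <- pearson_per_spectrum(pred, target)
    out$pred_ratio <- vapply(seq_len(n), function(i) {
      p <- pmax(pred[i, ], 0)
      valid <- target[i, ] != -1
      if (!any(valid)) return(NA_real_)
      top <- max(p[valid])
      if (top > 0) p <- p / top
      predicted_ion_ratio(target[i, ], p, floor = floor)
    }, numeric(1))
  }
  if (!is.null(spectra)) {
    key <- paste(spectra$raw_file, spectra$scan, sep = "\r")
    hit <- match(paste(records$raw_file, records$scan, sep = "\r"), key)
    total <- vapply(hit, function(s) {
      if (is.na(s)) NA_real_ else sum(spectra$peaks[[s]]$intensity)
    }, numeric(1))
    explained <- vapply(seq_len(n), function(i) {
      sum(records$intensities[[i]])
    }, numeric(1))
    out$intensity_explained <- ifelse(total > 0, pmin(explained / total, 1),
                                      NA_real_)
  }
  out
}

#' Target-decoy competition q-values
#'
#' At every score threshold `s` the FDR is estimated conservatively as
#' `(#decoys >= s + 1) / (#targets >= s)`; q-values are the running
#' minimum of that estimate over decreasing score (monotonisation).
#' Tied scores share a q-value.
#'
#' @param scores Numeric PSM scores (higher = better).
#' @param is_decoy Logical decoy indicator.
#' @return Tibble (input order) with columns `score`, `is_decoy`,
#'   `qvalue`.
#' @export
tdc_qvalues <- function(scores, is_decoy) {
  stopifnot(length(scores) == length(is_decoy))
  is_decoy <- as.logical(is_decoy)
  if (!any(!is_decoy)) stop("no target PSMs", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  dec_sorted <- is_decoy[ord]
  n_dec <- cumsum(dec_sorted)
  n_tgt <- cumsum(!dec_sorted)
  fdr <- ifelse(n_tgt > 0, (n_dec + 1) / n_tgt, Inf)
  # tied scores share the estimate of their block's lowest-ranked row
  s_sorted <- scores[ord]
  block <- cumsum(!duplicated(s_sorted))
  fdr <- stats::ave(fdr, block, FUN = function(v) v[length(v)])
  q <- pmin(rev(cummin(rev(fdr))), 1)
  out <- tibble::tibble(score = scores, is_decoy = is_decoy,
                        qvalue = NA_real_)
  out$qvalue[ord] <- q
  out
}

#' Fraction of recoverable true positives at FDR thresholds
#'
#' At each threshold `t`, the estimated number of true positives among
#' accepted PSMs is `targets(q <= t) - decoys(q <= t)`; the
#' denominator is the total estimated true positives,
#' `total targets - total decoys`. Fractions are clipped to `[0, 1]`.
#'
#' @param fdr [tdc_qvalues()] result.
#' @param fdr_grid Thresholds in `(0, 1]`.
#' @return Tibble with columns `fdr` and `recovered`; `recovered` is
#'   `NA` when the denominator is not positive.
#' @export
recovered_tp_fraction <- function(fdr, fdr_grid = c(1e-4, 1e-3, 0.01, 0.05, 0.1, 1)) {
  stopifnot(all(fdr_grid > 0), all(fdr_grid <= 1))
  denom <- sum(!fdr$is_decoy) - sum(fdr$is_decoy)
  rec <- vapply(fdr_grid, function(t) {
    if (denom <= 0) return(NA_real_)
    acc <- fdr$qvalue <= t
    min(1, max(0, (sum(acc & !fdr$is_decoy) - sum(acc & fdr$is_decoy)) /
                 denom))
  }, numeric(1))
  tibble::tibble(fdr = fdr_grid, recovered = rec)
}

#' Identification efficiency
#'
#' The ratio of confidently identified PSMs to acquired MS2 scans,
#' expressed as a percentage.
#'
#' @param n_confident_psms Number of PSMs passing the FDR filter.
#' @param n_ms2_scans Number of acquired MS2 scans (> 0).
#' @return Percentage (`100 * n_confident_psms / n_ms2_scans`).
#' @export
identification_efficiency <- function(n_confident_psms, n_ms2_scans) {
  if (any(n_ms2_scans <= 0)) stop("n_ms2_scans must be > 0", call. = FALSE)
  100 * n_confident_psms / n_ms2_scans
}

#' Shared / gained / lost PSMs between two scorings
#'
#' Partitions the target PSMs passing either scoring at the FDR
#' threshold into those passing both (`shared`), only the rescored
#' run (`gained`) and only the base run (`lost`).
#'
#' @param base,rescored [tdc_qvalues()]-style tibbles over the same
#'   PSM universe (same row order), each with `is_decoy` and `qvalue`.
#' @param ids PSM identifiers (default row indices).
#' @param fdr_threshold q-value cut-off (default 0.01).
#' @return List of `shared`, `gained`, `lost` id vectors.
#' @export
gain_loss_quadrants <- function(base, rescored, ids = NULL,
                                fdr_threshold = 0.01) {
  if (nrow(base) != nrow(rescored) ||
      !identical(base$is_decoy, rescored$is_decoy)) {
    stop("base and rescored results must cover the same PSM universe",
         call. = FALSE)
  }
  if (is.null(ids)) ids <- seq_len(nrow(base))
  tgt <- !base$is_decoy
  pass_base <- tgt & base$qvalue <= fdr_threshold
  pass_new <- tgt & rescored$qvalue <= fdr_threshold
  list(
    shared = ids[pass_base & pass_new],
    gained = ids[!pass_base & pass_new],
    lost = ids[pass_base & !pass_new]
  )
}

#' Combine rescoring features into a single score
#'
#' Fits a logistic regression of target-vs-decoy status on the feature
#' columns using a held-out calibration split, then scores every PSM
#' with the fitted linear predictor. This stands in for the SVM-based
#' rescorers used downstream of intensity prediction in production
#' pipelines: the contract is only that a feature-aware combined score
#' separates targets from decoys at least as well as the base score.
#'
#' @param features Feature tibble (from [feature_table()]) with an
#'   `is_decoy` column.
#' @param feature_cols Feature columns to combine.
#' @param calibration_fraction Fraction of PSMs used to fit the
#'   combination (default 0.5); the calibration subset is drawn with
#'   `seed`.
#' @param seed RNG seed for the calibration split.
#' @return List of class `rescore_model`: `model` (the glm fit),
#'   `feature_cols`, and `scores` (combined score per input row).
#' @export
fit_rescore_model <- function(features,
                              feature_cols = c("spectral_angle", "pearson",
                                               "pred_ratio",
                                               "obs_theo_ratio",
                                               "matched_count"),
                              calibration_fraction = 0.5, seed = 1L) {
  feature_cols <- intersect(feature_cols, names(features))
  stopifnot(length(feature_cols) > 0L, "is_decoy" %in% names(features))
  dat <- features[, c(feature_cols, "is_decoy")]
  dat$label <- as.numeric(!dat$is_decoy)
  # NA features (undefined ratios) carry no evidence: impute 0
  for (col in feature_cols) {
    dat[[col]][!is.finite(dat[[col]])] <- 0
  }
  n <- nrow(dat)
  calib <- withr::with_seed(as.integer(seed), {
    sample.int(n, size = max(2L, floor(n * calibration_fraction)))
  })
  fml <- stats::as.formula(paste("label ~",
                                 paste(feature_cols, collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, data = dat[calib, , drop = FALSE],
               family = stats::binomial())
  )
  scores <- as.numeric(stats::predict(fit, newdata = dat, type = "link"))
  structure(
    list(model = fit, feature_cols = feature_cols, calibration = calib,
         scores = scores),
    class = "rescore_model"
  )
}

#' Tidy the coefficients of a rescoring combination
#' @param x `rescore_model` object.
#' @param ... Unused.
#' @return Tibble of terms and coefficients.
#' @export
tidy.rescore_model <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1L],
                 std_error = cf[, 2L], statistic = cf[, 3L],
                 p_value = cf[, 4L])
}

#' Write a Percolator-style feature file
#'
#' Tab-separated "pin"-like layout: id, label (+1 target / -1 decoy),
#' scan number, feature columns, peptide.
#'
#' @param features Feature tibble with `raw_file`, `scan`, `peptide`,
#'   `is_decoy` and feature columns.
#' @param path Output path.
#' @param feature_cols Feature columns to include.
#' @export
write_pin <- function(features, path,
                      feature_cols = c("spectral_angle", "pearson",
                                       "pred_ratio", "obs_theo_ratio",
                                       "matched_count",
                                       "intensity_explained")) {
  feature_cols <- intersect(feature_cols, names(features))
  pin <- tibble::tibble(
    SpecId = paste(features$raw_file, features$scan, features$peptide,
                   sep = "."),
    Label = ifelse(features$is_decoy, -1L, 1L),
    ScanNr = features$scan
  )
  pin <- dplyr::bind_cols(pin, features[, feature_cols])
  pin$Peptide <- features$peptide
  readr::write_tsv(pin, path, progress = FALSE)
  invisible(path)
}
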