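#' In-silico protease digestion
#'
#' Cleavage rules: trypsin cuts C-terminal to K/R except before P;
#' LysC C-terminal to K; LysN N-terminal to K; GluC C-terminal to
#' E/D; chymotrypsin C-terminal to F/W/Y/L except before P. Peptides
#' with up to `missed_cleavages` internal sites are also emitted, in
#' deterministic N-to-C order.
#'
#' @param sequence Protein sequence (plain upper-case letters).
#' @param enzyme One of `"trypsin"`, `"LysC"`, `"LysN"`, `"GluC"`,
#'   `"chymotrypsin"`.
#' @param missed_cleavages Maximum number of missed cleavage sites.
#' @return Tibble with columns `peptide`, `start`, `end`,
#'   `n_missed`.
#' @examples
#' digest("TESTKAAA", "trypsin")
#' @export
digest <- function(sequence, enzyme, missed_cleavages = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  aa <- strsplit(sequence, "")[[1]]
  if (!all(aa %in% names(.RESIDUES))) {
    stop("invalid residue letter(s) in protein sequence", call. = FALSE)
  }
  n <- length(aa)
  cut_after <- switch(
    enzyme,
    trypsin = which(aa %in% c("K", "R") &
                      c(aa[-1], "") != "P" & seq_len(n) < n),
    LysC = which(aa == "K" & seq_len(n) < n),
    LysN = which(c(aa[-1], "") == "K" & seq_len(n) < n),
    GluC = which(aa %in% c("E", "D") & seq_len(n) < n),
    chymotrypsin = which(aa %in% c("F", "W", "Y", "L") &
                           c(aa[-1], "") != "P" & seq_len(n) < n),
    stop("unknown enzyme: ", enzyme, call. = FALSE)
  )
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  n_seg <- length(starts)
  purrr::map_dfr(seq_len(n_seg), function(i) {
    j_max <- min(n_seg, i + missed_cleavages)
    purrr::map_dfr(i:j_max, function(j) {
      tibble::tibble(
        peptide = paste(aa[starts[i]:ends[j]], collapse = ""),
        start = starts[i], end = ends[j], n_missed = j - i
      )
    })
  })
}

#' Fragmentation-method simulation profile
#'
#' Describes how the simulator fragments peptides under one method:
#' ion-series propensity weights (summing to 1 over the method's
#' series), a positional intensity shape, fragment-charge shares, a
#' charge-dependence factor (ECD spectra of 2+ precursors are
#' attenuated relative to 3+/4+), detection probability, and the
#' noise model (multiplicative log-normal sigma plus additive
#' uniform-m/z noise peaks). The default weights qualitatively mirror
#' the observed per-method ion-series proportions; they are simulator
#' knobs, not measured values.
#'
#' @param method Fragmentation method.
#' @param series_weights Named numeric propensities (default per
#'   method).
#' @param charge_attenuation Multiplier applied to fragment
#'   intensities (relative to noise) for 2+ precursors (ECD default
#'   0.35; 1 for other methods).
#' @param noise_sigma Log-normal sd of the peptide-specific
#'   fragmentation pattern amplitudes.
#' @param replicate_sigma Log-normal sd of the per-scan multiplicative
#'   jitter between replicate spectra of the same precursor.
#' @param n_noise_peaks Number of additive random noise peaks.
#' @param noise_level Mean relative intensity of noise peaks.
#' @param detect_prob Marginal detection rate (over random sequences)
#'   of singly charged fragments of the highest-propensity series;
#'   lower-propensity series and higher fragment charges scale down
#'   proportionally.
#' @param site_sigma Log-scale spread of the sequence-dependent
#'   cleavage propensity across backbone sites.
#' @return List of class `method_profile`.
#' @export
method_profile <- function(method,
                           series_weights = default_series_weights(method),
                           charge_attenuation = if (method == "ECD") 0.35 else 1,
                           noise_sigma = 0.3, replicate_sigma = 0.1,
                           n_noise_peaks = 30L, noise_level = 0.02,
                           detect_prob = 0.9, site_sigma = 1) {
  stopifnot(all(series_weights >= 0), abs(sum(series_weights) - 1) < 1e-6)
  structure(
    list(method = method, series_weights = series_weights,
         charge_attenuation = charge_attenuation,
         noise_sigma = noise_sigma, replicate_sigma = replicate_sigma,
         n_noise_peaks = as.integer(n_noise_peaks),
         noise_level = noise_level, detect_prob = detect_prob,
         site_sigma = site_sigma),
    class = "method_profile"
  )
}

# fixed residue-level cleavage-propensity tables: the backbone-bond
# cleavability between residues j and j+1 is exp(sigma * (N[res_j] +
# C[res_j+1]) / sqrt(2)). These stand in for the sequence-dependent
# fragmentation chemistry (e.g. enhanced/suppressed cleavage next to
# particular residues) that intensity predictors learn from data; the
# values are arbitrary fixed constants of the simulator.
.SITE_N <- c(
  G = 0.317, A = 1.027, S = -0.590, P = 1.155, V = -0.635, T = 0.167,
  C = -1.527, L = -2.382, I = 0.103, N = 0.917, D = -0.215, Q = -1.090,
  K = 1.450, E = -0.569, M = -0.591, H = 0.368, F = 0.146, R = -0.969,
  Y = -2.902, W = -0.578, `C(cam)` = 3.020, `M(ox)` = -0.518
)
.SITE_C <- c(
  G = 1.108, A = 0.804, S = 0.772, P = 0.223, V = 0.489, T = -0.086,
  C = -0.005, L = -0.203, I = -0.429, N = 2.036, D = -0.318, Q = 1.637,
  K = -0.029, E = 1.084, M = 2.908, H = 0.307, F = 0.104, R = 1.622,
  Y = 0.419, W = 0.500, `C(cam)` = -0.798, `M(ox)` = 0.284
)

# deterministic 31-bit seed from a precursor identity string
pattern_hash <- function(peptide, charge, method, base = 0L) {
  s <- paste(peptide, charge, method, sep = "|")
  h <- as.double(base) %% 2147483647
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' @rdname method_profile
#' @export
default_series_weights <- function(method) {
  switch(
    method,
    HCD = c(y = 0.50, b = 0.33, a = 0.12, `a+1` = 0.05),
    ECD = c(c = 0.40, z = 0.40, `z+1` = 0.08, y = 0.08, b = 0.04),
    EID = c(y = 0.28, b = 0.22, a = 0.08, `a+1` = 0.07, c = 0.08,
            z = 0.08, x = 0.05, `x+1` = 0.05, `c-1` = 0.04,
            `z+1` = 0.05),
    UVPD = c(y = 0.30, b = 0.24, a = 0.10, `a+1` = 0.06, c = 0.07,
             z = 0.07, x = 0.06, `x+1` = 0.04, `c-1` = 0.03,
             `z+1` = 0.03),
    ETciD = c(c = 0.30, z = 0.22, y = 0.22, b = 0.18, `z+1` = 0.08),
    stop("unknown fragmentation method: ", method, call. = FALSE)
  )
}

#' Simulate one MS2 spectrum with known ground truth
#'
#' Fragmentation is modelled as deterministic sequence chemistry plus
#' measurement noise. Which fragments appear is decided by comparing
#' each backbone site's cleavage propensity — a fixed function of the
#' flanking residue pair — against a per-(series, fragment charge)
#' threshold calibrated so that the marginal detection rate over
#' random sequences is `detect_prob * w_s / max(w)` times a
#' fragment-charge fraction; the expected count proportion per series
#' therefore equals its propensity weight, while the realised fragment
#' set of a given precursor is fully determined by its sequence (and
#' hence learnable). Base amplitudes are positional shape x
#' fragment-charge share x a log-normal draw from an RNG seeded by
#' (peptide, charge, method), so replicate spectra of the same
#' precursor share the same pattern, as on a real instrument. The
#' per-scan RNG (`seed`) adds multiplicative replicate jitter,
#' precursor isotope peaks and uniform-m/z noise peaks. Peaks sit at
#' the exact theoretical m/z and the base peak is scaled to 1. The
#' ground-truth fragment map is returned alongside.
#'
#' @param peptide Peptide string (token grammar, 2-30 residues).
#' @param charge Precursor charge.
#' @param method Fragmentation method.
#' @param profile [method_profile()] for the method.
#' @param seed Integer seed for the scan-level noise; the same seed
#'   (with the same `pattern_seed`) reproduces the spectrum bit for
#'   bit.
#' @param pattern_seed Base seed mixed into the peptide-specific
#'   pattern hash (defaults to `seed`; a corpus generator passes one
#'   constant so replicates share patterns).
#' @param params [annotation_params()] (supplies the series set used
#'   for the theoretical enumeration; fragment charges are capped at
#'   the precursor charge).
#' @return List with `spectrum` (tibble `mz`, `intensity`) and
#'   `truth` (tibble `ion`, `series`, `ordinal`, `charge`, `mz`,
#'   `intensity` of the detected true fragments).
#' @export
simulate_spectrum <- function(peptide, charge, method,
                              profile = method_profile(method),
                              seed = 1L, pattern_seed = seed,
                              params = annotation_params()) {
  tokens <- peptide_tokens(peptide)
  stopifnot(length(tokens) >= 2L, length(tokens) <= 30L)
  series <- names(profile$series_weights)
  frag_charges <- seq_len(min(max(params$frag_charges), charge))
  theo <- theoretical_ions(peptide, series = series,
                           charges = frag_charges)
  len <- length(tokens)
  # which fragments exist is deterministic sequence chemistry: the
  # cleavability of site j (between residues j and j+1) is compared
  # with a per-(series, fragment charge) threshold calibrated so the
  # marginal detection rate over random sequences is
  # detect_prob * w_s / max(w) * charge fraction
  sigma <- profile$site_sigma
  lambda <- exp(sigma * (.SITE_N[tokens[-len]] + .SITE_C[tokens[-1L]]) /
                  sqrt(2))
  site <- ifelse(theo$series %in% c("a", "a+1", "b", "c-1", "c"),
                 theo$ordinal, len - theo$ordinal)
  w <- profile$series_weights[theo$series]
  zfrac <- c(1, 0.30, 0.08)[theo$charge]
  q <- pmin(profile$detect_prob * w / max(profile$series_weights) * zfrac,
            1 - 1e-12)
  tau <- stats::qlnorm(1 - q, 0, sigma)
  detected_pat <- lambda[site] > tau
  # peptide-specific amplitude pattern (reproducible across replicates)
  base_amp <- withr::with_seed(
    pattern_hash(peptide, charge, method, as.integer(pattern_seed)), {
      shape <- sin(pi * theo$ordinal / len)^0.5
      zshare <- c(0.70, 0.25, 0.05)[theo$charge]
      shape * zshare * stats::rlnorm(nrow(theo), 0, profile$noise_sigma)
    })
  pat <- list(base = base_amp, detected = detected_pat)
  withr::with_seed(as.integer(seed), {
    atten <- if (charge <= 2L) profile$charge_attenuation else 1
    intensity <- atten * pat$base *
      stats::rlnorm(nrow(theo), 0, profile$replicate_sigma)
    keep <- pat$detected & intensity > 0
    truth <- theo[keep, ]
    truth$intensity <- intensity[keep]

    precursor_mz <- ion_mz(peptide_mass(peptide), charge)
    iso <- precursor_isotope_mzs(precursor_mz, charge, params$n_isotope_peaks)
    iso_int <- 0.2 * stats::rlnorm(nrow(iso), 0, profile$noise_sigma) *
      0.5^iso$k
    mz_range <- range(c(truth$mz, precursor_mz, 100))
    noise <- tibble::tibble(
      mz = stats::runif(profile$n_noise_peaks, mz_range[1L],
                        mz_range[2L] + 50),
      intensity = stats::rexp(profile$n_noise_peaks,
                              1 / profile$noise_level)
    )
    spectrum <- dplyr::bind_rows(
      truth[, c("mz", "intensity")],
      tibble::tibble(mz = iso$mz, intensity = iso_int),
      noise
    ) |>
      dplyr::arrange(mz)
    if (nrow(spectrum) > 0L && max(spectrum$intensity) > 0) {
      top <- max(spectrum$intensity)
      spectrum$intensity <- spectrum$intensity / top
      truth$intensity <- truth$intensity / top
    }
    list(spectrum = spectrum,
         truth = truth[, c("ion", "series", "ordinal", "charge", "mz",
                           "intensity")])
  })
}

#' Corpus generation configuration
#'
#' @param n_proteins Number of random proteins.
#' @param protein_length Min/max protein length (uniform).
#' @param enzymes Protease(s) used for digestion.
#' @param missed_cleavages Maximum missed cleavages.
#' @param peptide_length Peptide length bounds retained after
#'   digestion (default 7-30).
#' @param charge_probs Named numeric vector of precursor-charge
#'   probabilities.
#' @param methods Fragmentation methods simulated.
#' @param n_psms_per_method Target PSMs generated per method (each
#'   paired with one decoy PSM).
#' @param oxidation_prob Probability that a Met residue is oxidised.
#' @param profiles Named list of [method_profile()] overrides.
#' @param seed Master seed; the whole corpus is bit-reproducible
#'   given the config.
#' @return List of class `corpus_config`.
#' @export
corpus_config <- function(n_proteins = 25L, protein_length = c(120L, 400L),
                          enzymes = "trypsin", missed_cleavages = 0L,
                          peptide_length = c(7L, 30L),
                          charge_probs = c(`2` = 0.5, `3` = 0.35, `4` = 0.15),
                          methods = fragmentation_methods(),
                          n_psms_per_method = 100L,
                          oxidation_prob = 0.1,
                          profiles = NULL, seed = 42L) {
  structure(
    list(n_proteins = as.integer(n_proteins),
         protein_length = as.integer(protein_length),
         enzymes = enzymes,
         missed_cleavages = as.integer(missed_cleavages),
         peptide_length = as.integer(peptide_length),
         charge_probs = charge_probs, methods = methods,
         n_psms_per_method = as.integer(n_psms_per_method),
         oxidation_prob = oxidation_prob,
         profiles = profiles, seed = as.integer(seed)),
    class = "corpus_config"
  )
}

# reversed-sequence decoy keeping the C-terminal residue in place
# (preserves the tryptic K/R anchor)
decoy_peptide <- function(peptide) {
  tokens <- peptide_tokens(peptide)
  n <- length(tokens)
  if (n <= 2L) return(paste(rev(tokens), collapse = ""))
  paste(c(rev(tokens[seq_len(n - 1L)]), tokens[n]), collapse = "")
}

#' Generate a complete synthetic corpus
#'
#' Random proteins are digested, peptides sampled, and one spectrum
#' simulated per (peptide, method) draw. Each spectrum is matched by
#' a target PSM (the true peptide) and a decoy PSM (reversed sequence
#' with the C-terminal residue kept in place). The synthetic
#' hyperscore is a monotone function of the fraction of the peptide's
#' theoretical ions found in the spectrum, plus noise; it makes no
#' claim of search-engine equivalence.
#'
#' @param config [corpus_config()].
#' @param params [annotation_params()] used for decoy matching.
#' @return List with `spectra` (tibble incl. `peaks` list-column),
#'   `psms` (target + decoy PSM table), `truth` (per-spectrum true
#'   fragment tables) and `config`.
#' @export
generate_corpus <- function(config = corpus_config(),
                            params = annotation_params()) {
  withr::with_seed(config$seed, {
    aa_pool <- names(.RESIDUES)
    # roughly uniform composition with common residues upweighted
    aa_w <- c(G = 7, A = 8, S = 7, P = 5, V = 7, T = 5, C = 2, L = 9,
              I = 6, N = 4, D = 5, Q = 4, K = 6, E = 7, M = 2, H = 2,
              F = 4, R = 5, Y = 3, W = 1)[aa_pool]
    proteins <- purrr::map_chr(seq_len(config$n_proteins), function(i) {
      len <- sample(config$protein_length[1L]:config$protein_length[2L], 1L)
      paste(sample(aa_pool, len, replace = TRUE, prob = aa_w),
            collapse = "")
    })
    peptides <- purrr::map_dfr(config$enzymes, function(enz) {
      purrr::map_dfr(proteins, digest, enzyme = enz,
                     missed_cleavages = config$missed_cleavages)
    }) |>
      dplyr::filter(nchar(.data$peptide) >= config$peptide_length[1L],
                    nchar(.data$peptide) <= config$peptide_length[2L]) |>
      dplyr::distinct(.data$peptide)
    if (nrow(peptides) == 0L) stop("no peptides after digestion",
                                   call. = FALSE)
    # apply fixed carbamidomethyl-C and random Met oxidation tokens
    modify <- function(p) {
      tok <- strsplit(p, "")[[1]]
      tok[tok == "C"] <- "C(cam)"
      ox <- tok == "M" & stats::runif(length(tok)) < config$oxidation_prob
      tok[ox] <- "M(ox)"
      paste(tok, collapse = "")
    }

    spectra <- list()
    psms <- list()
    truths <- list()
    scan <- 0L
    for (method in config$methods) {
      profile <- config$profiles[[method]]
      if (is.null(profile)) profile <- method_profile(method)
      raw_file <- paste0("sim_", method, ".mgf")
      draw <- sample.int(nrow(peptides), config$n_psms_per_method,
                         replace = config$n_psms_per_method > nrow(peptides))
      for (i in seq_len(config$n_psms_per_method)) {
        scan <- scan + 1L
        pep <- modify(peptides$peptide[draw[i]])
        charge <- as.integer(sample(names(config$charge_probs), 1L,
                                    prob = config$charge_probs))
        sim <- simulate_spectrum(pep, charge, method, profile,
                                 seed = config$seed + scan,
                                 pattern_seed = config$seed,
                                 params = params)
        precursor_mz <- ion_mz(peptide_mass(pep), charge)
        spectra[[scan]] <- tibble::tibble(
          raw_file = raw_file, scan = scan,
          title = sprintf("%s scan=%d", raw_file, scan),
          precursor_mz = precursor_mz, precursor_charge = charge,
          rt = 60 * scan / config$n_psms_per_method,
          peaks = list(sim$spectrum)
        )
        truths[[scan]] <- dplyr::mutate(sim$truth, raw_file = raw_file,
                                        scan = scan, .before = 1L)
        # matched-ion fractions for the hyperscore surrogate
        n_theo <- length(method_series(method, params)) *
          min(params$max_ordinal,
              length(peptide_tokens(pep)) - 1L) *
          length(params$frag_charges)
        f_target <- nrow(sim$truth) / n_theo
        dec <- decoy_peptide(pep)
        dec_ann <- annotate_spectrum(sim$spectrum, dec, precursor_mz,
                                     charge, method, params)
        f_decoy <- sum(dec_ann$status == "assigned") / n_theo
        psms[[scan]] <- tibble::tibble(
          raw_file = raw_file, scan = scan,
          peptide = c(pep, dec),
          modifications = "",
          charge = charge, method = method,
          hyperscore = pmax(0, 30 * c(f_target, f_decoy) +
                              stats::rnorm(2L, 0, 1.5)),
          is_decoy = c(FALSE, TRUE)
        )
      }
    }
    list(
      spectra = dplyr::bind_rows(spectra),
      psms = dplyr::bind_rows(psms),
      truth = dplyr::bind_rows(truths),
      config = config
    )
  })
}

#' Write a corpus to disk (MGF + TSV)
#'
#' One MGF per raw file, plus `psms.tsv` and `truth.tsv`,
#' cross-referenced by (`raw_file`, `scan`).
#'
#' @param corpus [generate_corpus()] result.
#' @param dir Output directory.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rf in unique(corpus$spectra$raw_file)) {
    write_mgf(dplyr::filter(corpus$spectra, .data$raw_file == rf),
              file.path(dir, rf))
  }
  write_psms(corpus$psms, file.path(dir, "psms.tsv"))
  readr::write_tsv(corpus$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
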