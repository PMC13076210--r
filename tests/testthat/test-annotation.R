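make_peaks <- function(mz, intensity = rep(1, length(mz))) {
  tibble::tibble(mz = mz, intensity = intensity)
}

test_that("empty peak lists annotate to an empty valid result", {
  ann <- annotate_spectrum(make_peaks(numeric(0)), "PEPTIDEK",
                           precursor_mz = 450, precursor_charge = 2,
                           method = "HCD")
  expect_equal(nrow(ann), 0)
})

test_that("peaks at exact theoretical positions annotate at 0 ppm", {
  p <- "PEPTIDEK"
  b2 <- ion_mz(fragment_mass(p, "b", 2), 1)
  y3 <- ion_mz(fragment_mass(p, "y", 3), 1)
  ann <- annotate_spectrum(make_peaks(c(b2, y3)), p,
                           precursor_mz = ion_mz(peptide_mass(p), 2),
                           precursor_charge = 2, method = "HCD")
  assigned <- ann[ann$status == "assigned", ]
  expect_setequal(assigned$ion, c("b:2:1", "y:3:1"))
  expect_equal(assigned$ppm, c(0, 0), tolerance = 1e-9)
})

test_that("the precursor window excludes peaks by full-width arithmetic", {
  p <- "PEPTIDEK"
  pre <- ion_mz(peptide_mass(p), 2)
  ann <- annotate_spectrum(make_peaks(c(pre + 1.0, pre + 1.3)), p,
                           precursor_mz = pre, precursor_charge = 2,
                           method = "HCD")
  expect_equal(ann$status[ann$mz == pre + 1.0], "precursor_window")
  expect_true(ann$status[ann$mz == pre + 1.3] != "precursor_window")
})

test_that("precursor isotope peaks are flagged and never assigned", {
  p <- "LNDAEKPTR"
  pre <- ion_mz(peptide_mass(p), 2)
  iso <- precursor_isotope_mzs(pre, 2)
  far_iso <- iso$mz[abs(iso$mz - pre) > 1.2]
  ann <- annotate_spectrum(make_peaks(far_iso), p, pre, 2, "EID")
  expect_true(all(ann$status %in% c("precursor_isotope", "unassigned")))
  expect_true(any(ann$status == "precursor_isotope"))
})

test_that("clash resolution is greedy by ppm with fixed tie priority", {
  cand <- tibble::tibble(
    peak = c(1, 1), series = c("b", "y"), ordinal = c(2, 5),
    charge = c(1, 1), ppm = c(5, 1), intensity = c(10, 1)
  )
  expect_identical(resolve_clashes(cand)$series, "y")
  # identical ppm: series priority decides (y beats a+1)
  cand2 <- tibble::tibble(
    peak = c(1, 1), series = c("a+1", "y"), ordinal = c(3, 3),
    charge = c(1, 1), ppm = c(2, 2), intensity = c(1, 1)
  )
  expect_identical(resolve_clashes(cand2)$series, "y")
  # one ion matching two peaks goes to the nearer; the other peak
  # stays free for other ions
  cand3 <- tibble::tibble(
    peak = c(1, 2, 1), series = c("b", "b", "z"), ordinal = c(4, 4, 2),
    charge = c(1, 1, 1), ppm = c(3, -1, 4), intensity = c(1, 1, 1)
  )
  got <- resolve_clashes(cand3)
  expect_equal(got$peak[got$series == "b"], 2)
  expect_equal(got$peak[got$series == "z"], 1)
  expect_equal(nrow(got), 2)
  # under the intensity rule the most intense peak wins instead
  cand4 <- tibble::tibble(
    peak = c(1, 2), series = c("b", "b"), ordinal = c(4, 4),
    charge = c(1, 1), ppm = c(1, 8), intensity = c(1, 100)
  )
  expect_equal(resolve_clashes(cand4, peak_rule = "intense")$peak, 2)
})

test_that("annotation agrees with the brute-force reference matcher", {
  corpus <- small_corpus()
  psms <- corpus$psms[!corpus$psms$is_decoy, ][1:20, ]
  key <- paste(corpus$spectra$raw_file, corpus$spectra$scan)
  for (i in seq_len(nrow(psms))) {
    s <- match(paste(psms$raw_file[i], psms$scan[i]), key)
    sp <- corpus$spectra[s, ]
    fast <- annotate_spectrum(sp$peaks[[1]], psms$peptide[i],
                              sp$precursor_mz, sp$precursor_charge,
                              psms$method[i])
    slow <- brute_annotate(sp$peaks[[1]], psms$peptide[i],
                           sp$precursor_mz, sp$precursor_charge,
                           psms$method[i])
    expect_identical(fast$status, slow$status)
    expect_identical(fast$ion, slow$ion)
  }
})

test_that("assignments respect tolerance and stay outside the window", {
  pipe <- small_pipeline()
  corpus <- pipe$corpus
  ann <- pipe$ann
  expect_true(all(abs(ann$ppm) <= 10))
  key <- paste(corpus$spectra$raw_file, corpus$spectra$scan)
  pre <- corpus$spectra$precursor_mz[match(paste(ann$raw_file, ann$scan),
                                           key)]
  expect_true(all(abs(ann$mz - pre) > 1.2))
})

test_that("annotation is invariant to input peak order", {
  p <- "ELVISLIVESK"
  sim <- simulate_spectrum(p, 3, "EID", seed = 4)
  pre <- ion_mz(peptide_mass(p), 3)
  shuffled <- sim$spectrum[sample(nrow(sim$spectrum)), ]
  a1 <- annotate_spectrum(sim$spectrum, p, pre, 3, "EID")
  a2 <- annotate_spectrum(shuffled, p, pre, 3, "EID")
  expect_identical(a1, a2)
})

test_that("tightening the tolerance never gains assignments", {
  p <- "ELVISLIVESK"
  sim <- simulate_spectrum(p, 3, "UVPD", seed = 6)
  pre <- ion_mz(peptide_mass(p), 3)
  counts <- vapply(c(20, 10, 5, 2, 0.5), function(tol) {
    ann <- annotate_spectrum(sim$spectrum, p, pre, 3, "UVPD",
                             annotation_params(tol_ppm = tol))
    sum(ann$status == "assigned")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("unknown methods are rejected", {
  expect_error(
    annotate_spectrum(make_peaks(100), "PEPTIDEK", 450, 2, "SID"),
    "unknown fragmentation method"
  )
})

test_that("series proportions average per-spectrum count fractions", {
  one <- tibble::tibble(psm = 1, method = "HCD", series = c("y", "y"))
  p1 <- annotation_proportions(one, series = c("y", "b"))
  expect_equal(p1$proportion[p1$series == "y"], 1)
  expect_equal(p1$proportion[p1$series == "b"], 0)
  two <- tibble::tibble(
    psm = c(1, 2, 2), method = "HCD", series = c("y", "y", "b")
  )
  p2 <- annotation_proportions(two, series = c("y", "b"))
  expect_equal(p2$proportion[p2$series == "y"], 0.75)
  expect_equal(p2$proportion[p2$series == "b"], 0.25)
  # row sums are 1 per method on real annotations
  pipe <- small_pipeline()
  props <- annotation_proportions(pipe$ann)
  sums <- as.numeric(tapply(props$proportion, props$method, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
})

test_that("a+1/a ratio handles present and absent denominators", {
  df <- tibble::tibble(series = c("a", "a+1"), intensity = c(100, 50))
  expect_equal(a1_over_a_ratio(df), 0.5)
  df2 <- tibble::tibble(series = "y", intensity = 10)
  expect_true(is.na(a1_over_a_ratio(df2)))
})
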