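# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (hand-summed mass tables, quadratic
# matchers, explicit threshold sweeps) so that agreement is evidence,
# not tautology.

# independently transcribed residue monoisotopic masses (Da)
ORACLE_RESIDUES <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
  C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
  H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
  M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)
ORACLE_H2O <- 18.0105646
ORACLE_PROTON <- 1.0072765

oracle_peptide_mass <- function(seq) {
  sum(ORACLE_RESIDUES[strsplit(seq, "")[[1]]]) + ORACLE_H2O
}

# quadratic reference matcher implementing the annotation rules
# directly: window exclusion, isotope flagging, then a global greedy
# selection over the full candidate list
brute_annotate <- function(peaks, peptide, precursor_mz, precursor_charge,
                           method, params = annotation_params()) {
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  n <- nrow(peaks)
  status <- rep("unassigned", n)
  ion <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (abs(peaks$mz[i] - precursor_mz) <= params$precursor_window_da / 2) {
      status[i] <- "precursor_window"
    }
  }
  iso <- precursor_isotope_mzs(precursor_mz, precursor_charge,
                               params$n_isotope_peaks)
  for (i in seq_len(n)) {
    if (status[i] != "unassigned") next
    for (j in seq_len(nrow(iso))) {
      if (abs(peaks$mz[i] - iso$mz[j]) / iso$mz[j] * 1e6 <= params$tol_ppm) {
        status[i] <- "precursor_isotope"
        break
      }
    }
  }
  theo <- theoretical_ions(peptide, series = method_series(method, params),
                           max_ordinal = params$max_ordinal,
                           charges = params$frag_charges)
  cand <- list()
  for (i in seq_len(n)) {
    if (status[i] != "unassigned") next
    for (j in seq_len(nrow(theo))) {
      ppm <- (peaks$mz[i] - theo$mz[j]) / theo$mz[j] * 1e6
      if (abs(ppm) <= params$tol_ppm) {
        cand[[length(cand) + 1L]] <- data.frame(
          peak = i, j = j, ppm = ppm,
          prio = match(theo$series[j],
                       c("y", "b", "c", "z", "a", "x", "z+1", "a+1",
                         "c-1", "x+1")),
          charge = theo$charge[j], ordinal = theo$ordinal[j]
        )
      }
    }
  }
  assigned <- data.frame()
  if (length(cand) > 0L) {
    cand <- do.call(rbind, cand)
    repeat {
      if (nrow(cand) == 0L) break
      ord <- order(abs(cand$ppm), cand$prio, cand$charge, cand$ordinal,
                   cand$peak)
      best <- cand[ord[1L], ]
      assigned <- rbind(assigned, best)
      status[best$peak] <- "assigned"
      ion[best$peak] <- theo$ion[best$j]
      cand <- cand[cand$peak != best$peak & cand$j != best$j, , drop = FALSE]
    }
  }
  data.frame(peak = seq_len(n), mz = peaks$mz, status = status, ion = ion,
             stringsAsFactors = FALSE)
}

# explicit threshold sweep for target-decoy q-values:
# q(s) = min over accepting thresholds t <= s of (D(t)+1)/T(t)
brute_tdc <- function(scores, is_decoy) {
  thresholds <- sort(unique(scores))
  fdr_at <- vapply(thresholds, function(t) {
    d <- sum(is_decoy & scores >= t)
    tg <- sum(!is_decoy & scores >= t)
    if (tg == 0) Inf else (d + 1) / tg
  }, numeric(1))
  vapply(scores, function(s) {
    min(1, min(fdr_at[thresholds <= s]))
  }, numeric(1))
}
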