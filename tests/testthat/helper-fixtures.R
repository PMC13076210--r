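# Shared fixtures, built once per session and cached. Sizes here are
# the desk-scale study conditions described in the methods vignette.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small two-method corpus for unit tests
small_corpus <- function() {
  fixture("small_corpus", function() {
    generate_corpus(corpus_config(
      n_proteins = 15L, n_psms_per_method = 25L,
      methods = c("HCD", "ECD"), seed = 101L
    ))
  })
}

small_pipeline <- function() {
  fixture("small_pipeline", function() {
    corpus <- small_corpus()
    ann <- annotate_psms(corpus$spectra, corpus$psms)
    clean <- suppressMessages(clean_psms(corpus$psms, ann))
    uniq <- deduplicate_psms(clean)
    dict <- build_ion_dictionary(ann[ann$psm %in% uniq$psm, ],
                                 min_count = 3L)
    records <- vectorize_psms(uniq, ann, dict)
    list(corpus = corpus, ann = ann, clean = clean, uniq = uniq,
         dict = dict, records = records)
  })
}

# the full five-method corpus used by the acceptance suite:
# 400 spectra per method (2,000 spectra), each with a target and a
# reversed-sequence decoy PSM (4,000 PSMs)
acceptance_corpus <- function() {
  fixture("acceptance_corpus", function() {
    generate_corpus(corpus_config(
      n_proteins = 40L, n_psms_per_method = 400L,
      methods = fragmentation_methods(), seed = 2026L
    ))
  })
}

acceptance_pipeline <- function() {
  fixture("acceptance_pipeline", function() {
    corpus <- acceptance_corpus()
    ann <- annotate_psms(corpus$spectra, corpus$psms)
    clean <- suppressMessages(clean_psms(corpus$psms, ann))
    uniq <- deduplicate_psms(clean)
    dict <- build_ion_dictionary(ann[ann$psm %in% uniq$psm, ],
                                 min_count = 100L)
    records <- split_dataset(vectorize_psms(uniq, ann, dict), seed = 17L)
    list(corpus = corpus, ann = ann, uniq = uniq, dict = dict,
         records = records)
  })
}

# tiny-preset model trained on the acceptance corpus training split
acceptance_model <- function() {
  fixture("acceptance_model", function() {
    pipe <- acceptance_pipeline()
    train <- dplyr::filter(pipe$records, split == "train")
    val <- dplyr::filter(pipe$records, split == "validation")
    steps_per_epoch <- ceiling(nrow(train) / 64)
    fit_intensity_model(
      train, pipe$dict,
      model_config(dict_size = nrow(pipe$dict), preset = "tiny"),
      train_config(epochs = 30L, lr = 5e-3,
                   warmup_steps = ceiling(1.5 * steps_per_epoch),
                   batch_size = 64L, seed = 7L),
      validation = val
    )
  })
}
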