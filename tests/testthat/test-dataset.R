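fake_psms <- function(n, decoy = FALSE) {
  tibble::tibble(
    raw_file = "f.mgf", scan = seq_len(n),
    peptide = replicate(n, paste(sample(LETTERS[c(1, 7, 11, 12, 19)],
                                        8, replace = TRUE),
                                 collapse = "")),
    modifications = "", charge = 2L, method = "HCD",
    hyperscore = stats::runif(n, 5, 25), is_decoy = decoy
  )
}

test_that("cleaning removes decoys and unannotated PSMs, idempotently", {
  set.seed(21)
  psms <- dplyr::bind_rows(fake_psms(10), fake_psms(4, decoy = TRUE))
  ann <- tibble::tibble(psm = c(1:7, 11), ion = "y:3:1", intensity = 1)
  out <- suppressMessages(clean_psms(psms, ann))
  expect_equal(nrow(out), 7)  # 3 targets unannotated, decoys dropped
  expect_true(all(!out$is_decoy))
  again <- suppressMessages(clean_psms(out, dplyr::mutate(ann, psm = match(psm, out$psm))))
  expect_equal(nrow(again), nrow(out))
  all_decoy <- fake_psms(5, decoy = TRUE)
  expect_equal(nrow(suppressMessages(clean_psms(all_decoy, ann))), 0)
})

test_that("deduplication keeps the top hyperscore per key", {
  psms <- tibble::tibble(
    raw_file = c("a", "b", "a"), scan = c(1L, 2L, 3L),
    peptide = "PEPTIDEK", charge = 2L, method = "HCD",
    hyperscore = c(10, 20, 15), is_decoy = FALSE
  )
  out <- deduplicate_psms(psms)
  expect_equal(nrow(out), 1)
  expect_equal(out$hyperscore, 20)
  # distinct charges and methods are distinct keys
  multi <- dplyr::bind_rows(
    dplyr::mutate(psms[1, ], charge = 2L),
    dplyr::mutate(psms[1, ], charge = 3L),
    dplyr::mutate(psms[1, ], method = "ECD")
  )
  expect_equal(nrow(deduplicate_psms(multi)), 3)
  # hyperscore ties break deterministically by (raw_file, scan)
  tie <- tibble::tibble(
    raw_file = c("z", "a"), scan = c(9L, 1L), peptide = "PEPTIDEK",
    charge = 2L, method = "HCD", hyperscore = 12, is_decoy = FALSE
  )
  expect_equal(deduplicate_psms(tie)$raw_file, "a")
})

test_that("ion dictionary applies the occurrence threshold inclusively", {
  ann <- tibble::tibble(
    ion = c(rep("y:3:1", 100), rep("b:2:1", 99), rep("a+1:4:2", 150))
  )
  dict <- build_ion_dictionary(ann, min_count = 100)
  expect_setequal(dict$ion, c("y:3:1", "a+1:4:2"))
  expect_identical(dict$index, seq_len(nrow(dict)))
  # canonical priority order: y before a+1
  expect_identical(dict$ion, c("y:3:1", "a+1:4:2"))
  # empty corpus gives a valid empty dictionary
  empty <- build_ion_dictionary(ann[0, ], min_count = 100)
  expect_equal(nrow(empty), 0)
  # order of input rows is irrelevant
  dict2 <- build_ion_dictionary(ann[sample(nrow(ann)), ], min_count = 100)
  expect_identical(dict$ion, dict2$ion)
})

test_that("doubling every count never drops dictionary labels", {
  pipe <- small_pipeline()
  ann <- pipe$ann
  d1 <- build_ion_dictionary(ann, min_count = 7)
  d2 <- build_ion_dictionary(dplyr::bind_rows(ann, ann), min_count = 7)
  expect_true(all(d1$ion %in% d2$ion))
})

test_that("vectorization masks impossible ions and max-scales the rest", {
  dict <- build_ion_dictionary(
    tibble::tibble(ion = rep(c("y:3:1", "b:2:1", "b:10:1", "y:3:3"),
                             each = 5)),
    min_count = 1
  )
  v <- vectorize_ions("y:3:1", 500, "PEPTIK", 2, dict)
  expect_equal(v[dict$ion == "y:3:1"], 1.0)
  expect_equal(v[dict$ion == "b:2:1"], 0.0)
  # ordinal 10 >= length 6 is masked
  expect_equal(v[dict$ion == "b:10:1"], -1)
  # fragment charge 3 above the 2+ precursor is masked
  expect_equal(v[dict$ion == "y:3:3"], -1)
  expect_error(
    vectorize_ions("y:3:1", 1, paste(rep("A", 31), collapse = ""), 2, dict),
    "maximum"
  )
})

test_that("mask counts match the closed form on pipeline records", {
  pipe <- small_pipeline()
  dict <- pipe$dict
  for (i in seq_len(nrow(pipe$records))) {
    r <- pipe$records[i, ]
    len <- length(peptide_tokens(r$peptide))
    expected <- sum(dict$ordinal >= len | dict$charge > r$charge)
    expect_equal(sum(r$target[[1]] == -1), expected)
    nonmask <- r$target[[1]][r$target[[1]] != -1]
    expect_true(max(nonmask) %in% c(0, 1))
    expect_true(all(nonmask >= 0 & nonmask <= 1))
  }
})

test_that("splits are exact, disjoint, exhaustive and reproducible", {
  records <- tibble::tibble(id = 1:1000)
  s1 <- split_dataset(records, seed = 5)
  expect_equal(as.vector(table(s1$split)), c(800, 100, 100))
  s2 <- split_dataset(records, seed = 5)
  expect_identical(s1$split, s2$split)
  s3 <- split_dataset(records, seed = 6)
  expect_false(identical(s1$split, s3$split))
  expect_equal(sort(records$id), sort(c(
    s1$id[s1$split == "train"], s1$id[s1$split == "validation"],
    s1$id[s1$split == "test"]
  )))
  expect_warning(split_dataset(tibble::tibble(id = 1:5), seed = 1),
                 "degenerate")
})

test_that("datasets round-trip through Parquet with traceability", {
  skip_if_not_installed("arrow")
  pipe <- small_pipeline()
  records <- split_dataset(pipe$records, seed = 17)
  dir <- withr::local_tempdir()
  write_dataset(records, dir, pipe$dict)
  shards <- list.files(dir, pattern = "^train-")
  expect_gte(length(shards), 8)
  back <- read_dataset(dir)
  expect_equal(nrow(back$records), nrow(records))
  expect_identical(back$dictionary$ion, pipe$dict$ion)
  ord1 <- order(records$raw_file, records$scan, records$peptide)
  ord2 <- order(back$records$raw_file, back$records$scan,
                back$records$peptide)
  expect_identical(records$peptide[ord1], back$records$peptide[ord2])
  expect_equal(records$target[ord1], back$records$target[ord2])
  # every record maps back to its raw spectrum
  key <- paste(pipe$corpus$spectra$raw_file, pipe$corpus$spectra$scan)
  expect_true(all(paste(back$records$raw_file, back$records$scan) %in% key))
  # unknown extra columns warn; missing required columns error
  extra <- dplyr::mutate(records, bogus = 1)
  dir2 <- withr::local_tempdir()
  write_dataset(records, dir2, pipe$dict)
  f <- file.path(dir2, "test.parquet")
  x <- tibble::as_tibble(arrow::read_parquet(f))
  arrow::write_parquet(dplyr::mutate(x, bogus = 1), f)
  expect_warning(read_dataset(dir2), "bogus")
  arrow::write_parquet(dplyr::select(x, -"peptide"), f)
  expect_error(read_dataset(dir2), "peptide")
})
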