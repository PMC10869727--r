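test_that("survival table round-trips exactly and validates its schema", {
  d <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    time_days = c(10.5, 200, 1825),
    event = c(1L, 0L, 1L)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_survival_table(d, path)
  expect_identical(read_survival_table(path), d)

  bad <- dplyr::mutate(d, time_days = c(0, 200, 1825))
  write_survival_table(bad, path)
  expect_error(read_survival_table(path), "non-positive")

  dup <- dplyr::mutate(d, subject_id = c("a", "a", "c"))
  write_survival_table(dup, path)
  expect_error(read_survival_table(path), "duplicate")

  readr::write_csv(d[c("subject_id", "time_days")], path)
  expect_error(read_survival_table(path), "missing required column")

  bad_event <- dplyr::mutate(d, event = c(1L, 2L, 0L))
  write_survival_table(bad_event, path)
  expect_error(read_survival_table(path), "0 or 1")
})

test_that("clinical tables reject missing values and non-binary flags", {
  d <- tibble::tibble(
    subject_id = c("a", "b"), age = c(64, 71), sex = c(1, 0),
    diabetes = c(0, 1), hypertension = c(1, 1), hyperlipidemia = c(0, 0),
    smoking = c(0, 1)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d, path)
  expect_identical(read_clinical_table(path), d)
  d2 <- d
  d2$age[2] <- NA
  readr::write_csv(d2, path)
  expect_error(read_clinical_table(path), "missing values")
  d3 <- d
  d3$smoking[1] <- 2
  readr::write_csv(d3, path)
  expect_error(read_clinical_table(path), "0/1")
})

test_that("the paper-conformant layout has 96 slices split 24/12/12 per condition", {
  layout <- tomogram_layout("paper_conformant_96")
  expect_equal(nrow(layout), 96)
  counts <- dplyr::count(layout, condition, axis)
  expect_setequal(counts$n[counts$axis == "short"], 24)
  expect_setequal(counts$n[counts$axis != "short"], 12)
  expect_equal(sum(layout$condition == "rest"), 48)
  expect_equal(sum(layout$condition == "stress"), 48)
})

test_that("slice ordering is canonical: permuted manifests give identical studies", {
  set.seed(41)
  layout <- tomogram_layout("reduced")
  slices <- array(runif(32 * 32 * nrow(layout)), c(32, 32, nrow(layout)))
  s1 <- tomogram_study("s", slices, layout)
  perm <- sample(nrow(layout))
  s2 <- tomogram_study("s", slices[, , perm], layout[perm, ])
  expect_identical(s1$layout, s2$layout)
  expect_identical(s1$slices, s2$slices)
})

test_that("strict mode rejects non-conformant slice counts", {
  layout <- tomogram_layout("paper_conformant_96")
  slices <- array(runif(8 * 8 * 96), c(8, 8, 96))
  expect_silent(tomogram_study("s", slices, layout, strict = TRUE))
  expect_error(
    tomogram_study("s", slices[, , -1], layout[-1, ], strict = TRUE),
    "non-conformant"
  )
  expect_error(
    tomogram_study("s", slices[, , 1:8], tomogram_layout("reduced"),
                   strict = TRUE),
    "non-conformant"
  )
})

test_that("constant-intensity studies normalize to zero with a warning", {
  layout <- tomogram_layout("reduced")
  slices <- array(0.42, c(8, 8, nrow(layout)))
  expect_warning(s <- tomogram_study("s", slices, layout), "constant")
  expect_true(all(s$slices == 0))
})

test_that("layout metadata is validated", {
  layout <- tomogram_layout("reduced")
  slices <- array(runif(8 * 8 * 8), c(8, 8, 8))
  bad <- layout
  bad$condition[3] <- NA
  expect_error(tomogram_study("s", slices, bad), "missing layout")
  dup <- layout
  dup$slice_index[2] <- dup$slice_index[1]
  dup$condition[2] <- dup$condition[1]
  dup$axis[2] <- dup$axis[1]
  expect_error(tomogram_study("s", slices, dup), "duplicate layout")
})

test_that("PNG-manifest and array-container dialects load identical studies", {
  set.seed(7)
  cfg <- tiny_phantom(2, seed = 7)
  study <- withr::with_seed(1, render_phantom_study(0.6, cfg, "px"))
  dir <- withr::local_tempdir()
  manifest <- write_tomogram_study(study, file.path(dir, "png"), "png")
  from_png <- load_tomogram_study(manifest, file.path(dir, "png"))
  cpath <- write_tomogram_study(study, file.path(dir, "arr"), "array")
  from_arr <- read_tomogram_container(cpath)
  expect_identical(from_png$layout, from_arr$layout)
  # PNG quantizes to 8 bits; the container is full precision
  expect_lt(max(abs(from_png$slices - from_arr$slices)), 1 / 250)
  expect_equal(from_arr$slices, study$slices, tolerance = 1e-12)
  # mismatched slice dimensions are rejected
  manifest2 <- manifest
  png::writePNG(matrix(0.5, 8, 8), file.path(dir, "png", manifest2$file[1]))
  expect_error(load_tomogram_study(manifest2, file.path(dir, "png")),
               "mismatched slice dimensions")
})

test_that("split_cohort produces the documented sizes and is deterministic", {
  d <- tibble::tibble(subject_id = sprintf("s%03d", 1:100))
  s1 <- split_cohort(d, 0.2, 5, seed = 3)
  expect_equal(sum(s1$role == "test"), 20)
  expect_equal(unname(table(s1$role[s1$role != "test"])), rep(16L, 5),
               ignore_attr = TRUE)
  s2 <- split_cohort(d, 0.2, 5, seed = 3)
  expect_identical(s1, s2)
  s3 <- split_cohort(d, 0.2, 5, seed = 4)
  expect_false(identical(s1$role, s3$role))

  small <- split_cohort(tibble::tibble(subject_id = letters[1:10]), 0.2, 5,
                        seed = 1)
  expect_equal(sum(small$role == "test"), 2)
  expect_true(all(table(small$role[small$role != "test"]) <= 2))
  expect_error(split_cohort(d, 1.2, 5, 1), "test_fraction")
  expect_error(
    split_cohort(tibble::tibble(subject_id = letters[1:4]), 0.2, 5, 1),
    "too few"
  )
})

test_that("split roles partition the cohort for random sizes and seeds", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    k <- sample(2:6, 1)
    if (n < k + 1) next
    frac <- runif(1, 0.1, 0.4)
    d <- tibble::tibble(subject_id = sprintf("s%04d", seq_len(n)))
    s <- split_cohort(d, frac, k, seed = sample.int(1e6, 1))
    expect_equal(sort(s$subject_id), sort(d$subject_id))
    expect_true(all(s$role %in% c("test", paste0("fold", 1:k))))
    fold_sizes <- table(s$role[s$role != "test"])
    expect_lte(diff(range(fold_sizes)), 1)
  }
})
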