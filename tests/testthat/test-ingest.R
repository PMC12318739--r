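test_that("cohort selection applies the size and reader-count rules inclusively", {
  ann <- make_toy_annotations()
  sel <- select_cohort(ann)
  kept <- unique(sel$nodule_id)
  expect_setequal(kept, c("n1", "n2", "n3", "n4", "n5"))
  rejected <- attr(sel, "rejected")
  expect_equal(rejected$nodule_id, "n6")
  expect_match(rejected$reason, "diameter")

  # boundary cases: 3.0 mm and exactly 3 readers are both included,
  # 2.9 mm or 2 readers are not
  edge <- dplyr::bind_rows(
    purrr::map_dfr(paste0("r", 1:4), ~toy_reader_row("s", "small", .x, 2, 2.9)),
    purrr::map_dfr(paste0("r", 1:2), ~toy_reader_row("s", "few", .x, 2, 10)),
    purrr::map_dfr(paste0("r", 1:3), ~toy_reader_row("s", "edge", .x, 2, 3.0))
  )
  sel2 <- select_cohort(edge)
  expect_equal(unique(sel2$nodule_id), "edge")
  expect_setequal(attr(sel2, "rejected")$nodule_id, c("small", "few"))

  # idempotent, order preserved
  sel3 <- select_cohort(sel)
  expect_equal(sel3$nodule_id, sel$nodule_id)
})

test_that("consensus labels follow the rounded-mean rule with half-up ties", {
  expect_equal(derive_label(c(1, 1, 1, 1)), "benign")
  expect_equal(derive_label(c(3, 3, 3)), "excluded")
  expect_equal(derive_label(c(4, 5, 5, 4)), "malignant")  # mean 4.5 -> 5
  expect_equal(derive_label(c(2, 3, 3, 2)), "excluded")   # mean 2.5 -> 3
  # banker's rounding changes the tie cases only
  expect_equal(derive_label(c(2, 3, 3, 2), rounding = "banker"), "benign")
  # permutation invariance
  withr::with_seed(1, {
    for (i in 1:20) {
      scores <- sample(1:5, 4, replace = TRUE)
      expect_equal(derive_label(scores), derive_label(sample(scores)))
    }
  })
  expect_error(derive_label(c(1, 2, 6)), "1\\.\\.5")
  expect_error(derive_label(c(1, 2, 0), nodule_id = "bad-one"), "bad-one")
})

test_that("fourth-reader imputation is the clamped rounded mean of three", {
  expect_equal(impute_reader(c(2, 2, 2)), 2)
  expect_equal(impute_reader(c(4, 2, 3)), 3)
  expect_equal(impute_reader(c(4, 5, 4)), 4)   # 4.33 -> 4
  expect_equal(impute_reader(c(4, 5, 5)), 5)   # 4.67 -> 5
  expect_equal(impute_reader(c(1, 2, 2)), 2)   # 1.67 -> 2
  # fixed point and clamping
  for (x in 1:5) expect_equal(impute_reader(c(x, x, x)), x)
  expect_equal(impute_reader(c(5, 5, 5), range = c(1, 4)), 4)
  expect_error(impute_reader(c(1, 2)), "exactly 3")
  expect_error(impute_reader(c(1, 2, NA)), "exactly 3")
})

test_that("rating matrices are 9 x 4, ordered, and imputed where allowed", {
  ann <- make_toy_annotations()
  # 4 complete readers apart from one missing margin cell
  m1 <- build_rating_matrix(ann[ann$nodule_id == "n1", ])
  expect_identical(dim(m1), c(9L, 4L))
  expect_identical(rownames(m1), nodule_attributes()$attribute)
  expect_false(anyNA(m1))
  expect_equal(unname(m1["margin", 3]), 4)  # imputed from (4,4,4)
  expect_equal(unname(m1["diameter", ]), rep(8, 4))

  # 3 readers: fourth column fully imputed, named "imputed"
  m4 <- build_rating_matrix(ann[ann$nodule_id == "n4", ])
  expect_identical(colnames(m4)[4], "imputed")
  expect_equal(unname(m4["subtlety", ]), c(4, 2, 3, 3))  # mean 3 -> 3
  expect_equal(unname(m4["diameter", ]), rep(12, 4))

  # attribute missing for >= 2 readers is surfaced, not guessed
  broken <- ann[ann$nodule_id == "n1", ]
  broken$margin[c(1, 3)] <- NA
  expect_error(build_rating_matrix(broken), "missing for 2 readers")
})

test_that("build_cohort partitions nodules and derives labels from malignancy only", {
  cohort <- build_cohort(make_toy_annotations())
  expect_equal(cohort$summary,
               list(benign = 2L, malignant = 2L, excluded = 1L,
                    rejected = 1L))
  expect_setequal(cohort$manifest$nodule_id[cohort$manifest$label == 0],
                  c("n1", "n2"))
  expect_setequal(cohort$manifest$nodule_id[cohort$manifest$label == 1],
                  c("n3", "n4"))
  # every selected nodule lands in exactly one of the three outcomes
  n_selected <- length(unique(select_cohort(make_toy_annotations())$nodule_id))
  expect_equal(nrow(cohort$manifest) + cohort$summary$excluded, n_selected)
  # flattened ratings round-trip against the stored matrices
  expect_equal(unname(cohort$manifest$spiculation_r1[
    cohort$manifest$nodule_id == "n3"]),
    unname(cohort$rating_matrices[["n3"]]["spiculation", 1]))
})

test_that("CSV and XML annotation readers produce identical record streams", {
  ann <- make_toy_annotations()
  csv <- withr::local_tempfile(fileext = ".csv")
  xml <- withr::local_tempfile(fileext = ".xml")
  readr::write_csv(ann, csv)
  write_annotations_xml(ann, xml)
  from_csv <- read_annotations_csv(csv)
  from_xml <- read_annotations_xml(xml)
  key <- function(x) dplyr::arrange(x, nodule_id, reader_id)
  expect_equal(key(from_xml), key(from_csv), tolerance = 1e-12)
  expect_error(read_annotations_csv(withr::local_tempfile()), "not found")
})
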