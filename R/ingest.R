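#' @importFrom rlang .data
NULL

annotation_columns <- function() {
  c("scan_id", "nodule_id", "reader_id",
    "subtlety", "internal_structure", "calcification", "sphericity",
    "margin", "lobulation", "spiculation", "texture", "malignancy",
    "diameter_mm", "centre_z", "centre_y", "centre_x")
}

#' Read a flat annotation table
#'
#' One row per nodule-reader pair: scan and nodule identifiers, the reader
#' identifier, the eight per-reader ordinal characteristics plus the
#' malignancy score, and the per-nodule diameter (mm) and physical centre
#' (mm, scanner frame, z/y/x), repeated on every reader row. Missing
#' per-reader characteristics are empty cells.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the columns of `annotation_columns()`.
#' @export
read_annotations_csv <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(annotation_columns(), names(tbl))
  if (length(missing) > 0) {
    stopf("annotation table is missing columns: %s",
          paste(missing, collapse = ", "))
  }
  tbl <- dplyr::select(tbl, dplyr::all_of(annotation_columns()))
  tbl$scan_id <- as.character(tbl$scan_id)
  tbl$nodule_id <- as.character(tbl$nodule_id)
  tbl$reader_id <- as.character(tbl$reader_id)
  tbl
}

#' Read a clustered LIDC-style XML annotation file
#'
#' Reads an XML layout in which reader contours have already been grouped
#' into nodules (as LIDC tooling provides): `<scan id>` elements contain
#' `<nodule id diameterMm centreZ centreY centreX>` elements, each holding
#' one `<reading reader>` element per radiologist with the eight ordinal
#' characteristics and the malignancy score as child elements. Absent child
#' elements are missing annotations. The result is identical in shape and
#' content to [read_annotations_csv()] on the equivalent flat table, so
#' both feed the same cohort pipeline.
#'
#' @param path Path to an XML file.
#' @return A tibble with the columns of `annotation_columns()`.
#' @export
read_annotations_xml <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  doc <- xml2::read_xml(path)
  per_reader_fields <- c("subtlety", "internal_structure", "calcification",
                         "sphericity", "margin", "lobulation", "spiculation",
                         "texture", "malignancy")
  rows <- list()
  for (scan in xml2::xml_find_all(doc, ".//scan")) {
    scan_id <- xml2::xml_attr(scan, "id")
    for (nod in xml2::xml_find_all(scan, "./nodule")) {
      nodule_id <- xml2::xml_attr(nod, "id")
      diameter <- as.numeric(xml2::xml_attr(nod, "diameterMm"))
      centre <- as.numeric(c(xml2::xml_attr(nod, "centreZ"),
                             xml2::xml_attr(nod, "centreY"),
                             xml2::xml_attr(nod, "centreX")))
      for (rd in xml2::xml_find_all(nod, "./reading")) {
        vals <- vapply(per_reader_fields, function(f) {
          node <- xml2::xml_find_first(rd, paste0("./", f))
          if (inherits(node, "xml_missing")) NA_real_
          else as.numeric(xml2::xml_text(node))
        }, numeric(1))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scan_id = scan_id, nodule_id = nodule_id,
          reader_id = xml2::xml_attr(rd, "reader"),
          !!!as.list(vals),
          diameter_mm = diameter,
          centre_z = centre[1], centre_y = centre[2], centre_x = centre[3]
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(annotation_columns())),
      annotation_columns()
    )))
  }
  dplyr::bind_rows(rows)[, annotation_columns()]
}

#' Select the analysis cohort
#'
#' Keeps nodules at least 3 mm in diameter that were annotated by at least
#' three radiologists (both bounds inclusive). Nodules failing either rule
#' -- or carrying no annotations at all -- are dropped, with the reason
#' recorded in the `rejected` attribute of the result rather than raised as
#' an error. Input row order is preserved, so the selection is idempotent
#' and byte-stable across reruns.
#'
#' @param annotations A per-reader annotation tibble
#'   (see [read_annotations_csv()]).
#' @param min_diameter_mm,min_readers Inclusive selection thresholds.
#' @return The annotation rows of the selected nodules, with a `rejected`
#'   attribute tibble (`nodule_id`, `reason`).
#' @export
select_cohort <- function(annotations, min_diameter_mm = 3, min_readers = 3) {
  counts <- annotations |>
    dplyr::summarise(
      n_readers = sum(!is.na(.data$reader_id)),
      diameter_mm = .data$diameter_mm[1],
      .by = "nodule_id"
    )
  counts$reason <- dplyr::case_when(
    counts$n_readers == 0 ~ "no annotations",
    counts$diameter_mm < min_diameter_mm ~
      sprintf("diameter below %g mm", min_diameter_mm),
    counts$n_readers < min_readers ~
      sprintf("fewer than %d readers", min_readers),
    .default = NA_character_
  )
  rejected <- counts[!is.na(counts$reason), c("nodule_id", "reason")]
  kept <- annotations[annotations$nodule_id %in%
                        counts$nodule_id[is.na(counts$reason)], ]
  attr(kept, "rejected") <- tibble::as_tibble(rejected)
  kept
}

#' Derive the consensus benign/malignant label
#'
#' The malignancy scores of the available readers (three or four, each an
#' ordinal 1-5) are averaged and rounded to the nearest integer, ties going
#' up by default. Rounded scores 1-2 are benign, 4-5 malignant; the
#' intermediate score 3 marks the nodule excluded from the cohort. The
#' result depends only on the multiset of scores, never on reader order.
#'
#' @param malignancy_scores Numeric vector of per-reader scores in 1..5.
#' @param rounding `"half_up"` (default) or `"banker"`.
#' @param nodule_id Optional identifier used in error messages.
#' @return One of `"benign"`, `"malignant"`, `"excluded"`.
#' @export
#' @examples
#' derive_label(c(4, 5, 5, 4))  # mean 4.5 rounds up to 5 -> malignant
#' derive_label(c(2, 3, 3, 2))  # mean 2.5 rounds up to 3 -> excluded
derive_label <- function(malignancy_scores, rounding = "half_up",
                         nodule_id = NULL) {
  scores <- malignancy_scores[!is.na(malignancy_scores)]
  who <- if (is.null(nodule_id)) "" else sprintf(" for nodule '%s'", nodule_id)
  if (length(scores) == 0) stopf("no malignancy scores%s", who)
  if (any(scores < 1 | scores > 5 | scores != round(scores))) {
    stopf("malignancy scores%s must be integers in 1..5, got: %s",
          who, paste(malignancy_scores, collapse = ", "))
  }
  consensus <- round_by_rule(mean(scores), rounding)
  if (consensus <= 2) "benign" else if (consensus >= 4) "malignant" else "excluded"
}

#' Impute a missing fourth reader's rating
#'
#' When only three of four readers rated an attribute, the fourth entry is
#' the rounded mean of the three present values, clamped to that
#' attribute's ordinal range. The rule is only defined for exactly three
#' present values; fewer is an error, never a guess.
#'
#' @param attribute_values Numeric vector of exactly three present ratings.
#' @param range Length-2 ordinal range to clamp into.
#' @param rounding `"half_up"` (default) or `"banker"`.
#' @return A single imputed ordinal value.
#' @export
#' @examples
#' impute_reader(c(4, 2, 3))  # mean 3 -> 3
#' impute_reader(c(4, 5, 4))  # mean 4.33 -> 4
impute_reader <- function(attribute_values, range = c(1, 5),
                          rounding = "half_up") {
  values <- attribute_values[!is.na(attribute_values)]
  if (length(values) != 3) {
    stopf("imputation requires exactly 3 present values, got %d",
          length(values))
  }
  clamp(round_by_rule(mean(values), rounding), range[1], range[2])
}

#' Build the 9 x 4 rating matrix for one nodule
#'
#' Rows are the nine attributes in the canonical order of
#' [nodule_attributes()]; columns are readers sorted by reader identifier,
#' with the imputed reader always in the fourth column when only three
#' annotated. Per-attribute gaps with three present values are filled by
#' [impute_reader()]; an attribute missing for two or more readers is an
#' error. The per-nodule diameter is replicated across all four reader
#' columns.
#'
#' @param nodule_annotations Annotation rows (3 or 4) of a single nodule.
#' @param rounding Rounding rule passed to [impute_reader()].
#' @return A 9 x 4 numeric matrix with attribute row names and reader
#'   column names (imputed column named `"imputed"`).
#' @export
build_rating_matrix <- function(nodule_annotations, rounding = "half_up") {
  ann <- nodule_annotations
  nid <- ann$nodule_id[1]
  if (length(unique(ann$nodule_id)) != 1) {
    stopf("annotations for multiple nodules passed to build_rating_matrix")
  }
  n_readers <- nrow(ann)
  if (n_readers < 3 || n_readers > 4) {
    stopf("nodule '%s' has %d readers; 3 or 4 required", nid, n_readers)
  }
  ann <- ann[order(ann$reader_id), ]
  spec <- nodule_attributes()
  per_reader <- setdiff(spec$attribute, "diameter")

  mat <- matrix(NA_real_, nrow = 9, ncol = 4,
                dimnames = list(spec$attribute,
                                c(ann$reader_id,
                                  rep("imputed", 4 - n_readers))))
  for (i in seq_along(per_reader)) {
    a <- per_reader[i]
    vals <- c(ann[[a]], rep(NA_real_, 4 - n_readers))
    n_present <- sum(!is.na(vals))
    rng <- c(spec$lo[i], spec$hi[i])
    if (any(!is.na(vals) & (vals < rng[1] | vals > rng[2]))) {
      stopf("nodule '%s': %s value out of range [%g, %g]", nid, a,
            rng[1], rng[2])
    }
    if (n_present == 4) {
      mat[a, ] <- vals
    } else if (n_present == 3) {
      vals[is.na(vals)] <- impute_reader(vals, range = rng,
                                         rounding = rounding)
      mat[a, ] <- vals
    } else {
      stopf("nodule '%s': attribute '%s' missing for %d readers; only a single missing reader can be imputed",
            nid, a, 4 - n_present)
    }
  }
  mat["diameter", ] <- rep(ann$diameter_mm[1], 4)
  mat
}

#' Construct the labelled cohort from raw annotations
#'
#' Runs the full cohort pipeline: selection (>= 3 mm, >= 3 readers),
#' consensus label derivation from the malignancy scores alone, exclusion
#' of consensus-3 nodules, and rating-matrix construction with fourth-reader
#' imputation. Labels never see the nine structured attributes.
#'
#' @param annotations Per-reader annotation tibble.
#' @param rounding Rounding rule for labels and imputation.
#' @return A `noduleca_cohort`: list with `manifest` (one tibble row per
#'   labelled nodule: ids, label (`benign = 0`, `malignant = 1`), centre,
#'   diameter, and the 9 x 4 ratings flattened as `<attribute>_r1..r4`),
#'   `rating_matrices` (named list of 9 x 4 matrices), `summary` (counts of
#'   benign / malignant / excluded / rejected) and `rejected` (reasons).
#' @export
build_cohort <- function(annotations, rounding = "half_up") {
  selected <- select_cohort(annotations)
  rejected <- attr(selected, "rejected")
  nodule_ids <- unique(selected$nodule_id)

  manifest_rows <- list()
  matrices <- list()
  n_excluded <- 0L
  for (nid in nodule_ids) {
    ann <- selected[selected$nodule_id == nid, ]
    label_name <- derive_label(ann$malignancy, rounding = rounding,
                               nodule_id = nid)
    if (label_name == "excluded") {
      n_excluded <- n_excluded + 1L
      next
    }
    ratings <- build_rating_matrix(ann, rounding = rounding)
    matrices[[nid]] <- ratings
    flat <- as.list(as.vector(t(ratings)))
    names(flat) <- paste0(rep(rownames(ratings), each = 4), "_r", 1:4)
    manifest_rows[[nid]] <- tibble::tibble(
      nodule_id = nid, scan_id = ann$scan_id[1],
      label_name = label_name,
      label = if (label_name == "malignant") 1L else 0L,
      diameter_mm = ann$diameter_mm[1],
      centre_z = ann$centre_z[1], centre_y = ann$centre_y[1],
      centre_x = ann$centre_x[1],
      !!!flat
    )
  }
  manifest <- if (length(manifest_rows) > 0) dplyr::bind_rows(manifest_rows)
              else tibble::tibble()
  out <- list(
    manifest = manifest,
    rating_matrices = matrices,
    summary = list(
      benign = sum(manifest$label == 0L),
      malignant = sum(manifest$label == 1L),
      excluded = n_excluded,
      rejected = nrow(rejected)
    ),
    rejected = rejected,
    rounding = rounding
  )
  class(out) <- "noduleca_cohort"
  out
}

#' @export
print.noduleca_cohort <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<noduleca_cohort> %d labelled nodules (%d benign, %d malignant); %d excluded (consensus 3), %d rejected\n",
    nrow(x$manifest), s$benign, s$malignant, s$excluded, s$rejected))
  invisible(x)
}

#' Write a cohort manifest and summary to disk
#'
#' @param cohort A `noduleca_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `manifest.csv` and `summary.json`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   progress = FALSE)
  jsonlite::write_json(cohort$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
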