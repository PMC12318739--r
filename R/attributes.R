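#' The nine structured nodule attributes
#'
#' Radiologists score each nodule on ordinal scales for subtlety, internal
#' structure, calcification, sphericity, margin, lobulation, spiculation and
#' texture; the ninth row of the rating matrix carries the nodule diameter
#' in millimetres, which is reported per nodule rather than per reader and
#' is replicated across the four reader columns. Malignancy is deliberately
#' absent: it is the prediction target, never a feature.
#'
#' @return A tibble with columns `attribute`, `lo`, `hi` (the fixed scale
#'   bounds used for validation and for affine rescaling to `[0, 1]`) and
#'   `ordinal` (whether entries must be integers).
#' @export
#' @examples
#' nodule_attributes()
nodule_attributes <- function() {
  tibble::tibble(
    attribute = c(
      "subtlety", "internal_structure", "calcification", "sphericity",
      "margin", "lobulation", "spiculation", "texture", "diameter"
    ),
    lo = c(1, 1, 1, 1, 1, 1, 1, 1, 0),
    hi = c(5, 4, 6, 5, 5, 5, 5, 5, 40),
    ordinal = c(rep(TRUE, 8L), FALSE)
  )
}

attribute_names <- function() nodule_attributes()$attribute

#' Rescale a rating matrix to the unit interval
#'
#' The model consumes structured features after a per-attribute affine map
#' to `[0, 1]` computed from the fixed ordinal ranges in
#' [nodule_attributes()], never from the data, so cross-validation folds
#' stay independent. Diameter uses a fixed 0-40 mm window; values outside
#' any range are clipped.
#'
#' @param ratings A 9 x 4 rating matrix with rows in the canonical
#'   attribute order.
#' @return A 9 x 4 numeric matrix with entries in `[0, 1]`.
#' @export
scale_ratings <- function(ratings) {
  check_rating_matrix_shape(ratings)
  spec <- nodule_attributes()
  scaled <- (ratings - spec$lo) / (spec$hi - spec$lo)
  clamp(scaled, 0, 1)
}

check_rating_matrix_shape <- function(ratings) {
  if (!is.matrix(ratings) || !identical(dim(ratings), c(9L, 4L))) {
    stopf("rating matrix must be 9 x 4, got %s",
          paste(dim(ratings), collapse = " x "))
  }
  if (anyNA(ratings)) stopf("rating matrix contains missing entries")
  invisible(ratings)
}
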