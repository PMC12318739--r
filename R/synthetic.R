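#' Synthetic dataset configuration
#'
#' The generator emulates the preprocessed study inputs -- one normalized
#' 32^3 cube plus one 9 x 4 rating matrix per nodule -- with a single
#' separation knob. Defaults mirror the study cohort: 684 nodules with
#' 330 malignant (354 benign). `delta` scales every class-conditional
#' difference in both modalities (larger, spiculated, irregular cubes and
#' shifted spiculation/lobulation/margin/diameter ratings for malignant
#' nodules), so `delta = 0` is an exact null dataset in which the two
#' class-conditional distributions coincide. Signal is injected into the
#' two modalities with independent noise, so fusing them is genuinely
#' informative rather than redundant.
#'
#' @param n_samples Number of nodules.
#' @param malignant_fraction Fraction labelled malignant.
#' @param delta Class-separation strength in `[0, 1]`.
#' @param sigma Additive voxel noise sd on the cubes.
#' @param reader_jitter Per-reader rating noise sd (ordinal steps).
#' @param seed Seed for the whole dataset.
#' @return A `noduleca_synth_config` list.
#' @export
synth_config <- function(n_samples = 684L, malignant_fraction = 330 / 684,
                         delta = 1, sigma = 0.05, reader_jitter = 0.7,
                         seed = 1L) {
  stopifnot(delta >= 0, delta <= 1, sigma >= 0, reader_jitter >= 0)
  structure(
    list(n_samples = as.integer(n_samples),
         malignant_fraction = malignant_fraction, delta = delta,
         sigma = sigma, reader_jitter = reader_jitter,
         seed = as.integer(seed)),
    class = "noduleca_synth_config"
  )
}

# unit-offset voxel coordinate components relative to the cube centre
cube_geometry <- local({
  geom <- NULL
  function() {
    if (is.null(geom)) {
      ax <- (1:32) - 16.5
      zc <- array(ax, c(32, 32, 32))
      yc <- array(rep(ax, each = 32), c(32, 32, 32))
      xc <- array(rep(ax, each = 1024), c(32, 32, 32))
      r <- sqrt(zc^2 + yc^2 + xc^2)
      geom <<- list(z = zc / r, y = yc / r, x = xc / r, r = r)
    }
    geom
  }
})

#' Generate one synthetic nodule cube
#'
#' A soft sphere on a noisy background, already in `[0, 1]`. Malignant
#' cubes (`label = 1`) get a `delta`-scaled larger radius, narrow radial
#' spikes (spiculation) and wide boundary bumps (irregular margin);
#' benign cubes are smooth. At `delta = 0` the two classes are drawn from
#' the same distribution. Uses the current RNG state; seed upstream.
#'
#' @param label 0 (benign) or 1 (malignant).
#' @param config A [synth_config()].
#' @return A normalized `nodule_cube`.
#' @export
gen_cube <- function(label, config = synth_config()) {
  stopifnot(label %in% c(0, 1))
  geom <- cube_geometry()
  strength <- config$delta * label
  radius <- max(3, stats::rnorm(1, 6 + 2.5 * strength, 0.6))

  ang_field <- function(n_dirs, width) {
    dirs <- matrix(stats::rnorm(3 * n_dirs), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    field <- 0
    for (i in seq_len(n_dirs)) {
      cosang <- geom$z * dirs[i, 1] + geom$y * dirs[i, 2] +
        geom$x * dirs[i, 3]
      field <- field + exp(-(1 - cosang) / width)
    }
    field
  }
  # draw both fields unconditionally so RNG use is label-independent
  spikes <- ang_field(6L, 0.05)
  bumps <- ang_field(4L, 0.40)

  core <- 0.65 * stats::plogis((radius - geom$r) / 1.2)
  shell <- exp(-((geom$r - radius) / 2.5)^2)
  intensity <- 0.12 + core +
    strength * (0.35 * pmin(spikes, 1) + 0.15 * pmin(bumps, 1)) * shell
  if (config$sigma > 0) {
    intensity <- intensity + stats::rnorm(length(intensity), 0, config$sigma)
  }
  structure(
    list(voxels = array(clamp(intensity, 0, 1), c(32L, 32L, 32L)),
         scan_id = "synthetic", nodule_id = NA_character_,
         centre_mm = c(16, 16, 16), centre_voxel = c(16L, 16L, 16L),
         padded = FALSE, normalized = TRUE),
    class = "nodule_cube"
  )
}

synth_rating_profile <- function() {
  list(
    base = c(subtlety = 3, internal_structure = 1, calcification = 5,
             sphericity = 4, margin = 4, lobulation = 1.5,
             spiculation = 1.5, texture = 4.5, diameter = 8),
    # ordinal-step shift applied to malignant nodules at delta = 1
    shift = c(subtlety = 0, internal_structure = 0, calcification = 0,
              sphericity = 0, margin = -2, lobulation = 2,
              spiculation = 2.5, texture = 0, diameter = 10)
  )
}

#' Generate one synthetic 9 x 4 rating matrix
#'
#' Per-attribute latent class means (malignant shifted by `delta` on the
#' spiculation, lobulation, margin and diameter rows), nodule-level
#' variation, independent per-reader jitter, then rounding and clamping
#' to each attribute's ordinal range. Diameter is continuous, clamped to
#' 3-40 mm and replicated across the four reader columns, mirroring the
#' real preprocessing. Uses the current RNG state.
#'
#' @inheritParams gen_cube
#' @return A 9 x 4 rating matrix with attribute row names.
#' @export
gen_ratings <- function(label, config = synth_config()) {
  stopifnot(label %in% c(0, 1))
  spec <- nodule_attributes()
  profile <- synth_rating_profile()
  latent <- profile$base + profile$shift * config$delta * label +
    stats::rnorm(9, 0, 0.4)
  mat <- matrix(NA_real_, 9, 4,
                dimnames = list(spec$attribute, paste0("r", 1:4)))
  jitter <- matrix(stats::rnorm(32, 0, config$reader_jitter), 8, 4)
  for (i in 1:8) {
    mat[i, ] <- clamp(round_half_up(latent[i] + jitter[i, ]),
                      spec$lo[i], spec$hi[i])
  }
  mat["diameter", ] <- rep(clamp(latent["diameter"], 3, spec$hi[9]), 4)
  mat
}

#' Generate a labelled synthetic dataset
#'
#' Draws the requested number of nodules at the requested prevalence
#' (counts fixed by rounding, order shuffled), each with a cube from
#' [gen_cube()] and ratings from [gen_ratings()]. All randomness flows
#' from `config$seed`; the same config always yields the identical
#' dataset.
#'
#' @param config A [synth_config()].
#' @return A `noduleca_dataset`: list of `samples` (each with
#'   `nodule_id`, `ratings`, `cube`, `label`), a `manifest` tibble and
#'   the generating `config`.
#' @export
gen_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "noduleca_synth_config"))
  withr::with_seed(config$seed, {
    n <- config$n_samples
    n_mal <- round(n * config$malignant_fraction)
    labels <- sample(c(rep(1L, n_mal), rep(0L, n - n_mal)))
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      cube <- gen_cube(labels[i], config)
      cube$nodule_id <- sprintf("synth-%04d", i)
      samples[[i]] <- list(
        nodule_id = cube$nodule_id,
        ratings = gen_ratings(labels[i], config),
        cube = cube,
        label = labels[i]
      )
    }
    structure(
      list(samples = samples,
           manifest = tibble::tibble(
             nodule_id = vapply(samples, `[[`, "", "nodule_id"),
             label = labels),
           config = config),
      class = "noduleca_dataset"
    )
  })
}

#' @export
print.noduleca_dataset <- function(x, ...) {
  cat(sprintf(
    "<noduleca_dataset> %d samples (%d benign, %d malignant), delta=%g, seed=%d\n",
    length(x$samples), sum(x$manifest$label == 0),
    sum(x$manifest$label == 1), x$config$delta %||% NA, x$config$seed))
  invisible(x)
}

#' Write / read a dataset directory
#'
#' One directory per dataset: `samples.rds` (the labelled samples),
#' `manifest.csv` and `config.json`. The synthetic generator and the
#' preprocessing pipeline both write this layout, so downstream code
#' loads either through the same reader; the round trip is exact.
#'
#' @param dataset A `noduleca_dataset`.
#' @param dir Directory path.
#' @return `dir` invisibly (write); the dataset (read).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(dataset$samples, file.path(dir, "samples.rds"))
  readr::write_csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   progress = FALSE)
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  samples <- readRDS(file.path(dir, "samples.rds"))
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  structure(list(samples = samples, manifest = manifest, config = config),
            class = "noduleca_dataset")
}
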