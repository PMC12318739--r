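# Fixtures are built in code at test time: a small hand-constructed
# annotation table exercising every cohort rule, an XML writer mirroring
# the clustered LIDC-style reader, and tiny synthetic volumes.

toy_reader_row <- function(scan, nodule, reader, malignancy, diameter,
                           subtlety = 3, internal_structure = 1,
                           calcification = 5, sphericity = 4, margin = 4,
                           lobulation = 2, spiculation = 2, texture = 5,
                           centre = c(16, 16, 16)) {
  tibble::tibble(
    scan_id = scan, nodule_id = nodule, reader_id = reader,
    subtlety = subtlety, internal_structure = internal_structure,
    calcification = calcification, sphericity = sphericity,
    margin = margin, lobulation = lobulation, spiculation = spiculation,
    texture = texture, malignancy = malignancy, diameter_mm = diameter,
    centre_z = centre[1], centre_y = centre[2], centre_x = centre[3]
  )
}

# 6 nodules: 2 benign, 2 malignant, 1 excluded (consensus 3),
# 1 rejected (< 3 mm). n1 has a missing margin for one of 4 readers
# (imputable); n4 has only 3 readers (fourth column imputed).
make_toy_annotations <- function() {
  dplyr::bind_rows(
    purrr::map2_dfr(paste0("r", 1:4), c(1, 2, 2, 1), function(r, mal) {
      toy_reader_row("s1", "n1", r, mal, 8,
                     margin = if (r == "r3") NA_real_ else 4)
    }),
    purrr::map2_dfr(paste0("r", 1:3), c(1, 1, 2), function(r, mal) {
      toy_reader_row("s1", "n2", r, mal, 5)
    }),
    purrr::map2_dfr(paste0("r", 1:4), c(5, 4, 4, 5), function(r, mal) {
      toy_reader_row("s2", "n3", r, mal, 15, spiculation = 5,
                     lobulation = 4)
    }),
    purrr::map2_dfr(paste0("r", 1:3), c(4, 4, 5), function(r, mal) {
      toy_reader_row("s2", "n4", r, mal, 12, subtlety = c(r1 = 4, r2 = 2,
                                                          r3 = 3)[[r]])
    }),
    purrr::map2_dfr(paste0("r", 1:3), c(3, 3, 3), function(r, mal) {
      toy_reader_row("s3", "n5", r, mal, 6)
    }),
    purrr::map2_dfr(paste0("r", 1:4), c(4, 5, 4, 4), function(r, mal) {
      toy_reader_row("s3", "n6", r, mal, 2.5)
    })
  )
}

# write an annotation tibble as the clustered XML layout read by
# read_annotations_xml()
write_annotations_xml <- function(annotations, path) {
  doc <- xml2::xml_new_root("annotationSession")
  per_reader <- c("subtlety", "internal_structure", "calcification",
                  "sphericity", "margin", "lobulation", "spiculation",
                  "texture", "malignancy")
  for (sid in unique(annotations$scan_id)) {
    scan_node <- xml2::xml_add_child(doc, "scan", id = sid)
    scan_rows <- annotations[annotations$scan_id == sid, ]
    for (nid in unique(scan_rows$nodule_id)) {
      rows <- scan_rows[scan_rows$nodule_id == nid, ]
      nod <- xml2::xml_add_child(
        scan_node, "nodule", id = nid,
        diameterMm = format(rows$diameter_mm[1]),
        centreZ = format(rows$centre_z[1]),
        centreY = format(rows$centre_y[1]),
        centreX = format(rows$centre_x[1]))
      for (i in seq_len(nrow(rows))) {
        rd <- xml2::xml_add_child(nod, "reading",
                                  reader = rows$reader_id[i])
        for (f in per_reader) {
          val <- rows[[f]][i]
          if (!is.na(val)) {
            xml2::xml_add_child(rd, f, format(val))
          }
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# small deterministic HU volume for resampling/extraction tests
make_toy_volume <- function(n = c(20L, 20L, 20L), spacing = c(2, 2, 2),
                            origin = c(0, 0, 0), seed = 99) {
  withr::with_seed(seed, {
    ct_volume(array(stats::rnorm(prod(n), mean = -400, sd = 300), dim = n),
              spacing = spacing, origin = origin, scan_id = "toy")
  })
}

tiny_model_config <- function(...) {
  model_config(model_dim = 16L, n_blocks = 1L, n_heads = 4L,
               ffn_dim = 32L, dropout = 0, ...)
}
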