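#' The thirteen koi variety specifications
#'
#' Registry of the thirteen ornamental koi varieties the classifier
#' distinguishes, each paired with the procedural pattern recipe the synthetic
#' renderer uses to emulate that variety's discriminative visual cue: the red
#' head disc of Tancho, the two- and three-colour patch layouts of Kohaku,
#' Taisho and Showa, the metallic sheen of the Hikari groups and Ogon, Asagi's
#' reticulated back, Kinginrin's sparkling scales, and so on. The recipes are
#' stylised stand-ins for the real phenotypes — each maps one named field cue
#' to a geometric program with a known ground-truth mask, which is what makes
#' visual-attention checks on the trained network assertable.
#'
#' @return A tibble with one row per variety: `class_id` (0–12, fixed),
#'   `class_name` (the abbreviated variety name), `recipe` (pattern program),
#'   `body_color` / `patch_colors` (sRGB in `[0,1]`, list-columns),
#'   `patch_range` (admissible patch count, list-column of length-2 integer
#'   vectors), and logical cue flags `sheen`, `sparkle`, `reticulated`,
#'   `head_disc`.
#' @examples
#' variety_registry()
#' @export
variety_registry <- function() {
  rgb_ <- function(r, g, b) c(r, g, b)
  tibble::tibble(
    class_id = 0:12,
    class_name = c("Tancho", "Hikariu", "Utsurimono", "Bekko", "Kawarimono",
                   "Taisho", "Showa", "Asagi", "Kohaku", "Hikarim", "Koromo",
                   "Kinginrin", "Ogon"),
    recipe = c("head_disc", "sheen_patches", "two_color_patches", "spot_scatter",
               "solid", "three_color_patches", "three_color_patches",
               "reticulated", "two_color_patches", "sheen_patches",
               "two_color_patches", "scale_sparkle", "sheen_gradient"),
    body_color = list(
      rgb_(0.97, 0.97, 0.95),  # Tancho: white ground
      rgb_(0.80, 0.82, 0.86),  # Hikariu: metallic silver
      rgb_(0.12, 0.12, 0.13),  # Utsurimono: black ground
      rgb_(0.96, 0.96, 0.93),  # Bekko: white ground
      rgb_(0.45, 0.55, 0.28),  # Kawarimono: olive green
      rgb_(0.97, 0.96, 0.94),  # Taisho: white ground
      rgb_(0.15, 0.14, 0.15),  # Showa: black ground
      rgb_(0.42, 0.52, 0.68),  # Asagi: blue-grey back
      rgb_(0.98, 0.97, 0.95),  # Kohaku: white ground
      rgb_(0.88, 0.72, 0.35),  # Hikarim: metallic gold
      rgb_(0.95, 0.94, 0.93),  # Koromo: white ground
      rgb_(0.93, 0.93, 0.94),  # Kinginrin: white ground
      rgb_(0.93, 0.82, 0.25)   # Ogon: metallic yellow
    ),
    patch_colors = list(
      list(rgb_(0.85, 0.10, 0.08)),                         # red disc
      list(rgb_(0.10, 0.10, 0.11)),                         # black patches
      list(rgb_(0.95, 0.95, 0.92)),                         # white patches
      list(rgb_(0.10, 0.10, 0.11)),                         # black spots
      list(),
      list(rgb_(0.85, 0.12, 0.08), rgb_(0.10, 0.10, 0.11)), # red + black
      list(rgb_(0.85, 0.12, 0.08), rgb_(0.94, 0.94, 0.92)), # red + white
      list(rgb_(0.85, 0.30, 0.12)),                         # red belly band
      list(rgb_(0.86, 0.12, 0.07)),                         # red patches
      list(rgb_(0.83, 0.14, 0.10)),                         # red patches
      list(rgb_(0.48, 0.10, 0.22)),                         # maroon (robed) patches
      list(rgb_(1.00, 1.00, 1.00)),                         # sparkle highlights
      list()
    ),
    patch_range = list(
      c(1L, 1L), c(2L, 4L), c(2L, 4L), c(4L, 7L), c(0L, 0L),
      c(3L, 5L), c(3L, 5L), c(1L, 1L), c(2L, 4L), c(2L, 3L),
      c(2L, 4L), c(20L, 35L), c(0L, 0L)
    ),
    sheen = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
              TRUE, FALSE, FALSE, TRUE),
    sparkle = c(rep(FALSE, 11), TRUE, FALSE),
    reticulated = c(rep(FALSE, 7), TRUE, rep(FALSE, 5)),
    head_disc = c(TRUE, rep(FALSE, 12))
  )
}

#' Look up one variety specification
#'
#' @param class_id Integer class id in 0–12.
#' @return One-row tibble from [variety_registry()].
#' @export
variety_spec <- function(class_id) {
  reg <- variety_registry()
  row <- reg[reg$class_id == class_id, ]
  if (nrow(row) != 1L) {
    stop_koi(sprintf("Unknown class_id %s; registry holds ids 0-12.", class_id),
             "koi_registry_error")
  }
  row
}
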