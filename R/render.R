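#' Rendering configuration for the synthetic koi generator
#'
#' @param image_size Side length in pixels of the square output image
#'   (minimum 32; default 128).
#' @param seed Integer seed; together with the class id it fully determines
#'   the output bytes.
#' @param background `"flat"` for a uniform water tone or `"ripple"` for a
#'   sinusoidally textured one.
#' @param pose_jitter Fraction of the image size by which the fish centre,
#'   orientation and scale are jittered.
#' @param patch_jitter Relative jitter applied to patch placement and size.
#' @return A list of class `koi_render_config`.
#' @export
render_config <- function(image_size = 128, seed = 1L,
                          background = c("flat", "ripple"),
                          pose_jitter = 0.05, patch_jitter = 0.25) {
  background <- match.arg(background)
  if (!is_count(image_size) || image_size < 32) {
    stop_koi("`image_size` must be an integer >= 32.", "koi_argument_error")
  }
  structure(list(image_size = as.integer(image_size), seed = as.integer(seed),
                 background = background, pose_jitter = pose_jitter,
                 patch_jitter = patch_jitter),
            class = "koi_render_config")
}

# Elliptical membership in body coordinates (u along the axis, v across).
ellipse_mask <- function(u, v, cu, cv, au, av) {
  ((u - cu) / au)^2 + ((v - cv) / av)^2 <= 1
}

#' Render one synthetic variety image
#'
#' Draws a stylised fish silhouette on a water background and decorates it
#' according to the variety's pattern recipe (head disc, colour patches,
#' metallic sheen, reticulation, sparkle). Alongside the RGB image the
#' renderer emits the ground-truth silhouette and pattern masks, which is what
#' makes class-signature and visual-attention checks assertable downstream.
#'
#' @param class_id Variety class id, 0-12 (see [variety_registry()]).
#' @param cfg A [render_config()].
#' @return An object of class `koi_image`: a list with `image`
#'   (`image_size x image_size x 3` array in `[0,1]`), logical matrices
#'   `silhouette` and `pattern`, `class_id`, `class_name`, `pose` (centre,
#'   angle, half-axes and head centre in pixel coordinates) and `seed`.
#' @examples
#' img <- render_variety_image(0, render_config(seed = 7))
#' dim(img$image)
#' @export
render_variety_image <- function(class_id, cfg = render_config()) {
  spec <- variety_spec(class_id)
  S <- cfg$image_size
  with_seed_(derive_seed(cfg$seed, class_id, 977L), {
    # background
    img <- array(0, c(S, S, 3))
    bg <- c(0.62, 0.74, 0.84)
    for (ch in 1:3) img[, , ch] <- bg[ch]
    if (cfg$background == "ripple") {
      rows <- matrix(seq_len(S), S, S)
      cols <- matrix(seq_len(S), S, S, byrow = TRUE)
      rip <- 0.035 * sin(2 * pi * (rows / runif(1, 18, 30) +
                                   cols / runif(1, 22, 36)) + runif(1, 0, 2 * pi))
      for (ch in 1:3) img[, , ch] <- img[, , ch] + rip
    }

    # pose
    j <- cfg$pose_jitter * S
    cy <- S / 2 + runif(1, -j, j)
    cx <- S / 2 + runif(1, -j, j)
    th <- runif(1, -0.12, 0.12)
    sc <- runif(1, 0.88, 1.05)
    a <- 0.33 * S * sc   # half-length along body axis
    b <- 0.15 * S * sc   # half-height across

    rows <- matrix(seq_len(S), S, S)
    cols <- matrix(seq_len(S), S, S, byrow = TRUE)
    u <- (cols - cx) * cos(th) + (rows - cy) * sin(th)
    v <- -(cols - cx) * sin(th) + (rows - cy) * cos(th)

    body <- ellipse_mask(u, v, 0, 0, a, b)
    tail <- ellipse_mask(u, v, -1.08 * a, 0, 0.35 * a, 0.55 * b)
    sil <- body | tail

    # base coat
    bc <- spec$body_color[[1]]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sil] <- bc[ch]
      img[, , ch] <- plane
    }
    if (spec$sheen) {
      # metallic sheen: smooth luminance gradient across the body
      g <- 0.78 + 0.45 * (v / b + 1) / 2
      g <- pmin(pmax(g, 0.6), 1.25)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sil] <- clamp01((plane * g)[sil])
        img[, , ch] <- plane
      }
    }
    if (spec$reticulated) {
      # net-like scale edges on the back half
      net <- ((u %% 7) < 1.4 | (v %% 7) < 1.4) & sil & (v < 0.35 * b)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[net] <- plane[net] * 0.72
        img[, , ch] <- plane
      }
    }

    # pattern decoration per recipe
    pat <- matrix(FALSE, S, S)
    colors <- spec$patch_colors[[1]]
    rng <- spec$patch_range[[1]]
    n_pat <- if (rng[2] >= rng[1] && rng[2] > 0)
      sample(seq(rng[1], rng[2]), 1) else 0L
    pj <- cfg$patch_jitter
    recipe <- spec$recipe

    paint <- function(img, mask, col) {
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- col[ch]
        img[, , ch] <- plane
      }
      img
    }

    if (recipe == "head_disc") {
      hu <- 0.68 * a
      du <- hu + runif(1, -0.06, 0.06) * a
      dv <- runif(1, -0.15, 0.15) * b
      r0 <- 0.62 * b * runif(1, 1 - pj / 3, 1 + pj / 3)
      disc <- ellipse_mask(u, v, du, dv, r0, r0) & sil
      img <- paint(img, disc, colors[[1]])
      pat <- pat | disc
    } else if (recipe %in% c("two_color_patches", "three_color_patches",
                             "sheen_patches", "spot_scatter")) {
      small <- recipe == "spot_scatter"
      for (k in seq_len(n_pat)) {
        col <- colors[[(k - 1) %% length(colors) + 1]]
        # placement avoids overpainting earlier patches: a later patch must
        # not cover what makes the class signature visible
        best <- NULL; best_ov <- Inf
        for (try in 1:25) {
          pu <- runif(1, -0.65, 0.65) * a
          pv <- runif(1, -0.55, 0.55) * b
          if (small) {
            ru <- runif(1, 0.14, 0.22) * b
            rv <- ru * runif(1, 0.8, 1.2)
          } else {
            ru <- runif(1, 0.22, 0.34) * a * runif(1, 1 - pj, 1 + pj)
            rv <- runif(1, 0.45, 0.7) * b
          }
          patch <- ellipse_mask(u, v, pu, pv, ru, rv) & sil
          npx <- sum(patch)
          if (npx == 0) next
          ov <- sum(patch & pat) / npx
          if (ov < best_ov) { best <- patch; best_ov <- ov }
          if (ov < 0.25) break
        }
        if (is.null(best)) next
        img <- paint(img, best, col)
        pat <- pat | best
      }
    } else if (recipe == "reticulated") {
      # red belly band below the lateral line
      band <- sil & (v > 0.45 * b)
      img <- paint(img, band, colors[[1]])
      pat <- pat | band
    } else if (recipe == "scale_sparkle") {
      for (k in seq_len(n_pat)) {
        pu <- runif(1, -0.8, 0.8) * a
        pv <- runif(1, -0.7, 0.7) * b
        r0 <- runif(1, 1.2, 2.2)
        dot <- ellipse_mask(u, v, pu, pv, r0, r0) & sil
        img <- paint(img, dot, colors[[1]])
        pat <- pat | dot
      }
    }
    # recipes "solid" and "sheen_gradient" add no pattern

    # eye: a small dark dot near the head, common to all classes
    eye <- ellipse_mask(u, v, 0.8 * a, -0.3 * b, 0.09 * b, 0.09 * b) & sil
    img <- paint(img, eye, c(0.05, 0.05, 0.05))

    img <- clamp01(img + array(rnorm(S * S * 3, 0, 0.012), c(S, S, 3)))

    head_px <- c(
      y = cy + sin(th) * 0.68 * a,
      x = cx + cos(th) * 0.68 * a
    )
    structure(list(
      image = img, silhouette = sil, pattern = pat,
      class_id = spec$class_id, class_name = spec$class_name,
      pose = list(center = c(y = cy, x = cx), angle = th, a = a, b = b,
                  head_center = head_px),
      seed = cfg$seed
    ), class = "koi_image")
  })
}

#' Check a rendered image against its variety's signature predicate
#'
#' Every pattern recipe implies a verifiable signature on the emitted masks:
#' the Tancho-like head disc must be a single red component whose centroid
#' lies in the head region, patch recipes must produce a plausible number of
#' pattern components, solid and sheen-only recipes must leave the pattern
#' mask empty, and so on.
#'
#' @param sample A `koi_image` from [render_variety_image()].
#' @return `TRUE` if the sample satisfies its class signature, else `FALSE`.
#' @export
class_signature_ok <- function(sample) {
  stopifnot(inherits(sample, "koi_image"))
  spec <- variety_spec(sample$class_id)
  recipe <- spec$recipe
  pat <- sample$pattern
  n_comp <- pattern_component_count(pat)
  rng <- spec$patch_range[[1]]
  if (recipe %in% c("solid", "sheen_gradient")) {
    return(!any(pat))
  }
  if (!any(pat)) return(FALSE)
  if (recipe == "head_disc") {
    idx <- which(pat, arr.ind = TRUE)
    cen <- colMeans(idx)  # (row, col)
    pose <- sample$pose
    u_cen <- (cen[2] - pose$center["x"]) * cos(pose$angle) +
             (cen[1] - pose$center["y"]) * sin(pose$angle)
    return(n_comp == 1L && u_cen > 0.35 * pose$a && mean_is_reddish(sample))
  }
  if (recipe == "scale_sparkle") return(n_comp >= rng[1] / 2 && n_comp <= rng[2] * 1.5)
  if (recipe == "reticulated") return(n_comp >= 1L)
  # patch recipes: overlap can merge patches, so allow [1, max]; every
  # palette colour must also be visibly present, which is what makes a
  # three-colour layout a three-colour layout
  n_comp >= 1L && n_comp <= rng[2] && all_colors_visible(sample, spec)
}

all_colors_visible <- function(sample, spec, min_px = 12L) {
  pat <- sample$pattern
  if (!any(pat)) return(FALSE)
  px <- cbind(sample$image[, , 1][pat], sample$image[, , 2][pat],
              sample$image[, , 3][pat])
  all(vapply(spec$patch_colors[[1]], function(col) {
    d2 <- rowSums(sweep(px, 2, col)^2)
    sum(d2 < 0.09) >= min_px
  }, logical(1)))
}

mean_is_reddish <- function(sample) {
  pat <- sample$pattern
  r <- mean(sample$image[, , 1][pat])
  g <- mean(sample$image[, , 2][pat])
  b <- mean(sample$image[, , 3][pat])
  r > g + 0.2 && r > b + 0.2
}

# Count pattern components of at least `min_px` pixels.
pattern_component_count <- function(mask, min_px = 4L) {
  if (!any(mask)) return(0L)
  lab <- label_components_cpp(mask)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= min_px)
}

#' Write a `koi_image` and its masks to PNG files
#'
#' @param sample A `koi_image`.
#' @param path Output path of the RGB PNG; masks are written alongside it as
#'   `<stem>_silhouette.png` and `<stem>_pattern.png`.
#' @return `path`, invisibly.
#' @export
write_koi_image <- function(sample, path) {
  stopifnot(inherits(sample, "koi_image"))
  png::writePNG(sample$image, path)
  stem <- sub("\\.png$", "", path)
  png::writePNG(sample$silhouette * 1, paste0(stem, "_silhouette.png"))
  png::writePNG(sample$pattern * 1, paste0(stem, "_pattern.png"))
  invisible(path)
}

#' Generate a synthetic thirteen-class dataset on disk
#'
#' Renders `n_per_class` images for each of the thirteen varieties, writes
#' them (plus ground-truth masks) under `out_dir`, and returns the dataset
#' manifest. A fixed seed reproduces the dataset bit for bit.
#'
#' @param n_per_class Images per variety (>= 1).
#' @param cfg A [render_config()]; its seed drives every image.
#' @param out_dir Output directory (created if missing).
#' @return The manifest tibble (also written to `out_dir/manifest.csv`) with
#'   columns `path`, `class_id`, `class_name`, `split`, `provenance`,
#'   `transform_json`, `seed`.
#' @export
generate_dataset <- function(n_per_class, cfg = render_config(), out_dir) {
  if (!is_count(n_per_class) || n_per_class < 1) {
    stop_koi("`n_per_class` must be a positive integer.", "koi_argument_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reg <- variety_registry()
  rows <- purrr::map_dfr(reg$class_id, function(cid) {
    purrr::map_dfr(seq_len(n_per_class), function(i) {
      s <- derive_seed(cfg$seed, cid, i)
      icfg <- cfg
      icfg$seed <- s
      img <- render_variety_image(cid, icfg)
      fn <- file.path(out_dir, sprintf("class%02d_%04d.png", cid, i))
      write_koi_image(img, fn)
      tibble::tibble(path = fn, class_id = cid,
                     class_name = reg$class_name[reg$class_id == cid],
                     split = "unassigned", provenance = "original",
                     transform_json = "", seed = s)
    })
  })
  write_manifest(rows, file.path(out_dir, "manifest.csv"))
  rows
}

#' Leave-one-out separability of a rendered dataset
#'
#' Guards end-to-end runs: classifies every image with a nearest-class-mean
#' rule on cheap features (per-channel mean colour plus pattern-component
#' count), leaving the image itself out of its class mean. The default
#' generator configuration is designed to score well above chance here, which
#' is what makes the pipeline-level accuracy checks meaningful.
#'
#' @param manifest A dataset manifest whose `path`s point at rendered PNGs.
#' @param labels Optional integer vector overriding `manifest$class_id`
#'   (used for permutation-null checks).
#' @return Leave-one-out accuracy in `[0, 1]`.
#' @export
separability_check <- function(manifest, labels = NULL) {
  validate_manifest(manifest)
  y <- if (is.null(labels)) manifest$class_id else as.integer(labels)
  if (length(unique(y)) < 2) {
    stop_koi("separability_check needs at least two classes.", "koi_degenerate_error")
  }
  feats <- t(vapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(manifest$path[i])
    stem <- sub("\\.png$", "", manifest$path[i])
    pf <- paste0(stem, "_pattern.png")
    npat <- if (file.exists(pf)) {
      pattern_component_count(png::readPNG(pf) > 0.5)
    } else 0L
    c(mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3]), npat)
  }, numeric(4)))
  sds <- apply(feats, 2, stats::sd)
  sds[sds == 0] <- 1
  feats <- sweep(feats, 2, sds, "/")
  n <- nrow(feats)
  correct <- 0L
  classes <- sort(unique(y))
  sums <- rowsum(feats, y)
  cnts <- as.vector(table(factor(y, levels = classes)))
  for (i in seq_len(n)) {
    ci <- match(y[i], classes)
    mu <- sums
    cn <- cnts
    mu[ci, ] <- mu[ci, ] - feats[i, ]
    cn[ci] <- cn[ci] - 1L
    if (cn[ci] == 0L) next  # lone sample: its class has no mean to compare to
    mu <- mu / cn
    d <- rowSums(sweep(mu, 2, feats[i, ])^2)
    if (classes[which.min(d)] == y[i]) correct <- correct + 1L
  }
  correct / n
}
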