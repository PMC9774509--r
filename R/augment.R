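AUG_KINDS <- c("brightness", "contrast", "chroma", "mirror", "rotate", "translate")

#' Construct an augmentation operator
#'
#' One of the six photometric/geometric operators used to enlarge and balance
#' the image set: brightness, contrast and chroma scaling, mirroring,
#' rotation, and horizontal/vertical translation. Geometric operators keep
#' the image size and fill uncovered pixels by edge replication, so borders
#' never become an artificial class cue.
#'
#' @param kind Operator kind, one of
#'   `"brightness"`, `"contrast"`, `"chroma"`, `"mirror"`, `"rotate"`,
#'   `"translate"`.
#' @param factor Positive multiplier (brightness/contrast/chroma).
#' @param axis `"horizontal"` or `"vertical"` (mirror).
#' @param degrees Rotation angle, `|degrees| <= 180`.
#' @param dx,dy Translation in pixels (right/down positive).
#' @return A list of class `koi_augment_op`.
#' @export
augment_op <- function(kind, factor = 1, axis = "horizontal", degrees = 0,
                       dx = 0, dy = 0) {
  kind <- match.arg(kind, AUG_KINDS)
  if (kind %in% c("brightness", "contrast", "chroma") && factor <= 0) {
    stop_koi("`factor` must be > 0.", "koi_argument_error")
  }
  if (kind == "mirror") axis <- match.arg(axis, c("horizontal", "vertical"))
  if (kind == "rotate" && abs(degrees) > 180) {
    stop_koi("`degrees` must satisfy |degrees| <= 180.", "koi_argument_error")
  }
  structure(list(kind = kind, factor = factor, axis = axis,
                 degrees = degrees, dx = dx, dy = dy),
            class = "koi_augment_op")
}

#' Apply an augmentation operator to an image
#'
#' @param image `(H, W, 3)` array in `[0,1]`.
#' @param op A [augment_op()] (or a list of them, applied in order).
#' @return The transformed image, same dimensions.
#' @export
apply_augment <- function(image, op) {
  if (is.list(op) && !inherits(op, "koi_augment_op")) {
    for (o in op) image <- apply_augment(image, o)
    return(image)
  }
  stopifnot(inherits(op, "koi_augment_op"), length(dim(image)) == 3)
  d <- dim(image)
  if (op$kind %in% c("translate", "rotate") &&
      (abs(op$dx) >= d[2] || abs(op$dy) >= d[1])) {
    stop_koi("Translation exceeds the image size.", "koi_argument_error")
  }
  switch(op$kind,
    brightness = clamp01(image * op$factor),
    contrast = {
      m <- mean(image)
      clamp01((image - m) * op$factor + m)
    },
    chroma = {
      # saturation scaling in HSV space, in full double precision
      px <- matrix(aperm(image, c(3, 1, 2)), nrow = 3)
      hsv <- grDevices::rgb2hsv(px, maxColorValue = 1)
      s <- pmin(hsv[2, ] * op$factor, 1)
      h6 <- hsv[1, ] * 6
      v <- hsv[3, ]
      i <- floor(h6) %% 6
      f <- h6 - floor(h6)
      p <- v * (1 - s); q <- v * (1 - s * f); t1 <- v * (1 - s * (1 - f))
      r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
             ifelse(i == 3, p, ifelse(i == 4, t1, v)))))
      g2 <- ifelse(i == 0, t1, ifelse(i == 1, v, ifelse(i == 2, v,
             ifelse(i == 3, q, ifelse(i == 4, p, p)))))
      b2 <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t1,
             ifelse(i == 3, v, ifelse(i == 4, v, q)))))
      out <- rbind(r, g2, b2)
      aperm(array(out, c(3, d[1], d[2])), c(2, 3, 1))
    },
    mirror = {
      if (op$axis == "horizontal") image[, rev(seq_len(d[2])), , drop = FALSE]
      else image[rev(seq_len(d[1])), , , drop = FALSE]
    },
    rotate = {
      th <- op$degrees * pi / 180
      # output (r, c) samples input rotated by -th about the centre
      warp_affine_cpp(image, c(cos(th), -sin(th), sin(th), cos(th)), c(0, 0))
    },
    translate = warp_affine_cpp(image, c(1, 0, 0, 1), c(-op$dy, -op$dx))
  )
}

#' Plan class balancing by augmentation
#'
#' Given per-class original and target counts, computes how many augmented
#' copies each class needs (`n_augment = target - original`). Down-sampling
#' is not part of this scheme, so targets below the original counts are an
#' error. With the published study counts this reproduces the augmentation
#' column of the study's bookkeeping table (e.g. 74 copies for Tancho, none
#' for Showa).
#'
#' @param original_counts,target_counts Equal-length non-negative integer
#'   vectors; names (or the order) identify classes.
#' @param class_id Optional class ids (default `0:(k-1)`).
#' @return Tibble of class `koi_balance_plan`: `class_id`, `original`,
#'   `target`, `n_augment`.
#' @examples
#' counts <- variety_image_counts()
#' plan_balance(counts$original, counts$after_augmentation)
#' @export
plan_balance <- function(original_counts, target_counts,
                         class_id = seq_along(original_counts) - 1L) {
  if (length(original_counts) != length(target_counts)) {
    stop_koi("Count vectors must have equal length.", "koi_argument_error")
  }
  if (any(target_counts < original_counts)) {
    stop_koi("Targets below original counts: this scheme only adds images.",
             "koi_plan_error")
  }
  tibble::new_tibble(tibble::tibble(
    class_id = as.integer(class_id),
    original = as.integer(original_counts),
    target = as.integer(target_counts),
    n_augment = as.integer(target_counts - original_counts)
  ), class = "koi_balance_plan")
}

# Draw a random 1-3 operator chain with the package's default parameter
# ranges (factors 0.7-1.3, rotation within +/-25 degrees, translation up to
# 10% of the image size).
sample_op_chain <- function(img_size) {
  n_ops <- sample(1:3, 1)
  kinds <- sample(AUG_KINDS, n_ops)
  lapply(kinds, function(k) {
    switch(k,
      brightness = augment_op("brightness", factor = runif(1, 0.7, 1.3)),
      contrast = augment_op("contrast", factor = runif(1, 0.7, 1.3)),
      chroma = augment_op("chroma", factor = runif(1, 0.7, 1.3)),
      mirror = augment_op("mirror", axis = sample(c("horizontal", "vertical"), 1)),
      rotate = augment_op("rotate", degrees = runif(1, -25, 25)),
      translate = augment_op("translate",
                             dx = round(runif(1, -0.1, 0.1) * img_size),
                             dy = round(runif(1, -0.1, 0.1) * img_size))
    )
  })
}

op_chain_json <- function(chain) {
  jsonlite::toJSON(lapply(chain, function(o) {
    o <- unclass(o)
    o[c("kind", switch(o$kind,
                       brightness = , contrast = , chroma = "factor",
                       mirror = "axis", rotate = "degrees",
                       translate = c("dx", "dy")))]
  }), auto_unbox = TRUE, digits = 6)
}

#' Execute a balancing plan on a manifest
#'
#' Adds exactly `n_augment` augmented rows per class. Source images are the
#' class's *original* rows, cycled round-robin; each new row records its
#' seeded 1-3 operator chain as JSON in `transform_json`. When
#' `materialize = TRUE` the transformed images are written next to their
#' sources; otherwise only the manifest grows (count bookkeeping).
#'
#' @param m A manifest.
#' @param plan A [plan_balance()] result whose classes are present in `m`.
#' @param seed Integer seed driving operator sampling.
#' @param materialize Write the augmented PNGs (default `TRUE` when the
#'   source files exist).
#' @return The enlarged manifest.
#' @export
execute_plan <- function(m, plan, seed = 1L,
                         materialize = all(file.exists(m$path))) {
  validate_manifest(m)
  stopifnot(inherits(plan, "koi_balance_plan"))
  new_rows <- list()
  with_seed_(derive_seed(seed, 409L), {
    for (r in seq_len(nrow(plan))) {
      cid <- plan$class_id[r]
      n_aug <- plan$n_augment[r]
      if (n_aug == 0) next
      src <- m[m$class_id == cid & m$provenance == "original", ]
      if (nrow(src) == 0) {
        stop_koi(sprintf("Class %d has no original images to augment.", cid),
                 "koi_plan_error")
      }
      src <- src[order(src$path), ]
      for (k in seq_len(n_aug)) {
        s_row <- src[(k - 1) %% nrow(src) + 1, ]
        size_guess <- 128L
        img <- NULL
        if (materialize) {
          img <- png::readPNG(s_row$path)
          if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
          if (dim(img)[3] > 3) img <- img[, , 1:3]
          size_guess <- max(dim(img)[1:2])
        }
        chain <- sample_op_chain(size_guess)
        new_path <- paste0(sub("\\.png$", "", s_row$path),
                           sprintf("_aug%04d.png", k))
        if (materialize) {
          png::writePNG(clamp01(apply_augment(img, chain)), new_path)
        }
        new_rows[[length(new_rows) + 1]] <- tibble::tibble(
          path = new_path, class_id = cid, class_name = s_row$class_name,
          split = "unassigned", provenance = "augmented",
          transform_json = as.character(op_chain_json(chain)),
          seed = derive_seed(seed, cid, k)
        )
      }
    }
  })
  out <- dplyr::bind_rows(m, !!!new_rows)
  validate_manifest(out)
  out
}
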