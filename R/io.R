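# Annotation and image I/O: COCO JSON (the native annotation dialect),
# LabelMe JSON (convertible input), PNG images, letterbox preprocessing.

#' The five posture categories
#'
#' Fixed category registry: standing (STD), lying-on-belly (LOB),
#' lying-on-side (LOS), sitting (SIT) and mounting (MOT), with category
#' ids 1 to 5 in that order.
#'
#' @return A data frame with columns `id` and `name`.
#' @export
posture_categories <- function() {
  data.frame(id = 1:5, name = c("STD", "LOB", "LOS", "SIT", "MOT"))
}

#' Construct an annotation set
#'
#' The in-memory form of a COCO-style annotation collection: an images
#' table, an annotations table (bboxes as `x, y, w, h` with a 0-based
#' top-left origin and half-open pixel intervals) and a categories table.
#'
#' @param images data frame with columns `id`, `file_name`, `width`,
#'   `height`.
#' @param annotations data frame with columns `id`, `image_id`,
#'   `category_id`, `x`, `y`, `w`, `h` (and optionally `area`, `iscrowd`).
#' @param categories data frame with `id`, `name`; defaults to
#'   [posture_categories()].
#' @param validate run [validate_annotation_set()] on the result.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(images, annotations,
                           categories = posture_categories(),
                           validate = TRUE) {
  if (is.null(annotations$area)) annotations$area <- annotations$w * annotations$h
  if (is.null(annotations$iscrowd)) annotations$iscrowd <- 0L
  aset <- structure(list(images = images, annotations = annotations,
                         categories = categories),
                    class = "annotation_set")
  if (validate) validate_annotation_set(aset)
  aset
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d images, %d annotations, %d categories>\n",
              nrow(x$images), nrow(x$annotations), nrow(x$categories)))
  invisible(x)
}

validation_error <- function(msgs) {
  stop(errorCondition(paste0("validation error:\n", paste("-", msgs, collapse = "\n")),
                      class = c("sdet_validation_error", "error", "condition")))
}

#' Validate an annotation set
#'
#' Checks id uniqueness, referential integrity (every annotation's
#' `image_id` and `category_id` must resolve), finite positive image
#' dimensions, and boxes that are finite, non-negative and inside their
#' image. All violations are collected and reported together.
#'
#' @param aset an [annotation_set()].
#' @return `aset`, invisibly, if valid; otherwise an error of class
#'   `sdet_validation_error` listing every offending record.
#' @export
validate_annotation_set <- function(aset) {
  msgs <- character()
  im <- aset$images
  an <- aset$annotations
  ct <- aset$categories
  if (anyDuplicated(im$id)) {
    msgs <- c(msgs, paste("duplicate image ids:",
                          paste(unique(im$id[duplicated(im$id)]), collapse = ", ")))
  }
  if (nrow(an) && anyDuplicated(an$id)) {
    msgs <- c(msgs, paste("duplicate annotation ids:",
                          paste(unique(an$id[duplicated(an$id)]), collapse = ", ")))
  }
  bad <- which(!is.finite(im$width) | !is.finite(im$height) |
                 im$width <= 0 | im$height <= 0)
  for (i in bad) {
    msgs <- c(msgs, sprintf("image id %s has invalid dimensions %s x %s",
                            im$id[i], im$width[i], im$height[i]))
  }
  if (nrow(an)) {
    dangling <- !an$image_id %in% im$id
    for (i in which(dangling)) {
      msgs <- c(msgs, sprintf("annotation id %s references missing image_id %s",
                              an$id[i], an$image_id[i]))
    }
    badcat <- !an$category_id %in% ct$id
    for (i in which(badcat)) {
      msgs <- c(msgs, sprintf("annotation id %s references missing category_id %s",
                              an$id[i], an$category_id[i]))
    }
    boxbad <- !is.finite(an$x) | !is.finite(an$y) | !is.finite(an$w) |
      !is.finite(an$h) | an$w <= 0 | an$h <= 0 | an$x < 0 | an$y < 0
    for (i in which(boxbad)) {
      msgs <- c(msgs, sprintf("annotation id %s has invalid bbox [%s, %s, %s, %s]",
                              an$id[i], an$x[i], an$y[i], an$w[i], an$h[i]))
    }
    ok <- !boxbad & !dangling
    if (any(ok)) {
      idx <- match(an$image_id, im$id)
      oob <- ok & (an$x + an$w > im$width[idx] + 1e-6 |
                     an$y + an$h > im$height[idx] + 1e-6)
      for (i in which(oob)) {
        msgs <- c(msgs, sprintf("annotation id %s bbox exceeds image %s bounds",
                                an$id[i], an$image_id[i]))
      }
    }
  }
  if (length(msgs)) validation_error(msgs)
  invisible(aset)
}

#' Read and write COCO JSON
#'
#' `read_coco()` parses a COCO annotation file into an [annotation_set()]
#' (validating it); `write_coco()` serialises one back with canonical key
#' ordering, so write-read-write round trips are byte identical.
#'
#' @param path JSON file path.
#' @param validate validate after reading (default `TRUE`).
#' @return `read_coco()` returns an [annotation_set()].
#' @export
read_coco <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                 error = function(e) {
                   validation_error(paste("malformed JSON:", conditionMessage(e)))
                 })
  images <- as.data.frame(js$images)
  cats <- as.data.frame(js$categories)
  an <- js$annotations
  if (is.null(an) || NROW(an) == 0L) {
    annotations <- data.frame(id = integer(), image_id = integer(),
                              category_id = integer(), x = numeric(),
                              y = numeric(), w = numeric(), h = numeric(),
                              area = numeric(), iscrowd = integer())
  } else {
    bb <- an$bbox
    if (is.list(bb)) bb <- do.call(rbind, lapply(bb, as.numeric))
    annotations <- data.frame(id = an$id, image_id = an$image_id,
                              category_id = an$category_id,
                              x = bb[, 1], y = bb[, 2], w = bb[, 3], h = bb[, 4],
                              area = if (!is.null(an$area)) an$area else bb[, 3] * bb[, 4],
                              iscrowd = if (!is.null(an$iscrowd)) an$iscrowd else 0L)
  }
  annotation_set(images[, c("id", "file_name", "width", "height")],
                 annotations, cats[, c("id", "name")], validate = validate)
}

#' @param aset an [annotation_set()].
#' @rdname read_coco
#' @export
write_coco <- function(aset, path) {
  im <- aset$images
  an <- aset$annotations
  ct <- aset$categories
  out <- list(
    images = lapply(seq_len(nrow(im)), function(i) {
      list(id = im$id[i], file_name = im$file_name[i],
           width = im$width[i], height = im$height[i])
    }),
    annotations = lapply(seq_len(nrow(an)), function(i) {
      list(id = an$id[i], image_id = an$image_id[i],
           category_id = an$category_id[i],
           bbox = c(an$x[i], an$y[i], an$w[i], an$h[i]),
           area = an$area[i], iscrowd = an$iscrowd[i])
    }),
    categories = lapply(seq_len(nrow(ct)), function(i) {
      list(id = ct$id[i], name = ct$name[i])
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert LabelMe JSON files to an annotation set
#'
#' LabelMe polygon shapes become bounding boxes via the min/max of their
#' vertices; rectangle shapes pass through. Labels must be posture
#' category names (or be mapped to them via `label_map`); any other label
#' is an error.
#'
#' @param paths character vector of LabelMe JSON file paths.
#' @param label_map optional named character vector mapping LabelMe labels
#'   to category names.
#' @param categories category table (default [posture_categories()]).
#' @return An [annotation_set()].
#' @export
labelme_to_coco <- function(paths, label_map = NULL,
                            categories = posture_categories()) {
  images <- list()
  anns <- list()
  aid <- 0L
  for (i in seq_along(paths)) {
    js <- jsonlite::fromJSON(paths[i], simplifyVector = FALSE)
    images[[i]] <- data.frame(id = i, file_name = js$imagePath %||% basename(paths[i]),
                              width = js$imageWidth, height = js$imageHeight)
    for (sh in js$shapes) {
      label <- sh$label
      if (!is.null(label_map) && label %in% names(label_map)) {
        label <- label_map[[label]]
      }
      cid <- categories$id[match(label, categories$name)]
      if (is.na(cid)) {
        validation_error(sprintf("unknown label '%s' in %s", sh$label, paths[i]))
      }
      pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
      x1 <- min(pts[, 1]); x2 <- max(pts[, 1])
      y1 <- min(pts[, 2]); y2 <- max(pts[, 2])
      aid <- aid + 1L
      anns[[aid]] <- data.frame(id = aid, image_id = i, category_id = cid,
                                x = x1, y = y1, w = x2 - x1, h = y2 - y1)
    }
  }
  annotation_set(do.call(rbind, images),
                 if (length(anns)) do.call(rbind, anns) else
                   data.frame(id = integer(), image_id = integer(),
                              category_id = integer(), x = numeric(),
                              y = numeric(), w = numeric(), h = numeric()),
                 categories)
}

#' Write a LabelMe-style JSON file for one image
#'
#' Emits rectangle shapes for each annotation; useful for round-trip tests
#' of the LabelMe converter.
#'
#' @param annotations data frame with `category_id`, `x`, `y`, `w`, `h`.
#' @param file_name,width,height image metadata.
#' @param path output JSON path.
#' @param categories category table.
#' @export
write_labelme <- function(annotations, file_name, width, height, path,
                          categories = posture_categories()) {
  shapes <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    list(label = categories$name[match(a$category_id, categories$id)],
         points = list(c(a$x, a$y), c(a$x + a$w, a$y + a$h)),
         shape_type = "rectangle")
  })
  jsonlite::write_json(list(imagePath = file_name, imageWidth = width,
                            imageHeight = height, shapes = shapes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- images and letterbox ----------------------------------------------

#' Read / write PNG images
#'
#' Images are numeric arrays in `[0, 1]`, `H x W` (grayscale) or
#' `H x W x 3`.
#'
#' @param path PNG file path.
#' @param image numeric array.
#' @export
read_image <- function(path) png::readPNG(path)

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Letterbox an image to a square network input
#'
#' Aspect-preserving bilinear resize followed by symmetric neutral-gray
#' padding to `target x target`. The returned transform maps boxes in both
#' directions; round trips are exact to well under half a pixel.
#'
#' @param image `H x W` or `H x W x C` numeric array in `[0, 1]`.
#' @param target output side length (must be divisible by 32 for the
#'   network; the function itself accepts any positive size).
#' @param fill padding intensity (default 114/255, the customary neutral
#'   gray).
#' @return A list with `image` (the letterboxed array) and `transform`
#'   (class `letterbox_transform`: `scale`, `pad_x`, `pad_y`, `src_h`,
#'   `src_w`, `target`).
#' @export
letterbox <- function(image, target, fill = 114 / 255) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (h <= 0 || w <= 0) stop("invalid-input: empty image")
  nch <- if (length(d) == 3L) d[3] else 1L
  scale <- min(target / h, target / w)
  nh <- as.integer(max(1, round(h * scale)))
  nw <- as.integer(max(1, round(w * scale)))
  resized <- if (nh == h && nw == w) image else resize_bilinear(image, nh, nw)
  canvas <- array(fill, c(target, target, nch))
  pad_y <- as.integer((target - nh) %/% 2)
  pad_x <- as.integer((target - nw) %/% 2)
  if (length(dim(resized)) == 2L) resized <- array(resized, c(nh, nw, 1L))
  canvas[pad_y + seq_len(nh), pad_x + seq_len(nw), ] <- resized
  if (nch == 1L) canvas <- canvas[, , 1L]
  tr <- structure(list(scale = scale, pad_x = pad_x, pad_y = pad_y,
                       src_h = h, src_w = w, target = target),
                  class = "letterbox_transform")
  list(image = canvas, transform = tr)
}

resize_bilinear <- function(image, nh, nw) {
  d <- dim(image)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    out <- EBImage::resize(image, w = nh, h = nw)
    return(if (length(d) == 2L) as.matrix(out) else as.array(out))
  }
  # plain bilinear fallback
  h <- d[1]; w <- d[2]
  ys <- (seq_len(nh) - 0.5) * h / nh + 0.5
  xs <- (seq_len(nw) - 0.5) * w / nw + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h); fy <- ys - y0
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w); fx <- xs - x0
  fy <- pmin(pmax(fy, 0), 1); fx <- pmin(pmax(fx, 0), 1)
  one <- function(m) {
    a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
      m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
      m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
      m[y1, x1, drop = FALSE] * outer(fy, fx)
    a
  }
  if (length(d) == 2L) return(one(image))
  out <- array(0, c(nh, nw, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- one(image[, , c])
  out
}

#' Map boxes through a letterbox transform
#'
#' @param boxes data frame with columns `x`, `y`, `w`, `h` (top-left
#'   convention).
#' @param transform a `letterbox_transform`.
#' @param direction `"to_target"` (source to letterboxed) or
#'   `"to_source"`.
#' @return The data frame with mapped coordinates.
#' @export
letterbox_boxes <- function(boxes, transform,
                            direction = c("to_target", "to_source")) {
  direction <- match.arg(direction)
  tr <- transform
  if (direction == "to_target") {
    boxes$x <- boxes$x * tr$scale + tr$pad_x
    boxes$y <- boxes$y * tr$scale + tr$pad_y
    boxes$w <- boxes$w * tr$scale
    boxes$h <- boxes$h * tr$scale
  } else {
    boxes$x <- (boxes$x - tr$pad_x) / tr$scale
    boxes$y <- (boxes$y - tr$pad_y) / tr$scale
    boxes$w <- boxes$w / tr$scale
    boxes$h <- boxes$h / tr$scale
  }
  boxes
}

# map centre-format detections back to source-image coordinates, clipping
unletterbox_detections <- function(det, transform, src_dim) {
  if (!nrow(det)) return(det)
  tr <- transform
  det$x <- (det$x - tr$pad_x) / tr$scale
  det$y <- (det$y - tr$pad_y) / tr$scale
  det$w <- det$w / tr$scale
  det$h <- det$h / tr$scale
  x1 <- pmax(det$x - det$w / 2, 0)
  y1 <- pmax(det$y - det$h / 2, 0)
  x2 <- pmin(det$x + det$w / 2, src_dim[2])
  y2 <- pmin(det$y + det$h / 2, src_dim[1])
  keep <- x2 > x1 & y2 > y1
  det <- det[keep, , drop = FALSE]
  if (nrow(det)) {
    det$x <- (x1[keep] + x2[keep]) / 2
    det$y <- (y1[keep] + y2[keep]) / 2
    det$w <- x2[keep] - x1[keep]
    det$h <- y2[keep] - y1[keep]
  }
  det
}

#' Export detections as COCO results
#'
#' Converts centre-format detections to the COCO results convention
#' (`[{image_id, category_id, bbox [x, y, w, h], score}]`, top-left
#' origin).
#'
#' @param det an `sdet_detections` data frame.
#' @param image_id id of the image the detections belong to.
#' @return A data frame with columns `image_id`, `category_id`, `x`, `y`,
#'   `w`, `h`, `score`.
#' @export
detections_to_results <- function(det, image_id) {
  data.frame(image_id = rep(image_id, nrow(det)),
             category_id = det$class_id,
             x = det$x - det$w / 2, y = det$y - det$h / 2,
             w = det$w, h = det$h, score = det$score)
}

#' Write / read COCO results JSON
#'
#' @param results data frame as produced by [detections_to_results()].
#' @param path JSON file path.
#' @export
write_coco_results <- function(results, path) {
  out <- lapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    list(image_id = r$image_id, category_id = r$category_id,
         bbox = c(r$x, r$y, r$w, r$h), score = r$score)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco_results
#' @export
read_coco_results <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (NROW(js) == 0L) {
    return(data.frame(image_id = integer(), category_id = integer(),
                      x = numeric(), y = numeric(), w = numeric(),
                      h = numeric(), score = numeric()))
  }
  bb <- js$bbox
  if (is.list(bb)) bb <- do.call(rbind, lapply(bb, as.numeric))
  data.frame(image_id = js$image_id, category_id = js$category_id,
             x = bb[, 1], y = bb[, 2], w = bb[, 3], h = bb[, 4],
             score = js$score)
}
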