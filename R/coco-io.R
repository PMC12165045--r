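# COCO-dialect instance segmentation JSON, PNG image I/O, and the
# per-instance liveweight table. Only polygon segmentations are used; masks
# can be exchanged as uncompressed COCO-style RLE when needed.

#' Write COCO-format instance annotations
#'
#' @param images data.frame with columns id, file_name, height, width.
#' @param annotations list of lists with elements id, image_id, polygon
#'   (N x 2 matrix, pixel coordinates), and optional score.
#' @param path output JSON path.
#' @export
write_coco <- function(images, annotations, path) {
  anns <- lapply(annotations, function(a) {
    poly <- as_contour(a$polygon)
    seg <- as.vector(t(poly))              # x1,y1,x2,y2,... flattened
    bb <- c(min(poly[, 1]), min(poly[, 2]),
            diff(range(poly[, 1])), diff(range(poly[, 2])))
    out <- list(id = a$id, image_id = a$image_id, category_id = 1L,
                segmentation = list(seg), area = polygon_area(poly),
                bbox = bb, iscrowd = 0L)
    if (!is.null(a$score)) out$score <- a$score
    out
  })
  obj <- list(
    images = lapply(seq_len(nrow(images)), function(i) as.list(images[i, ])),
    annotations = anns,
    categories = list(list(id = 1L, name = "animal", supercategory = "animal"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Read COCO-format instance annotations
#'
#' @param path JSON path written by [write_coco()] or any COCO polygon file.
#' @return list with `images` (data.frame) and `annotations` (list with
#'   `polygon` matrices).
#' @export
read_coco <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  images <- do.call(rbind, lapply(obj$images, function(im)
    data.frame(id = im$id, file_name = im$file_name,
               height = im$height, width = im$width,
               stringsAsFactors = FALSE)))
  anns <- lapply(obj$annotations, function(a) {
    seg <- unlist(a$segmentation[[1]])
    poly <- matrix(seg, ncol = 2, byrow = TRUE,
                   dimnames = list(NULL, c("x", "y")))
    list(id = a$id, image_id = a$image_id, polygon = poly,
         area = a$area, score = a$score)
  })
  list(images = images, annotations = anns)
}

#' Read / write an RGB image array as PNG
#'
#' Images are H x W x 3 arrays with values in `[0, 1]`.
#' @param image H x W x 3 array.
#' @param path file path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}
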