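#' Image preprocessing for GGENet
#'
#' Decodes an image (or takes a decoded `H x W x 3` array in \[0, 1\]),
#' bilinearly resizes it to the target square size, and standardizes each
#' channel with the ImageNet statistics (means 0.485/0.456/0.406, standard
#' deviations 0.229/0.224/0.225), the same normalization used for training.
#' Returns a `(3, size, size)` channel-first array.
#'
#' @param image file path or decoded `H x W x 3` numeric array in \[0, 1\].
#' @param size output side in pixels (default 224).
#' @return numeric array, dim `(3, size, size)`.
#' @examples
#' img <- array(1, dim = c(8, 8, 3))           # pure white
#' x <- preprocess(img, size = 8)
#' round(x[, 1, 1], 4)                          # 2.2489 2.4286 2.6400
#' @export
preprocess <- function(image, size = 224) {
  if (is.character(image)) {
    image <- tryCatch(png::readPNG(image),
                      error = function(e) stop("cannot decode image: ",
                                               conditionMessage(e)))
  }
  if (length(dim(image)) == 2) image <- array(rep(image, 3), c(dim(image), 3))
  if (dim(image)[3] == 4) image <- image[, , 1:3]       # drop alpha
  if (dim(image)[3] != 3) stop("expected an RGB image")
  if (dim(image)[1] != size || dim(image)[2] != size)
    image <- resize_bilinear(image, size)
  means <- c(0.485, 0.456, 0.406)
  sds <- c(0.229, 0.224, 0.225)
  out <- array(0, dim = c(3, size, size))
  for (ch in 1:3) out[ch, , ] <- (image[, , ch] - means[ch]) / sds[ch]
  out
}

imagenet_stats <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

resize_bilinear <- function(img, size) {
  if (requireNamespace("EBImage", quietly = TRUE))
    return(EBImage::resize(img, w = size, h = size))
  # plain bilinear fallback
  H <- dim(img)[1]; W <- dim(img)[2]
  ys <- (seq_len(size) - 0.5) * H / size + 0.5
  xs <- (seq_len(size) - 0.5) * W / size + 0.5
  y0 <- pmin(pmax(floor(ys), 1), H); y1 <- pmin(y0 + 1, H); fy <- ys - y0
  x0 <- pmin(pmax(floor(xs), 1), W); x1 <- pmin(x0 + 1, W); fx <- xs - x0
  fy <- pmin(pmax(fy, 0), 1); fx <- pmin(pmax(fx, 0), 1)
  out <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    m <- img[, , ch]
    a <- m[y0, x0]; b <- m[y0, x1]; cc <- m[y1, x0]; d <- m[y1, x1]
    out[, , ch] <- (1 - fy) * ((1 - rep(fx, each = size)) * a + rep(fx, each = size) * b) +
      fy * ((1 - rep(fx, each = size)) * cc + rep(fx, each = size) * d)
  }
  out
}

#' Load a dataset index into a batched tensor
#'
#' Reads every image of an index, preprocesses it with [preprocess()], and
#' stacks the results into a `(N, 3, size, size)` feature map plus integer
#' labels. Undecodable files are skipped with a warning.
#'
#' @param index data.frame with `path` and `label` columns.
#' @param size target square side in pixels.
#' @return list with `x` (feature map), `y` (integer labels 1..K), and
#'   `classes` (level names).
#' @export
load_images <- function(index, size = 64) {
  N <- nrow(index)
  x <- array(0, dim = c(N, 3, size, size))
  keep <- logical(N)
  for (i in seq_len(N)) {
    xi <- tryCatch(preprocess(index$path[i], size), error = function(e) NULL)
    if (is.null(xi)) {
      warning("skipping undecodable image: ", index$path[i])
      next
    }
    x[i, , , ] <- xi
    keep[i] <- TRUE
  }
  lab <- if (is.factor(index$label)) index$label else factor(index$label)
  list(x = x[keep, , , , drop = FALSE], y = as.integer(lab)[keep],
       classes = levels(lab))
}
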