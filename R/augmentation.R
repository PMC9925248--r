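# Deterministic 15-fold geometric augmentation of image/mask pairs. The
# registry mirrors the training recipe's transform table: right-angle
# rotations, fixed-size side crops (resized back to the original frame), a
# left-right flip and a (25, 25) pixel shift. The mask always receives
# exactly the same geometric transform as its image.

#' Augmentation specification
#'
#' The default registry generates exactly 15 variants per input: rotations by
#' 90/180/270 degrees plus crops of 45, 60 and 90 pixels from each of the
#' four sides (3 + 12 = 15). The transform table additionally lists a
#' left-right flip and a (25, 25) shift; enabling both raises the count to 17,
#' so they are off by default to honour the stated 15-per-image sampling.
#' Crop amounts are interpreted as pixels (their printed degree sign is
#' meaningless for a crop).
#'
#' @param rotations integer angles, multiples of 90.
#' @param crop_amounts integer pixel amounts applied to each side.
#' @param include_flip include the left-right flip variant.
#' @param include_shift include the (25, 25) pixel shift variant.
#' @param shift_offset integer pair (rows, cols).
#' @return object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotations = c(90L, 180L, 270L),
                              crop_amounts = c(45L, 60L, 90L),
                              include_flip = FALSE,
                              include_shift = FALSE,
                              shift_offset = c(25L, 25L)) {
  if (any(rotations %% 90L != 0L)) stop("rotations must be multiples of 90")
  structure(list(rotations = as.integer(rotations),
                 crop_amounts = as.integer(crop_amounts),
                 include_flip = isTRUE(include_flip),
                 include_shift = isTRUE(include_shift),
                 shift_offset = as.integer(shift_offset)),
            class = "augmentation_spec")
}

rot90_once <- function(x) {
  # counter-clockwise quarter turn: new[i, j] = old[j, H-i+1]
  d <- dim(x)
  if (length(d) == 2L) return(t(x)[ncol(x):1, , drop = FALSE])
  out <- array(0, c(d[2], d[1], d[3]))
  for (c in seq_len(d[3])) out[, , c] <- t(x[, , c])[d[2]:1, , drop = FALSE]
  out
}

#' Rotate an image/mask pair by a right angle
#'
#' Lossless rotation of both grids by the same multiple of 90 degrees.
#'
#' @param image `H x W (x C)` array.
#' @param mask `H x W` binary matrix.
#' @param angle one of 90, 180, 270 (any multiple of 90 is accepted).
#' @return list with transformed `image` and `mask`.
#' @export
rotate_pair <- function(image, mask, angle) {
  if (angle %% 90 != 0) stop("unsupported angle: must be a multiple of 90")
  turns <- (as.integer(angle) %/% 90L) %% 4L
  for (t in seq_len(turns)) {
    image <- rot90_once(image)
    mask <- rot90_once(mask)
  }
  list(image = image, mask = mask)
}

#' Bilinear image resize
#'
#' Pixel-center aligned bilinear interpolation, per channel.
#'
#' @param image `H x W (x C)` array.
#' @param out_h,out_w output dimensions.
#' @return resized array.
#' @export
resize_bilinear <- function(image, out_h, out_w) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  fy <- pmin(pmax((seq_len(out_h) - 0.5) * H / out_h - 0.5, 0), H - 1)
  fx <- pmin(pmax((seq_len(out_w) - 0.5) * W / out_w - 0.5, 0), W - 1)
  y0 <- pmin(floor(fy), H - 1); y1 <- pmin(y0 + 1, H - 1)
  x0 <- pmin(floor(fx), W - 1); x1 <- pmin(x0 + 1, W - 1)
  wy <- fy - y0; wx <- fx - x0
  interp1 <- function(ch) {
    ch[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - wy, 1 - wx) +
      ch[y1 + 1, x0 + 1, drop = FALSE] * outer(wy, 1 - wx) +
      ch[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - wy, wx) +
      ch[y1 + 1, x1 + 1, drop = FALSE] * outer(wy, wx)
  }
  resample_channels(image, interp1, out_h, out_w)
}

# like per_channel but the op may change the spatial size
resample_channels <- function(image, f, out_h, out_w) {
  d <- dim(image)
  if (length(d) == 2L) return(f(image))
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- f(image[, , c])
  out
}

#' Nearest-neighbour resize
#'
#' Keeps masks binary; pixel-center aligned.
#'
#' @inheritParams resize_bilinear
#' @return resized array/matrix.
#' @export
resize_nearest <- function(image, out_h, out_w) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  iy <- pmin(pmax(floor((seq_len(out_h) - 0.5) * H / out_h) + 1, 1), H)
  ix <- pmin(pmax(floor((seq_len(out_w) - 0.5) * W / out_w) + 1, 1), W)
  resample_channels(image, function(ch) ch[iy, ix, drop = FALSE],
                    out_h, out_w)
}

#' Crop pixels from one side, then resize back
#'
#' Removes `amount` pixels from the named side of both grids and resizes back
#' to the original shape (bilinear for the image, nearest-neighbour for the
#' mask so it stays binary).
#'
#' @inheritParams rotate_pair
#' @param side one of `"left"`, `"right"`, `"top"`, `"bottom"`.
#' @param amount non-negative integer pixels, smaller than the cropped
#'   dimension.
#' @return list with transformed `image` and `mask`.
#' @export
crop_side <- function(image, mask, side = c("left", "right", "top", "bottom"),
                      amount) {
  side <- match.arg(side)
  amount <- as.integer(amount)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  lim <- if (side %in% c("left", "right")) W else H
  if (amount >= lim) stop("crop amount must be smaller than the dimension")
  if (amount == 0L) return(list(image = image, mask = mask))
  ri <- seq_len(H); rj <- seq_len(W)
  switch(side,
         left = { rj <- (amount + 1L):W },
         right = { rj <- seq_len(W - amount) },
         top = { ri <- (amount + 1L):H },
         bottom = { ri <- seq_len(H - amount) })
  img <- if (length(d) == 3L) image[ri, rj, , drop = FALSE] else
    image[ri, rj, drop = FALSE]
  msk <- mask[ri, rj, drop = FALSE]
  list(image = resize_bilinear(img, H, W),
       mask = resize_nearest(msk, H, W))
}

#' Left-right flip of an image/mask pair
#'
#' @inheritParams rotate_pair
#' @return list with mirrored `image` and `mask`.
#' @export
flip_lr <- function(image, mask) {
  d <- dim(image)
  rj <- rev(seq_len(d[2]))
  img <- if (length(d) == 3L) image[, rj, , drop = FALSE] else
    image[, rj, drop = FALSE]
  list(image = img, mask = mask[, rj, drop = FALSE])
}

#' Shift an image/mask pair, zero-filling vacated pixels
#'
#' Translates both grids by `offset = (rows down, cols right)`.
#'
#' @inheritParams rotate_pair
#' @param offset integer pair; each must be smaller than the matching
#'   dimension in absolute value.
#' @return list with shifted `image` and `mask`.
#' @export
shift_pair <- function(image, mask, offset = c(25L, 25L)) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  dy <- as.integer(offset[1]); dx <- as.integer(offset[2])
  if (abs(dy) >= H || abs(dx) >= W) stop("offset too large")
  if (dy == 0L && dx == 0L) return(list(image = image, mask = mask))
  shift1 <- function(ch) {
    out <- array(0, dim(ch))
    src_i <- seq_len(H - abs(dy)); src_j <- seq_len(W - abs(dx))
    if (dy < 0) src_i <- src_i + abs(dy)
    if (dx < 0) src_j <- src_j + abs(dx)
    dst_i <- src_i + dy; dst_j <- src_j + dx
    out[dst_i, dst_j] <- ch[src_i, src_j]
    out
  }
  list(image = per_channel(image, shift1), mask = per_channel(mask, shift1))
}

#' Generate the augmentation set for one sample
#'
#' Applies the full registry of [augmentation_spec()] to an image/mask pair.
#' With the default spec this yields exactly 15 pairs; each output mask was
#' produced by the same geometric transform as its image. Fully deterministic.
#'
#' @inheritParams rotate_pair
#' @param spec an [augmentation_spec()].
#' @return list of `list(image=, mask=, transform=)` entries; `transform` is a
#'   human-readable label of the applied operation.
#' @export
augment_sample <- function(image, mask, spec = augmentation_spec()) {
  stopifnot(inherits(spec, "augmentation_spec"))
  out <- list()
  for (a in spec$rotations) {
    p <- rotate_pair(image, mask, a)
    p$transform <- sprintf("rotate_%d", a)
    out[[length(out) + 1L]] <- p
  }
  for (side in c("right", "left", "top", "bottom")) {
    for (amt in spec$crop_amounts) {
      p <- crop_side(image, mask, side, amt)
      p$transform <- sprintf("crop_%s_%d", side, amt)
      out[[length(out) + 1L]] <- p
    }
  }
  if (spec$include_flip) {
    p <- flip_lr(image, mask)
    p$transform <- "flip_lr"
    out[[length(out) + 1L]] <- p
  }
  if (spec$include_shift) {
    p <- shift_pair(image, mask, spec$shift_offset)
    p$transform <- sprintf("shift_%d_%d", spec$shift_offset[1],
                           spec$shift_offset[2])
    out[[length(out) + 1L]] <- p
  }
  out
}
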