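# Image/mask readers and writers, dataset folder conventions and run-config
# loading. Folder convention: <root>/images and <root>/masks, pairs matched
# by identical filename stems; masks stored as 0/255 PNG.

#' Read an image file
#'
#' PNG or JPEG, 8- or 16-bit; values scaled to `[0,1]`. Alpha channels are
#' dropped; grayscale files come back as a matrix, colour files as an
#' `H x W x 3` array.
#'
#' @param path file path ending in .png, .jpg or .jpeg.
#' @return numeric matrix or array in `[0,1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                jpg = , jpeg = jpeg::readJPEG(path),
                stop("unsupported image format: ", ext))
  d <- dim(img)
  if (length(d) == 3L && d[3] %in% c(2L, 4L)) { # drop alpha
    img <- if (d[3] == 2L) img[, , 1] else img[, , 1:3]
  }
  img
}

#' Write an image file
#'
#' PNG (lossless) or JPEG. Values are clipped to `[0,1]`.
#'
#' @param path output path; format chosen by extension.
#' @param grid matrix or `H x W x 3` array in `[0,1]`.
#' @return `path`, invisibly.
#' @export
write_image <- function(path, grid) {
  grid[grid < 0] <- 0
  grid[grid > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(grid, path),
         jpg = , jpeg = jpeg::writeJPEG(grid, path, quality = 0.95),
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Read a binary mask
#'
#' Reads an image and thresholds at > 127 on the 8-bit scale; multi-channel
#' files use their first channel.
#'
#' @param path mask file path.
#' @return `H x W` 0/1 matrix.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  (m > 127 / 255) * 1
}

#' Write a binary mask as 0/255 PNG
#'
#' @param path output .png path.
#' @param mask `H x W` 0/1 matrix.
#' @return `path`, invisibly.
#' @export
write_mask <- function(path, mask) {
  write_image(path, mask * 1.0)
}

list_images <- function(dir) {
  f <- list.files(dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
  sort(f)
}

#' Load a paired image/mask dataset folder
#'
#' Expects `<root>/images` and `<root>/masks` with pairs matched by filename
#' stem, in deterministic sorted order. Images are bilinear-resized and masks
#' nearest-neighbour-resized (staying binary) to `target_size`. In lenient
#' mode unmatched images are skipped with a warning; strict mode errors.
#'
#' @param root dataset root directory.
#' @param target_size square output side in pixels.
#' @param strict error on pairing violations (default FALSE).
#' @return list of `list(image=, mask=, stem=)` entries.
#' @export
load_dataset <- function(root, target_size = 256L, strict = FALSE) {
  idir <- file.path(root, "images")
  mdir <- file.path(root, "masks")
  if (!dir.exists(idir) || !dir.exists(mdir)) {
    stop("dataset root must contain images/ and masks/")
  }
  ifiles <- list_images(idir)
  mfiles <- list_images(mdir)
  mstems <- tools::file_path_sans_ext(mfiles)
  out <- list()
  for (f in ifiles) {
    stem <- tools::file_path_sans_ext(f)
    hit <- which(mstems == stem)
    if (length(hit) != 1L) {
      msg <- sprintf("image '%s' has %d matching masks", f, length(hit))
      if (strict) stop(msg)
      warning(msg, call. = FALSE)
      next
    }
    img <- read_image(file.path(idir, f))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    d <- dim(img)
    if (d[1] != d[2]) {
      message(sprintf("resizing non-square %dx%d image '%s'", d[1], d[2], f))
    }
    msk <- read_mask(file.path(mdir, mfiles[hit]))
    out[[length(out) + 1L]] <- list(
      image = resize_bilinear(img, target_size, target_size),
      mask = resize_nearest(msk, target_size, target_size),
      stem = stem)
  }
  out
}

#' Write a dataset to the standard folder layout
#'
#' @param dataset list of `list(image=, mask=)` pairs.
#' @param root output root; `images/` and `masks/` are created.
#' @param stems optional character names; default `scene_000`...
#' @return `root`, invisibly.
#' @export
write_dataset <- function(dataset, root, stems = NULL) {
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (is.null(stems)) {
    stems <- sprintf("scene_%03d", seq_along(dataset) - 1L)
  }
  for (i in seq_along(dataset)) {
    write_image(file.path(root, "images", paste0(stems[i], ".png")),
                dataset[[i]]$image)
    write_mask(file.path(root, "masks", paste0(stems[i], ".png")),
               dataset[[i]]$mask)
  }
  invisible(root)
}

run_config_sections <- c("model", "train", "preprocess", "augment", "scene",
                         "data", "output")

#' Load a YAML run configuration
#'
#' One document with optional sections `model`, `train`, `preprocess`,
#' `augment`, `scene`, `data` (`dir`, `target_size`), `output` (`checkpoint`,
#' `history`). Unknown sections or keys are rejected.
#'
#' @param path YAML file.
#' @return list with constructed config objects and the raw `data`/`output`
#'   lists.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), run_config_sections)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  build <- function(section, fn) {
    args <- raw[[section]] %||% list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in '%s': %s", section,
                   paste(bad, collapse = ", ")))
    }
    do.call(fn, args)
  }
  list(model = build("model", model_config),
       train = build("train", train_config),
       preprocess = build("preprocess", preprocess_config),
       augment = build("augment", augmentation_spec),
       scene = build("scene", scene_spec),
       data = raw$data %||% list(),
       output = raw$output %||% list())
}

#' Write a run configuration to YAML
#'
#' Dumps the raw section lists; `load_run_config(save_run_config(x))` is
#' semantically identical to `x`.
#'
#' @param config named list of sections (as plain lists).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
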