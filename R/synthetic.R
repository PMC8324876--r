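#' Configuration for the synthetic tile generator
#'
#' Defaults emulate the shape of an eight-class colorectal-histology tile
#' collection: 8 balanced classes of 625 tiles, each 150x150 pixels at 8-bit
#' depth (5000 tiles in total).
#'
#' @param n_classes Number of texture classes (>= 2).
#' @param n_per_class Tiles per class (>= 1).
#' @param tile_side Tile side length in pixels (>= 8).
#' @param seed Integer master seed; the generator is fully deterministic
#'   given the seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 8L, n_per_class = 625L,
                         tile_side = 150L, seed = 1L) {
  n_classes <- as.integer(n_classes)
  n_per_class <- as.integer(n_per_class)
  tile_side <- as.integer(tile_side)
  seed <- as.integer(seed)
  if (is.na(n_classes) || n_classes < 2L) stop("n_classes must be >= 2")
  if (is.na(n_per_class) || n_per_class < 1L) stop("n_per_class must be >= 1")
  if (is.na(tile_side) || tile_side < 8L) stop("tile_side must be >= 8")
  if (is.na(seed)) stop("seed must be an integer")
  structure(
    list(n_classes = n_classes, n_per_class = n_per_class,
         tile_side = tile_side, seed = seed),
    class = "synth_config"
  )
}

# The eight parametric texture families. Classes differ in characteristic
# scale and orientation so that a multi-scale descriptor stack (wavelet
# approximation, Gabor, LBP, GLCM) can tell them apart; they do not imitate
# H&E tissue appearance.
.synth_class_names <- c(
  "flat", "checker2", "grating12_0", "grating6_45",
  "blobs3", "blobs10", "speckle", "grating_blobs"
)

clip8 <- function(x) {
  x <- floor(x + 0.5)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

# One tile of class `ci` (1-based); RNG state is assumed already seeded.
synth_tile_pixels <- function(ci, s) {
  rr <- matrix(seq_len(s), s, s)
  cc <- matrix(seq_len(s), s, s, byrow = TRUE)
  noise <- function(sd) matrix(rnorm(s * s, 0, sd), s, s)
  grating <- function(lambda, theta_deg, amp) {
    th <- theta_deg * pi / 180
    phase <- runif(1, 0, 2 * pi)
    amp * sin(2 * pi * (rr * cos(th) + cc * sin(th)) / lambda + phase)
  }
  blobs <- function(corr_len, sd_out) {
    b <- gaussian_blur(matrix(rnorm(s * s), s, s), corr_len)
    b <- b / max(stats::sd(b), 1e-12) * sd_out
    b - mean(b)
  }
  base <- 128 + runif(1, -10, 10)
  x <- switch(ci,
    base + noise(8),                                    # flat + low noise
    {                                                   # 2-px checkerboard
      orr <- sample.int(4L, 1L) - 1L
      occ <- sample.int(4L, 1L) - 1L
      par <- ((rr + orr) %/% 2L + (cc + occ) %/% 2L) %% 2L
      ifelse(par == 0L, 96, 160) + noise(4)
    },
    base + grating(12, 0, 60) + noise(4),               # grating 12 px, 0 deg
    base + grating(6, 45, 60) + noise(4),               # grating 6 px, 45 deg
    base + blobs(3, 40),                                # blobs, corr len ~3
    base + blobs(10, 40),                               # blobs, corr len ~10
    {                                                   # salt & pepper speckle
      x0 <- 128 + noise(4)
      u <- matrix(runif(s * s), s, s)
      x0[u < 0.05] <- 0
      x0[u > 0.95] <- 255
      x0
    },
    base + grating(12, 0, 40) + blobs(10, 30)           # grating + blobs
  )
  clip8(x)
}

# Sub-seed for (master seed, class, tile), kept below 2^31 and exact in
# double arithmetic; tiles are independent of generation order.
synth_subseed <- function(seed, ci, ti) {
  m <- 2147483629
  as.integer((((seed %% m) * 48271 + ci * 69621 + ti * 16807) %% m))
}

#' Generate a labelled synthetic texture dataset
#'
#' Produces `n_classes x n_per_class` tiles from eight parametric texture
#' families (flat noise, fine checkerboard, two oriented gratings, two
#' blob fields of different correlation length, salt-and-pepper speckle,
#' and a grating-plus-blob superposition). Per-tile phase, offsets and noise
#' are drawn from a stream seeded by (seed, class, tile index), so an
#' identical seed reproduces the dataset bit for bit and generation order
#' does not matter. With more than eight classes the texture families cycle.
#'
#' @param config A [synth_config()].
#' @return A [tile_set()] with one label per texture family.
#' @examples
#' ts <- generate_dataset(synth_config(n_per_class = 2, tile_side = 32))
#' length(ts)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  cls <- .synth_class_names[((seq_len(config$n_classes) - 1L) %% 8L) + 1L]
  cls <- make.unique(cls, sep = "_")
  tiles <- vector("list", config$n_classes * config$n_per_class)
  k <- 0L
  for (ci in seq_len(config$n_classes)) {
    fam <- ((ci - 1L) %% 8L) + 1L
    for (ti in seq_len(config$n_per_class)) {
      set.seed(synth_subseed(config$seed, ci, ti))
      k <- k + 1L
      tiles[[k]] <- tile(
        synth_tile_pixels(fam, config$tile_side),
        label = cls[ci],
        id = sprintf("synth_%s_%04d", cls[ci], ti)
      )
    }
  }
  tile_set(tiles, class_names = cls)
}

#' Read a class-per-folder tile directory
#'
#' Expects one subdirectory per class holding PNG/TIFF tiles (the layout of
#' public tile collections). Labels are taken from subdirectory names; RGB
#' images are converted to luminance with [to_grayscale()]. Directories and
#' files are visited in lexicographic order, so the result is deterministic.
#'
#' @param path Directory containing one subdirectory per class.
#' @param extensions File extensions treated as images (case-insensitive).
#' @param strict If `TRUE`, a file with an unexpected extension is an error;
#'   otherwise it is skipped with a warning.
#' @return A [tile_set()].
#' @export
read_tile_folder <- function(path, extensions = c("png", "tif", "tiff"),
                             strict = FALSE) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("no class subdirectories in ", path)
  tiles <- list()
  for (cl in classes) {
    files <- sort(list.files(file.path(path, cl), full.names = TRUE))
    for (f in files) {
      ext <- tolower(tools::file_ext(f))
      if (!(ext %in% tolower(extensions))) {
        if (strict) stop("unexpected non-image file: ", f)
        warning("skipping non-image file: ", f)
        next
      }
      img <- tryCatch(
        if (ext == "png") png::readPNG(f) else tiff::readTIFF(f),
        error = function(e) stop("failed to read image '", f, "': ",
                                 conditionMessage(e), call. = FALSE)
      )
      px <- decode_to_8bit(img)
      tiles[[length(tiles) + 1L]] <- tile(px, label = cl,
                                          id = file.path(cl, basename(f)))
    }
  }
  if (length(tiles) == 0L) stop("no image tiles found under ", path)
  tile_set(tiles, class_names = classes)
}

# PNG/TIFF decoders return values in [0,1]; map to 8-bit and collapse RGB(A).
decode_to_8bit <- function(img) {
  if (is.matrix(img)) return(clip8(img * 255))
  d <- dim(img)
  if (length(d) == 3L && d[3] >= 3L) {
    return(to_grayscale(img[, , 1:3, drop = FALSE] * 255))
  }
  if (length(d) == 3L && d[3] == 1L) return(clip8(img[, , 1] * 255))
  stop("unsupported image shape: ", paste(d, collapse = "x"))
}

#' Write a tile set as a class-per-folder PNG tree
#'
#' @param tileset A [tile_set()].
#' @param path Output directory (created if needed); one subdirectory per
#'   class is written, mirroring the layout [read_tile_folder()] expects.
#' @return Invisibly, the number of files written.
#' @export
write_tile_folder <- function(tileset, path) {
  stopifnot(inherits(tileset, "tile_set"))
  n <- 0L
  for (t in tileset$tiles) {
    d <- file.path(path, t$label)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    png::writePNG(t$pixels / 255, file.path(d, paste0(basename(t$id), ".png")))
    n <- n + 1L
  }
  invisible(n)
}
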