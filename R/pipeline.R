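# Assembly of the 532-dimensional multi-level pathomics vector.
#
# Per tile and wavelet setting the pipeline derives 26 feature maps:
#   - the WPT approximation (full floating precision),
#   - its 8-bit quantisation,
#   - 20 Gabor magnitude maps of the quantised approximation
#     (5 orientations x 4 wavelengths) and their pixelwise mean,
#   - 3 LBP maps of the quantised approximation (rotation-invariant,
#     variance, uniform),
#   - the pixelwise mean of a rotation-angle Gabor bank applied to the
#     ORIGINAL undecomposed tile.
# First-order statistics (4) are taken on 25 maps (approximation, 20 Gabor,
# 3 LBP, Gabor aggregate) = 100 features; GLCM statistics (6 stats x 4
# angles x 3 distances = 72) are taken on 6 quantised maps (approximation,
# 3 LBP, Gabor aggregate, rotated-Gabor aggregate) = 432 features;
# 100 + 432 = 532.

#' Default extraction configuration
#'
#' Collects every descriptor parameter of the feature pipeline: the Gabor
#' bank geometry (five orientations, four wavelengths from 4 to 20 pixels
#' per cycle), the rotation-angle bank applied to the original tile (70 to
#' 190 degrees), the GLCM geometry (angles 0 to 135 degrees, distances 1 to
#' 5 pixels, 256 gray levels) and the LBP neighborhood (8 neighbors, radius
#' 1).
#'
#' @return A named list of parameter groups; pass (possibly modified) to
#'   [extract_pathomics()].
#' @export
default_extract_config <- function() {
  list(
    gabor = list(
      orientations = default_gabor_orientations(),
      wavelengths = default_gabor_wavelengths(),
      K = 1, sigma_factor = 0.56
    ),
    rotation_angles = default_gabor_rotations(),
    glcm = list(
      angles = default_glcm_angles(),
      distances = default_glcm_distances(),
      levels = 256L
    ),
    lbp = list(P = 8L, R = 1)
  )
}

fos_map_names <- function(config) {
  gnames <- sprintf(
    "wpt_gabor_o%03d_w%04.1f",
    rep(round(config$gabor$orientations), each = length(config$gabor$wavelengths)),
    rep(config$gabor$wavelengths, length(config$gabor$orientations))
  )
  c("wpt_approx", gnames, "wpt_lbp_rot", "wpt_lbp_var", "wpt_lbp_unif",
    "wpt_gabor_agg")
}

glcm_map_names <- function() {
  c("wpt_approx", "wpt_lbp_rot", "wpt_lbp_var", "wpt_lbp_unif",
    "wpt_gabor_agg", "rot_gabor_agg")
}

#' Ledger of the default 532-feature composition
#'
#' Itemises which descriptor is applied to which feature map and how many
#' features each pairing contributes. Under the default configuration the
#' ledger totals exactly 532.
#'
#' @param config An extraction configuration, see [default_extract_config()].
#' @return A data frame with columns `source_map`, `descriptor`, `count`
#'   and attribute `total`.
#' @examples
#' sum(default_ledger()$count)  # 532
#' @export
default_ledger <- function(config = default_extract_config()) {
  n_glcm <- 6L * length(config$glcm$angles) * length(config$glcm$distances)
  led <- rbind(
    data.frame(source_map = fos_map_names(config), descriptor = "fos",
               count = 4L, stringsAsFactors = FALSE),
    data.frame(source_map = glcm_map_names(), descriptor = "glcm_hos",
               count = n_glcm, stringsAsFactors = FALSE)
  )
  attr(led, "total") <- sum(led$count)
  led
}

feature_names <- function(config = default_extract_config()) {
  fos <- as.vector(t(outer(fos_map_names(config),
                           c("fos_max", "fos_min", "fos_mean", "fos_std"),
                           paste, sep = "|")))
  stats <- c("contrast", "dissimilarity", "homogeneity", "correlation",
             "ASM", "energy")
  combos <- expand.grid(stat = stats, d = config$glcm$distances,
                        a = config$glcm$angles, map = glcm_map_names(),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  glcm_n <- sprintf("%s|glcm_a%03d_d%d_%s", combos$map, combos$a, combos$d,
                    combos$stat)
  c(fos, glcm_n)
}

glcm_block <- function(map8, config) {
  unlist(lapply(config$glcm$angles, function(a) {
    lapply(config$glcm$distances, function(d) {
      glcm_features(glcm(map8, a, d, config$glcm$levels))
    })
  }), use.names = FALSE)
}

#' Extract the 532-feature pathomics vector of one tile
#'
#' Computes the wavelet-packet approximation for `spec`, derives the Gabor,
#' LBP and co-occurrence feature maps described in [default_ledger()], and
#' concatenates first-order and GLCM statistics in ledger order. Maps that
#' feed GLCM or LBP are quantised with [rescale_to_8bit()]; first-order
#' statistics of the approximation use the full-precision coefficients.
#' The result is deterministic in the tile and configuration.
#'
#' @param tile A [tile()] (at least 8x8 pixels).
#' @param spec A [wavelet_spec()] with a feasible level.
#' @param config Extraction parameters, see [default_extract_config()].
#' @return An object of class `feature_vector`: named numeric vector of 532
#'   finite values with attributes `tile_id` and `wavelet`.
#' @export
extract_pathomics <- function(tile, spec, config = default_extract_config()) {
  px <- tile_pixels(tile)
  if (nrow(px) < 8L || ncol(px) < 8L) stop("tile must be at least 8x8")
  approx <- wpt_approximation(tile, spec)
  a8 <- rescale_to_8bit(approx)

  gmaps <- gabor_bank_responses(
    a8, orientations = config$gabor$orientations,
    wavelengths = config$gabor$wavelengths,
    K = config$gabor$K, sigma_factor = config$gabor$sigma_factor
  )
  gagg <- Reduce(`+`, gmaps) / length(gmaps)

  lrot <- lbp_map(a8, config$lbp$P, config$lbp$R, "rotation")
  lvar <- lbp_map(a8, config$lbp$P, config$lbp$R, "variance")
  luni <- lbp_map(a8, config$lbp$P, config$lbp$R, "uniform")

  rmaps <- gabor_bank_responses(
    px, orientations = config$rotation_angles,
    wavelengths = config$gabor$wavelengths,
    K = config$gabor$K, sigma_factor = config$gabor$sigma_factor
  )
  ragg <- Reduce(`+`, rmaps) / length(rmaps)

  fos_maps <- c(list(approx$coefficients), gmaps,
                list(lrot, lvar, luni, gagg))
  fos_vals <- unlist(lapply(fos_maps, first_order_stats), use.names = FALSE)

  glcm_maps8 <- list(a8, lrot, rescale_to_8bit(lvar), luni,
                     rescale_to_8bit(gagg), rescale_to_8bit(ragg))
  glcm_vals <- unlist(lapply(glcm_maps8, glcm_block, config = config),
                      use.names = FALSE)

  v <- c(fos_vals, glcm_vals)
  names(v) <- feature_names(config)
  stopifnot(all(is.finite(v)))
  structure(v, class = "feature_vector",
            tile_id = tile_id(tile), wavelet = spec$name, level = spec$level)
}

#' Batch feature extraction over a tile set
#'
#' Applies [extract_pathomics()] to every tile, preserving tile order and
#' carrying the labels through. A per-tile failure is re-raised with the
#' tile id.
#'
#' @param tiles A [tile_set()].
#' @param spec A [wavelet_spec()].
#' @param config Extraction parameters.
#' @param file Optional path: the table is also written as CSV
#'   (feature columns, then `label`), readable by [read_feature_csv()].
#' @param progress If `TRUE`, prints a dot per 50 tiles to stderr.
#' @return An object of class `feature_table`: list with `features`
#'   (numeric matrix, one named row per tile), `labels`, `tile_ids`,
#'   `wavelet`, `level`.
#' @export
extract_batch <- function(tiles, spec, config = default_extract_config(),
                          file = NULL, progress = FALSE) {
  stopifnot(inherits(tiles, "tile_set"))
  n <- length(tiles$tiles)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch(
      as.numeric(extract_pathomics(tiles$tiles[[i]], spec, config)),
      error = function(e) stop("feature extraction failed for tile '",
                               tiles$tiles[[i]]$id, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    if (progress && i %% 50L == 0L) cat(".", file = stderr())
  }
  feats <- do.call(rbind, rows)
  colnames(feats) <- feature_names(config)
  tab <- structure(
    list(features = feats, labels = tile_labels(tiles),
         tile_ids = vapply(tiles$tiles, `[[`, character(1), "id"),
         wavelet = spec$name, level = spec$level),
    class = "feature_table"
  )
  if (!is.null(file)) write_feature_csv(tab, file)
  tab
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d tiles x %d features (%s, level %d)\n",
              nrow(x$features), ncol(x$features), x$wavelet, x$level))
  invisible(x)
}

# Row subset helper used by the evaluation protocol.
ft_subset <- function(tab, idx) {
  structure(
    list(features = tab$features[idx, , drop = FALSE],
         labels = tab$labels[idx], tile_ids = tab$tile_ids[idx],
         wavelet = tab$wavelet, level = tab$level),
    class = "feature_table"
  )
}

#' Feature-table CSV input/output
#'
#' Values are written with 17 significant digits so a round trip is exact to
#' double precision. Columns are the feature names, then `label`, then
#' `tile_id`.
#'
#' @param tab A `feature_table`.
#' @param file Path to write/read.
#' @return `read_feature_csv()` returns a `feature_table`.
#' @export
write_feature_csv <- function(tab, file) {
  stopifnot(inherits(tab, "feature_table"))
  hdr <- paste(c(colnames(tab$features), "label", "tile_id"), collapse = ",")
  body <- vapply(seq_len(nrow(tab$features)), function(i) {
    paste(c(sprintf("%.17g", tab$features[i, ]), tab$labels[i],
            tab$tile_ids[i]), collapse = ",")
  }, character(1))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' @rdname write_feature_csv
#' @param wavelet,level Provenance recorded on the returned table.
#' @export
read_feature_csv <- function(file, wavelet = NA_character_, level = NA_integer_) {
  df <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "tile_id") %in% colnames(df)))
  fcols <- setdiff(colnames(df), c("label", "tile_id"))
  feats <- as.matrix(df[, fcols, drop = FALSE])
  structure(
    list(features = feats, labels = as.character(df$label),
         tile_ids = as.character(df$tile_id),
         wavelet = wavelet, level = level),
    class = "feature_table"
  )
}
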