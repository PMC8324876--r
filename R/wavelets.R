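#' Discrete wavelet families and their decomposition filters
#'
#' The package works with the six discrete wavelet families used for
#' texture decomposition: Haar (`haar`), Daubechies (`db`), Symlets (`sym`),
#' Coiflets (`coif`), Biorthogonal (`bior`) and Reverse biorthogonal
#' (`rbio`). Continuous families (Gaussian, Mexican hat, Morlet, Shannon,
#' frequency B-spline and their complex variants) have no finite filter bank
#' and are excluded by construction.
#'
#' Filter coefficients are the standard published values, shipped as a
#' plain-text table; only the decomposition low-pass filter is needed for
#' approximation images.
#'
#' @return A named list with one element per family, each a character vector
#'   of concrete wavelet names (e.g. `"db4"`, `"bior1.1"`).
#' @examples
#' names(list_discrete_wavelets())
#' list_discrete_wavelets()$haar
#' @export
list_discrete_wavelets <- function() {
  tab <- wavelet_filter_table()
  fams <- c("haar", "db", "sym", "coif", "bior", "rbio")
  out <- lapply(fams, function(f) tab$name[tab$family == f])
  names(out) <- fams
  out
}

# Lazily parsed filter table: name, family, dec_lo (list of numeric vectors).
wavelet_filter_table <- function() {
  pw_cache_get("wavelet_filter_table", function() {
    path <- system.file("extdata", "wavelet_filters.csv", package = "pathowave")
    if (!nzchar(path)) stop("wavelet filter table not found")
    raw <- read.csv(path, stringsAsFactors = FALSE)
    raw$dec_lo <- lapply(strsplit(raw$dec_lo, " ", fixed = TRUE), as.numeric)
    raw
  })
}

#' Decomposition low-pass filter of a discrete wavelet
#'
#' @param name Wavelet identifier in the conventional compact form
#'   (`"haar"`, `"db4"`, `"sym2"`, `"bior1.1"`, ...).
#' @return Numeric vector of decomposition low-pass coefficients
#'   (normalised so that the coefficients sum to `sqrt(2)`).
#' @export
wavelet_filter <- function(name) {
  tab <- wavelet_filter_table()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown discrete wavelet '", name, "'; see list_discrete_wavelets()")
  }
  tab$dec_lo[[i]]
}

#' Construct a wavelet decomposition specification
#'
#' Bundles a concrete mother wavelet with a decomposition level. The boundary
#' rule is fixed to symmetric half-point extension, under which the side
#' length at each level follows `floor((n + m - 1) / 2)` for filter length
#' `m`.
#'
#' @param name Concrete wavelet name (see [list_discrete_wavelets()]).
#' @param level Decomposition level, integer `>= 1`.
#' @return An object of class `wavelet_spec` with fields `name`, `family`,
#'   `level`, `filter` and `boundary_mode`.
#' @examples
#' wavelet_spec("bior1.1", 2)
#' @export
wavelet_spec <- function(name, level = 1L) {
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop("level must be an integer >= 1")
  tab <- wavelet_filter_table()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown discrete wavelet '", name, "'; see list_discrete_wavelets()")
  }
  structure(
    list(
      name = name,
      family = tab$family[i],
      level = level,
      filter = tab$dec_lo[[i]],
      boundary_mode = "symmetric"
    ),
    class = "wavelet_spec"
  )
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf(
    "<wavelet_spec> %s (family %s), level %d, filter length %d, %s boundary\n",
    x$name, x$family, x$level, length(x$filter), x$boundary_mode
  ))
  invisible(x)
}
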