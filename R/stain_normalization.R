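# Reinhard color transfer operates in Ruderman's lalphabeta opponent space:
# RGB -> LMS cone response -> log -> fixed orthogonal transform. The log is
# taken as log(1 + x) on 0-1 linearized RGB-derived LMS so zeros are safe.

.rgb2lms <- matrix(c(
  0.3811, 0.5783, 0.0402,
  0.1967, 0.7244, 0.0782,
  0.0241, 0.1288, 0.8444
), nrow = 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)

# log-LMS -> lalphabeta (orthogonal up to the diagonal scaling)
.lms2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1,
           1, 1, -2,
           1, -1, 0), nrow = 3, byrow = TRUE)
.lab2lms <- solve(.lms2lab)

flatten_channels <- function(img) {
  d <- dim(img)
  matrix(as.numeric(img), nrow = d[1L] * d[2L], ncol = 3L)
}

unflatten_channels <- function(m, d) array(m, dim = d)

#' Convert an 8-bit RGB image to Ruderman lalphabeta
#'
#' Maps RGB (0-255) to the decorrelated log-opponent space used by Reinhard
#' color transfer: linearize to 0-1, project to LMS cone responses, take
#' `log(1 + x)`, then apply the fixed orthogonal opponent transform
#' (l = luminance, alpha = yellow-blue, beta = red-green). On pure gray the
#' opponent channels are approximately zero.
#'
#' @param img H x W x 3 numeric/integer array, values in \[0, 255\].
#' @return H x W x 3 double array in lalphabeta.
#' @export
rgb_to_lab <- function(img) {
  d <- dim(img)
  m <- flatten_channels(img) / 255
  lms <- m %*% t(.rgb2lms)
  lab <- log1p(lms) %*% t(.lms2lab)
  unflatten_channels(lab, d)
}

#' Convert a Ruderman lalphabeta image back to 8-bit RGB
#'
#' Inverts [rgb_to_lab()] with clipping: LMS values are floored at zero
#' before the inverse cone projection and RGB is clipped to \[0, 255\].
#' A round trip errs by at most one gray level per channel.
#'
#' @param lab H x W x 3 double array in lalphabeta.
#' @return H x W x 3 integer array in \[0, 255\].
#' @export
lab_to_rgb <- function(lab) {
  d <- dim(lab)
  loglms <- flatten_channels(lab) %*% t(.lab2lms)
  lms <- pmax(expm1(loglms), 0)
  rgb <- lms %*% t(.lms2rgb)
  out <- clip255(round(rgb * 255))
  array(as.integer(out), dim = d)
}

#' Fit Reinhard target statistics
#'
#' Computes the per-channel mean and standard deviation of the reference
#' image in lalphabeta space. These are the targets every normalized tile is
#' mapped onto. With `preset = TRUE` the packaged constants are returned:
#' the statistics of the package's deterministic synthetic H&E-like
#' reference tile (see [reinhard_reference_image()]).
#'
#' @param reference H x W x 3 RGB array (ignored when `preset = TRUE`).
#' @param preset use the shipped reference constants.
#' @return A `reinhard_fit`: list with `target_mean`, `target_sd` (length-3
#'   doubles) and `space_tag = "ruderman-lab"`.
#' @export
fit_reinhard <- function(reference = NULL, preset = FALSE) {
  if (preset) {
    return(reinhard_preset())
  }
  if (is.null(reference)) {
    abort_wsimil("either a reference image or preset = TRUE is required",
                 "wsimil_parameter_error")
  }
  lab <- rgb_to_lab(reference)
  m <- flatten_channels(lab)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds < 1e-9)) {
    abort_wsimil("reference image has a zero-variance lalphabeta channel",
                 "wsimil_zero_variance")
  }
  structure(
    list(target_mean = colMeans(m), target_sd = sds, space_tag = "ruderman-lab"),
    class = "reinhard_fit"
  )
}

#' Deterministic synthetic H&E-like reference tile
#'
#' A 256 x 256 tile with pink tissue base and dark nuclei-like spots,
#' generated from a fixed internal seed. Its lalphabeta statistics are the
#' package's preset normalization target.
#'
#' @return 256 x 256 x 3 integer RGB array.
#' @export
reinhard_reference_image <- function() {
  spec <- cohort_spec(
    datasets = data.frame(dataset_id = "REF", n_control = 1L, n_tumor = 0L),
    slide_size = c(256L, 256L), tissue_fraction = 1.0,
    texture_params = list(control = list(density = 4, radius = 4),
                          tumor = list(density = 8, radius = 6)),
    seed = 424242L
  )
  generate_slide("REF_C001", "control", "REF", spec, seed = 424242L)$image
}

.wsimil_cache <- new.env(parent = emptyenv())

#' Packaged preset Reinhard fit
#' @return The `reinhard_fit` of [reinhard_reference_image()], cached.
#' @export
reinhard_preset <- function() {
  if (is.null(.wsimil_cache$preset_fit)) {
    .wsimil_cache$preset_fit <- fit_reinhard(reinhard_reference_image())
  }
  .wsimil_cache$preset_fit
}

#' Apply Reinhard normalization to a tile
#'
#' The fast variant: a single affine moment transfer per lalphabeta channel
#' (subtract the tile's channel mean, rescale by the ratio of target to tile
#' standard deviation, add the target mean) with no separate brightness
#' standardization step, then conversion back to RGB with gamut clipping.
#' Before clipping, the output's lalphabeta moments equal the fit targets
#' exactly. A tile with a zero-variance channel (blank tile) is returned
#' unchanged with a warning.
#'
#' @param tile H x W x 3 RGB array in \[0, 255\].
#' @param fit a `reinhard_fit`.
#' @param output `"rgb"` (default) for the clipped 8-bit result, `"lab"` for
#'   the pre-clipping lalphabeta image (useful to verify moment matching).
#' @return H x W x 3 array: integer RGB or double lalphabeta.
#' @export
apply_reinhard <- function(tile, fit, output = c("rgb", "lab")) {
  output <- match.arg(output)
  stopifnot(inherits(fit, "reinhard_fit"))
  lab <- rgb_to_lab(tile)
  m <- flatten_channels(lab)
  mu <- colMeans(m)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds < 1e-9)) {
    warning("tile has a zero-variance lalphabeta channel; returned unchanged")
    return(tile)
  }
  out <- sweep(m, 2L, mu, `-`)
  out <- sweep(out, 2L, fit$target_sd / sds, `*`)
  out <- sweep(out, 2L, fit$target_mean, `+`)
  lab_out <- unflatten_channels(out, dim(lab))
  if (output == "lab") lab_out else lab_to_rgb(lab_out)
}

#' Serialize / deserialize a Reinhard fit as JSON
#'
#' @param fit a `reinhard_fit`.
#' @param path JSON file path.
#' @return `path` invisibly (write) or the `reinhard_fit` (read).
#' @export
write_reinhard_fit <- function(fit, path) {
  jsonlite::write_json(
    list(space_tag = fit$space_tag,
         target_mean = fit$target_mean, target_sd = fit$target_sd),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_reinhard_fit
#' @export
read_reinhard_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$space_tag, "ruderman-lab")) {
    abort_wsimil("unknown color-space tag in fit file", "wsimil_format_error")
  }
  structure(
    list(target_mean = as.numeric(obj$target_mean),
         target_sd = as.numeric(obj$target_sd),
         space_tag = obj$space_tag),
    class = "reinhard_fit"
  )
}
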