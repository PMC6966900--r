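#' End-to-end chemical imaging of a hyperspectral Raman map
#'
#' Runs the full analysis chain on one map: noise reduction
#' ([preprocess_map()]), optional matched baseline correction of the
#' reference set, FCLS unmixing ([unmix_map()]), calibration
#' ([calibrate()]) and image rendering ([chemical_images()]).
#'
#' When the map is baseline-corrected, the references are corrected with
#' the same airPLS settings so that pixels and references live on the
#' same (peaks-only) signal scale; otherwise both keep their fluorescence
#' and unmixing exploits the full-range signal including the background.
#'
#' @param map A [raman_map].
#' @param refs A [reference_set] on the same axis.
#' @param W Optional calibration total (percent dry base).
#' @param normalize Unmixing scale convention, see [unmix_map()].
#' @param ... Stage switches and parameters passed to [preprocess_map()].
#' @return List with `map` (preprocessed), `refs` (as used), `result`
#'   (calibrated [unmix_map()] result), `images` (chemical images) and
#'   `reports` (preprocessing reports).
#' @export
chemical_imaging_pipeline <- function(map, refs, W = NULL,
                                      normalize = "max", ...) {
  pp <- preprocess_map(map, ...)
  args <- list(...)
  refs_used <- refs
  if (isTRUE(args$baseline %||% TRUE)) {
    lam <- args$lambda %||% 1e5
    refs_used$spectra <- airpls_matrix(refs$spectra, lambda = lam)
  }
  result <- unmix_map(pp$map, refs_used, normalize = normalize)
  if (!is.null(W)) result <- calibrate(result, W)
  list(map = pp$map, refs = refs_used, result = result,
       images = chemical_images(result), reports = pp$reports)
}
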