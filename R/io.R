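# File formats: 16-bit single-channel TIFF for images and label maps, CSV
# with header row / '.' decimal / UTF-8 for tables, JSON for configuration
# and fit results.

#' Read and write fluorescence channels and label maps
#'
#' Channels are stored as 16-bit single-channel TIFF; intensities on [0, 1]
#' are quantized to 1/65535 steps. Label maps are stored in the same
#' container with the integer label in the 16-bit sample, read back exactly
#' for labels up to 65535.
#'
#' @param path file path.
#' @param img numeric intensity matrix on [0, 1].
#' @return `read_channel()` a numeric matrix; `read_label_map()` an integer
#'   matrix.
#' @name channel_io
NULL

#' @rdname channel_io
#' @export
write_channel <- function(img, path) {
  stopifnot(is.matrix(img), is.numeric(img))
  tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname channel_io
#' @export
read_channel <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' @rdname channel_io
#' @param labels integer matrix of region labels (0..65535).
#' @export
write_label_map <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels >= 0), all(labels <= 65535))
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname channel_io
#' @export
read_label_map <- function(path) {
  m <- read_channel(path)
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' Relative expression by the -ddCt method
#'
#' Standard relative qPCR quantification: `dCt = Ct(target) -
#' Ct(housekeeping)` in sample and reference, and the fold change is
#' `2^-(dCt_sample - dCt_reference)`. Housekeeping Ct values are expected to
#' come from the assay's normalizer genes (e.g. 18S, GAPDH, beta-actin). Vectorized over replicates.
#'
#' @param ct_target_sample,ct_housekeeping_sample,ct_target_reference,ct_housekeeping_reference
#'   PCR cycle-threshold values (finite numerics of equal length).
#' @return Fold change(s), positive numeric.
#' @examples
#' relative_expression_ddct(20, 15, 22, 15)  # dCt 5 vs 7 -> fold 4
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_housekeeping_sample,
                                     ct_target_reference,
                                     ct_housekeeping_reference) {
  vals <- list(ct_target_sample, ct_housekeeping_sample,
               ct_target_reference, ct_housekeeping_reference)
  if (!all(vapply(vals, function(v) is.numeric(v) && all(is.finite(v)),
                  TRUE)))
    stop("all Ct values must be finite numbers", call. = FALSE)
  dct_sample <- ct_target_sample - ct_housekeeping_sample
  dct_ref <- ct_target_reference - ct_housekeeping_reference
  2^-(dct_sample - dct_ref)
}
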