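#' The 17-region gray-matter atlas
#'
#' Whole-brain gray matter merged into 17 regions of interest: seven lobar
#' cortical regions, Broca's area, insula, cingulate, cerebellum and six
#' subcortical structures. The order below is the canonical column order
#' used throughout the package.
#'
#' @param names character vector of region labels (default: the 17-region
#'   merge used for schizophrenia staging)
#' @param loss_direction per-region sign; `+1` means the disease lowers
#'   volume in that region (all regions by default)
#' @return an object of class `roi_atlas`
#' @export
roi_atlas <- function(names = default_roi_names(),
                      loss_direction = rep(1, length(names))) {
  if (anyDuplicated(names)) stop("atlas region names must be unique")
  if (length(loss_direction) != length(names))
    stop("loss_direction must match names in length")
  structure(list(names = as.character(names),
                 loss_direction = as.numeric(loss_direction)),
            class = "roi_atlas")
}

#' @rdname roi_atlas
#' @export
default_roi_names <- function() {
  c("frontal lobe", "temporal lobe", "parietal lobe", "occipital lobe",
    "insula", "cingulate", "sensorimotor", "Broca's area", "cerebellum",
    "hippocampus", "parahippocampus", "amygdala", "caudate", "putamen",
    "pallidum", "accumbens", "thalamus")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("ROI atlas with", length(x$names), "regions:\n")
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}
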