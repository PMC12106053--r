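# Macrostructural comparators: volume fractions of total intracranial
# volume and the cortical-thickness AD signature.

#' Volume fractions of total intracranial volume
#'
#' Expresses the morphometric volumes as fractions of total intracranial
#' volume (TIV) to account for head size: the bilateral hippocampal volume
#' fraction (HVF) averages left and right hippocampal volumes before
#' dividing by TIV; cortical (CVF), white-matter and white-matter
#' hypointensity fractions divide the respective volume by TIV.
#'
#' @param m Data frame with columns `hippocampus_left_mm3`,
#'   `hippocampus_right_mm3`, `cortical_volume_mm3`, `tiv_mm3` and
#'   optionally `white_matter_mm3`, `wm_hypointensities_mm3`.
#' @return Data frame with `hvf`, `cvf` and, when inputs are present,
#'   `wmf`, `wmhf`. Missing TIV propagates NA with a warning.
#' @export
volume_fractions <- function(m) {
  need <- c("hippocampus_left_mm3", "hippocampus_right_mm3",
            "cortical_volume_mm3", "tiv_mm3")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0L) {
    stop(sprintf("morphometry table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tiv <- m$tiv_mm3
  if (anyNA(tiv)) {
    warning(sprintf("%d subject(s) with missing TIV: fractions set to NA",
                    sum(is.na(tiv))))
  }
  if (any(tiv <= 0, na.rm = TRUE)) {
    stop("TIV must be > 0", call. = FALSE)
  }
  out <- data.frame(
    hvf = (m$hippocampus_left_mm3 + m$hippocampus_right_mm3) / 2 / tiv,
    cvf = m$cortical_volume_mm3 / tiv)
  if ("white_matter_mm3" %in% names(m)) {
    out$wmf <- m$white_matter_mm3 / tiv
  }
  if ("wm_hypointensities_mm3" %in% names(m)) {
    out$wmhf <- m$wm_hypointensities_mm3 / tiv
  }
  if ("subject_id" %in% names(m)) out <- cbind(m["subject_id"], out)
  out
}

#' Cortical-thickness AD signature
#'
#' Unweighted mean of the bilateral mean thicknesses of the signature
#' regions (superior temporal, parahippocampal, middle temporal, inferior
#' parietal, inferior temporal, fusiform, precuneus): 14 values per
#' subject. Thickness columns are named `thick_<hemi>_<region>` with hemi
#' in lh/rh.
#'
#' @param m Data frame of per-region mean thicknesses (mm).
#' @param regions Signature region set (defaults to the 7 standard regions).
#' @return Numeric vector of signature thicknesses (NA, with a warning,
#'   for subjects/regions with missing values).
#' @export
ct_signature <- function(m, regions = ct_signature_regions()) {
  check_region_names(regions, "thickness signature region set")
  cols <- as.vector(outer(c("thick_lh_", "thick_rh_"), regions, paste0))
  miss <- setdiff(cols, names(m))
  if (length(miss) > 0L) {
    warning(sprintf("missing thickness column(s): %s; signature set to NA",
                    paste(miss, collapse = ", ")))
    return(rep(NA_real_, nrow(m)))
  }
  x <- as.matrix(m[, cols, drop = FALSE])
  out <- rowMeans(x)
  if (anyNA(out)) {
    warning(sprintf("%d subject(s) with missing regional thickness: signature set to NA",
                    sum(is.na(out))))
  }
  out
}
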