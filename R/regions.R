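#' Desikan-Killiany cortical region names
#'
#' The 34 gyral-based cortical regions of the Desikan-Killiany atlas, per
#' hemisphere. All per-vertex labels handled by the package must come from
#' this list.
#'
#' @return Character vector of 34 region names.
#' @export
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
    "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
    "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
    "precentral", "precuneus", "rostralanteriorcingulate",
    "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
    "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")
}

#' Cortical-thickness AD-signature regions
#'
#' The bilateral temporo-parietal meta-region used for the cortical-thickness
#' signature: superior temporal, parahippocampal, middle temporal, inferior
#' parietal, inferior temporal, fusiform and precuneus.
#'
#' @return Character vector of 7 region names.
#' @export
ct_signature_regions <- function() {
  c("superiortemporal", "parahippocampal", "middletemporal",
    "inferiorparietal", "inferiortemporal", "fusiform", "precuneus")
}

#' Diffusivity AD-signature regions
#'
#' Default meta-region over which the cortical diffusivity metrics are
#' averaged: the thickness-signature regions plus the more medial posterior
#' regions (posterior cingulate and isthmus cingulate). Configurable wherever
#' a signature set is accepted.
#'
#' @return Character vector of 9 region names.
#' @export
diffusivity_signature_regions <- function() {
  c(ct_signature_regions(), "posteriorcingulate", "isthmuscingulate")
}

check_region_names <- function(regions, what = "region set") {
  bad <- setdiff(regions, dk_regions())
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s: unknown region name(s): %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(regions)
}
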