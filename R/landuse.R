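#' Land-use categories and derived land-use rank
#'
#' The five land-use categories surveyed, in derived land-use rank (DLUR)
#' order. DLUR is the numeric rank 1-5 assigned in the fixed order natural
#' forest > planted forest > low-producing grassland > high-producing
#' grassland > perennial cropland; it is a deterministic function of the
#' category, reflecting the observed ordering of community change rather
#' than an a priori intensity scale.
#'
#' @return `landUseLevels()` returns the five category labels in DLUR
#'   order; `dlurRank()` maps category labels to integer ranks 1-5.
#' @examples
#' dlurRank("NaturalForest")       # 1
#' dlurRank("perennial_cropland")  # 5
#' @export
landUseLevels <- function() {
  c("NaturalForest", "PlantedForest", "LowProducingGrassland",
    "HighProducingGrassland", "PerennialCropland")
}

# tolerant matching: "natural_forest", "Natural forest", "naturalforest"
# all map to the canonical label
.normalizeLandUse <- function(x) {
  key <- tolower(gsub("[^A-Za-z]", "", as.character(x)))
  canon <- landUseLevels()
  names(canon) <- tolower(canon)
  alias <- c(
    naturalforest = "NaturalForest",
    plantedforest = "PlantedForest",
    lowproducinggrassland = "LowProducingGrassland",
    highproducinggrassland = "HighProducingGrassland",
    perennialcropland = "PerennialCropland"
  )
  out <- unname(alias[key])
  bad <- !is.na(x) & nzchar(trimws(as.character(x))) & is.na(out)
  if (any(bad)) {
    stop("unknown land-use category: ",
         paste(unique(x[bad]), collapse = ", "),
         "; accepted values are ", paste(landUseLevels(), collapse = ", "),
         " (case/underscore variants allowed)")
  }
  out
}

#' @rdname landUseLevels
#' @param land_use character vector of land-use labels (canonical or
#'   case/underscore variants).
#' @export
dlurRank <- function(land_use) {
  lu <- .normalizeLandUse(land_use)
  match(lu, landUseLevels())
}
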