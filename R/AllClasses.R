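#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setOldClass("phylo")
setClassUnion("phyloOrNULL", members = c("phylo", "NULL"))

#' Container for an OTU-by-sample metabarcoding survey
#'
#' `RarescapeExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with the two extra pieces
#' of state this kind of survey carries around: a rooted, branch-lengthed
#' phylogeny over the OTUs, and the identities of the negative-control
#' samples used for tag-jump decontamination. The `"counts"` assay holds
#' non-negative integer read counts with OTUs as rows and samples as
#' columns; taxonomy lives in `rowData()`, sample metadata (land use,
#' derived land-use rank, coordinates, soil chemistry) in `colData()`.
#'
#' Subsetting with `[` keeps the tree and control list consistent: rows
#' prune the tree to the retained tips, columns drop absent controls.
#'
#' @slot tree a `phylo` object (or `NULL`) whose tip labels cover all OTU
#'   ids in the object.
#' @slot controlSamples character vector of column names that are
#'   negative controls.
#'
#' @seealso [RarescapeExperiment()] for construction, [otuCounts()],
#'   [otuTree()], [presenceAbsence()], [controlSamples()].
#' @export
setClass("RarescapeExperiment",
  contains = "SummarizedExperiment",
  slots = c(tree = "phyloOrNULL", controlSamples = "character")
)

.validRarescape <- function(object) {
  msg <- character()
  if (!("counts" %in% SummarizedExperiment::assayNames(object))) {
    return("assay 'counts' is required")
  }
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(cnt)) || is.null(colnames(cnt))) {
    msg <- c(msg, "counts must have OTU row names and sample column names")
  } else {
    if (anyDuplicated(rownames(cnt))) msg <- c(msg, "duplicated OTU ids")
    if (anyDuplicated(colnames(cnt))) msg <- c(msg, "duplicated sample ids")
  }
  if (anyNA(cnt) || any(cnt < 0)) {
    msg <- c(msg, "counts must be non-negative and non-missing")
  } else if (any(cnt != round(cnt))) {
    msg <- c(msg, "counts must be integral read counts")
  }
  bad <- setdiff(object@controlSamples, colnames(cnt))
  if (length(bad)) {
    msg <- c(msg, paste0("control samples not in table: ",
                         paste(bad, collapse = ", ")))
  }
  tr <- object@tree
  if (!is.null(tr)) {
    if (is.null(tr$edge.length)) {
      msg <- c(msg, "tree must have branch lengths")
    } else if (anyNA(tr$edge.length) || any(tr$edge.length < 0)) {
      msg <- c(msg, "tree branch lengths must be finite and >= 0")
    }
    if (anyDuplicated(tr$tip.label)) msg <- c(msg, "duplicated tree tips")
    miss <- setdiff(rownames(cnt), tr$tip.label)
    if (length(miss)) {
      msg <- c(msg, paste0(length(miss), " OTU(s) missing from the tree"))
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("RarescapeExperiment", .validRarescape)

#' Model of cross-sample tag-jump contamination
#'
#' Fitted by [fitTagJump()]: a single through-origin quantile-regression
#' coefficient `beta` relating an OTU's count in a negative control to the
#' maximum of its counts over all other samples.
#'
#' @slot beta non-negative slope at quantile `tau`.
#' @slot tau quantile level of the fit (default 0.90).
#' @slot nPoints number of (max-count, control-count) pairs used.
#' @export
setClass("TagJumpModel",
  slots = c(beta = "numeric", tau = "numeric", nPoints = "integer")
)

setValidity("TagJumpModel", function(object) {
  msg <- character()
  if (length(object@beta) != 1L || is.na(object@beta) || object@beta < 0) {
    msg <- c(msg, "beta must be a single non-negative number")
  }
  if (length(object@tau) != 1L || object@tau <= 0 || object@tau >= 1) {
    msg <- c(msg, "tau must lie strictly between 0 and 1")
  }
  if (length(msg)) msg else TRUE
})
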