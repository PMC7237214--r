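#' Build a RarescapeExperiment
#'
#' Assembles the OTU count matrix, taxonomy, sample metadata, phylogeny and
#' control-sample list into one validated object.
#'
#' @param counts integer matrix of read counts, OTUs in rows (row names =
#'   OTU ids), samples in columns (column names = sample ids).
#' @param taxonomy optional data.frame of lineage ranks, one row per OTU.
#'   Either row names or an `otu_id` column must match `rownames(counts)`.
#' @param sampleData optional data.frame of per-sample metadata (see
#'   [readSampleMetadata()]); matched to `colnames(counts)` by row names or
#'   a `sample_id` column.
#' @param tree optional rooted `phylo` tree with branch lengths whose tips
#'   include every OTU id.
#' @param controls character vector of control sample ids.
#' @return a [RarescapeExperiment-class] object.
#' @examples
#' cnt <- matrix(c(3L, 0L, 1L, 2L), 2, byrow = TRUE,
#'               dimnames = list(c("A", "B"), c("s1", "s2")))
#' RarescapeExperiment(cnt)
#' @export
RarescapeExperiment <- function(counts, taxonomy = NULL, sampleData = NULL,
                                tree = NULL, controls = character()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  rowDf <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if ("otu_id" %in% names(taxonomy)) {
      rownames(taxonomy) <- taxonomy$otu_id
      taxonomy$otu_id <- NULL
    }
    miss <- setdiff(rownames(counts), rownames(taxonomy))
    if (length(miss)) {
      stop("taxonomy is missing ", length(miss), " OTU(s), e.g. ", miss[1L])
    }
    rowDf <- S4Vectors::DataFrame(taxonomy[rownames(counts), , drop = FALSE])
  }
  colDf <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(sampleData)) {
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% names(sampleData)) {
      rownames(sampleData) <- sampleData$sample_id
      sampleData$sample_id <- NULL
    }
    miss <- setdiff(colnames(counts), rownames(sampleData))
    if (length(miss)) {
      stop("metadata is missing ", length(miss), " sample(s), e.g. ", miss[1L])
    }
    colDf <- S4Vectors::DataFrame(sampleData[colnames(counts), , drop = FALSE])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rowDf, colData = colDf
  )
  if (!is.null(tree)) {
    extra <- setdiff(tree$tip.label, rownames(counts))
    if (length(extra) && length(extra) < length(tree$tip.label)) {
      tree <- ape::drop.tip(tree, extra)
    }
  }
  new("RarescapeExperiment", se, tree = tree,
      controlSamples = as.character(controls))
}

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname accessors
#' @export
setGeneric("otuTree", function(x) standardGeneric("otuTree"))

#' @rdname accessors
#' @export
setGeneric("otuTree<-", function(x, value) standardGeneric("otuTree<-"))

#' @rdname accessors
#' @export
setGeneric("controlSamples", function(x) standardGeneric("controlSamples"))

#' @rdname accessors
#' @export
setGeneric("controlSamples<-",
           function(x, value) standardGeneric("controlSamples<-"))

#' @rdname accessors
#' @export
setGeneric("otuTaxonomy", function(x) standardGeneric("otuTaxonomy"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setGeneric("presenceAbsence",
           function(x, ...) standardGeneric("presenceAbsence"))

#' Accessors for RarescapeExperiment
#'
#' `otuCounts()` returns the integer count matrix (OTUs x samples);
#' `otuTaxonomy()` and `sampleData()` return the row/column annotations as
#' plain data.frames; `otuTree()` the phylogeny; `controlSamples()` the
#' negative-control sample ids. `presenceAbsence()` converts counts to a
#' 0/1 incidence matrix with the same dimnames; incidence is 1 exactly
#' where the count is positive.
#'
#' @param x a [RarescapeExperiment-class].
#' @param value replacement value.
#' @param dropControls logical; drop control columns from the incidence
#'   matrix (default `FALSE`).
#' @param ... passed on to methods.
#' @name accessors
#' @aliases otuCounts otuTree controlSamples otuTaxonomy sampleData
#'   presenceAbsence
NULL

#' @rdname accessors
#' @export
setMethod("otuCounts", "RarescapeExperiment", function(x) {
  SummarizedExperiment::assay(x, "counts")
})

#' @rdname accessors
#' @export
setMethod("otuTree", "RarescapeExperiment", function(x) x@tree)

#' @rdname accessors
#' @export
setMethod("otuTree<-", "RarescapeExperiment", function(x, value) {
  x@tree <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("controlSamples", "RarescapeExperiment", function(x) {
  x@controlSamples
})

#' @rdname accessors
#' @export
setMethod("controlSamples<-", "RarescapeExperiment", function(x, value) {
  x@controlSamples <- as.character(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("otuTaxonomy", "RarescapeExperiment", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @rdname accessors
#' @export
setMethod("sampleData", "RarescapeExperiment", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @rdname accessors
#' @export
setMethod("presenceAbsence", "RarescapeExperiment",
  function(x, dropControls = FALSE) {
    cnt <- otuCounts(x)
    if (dropControls && length(controlSamples(x))) {
      cnt <- cnt[, setdiff(colnames(cnt), controlSamples(x)), drop = FALSE]
    }
    pa <- (cnt > 0) + 0L
    dimnames(pa) <- dimnames(cnt)
    pa
  })

#' @export
setMethod("[", c("RarescapeExperiment", "ANY", "ANY", "ANY"),
  function(x, i, j, ..., drop = FALSE) {
    out <- callNextMethod()
    if (!missing(j)) {
      out@controlSamples <- intersect(x@controlSamples, colnames(out))
    }
    if (!missing(i) && !is.null(out@tree)) {
      if (nrow(out) == 0L) {
        out@tree <- NULL
      } else if (nrow(out) < length(out@tree$tip.label)) {
        if (nrow(out) < 2L) {
          out@tree <- NULL  # a one-tip tree is not representable
        } else {
          out@tree <- ape::keep.tip(out@tree, rownames(out))
        }
      }
    }
    out
  })

setMethod("show", "RarescapeExperiment", function(object) {
  cnt <- otuCounts(object)
  cat("RarescapeExperiment with", nrow(cnt), "OTUs x", ncol(cnt), "samples\n")
  cat("  total reads:", sum(cnt), "\n")
  cat("  controls:", if (length(object@controlSamples))
    paste(object@controlSamples, collapse = ", ") else "none", "\n")
  cat("  tree:", if (is.null(object@tree)) "none" else
    paste0(length(object@tree$tip.label), " tips"), "\n")
  tx <- otuTaxonomy(object)
  if (ncol(tx)) cat("  taxonomy ranks:", paste(names(tx), collapse = ", "), "\n")
  md <- sampleData(object)
  if ("land_use" %in% names(md)) {
    tb <- table(md$land_use)
    cat("  land uses:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "TagJumpModel", function(object) {
  cat("TagJumpModel: beta =", format(object@beta, digits = 6),
      "at tau =", object@tau, "(", object@nPoints, "pairs )\n")
  invisible(NULL)
})

#' @rdname accessors
#' @export
setGeneric("tagJumpBeta", function(x) standardGeneric("tagJumpBeta"))

#' @rdname accessors
#' @export
setMethod("tagJumpBeta", "TagJumpModel", function(x) x@beta)
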