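#' Read an OTU-by-sample count table
#'
#' Reads a tab-separated OTU table with OTU ids in the first column and
#' sample ids in the header row — the usual amplicon-table orientation
#' (OTUs as rows, samples as columns).
#'
#' @param path path to a TSV file.
#' @return integer matrix of counts with OTU row names and sample column
#'   names.
#' @export
readOtuTable <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (nrow(raw) == 0L) stop("no OTUs: the table body is empty")
  if (ncol(raw) < 2L) stop("no samples: the table has no count columns")
  ids <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(ids)) {
    stop("duplicated OTU id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicated sample id(s) in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("malformed count (non-integer or negative) at OTU '",
         ids[bad[1L, 1L]], "', sample '", samples[bad[1L, 2L]], "'")
  }
  storage.mode(num) <- "integer"
  dimnames(num) <- list(ids, samples)
  num
}

#' Write an OTU-by-sample count table
#'
#' @param counts integer matrix (OTUs x samples) with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(counts, path) {
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted Newick phylogeny
#'
#' Parses a single Newick tree and validates it for downstream use: unique
#' tip labels and a defined, finite, non-negative length on every branch.
#' The basal node of the tree is treated as the root (a basal polytomy is
#' accepted).
#'
#' @param path path to a Newick file containing one tree.
#' @param missingLengthZero if `TRUE`, branches without a stated length
#'   are assigned length 0 instead of being rejected.
#' @return a `phylo` object.
#' @export
readPhylogeny <- function(path, missingLengthZero = FALSE) {
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e))
  )
  if (is.null(tr)) stop("Newick parse error: no tree could be read")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1L]]
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicated tip label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (is.null(tr$edge.length)) {
    if (missingLengthZero) {
      tr$edge.length <- rep(0, nrow(tr$edge))
    } else {
      stop("tree has no branch lengths")
    }
  }
  if (anyNA(tr$edge.length) || any(!is.finite(tr$edge.length))) {
    if (missingLengthZero) {
      tr$edge.length[!is.finite(tr$edge.length)] <- 0
    } else {
      stop("tree has branches with missing lengths")
    }
  }
  if (any(tr$edge.length < 0)) stop("tree has negative branch lengths")
  tr
}

#' Read per-sample metadata
#'
#' Reads a CSV of sample metadata. Requires `sample_id` and `land_use`
#' columns; land-use labels are validated against the five accepted
#' categories (case/underscore variants tolerated) and the derived
#' land-use rank (`dlur`, 1-5) is assigned deterministically from the
#' category. An optional logical `is_control` column marks negative
#' controls, which may leave `land_use` empty. Any further columns
#' (latitude, altitude, soil chemistry) are carried through unchanged;
#' missing values are allowed and propagate to case-wise exclusion in the
#' covariate models.
#'
#' @param path path to a CSV file.
#' @return data.frame with one row per sample, including `land_use`
#'   (canonical labels), `dlur`, and `is_control`.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "land_use")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  if (!"is_control" %in% names(df)) df$is_control <- FALSE
  df$is_control <- as.logical(df$is_control)
  df$is_control[is.na(df$is_control)] <- FALSE
  blank <- is.na(df$land_use) | !nzchar(trimws(df$land_use))
  if (any(blank & !df$is_control)) {
    stop("non-control sample(s) without a land-use category: ",
         paste(df$sample_id[blank & !df$is_control], collapse = ", "))
  }
  lu <- rep(NA_character_, nrow(df))
  lu[!blank] <- .normalizeLandUse(df$land_use[!blank])
  df$land_use <- lu
  df$dlur <- ifelse(is.na(lu), NA_integer_, match(lu, landUseLevels()))
  rownames(df) <- df$sample_id
  df
}

#' Write a results table as TSV
#'
#' Writes any of the package's tabular results (metric tables, test
#' summaries, bootstrap output) with a deterministic column order and
#' numeric values at 6 significant digits, so that a round-trip read
#' reproduces the values to written precision.
#'
#' @param df non-empty data.frame of results.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(df, path) {
  df <- as.data.frame(df)
  if (nrow(df) == 0L) stop("refusing to write an empty results table")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
  utils::read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
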