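#' Restrict to terrestrial invertebrate phyla
#'
#' Drops every OTU whose phylum is not on the allow-list of expected
#' terrestrial invertebrate phyla. The default list matches the phyla
#' retained in the survey the package emulates.
#'
#' @param x a [RarescapeExperiment-class] with a `phylum` column in its
#'   taxonomy.
#' @param allow character vector of phylum names to keep.
#' @return the filtered object; a message reports how many OTUs were
#'   removed per kingdom.
#' @export
filterTerrestrial <- function(x, allow = terrestrialPhyla()) {
  tax <- otuTaxonomy(x)
  if (!"phylum" %in% names(tax)) stop("taxonomy lacks a 'phylum' column")
  keep <- !is.na(tax$phylum) & tax$phylum %in% allow
  if (!any(keep)) {
    warning("no OTUs left after terrestrial filtering")
  }
  removed <- tax[!keep, , drop = FALSE]
  if (nrow(removed)) {
    kg <- if ("kingdom" %in% names(removed)) removed$kingdom else "unknown"
    tb <- table(ifelse(is.na(kg), "unknown", kg))
    message("filterTerrestrial: removed ", nrow(removed), " OTU(s) [",
            paste(names(tb), tb, sep = ": ", collapse = "; "), "]")
  }
  x[keep, ]
}

#' @rdname filterTerrestrial
#' @export
terrestrialPhyla <- function() {
  c("Arthropoda", "Rotifera", "Nematoda", "Mollusca", "Annelida",
    "Platyhelminthes", "Tardigrada", "Gastrotricha", "Onychophora")
}

#' Drop OTUs found in only one sample
#'
#' Sensitivity variant of the analyses: removes every OTU whose occurrence
#' across the (non-control) samples is exactly 1, so that single-site
#' endemics no longer contribute.
#'
#' @param x a [RarescapeExperiment-class] or a presence/absence (or
#'   count) matrix with OTUs as rows.
#' @return the filtered object / matrix.
#' @export
dropSingleSiteOtus <- function(x) {
  if (is(x, "RarescapeExperiment")) {
    pa <- presenceAbsence(x, dropControls = TRUE)
  } else {
    pa <- (as.matrix(x) > 0) + 0L
  }
  occ <- rowSums(pa)
  keep <- occ != 1L
  if (!any(keep)) warning("all OTUs are single-site; returning empty table")
  if (is(x, "RarescapeExperiment")) x[keep, ] else x[keep, , drop = FALSE]
}

#' Flag samples with unusually low read abundance
#'
#' For ordinations of a taxonomic subset, samples whose total reads within
#' the subset fall below `fraction` times the mean per-sample total for
#' that subset are excluded. With the default `fraction = 0.05` this is
#' the "less than 5% of the mean sequence abundance" rule.
#'
#' @param x a [RarescapeExperiment-class] or count matrix.
#' @param otus OTU ids defining the subset (default: all rows).
#' @param fraction threshold as a fraction of the mean per-sample total.
#' @param manualExclude sample ids to exclude regardless of abundance
#'   (e.g. a sample that renders an ordination uninterpretable).
#' @return character vector of excluded sample ids.
#' @export
excludeLowAbundance <- function(x, otus = NULL, fraction = 0.05,
                                manualExclude = character()) {
  cnt <- if (is(x, "RarescapeExperiment")) {
    ids <- setdiff(colnames(x), controlSamples(x))
    otuCounts(x)[, ids, drop = FALSE]
  } else {
    as.matrix(x)
  }
  if (!is.null(otus)) {
    if (!length(otus)) stop("the group subset is empty")
    cnt <- cnt[intersect(otus, rownames(cnt)), , drop = FALSE]
  }
  tot <- colSums(cnt)
  thr <- fraction * mean(tot)
  out <- colnames(cnt)[tot < thr]
  union(out, intersect(manualExclude, colnames(cnt)))
}
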