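#' The 17 taxonomic analysis groups
#'
#' Per-group biodiversity metrics are computed for the five dominant
#' insect orders, a pooled group of all other insects, five non-insect
#' arthropod groups, and six non-arthropod phyla. OTUs that fit none of
#' these (including minor terrestrial phyla such as Gastrotricha and
#' Onychophora, which stay in the overall community but have no group of
#' their own) are labelled `"Excluded"`.
#'
#' @return character vector of the 17 group labels.
#' @export
analysisGroups <- function() {
  c("Coleoptera", "Diptera", "Hymenoptera", "Lepidoptera", "Hemiptera",
    "OtherInsects", "Collembola", "Mites", "NonMiteArachnida",
    "Malacostraca", "Myriapods", "Annelida", "Mollusca", "Nematoda",
    "Platyhelminthes", "Rotifera", "Tardigrada")
}

#' Assign OTUs to taxonomic analysis groups
#'
#' Maps lineages onto the 17 analysis groups (see [analysisGroups()]):
#' insects in the five dominant orders keep their order, all other insect
#' orders pool into `"OtherInsects"`; Collembola and Malacostraca are
#' their classes; Acari (by subclass or order) are `"Mites"` and all other
#' Arachnida `"NonMiteArachnida"`; the myriapod classes (Chilopoda,
#' Diplopoda, Symphyla, Pauropoda) pool into `"Myriapods"`; the six
#' non-arthropod phyla map to their phylum label; everything else is
#' `"Excluded"`. The labels partition the OTUs: each OTU gets exactly one.
#'
#' @param taxonomy data.frame of lineages with (some of) the columns
#'   `phylum`, `class`, `subclass`, `order`; row names or an `otu_id`
#'   column identify OTUs.
#' @return named character vector, OTU id -> group label.
#' @export
assignGroups <- function(taxonomy) {
  taxonomy <- as.data.frame(taxonomy)
  if ("otu_id" %in% names(taxonomy)) {
    rownames(taxonomy) <- taxonomy$otu_id
  }
  col <- function(nm) {
    if (nm %in% names(taxonomy)) as.character(taxonomy[[nm]])
    else rep(NA_character_, nrow(taxonomy))
  }
  phylum <- col("phylum"); cls <- col("class")
  subcls <- col("subclass"); ord <- col("order")
  ins5 <- c("Coleoptera", "Diptera", "Hymenoptera", "Lepidoptera",
            "Hemiptera")
  myri <- c("Chilopoda", "Diplopoda", "Symphyla", "Pauropoda")
  npPhyla <- c("Annelida", "Mollusca", "Nematoda", "Platyhelminthes",
               "Rotifera", "Tardigrada")
  out <- rep("Excluded", nrow(taxonomy))
  isArth <- !is.na(phylum) & phylum == "Arthropoda"
  isIns <- isArth & !is.na(cls) & cls == "Insecta"
  out[isIns] <- "OtherInsects"
  out[isIns & ord %in% ins5] <- ord[isIns & ord %in% ins5]
  out[isIns & is.na(ord)] <- "OtherInsects"
  out[isArth & !is.na(cls) & cls == "Collembola"] <- "Collembola"
  isArach <- isArth & !is.na(cls) & cls == "Arachnida"
  out[isArach] <- "NonMiteArachnida"
  acari <- isArach & ((!is.na(subcls) & subcls == "Acari") |
                        (!is.na(ord) & ord == "Acari"))
  out[acari] <- "Mites"
  out[isArth & !is.na(cls) & cls == "Malacostraca"] <- "Malacostraca"
  out[isArth & !is.na(cls) & cls %in% myri] <- "Myriapods"
  out[!is.na(phylum) & phylum %in% npPhyla] <- phylum[
    !is.na(phylum) & phylum %in% npPhyla]
  names(out) <- rownames(taxonomy)
  out
}
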