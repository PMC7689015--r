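# Controlled vocabulary for repeat and gene annotation types.
#
# Heterogeneous GFF3 feature types are mapped onto a fixed set of classes
# so that landscape and region summaries are computable from any
# annotation source; unmapped types fall into "other".

FEATURE_CLASSES <- c("gene", "LTR_gypsy", "LTR_copia", "LINE",
                     "ClassI_other", "ClassII", "rDNA_45S", "rDNA_5S",
                     "other")

TE_CLASSES <- c("LTR_gypsy", "LTR_copia", "LINE", "ClassI_other", "ClassII")
RDNA_CLASSES <- c("rDNA_45S", "rDNA_5S")

# free-text GFF3 type (lowercased) -> controlled class
default_class_map <- function() {
  c(gene = "gene", mrna = "gene", cds = "gene",
    ltr_gypsy = "LTR_gypsy", gypsy = "LTR_gypsy", rlg = "LTR_gypsy",
    ltr_copia = "LTR_copia", copia = "LTR_copia", rlc = "LTR_copia",
    line = "LINE", rix = "LINE",
    classi_other = "ClassI_other", classi = "ClassI_other",
    sine = "ClassI_other", ltr_unknown = "ClassI_other", rlx = "ClassI_other",
    classii = "ClassII", classii_other = "ClassII", tir = "ClassII",
    dna_transposon = "ClassII", dtx = "ClassII", helitron = "ClassII",
    rdna_45s = "rDNA_45S", rrna_45s = "rDNA_45S", rdna45s = "rDNA_45S",
    rdna_5s = "rDNA_5S", rrna_5s = "rDNA_5S", rdna5s = "rDNA_5S")
}

#' Map annotation feature types onto the controlled repeat vocabulary
#'
#' @param types Character vector of GFF3 feature types.
#' @param class_map Named character vector from lowercased free-text type
#'   to controlled class; defaults cover common REPET-style labels.
#' @return Factor with levels `gene, LTR_gypsy, LTR_copia, LINE,
#'   ClassI_other, ClassII, rDNA_45S, rDNA_5S, other`.
#' @export
classify_features <- function(types, class_map = default_class_map()) {
  cls <- unname(class_map[tolower(types)])
  cls[is.na(cls)] <- "other"
  factor(cls, levels = FEATURE_CLASSES)
}

#' Is a controlled class a transposable-element class?
#' @param classes Character or factor of controlled classes.
#' @return Logical vector.
#' @export
is_te_class <- function(classes) as.character(classes) %in% TE_CLASSES

#' Is a controlled class a ribosomal-DNA class?
#' @param classes Character or factor of controlled classes.
#' @return Logical vector.
#' @export
is_rdna_class <- function(classes) as.character(classes) %in% RDNA_CLASSES
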