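#' @include AllClasses.R
NULL

#' Oligotype count matrix accessor
#'
#' @param x An \code{OligotypeExperiment}.
#' @return Integer matrix, oligotypes x samples.
#' @export
setGeneric("oligotypeCounts", function(x) standardGeneric("oligotypeCounts"))

#' @rdname oligotypeCounts
#' @export
setMethod("oligotypeCounts", "OligotypeExperiment", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' Environment-group labels of the samples
#'
#' @param x An \code{OligotypeExperiment}.
#' @return Character vector, one label per sample.
#' @export
setGeneric("environmentGroups", function(x) standardGeneric("environmentGroups"))

#' @rdname environmentGroups
#' @export
setMethod("environmentGroups", "OligotypeExperiment", function(x)
  as.character(SummarizedExperiment::colData(x)$environment_group))

#' Representative sequences of oligotypes
#'
#' @param x An \code{OligotypeExperiment} or \code{MedDecomposition}.
#' @return Named character vector of representative sequences.
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname representatives
#' @export
setMethod("representatives", "OligotypeExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  setNames(as.character(rd$representative), rownames(x))
})

#' @rdname representatives
#' @export
setMethod("representatives", "MedDecomposition", function(x)
  setNames(x@nodes$representative, x@nodes$node_id))

#' Per-sample taxon sequence totals
#'
#' @param x An \code{OligotypeExperiment}.
#' @return Named integer vector, summed oligotype counts per sample.
#' @export
setGeneric("taxonTotals", function(x) standardGeneric("taxonTotals"))

#' @rdname taxonTotals
#' @export
setMethod("taxonTotals", "OligotypeExperiment", function(x)
  colSums(oligotypeCounts(x)))
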