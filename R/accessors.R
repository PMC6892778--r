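## Accessor generics and methods. Slot access from user code is discouraged;
## these are the supported surface.

#' @name accessors
#' @title Accessors for pathMG classes
#' @param x a pathMG object.
#' @description Small accessor functions for the S4 containers:
#' gene/sample rosters and derived statistics of a [MutationProfile-class],
#' pathway membership and graph structure of a [Pathway-class], and the
#' fields of extraction results.
NULL

#' @rdname accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
#' @rdname accessors
#' @export
setGeneric("mutationMatrix", function(x) standardGeneric("mutationMatrix"))
#' @rdname accessors
#' @export
setGeneric("mutationFrequency", function(x) standardGeneric("mutationFrequency"))
#' @rdname accessors
#' @export
setGeneric("sampleMutationCounts",
           function(x) standardGeneric("sampleMutationCounts"))
#' @rdname accessors
#' @export
setGeneric("pathwayId", function(x) standardGeneric("pathwayId"))
#' @rdname accessors
#' @export
setGeneric("pathwayName", function(x) standardGeneric("pathwayName"))
#' @rdname accessors
#' @export
setGeneric("pathwayGenes", function(x) standardGeneric("pathwayGenes"))
#' @rdname accessors
#' @export
setGeneric("pathwayEdges", function(x) standardGeneric("pathwayEdges"))
#' @rdname accessors
#' @export
setGeneric("pathwayGraph", function(x) standardGeneric("pathwayGraph"))
#' @rdname accessors
#' @export
setGeneric("geneListLabel", function(x) standardGeneric("geneListLabel"))
#' @rdname accessors
#' @export
setGeneric("geneListGenes", function(x) standardGeneric("geneListGenes"))
#' @rdname accessors
#' @export
setGeneric("memberGenes", function(x) standardGeneric("memberGenes"))
#' @rdname accessors
#' @export
setGeneric("greedyTrace", function(x) standardGeneric("greedyTrace"))

#' @rdname accessors
#' @export
setMethod("geneNames", "MutationProfile", function(x) rownames(x@mat))
#' @rdname accessors
#' @export
setMethod("sampleNames", "MutationProfile", function(x) colnames(x@mat))
#' @rdname accessors
#' @export
setMethod("nSamples", "MutationProfile", function(x) ncol(x@mat))
#' @rdname accessors
#' @export
setMethod("nGenes", "MutationProfile", function(x) nrow(x@mat))
#' @rdname accessors
#' @export
setMethod("mutationMatrix", "MutationProfile", function(x) x@mat)

#' @rdname accessors
#' @export
setMethod("mutationFrequency", "MutationProfile", function(x) {
    if (ncol(x@mat) == 0L) stop("profile has no samples")
    Matrix::rowSums(x@mat) / ncol(x@mat)
})

#' @rdname accessors
#' @export
setMethod("sampleMutationCounts", "MutationProfile",
          function(x) Matrix::colSums(x@mat))

#' @rdname accessors
#' @export
setMethod("pathwayId", "Pathway", function(x) x@pathwayId)
#' @rdname accessors
#' @export
setMethod("pathwayName", "Pathway", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("pathwayGenes", "Pathway", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("pathwayEdges", "Pathway", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("pathwayGraph", "Pathway", function(x) {
    igraph::graph_from_data_frame(
        as.data.frame(x@edges, stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = x@genes, stringsAsFactors = FALSE))
})

#' @rdname accessors
#' @export
setMethod("geneListLabel", "GeneList", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("geneListGenes", "GeneList", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("pathwayId", "SubPathway", function(x) x@pathwayId)
#' @rdname accessors
#' @export
setMethod("pathwayId", "SubtypeSubPathway", function(x) x@pathwayId)
#' @rdname accessors
#' @export
setMethod("memberGenes", "SubPathway", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("memberGenes", "SubtypeSubPathway", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("greedyTrace", "SubPathway", function(x) x@trace)
#' @rdname accessors
#' @export
setMethod("greedyTrace", "SubtypeSubPathway", function(x) x@trace)

## internal: accept GeneList or character
.asGenes <- function(x) {
    if (is(x, "GeneList")) geneListGenes(x) else unique(as.character(x))
}
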