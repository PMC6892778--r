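#' @importClassesFrom Matrix dgCMatrix
#' @importFrom methods new validObject is as setValidity show slot
#' @importFrom stats rnbinom fisher.test phyper p.adjust chisq.test setNames
#' @importFrom utils read.delim write.table head packageVersion
NULL

## ---------------------------------------------------------------------------
## MutationProfile: binary gene x sample somatic mutation indicator matrix.
## Stored sparse; a cell is 1 iff the gene carries >= 1 somatic variant in
## that sample (variant multiplicity is collapsed on construction).
## ---------------------------------------------------------------------------

#' Binary somatic mutation profile
#'
#' An S4 container for a binary gene-by-sample mutation indicator matrix.
#' Rows are gene symbols, columns are tumour sample identifiers; a cell is 1
#' iff the gene carries at least one somatic variant in that sample. The
#' matrix is stored as a sparse [Matrix::dgCMatrix-class].
#'
#' @slot mat sparse numeric matrix of 0/1 indicators with gene rownames and
#'   sample colnames.
#' @export
setClass("MutationProfile", slots = c(mat = "dgCMatrix"))

setValidity("MutationProfile", function(object) {
    m <- object@mat
    msg <- character()
    if ((nrow(m) > 0L && is.null(rownames(m))) ||
        (ncol(m) > 0L && is.null(colnames(m))))
        msg <- c(msg, "gene rownames and sample colnames are required")
    if (!is.null(rownames(m)) && anyDuplicated(rownames(m)))
        msg <- c(msg, "duplicated gene identifiers")
    if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
        msg <- c(msg, "duplicated sample identifiers")
    if (length(m@x) && !all(m@x == 1))
        msg <- c(msg, "mutation indicators must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' Construct a MutationProfile
#'
#' @param x a matrix-like object (base matrix, data.frame or Matrix) of 0/1
#'   indicators with gene rownames and sample colnames. Values other than 0
#'   and 1 are rejected.
#' @return a [MutationProfile-class] object.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("TP53", "KRAS"), c("s1", "s2")))
#' MutationProfile(m)
#' @export
MutationProfile <- function(x) {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (is(x, "MutationProfile")) return(x)
    vals <- if (is(x, "Matrix")) x@x else as.vector(x)
    if (length(vals) && !all(vals %in% c(0, 1)))
        stop("mutation indicators must be 0 or 1")
    m <- as(as(as(Matrix::Matrix(x, sparse = TRUE), "dMatrix"),
               "generalMatrix"), "CsparseMatrix")
    m <- Matrix::drop0(m)
    new("MutationProfile", mat = m)
}

## internal: build from (gene index, sample index) pairs
.newProfile <- function(gi, si, genes, samples) {
    m <- Matrix::sparseMatrix(i = gi, j = si, x = 1,
                              dims = c(length(genes), length(samples)),
                              dimnames = list(genes, samples),
                              use.last.ij = TRUE)
    m@x[] <- 1  # collapse multiplicities
    new("MutationProfile", mat = Matrix::drop0(m))
}

setMethod("show", "MutationProfile", function(object) {
    m <- object@mat
    cat("MutationProfile:", nrow(m), "genes x", ncol(m), "samples\n")
    cat("  mutated (gene,sample) pairs:", length(m@x), "\n")
    cs <- Matrix::colSums(m)
    cat("  per-sample mutated genes: median", stats::median(cs),
        " range [", min(cs), ",", max(cs), "]\n")
})

setMethod("[", "MutationProfile", function(x, i, j, ..., drop = FALSE) {
    m <- x@mat
    if (missing(i)) i <- seq_len(nrow(m))
    if (missing(j)) j <- seq_len(ncol(m))
    new("MutationProfile", mat = m[i, j, drop = FALSE])
})

## ---------------------------------------------------------------------------
## Pathway: named gene set plus undirected gene-gene interaction edges.
## ---------------------------------------------------------------------------

#' Pathway gene set with interaction edges
#'
#' A pathway is a named set of gene symbols together with undirected
#' gene--gene interaction edges (e.g. from a curated pathway database).
#' Edges are stored as unordered pairs, deduplicated, with both endpoints
#' required to be pathway members; genes without any edge are legal
#' (isolated) members.
#'
#' @slot pathwayId stable identifier.
#' @slot name display name.
#' @slot genes character vector of member gene symbols.
#' @slot edges two-column character matrix of unordered gene pairs.
#' @export
setClass("Pathway", slots = c(pathwayId = "character", name = "character",
                              genes = "character", edges = "matrix"))

setValidity("Pathway", function(object) {
    msg <- character()
    if (length(object@pathwayId) != 1L) msg <- c(msg, "pathwayId must be length 1")
    if (anyDuplicated(object@genes)) msg <- c(msg, "duplicated genes")
    e <- object@edges
    if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
    else if (nrow(e)) {
        if (!all(e %in% object@genes))
            msg <- c(msg, "edge endpoints must be pathway members")
        if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loop edges not allowed")
        key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
        if (anyDuplicated(key)) msg <- c(msg, "duplicated edges")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Pathway
#'
#' @param id stable pathway identifier.
#' @param genes character vector of member gene symbols (deduplicated).
#' @param edges two-column matrix or data.frame of gene pairs; orientation is
#'   ignored and duplicate pairs are collapsed. Both endpoints must be in
#'   `genes`. `NULL` means no edges.
#' @param name display name; defaults to `id`.
#' @return a [Pathway-class] object.
#' @examples
#' Pathway("P1", genes = c("g1", "g2", "g3"),
#'         edges = rbind(c("g1", "g2"), c("g2", "g1")))
#' @export
Pathway <- function(id, genes, edges = NULL, name = id) {
    genes <- unique(as.character(genes))
    if (is.null(edges) || NROW(edges) == 0L) {
        em <- matrix(character(), 0L, 2L)
    } else {
        if (is.data.frame(edges)) edges <- as.matrix(edges)
        a <- as.character(edges[, 1L]); b <- as.character(edges[, 2L])
        keep <- a != b
        a <- a[keep]; b <- b[keep]
        lo <- pmin(a, b); hi <- pmax(a, b)
        key <- !duplicated(paste(lo, hi))
        em <- cbind(lo[key], hi[key])
    }
    dimnames(em) <- NULL
    new("Pathway", pathwayId = as.character(id), name = as.character(name),
        genes = genes, edges = em)
}

setMethod("show", "Pathway", function(object) {
    cat("Pathway", object@pathwayId, "(", object@name, "):",
        length(object@genes), "genes,", nrow(object@edges), "edges\n")
})

## ---------------------------------------------------------------------------
## GeneList: labelled gene set (background universe, cancer genes, ...).
## ---------------------------------------------------------------------------

#' Labelled gene list
#'
#' @slot label what the list represents, e.g. `"background"`,
#'   `"cancer_genes"`, `"drug_targets"` or `"custom"`.
#' @slot genes non-empty character vector of unique gene symbols.
#' @export
setClass("GeneList", slots = c(label = "character", genes = "character"))

setValidity("GeneList", function(object) {
    msg <- character()
    if (length(object@genes) == 0L) msg <- c(msg, "gene list is empty")
    if (anyDuplicated(object@genes)) msg <- c(msg, "duplicated genes")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneList
#'
#' @param genes character vector of gene symbols; duplicates are collapsed.
#' @param label list label (default `"custom"`).
#' @return a [GeneList-class] object.
#' @export
GeneList <- function(genes, label = "custom") {
    genes <- unique(as.character(genes))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("gene list is empty")
    new("GeneList", label = as.character(label), genes = genes)
}

setMethod("show", "GeneList", function(object) {
    cat("GeneList [", object@label, "]: ", length(object@genes), " genes\n",
        sep = "")
})

## ---------------------------------------------------------------------------
## SubtypeLabels: sample -> subtype assignment for two-group comparisons.
## ---------------------------------------------------------------------------

#' Sample-to-subtype assignment
#'
#' Maps each labelled sample to one of exactly two subtype tags (e.g. LUAD
#' vs LSCC). Both subtypes must contain at least one sample.
#'
#' @slot sample character vector of sample identifiers.
#' @slot subtype parallel character vector of subtype tags.
#' @export
setClass("SubtypeLabels", slots = c(sample = "character", subtype = "character"))

setValidity("SubtypeLabels", function(object) {
    msg <- character()
    if (length(object@sample) != length(object@subtype))
        msg <- c(msg, "sample and subtype must have equal length")
    if (anyDuplicated(object@sample)) msg <- c(msg, "duplicated sample labels")
    tags <- unique(object@subtype)
    if (length(tags) != 2L)
        msg <- c(msg, "exactly two subtype tags are required")
    if (length(msg)) msg else TRUE
})

#' Construct SubtypeLabels
#'
#' @param sample sample identifiers, or a named character vector of subtype
#'   tags (names = samples) if `subtype` is missing.
#' @param subtype subtype tag per sample; exactly two distinct tags.
#' @return a [SubtypeLabels-class] object.
#' @export
SubtypeLabels <- function(sample, subtype) {
    if (missing(subtype)) {
        subtype <- unname(as.character(sample))
        sample <- names(sample)
    }
    new("SubtypeLabels", sample = as.character(sample),
        subtype = as.character(subtype))
}

setMethod("show", "SubtypeLabels", function(object) {
    cat("SubtypeLabels:", length(object@sample), "samples;",
        paste(sprintf("%s=%d", names(table(object@subtype)),
                      as.integer(table(object@subtype))), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## SubPathway / SubtypeSubPathway: greedy extraction results.
## ---------------------------------------------------------------------------

#' Common sub-pathway
#'
#' A connected gene set extracted from one connected component of a pathway
#' interaction graph, whose member-gene mutations jointly cover at least the
#' configured fraction of cohort samples.
#'
#' @slot pathwayId source pathway identifier.
#' @slot pathwayName source pathway display name.
#' @slot componentIndex 1-based index of the connected component.
#' @slot genes member genes in insertion order.
#' @slot coverage fraction of cohort samples with >= 1 mutation in the set.
#' @slot trace data.frame log of the greedy growth (gene, gain, class).
#' @export
setClass("SubPathway",
         slots = c(pathwayId = "character", pathwayName = "character",
                   componentIndex = "integer", genes = "character",
                   coverage = "numeric", trace = "data.frame"))

setMethod("show", "SubPathway", function(object) {
    cat(sprintf("SubPathway [%s #%d]: %d genes, coverage %.3f\n",
                object@pathwayId, object@componentIndex,
                length(object@genes), object@coverage))
    cat(" ", paste(object@genes, collapse = "; "), "\n")
})

#' Subtype-specific sub-pathway
#'
#' A connected gene set whose mutation coverage differs between two cancer
#' subtypes by at least the configured threshold, with a significant
#' two-sided Fisher exact test on the sub-pathway mutation status vs subtype.
#'
#' @slot pathwayId,pathwayName,componentIndex,genes,trace as in
#'   [SubPathway-class].
#' @slot direction `"A-specific"` or `"B-specific"`.
#' @slot coverageA,coverageB sub-pathway mutation frequency per subtype.
#' @slot diff coverageA - coverageB.
#' @slot fisherP two-sided Fisher exact p on the 2x2 mutated-status table.
#' @export
setClass("SubtypeSubPathway",
         slots = c(pathwayId = "character", pathwayName = "character",
                   componentIndex = "integer", direction = "character",
                   genes = "character", coverageA = "numeric",
                   coverageB = "numeric", diff = "numeric",
                   fisherP = "numeric", trace = "data.frame"))

setMethod("show", "SubtypeSubPathway", function(object) {
    cat(sprintf(
        "SubtypeSubPathway [%s #%d, %s]: %d genes, covA %.3f covB %.3f diff %+.3f (Fisher p=%.3g)\n",
        object@pathwayId, object@componentIndex, object@direction,
        length(object@genes), object@coverageA, object@coverageB,
        object@diff, object@fisherP))
    cat(" ", paste(object@genes, collapse = "; "), "\n")
})
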