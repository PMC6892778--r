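## Hypergeometric enrichment of sub-pathway gene sets against curated gene
## lists (cancer genes, drug targets) over a background universe, normally
## the union of genes in the loaded pathway collection. Raw upper-tail p
## values are reported; no multiplicity correction is applied.

#' Upper-tail hypergeometric enrichment of a gene set
#'
#' Tests whether `query` overlaps `target` more than expected when drawing
#' `|query|` genes from `background`:
#' `p = P(X >= overlap)` with `X ~ Hypergeometric(N = |background|,
#' K = |target intersect background|, n = |query intersect background|)`.
#' Query genes
#' outside the background are dropped with a warning; the target is
#' intersected with the background before testing.
#'
#' @param query gene set to test (character, [GeneList-class],
#'   [SubPathway-class] or [SubtypeSubPathway-class]).
#' @param target a [GeneList-class] (or character) to test against.
#' @param background the gene universe ([GeneList-class] or character).
#' @param id identifier recorded in the result row (default `""`).
#' @return one-row data.frame: `subpathway_id`, `list_label`, `n_query`,
#'   `n_overlap`, `n_list`, `n_background`, `p`.
#' @export
hypergeomEnrichment <- function(query, target, background, id = "") {
    if (is(query, "SubPathway") || is(query, "SubtypeSubPathway")) {
        if (identical(id, ""))
            id <- paste0(query@pathwayId, ":", query@componentIndex)
        query <- memberGenes(query)
    }
    label <- if (is(target, "GeneList")) geneListLabel(target) else "custom"
    bg <- .asGenes(background)
    if (!length(bg)) stop("background universe is empty")
    query <- .asGenes(query)
    outside <- setdiff(query, bg)
    if (length(outside)) {
        warning(length(outside),
                " query gene(s) outside the background were dropped")
        query <- intersect(query, bg)
    }
    K <- length(intersect(.asGenes(target), bg))
    n <- length(query)
    x <- length(intersect(query, .asGenes(target)))
    N <- length(bg)
    p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(subpathway_id = id, list_label = label, n_query = n,
               n_overlap = x, n_list = K, n_background = N, p = p,
               stringsAsFactors = FALSE)
}

#' Enrichment of every sub-pathway against every gene list
#'
#' @param subpathways list of [SubPathway-class] /
#'   [SubtypeSubPathway-class] objects.
#' @param lists list of [GeneList-class] objects (e.g. cancer genes, drug
#'   targets).
#' @param background the gene universe; by convention the union of genes
#'   across the loaded pathway collection.
#' @param alpha significance flag cutoff on the raw p (default 0.05).
#' @return data.frame with one row per (sub-pathway, list) and a logical
#'   `significant` column; zero rows on empty input.
#' @export
enrichAll <- function(subpathways, lists, background, alpha = 0.05) {
    if (!length(subpathways) || !length(lists)) {
        return(data.frame(subpathway_id = character(),
                          list_label = character(), n_query = integer(),
                          n_overlap = integer(), n_list = integer(),
                          n_background = integer(), p = numeric(),
                          significant = logical(), stringsAsFactors = FALSE))
    }
    rows <- list()
    for (i in seq_along(subpathways))
        for (gl in lists)
            rows[[length(rows) + 1L]] <-
                hypergeomEnrichment(subpathways[[i]], gl, background)
    d <- do.call(rbind, rows)
    d$significant <- d$p < alpha
    d
}

#' Background universe of a pathway collection
#'
#' @param pathways list of [Pathway-class] objects.
#' @return a [GeneList-class] labelled `"background"` holding the union of
#'   member genes.
#' @export
pathwayUniverse <- function(pathways) {
    GeneList(unique(unlist(lapply(pathways, pathwayGenes),
                           use.names = FALSE)),
             label = "background")
}
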