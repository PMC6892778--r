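## Readers and writers for the plain-text formats the pipeline consumes:
## MAF variant tables, binary gene x sample matrices, GMT gene sets plus
## per-pathway edge lists, line-per-gene lists and sample->subtype labels.
## Gene identifiers are matched by exact, case-sensitive string equality
## throughout; no alias resolution is attempted.

#' Read a MAF somatic variant table into a binary mutation profile
#'
#' Reads a tab-separated Mutation Annotation Format file and collapses it to
#' a gene-level binary indicator: a (gene, sample) cell is 1 iff at least one
#' retained variant row maps to that pair. Samples whose variants are all
#' excluded by `excludeClasses` are kept in the roster with all-zero
#' indicators, so the cohort size N reflects every sample seen in the file.
#'
#' @param path MAF file; must contain columns `Hugo_Symbol` and
#'   `Tumor_Sample_Barcode`, optionally `Variant_Classification`.
#' @param excludeClasses character vector of `Variant_Classification` values
#'   to drop (e.g. `"Silent"`); default keeps every row.
#' @return a [MutationProfile-class].
#' @export
readMAF <- function(path, excludeClasses = character()) {
    d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
    req <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
    miss <- setdiff(req, colnames(d))
    if (length(miss))
        stop("MAF file is missing required column(s): ",
             paste(miss, collapse = ", "))
    if (nrow(d) == 0L) stop("MAF file contains no variant rows")
    samples <- unique(as.character(d$Tumor_Sample_Barcode))
    if (length(excludeClasses)) {
        if (!"Variant_Classification" %in% colnames(d))
            stop("excludeClasses given but MAF has no Variant_Classification column")
        d <- d[!(d$Variant_Classification %in% excludeClasses), , drop = FALSE]
    }
    genes <- unique(as.character(d$Hugo_Symbol))
    if (!length(genes)) {
        # all variants excluded: 0-gene profile over the full sample roster
        m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(0L, length(samples)),
                                  dimnames = list(character(), samples))
        warning("all variants excluded; profile has no mutated genes")
        return(new("MutationProfile", mat = m))
    }
    .newProfile(gi = match(as.character(d$Hugo_Symbol), genes),
                si = match(as.character(d$Tumor_Sample_Barcode), samples),
                genes = genes, samples = samples)
}

#' Read a binary gene x sample mutation matrix
#'
#' @param path TSV with a header of sample identifiers, one row per gene
#'   (first column = gene symbol) and cell values 0/1.
#' @return a [MutationProfile-class] preserving the file's row and column
#'   order.
#' @export
readMutationMatrix <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(d) == 0L || ncol(d) < 2L)
        stop("mutation matrix is empty")
    genes <- as.character(d[[1L]])
    if (anyDuplicated(genes))
        stop("duplicated gene row(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    m <- as.matrix(d[, -1L, drop = FALSE])
    if (!is.numeric(m) || !all(m %in% c(0, 1)))
        stop("mutation matrix cells must be 0 or 1")
    rownames(m) <- genes
    MutationProfile(m)
}

#' Write a mutation profile as a binary TSV matrix
#'
#' Inverse of [readMutationMatrix()]; round-trips exactly.
#'
#' @param profile a [MutationProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMutationMatrix <- function(profile, path) {
    m <- as.matrix(mutationMatrix(profile))
    storage.mode(m) <- "integer"
    d <- data.frame(gene = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a pathway collection from GMT gene sets plus an edge list
#'
#' @param gmtPath GMT file: tab-separated lines `pathway_id`, `name`,
#'   member genes...
#' @param edgesPath TSV of interaction edges with three columns
#'   `pathway_id`, `geneA`, `geneB` (no header). Edges naming an unknown
#'   pathway or an endpoint outside that pathway's gene set are format
#'   errors, reported with their line number. Duplicate and reversed pairs
#'   collapse to one undirected edge; `NULL` loads edge-free pathways.
#' @return a list of [Pathway-class] objects, in GMT order.
#' @export
readPathways <- function(gmtPath, edgesPath = NULL) {
    lines <- readLines(gmtPath)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("GMT file is empty")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad))
        stop("GMT line ", bad[1L], " has fewer than three fields")
    ids <- vapply(parts, `[[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicated pathway id(s) in GMT: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    edges <- rep(list(NULL), length(ids))
    names(edges) <- ids
    e <- NULL
    if (!is.null(edgesPath)) {
        e <- read.delim(edgesPath, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
        if (ncol(e) < 3L) stop("edge file must have three columns")
        unknown <- which(!(e[[1L]] %in% ids))
        if (length(unknown))
            stop("edge file line ", unknown[1L], ": unknown pathway id '",
                 e[[1L]][unknown[1L]], "'")
    }
    out <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        p <- parts[[i]]
        genes <- unique(p[-(1:2)])
        genes <- genes[nzchar(genes)]
        em <- NULL
        if (!is.null(e)) {
            sel <- which(e[[1L]] == ids[i])
            if (length(sel)) {
                outside <- !(e[[2L]][sel] %in% genes & e[[3L]][sel] %in% genes)
                if (any(outside)) {
                    ln <- sel[which(outside)[1L]]
                    badg <- setdiff(c(e[[2L]][ln], e[[3L]][ln]), genes)
                    stop("edge file line ", ln, ": gene(s) ",
                         paste(badg, collapse = ", "),
                         " not in gene set of pathway ", ids[i])
                }
                em <- cbind(e[[2L]][sel], e[[3L]][sel])
            }
        }
        out[[i]] <- Pathway(ids[i], genes = genes, edges = em,
                            name = p[[2L]])
    }
    out
}

#' Write a pathway collection as GMT + edge list
#'
#' Inverse of [readPathways()].
#'
#' @param pathways list of [Pathway-class] objects.
#' @param gmtPath,edgesPath output files.
#' @return invisibly, a list with the two paths.
#' @export
writePathways <- function(pathways, gmtPath, edgesPath) {
    gmt <- vapply(pathways, function(p)
        paste(c(pathwayId(p), pathwayName(p), pathwayGenes(p)),
              collapse = "\t"), "")
    writeLines(gmt, gmtPath)
    rows <- do.call(rbind, lapply(pathways, function(p) {
        e <- pathwayEdges(p)
        if (!nrow(e)) return(NULL)
        cbind(pathwayId(p), e)
    }))
    if (is.null(rows)) rows <- matrix(character(), 0L, 3L)
    write.table(rows, edgesPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(list(gmt = gmtPath, edges = edgesPath))
}

#' Read a plain-text gene list
#'
#' @param path file with one gene symbol per line; blank lines are ignored
#'   and duplicates collapsed.
#' @param label list label (see [GeneList()]).
#' @return a [GeneList-class].
#' @export
readGeneList <- function(path, label = "custom") {
    g <- trimws(readLines(path))
    g <- g[nzchar(g)]
    if (!length(g)) stop("gene list file is empty: ", path)
    GeneList(g, label = label)
}

#' Write a gene list
#' @param geneList a [GeneList-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneList <- function(geneList, path) {
    writeLines(geneListGenes(geneList), path)
    invisible(path)
}

#' Read sample-to-subtype labels
#'
#' @param path two-column TSV (sample, subtype) with header.
#' @return a [SubtypeLabels-class].
#' @export
readSubtypeLabels <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE)
    if (ncol(d) < 2L) stop("subtype label file must have two columns")
    SubtypeLabels(sample = as.character(d[[1L]]),
                  subtype = as.character(d[[2L]]))
}

#' Split a mutation profile by subtype
#'
#' Labelled samples missing from the profile are a hard error (a silent drop
#' would hide a cohort mismatch); profile samples without a label are
#' excluded from the split with a message. The two subtype tags are ordered
#' alphabetically: the first becomes element `A`, the second element `B`.
#'
#' @param profile a [MutationProfile-class].
#' @param labels a [SubtypeLabels-class].
#' @return named list with elements `A` and `B` ([MutationProfile-class]
#'   each) and attribute `tags` giving the tag mapped to each element.
#' @export
splitBySubtype <- function(profile, labels) {
    stopifnot(is(profile, "MutationProfile"), is(labels, "SubtypeLabels"))
    missing <- setdiff(labels@sample, sampleNames(profile))
    if (length(missing))
        stop("labelled sample(s) not in profile: ",
             paste(head(missing, 5L), collapse = ", "))
    unlabelled <- setdiff(sampleNames(profile), labels@sample)
    if (length(unlabelled))
        message(length(unlabelled),
                " unlabelled sample(s) excluded from the subtype split")
    tags <- sort(unique(labels@subtype))
    sA <- labels@sample[labels@subtype == tags[1L]]
    sB <- labels@sample[labels@subtype == tags[2L]]
    structure(list(A = profile[, sA], B = profile[, sB]),
              tags = c(A = tags[1L], B = tags[2L]))
}

## ---------------------------------------------------------------------------
## Report writers. Reports are TSV with '#'-prefixed provenance header lines
## (tool version, seed, effective parameters) so a run is self-describing;
## no timestamps, so identical runs are byte-identical.
## ---------------------------------------------------------------------------

.reportHeader <- function(params = NULL, seed = NULL) {
    h <- paste0("# pathMG ", as.character(utils::packageVersion("pathMG")))
    if (!is.null(seed)) h <- c(h, paste0("# seed: ", seed))
    if (!is.null(params)) {
        flat <- vapply(names(params), function(nm) {
            v <- params[[nm]]
            paste0(nm, "=", if (is.null(v)) "NULL" else
                   paste(v, collapse = ","))
        }, "")
        h <- c(h, paste0("# params: ", paste(flat, collapse = " ")))
    }
    h
}

.writeReport <- function(d, path, params = NULL, seed = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.reportHeader(params, seed), con)
    write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Turn a list of sub-pathways into a report table
#'
#' @param subpathways list of [SubPathway-class] or
#'   [SubtypeSubPathway-class] objects (one kind per call).
#' @return a data.frame, one row per sub-pathway, genes semicolon-joined in
#'   insertion order. Zero-row with the right columns on empty input.
#' @export
subPathwayTable <- function(subpathways) {
    if (!length(subpathways)) {
        return(data.frame(pathway_id = character(), name = character(),
                          component_index = integer(), n_genes = integer(),
                          coverage = numeric(), genes = character(),
                          stringsAsFactors = FALSE))
    }
    if (is(subpathways[[1L]], "SubtypeSubPathway")) {
        return(do.call(rbind, lapply(subpathways, function(s)
            data.frame(pathway_id = s@pathwayId, name = s@pathwayName,
                       component_index = s@componentIndex,
                       direction = s@direction, n_genes = length(s@genes),
                       coverage_A = s@coverageA, coverage_B = s@coverageB,
                       diff = s@diff, fisher_p = s@fisherP,
                       genes = paste(s@genes, collapse = ";"),
                       stringsAsFactors = FALSE))))
    }
    do.call(rbind, lapply(subpathways, function(s)
        data.frame(pathway_id = s@pathwayId, name = s@pathwayName,
                   component_index = s@componentIndex,
                   n_genes = length(s@genes), coverage = s@coverage,
                   genes = paste(s@genes, collapse = ";"),
                   stringsAsFactors = FALSE)))
}
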