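#' @name tcrclone-generics
#' @title Accessor generics
#' @description Accessors for the package's S4 containers; use these rather
#'   than slot access.
#' @param x an object.
#' @param ... passed to methods.
NULL

#' @rdname tcrclone-generics
#' @export
setGeneric("chainRecords", function(x) standardGeneric("chainRecords"))

#' @rdname tcrclone-generics
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname tcrclone-generics
#' @export
setGeneric("referenceEntries", function(x) standardGeneric("referenceEntries"))

#' @rdname tcrclone-generics
#' @export
setGeneric("vertexTable", function(x) standardGeneric("vertexTable"))

#' @rdname tcrclone-generics
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname tcrclone-generics
#' @export
setGeneric("junctionSummary", function(x) standardGeneric("junctionSummary"))

#' @rdname tcrclone-generics
#' @export
setGeneric("donorMatrix", function(x) standardGeneric("donorMatrix"))

#' @rdname tcrclone-generics
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname tcrclone-generics
#' @export
setGeneric("distancePairs", function(x) standardGeneric("distancePairs"))

#' @rdname tcrclone-generics
#' @param path output file path.
#' @export
setGeneric("writeTable", function(x, path, ...) standardGeneric("writeTable"))

## ---- accessor methods ----

#' @rdname tcrclone-generics
#' @export
setMethod("chainRecords", "RepertoireTable", function(x) x@records)

#' @rdname tcrclone-generics
#' @export
setMethod("provenance", "RepertoireTable", function(x) x@provenance)

#' @rdname tcrclone-generics
#' @export
setMethod("referenceEntries", "ReferenceJunctionSet", function(x) x@entries)

#' @rdname tcrclone-generics
#' @export
setMethod("junctionSummary", "SharingSummary", function(x) x@junctions)

#' @rdname tcrclone-generics
#' @export
setMethod("donorMatrix", "SharingSummary", function(x) x@donorMatrix)

#' @rdname tcrclone-generics
#' @export
setMethod("distances", "DistanceSet", function(x) x@distances)

#' @rdname tcrclone-generics
#' @export
setMethod("distancePairs", "DistanceSet", function(x) x@pairs)

#' Number of distinct cells in a repertoire table
#' @param x a RepertoireTable.
#' @return integer count of distinct cell ids.
#' @export
nCells <- function(x) length(unique(chainRecords(x)$cell_id))

#' Donor ids present in a repertoire table
#' @param x a RepertoireTable.
#' @return character vector of donor ids.
#' @export
donors <- function(x) sort(unique(chainRecords(x)$donor_id))

#' Donor-to-disease-group map
#' @param x a RepertoireTable.
#' @return named character vector, donor id -> disease group.
#' @export
diseaseGroups <- function(x) {
    map <- unique(chainRecords(x)[, c("donor_id", "disease_group")])
    structure(map$disease_group, names = map$donor_id)
}

## ---- show methods ----

setMethod("show", "RepertoireTable", function(object) {
    rec <- object@records
    cat(sprintf("RepertoireTable: %d chain records, %d cells, %d donors (%s)\n",
                nrow(rec), length(unique(rec$cell_id)),
                length(unique(rec$donor_id)),
                paste(sort(unique(rec$disease_group)), collapse = "/")))
    tab <- table(rec$locus)
    cat("  loci:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    drop <- object@provenance$n_dropped_empty_junction
    if (!is.null(drop) && drop > 0)
        cat("  dropped", drop, "record(s) with empty junction_aa\n")
})

setMethod("show", "ReferenceJunctionSet", function(object) {
    tab <- table(object@entries$locus)
    cat(sprintf("ReferenceJunctionSet: %d unique junctions (%s)\n",
                nrow(object@entries),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "CloneGraph", function(object) {
    cat(sprintf("CloneGraph (%s%s): %d chains, %d pairing edges, %d clones\n",
                object@resolution,
                if (object@strictGenes) ", strict genes" else "",
                igraph::vcount(object@graph), igraph::ecount(object@graph),
                igraph::components(object@graph)$no))
})

setMethod("show", "SharingSummary", function(object) {
    j <- object@junctions
    cat(sprintf("SharingSummary: %d unique junctions (%d public / %d private), %d expanded\n",
                nrow(j), sum(j$publicness == "public"),
                sum(j$publicness == "private"), sum(j$expanded)))
    cat(sprintf("  expanded cells: %d / %d\n",
                object@stats$n_expanded_cells %||% NA_integer_,
                object@stats$n_cells %||% NA_integer_))
})

setMethod("show", "DistanceSet", function(object) {
    cat(sprintf("DistanceSet '%s' (%s): %d distances, median %s\n",
                object@label, object@source, length(object@distances),
                if (length(object@distances))
                    format(stats::median(object@distances)) else "NA"))
})

setMethod("show", "RecombinationModel", function(object) {
    cat(sprintf("RecombinationModel [%s]: %d V x %d J segments, d_max V/J = %d/%d, L_max = %d\n",
                object@locus, nrow(object@vSegments), nrow(object@jSegments),
                ncol(object@vDel) - 1L, ncol(object@jDel) - 1L,
                length(object@insLen) - 1L))
})

setMethod("show", "RepertoireDesign", function(object) {
    g <- object@groups
    cat("RepertoireDesign:",
        paste(sprintf("%s(%dx%d)", g$name, g$n_donors, g$cells_per_donor),
              collapse = " "), "\n")
    cat(sprintf("  clones: %s(%.2f); public: %d (spread %.1f donors%s); convergent TRA: %d x %d (d<=%d)\n",
                object@cloneDist, object@cloneParam, object@nPublic,
                object@publicDonorSpread,
                if (object@zeroInsertionBias) ", zero-insertion bias" else "",
                object@nConvergentTra, object@trbPartnersPerTra,
                object@trbMutationDistance))
    cat(sprintf("  invariant rate %.3f, dropout %.3f, memory fraction %.2f, seed %d\n",
                object@invariantRate, object@dropout, object@memoryFraction,
                object@seed))
})
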