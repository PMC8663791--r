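## The chain-pairing graph: vertices are unique chains, edges are within-cell
## codetections, clones are connected components. This is the clonotype
## definition used throughout the package: a clone is a maximal set of chains
## paired with one another but not with chains outside the set.

chainKey <- function(rec, resolution, strictGenes) {
    junc <- if (resolution == "aa") rec$junction_aa else rec$junction_nt
    if (strictGenes)
        paste(rec$locus, junc, rec$v_call, rec$j_call, sep = "|")
    else
        paste(rec$locus, junc, sep = "|")
}

#' Build the undirected chain-pairing graph
#'
#' One vertex per unique chain (locus + junction at the requested resolution;
#' \code{strictGenes = TRUE} adds V/J calls to the key). Two chains are joined
#' by an edge iff at least \code{minEdgeCells} distinct cells contain both.
#' Vertex weight is the number of distinct cells carrying the chain; edge
#' weight the number of distinct cells supporting the codetection, so a
#' vertex weight is always at least the largest incident edge weight.
#'
#' By default chains are keyed on the amino-acid junction without requiring
#' V/J identity: at this resolution junction identity almost always extends
#' to gene identity anyway, and amino-acid matching is what the sharing
#' analyses operate on.
#'
#' @param table a \linkS4class{RepertoireTable}.
#' @param resolution "aa" (default) or "nt"; records lacking junction_nt are
#'   excluded under "nt" and the count is logged.
#' @param strictGenes include V/J calls in the chain key.
#' @param minEdgeCells minimum number of supporting cells for an edge
#'   (default 1).
#' @return A \linkS4class{CloneGraph}.
#' @export
buildCloneGraph <- function(table, resolution = c("aa", "nt"),
                            strictGenes = FALSE, minEdgeCells = 1L) {
    resolution <- match.arg(resolution)
    rec <- chainRecords(table)
    if (!nrow(rec)) stopData("cannot build a clone graph from an empty table")
    if (resolution == "nt") {
        no_nt <- !nzchar(rec$junction_nt)
        if (any(no_nt))
            message(sprintf("buildCloneGraph: excluding %d record(s) without junction_nt",
                            sum(no_nt)))
        rec <- rec[!no_nt, , drop = FALSE]
        if (!nrow(rec)) stopData("no records carry junction_nt")
    }
    key <- chainKey(rec, resolution, strictGenes)
    junc <- if (resolution == "aa") rec$junction_aa else rec$junction_nt

    cells_by_key <- lapply(split(rec$cell_id, key), unique)
    vert <- data.frame(name = names(cells_by_key),
                       weight = lengths(cells_by_key),
                       stringsAsFactors = FALSE)
    meta <- rec[!duplicated(key), , drop = FALSE]
    mkey <- key[!duplicated(key)]
    vert$locus <- meta$locus[match(vert$name, mkey)]
    vert$junction <- junc[!duplicated(key)][match(vert$name, mkey)]

    ## all unordered within-cell chain pairs, weighted by distinct cells
    per_cell <- split(key, rec$cell_id)
    pair_list <- lapply(per_cell, function(k) {
        k <- sort(unique(k))
        if (length(k) < 2L) return(NULL)
        idx <- utils::combn(length(k), 2L)
        cbind(k[idx[1L, ]], k[idx[2L, ]])
    })
    pairs <- do.call(rbind, pair_list)
    if (is.null(pairs)) {
        edges <- data.frame(from = character(), to = character(),
                            weight = integer())
    } else {
        pk <- paste(pairs[, 1L], pairs[, 2L], sep = "\r")
        cnt <- table(pk)
        first <- !duplicated(pk)
        edges <- data.frame(from = pairs[first, 1L], to = pairs[first, 2L],
                            weight = as.integer(cnt[pk[first]]),
                            stringsAsFactors = FALSE)
        edges <- edges[edges$weight >= minEdgeCells, , drop = FALSE]
    }
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
    new("CloneGraph", graph = g, vertexCells = cells_by_key,
        resolution = resolution, strictGenes = strictGenes)
}

#' @rdname tcrclone-generics
#' @export
setMethod("vertexTable", "CloneGraph", function(x) {
    data.frame(chain = igraph::vertex_attr(x@graph, "name"),
               locus = igraph::vertex_attr(x@graph, "locus"),
               junction = igraph::vertex_attr(x@graph, "junction"),
               weight = igraph::vertex_attr(x@graph, "weight"),
               stringsAsFactors = FALSE)
})

#' @rdname tcrclone-generics
#' @export
setMethod("edgeTable", "CloneGraph", function(x) {
    e <- igraph::as_data_frame(x@graph, what = "edges")
    if (!nrow(e)) data.frame(from = character(), to = character(),
                             weight = integer())
    else e[, c("from", "to", "weight")]
})

#' Call clones as connected components of the pairing graph
#'
#' Each connected component is one clone; its member cells are the union of
#' cells supporting its member chains, and its topology label counts distinct
#' TRA and TRB chains in the component ("1 TRA-2 TRB" etc.). Clone ids
#' "Clone_k" are assigned deterministically: components sorted by descending
#' member-cell count, ties broken by the lexicographically smallest member
#' chain key. The ids are stable across runs but are not meant to match any
#' external numbering.
#'
#' @param graph a \linkS4class{CloneGraph}.
#' @return data.frame with one row per clone: clone_id, topology_label,
#'   n_tra, n_trb, n_chains, n_cells, and list columns member_chains,
#'   member_cells.
#' @export
callClones <- function(graph) {
    g <- graph@graph
    comp <- igraph::components(g)
    keys <- igraph::vertex_attr(g, "name")
    loci <- igraph::vertex_attr(g, "locus")
    members <- split(seq_along(keys), comp$membership)
    clones <- lapply(members, function(idx) {
        ch <- sort(keys[idx])
        cells <- sort(unique(unlist(graph@vertexCells[keys[idx]], use.names = FALSE)))
        n_tra <- sum(loci[idx] == "TRA")
        n_trb <- sum(loci[idx] == "TRB")
        list(chains = ch, cells = cells, n_tra = n_tra, n_trb = n_trb)
    })
    n_cells <- vapply(clones, function(cl) length(cl$cells), 0L)
    first_chain <- vapply(clones, function(cl) cl$chains[1L], "")
    ord <- order(-n_cells, first_chain)
    clones <- clones[ord]
    data.frame(
        clone_id = paste0("Clone_", seq_along(clones)),
        topology_label = vapply(clones, function(cl)
            sprintf("%d TRA-%d TRB", cl$n_tra, cl$n_trb), ""),
        n_tra = vapply(clones, `[[`, 0L, "n_tra"),
        n_trb = vapply(clones, `[[`, 0L, "n_trb"),
        n_chains = vapply(clones, function(cl) length(cl$chains), 0L),
        n_cells = n_cells[ord],
        member_chains = I(lapply(clones, `[[`, "chains")),
        member_cells = I(lapply(clones, `[[`, "cells")),
        stringsAsFactors = FALSE)
}

#' Count opposite-locus partners per junction
#'
#' For each unique junction of \code{fromLocus}, the number of distinct
#' opposite-locus junction_aa values codetected with it in at least one cell.
#' Junctions never codetected with the opposite locus get a count of 0.
#' Swapping \code{fromLocus} gives the reverse control (e.g. how many TRA
#' junctions each TRB pairs with).
#'
#' @param table a \linkS4class{RepertoireTable} containing both loci.
#' @param fromLocus "TRA" or "TRB".
#' @return data.frame: junction_aa, n_partners, n_cells.
#' @export
partnerCounts <- function(table, fromLocus = c("TRA", "TRB")) {
    fromLocus <- match.arg(fromLocus)
    rec <- chainRecords(table)
    if (!any(rec$locus == fromLocus))
        stopData("locus %s absent from table", fromLocus)
    toLocus <- setdiff(VALID_LOCI, fromLocus)
    from <- rec[rec$locus == fromLocus, c("cell_id", "junction_aa")]
    to <- rec[rec$locus == toLocus, c("cell_id", "junction_aa")]
    joined <- merge(from, to, by = "cell_id",
                    suffixes = c("_from", "_to"))
    partners <- lapply(split(joined$junction_aa_to, joined$junction_aa_from),
                       unique)
    all_j <- sort(unique(from$junction_aa))
    n_cells <- vapply(split(from$cell_id, from$junction_aa),
                      function(x) length(unique(x)), 0L)
    data.frame(junction_aa = all_j,
               n_partners = vapply(all_j, function(j)
                   length(partners[[j]] %||% character()), 0L),
               n_cells = as.integer(n_cells[all_j]),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Test enrichment of multi-partner junctions in public vs private chains
#'
#' Tabulates, for each unique \code{fromLocus} junction with at least one
#' opposite-locus partner, whether it pairs with one or with multiple distinct
#' partner junctions, splits the junctions by publicness, and tests the 2x2
#' association (single vs multiple partners, public vs private) with
#' Fisher's exact test.
#'
#' @param table a \linkS4class{RepertoireTable}.
#' @param summary a \linkS4class{SharingSummary} for the same table.
#' @param fromLocus direction; "TRA" tests TRB partners per TRA junction,
#'   "TRB" is the reverse control.
#' @param groups optional character vector of two disease groups: restrict to
#'   public junctions and compare multi-partner fractions between the groups
#'   instead of public vs private.
#' @return list: counts (per-junction data.frame), table (2x2 matrix),
#'   p (two-sided Fisher p), fraction_multi (named per class).
#' @export
pairingEnrichment <- function(table, summary, fromLocus = c("TRA", "TRB"),
                              groups = NULL) {
    fromLocus <- match.arg(fromLocus)
    pc <- partnerCounts(table, fromLocus)
    pc <- pc[pc$n_partners >= 1L, , drop = FALSE]
    js <- junctionSummary(summary)
    js <- js[js$locus == fromLocus, , drop = FALSE]
    idx <- match(pc$junction_aa, js$junction_aa)
    pc$publicness <- js$publicness[idx]
    pc$multi <- pc$n_partners >= 2L
    pc <- pc[!is.na(pc$publicness), , drop = FALSE]
    if (is.null(groups)) {
        cls <- factor(pc$publicness, levels = c("public", "private"))
    } else {
        if (length(groups) != 2L) stopConfig("groups must name exactly 2 groups")
        grp_of <- lapply(js$groups[idx], unlist)
        keep <- pc$publicness == "public"
        in_g1 <- vapply(grp_of, function(g) groups[1] %in% g, TRUE) & keep
        in_g2 <- vapply(grp_of, function(g) groups[2] %in% g, TRUE) & keep
        ## a junction present in both groups contributes to both columns
        pc <- rbind(pc[in_g1, ], pc[in_g2, ])
        cls <- factor(rep(groups, c(sum(in_g1), sum(in_g2))), levels = groups)
    }
    if (!nrow(pc)) stopData("no junctions available for pairing enrichment")
    tab <- table(factor(ifelse(pc$multi, "multi", "single"),
                        levels = c("multi", "single")), cls)
    m <- matrix(as.integer(tab), 2L, 2L, dimnames = dimnames(tab))
    p <- if (sum(m) > 0) stats::fisher.test(m)$p.value else NA_real_
    frac <- m["multi", ] / pmax(colSums(m), 1L)
    list(counts = pc, table = m, p = p, fraction_multi = frac)
}

#' Export / import a clone graph
#'
#' \code{exportGraph} writes GraphML or DOT (via igraph) or a lossless
#' edge-TSV with a vertex section (chain, locus, junction, weight, supporting
#' cells) and an edge section; \code{importGraphEdges} rebuilds the
#' \linkS4class{CloneGraph} from the edge-TSV.
#'
#' @param graph a \linkS4class{CloneGraph}.
#' @param path output file path.
#' @param format "edge_tsv", "graphml" or "dot".
#' @export
exportGraph <- function(graph, path, format = c("edge_tsv", "graphml", "dot")) {
    if (!is.character(format) || !all(format %in% c("edge_tsv", "graphml", "dot")))
        stopConfig("unknown graph export format: %s",
                   paste(setdiff(format, c("edge_tsv", "graphml", "dot")),
                         collapse = ", "))
    format <- match.arg(format)
    if (format %in% c("graphml", "dot")) {
        igraph::write_graph(graph@graph, path, format = format)
        return(invisible(path))
    }
    vt <- vertexTable(graph)
    vt$cells <- vapply(graph@vertexCells[vt$chain], paste, "", collapse = ",")
    et <- edgeTable(graph)
    vpart <- data.frame(record = "vertex", from = vt$chain, to = "",
                        weight = vt$weight, locus = vt$locus,
                        junction = vt$junction, cells = vt$cells,
                        stringsAsFactors = FALSE)
    epart <- if (nrow(et))
        data.frame(record = "edge", from = et$from, to = et$to,
                   weight = et$weight, locus = "", junction = "", cells = "",
                   stringsAsFactors = FALSE)
    else vpart[0, ]
    write_tsv(rbind(vpart, epart), path)
    invisible(path)
}

#' @rdname exportGraph
#' @param resolution,strictGenes stored back on the imported graph.
#' @export
importGraphEdges <- function(path, resolution = "aa", strictGenes = FALSE) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    v <- df[df$record == "vertex", ]
    e <- df[df$record == "edge", ]
    vert <- data.frame(name = v$from, weight = as.integer(v$weight),
                       locus = v$locus, junction = v$junction,
                       stringsAsFactors = FALSE)
    edges <- data.frame(from = e$from, to = e$to,
                        weight = as.integer(e$weight),
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vert)
    cells <- lapply(strsplit(v$cells, ",", fixed = TRUE), sort)
    names(cells) <- v$from
    new("CloneGraph", graph = g, vertexCells = cells,
        resolution = resolution, strictGenes = strictGenes)
}
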