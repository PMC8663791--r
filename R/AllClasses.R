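## Central S4 classes. Tabular slots are plain data.frames with fixed canonical
## columns; accessors (not slot access) are the supported interface.

CANONICAL_COLUMNS <- c("cell_id", "donor_id", "disease_group", "locus",
                       "v_call", "j_call", "junction_aa", "junction_nt",
                       "phenotype", "umi_count")

#' RepertoireTable: paired single-cell TCR chain observations
#'
#' One row per detected chain in one cell (the atomic observation), with donor
#' and disease-group metadata. Junctions follow the IMGT convention: the
#' junction amino-acid string includes the conserved C and F/W anchors
#' (e.g. CVVSDRGSTLGRLYF). Junction sequences are uppercased on construction;
#' gene calls are kept verbatim. Duplicate observations of the same chain
#' within a cell, keyed by (cell_id, locus, junction_aa, v_call, j_call), are
#' collapsed. junction_aa is authoritative: a junction_nt that does not
#' translate to it raises a validation warning, not an error, because
#' single-cell assemblies are noisy.
#'
#' @slot records data.frame with the canonical columns (see Details).
#' @slot provenance list: source path, dialect, and a filter/drop log.
#' @export
setClass("RepertoireTable",
         representation(records = "data.frame", provenance = "list"))

setValidity("RepertoireTable", function(object) {
    rec <- object@records
    msgs <- character()
    missing <- setdiff(CANONICAL_COLUMNS, names(rec))
    if (length(missing))
        msgs <- c(msgs, paste("missing columns:", paste(missing, collapse = ", ")))
    if (!length(msgs) && nrow(rec)) {
        if (any(!grepl(AA_REGEX, rec$junction_aa)))
            msgs <- c(msgs, "junction_aa contains non-amino-acid characters")
        if (any(!rec$locus %in% VALID_LOCI))
            msgs <- c(msgs, "locus values outside {TRA, TRB}")
        map <- unique(rec[, c("donor_id", "disease_group")])
        if (anyDuplicated(map$donor_id))
            msgs <- c(msgs, "a donor_id maps to more than one disease_group")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a RepertoireTable from a data.frame of chain records
#'
#' Normalizes column content (uppercases junctions, fills optional columns),
#' drops rows with empty junction_aa (counted in provenance), collapses
#' duplicate chain observations within a cell, and checks junction_nt
#' translation against junction_aa (warning on disagreement).
#'
#' @param records data.frame carrying at least cell_id, donor_id,
#'   disease_group, locus, junction_aa.
#' @param provenance list of provenance metadata to seed the table with.
#' @return A \linkS4class{RepertoireTable}.
#' @export
RepertoireTable <- function(records, provenance = list()) {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    need <- c("cell_id", "donor_id", "disease_group", "locus", "junction_aa")
    missing <- setdiff(need, names(records))
    if (length(missing))
        stopConfig("required column(s) missing: %s", paste(missing, collapse = ", "))
    for (col in c("v_call", "j_call", "junction_nt"))
        if (is.null(records[[col]])) records[[col]] <- ""
    if (is.null(records[["phenotype"]])) records[["phenotype"]] <- "unknown"
    if (is.null(records[["umi_count"]])) records[["umi_count"]] <- NA_integer_
    records <- records[, CANONICAL_COLUMNS, drop = FALSE]
    for (col in setdiff(CANONICAL_COLUMNS, "umi_count"))
        records[[col]] <- as.character(records[[col]])
    records$umi_count <- as.integer(records$umi_count)
    records$junction_aa <- toupper(trimws(records$junction_aa))
    records$junction_nt <- toupper(trimws(records$junction_nt))
    records$junction_nt[is.na(records$junction_nt)] <- ""

    empty <- is.na(records$junction_aa) | !nzchar(records$junction_aa)
    provenance$n_dropped_empty_junction <- sum(empty)
    records <- records[!empty, , drop = FALSE]

    bad_locus <- which(!records$locus %in% VALID_LOCI)
    if (length(bad_locus))
        stopData("unparseable locus value '%s' at row %d",
                 records$locus[bad_locus[1]], bad_locus[1])

    key <- paste(records$cell_id, records$locus, records$junction_aa,
                 records$v_call, records$j_call, sep = "\r")
    dup <- duplicated(key)
    provenance$n_collapsed_duplicates <- sum(dup)
    records <- records[!dup, , drop = FALSE]

    has_nt <- nzchar(records$junction_nt)
    if (any(has_nt)) {
        tr <- translateNt(records$junction_nt[has_nt])
        bad <- !is.na(records$junction_aa[has_nt]) &
            (is.na(tr) | tr != records$junction_aa[has_nt])
        if (any(bad))
            warnValidation(
                "%d record(s) have junction_nt that does not translate to junction_aa; junction_aa kept as authoritative",
                sum(bad))
        provenance$n_translation_mismatch <- sum(bad)
    }
    rownames(records) <- NULL
    new("RepertoireTable", records = records, provenance = provenance)
}

#' ReferenceJunctionSet: a deduplicated set of reference junctions
#'
#' Junction entries from an external database (e.g. a VDJdb export) with set
#' semantics on (locus, junction_aa); optional gene and antigen annotation is
#' retained from the first occurrence.
#'
#' @slot entries data.frame: locus, junction_aa, v_call, j_call,
#'   antigen_species, mhc_class.
#' @export
setClass("ReferenceJunctionSet", representation(entries = "data.frame"))

setValidity("ReferenceJunctionSet", function(object) {
    e <- object@entries
    if (!all(c("locus", "junction_aa") %in% names(e)))
        return("entries need locus and junction_aa")
    if (nrow(e) && any(!nzchar(e$junction_aa)))
        return("empty junction_aa in reference entries")
    if (anyDuplicated(paste(e$locus, e$junction_aa)))
        return("entries are not deduplicated on (locus, junction_aa)")
    TRUE
})

#' @rdname ReferenceJunctionSet-class
#' @param entries data.frame with at least locus and junction_aa.
#' @export
ReferenceJunctionSet <- function(entries) {
    entries <- as.data.frame(entries, stringsAsFactors = FALSE)
    if (!all(c("locus", "junction_aa") %in% names(entries)))
        stopConfig("reference entries need 'locus' and 'junction_aa' columns")
    for (col in c("v_call", "j_call", "antigen_species", "mhc_class"))
        if (is.null(entries[[col]])) entries[[col]] <- ""
    entries$junction_aa <- toupper(trimws(entries$junction_aa))
    entries <- entries[nzchar(entries$junction_aa), , drop = FALSE]
    if (!nrow(entries)) stopData("zero parseable reference entries")
    entries <- entries[!duplicated(paste(entries$locus, entries$junction_aa)),
                       c("locus", "junction_aa", "v_call", "j_call",
                         "antigen_species", "mhc_class"), drop = FALSE]
    rownames(entries) <- NULL
    new("ReferenceJunctionSet", entries = entries)
}

#' CloneGraph: the undirected chain-pairing graph
#'
#' Vertices are unique chains (locus + junction at the chosen resolution,
#' optionally + V/J genes), weighted by the number of distinct cells carrying
#' the chain ("clone counts"); an edge joins two chains codetected in at least
#' one cell, weighted by the number of distinct cells supporting the
#' codetection. Clones are the connected components.
#'
#' @slot graph igraph object with vertex attributes locus, junction, weight
#'   and edge attribute weight.
#' @slot vertexCells named list: chain key -> character vector of cell ids.
#' @slot resolution "aa" or "nt".
#' @slot strictGenes logical; whether V/J genes are part of the chain key.
#' @export
setClass("CloneGraph",
         representation(graph = "ANY", vertexCells = "list",
                        resolution = "character", strictGenes = "logical"))

setValidity("CloneGraph", function(object) {
    g <- object@graph
    if (!inherits(g, "igraph")) return("graph slot must be an igraph object")
    if (igraph::ecount(g)) {
        ew <- igraph::edge_attr(g, "weight")
        if (any(ew < 1)) return("edge weight below 1")
        ends <- igraph::as_data_frame(g, what = "edges")
        if (any(ends$from == ends$to)) return("self-edge present")
    }
    TRUE
})

#' SharingSummary: junction-level expansion and publicness calls
#'
#' Per unique (locus, junction_aa): the number of distinct cells and donors,
#' the donor set, expanded (>= 2 cells) and publicness (public = found in
#' more than one donor, else private) calls, disease-group presence, and a
#' symmetric zero-diagonal donor-by-donor matrix of shared junction counts.
#'
#' @slot junctions data.frame, one row per unique (locus, junction_aa).
#' @slot donorMatrix symmetric integer matrix of pairwise shared junctions.
#' @slot stats list of dataset-level totals (expanded cells, per-group counts,
#'   donor-to-group map).
#' @export
setClass("SharingSummary",
         representation(junctions = "data.frame", donorMatrix = "matrix",
                        stats = "list"))

setValidity("SharingSummary", function(object) {
    j <- object@junctions
    m <- object@donorMatrix
    msgs <- character()
    if (nrow(j)) {
        if (!identical(j$expanded, j$n_cells >= 2L))
            msgs <- c(msgs, "expanded flag inconsistent with n_cells >= 2")
        if (!identical(j$publicness == "public", j$n_donors >= 2L))
            msgs <- c(msgs, "publicness inconsistent with n_donors >= 2")
    }
    if (length(m)) {
        if (!isSymmetric(unname(m))) msgs <- c(msgs, "donor matrix not symmetric")
        if (any(diag(m) != 0)) msgs <- c(msgs, "donor matrix diagonal not zero")
    }
    if (length(msgs)) msgs else TRUE
})

#' DistanceSet: a labelled multiset of pairwise Levenshtein distances
#'
#' @slot label set label (e.g. "public" or "null_12").
#' @slot distances integer vector of pairwise distances.
#' @slot source "observed" or "null_iteration".
#' @slot pairs data.frame of pair provenance (for observed sets:
#'   tra_junction, trb_a, trb_b, distance, rank-ordered by ascending distance).
#' @export
setClass("DistanceSet",
         representation(label = "character", distances = "integer",
                        source = "character", pairs = "data.frame"))

setValidity("DistanceSet", function(object) {
    if (length(object@distances) && any(object@distances < 0))
        return("negative distance")
    if (!object@source %in% c("observed", "null_iteration"))
        return("source must be 'observed' or 'null_iteration'")
    TRUE
})

#' RecombinationModel: a simplified, exactly-computable V(D)J generative model
#'
#' Junctions are generated as V-prefix (3' trimmed by a per-segment deletion
#' distribution) + untemplated insertion (length distribution + per-position
#' nucleotide distribution) + J-suffix (5' trimmed). No D segment, no
#' palindromic nucleotides, insertions independent across positions. The model
#' supports both sampling and exact generation-probability (pgen) computation
#' by enumeration over recombination scenarios.
#'
#' @slot locus locus the model is parameterized for.
#' @slot vSegments data.frame: name, seq (junction prefix, nt), prob.
#' @slot jSegments data.frame: name, seq (junction suffix, nt), prob.
#' @slot vDel,jDel matrix of deletion probabilities, one row per segment,
#'   columns 0..d_max trimmed bases.
#' @slot insLen numeric vector of insertion-length probabilities over 0..L_max.
#' @slot ntProb named numeric over A, C, G, T.
#' @export
setClass("RecombinationModel",
         representation(locus = "character", vSegments = "data.frame",
                        jSegments = "data.frame", vDel = "matrix",
                        jDel = "matrix", insLen = "numeric", ntProb = "numeric"))

setValidity("RecombinationModel", function(object) {
    msgs <- character()
    tol <- 1e-12
    chk1 <- function(p, what) {
        if (any(p < 0) || abs(sum(p) - 1) > tol)
            paste(what, "probabilities do not sum to 1") else character()
    }
    msgs <- c(msgs, chk1(object@vSegments$prob, "V usage"),
              chk1(object@jSegments$prob, "J usage"),
              chk1(object@insLen, "insertion length"),
              chk1(object@ntProb, "nucleotide"))
    for (i in seq_len(nrow(object@vDel)))
        msgs <- c(msgs, chk1(object@vDel[i, ], paste0("V deletion [", i, "]")))
    for (i in seq_len(nrow(object@jDel)))
        msgs <- c(msgs, chk1(object@jDel[i, ], paste0("J deletion [", i, "]")))
    if (any(!nzchar(object@vSegments$seq)) || any(!nzchar(object@jSegments$seq)))
        msgs <- c(msgs, "empty segment sequence")
    d_max_v <- ncol(object@vDel) - 1L
    d_max_j <- ncol(object@jDel) - 1L
    if (d_max_v >= min(nchar(object@vSegments$seq)))
        msgs <- c(msgs, "V d_max must be smaller than the shortest V contribution")
    if (d_max_j >= min(nchar(object@jSegments$seq)))
        msgs <- c(msgs, "J d_max must be smaller than the shortest J contribution")
    if (!setequal(names(object@ntProb), c("A", "C", "G", "T")))
        msgs <- c(msgs, "ntProb must be named over A,C,G,T")
    if (length(msgs)) msgs else TRUE
})

#' DownsampleSpec: how to equalize groups before comparison
#'
#' @slot unit sampling unit: "junctions", "donors" or "cells".
#' @slot targetSize number of units drawn per group per iteration.
#' @slot nIter number of downsampling iterations (default 10000).
#' @slot seed master seed for the iteration seed stream.
#' @export
setClass("DownsampleSpec",
         representation(unit = "character", targetSize = "integer",
                        nIter = "integer", seed = "integer"))

#' @rdname DownsampleSpec-class
#' @param unit,targetSize,nIter,seed see slots.
#' @export
downsampleSpec <- function(unit = c("junctions", "donors", "cells"),
                           targetSize = 183L, nIter = 10000L, seed = 1L) {
    unit <- match.arg(unit)
    targetSize <- as.integer(targetSize)
    nIter <- as.integer(nIter)
    if (targetSize < 1L) stopConfig("targetSize must be positive")
    if (nIter < 1L) stopConfig("nIter must be positive")
    new("DownsampleSpec", unit = unit, targetSize = targetSize,
        nIter = nIter, seed = as.integer(seed))
}

#' RepertoireDesign: parameters of the synthetic repertoire generator
#'
#' Encodes the structures the analyses are built to detect: multi-donor
#' disease groups, clonal expansion with a configurable clone-size
#' distribution, injected cross-donor public junctions (optionally generated
#' with zero untemplated insertions, making them germline-like), convergent
#' TRA chains paired with several near-duplicate TRB partners, an invariant
#' iNKT chain spike, and per-cell chain dropout.
#'
#' @slot groups data.frame: name, n_donors, cells_per_donor.
#' @slot cloneDist "geometric" or "zipf" clone-size distribution.
#' @slot cloneParam distribution parameter (geometric success prob, or zipf
#'   exponent).
#' @slot nPublic number of injected public junctions (split across loci).
#' @slot publicDonorSpread mean number of donors carrying an injected public
#'   junction (minimum 2).
#' @slot zeroInsertionBias logical; injected public junctions are drawn with
#'   zero untemplated insertions.
#' @slot nConvergentTra number of convergent TRA junctions.
#' @slot trbPartnersPerTra distinct TRB partners per convergent TRA.
#' @slot trbMutationDistance maximum amino-acid edit distance between TRB
#'   partners of the same TRA.
#' @slot invariantRate fraction of cells whose TRA is replaced by the
#'   invariant iNKT chain (TRAV10 / CVVSDRGSTLGRLYF / TRAJ18).
#' @slot dropout per-cell probability of losing one locus.
#' @slot memoryFraction fraction of cells labelled memory (rest naive).
#' @slot seed generator seed.
#' @export
setClass("RepertoireDesign",
         representation(groups = "data.frame", cloneDist = "character",
                        cloneParam = "numeric", nPublic = "integer",
                        publicDonorSpread = "numeric",
                        zeroInsertionBias = "logical",
                        nConvergentTra = "integer",
                        trbPartnersPerTra = "integer",
                        trbMutationDistance = "integer",
                        invariantRate = "numeric", dropout = "numeric",
                        memoryFraction = "numeric", seed = "integer"))

setValidity("RepertoireDesign", function(object) {
    msgs <- character()
    g <- object@groups
    if (!all(c("name", "n_donors", "cells_per_donor") %in% names(g)))
        msgs <- c(msgs, "groups needs name, n_donors, cells_per_donor")
    else if (any(g$n_donors < 1) || any(g$cells_per_donor < 1))
        msgs <- c(msgs, "donor and cell counts must be positive")
    for (r in c(object@invariantRate, object@dropout, object@memoryFraction))
        if (r < 0 || r > 1) msgs <- c(msgs, "rates must lie in [0, 1]")
    if (object@publicDonorSpread < 2 && object@nPublic > 0)
        msgs <- c(msgs, "publicDonorSpread must be >= 2")
    if (!object@cloneDist %in% c("geometric", "zipf"))
        msgs <- c(msgs, "cloneDist must be 'geometric' or 'zipf'")
    if (length(msgs)) msgs else TRUE
})
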