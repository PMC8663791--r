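## Expansion and public/private classification, filtering, donor-sharing
## matrices, and reference-database overlap.
##
## Definitions used throughout: a junction is *expanded* when observed in two
## or more cells, and *public* when found in more than one donor (otherwise
## private). Both are computed per unique (locus, junction_aa).

#' Default invariant-chain blocklist
#'
#' The iNKT invariant alpha chain (TRAV10 / CVVSDRGSTLGRLYF / TRAJ18), a
#' non-antigen-specific contaminant lineage in enriched CD4 T cell data, plus
#' the canonical MAIT alpha chain (TRAV1-2 / TRAJ33) as an extension default
#' for the same class of invariant lineages.
#'
#' @return data.frame: v_call, junction_aa, j_call, label.
#' @export
defaultInvariantBlocklist <- function() {
    data.frame(
        v_call = c("TRAV10", "TRAV1-2"),
        junction_aa = c("CVVSDRGSTLGRLYF", ""),
        j_call = c("TRAJ18", "TRAJ33"),
        label = c("iNKT", "MAIT"),
        stringsAsFactors = FALSE)
}

#' Filter settings for a repertoire table
#'
#' @param invariant_blocklist data.frame of (v_call, junction_aa, j_call)
#'   chains to remove; junction_aa equality plus allele-insensitive gene
#'   prefix match. Empty fields in a blocklist row match anything.
#' @param memory_only drop cells that are not labelled memory.
#' @param min_umi minimum read/UMI support per record (NA support passes).
#' @param max_chains_per_locus drop cells with more than this many chains of
#'   either locus (doublet guard); Inf disables.
#' @return filter configuration list.
#' @export
filterConfig <- function(invariant_blocklist = defaultInvariantBlocklist(),
                         memory_only = FALSE, min_umi = 0L,
                         max_chains_per_locus = Inf) {
    structure(list(invariant_blocklist = invariant_blocklist,
                   memory_only = isTRUE(memory_only),
                   min_umi = min_umi,
                   max_chains_per_locus = max_chains_per_locus),
              class = "tcr_filter_config")
}

match_blocklist <- function(rec, bl) {
    hit <- rep(FALSE, nrow(rec))
    for (i in seq_len(nrow(bl))) {
        m <- rep(TRUE, nrow(rec))
        if (nzchar(bl$junction_aa[i])) m <- m & rec$junction_aa == bl$junction_aa[i]
        if (nzchar(bl$v_call[i])) m <- m & startsWith(rec$v_call, bl$v_call[i])
        if (nzchar(bl$j_call[i])) m <- m & startsWith(rec$j_call, bl$j_call[i])
        hit <- hit | m
    }
    hit
}

#' Apply the configured filters to a repertoire table
#'
#' Filters run in a fixed declared order, each appending its removal count to
#' the table's provenance filter log: (a) invariant-chain blocklist,
#' (b) memory-only cell restriction, (c) minimum read/UMI support,
#' (d) per-cell chain-count cap per locus. An empty config is the identity.
#'
#' @param table a \linkS4class{RepertoireTable}.
#' @param config a \code{\link{filterConfig}}.
#' @return the filtered \linkS4class{RepertoireTable}, filter log in
#'   \code{provenance(x)$filter_log}.
#' @export
applyFilters <- function(table, config = filterConfig()) {
    stopifnot(inherits(config, "tcr_filter_config"))
    rec <- chainRecords(table)
    log <- list()
    chk <- function(rec, name) {
        if (!nrow(rec)) stopData("filter '%s' removed all records", name)
        rec
    }

    bl <- config$invariant_blocklist
    if (!is.null(bl) && nrow(bl)) {
        hit <- match_blocklist(rec, bl)
        log$invariant_blocklist <- sum(hit)
        rec <- chk(rec[!hit, , drop = FALSE], "invariant_blocklist")
    }
    if (config$memory_only) {
        ## a cell counts as memory if any of its records says so
        mem_cells <- unique(rec$cell_id[rec$phenotype == "memory"])
        drop <- !rec$cell_id %in% mem_cells
        log$memory_only <- sum(drop)
        rec <- chk(rec[!drop, , drop = FALSE], "memory_only")
    }
    if (config$min_umi > 0) {
        drop <- !is.na(rec$umi_count) & rec$umi_count < config$min_umi
        log$min_umi <- sum(drop)
        rec <- chk(rec[!drop, , drop = FALSE], "min_umi")
    }
    if (is.finite(config$max_chains_per_locus)) {
        per <- table(rec$cell_id, rec$locus)
        bad_cells <- rownames(per)[apply(per, 1L,
                                         function(x) any(x > config$max_chains_per_locus))]
        drop <- rec$cell_id %in% bad_cells
        log$max_chains_per_locus <- sum(drop)
        rec <- chk(rec[!drop, , drop = FALSE], "max_chains_per_locus")
    }
    prov <- provenance(table)
    prov$filter_log <- c(prov$filter_log, log)
    out <- RepertoireTable(rec, provenance = prov)
    out
}

#' Classify junctions as expanded and public vs private
#'
#' Per unique (locus, junction_aa): distinct cell and donor counts, expanded
#' (>= 2 cells) and publicness (public iff > 1 donor) calls, the disease
#' groups the junction occurs in (with a cross-group flag when it spans more
#' than one), the symmetric donor-by-donor matrix of shared junction counts,
#' and the number of expanded cells (cells carrying at least one expanded
#' junction).
#'
#' @param table a \linkS4class{RepertoireTable}.
#' @return A \linkS4class{SharingSummary}.
#' @export
classifyJunctions <- function(table) {
    rec <- chainRecords(table)
    if (!nrow(rec)) stopData("cannot classify an empty table")
    if (length(unique(rec$donor_id)) == 1L)
        warnValidation("single donor in table: every junction is private")

    key <- paste(rec$locus, rec$junction_aa, sep = "|")
    first <- !duplicated(key)
    cells <- lapply(split(rec$cell_id, key), unique)
    dnrs <- lapply(split(rec$donor_id, key), function(x) sort(unique(x)))
    grps <- lapply(split(rec$disease_group, key), function(x) sort(unique(x)))
    ord <- key[first]
    j <- data.frame(locus = rec$locus[first], junction_aa = rec$junction_aa[first],
                    stringsAsFactors = FALSE)
    j$n_cells <- lengths(cells[ord])
    j$n_donors <- lengths(dnrs[ord])
    j$donors <- I(unname(dnrs[ord]))
    j$groups <- I(unname(grps[ord]))
    j$expanded <- j$n_cells >= 2L
    j$publicness <- ifelse(j$n_donors >= 2L, "public", "private")
    j$cross_group <- lengths(grps[ord]) >= 2L
    j <- j[order(j$locus, j$junction_aa), , drop = FALSE]
    rownames(j) <- NULL

    all_donors <- sort(unique(rec$donor_id))
    dm <- matrix(0L, length(all_donors), length(all_donors),
                 dimnames = list(all_donors, all_donors))
    shared <- j$donors[j$n_donors >= 2L]
    for (ds in shared) {
        idx <- match(ds, all_donors)
        prs <- utils::combn(idx, 2L)
        for (k in seq_len(ncol(prs))) {
            dm[prs[1L, k], prs[2L, k]] <- dm[prs[1L, k], prs[2L, k]] + 1L
            dm[prs[2L, k], prs[1L, k]] <- dm[prs[2L, k], prs[1L, k]] + 1L
        }
    }

    exp_keys <- paste(j$locus, j$junction_aa, sep = "|")[j$expanded]
    exp_cells <- unique(rec$cell_id[key %in% exp_keys])

    ## junctions expanded *within* one donor (>= 2 cells of that donor)
    cell_donor_key <- paste(key, rec$donor_id, sep = "\r")
    n_cells_dj <- vapply(split(rec$cell_id, cell_donor_key),
                         function(x) length(unique(x)), 0L)
    dj_donor <- sub("^.*\r", "", names(n_cells_dj))
    within_exp <- vapply(all_donors, function(d)
        sum(n_cells_dj[dj_donor == d] >= 2L), 0L)
    names(within_exp) <- all_donors
    grp_map <- diseaseGroups(table)
    per_group <- do.call(rbind, lapply(seq_len(nrow(j)), function(i)
        data.frame(group = unlist(j$groups[i]), publicness = j$publicness[i],
                   stringsAsFactors = FALSE)))
    group_counts <- as.data.frame(table(per_group$group, per_group$publicness),
                                  stringsAsFactors = FALSE)
    names(group_counts) <- c("group", "publicness", "n_junctions")

    new("SharingSummary", junctions = j, donorMatrix = dm,
        stats = list(n_cells = length(unique(rec$cell_id)),
                     n_expanded_cells = length(exp_cells),
                     donor_groups = grp_map,
                     group_counts = group_counts,
                     within_donor_expanded = within_exp))
}

#' Donor-sharing matrix and group-level totals
#'
#' Off-diagonal cell (i, j) counts unique junctions present in both donors;
#' within-donor expansion (junctions seen in >= 2 cells of one donor) is the
#' diagonal analog and is reported separately. Also returns a long
#' circos-compatible table (donor_a, donor_b, n_shared) and within/between
#' totals per disease-group pair.
#'
#' @param summary a \linkS4class{SharingSummary}.
#' @return list: matrix, long, within_donor_expanded, group_totals.
#' @export
sharingMatrix <- function(summary) {
    dm <- donorMatrix(summary)
    ds <- rownames(dm)
    long <- do.call(rbind, lapply(seq_along(ds), function(i) {
        jj <- seq_along(ds)[-seq_len(i)]
        if (!length(jj)) return(NULL)
        data.frame(donor_a = ds[i], donor_b = ds[jj], n_shared = dm[i, jj],
                   stringsAsFactors = FALSE)
    }))
    if (is.null(long))
        long <- data.frame(donor_a = character(), donor_b = character(),
                           n_shared = integer())
    rownames(long) <- NULL
    within <- summary@stats$within_donor_expanded
    grp <- summary@stats$donor_groups
    gt <- NULL
    if (!is.null(grp) && nrow(long)) {
        ga <- grp[long$donor_a]; gb <- grp[long$donor_b]
        pair <- paste(pmin(ga, gb), pmax(ga, gb), sep = "|")
        agg <- tapply(long$n_shared, pair, sum)
        gt <- data.frame(group_pair = names(agg), n_shared = as.integer(agg),
                         within = vapply(strsplit(names(agg), "|", fixed = TRUE),
                                         function(x) x[1] == x[2], TRUE),
                         row.names = NULL, stringsAsFactors = FALSE)
    }
    list(matrix = dm, long = long, within_donor_expanded = within,
         group_totals = gt)
}

hamming1 <- function(q, refs) {
    ## TRUE if any ref (same length as q) is within 1 substitution
    if (!length(refs)) return(FALSE)
    qc <- strsplit(q, "")[[1]]
    any(vapply(strsplit(refs, ""), function(rc) sum(qc != rc) <= 1L, TRUE))
}

#' Overlap of public and private junctions with a reference set
#'
#' A query junction matches when some reference junction of the same locus is
#' within \code{maxMismatch} of it. Exact matching (\code{maxMismatch = 0})
#' and single-mismatch matching are supported; the single-mismatch metric is
#' substitution-only (Hamming, same length) by default, switchable to
#' Levenshtein <= 1. Reports per (publicness x locus) stratum counts and
#' fractions and a per-locus Fisher's exact test of public vs private match
#' rates.
#'
#' @param summary a \linkS4class{SharingSummary}.
#' @param reference a \linkS4class{ReferenceJunctionSet}.
#' @param maxMismatch 0 or 1.
#' @param metric "hamming" or "levenshtein" (used when maxMismatch is 1).
#' @param expandedOnly restrict queries to expanded junctions (default TRUE,
#'   the usual comparison population).
#' @return list: strata (data.frame locus, publicness, n, n_matched,
#'   fraction), tests (per-locus Fisher p), matches (per-junction logical).
#' @export
overlapWithReference <- function(summary, reference, maxMismatch = 0L,
                                 metric = c("hamming", "levenshtein"),
                                 expandedOnly = TRUE) {
    metric <- match.arg(metric)
    if (!maxMismatch %in% c(0L, 1L))
        stopConfig("maxMismatch must be 0 or 1, got %s", format(maxMismatch))
    j <- junctionSummary(summary)
    if (expandedOnly) j <- j[j$expanded, , drop = FALSE]
    if (!nrow(j)) stopData("no query junctions in scope")
    ref <- referenceEntries(reference)
    if (!nrow(ref)) stopData("empty reference set")

    matched <- logical(nrow(j))
    for (loc in unique(j$locus)) {
        qi <- which(j$locus == loc)
        rj <- ref$junction_aa[ref$locus == loc]
        exact <- j$junction_aa[qi] %in% rj
        if (maxMismatch == 1L) {
            near <- vapply(seq_along(qi), function(k) {
                if (exact[k]) return(TRUE)
                q <- j$junction_aa[qi[k]]
                if (metric == "hamming") {
                    hamming1(q, rj[nchar(rj) == nchar(q)])
                } else {
                    cand <- rj[abs(nchar(rj) - nchar(q)) <= 1L]
                    length(cand) > 0 &&
                        any(levenshtein(rep(q, length(cand)), cand) <= 1L)
                }
            }, TRUE)
            matched[qi] <- near
        } else matched[qi] <- exact
    }
    j$matched <- matched
    strata <- do.call(rbind, lapply(split(j, list(j$locus, j$publicness)),
                                    function(s) {
        if (!nrow(s)) return(NULL)
        data.frame(locus = s$locus[1], publicness = s$publicness[1],
                   n = nrow(s), n_matched = sum(s$matched),
                   fraction = mean(s$matched), stringsAsFactors = FALSE)
    }))
    rownames(strata) <- NULL
    tests <- do.call(rbind, lapply(unique(j$locus), function(loc) {
        s <- j[j$locus == loc, ]
        pub <- s[s$publicness == "public", ]
        prv <- s[s$publicness == "private", ]
        if (!nrow(pub) || !nrow(prv)) return(NULL)
        p <- fisherExact2x2(sum(pub$matched), sum(!pub$matched),
                            sum(prv$matched), sum(!prv$matched))
        data.frame(locus = loc, p = p, stringsAsFactors = FALSE)
    }))
    list(strata = strata, tests = tests,
         matches = j[, c("locus", "junction_aa", "publicness", "matched")])
}
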