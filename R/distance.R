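## Levenshtein-distance convergence analysis: do the TRB junctions that share
## a TRA chain look more alike than random nonexpanded TRB junctions?

#' Levenshtein (edit) distance between amino-acid strings
#'
#' Minimum number of single-residue insertions, deletions or substitutions
#' (unit costs) turning one string into the other; vectorized over pairs with
#' the usual recycling.
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
    n <- max(length(a), length(b))
    .lev_pairs(rep_len(as.character(a), n), rep_len(as.character(b), n))
}

#' All pairwise Levenshtein distances within a string set
#'
#' @param x character vector.
#' @return integer vector of the choose(n, 2) pairwise distances, row-major
#'   over pairs (i < j).
#' @export
pairwiseDistances <- function(x) .lev_pairwise_set(as.character(x))

#' Pairwise distances of TRB junctions sharing a TRA chain
#'
#' Identifies every TRA junction (optionally restricted to public or private
#' TRA junctions) codetected with two or more distinct TRB junction_aa
#' values, computes all pairwise Levenshtein distances among each TRA's
#' partners, and pools them. Pair provenance is retained and rank-ordered by
#' ascending distance, the presentation used for alignment tables of the
#' most similar partner pairs.
#'
#' @param table a \linkS4class{RepertoireTable}.
#' @param summary optional \linkS4class{SharingSummary} (computed internally
#'   when absent and needed for scoping).
#' @param scope "public", "private" or "all": publicness of the shared TRA
#'   junction.
#' @return A \linkS4class{DistanceSet} with source "observed".
#' @export
sharedTraTrbDistances <- function(table, summary = NULL,
                                  scope = c("public", "private", "all")) {
    scope <- match.arg(scope)
    rec <- chainRecords(table)
    if (scope != "all" && is.null(summary))
        summary <- suppressWarnings(classifyJunctions(table))
    tra <- rec[rec$locus == "TRA", c("cell_id", "junction_aa")]
    trb <- rec[rec$locus == "TRB", c("cell_id", "junction_aa")]
    joined <- merge(tra, trb, by = "cell_id", suffixes = c("_tra", "_trb"))
    partners <- lapply(split(joined$junction_aa_trb, joined$junction_aa_tra),
                       function(x) sort(unique(x)))
    if (scope != "all") {
        js <- junctionSummary(summary)
        keep_tra <- js$junction_aa[js$locus == "TRA" & js$publicness == scope]
        partners <- partners[names(partners) %in% keep_tra]
    }
    partners <- partners[lengths(partners) >= 2L]
    if (!length(partners))
        stopData("no TRA junction in scope '%s' has >= 2 distinct TRB partners",
                 scope)
    pairs <- do.call(rbind, lapply(names(partners), function(tra_j) {
        p <- partners[[tra_j]]
        idx <- utils::combn(length(p), 2L)
        data.frame(tra_junction = tra_j, trb_a = p[idx[1L, ]],
                   trb_b = p[idx[2L, ]], stringsAsFactors = FALSE)
    }))
    pairs$distance <- levenshtein(pairs$trb_a, pairs$trb_b)
    pairs <- pairs[order(pairs$distance, pairs$tra_junction, pairs$trb_a), ,
                   drop = FALSE]
    rownames(pairs) <- NULL
    new("DistanceSet", label = scope, distances = as.integer(pairs$distance),
        source = "observed", pairs = pairs)
}

#' Null distance sets from nonexpanded TRB junctions
#'
#' Each null set draws \code{setSize} junctions without replacement from the
#' pool of unique nonexpanded TRB junction_aa (pooled across donors, or per
#' disease group) and computes all pairwise Levenshtein distances.
#' Deterministic under the seed.
#'
#' @param table a \linkS4class{RepertoireTable}.
#' @param summary optional \linkS4class{SharingSummary}.
#' @param setSize junctions per null set.
#' @param nSets number of null sets (default 1000).
#' @param seed RNG seed.
#' @param group optional disease group restricting the pool.
#' @return list of \linkS4class{DistanceSet}s with source "null_iteration".
#' @export
nullDistanceSets <- function(table, summary = NULL, setSize, nSets = 1000L,
                             seed = 1L, group = NULL) {
    if (is.null(summary)) summary <- suppressWarnings(classifyJunctions(table))
    js <- junctionSummary(summary)
    pool_rows <- js$locus == "TRB" & !js$expanded
    if (!is.null(group))
        pool_rows <- pool_rows & vapply(js$groups, function(g)
            group %in% unlist(g), TRUE)
    pool <- js$junction_aa[pool_rows]
    if (length(pool) < setSize)
        stopData("nonexpanded TRB pool too small: %d available, %d requested",
                 length(pool), setSize)
    set.seed(seed)
    lapply(seq_len(nSets), function(i) {
        draw <- sample(pool, setSize)
        new("DistanceSet", label = sprintf("null_%d", i),
            distances = .lev_pairwise_set(draw), source = "null_iteration",
            pairs = data.frame())
    })
}

#' Kolmogorov-Smirnov comparison of observed vs null distance sets
#'
#' Two-sample two-sided KS test of the observed distance multiset against
#' each null set; reports the per-set p-values, their median, and the
#' direction of the median location shift ("lower" when observed distances
#' are smaller than the pooled null, i.e. partner TRB junctions are more
#' alike than chance).
#'
#' @param observed a \linkS4class{DistanceSet}.
#' @param nulls list of \linkS4class{DistanceSet}s.
#' @return list: median_p, p_values, D (KS statistics), direction.
#' @export
ksMedianP <- function(observed, nulls) {
    obs <- distances(observed)
    if (!length(obs)) stopData("empty observed distance set")
    res <- vapply(nulls, function(nl) {
        d <- distances(nl)
        if (!length(d)) stopData("empty null distance set")
        kt <- suppressWarnings(stats::ks.test(obs, d,
                                              alternative = "two.sided"))
        c(p = kt$p.value, D = unname(kt$statistic))
    }, c(p = 0, D = 0))
    pooled_null <- unlist(lapply(nulls, distances))
    delta <- stats::median(obs) - stats::median(pooled_null)
    list(median_p = stats::median(res["p", ]),
         p_values = unname(res["p", ]),
         D = unname(res["D", ]),
         direction = if (delta < 0) "lower" else if (delta > 0) "higher"
         else "equal")
}
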