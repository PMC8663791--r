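## Diversity metrics, downsampling-equalized group comparisons, junction
## length statistics, and thin validated wrappers around the classical tests
## (Fisher's exact, Wilcoxon rank-sum, Benjamini-Hochberg FDR) used across
## every analysis.

#' Simpson's diversity of a clone-size multiset
#'
#' Gini-Simpson form 1 - sum(p_i^2) with p_i the clone-size fractions
#' (0 for a single clone, approaching 1 for many equal clones). The
#' inverse-Simpson form 1 / sum(p_i^2) is available as a variant.
#'
#' @param counts positive integer clone sizes.
#' @param variant "gini-simpson" (default) or "inverse".
#' @return diversity value; in [0, 1] for gini-simpson.
#' @examples
#' simpsonDiversity(c(2, 1, 1))  # 0.625
#' @export
simpsonDiversity <- function(counts, variant = c("gini-simpson", "inverse")) {
    variant <- match.arg(variant)
    if (!length(counts)) stopData("empty clone-count vector")
    if (any(counts <= 0)) stopData("clone counts must be positive")
    p <- counts / sum(counts)
    s <- sum(p^2)
    if (variant == "gini-simpson") 1 - s else 1 / s
}

#' Shannon entropy of a clone-size multiset, in bits
#'
#' @param counts positive integer clone sizes.
#' @return entropy in bits (>= 0).
#' @examples
#' shannonEntropy(c(1, 1, 1, 1))  # 2 bits
#' @export
shannonEntropy <- function(counts) {
    if (!length(counts)) stopData("empty clone-count vector")
    if (any(counts <= 0)) stopData("clone counts must be positive")
    p <- counts / sum(counts)
    -sum(p * log2(p))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value obtained by summing hypergeometric probabilities no
#' larger than that of the observed table (the classical two-sided
#' convention). The table is row-major: \code{matrix(c(a, b, c, d), 2,
#' byrow = TRUE)}.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return two-sided p-value.
#' @examples
#' fisherExact2x2(2, 4, 1, 40)  # ~0.0392
#' @export
fisherExact2x2 <- function(a, b, c, d) {
    cells <- c(a, b, c, d)
    if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
        stopData("cells must be nonnegative integers")
    if (sum(cells) == 0) stopData("all-zero 2x2 table")
    stats::fisher.test(matrix(as.integer(cells), 2L, byrow = TRUE))$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values with monotonicity enforced; q >= p always.
#'
#' @param pvals p-values in [0, 1].
#' @return q-values in input order.
#' @export
bhFDR <- function(pvals) {
    if (!length(pvals)) stopData("empty p-value vector")
    if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
        stopData("p-values must lie in [0, 1]")
    stats::p.adjust(pvals, method = "BH")
}

#' Unpaired two-sided Wilcoxon rank-sum p-value
#'
#' Exact for small samples without ties, normal approximation with continuity
#' correction otherwise. The strata compared in this package (public vs
#' private junctions) are unpaired, so the rank-sum (Mann-Whitney) form is
#' the appropriate test.
#'
#' @param x,y numeric samples.
#' @return two-sided p-value.
#' @export
wilcoxRankSum <- function(x, y) {
    p <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                             correct = TRUE))$p.value
    ## complete ties leave the normal approximation with zero variance;
    ## identical rank distributions carry no evidence of a shift
    if (is.nan(p)) 1 else p
}

#' Downsampling-equalized group summary
#'
#' For each disease group and each of \code{nIter} iterations, draws
#' \code{targetSize} units without replacement from the group's pool and
#' computes the statistic; reports the per-group median across iterations.
#' Deterministic under the given seed: a fresh seed stream per iteration is
#' derived from the master seed. The default unit is the unique expanded
#' junction (the population the publicness calls live on); publicness is
#' taken from the full-data classification, with \code{reclassify = TRUE}
#' re-deriving it inside each cell subsample.
#'
#' @param table a \linkS4class{RepertoireTable}.
#' @param summary the matching \linkS4class{SharingSummary}.
#' @param spec a \code{\link{downsampleSpec}}.
#' @param statistic "n_public", "n_private", "simpson" or "shannon".
#' @param junctionScope "expanded" (default) or "all" junctions as the
#'   sampling pool when unit is "junctions".
#' @param reclassify recompute publicness within each subsample (only
#'   meaningful for unit "cells" or "donors").
#' @return list: medians (named per group), iterations (nIter x nGroups
#'   matrix), spec.
#' @export
downsampledGroupSummary <- function(table, summary, spec,
                                    statistic = c("n_public", "n_private",
                                                  "simpson", "shannon"),
                                    junctionScope = c("expanded", "all"),
                                    reclassify = FALSE) {
    statistic <- match.arg(statistic)
    junctionScope <- match.arg(junctionScope)
    stopifnot(is(spec, "DownsampleSpec"))
    rec <- chainRecords(table)
    j <- junctionSummary(summary)
    if (junctionScope == "expanded" && spec@unit == "junctions")
        j_pool_all <- j[j$expanded, , drop = FALSE]
    else j_pool_all <- j
    groups <- sort(unique(rec$disease_group))

    pools <- lapply(groups, function(g) {
        switch(spec@unit,
               junctions = {
                   keep <- vapply(j_pool_all$groups, function(gr) g %in% unlist(gr), TRUE)
                   j_pool_all[keep, , drop = FALSE]
               },
               cells = unique(rec$cell_id[rec$disease_group == g]),
               donors = unique(rec$donor_id[rec$disease_group == g]))
    })
    names(pools) <- groups
    sizes <- vapply(pools, NROW, 0L)
    short <- sizes < spec@targetSize
    if (any(short))
        stopConfig("target size %d exceeds the %s pool of group %s (n = %d)",
                   spec@targetSize, spec@unit, names(sizes)[short][1],
                   sizes[short][1])

    stat_fun <- function(sub_j, sub_rec) {
        switch(statistic,
               n_public = sum(sub_j$publicness == "public"),
               n_private = sum(sub_j$publicness == "private"),
               simpson = simpsonDiversity(sub_j$n_cells),
               shannon = shannonEntropy(sub_j$n_cells))
    }

    set.seed(spec@seed)
    iter_seeds <- sample.int(.Machine$integer.max, spec@nIter)
    out <- matrix(NA_real_, spec@nIter, length(groups),
                  dimnames = list(NULL, groups))
    for (it in seq_len(spec@nIter)) {
        set.seed(iter_seeds[it])
        for (g in groups) {
            pool <- pools[[g]]
            if (spec@unit == "junctions") {
                take <- pool[sample.int(nrow(pool), spec@targetSize), ,
                             drop = FALSE]
                out[it, g] <- stat_fun(take, NULL)
            } else {
                ids <- sample(pool, spec@targetSize)
                sub <- if (spec@unit == "cells")
                    rec[rec$cell_id %in% ids, , drop = FALSE]
                else rec[rec$donor_id %in% ids, , drop = FALSE]
                sub_sum <- if (reclassify)
                    suppressWarnings(classifyJunctions(
                        RepertoireTable(sub)))
                else NULL
                sub_j <- if (reclassify) junctionSummary(sub_sum)
                else {
                    k <- unique(paste(sub$locus, sub$junction_aa, sep = "|"))
                    j[match(k, paste(j$locus, j$junction_aa, sep = "|")), ,
                      drop = FALSE]
                }
                if (junctionScope == "expanded")
                    sub_j <- sub_j[sub_j$expanded, , drop = FALSE]
                out[it, g] <- if (nrow(sub_j)) stat_fun(sub_j, sub) else NA_real_
            }
        }
    }
    list(medians = apply(out, 2L, stats::median, na.rm = TRUE),
         iterations = out, spec = spec, statistic = statistic)
}

#' Headline repertoire counts
#'
#' The dataset-level quantities reported together when summarizing a paired
#' single-cell repertoire: total and expanded cell counts, unique junction
#' counts per locus, public/private counts among expanded junctions, and
#' median junction lengths per (locus, publicness) stratum.
#'
#' @param table a \linkS4class{RepertoireTable}.
#' @param summary the matching \linkS4class{SharingSummary} (computed when
#'   absent).
#' @return named list of counts and medians.
#' @export
studyCounts <- function(table, summary = NULL) {
    if (is.null(summary)) summary <- suppressWarnings(classifyJunctions(table))
    j <- junctionSummary(summary)
    exp_j <- j[j$expanded, , drop = FALSE]
    med <- function(loc, pub) {
        x <- exp_j$junction_aa[exp_j$locus == loc & exp_j$publicness == pub]
        if (length(x)) stats::median(nchar(x)) else NA_real_
    }
    list(n_cells = summary@stats$n_cells,
         n_expanded_cells = summary@stats$n_expanded_cells,
         n_unique_junctions = nrow(j),
         n_tra = sum(j$locus == "TRA"),
         n_trb = sum(j$locus == "TRB"),
         n_public = sum(exp_j$publicness == "public"),
         n_private = sum(exp_j$publicness == "private"),
         median_length = c(tra_public = med("TRA", "public"),
                           tra_private = med("TRA", "private"),
                           trb_public = med("TRB", "public"),
                           trb_private = med("TRB", "private")))
}

#' Junction length distributions by publicness and locus
#'
#' Lengths are computed on unique junction_aa strings per (locus, publicness)
#' stratum; public vs private lengths are compared per locus with the
#' two-sided unpaired Wilcoxon rank-sum test and BH-adjusted across the
#' reported family. Strata with fewer than 2 junctions skip the test with a
#' warning.
#'
#' @param summary a \linkS4class{SharingSummary}.
#' @param expandedOnly restrict to expanded junctions (default TRUE).
#' @return list: strata (locus, publicness, n, median_length), tests (locus,
#'   p, q), lengths (named list of length vectors).
#' @export
junctionLengthStats <- function(summary, expandedOnly = TRUE) {
    j <- junctionSummary(summary)
    if (expandedOnly) j <- j[j$expanded, , drop = FALSE]
    if (!nrow(j)) stopData("no junctions in scope")
    j$len <- nchar(j$junction_aa)
    strata_split <- split(j, list(j$locus, j$publicness), drop = TRUE)
    strata <- do.call(rbind, lapply(strata_split, function(s)
        data.frame(locus = s$locus[1], publicness = s$publicness[1],
                   n = nrow(s), median_length = stats::median(s$len),
                   stringsAsFactors = FALSE)))
    rownames(strata) <- NULL
    lengths_list <- lapply(strata_split, `[[`, "len")

    tests <- do.call(rbind, lapply(unique(j$locus), function(loc) {
        pub <- j$len[j$locus == loc & j$publicness == "public"]
        prv <- j$len[j$locus == loc & j$publicness == "private"]
        if (length(pub) < 2L || length(prv) < 2L) {
            warnValidation("stratum with < 2 junctions for locus %s: length test skipped", loc)
            return(NULL)
        }
        data.frame(locus = loc, p = wilcoxRankSum(pub, prv),
                   stringsAsFactors = FALSE)
    }))
    if (!is.null(tests) && nrow(tests)) tests$q <- bhFDR(tests$p)
    list(strata = strata, tests = tests, lengths = lengths_list)
}
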