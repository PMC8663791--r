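## Independent oracles and small fixture builders. Each oracle is a separate
## route to the same quantity as the implementation under test: brute force,
## enumeration, or plain recursion — never a call into the code it checks.

## ---- repertoire fixtures ----

## cells: named list cell_id -> list(TRA = c(...), TRB = c(...)) of junctions
make_table <- function(cells, donor_of = NULL, group_of = NULL,
                       v_call = "", j_call = "", phenotype = "unknown") {
    rows <- list()
    for (cid in names(cells)) {
        for (loc in names(cells[[cid]])) {
            for (j in cells[[cid]][[loc]]) {
                rows[[length(rows) + 1L]] <- data.frame(
                    cell_id = cid,
                    donor_id = if (is.null(donor_of)) "d1" else donor_of[[cid]],
                    locus = loc, junction_aa = j,
                    v_call = v_call, j_call = j_call,
                    phenotype = phenotype, stringsAsFactors = FALSE)
            }
        }
    }
    df <- do.call(rbind, rows)
    grp <- if (is.null(group_of)) {
        structure(rep("HC", length(unique(df$donor_id))),
                  names = unique(df$donor_id))
    } else unlist(group_of)
    df$disease_group <- grp[df$donor_id]
    RepertoireTable(df)
}

## random amino-acid junction strings
rand_aa <- function(n, min_len = 8, max_len = 16) {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    lens <- if (min_len == max_len) rep(min_len, n)
    else sample(min_len:max_len, n, replace = TRUE)
    vapply(lens, function(l)
        paste(sample(aas, l, replace = TRUE), collapse = ""), "")
}

## ---- graph oracle: label propagation connected components ----

## vertices 1..n, edges as 2-column matrix; returns membership vector
brute_components <- function(n, edges) {
    lab <- seq_len(n)
    repeat {
        changed <- FALSE
        if (nrow(edges)) for (k in seq_len(nrow(edges))) {
            i <- edges[k, 1]; j <- edges[k, 2]
            m <- min(lab[i], lab[j])
            if (lab[i] != m || lab[j] != m) {
                lab[lab == max(lab[i], lab[j])] <- m
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    match(lab, unique(lab))
}

## ---- Levenshtein oracle: memoized recursion straight off the definition ----

lev_recursive <- function(a, b) {
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    n <- length(ac); m <- length(bc)
    memo <- matrix(NA_integer_, n + 1L, m + 1L)
    rec <- function(i, j) {
        if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
        r <- if (i == 0L) j
        else if (j == 0L) i
        else min(rec(i - 1L, j) + 1L,
                 rec(i, j - 1L) + 1L,
                 rec(i - 1L, j - 1L) + (ac[i] != bc[j]))
        memo[i + 1L, j + 1L] <<- r
        r
    }
    rec(n, m)
}

## ---- Fisher oracle: full enumeration of margin-fixed tables ----

fisher_enum <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
    ks <- max(0L, c1 - r2):min(r1, c1)
    probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
    p_obs <- probs[ks == a]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## ---- pgen oracle: exhaustive enumeration of the generative sample space ----

## returns data.frame(junction_nt, prob) aggregated over every scenario of a
## small model (feasible when segments, d_max and L_max are tiny)
enumerate_generable <- function(model) {
    v <- model@vSegments; j <- model@jSegments
    L_max <- length(model@insLen) - 1L
    nts <- c("A", "C", "G", "T")
    ins_strings <- unlist(lapply(0:L_max, function(l) {
        if (l == 0) return("")
        apply(do.call(expand.grid, rep(list(nts), l)), 1, paste, collapse = "")
    }))
    ins_len <- nchar(ins_strings)
    ins_prob <- model@insLen[ins_len + 1L] *
        vapply(ins_strings, function(s) {
            if (!nzchar(s)) return(1)
            prod(model@ntProb[strsplit(s, "")[[1]]])
        }, 0)
    out <- list()
    for (iv in seq_len(nrow(v))) for (ndv in 0:(ncol(model@vDel) - 1L))
        for (ij in seq_len(nrow(j))) for (ndj in 0:(ncol(model@jDel) - 1L)) {
            prefix <- substr(v$seq[iv], 1, nchar(v$seq[iv]) - ndv)
            suffix <- substring(j$seq[ij], ndj + 1)
            p_struct <- v$prob[iv] * model@vDel[iv, ndv + 1] *
                j$prob[ij] * model@jDel[ij, ndj + 1]
            out[[length(out) + 1L]] <- data.frame(
                junction_nt = paste0(prefix, ins_strings, suffix),
                prob = p_struct * ins_prob, stringsAsFactors = FALSE)
        }
    all <- do.call(rbind, out)
    agg <- tapply(all$prob, all$junction_nt, sum)
    data.frame(junction_nt = names(agg), prob = as.numeric(agg),
               stringsAsFactors = FALSE, row.names = NULL)
}

## a tiny model whose whole sample space can be enumerated
toy_model <- function(variant = 1L) {
    switch(variant,
           ## single V/J, no deletions, insertions 0-1
           recombinationModel("TRA",
                              data.frame(name = "V1", seq = "TGTGCA", prob = 1),
                              data.frame(name = "J1", seq = "TTT", prob = 1),
                              vDel = 1, jDel = 1, insLen = c(.5, .5)),
           ## two V, two J, deletions 0-2, insertions 0-2
           recombinationModel("TRA",
                              data.frame(name = c("V1", "V2"),
                                         seq = c("TGTGCAGCA", "TGTGTG"),
                                         prob = c(.6, .4)),
                              data.frame(name = c("J1", "J2"),
                                         seq = c("ACATTT", "CTCACCTTT"),
                                         prob = c(.7, .3)),
                              vDel = c(.5, .3, .2), jDel = c(.6, .3, .1),
                              insLen = c(.5, .3, .2)),
           ## skewed nucleotide distribution, insertions 0-3
           recombinationModel("TRB",
                              data.frame(name = c("V1", "V2", "V3"),
                                         seq = c("TGTGCC", "TGCAGT", "TGTAGC"),
                                         prob = c(.5, .3, .2)),
                              data.frame(name = "J1", seq = "TACTTC", prob = 1),
                              vDel = c(.7, .3), jDel = c(.8, .2),
                              insLen = c(.4, .3, .2, .1),
                              ntProb = c(A = .4, C = .3, G = .2, T = .1)))
}

## small three-group design for fast end-to-end runs
small_design <- function(seed = 1L, ...) {
    args <- list(groups = data.frame(name = c("HC", "newT1D", "T1D"),
                                     n_donors = c(3L, 4L, 3L),
                                     cells_per_donor = c(25L, 35L, 35L),
                                     stringsAsFactors = FALSE),
                 nPublic = 10L, nConvergentTra = 3L, invariantRate = 0.02,
                 dropout = 0.05, seed = seed)
    do.call(repertoireDesign, utils::modifyList(args, list(...)))
}

## deterministic two-letter amino-acid tag for integer ids (test fixtures)
aa_tag <- function(i) {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    paste0(aas[(i - 1) %/% 20 + 1], aas[(i - 1) %% 20 + 1])
}
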