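## A simplified V(D)J generative model with exact generation probabilities.
##
## A junction is built as: V prefix (trimmed from its 3' end by a per-segment
## deletion distribution) + an untemplated insertion (length distribution,
## independent per-position nucleotide distribution) + J suffix (trimmed from
## its 5' end). There is no D segment and no palindromic nucleotides, so the
## probability of a junction is an exact sum over the (V, nV del, insertion,
## nJ del, J) scenarios that concatenate to it. The model is approximate in
## absolute value relative to full inference-based recombination models, but
## preserves the rank structure the analyses need: fewer insertions <=>
## higher pgen <=> more germline-like.

## scenario table: one row per (V segment, V deletion, J segment, J deletion)
scenarios <- function(model) {
    v <- model@vSegments; j <- model@jSegments
    dv <- ncol(model@vDel) - 1L; dj <- ncol(model@jDel) - 1L
    grid <- expand.grid(iv = seq_len(nrow(v)), ndv = 0:dv,
                        ij = seq_len(nrow(j)), ndj = 0:dj)
    prefix <- substr(v$seq[grid$iv], 1L, nchar(v$seq[grid$iv]) - grid$ndv)
    suffix <- substring(j$seq[grid$ij], grid$ndj + 1L)
    data.frame(grid,
               v_name = v$name[grid$iv], j_name = j$name[grid$ij],
               prefix = prefix, suffix = suffix,
               a = nchar(prefix), b = nchar(suffix),
               p_struct = v$prob[grid$iv] *
                   model@vDel[cbind(grid$iv, grid$ndv + 1L)] *
                   j$prob[grid$ij] *
                   model@jDel[cbind(grid$ij, grid$ndj + 1L)],
               stringsAsFactors = FALSE)
}

#' Construct a recombination model
#'
#' @param locus locus label ("TRA" or "TRB").
#' @param vSegments,jSegments data.frames with columns name, seq
#'   (nucleotides contributed to the junction), prob (usage probability).
#' @param vDel,jDel per-segment deletion distributions: either a numeric
#'   vector over 0..d_max shared by all segments or a matrix with one row
#'   per segment.
#' @param insLen insertion-length distribution over 0..L_max.
#' @param ntProb per-position nucleotide distribution (default uniform).
#' @return A \linkS4class{RecombinationModel}.
#' @export
recombinationModel <- function(locus, vSegments, jSegments, vDel, jDel,
                               insLen,
                               ntProb = c(A = .25, C = .25, G = .25, T = .25)) {
    as_mat <- function(d, n) {
        if (is.matrix(d)) d else matrix(rep(d, each = n), nrow = n)
    }
    vSegments <- as.data.frame(vSegments, stringsAsFactors = FALSE)
    jSegments <- as.data.frame(jSegments, stringsAsFactors = FALSE)
    new("RecombinationModel", locus = locus,
        vSegments = vSegments, jSegments = jSegments,
        vDel = as_mat(vDel, nrow(vSegments)), jDel = as_mat(jDel, nrow(jSegments)),
        insLen = as.numeric(insLen),
        ntProb = ntProb[c("A", "C", "G", "T")])
}

pgen_result <- function(junction, level, pgen, n_scenarios) {
    data.frame(junction = junction, level = level, pgen = pgen,
               log10_pgen = ifelse(pgen > 0, log10(pgen), NA_real_),
               n_scenarios = n_scenarios, ungenerable = pgen <= 0,
               stringsAsFactors = FALSE)
}

#' Exact generation probability of a nucleotide junction
#'
#' Sums, over every recombination scenario whose trimmed V prefix +
#' insertion + trimmed J suffix equals the junction, the product
#' P(V) P(delV) P(insertion length) P(insertion nucleotides) P(delJ) P(J).
#' A junction no scenario can produce is flagged ungenerable (pgen 0) rather
#' than reported as -Inf on the log scale.
#'
#' @param model a \linkS4class{RecombinationModel}.
#' @param junction_nt nucleotide string over ACGT.
#' @return one-row data.frame: junction, level, pgen, log10_pgen,
#'   n_scenarios, ungenerable.
#' @export
pgenNt <- function(model, junction_nt, .scenarios = NULL) {
    junction_nt <- toupper(junction_nt)
    if (!nzchar(junction_nt) || !grepl("^[ACGT]+$", junction_nt))
        stopData("junction_nt must be a nonempty string over {A,C,G,T}")
    sc <- .scenarios %||% scenarios(model)
    L <- nchar(junction_nt)
    L_max <- length(model@insLen) - 1L
    ins_len <- L - sc$a - sc$b
    ok <- ins_len >= 0L & ins_len <= L_max &
        startsWith(junction_nt, sc$prefix) &
        endsWith(junction_nt, sc$suffix)
    if (!any(ok)) return(pgen_result(junction_nt, "nt", 0, 0L))
    sc <- sc[ok, , drop = FALSE]
    ins_len <- ins_len[ok]
    p_ins_nt <- vapply(seq_len(nrow(sc)), function(k) {
        if (ins_len[k] == 0L) return(1)
        ins <- substr(junction_nt, sc$a[k] + 1L, L - sc$b[k])
        prod(model@ntProb[strsplit(ins, "")[[1]]])
    }, 0)
    contrib <- sc$p_struct * model@insLen[ins_len + 1L] * p_ins_nt
    pgen_result(junction_nt, "nt", sum(contrib), sum(contrib > 0))
}

codon_table <- function() {
    gc <- Biostrings::GENETIC_CODE
    split(names(gc), unname(gc))
}

#' Exact generation probability of an amino-acid junction
#'
#' pgen of the amino-acid junction is the sum of pgenNt over every
#' nucleotide sequence translating to it. Rather than enumerating codings,
#' each scenario's contribution factorizes over codon positions: positions
#' covered by the (fixed) V prefix or J suffix must match, free insertion
#' positions carry the nucleotide distribution, and the per-codon weights
#' multiply. This keeps the computation exact at any junction length; the
#' \code{enumerationBound} guards against configuring absurdly long queries.
#'
#' @param model a \linkS4class{RecombinationModel}.
#' @param junction_aa amino-acid string.
#' @param enumerationBound maximum junction length in residues (default 40).
#' @return one-row data.frame as \code{\link{pgenNt}}.
#' @export
pgenAa <- function(model, junction_aa, enumerationBound = 40L) {
    junction_aa <- toupper(junction_aa)
    if (!grepl(AA_REGEX, junction_aa))
        stopData("junction_aa must be a nonempty amino-acid string")
    if (nchar(junction_aa) > enumerationBound)
        stopConfig("junction of %d residues exceeds enumeration bound %d; use nucleotide-level pgen or import externally computed values",
                   nchar(junction_aa), enumerationBound)
    codons <- codon_table()
    aa <- strsplit(junction_aa, "")[[1]]
    L <- 3L * length(aa)
    L_max <- length(model@insLen) - 1L
    sc <- scenarios(model)
    ins_len <- L - sc$a - sc$b
    sc <- sc[ins_len >= 0L & ins_len <= L_max, , drop = FALSE]
    if (!nrow(sc)) return(pgen_result(junction_aa, "aa", 0, 0L))
    ins_len <- L - sc$a - sc$b

    contrib <- vapply(seq_len(nrow(sc)), function(k) {
        a <- sc$a[k]; b <- sc$b[k]
        pre <- strsplit(sc$prefix[k], "")[[1]]
        suf <- strsplit(sc$suffix[k], "")[[1]]
        total <- 1
        for (i in seq_along(aa)) {
            pos <- (3L * (i - 1L) + 1L):(3L * i)
            w <- 0
            for (cd in codons[[aa[i]]]) {
                cc <- strsplit(cd, "")[[1]]
                wk <- 1
                for (t in 1:3) {
                    p <- pos[t]
                    if (p <= a) {
                        if (cc[t] != pre[p]) { wk <- 0; break }
                    } else if (p > L - b) {
                        if (cc[t] != suf[p - (L - b)]) { wk <- 0; break }
                    } else wk <- wk * model@ntProb[[cc[t]]]
                }
                w <- w + wk
            }
            if (w == 0) { total <- 0; break }
            total <- total * w
        }
        total * sc$p_struct[k] * model@insLen[ins_len[k] + 1L]
    }, 0)
    pgen_result(junction_aa, "aa", sum(contrib), sum(contrib > 0))
}

#' pgen for a vector of junctions
#'
#' @param model a \linkS4class{RecombinationModel}.
#' @param junctions character vector.
#' @param level "nt" or "aa".
#' @param ... passed to \code{\link{pgenAa}}.
#' @return data.frame with one row per junction.
#' @export
pgenTable <- function(model, junctions, level = c("nt", "aa"), ...) {
    level <- match.arg(level)
    sc <- if (level == "nt") scenarios(model) else NULL
    fun <- if (level == "nt") function(x) pgenNt(model, x, .scenarios = sc)
    else function(x) pgenAa(model, x, ...)
    out <- do.call(rbind, lapply(junctions, fun))
    rownames(out) <- NULL
    out
}

#' Sample junctions from the recombination model
#'
#' Draws recombination events from the model's distributions; junctions are
#' kept only when in frame (length divisible by 3) and free of in-frame stop
#' codons, by rejection, because the observed amino-acid junctions represent
#' productive rearrangements. The returned scenario probability
#' (\code{prob}) is exactly that scenario's contribution to pgenNt.
#'
#' @param model a \linkS4class{RecombinationModel}.
#' @param n number of junctions.
#' @param forceZeroInsertions draw with insertion length fixed at 0
#'   (germline-like junctions).
#' @param maxTries rejection budget multiplier.
#' @return data.frame: junction_nt, junction_aa, v_name, j_name, n_del_v,
#'   n_del_j, insertion, prob.
#' @export
sampleJunctions <- function(model, n, forceZeroInsertions = FALSE,
                            maxTries = 200L) {
    v <- model@vSegments; j <- model@jSegments
    L_max <- length(model@insLen) - 1L
    nts <- c("A", "C", "G", "T")
    out <- NULL
    tries <- 0L
    while (is.null(out) || nrow(out) < n) {
        tries <- tries + 1L
        if (tries > maxTries)
            stop("sampleJunctions: rejection budget exhausted; the model yields almost no productive in-frame junctions")
        m <- max(n * 2L, 16L)
        iv <- sample.int(nrow(v), m, replace = TRUE, prob = v$prob)
        ij <- sample.int(nrow(j), m, replace = TRUE, prob = j$prob)
        ndv <- integer(m); ndj <- integer(m)
        for (i in unique(iv)) {
            idx <- which(iv == i)
            ndv[idx] <- sample.int(ncol(model@vDel), length(idx),
                                   replace = TRUE, prob = model@vDel[i, ]) - 1L
        }
        for (i in unique(ij)) {
            idx <- which(ij == i)
            ndj[idx] <- sample.int(ncol(model@jDel), length(idx),
                                   replace = TRUE, prob = model@jDel[i, ]) - 1L
        }
        ilen <- if (forceZeroInsertions) rep(0L, m)
        else sample.int(L_max + 1L, m, replace = TRUE, prob = model@insLen) - 1L
        ins <- character(m)
        lp_ins <- numeric(m)
        if (any(ilen > 0L)) {
            who <- rep(seq_len(m), ilen)
            letters_ <- sample(nts, sum(ilen), replace = TRUE,
                               prob = model@ntProb)
            ins[unique(who)] <- vapply(split(letters_, who), paste, "",
                                       collapse = "")
            lp <- tapply(log(model@ntProb[letters_]), who, sum)
            lp_ins[as.integer(names(lp))] <- as.numeric(lp)
        }
        prefix <- substr(v$seq[iv], 1L, nchar(v$seq[iv]) - ndv)
        suffix <- substring(j$seq[ij], ndj + 1L)
        junction_nt <- paste0(prefix, ins, suffix)
        aa <- translateNt(junction_nt)
        keep <- !is.na(aa)
        if (!any(keep)) next
        p_ins <- model@insLen[ilen + 1L] * exp(lp_ins)
        batch <- data.frame(junction_nt = junction_nt, junction_aa = aa,
                            v_name = v$name[iv], j_name = j$name[ij],
                            n_del_v = ndv, n_del_j = ndj, insertion = ins,
                            prob = v$prob[iv] * model@vDel[cbind(iv, ndv + 1L)] *
                                p_ins * j$prob[ij] * model@jDel[cbind(ij, ndj + 1L)],
                            stringsAsFactors = FALSE)[keep, , drop = FALSE]
        out <- rbind(out, batch)
    }
    out <- out[seq_len(n), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Compare pgen between public and private junctions
#'
#' Per (locus, publicness) stratum medians of log10 pgen, with a two-sided
#' unpaired Wilcoxon rank-sum test of public vs private per locus and BH
#' adjustment across the family. Direction reports which class is more
#' germline-like (higher, i.e. less negative, median log10 pgen).
#'
#' @param pgen_df data.frame with columns locus, publicness, log10_pgen
#'   (ungenerable junctions, log10_pgen NA, are excluded with a message).
#' @return list: strata (medians), tests (locus, p, q, direction).
#' @export
comparePgen <- function(pgen_df) {
    keep <- !is.na(pgen_df$log10_pgen)
    if (!all(keep))
        message(sprintf("comparePgen: excluding %d ungenerable junction(s)",
                        sum(!keep)))
    pgen_df <- pgen_df[keep, , drop = FALSE]
    if (!nrow(pgen_df)) stopData("all junctions in a stratum are ungenerable")
    strata <- do.call(rbind, lapply(
        split(pgen_df, list(pgen_df$locus, pgen_df$publicness), drop = TRUE),
        function(s) data.frame(locus = s$locus[1], publicness = s$publicness[1],
                               n = nrow(s),
                               median_log10_pgen = stats::median(s$log10_pgen),
                               stringsAsFactors = FALSE)))
    rownames(strata) <- NULL
    tests <- do.call(rbind, lapply(unique(pgen_df$locus), function(loc) {
        pub <- pgen_df$log10_pgen[pgen_df$locus == loc &
                                      pgen_df$publicness == "public"]
        prv <- pgen_df$log10_pgen[pgen_df$locus == loc &
                                      pgen_df$publicness == "private"]
        if (!length(pub) || !length(prv)) return(NULL)
        data.frame(locus = loc, p = wilcoxRankSum(pub, prv),
                   direction = if (stats::median(pub) > stats::median(prv))
                       "public_higher"
                   else if (stats::median(pub) < stats::median(prv))
                       "private_higher" else "equal",
                   stringsAsFactors = FALSE)
    }))
    if (!is.null(tests) && nrow(tests)) tests$q <- bhFDR(tests$p)
    list(strata = strata, tests = tests)
}

#' Import externally computed pgen values
#'
#' Joins a (locus, junction_aa, pgen) table — e.g. values computed by an
#' inference-based recombination model — onto the junction classification.
#'
#' @param x data.frame or TSV path with columns locus, junction_aa (or
#'   junction_nt), pgen.
#' @param summary a \linkS4class{SharingSummary}.
#' @return junction summary with pgen, log10_pgen and matched columns;
#'   attribute "n_unmatched" counts junctions without an imported value.
#' @export
importPgen <- function(x, summary) {
    if (is.character(x)) x <- utils::read.delim(x, stringsAsFactors = FALSE)
    if (!"pgen" %in% names(x)) stopConfig("import needs a 'pgen' column")
    jcol <- intersect(c("junction_aa", "junction_nt"), names(x))[1]
    if (is.na(jcol)) stopConfig("import needs a junction_aa or junction_nt column")
    bad <- which(!is.finite(x$pgen) | x$pgen <= 0 | x$pgen > 1)
    if (length(bad))
        stopData("pgen outside (0, 1] at row %d (value %s)",
                 bad[1], format(x$pgen[bad[1]]))
    j <- junctionSummary(summary)
    key_in <- paste(x$locus, toupper(x[[jcol]]))
    idx <- match(paste(j$locus, j$junction_aa), key_in)
    j$pgen <- x$pgen[idx]
    j$log10_pgen <- log10(j$pgen)
    j$matched <- !is.na(idx)
    attr(j, "n_unmatched") <- sum(is.na(idx))
    j
}

## derive a gene family from base segments by swapping one interior codon;
## deterministic, keeps the conserved anchors at the segment ends
expand_family <- function(base, n_target, at = 4L) {
    swaps <- c("GGA", "CTG", "TCC", "AGA", "CAA", "GAT", "ACC", "TAC")
    seqs <- base$seq
    names_ <- base$name
    k <- 0L
    while (length(seqs) < n_target) {
        i <- k %% nrow(base) + 1L
        variant <- k %/% nrow(base)
        if (variant >= length(swaps))
            stop("expand_family: exhausted swap codons before reaching target")
        s <- base$seq[i]
        substr(s, at, at + 2L) <- swaps[variant + 1L]
        k <- k + 1L
        if (s %in% seqs) next
        seqs <- c(seqs, s)
        names_ <- c(names_, sprintf("%s-%d", base$name[i], variant + 2L))
    }
    prob <- 1 / (seq_along(seqs) + 4)
    data.frame(name = names_, seq = seqs, prob = prob / sum(prob),
               stringsAsFactors = FALSE)
}

#' Built-in default recombination models
#'
#' Fully declared TRA and TRB models for simulation and pgen scoring: 20 V
#' and 20 J segments per locus, built as families around eight base
#' sequences (one interior codon swapped per family member, mimicking
#' closely related germline genes). Segment prefixes begin at the conserved
#' junction cysteine (TGT/TGC) and suffixes end at the conserved F/W anchor.
#' The TRA model has a shorter insertion-length support than TRB, reflecting
#' the smaller number of untemplated nucleotides at the VJ joint compared
#' with the VDJ joint.
#'
#' @param locus "TRA" or "TRB".
#' @return A \linkS4class{RecombinationModel}.
#' @export
defaultRecombinationModel <- function(locus = c("TRA", "TRB")) {
    locus <- match.arg(locus)
    if (locus == "TRA") {
        v <- data.frame(
            name = sprintf("TRAV%d", 1:8),
            seq = c("TGTGCTGTGAGT", "TGTGTGGTGAGC", "TGTGCAGCAAGTA",
                    "TGTGCTGTGAGAG", "TGTATTGTGACTGC", "TGTGCAGGGGCTGG",
                    "TGTGCTACGGACTCT", "TGTGCTGCGTCGATC"),
            prob = c(.2, .15, .15, .12, .12, .1, .08, .08),
            stringsAsFactors = FALSE)
        j <- data.frame(
            name = sprintf("TRAJ%d", 1:8),
            seq = c("GGAGGAAGCTACATCCCTACATTT", "AATACTGGAAAACTCATCTTT",
                    "GATAGCAGCTATAAATTGATCTTT",
                    "AATTATGGAGGAAGCCAAGGAAATCTCATCTTT",
                    "GCTGGATCTTATCAACTCACTTTC", "AACACTGATAAGCTCATCTTT",
                    "TCAGGAACCTACAAATACATCTTT", "AATGCAGGCAACATGCTCACCTTT"),
            prob = c(.15, .15, .14, .12, .12, .12, .1, .1),
            stringsAsFactors = FALSE)
        ins <- c(.10, .15, .16, .15, .12, .10, .08, .07, .05, .02)  # 0..9
        v <- expand_family(v, 20L); j <- expand_family(j, 20L)
    } else {
        v <- data.frame(
            name = sprintf("TRBV%d", 1:8),
            seq = c("TGTGCCAGCAGT", "TGTGCCAGCAGC", "TGTAGTGCTAGAG",
                    "TGCAGTGCCAGGG", "TGTGCCAGCTCAGT", "TGTGCCTGGAGTGT",
                    "TGTGCCAGCAGCCAA", "TGTGCCAGTTCGACA"),
            prob = c(.2, .15, .15, .12, .12, .1, .08, .08),
            stringsAsFactors = FALSE)
        j <- data.frame(
            name = sprintf("TRBJ%d", 1:8),
            seq = c("AACACTGAAGCTTTCTTT", "TATGAGCAGTACTTC",
                    "TCCTACAATGAGCAGTTCTTC", "GCAAAAAATATTCAGTACTTC",
                    "AATTCACCCCTCCACTTT", "ACTGAAGCTTTCTTT",
                    "AGCACAGATACGCAGTATTTT", "TCAGGGGCCAACGTCCTGACTTTC"),
            prob = c(.15, .15, .14, .12, .12, .12, .1, .1),
            stringsAsFactors = FALSE)
        ins <- c(.04, .07, .10, .12, .13, .12, .11, .09, .07, .06, .04, .03,
                 .02)                                       # 0..12
        v <- expand_family(v, 20L); j <- expand_family(j, 20L)
    }
    recombinationModel(locus, v, j,
                       vDel = c(.30, .22, .17, .13, .09, .06, .03),
                       jDel = c(.30, .22, .17, .13, .09, .06, .03),
                       insLen = ins / sum(ins))
}
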