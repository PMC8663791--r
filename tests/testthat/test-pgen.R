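test_that("toy-model pgen: hand-computed scenario sums", {
    m <- toy_model(1)
    expect_equal(pgenNt(m, "TGTGCATTT")$pgen, 0.5)       # zero-insertion path
    expect_equal(pgenNt(m, "TGTGCAATTT")$pgen, 0.5 * 0.25)
    expect_true(pgenNt(m, "AAAAAA")$ungenerable)
    expect_error(pgenNt(m, "TGTXCA"), class = "tcrclone_data_error")
    ## log10 convention
    r <- pgenNt(m, "TGTGCAATTT")
    expect_equal(r$log10_pgen, log10(0.125))
})

test_that("pgen normalizes to 1 over the exhaustively enumerated sample space", {
    for (variant in 1:3) {
        m <- toy_model(variant)
        gen <- enumerate_generable(m)
        expect_equal(sum(gen$prob), 1, tolerance = 1e-12)
        pk <- vapply(gen$junction_nt, function(x) pgenNt(m, x)$pgen, 0)
        ## package pgen equals the enumeration oracle junction by junction
        expect_equal(unname(pk), gen$prob, tolerance = 1e-12)
        expect_equal(sum(pk), 1, tolerance = 1e-9)
    }
})

test_that("amino-acid pgen sums over synonymous codings", {
    m <- toy_model(2)
    gen <- enumerate_generable(m)
    gen$aa <- suppressWarnings(as.character(
        Biostrings::translate(Biostrings::DNAStringSet(gen$junction_nt),
                              if.fuzzy.codon = "X")))
    inframe <- !is.na(gen$aa) & nchar(gen$junction_nt) %% 3 == 0 &
        !grepl("\\*", gen$aa)
    agg <- tapply(gen$prob[inframe], gen$aa[inframe], sum)
    ## pick an amino-acid junction with more than one coding
    multi <- names(agg)[order(-tapply(rep(1, sum(inframe)),
                                      gen$aa[inframe], sum))]
    for (aa in utils::head(multi, 5)) {
        expect_equal(pgenAa(m, aa)$pgen, unname(agg[aa]), tolerance = 1e-12)
        ## aa-level pgen dominates any single coding
        codings <- gen$junction_nt[inframe & gen$aa == aa]
        for (nt in codings)
            expect_gte(pgenAa(m, aa)$pgen, pgenNt(m, nt)$pgen - 1e-15)
    }
    ## an amino acid unreachable by any scenario is ungenerable
    expect_true(pgenAa(m, "WWWW")$ungenerable)
    expect_error(pgenAa(m, "CAVF", enumerationBound = 2L),
                 class = "tcrclone_config_error")
})

test_that("sampling matches the model: provenance probability and frequencies", {
    ## point-mass model -> always the same junction, prob = its pgen
    m_point <- recombinationModel("TRA",
                                  data.frame(name = "V1", seq = "TGTGCA", prob = 1),
                                  data.frame(name = "J1", seq = "TTT", prob = 1),
                                  vDel = 1, jDel = 1, insLen = 1)
    set.seed(2)
    draws <- sampleJunctions(m_point, 10)
    expect_equal(unique(draws$junction_nt), "TGTGCATTT")
    expect_equal(unique(draws$prob), 1)

    ## scenario probability recorded on each draw equals its pgen contribution
    m <- toy_model(2)
    set.seed(7)
    d <- sampleJunctions(m, 50)
    for (i in seq_len(10)) {
        full <- pgenNt(m, d$junction_nt[i])
        expect_lte(d$prob[i], full$pgen + 1e-15)
        if (full$n_scenarios == 1L)
            expect_equal(d$prob[i], full$pgen, tolerance = 1e-12)
    }

    ## Monte-Carlo frequencies consistent with pgen (chi-squared GOF);
    ## expected probabilities renormalized over the in-frame stop-free
    ## support that rejection sampling conditions on
    gen <- enumerate_generable(m)
    aa <- suppressWarnings(as.character(
        Biostrings::translate(Biostrings::DNAStringSet(gen$junction_nt),
                              if.fuzzy.codon = "X")))
    ok <- nchar(gen$junction_nt) %% 3 == 0 & !grepl("\\*", aa)
    support <- gen[ok, ]
    support$prob <- support$prob / sum(support$prob)
    set.seed(11)
    big <- sampleJunctions(m, 10000)
    expect_true(all(big$junction_nt %in% support$junction_nt))
    obs <- table(factor(big$junction_nt, levels = support$junction_nt))
    keep <- support$prob * 10000 >= 5          # chi-squared validity bins
    chi <- suppressWarnings(stats::chisq.test(
        c(as.integer(obs[keep]), sum(obs[!keep])),
        p = c(support$prob[keep], sum(support$prob[!keep]))))
    expect_gt(chi$p.value, 0.01)

    ## unconditional sampler (no frame rejection bias): empirical insertion
    ## lengths match the marginal distribution within 3 SE
    m_free <- recombinationModel("TRA",
                                 data.frame(name = "V1", seq = "TGTGCA", prob = 1),
                                 data.frame(name = "J1", seq = "ACATTT", prob = 1),
                                 vDel = 1, jDel = 1,
                                 insLen = c(.5, 0, 0, .3, 0, 0, .2))
    set.seed(13)
    d_free <- sampleJunctions(m_free, 10000)
    ## codon-aligned insertions: rejection only removes draws whose insertion
    ## contains a stop codon, P(keep) = (61/64)^(l/3) under uniform nt
    p_marg <- m_free@insLen[c(0, 3, 6) + 1] * (61 / 64)^(c(0, 3, 6) / 3)
    p_cond <- p_marg / sum(p_marg)
    for (k in 1:3) {
        l <- c(0, 3, 6)[k]
        se <- sqrt(p_cond[k] * (1 - p_cond[k]) / 10000)
        expect_lt(abs(mean(nchar(d_free$insertion) == l) - p_cond[k]), 3.5 * se)
    }
})

test_that("zero-insertion draws are more germline-like than unconstrained ones", {
    m <- defaultRecombinationModel("TRB")
    set.seed(21)
    free <- sampleJunctions(m, 150)
    forced <- sampleJunctions(m, 150, forceZeroInsertions = TRUE)
    p_free <- vapply(free$junction_nt, function(x) pgenNt(m, x)$pgen, 0)
    p_forced <- vapply(forced$junction_nt, function(x) pgenNt(m, x)$pgen, 0)
    expect_gte(stats::median(p_forced), stats::median(p_free))
    expect_true(all(nchar(forced$insertion) == 0L))
})

test_that("built-in models: TRA has shorter insertion support than TRB", {
    tra <- defaultRecombinationModel("TRA")
    trb <- defaultRecombinationModel("TRB")
    expect_lt(length(tra@insLen), length(trb@insLen))
    expect_s4_class(tra, "RecombinationModel")
    ## malformed distributions are rejected by the validity method
    expect_error(recombinationModel("TRA",
                                    data.frame(name = "V1", seq = "TGTGCA", prob = 0.9),
                                    data.frame(name = "J1", seq = "TTT", prob = 1),
                                    vDel = 1, jDel = 1, insLen = 1))
})

test_that("comparePgen reports direction and medians per stratum", {
    df <- data.frame(locus = "TRA",
                     publicness = rep(c("public", "private"), each = 2),
                     log10_pgen = c(-6, -7, -10, -11))
    cp <- comparePgen(df)
    expect_equal(cp$tests$direction, "public_higher")
    st <- cp$strata
    expect_equal(st$median_log10_pgen[st$publicness == "public"], -6.5)
    ## identical strata -> no direction, p in the no-shift region
    df2 <- data.frame(locus = "TRA",
                      publicness = rep(c("public", "private"), each = 3),
                      log10_pgen = rep(c(-5, -6, -7), 2))
    cp2 <- comparePgen(df2)
    expect_equal(cp2$tests$direction, "equal")
    expect_gt(cp2$tests$p, 0.5)
    expect_error(comparePgen(data.frame(locus = "TRA", publicness = "public",
                                        log10_pgen = NA_real_)),
                 class = "tcrclone_data_error")
})

test_that("imported pgen values join onto the classification with validation", {
    tab <- make_table(list(c1 = list(TRA = "CAVAF"), c2 = list(TRA = "CAVAF"),
                           c3 = list(TRA = "CAVGF")),
                      donor_of = list(c1 = "d1", c2 = "d2", c3 = "d1"),
                      group_of = list(d1 = "HC", d2 = "HC"))
    s <- classifyJunctions(tab)
    full <- data.frame(locus = "TRA", junction_aa = c("CAVAF", "CAVGF"),
                       pgen = c(1e-5, 1e-7))
    j <- importPgen(full, s)
    expect_equal(attr(j, "n_unmatched"), 0L)
    expect_equal(j$log10_pgen[j$junction_aa == "CAVAF"], -5)

    partial <- full[1, ]
    j2 <- importPgen(partial, s)
    expect_equal(attr(j2, "n_unmatched"), 1L)
    expect_false(j2$matched[j2$junction_aa == "CAVGF"])

    expect_error(importPgen(data.frame(locus = "TRA", junction_aa = "CAVAF",
                                       pgen = 1.5), s),
                 class = "tcrclone_data_error")
})
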