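test_that("expansion and publicness follow the cell/donor definitions", {
    tab <- make_table(
        list(c1 = list(TRA = "CAAAF"), c2 = list(TRA = "CAAAF"),
             c3 = list(TRA = "CAAAF"),                      # 3 cells, 1 donor
             c4 = list(TRB = "CGGGF"), c5 = list(TRB = "CGGGF"),  # 2 donors
             c6 = list(TRB = "CGGHF")),                     # singleton
        donor_of = list(c1 = "d1", c2 = "d1", c3 = "d1", c4 = "d1",
                        c5 = "d2", c6 = "d2"),
        group_of = list(d1 = "HC", d2 = "T1D"))
    s <- classifyJunctions(tab)
    j <- junctionSummary(s)
    row <- function(aa) j[j$junction_aa == aa, ]
    expect_true(row("CAAAF")$expanded)
    expect_equal(row("CAAAF")$publicness, "private")
    expect_true(row("CGGGF")$expanded)          # 2 cells across donors
    expect_equal(row("CGGGF")$publicness, "public")
    expect_false(row("CGGHF")$expanded)
    expect_equal(row("CGGHF")$publicness, "private")
    expect_equal(s@stats$n_expanded_cells, 5L)
    expect_true(row("CGGGF")$cross_group)
})

test_that("a single-donor table warns and calls everything private", {
    tab <- make_table(list(c1 = list(TRA = "CAAAF"), c2 = list(TRA = "CAAAF")))
    expect_warning(s <- classifyJunctions(tab),
                   class = "tcrclone_validation_warning")
    expect_true(all(junctionSummary(s)$publicness == "private"))
})

test_that("publicness is monotone under donor merging", {
    set.seed(31)
    sim <- generateRepertoire(small_design(seed = 31))
    rec <- chainRecords(sim$table)
    s1 <- suppressWarnings(classifyJunctions(sim$table))
    ds <- unique(rec$donor_id)
    merged <- rec
    pick <- sample(ds, 2)
    merged$donor_id[merged$donor_id %in% pick] <- pick[1]
    ## merged donor keeps one group label to satisfy the donor->group map
    grp <- merged$disease_group[merged$donor_id == pick[1]][1]
    merged$disease_group[merged$donor_id == pick[1]] <- grp
    s2 <- suppressWarnings(classifyJunctions(RepertoireTable(merged)))
    j1 <- junctionSummary(s1); j2 <- junctionSummary(s2)
    idx <- match(paste(j1$locus, j1$junction_aa), paste(j2$locus, j2$junction_aa))
    ## merging can only demote public -> private, never promote
    expect_false(any(j1$publicness == "private" & j2$publicness[idx] == "public"))
})

test_that("classification totals are consistent", {
    sim <- generateRepertoire(small_design(seed = 37))
    s <- suppressWarnings(classifyJunctions(sim$table))
    j <- junctionSummary(s)
    expect_equal(sum(j$publicness == "public") + sum(j$publicness == "private"),
                 nrow(j))
    gc <- s@stats$group_counts
    ## junctions counted once per group they appear in
    expect_equal(sum(gc$n_junctions), sum(lengths(j$groups)))
})

test_that("invariant-chain filter removes the iNKT chain and logs it", {
    rec <- data.frame(cell_id = c("c1", "c2"), donor_id = "d1",
                      disease_group = "HC", locus = "TRA",
                      v_call = c("TRAV10", "TRAV2"),
                      j_call = c("TRAJ18", "TRAJ4"),
                      junction_aa = c("CVVSDRGSTLGRLYF", "CAVF"),
                      stringsAsFactors = FALSE)
    tab <- RepertoireTable(rec)
    out <- applyFilters(tab, filterConfig())
    expect_equal(chainRecords(out)$junction_aa, "CAVF")
    expect_equal(provenance(out)$filter_log$invariant_blocklist, 1L)
})

test_that("memory-only filter keeps memory cells; empty config is identity", {
    rec <- data.frame(cell_id = c("c1", "c2", "c3"), donor_id = "d1",
                      disease_group = "HC", locus = "TRA",
                      junction_aa = c("CAVAF", "CAVGF", "CAVCF"),
                      phenotype = c("memory", "memory", "naive"),
                      stringsAsFactors = FALSE)
    tab <- RepertoireTable(rec)
    out <- applyFilters(tab, filterConfig(invariant_blocklist = NULL,
                                          memory_only = TRUE))
    expect_equal(sort(unique(chainRecords(out)$cell_id)), c("c1", "c2"))

    ident <- applyFilters(tab, filterConfig(invariant_blocklist = NULL))
    expect_equal(chainRecords(ident), chainRecords(tab))

    expect_error(applyFilters(RepertoireTable(rec[3, ]),
                              filterConfig(invariant_blocklist = NULL,
                                           memory_only = TRUE)),
                 "memory_only", class = "tcrclone_data_error")
})

test_that("UMI and per-locus chain-count filters act as declared", {
    rec <- data.frame(cell_id = c("c1", "c1", "c1", "c2"), donor_id = "d1",
                      disease_group = "HC", locus = c("TRA", "TRA", "TRA", "TRB"),
                      junction_aa = c("CAVAF", "CAVGF", "CAVCF", "CASSF"),
                      umi_count = c(5L, 1L, 5L, 5L), stringsAsFactors = FALSE)
    tab <- RepertoireTable(rec)
    out <- applyFilters(tab, filterConfig(invariant_blocklist = NULL,
                                          min_umi = 2L))
    expect_equal(nrow(chainRecords(out)), 3L)
    out2 <- applyFilters(tab, filterConfig(invariant_blocklist = NULL,
                                           max_chains_per_locus = 2L))
    expect_equal(unique(chainRecords(out2)$cell_id), "c2")
})

test_that("donor sharing matrix counts pairwise shared junctions", {
    tab <- make_table(
        list(c1 = list(TRA = "CAAAF"), c2 = list(TRA = "CAAAF"),
             c3 = list(TRA = "CAAAF"),
             c4 = list(TRB = "CGGGF"), c5 = list(TRB = "CGGGF")),
        donor_of = list(c1 = "d1", c2 = "d2", c3 = "d3", c4 = "d1", c5 = "d2"),
        group_of = list(d1 = "HC", d2 = "HC", d3 = "T1D"))
    s <- classifyJunctions(tab)
    m <- donorMatrix(s)
    ## CAAAF in d1,d2,d3 contributes to all 3 pairs; CGGGF to (d1,d2)
    expect_equal(m["d1", "d2"], 2L)
    expect_equal(m["d1", "d3"], 1L)
    expect_equal(m["d2", "d3"], 1L)
    expect_true(isSymmetric(unname(m)))
    expect_true(all(diag(m) == 0))
    sm <- sharingMatrix(s)
    expect_equal(sum(sm$long$n_shared), 4L)
    expect_equal(sm$group_totals$n_shared[sm$group_totals$group_pair == "HC|HC"], 2L)

    ## no sharing -> zero matrix
    tab0 <- make_table(list(c1 = list(TRA = "CAAAF"), c2 = list(TRA = "CAAGF")),
                       donor_of = list(c1 = "d1", c2 = "d2"),
                       group_of = list(d1 = "HC", d2 = "HC"))
    expect_true(all(donorMatrix(classifyJunctions(tab0)) == 0))
})

test_that("reference overlap: exact and single-mismatch matching with Fisher test", {
    tab <- make_table(
        list(c1 = list(TRA = "CAVAAF"), c2 = list(TRA = "CAVAAF"),
             c3 = list(TRA = "CAVGGF"), c4 = list(TRA = "CAVGGF"),
             c5 = list(TRA = "CAVCCF"), c6 = list(TRA = "CAVCCF"),
             c7 = list(TRA = "CAVDDF"), c8 = list(TRA = "CAVDDF")),
        donor_of = list(c1 = "d1", c2 = "d2", c3 = "d1", c4 = "d2",
                        c5 = "d1", c6 = "d1", c7 = "d1", c8 = "d1"),
        group_of = list(d1 = "HC", d2 = "HC"))
    ## public: CAVAAF, CAVGGF; private expanded: CAVCCF, CAVDDF
    s <- classifyJunctions(tab)
    ref <- ReferenceJunctionSet(data.frame(locus = "TRA",
                                           junction_aa = "CAVAAF"))
    ov0 <- overlapWithReference(s, ref, maxMismatch = 0L)
    st <- ov0$strata
    expect_equal(st$n_matched[st$publicness == "public"], 1L)
    expect_equal(st$n_matched[st$publicness == "private"], 0L)
    ## Fisher 2x2 [[1,1],[0,2]] -> two-sided p = 1 (enumerated by hand)
    expect_equal(ov0$tests$p, 1.0)

    ## one substitution away matches only at maxMismatch = 1
    ref2 <- ReferenceJunctionSet(data.frame(locus = "TRA",
                                            junction_aa = "CAVACF"))
    m0 <- overlapWithReference(s, ref2, 0L)$matches
    m1 <- overlapWithReference(s, ref2, 1L)$matches
    expect_false(m0$matched[m0$junction_aa == "CAVAAF"])
    expect_true(m1$matched[m1$junction_aa == "CAVAAF"])
    ## mismatch-1 matches are a superset of exact matches
    expect_true(all(m1$matched >= m0$matched))
    ## invariant to reference duplication
    ref_dup <- ReferenceJunctionSet(
        data.frame(locus = rep("TRA", 2), junction_aa = rep("CAVAAF", 2)))
    expect_equal(overlapWithReference(s, ref_dup, 0L)$strata,
                 overlapWithReference(s, ref, 0L)$strata)
    ## levenshtein metric admits an indel at distance 1
    ref3 <- ReferenceJunctionSet(data.frame(locus = "TRA",
                                            junction_aa = "CAVAAAF"))
    mh <- overlapWithReference(s, ref3, 1L, metric = "hamming")$matches
    ml <- overlapWithReference(s, ref3, 1L, metric = "levenshtein")$matches
    expect_false(mh$matched[mh$junction_aa == "CAVAAF"])
    expect_true(ml$matched[ml$junction_aa == "CAVAAF"])

    expect_error(overlapWithReference(s, ref, 2L),
                 class = "tcrclone_config_error")
})
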