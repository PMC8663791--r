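test_that("graph construction: vertices, edges and weights from codetection", {
    tab <- make_table(list(c1 = list(TRA = "CAAAF", TRB = "CGGGF"),
                           c2 = list(TRA = "CAAAF", TRB = "CGGHF")))
    g <- buildCloneGraph(tab)
    vt <- vertexTable(g); et <- edgeTable(g)
    expect_equal(nrow(vt), 3L)
    expect_equal(nrow(et), 2L)
    expect_equal(vt$weight[vt$junction == "CAAAF"], 2L)
    expect_true(all(et$weight == 1L))

    ## same pair in two cells -> edge weight 2
    tab2 <- make_table(list(c1 = list(TRA = "CAAAF", TRB = "CGGGF"),
                            c2 = list(TRA = "CAAAF", TRB = "CGGGF")))
    et2 <- edgeTable(buildCloneGraph(tab2))
    expect_equal(nrow(et2), 1L)
    expect_equal(et2$weight, 2L)

    ## single-chain cell -> isolated vertex
    tab3 <- make_table(list(c1 = list(TRA = "CAAAF")))
    g3 <- buildCloneGraph(tab3)
    expect_equal(nrow(vertexTable(g3)), 1L)
    expect_equal(nrow(edgeTable(g3)), 0L)

    expect_error(buildCloneGraph(RepertoireTable(chainRecords(tab)[0, ])),
                 class = "tcrclone_data_error")
})

test_that("vertex weight is at least the max incident edge weight", {
    sim <- generateRepertoire(small_design(seed = 7))
    g <- buildCloneGraph(sim$table)
    vt <- vertexTable(g); et <- edgeTable(g)
    for (i in seq_len(nrow(et))) {
        expect_gte(vt$weight[vt$chain == et$from[i]], et$weight[i])
        expect_gte(vt$weight[vt$chain == et$to[i]], et$weight[i])
    }
})

test_that("clones are connected components with topology labels", {
    tab <- make_table(list(c1 = list(TRA = "CAAAF", TRB = "CGGGF"),
                           c2 = list(TRA = "CAAAF", TRB = "CGGHF"),
                           c3 = list(TRA = "CAADF", TRB = "CGGIF")))
    cl <- callClones(buildCloneGraph(tab))
    expect_equal(nrow(cl), 2L)
    expect_equal(cl$topology_label, c("1 TRA-2 TRB", "1 TRA-1 TRB"))
    expect_equal(sort(unlist(cl$member_chains[[1]])),
                 c("TRA|CAAAF", "TRB|CGGGF", "TRB|CGGHF"))

    ## a 2 TRA - 1 TRB component gets the dual-alpha label
    tab2 <- make_table(list(c1 = list(TRA = c("CAAAF", "CAAGF"), TRB = "CGGGF")))
    cl2 <- callClones(buildCloneGraph(tab2))
    expect_equal(cl2$topology_label, "2 TRA-1 TRB")

    ## fully disconnected vertices -> singleton clones
    tab3 <- make_table(list(c1 = list(TRA = "CAAAF"), c2 = list(TRA = "CAAGF"),
                            c3 = list(TRB = "CGGGF"), c4 = list(TRB = "CGGHF")))
    expect_equal(nrow(callClones(buildCloneGraph(tab3))), 4L)
})

test_that("clone calling matches brute-force components on random graphs", {
    set.seed(202)
    for (rep in 1:200) {
        n_cells <- sample(3:25, 1)
        tra <- rand_aa(sample(2:8, 1)); trb <- rand_aa(sample(2:8, 1))
        cells <- lapply(seq_len(n_cells), function(i)
            list(TRA = sample(tra, sample(1:2, 1)),
                 TRB = sample(trb, sample(0:2, 1))))
        names(cells) <- paste0("c", seq_len(n_cells))
        tab <- make_table(cells)
        g <- buildCloneGraph(tab)
        cl <- callClones(g)
        vt <- vertexTable(g); et <- edgeTable(g)
        memb <- brute_components(nrow(vt),
                                 cbind(match(et$from, vt$chain),
                                       match(et$to, vt$chain)))
        oracle_comp <- lapply(split(vt$chain, memb), sort)
        called_comp <- lapply(cl$member_chains, sort)
        expect_setequal(unname(vapply(oracle_comp, paste, "", collapse = ",")),
                        unname(vapply(called_comp, paste, "", collapse = ",")))
        ## clones partition the vertices
        expect_equal(sum(cl$n_chains), nrow(vt))
        expect_equal(sort(unlist(cl$member_chains, use.names = FALSE)), sort(vt$chain))
    }
})

test_that("clone membership is invariant to row order and cell relabeling", {
    sim <- generateRepertoire(small_design(seed = 13))
    rec <- chainRecords(sim$table)
    cl1 <- callClones(buildCloneGraph(sim$table))
    set.seed(5)
    perm <- RepertoireTable(rec[sample(nrow(rec)), ])
    cl2 <- callClones(buildCloneGraph(perm))
    expect_equal(cl1$clone_id, cl2$clone_id)
    expect_equal(cl1$member_chains, cl2$member_chains)

    relab <- rec
    relab$cell_id <- paste0("X", relab$cell_id)
    cl3 <- callClones(buildCloneGraph(RepertoireTable(relab)))
    expect_equal(cl3$member_chains, cl1$member_chains)
    expect_equal(cl3$topology_label, cl1$topology_label)
})

test_that("every cell's chains fall inside a single clone", {
    sim <- generateRepertoire(small_design(seed = 17))
    g <- buildCloneGraph(sim$table)
    cl <- callClones(g)
    chain_to_clone <- rep(cl$clone_id, lengths(cl$member_chains))
    names(chain_to_clone) <- unlist(cl$member_chains)
    rec <- chainRecords(sim$table)
    keys <- paste(rec$locus, rec$junction_aa, sep = "|")
    per_cell <- split(chain_to_clone[keys], rec$cell_id)
    expect_true(all(vapply(per_cell, function(x) length(unique(x)) == 1L, TRUE)))
})

test_that("partner counts per junction, both directions", {
    tab <- make_table(list(c1 = list(TRA = "CAAAF", TRB = "CGGGF"),
                           c2 = list(TRA = "CAAAF", TRB = "CGGGF"),
                           c3 = list(TRA = "CAAAF", TRB = "CGGGF"),
                           c4 = list(TRA = "CAAAF", TRB = "CGGHF"),
                           c5 = list(TRA = "CALNF")))
    pc <- partnerCounts(tab, "TRA")
    expect_equal(pc$n_partners[pc$junction_aa == "CAAAF"], 2L)
    expect_equal(pc$n_partners[pc$junction_aa == "CALNF"], 0L)
    rev <- partnerCounts(tab, "TRB")
    expect_equal(rev$n_partners, c(1L, 1L))
    only_tra <- make_table(list(c1 = list(TRA = "CAAAF")))
    expect_error(partnerCounts(only_tra, "TRB"),
                 class = "tcrclone_data_error")
})

test_that("graph export round-trips through edge TSV; graphml and dot written", {
    sim <- generateRepertoire(small_design(seed = 19))
    g <- buildCloneGraph(sim$table)
    path <- withr::local_tempfile(fileext = ".tsv")
    exportGraph(g, path, "edge_tsv")
    g2 <- importGraphEdges(path)
    expect_equal(vertexTable(g2)[order(vertexTable(g2)$chain), ],
                 vertexTable(g)[order(vertexTable(g)$chain), ],
                 ignore_attr = TRUE)
    canon_e <- function(x) {
        e <- edgeTable(x)
        e <- data.frame(a = pmin(e$from, e$to), b = pmax(e$from, e$to),
                        w = e$weight)
        e[order(e$a, e$b), ]
    }
    expect_equal(canon_e(g2), canon_e(g), ignore_attr = TRUE)
    expect_equal(callClones(g2)$topology_label, callClones(g)$topology_label)

    gml <- withr::local_tempfile(fileext = ".graphml")
    exportGraph(g, gml, "graphml")
    g3 <- igraph::read_graph(gml, format = "graphml")
    expect_equal(igraph::vcount(g3), igraph::vcount(g@graph))
    expect_equal(igraph::ecount(g3), igraph::ecount(g@graph))

    dot <- withr::local_tempfile(fileext = ".dot")
    exportGraph(g, dot, "dot")
    expect_gte(sum(grepl("--", readLines(dot), fixed = TRUE)),
               igraph::ecount(g@graph))

    expect_error(exportGraph(g, path, "svg"), class = "tcrclone_config_error")
})

test_that("nt resolution excludes records without junction_nt", {
    rec <- chainRecords(make_table(list(c1 = list(TRA = "CAAAF", TRB = "CGGGF"))))
    rec$junction_nt <- c("TGTGCTGCTGCTTTT", "")[match(rec$locus, c("TRA", "TRB"))]
    rec$junction_aa <- c("CAAAF", "CGGGF")[match(rec$locus, c("TRA", "TRB"))]
    tab <- suppressWarnings(RepertoireTable(rec))
    expect_message(g <- buildCloneGraph(tab, resolution = "nt"), "excluding 1")
    expect_equal(nrow(vertexTable(g)), 1L)
})
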