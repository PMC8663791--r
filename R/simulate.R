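## Synthetic paired-chain repertoires with ground truth. The generator plants
## exactly the structures the analyses are designed to detect — clonal
## expansion, cross-donor public junctions (optionally germline-like, i.e.
## zero-insertion), convergent TRA chains with near-duplicate TRB partners,
## an invariant iNKT spike, and chain dropout — so recovery can be scored
## against known labels without any external data.

INVARIANT_INKT <- list(v_call = "TRAV10", j_call = "TRAJ18",
                       junction_aa = "CVVSDRGSTLGRLYF",
                       junction_nt = "TGTGTGGTGAGTGATAGAGGTAGCACTTTAGGAAGACTTTATTTT")

#' Construct a synthetic repertoire design
#'
#' Defaults mirror a three-group antigen-reactive CD4 T cell study: groups
#' HC / newT1D / T1D with 12 / 24 / 12 donors and mean paired-chain yields of
#' about 38 / 62 / 68 cells per donor. Scale the groups down for fast tests.
#'
#' @param groups data.frame: name, n_donors, cells_per_donor.
#' @param cloneDist,cloneParam clone-size distribution ("geometric" with
#'   success probability, or "zipf" with exponent).
#' @param nPublic,publicDonorSpread,zeroInsertionBias injected public
#'   junction settings (see \linkS4class{RepertoireDesign}).
#' @param nConvergentTra,trbPartnersPerTra,trbMutationDistance convergent
#'   TRA settings.
#' @param invariantRate,dropout,memoryFraction cell-level rates.
#' @param seed generator seed.
#' @return A \linkS4class{RepertoireDesign}.
#' @export
repertoireDesign <- function(groups = data.frame(
                                 name = c("HC", "newT1D", "T1D"),
                                 n_donors = c(12L, 24L, 12L),
                                 cells_per_donor = c(38L, 62L, 68L),
                                 stringsAsFactors = FALSE),
                             cloneDist = "geometric", cloneParam = 0.85,
                             nPublic = 30L, publicDonorSpread = 2.5,
                             zeroInsertionBias = TRUE,
                             nConvergentTra = 6L, trbPartnersPerTra = 3L,
                             trbMutationDistance = 2L,
                             invariantRate = 0.02, dropout = 0.05,
                             memoryFraction = 0.85, seed = 1L) {
    new("RepertoireDesign", groups = as.data.frame(groups),
        cloneDist = cloneDist, cloneParam = cloneParam,
        nPublic = as.integer(nPublic), publicDonorSpread = publicDonorSpread,
        zeroInsertionBias = isTRUE(zeroInsertionBias),
        nConvergentTra = as.integer(nConvergentTra),
        trbPartnersPerTra = as.integer(trbPartnersPerTra),
        trbMutationDistance = as.integer(trbMutationDistance),
        invariantRate = invariantRate, dropout = dropout,
        memoryFraction = memoryFraction, seed = as.integer(seed))
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## substitute one interior residue; returns c(aa, nt) with the codon rewritten
mutate_junction <- function(aa, nt, pos, codons) {
    chars <- strsplit(aa, "")[[1]]
    new_res <- sample(setdiff(AA20, chars[pos]), 1L)
    chars[pos] <- new_res
    new_nt <- nt
    if (nzchar(nt)) {
        cd <- sample(codons[[new_res]], 1L)
        substr(new_nt, 3L * pos - 2L, 3L * pos) <- cd
    }
    c(paste(chars, collapse = ""), new_nt)
}

sample_distinct <- function(model, n, taken, zeroIns, max_retry = 50L) {
    ## n junctions distinct from each other and from `taken`
    out <- NULL
    for (r in seq_len(max_retry)) {
        cand <- sampleJunctions(model, n, forceZeroInsertions = zeroIns)
        cand <- cand[!duplicated(cand$junction_aa) &
                         !cand$junction_aa %in% taken, , drop = FALSE]
        out <- rbind(out, cand)
        out <- out[!duplicated(out$junction_aa), , drop = FALSE]
        if (nrow(out) >= n) return(out[seq_len(n), , drop = FALSE])
        taken <- c(taken, out$junction_aa)
    }
    stopData("design requires more unique junctions than the model yields (wanted %d)", n)
}

#' Generate a synthetic paired-chain repertoire with ground truth
#'
#' @param design a \linkS4class{RepertoireDesign}.
#' @param models list with TRA and TRB \linkS4class{RecombinationModel}s
#'   (defaults to the built-in models).
#' @return list: table (a \linkS4class{RepertoireTable}), truth (list with
#'   junction labels and per-cell latent clone assignment), design.
#' @export
generateRepertoire <- function(design,
                               models = list(TRA = defaultRecombinationModel("TRA"),
                                             TRB = defaultRecombinationModel("TRB"))) {
    stopifnot(is(design, "RepertoireDesign"))
    set.seed(design@seed)
    codons <- codon_table()
    g <- design@groups

    donor_tab <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
        data.frame(donor_id = sprintf("%s_d%02d", g$name[i], seq_len(g$n_donors[i])),
                   disease_group = g$name[i], n_cells = g$cells_per_donor[i],
                   stringsAsFactors = FALSE)))

    ## latent clones per donor: sizes from the clone-size distribution
    clone_sizes <- function(n) {
        sizes <- integer()
        while (sum(sizes) < n) {
            s <- if (design@cloneDist == "geometric")
                stats::rgeom(n, design@cloneParam) + 1L
            else sample(1:15, n, replace = TRUE,
                        prob = (1:15)^(-design@cloneParam))
            sizes <- c(sizes, s)
        }
        k <- which(cumsum(sizes) >= n)[1]
        sizes <- sizes[seq_len(k)]
        sizes[k] <- sizes[k] - (sum(sizes) - n)
        sizes[sizes > 0L]
    }
    clones <- do.call(rbind, lapply(seq_len(nrow(donor_tab)), function(i) {
        s <- clone_sizes(donor_tab$n_cells[i])
        data.frame(donor_id = donor_tab$donor_id[i],
                   disease_group = donor_tab$disease_group[i],
                   size = s, stringsAsFactors = FALSE)
    }))
    nC <- nrow(clones)
    clones$clone_index <- seq_len(nC)

    ## background chains, one TRA + one TRB per latent clone
    tra_bg <- sampleJunctions(models$TRA, nC)
    trb_bg <- sampleJunctions(models$TRB, nC)
    for (side in c("tra", "trb")) {
        src <- if (side == "tra") tra_bg else trb_bg
        clones[[paste0(side, "_aa")]] <- src$junction_aa
        clones[[paste0(side, "_nt")]] <- src$junction_nt
        clones[[paste0(side, "_v")]] <- src$v_name
        clones[[paste0(side, "_j")]] <- src$j_name
    }
    clones$label_tra <- "background"
    clones$label_trb <- "background"
    used <- rep(FALSE, nC)
    taken <- unique(c(clones$tra_aa, clones$trb_aa))

    ## convergent TRA chains: one public TRA, several near-duplicate TRBs,
    ## one partner clone per donor
    if (design@nConvergentTra > 0L) {
        conv_tra <- sample_distinct(models$TRA, design@nConvergentTra, taken,
                                    design@zeroInsertionBias)
        taken <- c(taken, conv_tra$junction_aa)
        for (k in seq_len(design@nConvergentTra)) {
            n_part <- design@trbPartnersPerTra
            cand_donors <- sample(donor_tab$donor_id,
                                  min(n_part, nrow(donor_tab)))
            slots <- vapply(cand_donors, function(d) {
                free <- which(clones$donor_id == d & !used)
                if (length(free)) free[sample.int(length(free), 1L)] else NA_integer_
            }, 0L)
            slots <- slots[!is.na(slots)]
            if (length(slots) < 2L) next
            used[slots] <- TRUE
            base <- sample_distinct(models$TRB, 1L, taken, FALSE)
            taken <- c(taken, base$junction_aa)
            inner <- 2:(nchar(base$junction_aa) - 1L)
            mut_pos <- sample(inner, length(slots) - 1L)
            for (s in seq_along(slots)) {
                i <- slots[s]
                clones$tra_aa[i] <- conv_tra$junction_aa[k]
                clones$tra_nt[i] <- conv_tra$junction_nt[k]
                clones$tra_v[i] <- conv_tra$v_name[k]
                clones$tra_j[i] <- conv_tra$j_name[k]
                clones$label_tra[i] <- "convergent_tra_member"
                if (s == 1L) {
                    trb <- c(base$junction_aa, base$junction_nt)
                } else {
                    trb <- mutate_junction(base$junction_aa, base$junction_nt,
                                           mut_pos[s - 1L], codons)
                }
                clones$trb_aa[i] <- trb[1]
                clones$trb_nt[i] <- trb[2]
                clones$trb_v[i] <- base$v_name
                clones$trb_j[i] <- base$j_name
                clones$label_trb[i] <- "convergent_trb_partner"
                taken <- c(taken, trb[1])
            }
        }
    }

    ## injected public junctions, alternating loci, spread over >= 2 donors
    if (design@nPublic > 0L) {
        loci <- rep(c("TRA", "TRB"), length.out = design@nPublic)
        inj <- list(TRA = NULL, TRB = NULL)
        if (any(loci == "TRA")) {
            inj$TRA <- sample_distinct(models$TRA, sum(loci == "TRA"), taken,
                                       design@zeroInsertionBias)
            taken <- c(taken, inj$TRA$junction_aa)
        }
        if (any(loci == "TRB")) {
            inj$TRB <- sample_distinct(models$TRB, sum(loci == "TRB"), taken,
                                       design@zeroInsertionBias)
            taken <- c(taken, inj$TRB$junction_aa)
        }
        ptr <- c(TRA = 0L, TRB = 0L)
        for (k in seq_len(design@nPublic)) {
            loc <- loci[k]
            ptr[loc] <- ptr[loc] + 1L
            jn <- inj[[loc]][ptr[loc], ]
            n_d <- min(2L + stats::rpois(1L, design@publicDonorSpread - 2),
                       nrow(donor_tab))
            ds <- sample(donor_tab$donor_id, n_d)
            slots <- vapply(ds, function(d) {
                free <- which(clones$donor_id == d & !used)
                if (length(free)) free[sample.int(length(free), 1L)] else NA_integer_
            }, 0L)
            slots <- slots[!is.na(slots)]
            if (length(slots) < 2L) next
            used[slots] <- TRUE
            side <- tolower(loc)
            for (i in slots) {
                clones[[paste0(side, "_aa")]][i] <- jn$junction_aa
                clones[[paste0(side, "_nt")]][i] <- jn$junction_nt
                clones[[paste0(side, "_v")]][i] <- jn$v_name
                clones[[paste0(side, "_j")]][i] <- jn$j_name
                clones[[paste0("label_", side)]][i] <- "injected_public"
            }
        }
    }

    ## expand clones into cells
    cell_clone <- rep(clones$clone_index, clones$size)
    n_cells <- length(cell_clone)
    cell_id <- sprintf("cell_%05d", seq_len(n_cells))
    ci <- clones[match(cell_clone, clones$clone_index), ]
    rec <- rbind(
        data.frame(cell_id = cell_id, donor_id = ci$donor_id,
                   disease_group = ci$disease_group, locus = "TRA",
                   v_call = ci$tra_v, j_call = ci$tra_j,
                   junction_aa = ci$tra_aa, junction_nt = ci$tra_nt,
                   label = ci$label_tra, stringsAsFactors = FALSE),
        data.frame(cell_id = cell_id, donor_id = ci$donor_id,
                   disease_group = ci$disease_group, locus = "TRB",
                   v_call = ci$trb_v, j_call = ci$trb_j,
                   junction_aa = ci$trb_aa, junction_nt = ci$trb_nt,
                   label = ci$label_trb, stringsAsFactors = FALSE))

    ## invariant iNKT spike, cell level
    if (design@invariantRate > 0) {
        spiked <- cell_id[stats::runif(n_cells) < design@invariantRate]
        hit <- rec$locus == "TRA" & rec$cell_id %in% spiked
        rec$v_call[hit] <- INVARIANT_INKT$v_call
        rec$j_call[hit] <- INVARIANT_INKT$j_call
        rec$junction_aa[hit] <- INVARIANT_INKT$junction_aa
        rec$junction_nt[hit] <- INVARIANT_INKT$junction_nt
        rec$label[hit] <- "invariant"
    }

    ## intended truth is taken before dropout: dropout only removes evidence
    jt_key <- paste(rec$locus, rec$junction_aa, sep = "|")
    jd <- lapply(split(rec$donor_id, jt_key), unique)
    jc <- lapply(split(rec$cell_id, jt_key), unique)
    first <- !duplicated(jt_key)
    truth_j <- data.frame(locus = rec$locus[first],
                          junction_aa = rec$junction_aa[first],
                          label = rec$label[first],
                          stringsAsFactors = FALSE)
    ord <- jt_key[first]
    truth_j$intended_public <- lengths(jd[ord]) >= 2L
    truth_j$intended_expanded <- lengths(jc[ord]) >= 2L
    truth_j$n_donors_intended <- lengths(jd[ord])

    ## chain dropout
    if (design@dropout > 0) {
        lost <- cell_id[stats::runif(n_cells) < design@dropout]
        lost_locus <- sample(VALID_LOCI, length(lost), replace = TRUE)
        m <- match(rec$cell_id, lost)
        drop <- !is.na(m) & rec$locus == lost_locus[pmax(m, 1L)]
        rec <- rec[!drop, , drop = FALSE]
    }

    phen <- ifelse(stats::runif(n_cells) < design@memoryFraction,
                   "memory", "naive")
    rec$phenotype <- phen[match(rec$cell_id, cell_id)]

    table <- RepertoireTable(rec[, setdiff(names(rec), "label")],
                             provenance = list(source = "generateRepertoire",
                                               seed = design@seed))
    truth <- list(junctions = truth_j,
                  cells = data.frame(cell_id = cell_id,
                                     donor_id = ci$donor_id,
                                     disease_group = ci$disease_group,
                                     clone_index = cell_clone,
                                     stringsAsFactors = FALSE),
                  seed = design@seed)
    list(table = table, truth = truth, design = design)
}

#' Score analysis output against generator ground truth
#'
#' Precision/recall of the public and expanded calls against the generator's
#' intended labels, per-label confusion counts, and (when partner counts are
#' supplied) recall of convergent TRA detection (a convergent TRA counts as
#' detected when it shows >= 2 distinct TRB partners).
#'
#' @param truth the truth component returned by
#'   \code{\link{generateRepertoire}}.
#' @param summary a \linkS4class{SharingSummary} computed from the generated
#'   table, or NULL (an empty analysis scores 0 recall).
#' @param partners optional \code{\link{partnerCounts}} output for TRA.
#' @return list of metrics.
#' @export
groundTruthReport <- function(truth, summary, partners = NULL) {
    tj <- truth$junctions
    if (is.null(summary)) {
        return(list(publicness = c(precision = NA_real_, recall = 0),
                    expansion = c(precision = NA_real_, recall = 0),
                    convergent_recall = if (is.null(partners)) NA_real_ else 0,
                    confusion = NULL))
    }
    js <- junctionSummary(summary)
    idx <- match(paste(js$locus, js$junction_aa),
                 paste(tj$locus, tj$junction_aa))
    if (any(is.na(idx)))
        stop("mismatched provenance: summary contains junctions absent from the ground truth")
    pred_pub <- js$publicness == "public"
    true_pub <- tj$intended_public[idx]
    pred_exp <- js$expanded
    true_exp <- tj$intended_expanded[idx]
    pr <- function(pred, truth) {
        c(precision = if (sum(pred)) sum(pred & truth) / sum(pred) else NA_real_,
          recall = if (sum(truth)) sum(pred & truth) / sum(truth) else NA_real_)
    }
    conv_recall <- NA_real_
    if (!is.null(partners)) {
        conv <- tj$junction_aa[tj$locus == "TRA" &
                                   tj$label == "convergent_tra_member"]
        if (length(conv)) {
            np <- partners$n_partners[match(conv, partners$junction_aa)]
            conv_recall <- mean(!is.na(np) & np >= 2L)
        }
    }
    list(publicness = pr(pred_pub, true_pub),
         expansion = pr(pred_exp, true_exp),
         convergent_recall = conv_recall,
         confusion = table(label = tj$label[idx],
                           predicted = js$publicness))
}
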