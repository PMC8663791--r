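## End-to-end pipeline composition behind the command-line entry point
## (inst/cli/tcrclone). Configuration is a declarative YAML list; one master
## seed governs every stochastic stage (stage seeds are fixed offsets of it)
## so identical config + seed gives identical output trees.

default_run_config <- function() {
    list(input = NULL, dialect = "airr", column_map = NULL,
         outdir = "tcrclone_out", seed = 1L,
         filters = list(invariant = TRUE, memory_only = FALSE, min_umi = 0,
                        max_chains_per_locus = NULL),
         downsample = list(unit = "junctions", target_size = 183L,
                           n_iter = 10000L, statistic = "n_public"),
         levnull = list(scope = "public", n_sets = 1000L, set_size = NULL),
         pgen = list(source = "builtin", level = "nt", import_file = NULL),
         skip = character(),
         design = list())
}

load_run_config <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config)) stopConfig("config file not found: %s", config)
        config <- yaml::read_yaml(config)
    }
    if (!is.list(config)) stopConfig("config must be a list or a YAML path")
    utils::modifyList(default_run_config(), config)
}

stage_seed <- function(config, offset) (as.integer(config$seed) + offset) %% .Machine$integer.max

with_stage <- function(name, log_env, n_in, expr) {
    res <- withCallingHandlers(
        tryCatch(expr, error = function(e) {
            stop(errorCondition(
                sprintf("stage '%s': %s", name, conditionMessage(e)),
                class = unique(c(class(e)[1], "tcrclone_stage_error",
                                 class(e)))))
        }),
        message = function(m) invokeRestart("muffleMessage"))
    log_env$log <- rbind(log_env$log,
                         data.frame(stage = name, records_in = n_in,
                                    records_out = attr(res, "n_out") %||% NA_integer_,
                                    stringsAsFactors = FALSE))
    res
}

design_from_config <- function(cfg) {
    d <- cfg$design %||% list()
    args <- list()
    if (!is.null(d$groups)) args$groups <- as.data.frame(do.call(rbind.data.frame, d$groups))
    for (nm in c("cloneDist", "cloneParam", "nPublic", "publicDonorSpread",
                 "zeroInsertionBias", "nConvergentTra", "trbPartnersPerTra",
                 "trbMutationDistance", "invariantRate", "dropout",
                 "memoryFraction"))
        if (!is.null(d[[nm]])) args[[nm]] <- d[[nm]]
    args$seed <- cfg$seed
    do.call(repertoireDesign, args)
}

#' Simulate a synthetic repertoire to disk
#'
#' Writes an AIRR rearrangement TSV, the junction-level ground truth, and the
#' design/config actually used into the output directory. Byte-identical
#' under a fixed seed.
#'
#' @param config list or YAML path; \code{design} entries override the
#'   \code{\link{repertoireDesign}} defaults, \code{seed} and \code{outdir}
#'   control the run.
#' @return invisible named vector of output paths.
#' @export
cmdSimulate <- function(config = list()) {
    cfg <- load_run_config(config)
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    design <- design_from_config(cfg)
    sim <- generateRepertoire(design)
    paths <- c(rearrangements = file.path(cfg$outdir, "rearrangements.tsv"),
               truth = file.path(cfg$outdir, "ground_truth.tsv"),
               config = file.path(cfg$outdir, "run_config.yaml"))
    writeTable(sim$table, paths["rearrangements"])
    writeTable(sim$truth$junctions, paths["truth"])
    yaml::write_yaml(cfg, paths["config"])
    invisible(paths)
}

#' Run the full analysis pipeline
#'
#' filters -> clone graph -> sharing -> diversity/downsampling -> junction
#' lengths -> chain pairing -> Levenshtein null test -> pgen comparison,
#' writing one TSV per analysis plus a run log with per-stage record counts.
#' Stages named in \code{config$skip} are omitted. Any stage error aborts
#' with the stage name prefixed to the message.
#'
#' @param config list or YAML path; \code{input} must point at a
#'   rearrangement TSV (e.g. from \code{\link{cmdSimulate}}).
#' @return invisible list of analysis results.
#' @export
cmdAnalyze <- function(config) {
    cfg <- load_run_config(config)
    if (is.null(cfg$input)) stopConfig("config field 'input' is required")
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(cfg, file.path(cfg$outdir, "run_config.yaml"))
    log_env <- new.env(); log_env$log <- NULL
    out <- list()
    n_out <- function(x, n) { attr(x, "n_out") <- n; x }
    skip <- cfg$skip %||% character()

    table <- with_stage("read", log_env, NA_integer_, {
        t <- readRearrangements(cfg$input, dialect = cfg$dialect,
                                column_map = cfg$column_map)
        n_out(t, nrow(chainRecords(t)))
    })

    table <- with_stage("filters", log_env, nrow(chainRecords(table)), {
        f <- cfg$filters
        conf <- filterConfig(
            invariant_blocklist = if (isTRUE(f$invariant))
                defaultInvariantBlocklist() else defaultInvariantBlocklist()[0, ],
            memory_only = isTRUE(f$memory_only),
            min_umi = f$min_umi %||% 0,
            max_chains_per_locus = f$max_chains_per_locus %||% Inf)
        t <- applyFilters(table, conf)
        n_out(t, nrow(chainRecords(t)))
    })

    summary <- with_stage("sharing", log_env, nrow(chainRecords(table)), {
        s <- suppressWarnings(classifyJunctions(table))
        writeTable(s, file.path(cfg$outdir, "classification.tsv"))
        sm <- sharingMatrix(s)
        writeTable(sm$long, file.path(cfg$outdir, "sharing_matrix.tsv"))
        n_out(s, nrow(junctionSummary(s)))
    })

    if (!"clones" %in% skip) {
        out$clones <- with_stage("clones", log_env, nrow(chainRecords(table)), {
            gr <- buildCloneGraph(table)
            cl <- callClones(gr)
            exportGraph(gr, file.path(cfg$outdir, "clone_graph.tsv"), "edge_tsv")
            flat <- cl[, c("clone_id", "topology_label", "n_tra", "n_trb",
                           "n_chains", "n_cells")]
            flat$chains <- vapply(cl$member_chains, paste, "", collapse = ",")
            writeTable(flat, file.path(cfg$outdir, "clones.tsv"))
            n_out(cl, nrow(cl))
        })
    }

    if (!"diversity" %in% skip) {
        out$diversity <- with_stage("diversity", log_env, NA_integer_, {
            ds <- cfg$downsample
            j <- junctionSummary(summary)
            exp_j <- j[j$expanded, , drop = FALSE]
            grp_sizes <- table(unlist(lapply(seq_len(nrow(exp_j)), function(i)
                unique(unlist(exp_j$groups[i])))))
            target <- min(ds$target_size, grp_sizes)
            spec <- downsampleSpec(ds$unit, target, ds$n_iter,
                                   seed = stage_seed(cfg, 101L))
            r <- downsampledGroupSummary(table, summary, spec,
                                         statistic = ds$statistic)
            res <- data.frame(group = names(r$medians), statistic = ds$statistic,
                              median = unname(r$medians),
                              target_size = target, n_iter = ds$n_iter)
            writeTable(res, file.path(cfg$outdir, "downsampled_medians.tsv"))
            n_out(r, nrow(res))
        })
    }

    if (!"lengths" %in% skip) {
        out$lengths <- with_stage("lengths", log_env, NA_integer_, {
            ls <- suppressWarnings(junctionLengthStats(summary))
            writeTable(ls$strata, file.path(cfg$outdir, "junction_lengths.tsv"))
            if (!is.null(ls$tests))
                writeTable(ls$tests, file.path(cfg$outdir, "junction_length_tests.tsv"))
            n_out(ls, nrow(ls$strata))
        })
    }

    if (!"pairing" %in% skip) {
        out$pairing <- with_stage("pairing", log_env, NA_integer_, {
            pe <- pairingEnrichment(table, summary, "TRA")
            rev <- tryCatch(pairingEnrichment(table, summary, "TRB"),
                            error = function(e) NULL)
            res <- data.frame(direction = c("per_TRA", "per_TRB_control"),
                              fraction_multi_public =
                                  c(pe$fraction_multi["public"],
                                    rev$fraction_multi["public"] %||% NA),
                              fraction_multi_private =
                                  c(pe$fraction_multi["private"],
                                    rev$fraction_multi["private"] %||% NA),
                              fisher_p = c(pe$p, rev$p %||% NA))
            writeTable(res, file.path(cfg$outdir, "pairing.tsv"))
            n_out(list(forward = pe, reverse = rev), nrow(res))
        })
    }

    if (!"levnull" %in% skip) {
        out$levnull <- with_stage("levnull", log_env, NA_integer_, {
            lv <- cfg$levnull
            obs <- sharedTraTrbDistances(table, summary, scope = lv$scope)
            set_size <- lv$set_size %||%
                length(unique(c(distancePairs(obs)$trb_a,
                                distancePairs(obs)$trb_b)))
            nulls <- nullDistanceSets(table, summary, setSize = set_size,
                                      nSets = lv$n_sets,
                                      seed = stage_seed(cfg, 202L))
            ks <- ksMedianP(obs, nulls)
            writeTable(distancePairs(obs),
                       file.path(cfg$outdir, "levnull_pairs.tsv"))
            writeTable(data.frame(set_index = seq_along(ks$p_values),
                                  p = ks$p_values, D = ks$D),
                       file.path(cfg$outdir, "levnull_sets.tsv"))
            writeTable(data.frame(median_p = ks$median_p,
                                  direction = ks$direction,
                                  n_sets = lv$n_sets, set_size = set_size),
                       file.path(cfg$outdir, "levnull_summary.tsv"))
            n_out(ks, length(ks$p_values))
        })
    }

    if (!"pgen" %in% skip) {
        out$pgen <- with_stage("pgen", log_env, NA_integer_, {
            pg <- cfg$pgen
            j <- junctionSummary(summary)
            j <- j[j$expanded, , drop = FALSE]
            if (identical(pg$source, "import")) {
                imp <- importPgen(pg$import_file, summary)
                pdf <- imp[imp$matched & imp$expanded, , drop = FALSE]
            } else {
                rec <- chainRecords(table)
                nt <- rec$junction_nt[match(paste(j$locus, j$junction_aa),
                                            paste(rec$locus, rec$junction_aa))]
                keep <- nzchar(nt)
                models <- list(TRA = defaultRecombinationModel("TRA"),
                               TRB = defaultRecombinationModel("TRB"))
                vals <- vapply(which(keep), function(i)
                    pgenNt(models[[j$locus[i]]], nt[i])$pgen, 0)
                pdf <- j[keep, , drop = FALSE]
                pdf$pgen <- vals
                pdf$log10_pgen <- ifelse(vals > 0, log10(vals), NA_real_)
            }
            cp <- comparePgen(pdf)
            writeTable(cp$strata, file.path(cfg$outdir, "pgen_strata.tsv"))
            if (!is.null(cp$tests))
                writeTable(cp$tests, file.path(cfg$outdir, "pgen_tests.tsv"))
            n_out(cp, nrow(pdf))
        })
    }

    writeTable(log_env$log, file.path(cfg$outdir, "run_log.tsv"))
    invisible(out)
}

#' Summarize analysis outputs in one human-readable file
#'
#' Reads the TSVs written by \code{\link{cmdAnalyze}} and writes
#' \code{summary.txt} with the headline statistics; analyses whose outputs
#' are absent are listed as such (warning, not an error).
#'
#' @param config list or YAML path with \code{outdir}.
#' @return invisible path of the summary file.
#' @export
cmdReport <- function(config) {
    cfg <- load_run_config(config)
    files <- c(classification = "classification.tsv",
               clones = "clones.tsv",
               downsampling = "downsampled_medians.tsv",
               lengths = "junction_lengths.tsv",
               pairing = "pairing.tsv",
               levnull = "levnull_summary.tsv",
               pgen = "pgen_strata.tsv")
    lines <- c("tcrclone analysis summary", "=========================")
    for (nm in names(files)) {
        path <- file.path(cfg$outdir, files[nm])
        lines <- c(lines, "", paste0("[", nm, "]"))
        if (!file.exists(path)) {
            warning(sprintf("output absent: %s", files[nm]))
            lines <- c(lines, "  (absent)")
            next
        }
        df <- utils::read.delim(path, stringsAsFactors = FALSE)
        if (nm == "classification") {
            lines <- c(lines, sprintf(
                "  %d unique junctions: %d public / %d private; %d expanded",
                nrow(df), sum(df$publicness == "public"),
                sum(df$publicness == "private"), sum(df$expanded)))
        } else if (nm == "clones") {
            top <- sort(table(df$topology_label), decreasing = TRUE)
            lines <- c(lines, sprintf("  %d clones; top topologies: %s",
                                      nrow(df),
                                      paste(sprintf("%s (n=%d)", names(top)[seq_len(min(3, length(top)))],
                                                    top[seq_len(min(3, length(top)))]),
                                            collapse = ", ")))
        } else {
            lines <- c(lines, paste0("  ", utils::capture.output(print(df, row.names = FALSE))))
        }
    }
    path <- file.path(cfg$outdir, "summary.txt")
    writeLines(lines, path)
    invisible(path)
}
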