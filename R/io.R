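## Readers and writers for rearrangement tables and reference junction sets.
## The AIRR Rearrangement TSV dialect is the native format; nonstandard TSVs
## are read through an explicit column map so misreads are loud, not silent.

AIRR_COLUMNS <- c(cell_id = "cell_id", donor_id = "donor_id",
                  disease_group = "disease_group", locus = "locus",
                  v_call = "v_call", j_call = "j_call",
                  junction_nt = "junction", junction_aa = "junction_aa",
                  phenotype = "phenotype", umi_count = "duplicate_count")

#' Read a single-cell rearrangement table
#'
#' Reads an AIRR Rearrangement TSV (columns cell_id, locus, v_call, j_call,
#' junction, junction_aa, plus extension columns donor_id, disease_group,
#' phenotype, duplicate_count) or a generic TSV through an explicit column
#' map. Rows with an empty junction_aa are dropped and counted in the table's
#' provenance; duplicate chain observations within a cell are collapsed.
#'
#' @param path path to a tab-separated file.
#' @param dialect "airr" or "generic_tsv".
#' @param column_map named character vector mapping canonical names
#'   (cell_id, donor_id, disease_group, locus, junction_aa, and optionally
#'   v_call, j_call, junction_nt, phenotype, umi_count) to file columns.
#'   Required for generic_tsv; entries override the AIRR defaults otherwise.
#' @return A \linkS4class{RepertoireTable}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' df <- data.frame(cell_id = c("c1", "c1"), donor_id = "d1",
#'                  disease_group = "HC", locus = c("TRA", "TRB"),
#'                  junction_aa = c("CAVSGGYQKVTF", "CASSLGGEQYF"))
#' write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
#' readRearrangements(tsv)
#' @export
readRearrangements <- function(path, dialect = c("airr", "generic_tsv"),
                               column_map = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stopConfig("input file does not exist: %s", path)
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE)
    map <- if (dialect == "airr") AIRR_COLUMNS else character()
    if (!is.null(column_map)) map[names(column_map)] <- column_map
    if (dialect == "generic_tsv" && is.null(column_map))
        stopConfig("dialect 'generic_tsv' requires a column_map")

    required <- c("cell_id", "donor_id", "disease_group", "locus", "junction_aa")
    for (canon in required) {
        col <- map[canon]
        if (is.na(col) || !col %in% names(raw))
            stopConfig("required column '%s' (mapped from '%s') not found in %s",
                       if (is.na(col)) canon else col, canon, path)
    }
    records <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                          lapply(map[required], function(col) raw[[col]]))
    names(records) <- required
    for (canon in c("v_call", "j_call", "junction_nt", "phenotype", "umi_count")) {
        col <- map[canon]
        if (!is.na(col) && col %in% names(raw)) records[[canon]] <- raw[[col]]
    }
    RepertoireTable(records,
                    provenance = list(source = path, dialect = dialect,
                                      n_rows_read = nrow(raw)))
}

#' Read a reference junction set
#'
#' Reads either a VDJdb-style export (columns gene / cdr3 / v.segm / j.segm /
#' species / antigen.species / mhc.class) or a plain TSV with locus and
#' junction_aa columns. Entries are deduplicated on (locus, junction_aa).
#'
#' @param path path to a tab-separated file.
#' @param dialect "vdjdb" or "plain_tsv".
#' @return A \linkS4class{ReferenceJunctionSet}.
#' @export
readReference <- function(path, dialect = c("vdjdb", "plain_tsv")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stopConfig("reference file does not exist: %s", path)
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE)
    if (dialect == "vdjdb") {
        pick <- function(...) {
            for (nm in c(...)) if (nm %in% names(raw)) return(raw[[nm]])
            rep("", nrow(raw))
        }
        entries <- data.frame(
            locus = pick("gene", "locus"),
            junction_aa = pick("cdr3", "CDR3", "junction_aa"),
            v_call = pick("v.segm", "V", "v_call"),
            j_call = pick("j.segm", "J", "j_call"),
            antigen_species = pick("antigen.species", "species"),
            mhc_class = pick("mhc.class"),
            stringsAsFactors = FALSE)
    } else {
        if (!all(c("locus", "junction_aa") %in% names(raw)))
            stopConfig("plain_tsv reference needs 'locus' and 'junction_aa' columns")
        entries <- raw
    }
    ref <- ReferenceJunctionSet(entries)
    message(sprintf("readReference: %d unique entries (%s)",
                    nrow(ref@entries),
                    paste(sprintf("%s=%d", names(table(ref@entries$locus)),
                                  table(ref@entries$locus)), collapse = ", ")))
    ref
}

write_tsv <- function(df, path) {
    ok <- tryCatch({
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop(errorCondition(
        sprintf("cannot write %s: %s", path, conditionMessage(ok)),
        class = c("tcrclone_io_error", "tcrclone_error")))
    invisible(path)
}

#' @describeIn writeTable write a repertoire table as an AIRR TSV; reading it
#'   back with \code{readRearrangements} reproduces the record multiset.
#' @export
setMethod("writeTable", "RepertoireTable", function(x, path, ...) {
    rec <- chainRecords(x)
    out <- rec
    names(out) <- AIRR_COLUMNS[names(rec)]
    out$duplicate_count[is.na(out$duplicate_count)] <- ""
    write_tsv(out, path)
})

#' @describeIn writeTable write any data.frame result as TSV (stable column
#'   order; an empty frame yields a header-only file).
#' @export
setMethod("writeTable", "data.frame", function(x, path, ...) write_tsv(x, path))

#' @describeIn writeTable write the junction classification table
#'   (locus, junction_aa, n_cells, n_donors, donors, expanded, publicness).
#' @export
setMethod("writeTable", "SharingSummary", function(x, path, ...) {
    j <- junctionSummary(x)
    j$donors <- vapply(j$donors, paste, "", collapse = ",")
    j$groups <- vapply(j$groups, paste, "", collapse = ",")
    write_tsv(j, path)
})
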