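## Condition system: configuration errors (bad arguments / settings, CLI exit 2)
## vs data errors (inputs that cannot support the requested analysis, CLI exit 3).

stopConfig <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("tcrclone_config_error", "tcrclone_error")))
}

stopData <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("tcrclone_data_error", "tcrclone_error")))
}

warnValidation <- function(fmt, ...) {
    warning(warningCondition(sprintf(fmt, ...),
                             class = "tcrclone_validation_warning"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## amino-acid alphabet used for junction validation (20 standard residues)
AA_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

VALID_LOCI <- c("TRA", "TRB")

#' Translate nucleotide junctions with the standard genetic code
#'
#' Thin wrapper over Biostrings; sequences whose length is not a multiple of
#' three, or that contain an in-frame stop, return NA.
#'
#' @param nt character vector of nucleotide sequences.
#' @return character vector of amino-acid translations (NA where untranslatable).
#' @keywords internal
translateNt <- function(nt) {
    out <- rep(NA_character_, length(nt))
    ok <- !is.na(nt) & nzchar(nt) & nchar(nt) %% 3L == 0L &
        grepl("^[ACGT]+$", nt)
    if (any(ok)) {
        aa <- as.character(suppressWarnings(
            Biostrings::translate(Biostrings::DNAStringSet(nt[ok]))))
        aa[grepl("\\*", aa)] <- NA_character_
        out[ok] <- aa
    }
    out
}
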