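## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Canonical string key for a variant identity; exact equality of all four
## fields defines sharing between samples.
variantKeyStrings <- function(df) {
    if (!nrow(df)) return(character())
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

.assertSamePatient <- function(a, b) {
    if (!identical(patientId(a), patientId(b)))
        stop("samples belong to different patients: ",
             patientId(a), " vs ", patientId(b), call. = FALSE)
}

## Strict TSV reader: all columns as character first, typed by caller.
.readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "")
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

.asNum <- function(x, what, path) {
    suppressWarnings(y <- as.numeric(x))
    bad <- which(is.na(y) & !is.na(x) & x != "NA" & x != "")
    if (length(bad))
        stop(sprintf("malformed %s at data row %d of %s: '%s'",
                     what, bad[1], path, x[bad[1]]), call. = FALSE)
    y[x %in% c("", "NA")] <- NA_real_
    y
}

.requireCols <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop("missing column(s) in ", path, ": ",
             paste(miss, collapse = ", "), call. = FALSE)
    invisible(df)
}
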