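#' Write a table as TSV with an optional '#'-prefixed metadata header
#'
#' @param df data.frame.
#' @param path output file.
#' @param meta named list serialized as `#key: value` header lines.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path, meta = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(meta)) {
        for (k in names(meta))
            writeLines(sprintf("#%s: %s", k,
                               paste(format(meta[[k]], trim = TRUE),
                                     collapse = ",")), con)
    }
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' Metadata header lines (leading `#`) are returned in the `meta`
#' attribute as a named character list.
#'
#' @param path input file.
#' @return data.frame with attribute `meta`.
#' @export
read_tsv <- function(path) {
    lines <- readLines(path)
    hdr <- grepl("^#", lines)
    n_hdr <- if (any(!hdr)) which(!hdr)[1L] - 1L else length(lines)
    meta <- list()
    if (n_hdr > 0) {
        kv <- sub("^#", "", lines[seq_len(n_hdr)])
        for (line in kv) {
            sep <- regexpr(": ", line, fixed = TRUE)
            if (sep > 0)
                meta[[substr(line, 1L, sep - 1L)]] <-
                    substr(line, sep + 2L, nchar(line))
        }
    }
    df <- read.delim(path, skip = n_hdr, stringsAsFactors = FALSE,
                     check.names = FALSE)
    attr(df, "meta") <- meta
    df
}

#' Write reads as a 4-line-record FASTQ file
#'
#' @param reads character vector of sequences.
#' @param path output file.
#' @param ids read identifiers (without the leading `@`).
#' @param qual_char constant Phred+33 quality character.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path, ids = sprintf("read%d", seq_along(reads)),
                        qual_char = "I") {
    stopifnot(length(ids) == length(reads))
    rec <- character(4L * length(reads))
    rec[seq(1L, length(rec), 4L)] <- paste0("@", ids)
    rec[seq(2L, length(rec), 4L)] <- reads
    rec[seq(3L, length(rec), 4L)] <- "+"
    rec[seq(4L, length(rec), 4L)] <- strrep(qual_char, nchar(reads))
    writeLines(rec, path)
    invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' Validates the 4-line record structure and names the offending record on
#' failure.
#'
#' @param path input FASTQ.
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
        stop(sprintf("truncated FASTQ record at record %d in %s",
                     length(lines) %/% 4L + 1L, path))
    ids <- lines[seq(1L, length(lines), 4L)]
    seqs <- lines[seq(2L, length(lines), 4L)]
    plus <- lines[seq(3L, length(lines), 4L)]
    qual <- lines[seq(4L, length(lines), 4L)]
    bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual))
    if (length(bad))
        stop(sprintf("malformed FASTQ record %d in %s", bad[1L], path))
    data.frame(id = sub("^@", "", ids), seq = seqs, qual = qual,
               stringsAsFactors = FALSE)
}
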