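## Reading, validating and writing long-format lexical wordlists and
## pipeline result tables.

#' Build a Wordlist from a data.frame
#'
#' @param df data.frame with columns \code{language_id}, \code{concept_id},
#'   \code{form}, and optionally a \code{segments} list column (filled by
#'   \code{\link{segmentIPA}} on \code{form} when absent).
#' @return a \linkS4class{Wordlist}.
#' @export
asWordlist <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("language_id", "concept_id", "form")
  if (!all(need %in% names(df)))
    stop("df must have columns: ", paste(need, collapse = ", "))
  df$language_id <- as.character(df$language_id)
  df$concept_id <- as.character(df$concept_id)
  df$form <- stringi::stri_trans_nfc(as.character(df$form))
  if (is.null(df$segments)) df$segments <- lapply(df$form, segmentIPA)
  out <- df[, c("language_id", "concept_id", "form", "segments")]
  rownames(out) <- NULL
  new("Wordlist", forms = out)
}

#' Read a long-format TSV wordlist
#'
#' One form per row, UTF-8, header row required; NFC normalisation is
#' applied on read. The default column mapping follows CLDF conventions.
#' When the mapped segments column is present its space-delimited content
#' is used as the segmentation; otherwise the form column is tokenized
#' with \code{\link{segmentIPA}}. Rows whose form/segments cell is empty
#' are skipped with a warning.
#'
#' @param path TSV file path.
#' @param column_map named character vector mapping the roles
#'   \code{language_id}, \code{concept_id}, \code{form} (and optionally
#'   \code{segments}) to column names in the file.
#' @return a \linkS4class{Wordlist}.
#' @export
readWordlist <- function(path,
                         column_map = c(language_id = "Language_ID",
                                        concept_id = "Parameter_ID",
                                        form = "Form",
                                        segments = "Segments")) {
  stopifnot(file.exists(path))
  raw <- read.delim(path, sep = "\t", quote = "", fileEncoding = "UTF-8",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  for (role in c("language_id", "concept_id", "form")) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(raw))
      stop("configuration error: mapped column '", col %||% role,
           "' (role ", role, ") not found in ", path)
  }
  df <- data.frame(language_id = raw[[column_map[["language_id"]]]],
                   concept_id = raw[[column_map[["concept_id"]]]],
                   form = stringi::stri_trans_nfc(
                     raw[[column_map[["form"]]]]),
                   stringsAsFactors = FALSE)
  segcol <- column_map["segments"]
  has_seg <- !is.na(segcol) && segcol %in% names(raw)
  ipa <- if (has_seg) stringi::stri_trans_nfc(raw[[segcol]]) else df$form
  keep <- !is.na(ipa) & nzchar(trimws(ipa))
  if (any(!keep))
    warning(sum(!keep), " row(s) with empty IPA skipped")
  df <- df[keep, , drop = FALSE]
  ipa <- ipa[keep]
  df$segments <- lapply(ipa, segmentIPA)
  asWordlist(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline result table as TSV
#'
#' UTF-8, tab-separated, header row, \code{NA} cells rendered as
#' \code{"NA"}, deterministic row order (sorted by the key columns).
#' Numeric values keep full precision (at least 6 significant digits).
#'
#' @param table data.frame.
#' @param path output file path.
#' @param key character, columns to sort by; defaults to all non-numeric
#'   columns in order.
#' @return invisibly, the sorted table.
#' @export
writeTable <- function(table, path, key = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(key))
    key <- names(table)[!vapply(table, is.numeric, logical(1))]
  key <- intersect(key, names(table))
  if (length(key) > 0L && nrow(table) > 1L)
    table <- table[do.call(order, table[key]), , drop = FALSE]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(table)
}

## --- Wordlist accessors -------------------------------------------------

#' @rdname accessors
#' @export
setMethod("forms", "Wordlist", function(x) x@forms)

#' @rdname accessors
#' @export
setMethod("languages", "Wordlist",
          function(x) sort(unique(x@forms$language_id)))

#' @rdname accessors
#' @export
setMethod("concepts", "Wordlist",
          function(x) sort(unique(x@forms$concept_id)))

#' @rdname accessors
#' @export
setMethod("nForms", "Wordlist", function(x) nrow(x@forms))

setMethod("show", "Wordlist", function(object) {
  f <- object@forms
  cat("Wordlist:", nrow(f), "forms,",
      length(unique(f$language_id)), "languages,",
      length(unique(f$concept_id)), "concepts\n")
  if (nrow(f) > 0L) {
    ex <- head(f, 3L)
    for (i in seq_len(nrow(ex)))
      cat(" ", ex$language_id[i], ex$concept_id[i],
          paste(ex$segments[[i]], collapse = " "), "\n")
  }
})
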