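#' Read a VA dataset from CSV
#'
#' Expected layout (wide): `record_id,module,site,gold_cause` followed by one
#' column per symptom in dictionary order. Symptom cells are `1` (endorsed),
#' `0` (not endorsed) or empty (missing / don't know).
#'
#' @param path CSV file path.
#' @param cause_list a [cause_list()] against which gold causes are checked.
#' @param symptom_dict a [symptom_dictionary()]; the file's symptom columns
#'   must match its ids in order.
#' @return A [va_dataset()].
#' @export
read_va_dataset <- function(path, cause_list, symptom_dict) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  required <- c("record_id", "module", "site", "gold_cause")
  if (!all(required %in% names(raw))) {
    stop("dataset CSV must start with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  sym_cols <- setdiff(names(raw), required)
  if (!identical(sym_cols, symptom_dict$symptom_id)) {
    stop("symptom columns do not match the symptom dictionary", call. = FALSE)
  }
  sym <- as.matrix(raw[, sym_cols, drop = FALSE])
  sym[sym == ""] <- NA_character_
  bad <- !is.na(sym) & !(sym %in% c("0", "1"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid symptom value '%s' at row %d, column '%s'",
                 sym[idx[1L], idx[2L]], idx[1L], sym_cols[idx[2L]]),
         call. = FALSE)
  }
  storage.mode(sym) <- "integer"
  va_dataset(raw[, required], sym, cause_list, symptom_dict)
}

#' Write a VA dataset to CSV
#'
#' Inverse of [read_va_dataset()]; missing symptom values are written as
#' empty cells.
#'
#' @param dataset a [va_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_va_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "va_dataset"))
  sym <- dataset$symptoms
  sym_chr <- matrix(as.character(sym), nrow = nrow(sym),
                    dimnames = dimnames(sym))
  sym_chr[is.na(sym_chr)] <- ""
  out <- cbind(dataset$records, as.data.frame(sym_chr, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a probbase from CSV
#'
#' Layout: first column `cause`, remaining columns one per symptom; cells are
#' probabilities in \[0, 1\]. Row and column order must match the supplied
#' cause list and dictionary.
#'
#' @param path CSV file path.
#' @param cause_list a [cause_list()].
#' @param symptom_dict a [symptom_dictionary()].
#' @param provenance `"fixed"` or `"trained"` tag for the result.
#' @return A [probbase()].
#' @export
read_probbase <- function(path, cause_list, symptom_dict,
                          provenance = "fixed") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(raw)[1L] != "cause") {
    stop("probbase CSV must start with a 'cause' column", call. = FALSE)
  }
  if (!identical(raw$cause, as.character(cause_list))) {
    stop("probbase causes do not match the cause list", call. = FALSE)
  }
  if (!identical(names(raw)[-1L], symptom_dict$symptom_id)) {
    stop("probbase symptom columns do not match the dictionary",
         call. = FALSE)
  }
  P <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(P) <- "double"
  out <- which(!is.finite(P) | P < 0 | P > 1, arr.ind = TRUE)
  if (nrow(out)) {
    stop(sprintf("probbase entry out of [0,1] at (row %d, col %d)",
                 out[1L, 1L], out[1L, 2L]), call. = FALSE)
  }
  probbase(P, cause_list, symptom_dict, provenance = provenance)
}

#' Write a probbase to CSV
#'
#' Probabilities are written with 15 significant digits so a write/read
#' round-trip preserves entries to better than 1e-12.
#'
#' @param pb a [probbase()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_probbase <- function(pb, path) {
  stopifnot(inherits(pb, "probbase"))
  cells <- format(pb$P, digits = 15, scientific = FALSE, trim = TRUE)
  out <- data.frame(cause = rownames(pb$P),
                    matrix(cells, nrow = nrow(pb$P),
                           dimnames = list(NULL, colnames(pb$P))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a symptom dictionary from CSV (`symptom_id,hce_flag`)
#' @param path CSV file path; `hce_flag` is 0/1 or TRUE/FALSE.
#' @return A [symptom_dictionary()].
#' @export
read_symptom_dictionary <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("symptom_id", "hce_flag") %in% names(raw))) {
    stop("dictionary CSV needs columns symptom_id, hce_flag", call. = FALSE)
  }
  symptom_dictionary(raw$symptom_id, as.logical(as.integer(raw$hce_flag)))
}

#' Write a symptom dictionary to CSV
#' @param symptom_dict a [symptom_dictionary()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_symptom_dictionary <- function(symptom_dict, path) {
  out <- data.frame(symptom_id = symptom_dict$symptom_id,
                    hce_flag = as.integer(symptom_dict$hce_flag))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cause list from CSV (single `cause` column)
#' @param path CSV file path.
#' @param module age module for the resulting [cause_list()].
#' @return A [cause_list()].
#' @export
read_cause_list <- function(path, module = "adult") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("cause" %in% names(raw))) {
    stop("cause list CSV needs a 'cause' column", call. = FALSE)
  }
  cause_list(raw$cause, module)
}

#' Write a cause list to CSV
#' @param cl a [cause_list()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cause_list <- function(cl, path) {
  utils::write.csv(data.frame(cause = as.character(cl)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
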