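#' Construct a cause list
#'
#' A cause list is the ordered set of cause-of-death identifiers for one age
#' module. The order is authoritative: every matrix indexed by cause (probbase
#' rows, misclassification matrices, CSMF vectors) follows it, and ties in
#' classification are broken towards the lowest index. The gold-standard
#' validation databases this package emulates use 34 adult, 21 child and 6
#' neonate causes (stillbirth counted among the neonate causes).
#'
#' @param causes character vector of unique, non-empty cause identifiers.
#' @param module one of `"adult"`, `"child"`, `"neonate"`.
#' @return An object of class `cause_list`: the character vector of causes
#'   with attributes `module`.
#' @examples
#' cl <- cause_list(c("stroke", "sepsis", "road_traffic"), "adult")
#' length(cl)
#' @export
cause_list <- function(causes, module = c("adult", "child", "neonate")) {
  module <- match.arg(module)
  causes <- as.character(causes)
  if (length(causes) < 2L) {
    stop("a cause list needs at least 2 causes", call. = FALSE)
  }
  if (anyDuplicated(causes)) {
    stop("cause identifiers must be unique", call. = FALSE)
  }
  if (any(!nzchar(causes))) {
    stop("cause identifiers must be non-empty", call. = FALSE)
  }
  structure(causes, module = module, class = "cause_list")
}

#' @export
print.cause_list <- function(x, ...) {
  cat(sprintf("<cause_list> %s module, %d causes\n",
              attr(x, "module"), length(x)))
  cat(" ", paste(utils::head(unclass(x), 8L), collapse = ", "))
  if (length(x) > 8L) cat(", ...")
  cat("\n")
  invisible(x)
}

#' Construct a symptom dictionary
#'
#' The symptom dictionary fixes the ordered set of symptom items and flags
#' those derived from health-care-experience (HCE) questions, i.e. prior
#' contact with the health system. Validation studies routinely run with and
#' without HCE items to mimic community deaths; see [apply_hce_mask()].
#'
#' @param symptom_id character vector of unique symptom identifiers.
#' @param hce_flag logical vector, `TRUE` for HCE-derived items. Recycled if
#'   scalar.
#' @return A `symptom_dictionary`: a data frame with columns `symptom_id` and
#'   `hce_flag`.
#' @export
symptom_dictionary <- function(symptom_id, hce_flag = FALSE) {
  symptom_id <- as.character(symptom_id)
  if (length(symptom_id) == 0L) {
    stop("symptom dictionary must contain at least one symptom", call. = FALSE)
  }
  if (anyDuplicated(symptom_id)) {
    stop("symptom identifiers must be unique", call. = FALSE)
  }
  hce_flag <- rep_len(as.logical(hce_flag), length(symptom_id))
  if (anyNA(hce_flag)) stop("hce_flag must be TRUE/FALSE", call. = FALSE)
  if (all(hce_flag)) {
    stop("at least one symptom must be non-HCE", call. = FALSE)
  }
  structure(
    data.frame(symptom_id = symptom_id, hce_flag = hce_flag,
               stringsAsFactors = FALSE),
    class = c("symptom_dictionary", "data.frame")
  )
}

#' Construct a verbal-autopsy dataset
#'
#' One row per death: a record id, age module, study site, the gold-standard
#' cause, and a ternary symptom vector (endorsed / not endorsed / missing).
#' Symptom responses are stored as an integer matrix with values 1 (yes),
#' 0 (no) and `NA` (missing / don't know).
#'
#' @param records data frame with columns `record_id`, `module`, `site`,
#'   `gold_cause`.
#' @param symptoms integer matrix, rows aligned with `records`, columns
#'   aligned with `symptom_dict`; entries in `{0, 1, NA}`.
#' @param cause_list a [cause_list()]; every `gold_cause` must belong to it.
#' @param symptom_dict a [symptom_dictionary()].
#' @return An object of class `va_dataset` with fields `records`, `symptoms`,
#'   `cause_list`, `symptom_dict`.
#' @export
va_dataset <- function(records, symptoms, cause_list, symptom_dict) {
  stopifnot(inherits(cause_list, "cause_list"),
            inherits(symptom_dict, "symptom_dictionary"))
  required <- c("record_id", "module", "site", "gold_cause")
  if (!all(required %in% names(records))) {
    stop("records must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  records$record_id <- as.character(records$record_id)
  records$gold_cause <- as.character(records$gold_cause)
  if (anyDuplicated(records$record_id)) {
    stop("record ids must be unique", call. = FALSE)
  }
  bad <- !(records$gold_cause %in% cause_list)
  if (any(bad)) {
    stop(sprintf("unknown gold cause '%s' in record '%s'",
                 records$gold_cause[which(bad)[1L]],
                 records$record_id[which(bad)[1L]]), call. = FALSE)
  }
  symptoms <- as.matrix(symptoms)
  storage.mode(symptoms) <- "integer"
  if (nrow(symptoms) != nrow(records)) {
    stop("symptom matrix rows must match records", call. = FALSE)
  }
  if (ncol(symptoms) != nrow(symptom_dict)) {
    stop("symptom matrix columns must match the symptom dictionary",
         call. = FALSE)
  }
  vals <- symptoms[!is.na(symptoms)]
  if (length(vals) && !all(vals %in% c(0L, 1L))) {
    stop("symptom values must be 0, 1 or NA", call. = FALSE)
  }
  colnames(symptoms) <- symptom_dict$symptom_id
  rownames(symptoms) <- records$record_id
  structure(
    list(records = records, symptoms = symptoms,
         cause_list = cause_list, symptom_dict = symptom_dict),
    class = "va_dataset"
  )
}

#' @export
print.va_dataset <- function(x, ...) {
  cat(sprintf(
    "<va_dataset> %d records, %d causes (%s), %d symptoms, %d site(s)\n",
    nrow(x$records), length(x$cause_list), attr(x$cause_list, "module"),
    nrow(x$symptom_dict), length(unique(x$records$site))))
  invisible(x)
}

#' Number of records in a VA dataset
#' @param dataset a [va_dataset()].
#' @return integer count.
#' @export
n_records <- function(dataset) {
  stopifnot(inherits(dataset, "va_dataset"))
  nrow(dataset$records)
}

#' Construct a probbase
#'
#' A probbase is the matrix of conditional endorsement probabilities
#' P\[cause, symptom\]: the probability that a symptom is reported given the
#' cause of death. Rows follow the cause list, columns the symptom
#' dictionary. A probbase can be expert-derived and fixed, or estimated
#' empirically from training data ([estimate_probbase()]).
#'
#' @param P numeric matrix, entries in \[0, 1\], dimension
#'   `length(cause_list) x nrow(symptom_dict)`.
#' @param cause_list a [cause_list()].
#' @param symptom_dict a [symptom_dictionary()].
#' @param provenance `"fixed"` or `"trained"`.
#' @return An object of class `probbase`.
#' @export
probbase <- function(P, cause_list, symptom_dict,
                     provenance = c("fixed", "trained")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(cause_list, "cause_list"),
            inherits(symptom_dict, "symptom_dictionary"))
  P <- as.matrix(P)
  storage.mode(P) <- "double"
  if (nrow(P) != length(cause_list) || ncol(P) != nrow(symptom_dict)) {
    stop("probbase must be N causes x S symptoms", call. = FALSE)
  }
  if (any(!is.finite(P))) stop("probbase entries must be finite", call. = FALSE)
  if (any(P < 0 | P > 1)) {
    bad <- which(P < 0 | P > 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("probbase entry out of [0,1] at (row %d, col %d)",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  rownames(P) <- as.character(cause_list)
  colnames(P) <- symptom_dict$symptom_id
  structure(
    list(P = P, cause_list = cause_list, symptom_dict = symptom_dict,
         provenance = provenance),
    class = "probbase"
  )
}

#' @export
print.probbase <- function(x, ...) {
  cat(sprintf("<probbase> %d causes x %d symptoms (%s)\n",
              nrow(x$P), ncol(x$P), x$provenance))
  invisible(x)
}

#' Construct a prediction set
#'
#' Holds one predicted (top) cause per record, and optionally the full
#' posterior weight vector over causes.
#'
#' @param record_id character vector of record ids.
#' @param predicted_cause character vector, each a member of `cause_list`.
#' @param cause_list a [cause_list()].
#' @param posterior optional numeric matrix (records x causes); rows must be
#'   non-negative and sum to 1 within 1e-9.
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(record_id, predicted_cause, cause_list,
                           posterior = NULL) {
  stopifnot(inherits(cause_list, "cause_list"))
  record_id <- as.character(record_id)
  predicted_cause <- as.character(predicted_cause)
  if (length(record_id) != length(predicted_cause)) {
    stop("record_id and predicted_cause lengths differ", call. = FALSE)
  }
  if (any(!(predicted_cause %in% cause_list))) {
    stop("predicted causes must belong to the cause list", call. = FALSE)
  }
  if (!is.null(posterior)) {
    posterior <- as.matrix(posterior)
    if (nrow(posterior) != length(record_id) ||
        ncol(posterior) != length(cause_list)) {
      stop("posterior must be records x causes", call. = FALSE)
    }
    if (any(posterior < 0) ||
        any(abs(rowSums(posterior) - 1) > 1e-9)) {
      stop("posterior rows must be non-negative and sum to 1", call. = FALSE)
    }
    colnames(posterior) <- as.character(cause_list)
  }
  structure(
    list(record_id = record_id, predicted_cause = predicted_cause,
         cause_list = cause_list, posterior = posterior),
    class = "prediction_set"
  )
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d records, %d causes%s\n",
              length(x$record_id), length(x$cause_list),
              if (is.null(x$posterior)) "" else ", with posteriors"))
  invisible(x)
}

#' Remove health-care-experience symptoms
#'
#' Drops all symptom columns flagged as HCE from a dataset or probbase, so
#' analyses can mimic deaths with no prior health-system contact. With
#' `include_hce = TRUE` the input is returned unchanged. Applying the mask
#' with the same dictionary to a dataset and its probbase keeps them aligned.
#'
#' @param x a [va_dataset()] or [probbase()].
#' @param include_hce if `TRUE`, keep all symptoms (identity).
#' @return The same class as `x`, with HCE columns removed and the symptom
#'   dictionary updated.
#' @export
apply_hce_mask <- function(x, include_hce = TRUE) {
  UseMethod("apply_hce_mask")
}

hce_keep <- function(symptom_dict) {
  keep <- !symptom_dict$hce_flag
  if (!any(keep)) {
    stop("HCE mask would remove all symptoms", call. = FALSE)
  }
  keep
}

#' @export
apply_hce_mask.va_dataset <- function(x, include_hce = TRUE) {
  if (include_hce) return(x)
  keep <- hce_keep(x$symptom_dict)
  va_dataset(x$records, x$symptoms[, keep, drop = FALSE],
             x$cause_list,
             symptom_dictionary(x$symptom_dict$symptom_id[keep],
                                x$symptom_dict$hce_flag[keep]))
}

#' @export
apply_hce_mask.probbase <- function(x, include_hce = TRUE) {
  if (include_hce) return(x)
  keep <- hce_keep(x$symptom_dict)
  probbase(x$P[, keep, drop = FALSE], x$cause_list,
           symptom_dictionary(x$symptom_dict$symptom_id[keep],
                              x$symptom_dict$hce_flag[keep]),
           provenance = x$provenance)
}
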