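# The individual-record APC dataset container and its text serialization.

#' Construct an APC dataset
#'
#' A thin S3 container: a data.frame of individual records with continuous
#' `age`, `period`, `cohort` (= period - age), their category indices under a
#' scheme, zero or more mediator columns, an optional binary confounder, and
#' an `outcome` column, plus attributes carrying the scheme and provenance.
#'
#' @param records data.frame with at least `age`, `period` and `outcome`
#'   columns. `cohort` and the category indices are derived if absent.
#' @param scheme an [apc_scheme()] used (or to be used) to categorize.
#' @param mediators character vector naming the mediator columns.
#' @param mediator_kinds named character vector, `"continuous"` or `"binary"`
#'   per mediator; inferred from the data when omitted.
#' @param confounder name of the binary confounder column, or `NULL`.
#' @param variant which generating/estimating family the data correspond to:
#'   `"probit"`, `"logistic"` or `"linear"`; `NA` for external data of unknown
#'   provenance.
#' @param provenance free-form list describing how the data arose.
#' @return an object of class `apc_dataset` (a data.frame).
#' @export
apc_dataset <- function(records, scheme, mediators = character(),
                        mediator_kinds = NULL, confounder = NULL,
                        variant = NA_character_, provenance = list()) {
  stopifnot(is.data.frame(records), inherits(scheme, "apc_scheme"))
  need <- c("age", "period", "outcome")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records lack required columns: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"cohort" %in% names(records)) {
    records$cohort <- records$period - records$age
  }
  if (!all(c("a_idx", "p_idx", "c_idx") %in% names(records))) {
    idx <- apc_categorize(records$age, records$period, scheme)
    records$a_idx <- idx$a_idx
    records$p_idx <- idx$p_idx
    records$c_idx <- idx$c_idx
  }
  miss_m <- setdiff(mediators, names(records))
  if (length(miss_m)) {
    stop("mediator columns not found: ", paste(miss_m, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(confounder) && !confounder %in% names(records)) {
    stop("confounder column not found: ", confounder, call. = FALSE)
  }
  if (is.null(mediator_kinds)) {
    mediator_kinds <- vapply(mediators, function(m) {
      v <- records[[m]]
      if (all(v %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  }
  binary_cols <- c(
    names(mediator_kinds)[mediator_kinds == "binary"], confounder
  )
  for (bc in binary_cols) {
    if (!all(records[[bc]] %in% c(0, 1))) {
      stop("binary column '", bc, "' takes values outside {0, 1}",
        call. = FALSE
      )
    }
  }
  structure(records,
    class = c("apc_dataset", "data.frame"),
    scheme = scheme, mediators = mediators,
    mediator_kinds = mediator_kinds, confounder = confounder,
    variant = variant, provenance = provenance
  )
}

#' @export
print.apc_dataset <- function(x, ...) {
  scheme <- attr(x, "scheme")
  cat(sprintf(
    "APC dataset: %d records, %d/%d/%d age/period/cohort categories\n",
    nrow(x), scheme$n_age, scheme$n_period, scheme$n_cohort
  ))
  med <- attr(x, "mediators")
  cat(
    "  mediators:", if (length(med)) paste(med, collapse = ", ") else "(none)",
    "\n"
  )
  conf <- attr(x, "confounder")
  if (!is.null(conf)) cat("  confounder:", conf, "\n")
  if (!is.na(attr(x, "variant"))) cat("  variant:", attr(x, "variant"), "\n")
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Check the APC linear identity on every record
#'
#' Passes iff every record satisfies both the continuous identity
#' `cohort == period - age` and the category-index identity
#' `c_idx == p_idx - a_idx + n_age` (within floating-point tolerance for the
#' continuous part). Returns a report rather than erroring.
#'
#' @param dataset an [apc_dataset()].
#' @param tol tolerance for the continuous identity.
#' @return list with `pass` (logical) and `offending` (integer row indices).
#' @export
validate_identity <- function(dataset, tol = 1e-8) {
  stopifnot(inherits(dataset, "apc_dataset"))
  if (nrow(dataset) == 0L) {
    return(list(pass = TRUE, offending = integer()))
  }
  scheme <- attr(dataset, "scheme")
  bad_cont <- abs(dataset$cohort - (dataset$period - dataset$age)) > tol
  bad_idx <- dataset$c_idx != dataset$p_idx - dataset$a_idx + scheme$n_age
  off <- which(bad_cont | bad_idx)
  list(pass = length(off) == 0L, offending = off)
}

#' Remove mediator columns from a dataset
#'
#' Mirrors the mediator-removal sequence used in mis-specification studies:
#' the returned dataset is identical except that the named mediator columns
#' (and their kind records) are gone.
#'
#' @param dataset an [apc_dataset()].
#' @param names character vector of mediator names to drop (may be empty).
#' @return an `apc_dataset`.
#' @export
drop_mediators <- function(dataset, names) {
  stopifnot(inherits(dataset, "apc_dataset"))
  med <- attr(dataset, "mediators")
  unknown <- setdiff(names, med)
  if (length(unknown)) {
    stop("unknown mediator(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (!length(names)) {
    return(dataset)
  }
  keep_attrs <- attributes(dataset)
  out <- as.data.frame(dataset)[, setdiff(colnames(dataset), names),
    drop = FALSE
  ]
  kinds <- attr(dataset, "mediator_kinds")
  apc_dataset(out,
    scheme = keep_attrs$scheme,
    mediators = setdiff(med, names),
    mediator_kinds = kinds[setdiff(med, names)],
    confounder = keep_attrs$confounder,
    variant = keep_attrs$variant,
    provenance = c(keep_attrs$provenance, list(dropped_mediators = names))
  )
}

#' Write an APC dataset to delimited text
#'
#' Comma-separated values with a mandatory header row, preceded by `#`-prefixed
#' key-value comment lines carrying the scheme (bin edges), mediator names and
#' kinds, confounder and variant, so the file round-trips losslessly through
#' [read_apc_data()].
#'
#' @param dataset an [apc_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_apc_data <- function(dataset, path) {
  stopifnot(inherits(dataset, "apc_dataset"))
  scheme <- attr(dataset, "scheme")
  kinds <- attr(dataset, "mediator_kinds")
  hdr <- c(
    paste("# age_edges:", paste(scheme$age_edges, collapse = " ")),
    paste("# period_edges:", paste(scheme$period_edges, collapse = " ")),
    paste("# width:", scheme$width),
    paste("# mediators:", paste(attr(dataset, "mediators"), collapse = " ")),
    paste("# mediator_kinds:", paste(kinds, collapse = " ")),
    paste("# confounder:", attr(dataset, "confounder") %||% "none"),
    paste("# variant:", attr(dataset, "variant"))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(dataset), con, row.names = FALSE)
  invisible(path)
}

#' Read an APC dataset written by [write_apc_data()]
#'
#' Also accepts plain CSV files without the comment header: then a `scheme`
#' must be supplied and mediator/confounder columns are named explicitly.
#'
#' @param path input file path.
#' @param scheme optional [apc_scheme()] overriding the header.
#' @param mediators,confounder optional overrides of the header metadata.
#' @return an [apc_dataset()].
#' @export
read_apc_data <- function(path, scheme = NULL, mediators = NULL,
                          confounder = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- strsplit(val, "\\s+")[[1]]
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
    collapse = "\n"
  ))
  if (is.null(scheme)) {
    if (is.null(meta$age_edges)) {
      stop("file has no scheme header; supply `scheme`", call. = FALSE)
    }
    ae <- as.numeric(meta$age_edges)
    pe <- as.numeric(meta$period_edges)
    scheme <- apc_scheme(
      range(ae), range(pe),
      width = as.numeric(meta$width)
    )
  }
  if (is.null(mediators)) mediators <- meta$mediators %||% character()
  mediators <- mediators[nzchar(mediators)]
  kinds <- NULL
  if (!is.null(meta$mediator_kinds) && length(meta$mediator_kinds) ==
    length(mediators)) {
    kinds <- stats::setNames(meta$mediator_kinds, mediators)
  }
  if (is.null(confounder)) {
    confounder <- meta$confounder
    if (is.null(confounder) || identical(confounder, "none")) confounder <- NULL
  }
  variant <- (meta$variant %||% NA_character_)[1]
  apc_dataset(df,
    scheme = scheme, mediators = mediators, mediator_kinds = kinds,
    confounder = confounder, variant = variant,
    provenance = list(file = path)
  )
}
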