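#' Construct and validate an OTU count table
#'
#' The package stores community observations as a plain integer matrix with
#' samples in rows and OTUs in columns, carrying sample ids as rownames and
#' OTU ids as colnames. `otu_table()` validates and classes such a matrix;
#' `as_otu_table()` coerces a data frame whose first column holds sample ids
#' (the tidy long/wide conventions used by `read_otu_table()`).
#'
#' Validity requires unique sample and OTU ids, non-negative integer counts
#' (floating-point counts are rejected, not rounded, because rarefaction
#' subsamples discrete reads), and at least one positive count per sample.
#'
#' @param counts Numeric matrix of counts, samples x OTUs.
#' @param sample_ids,otu_ids Optional character vectors overriding dimnames.
#' @return An integer matrix of class `"otu_table"`.
#' @examples
#' m <- matrix(c(5, 0, 3, 1, 2, 4), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("a", "b", "c")))
#' otu_table(m)
#' @export
otu_table <- function(counts, sample_ids = NULL, otu_ids = NULL) {
  if (!is.matrix(counts)) {
    rlang::abort("`counts` must be a matrix (samples x OTUs).")
  }
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(otu_ids)) colnames(counts) <- otu_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    rlang::abort("`counts` needs sample ids (rownames) and OTU ids (colnames).")
  }
  validate_otu_table(counts)
}

validate_otu_table <- function(counts) {
  sids <- rownames(counts)
  oids <- colnames(counts)
  dup_s <- unique(sids[duplicated(sids)])
  if (length(dup_s)) {
    rlang::abort(paste0("duplicated sample id(s): ",
                        paste(dup_s, collapse = ", ")))
  }
  dup_o <- unique(oids[duplicated(oids)])
  if (length(dup_o)) {
    rlang::abort(paste0("duplicated OTU id(s): ",
                        paste(dup_o, collapse = ", ")))
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    rlang::abort("counts must be numeric with no missing values.")
  }
  if (any(counts < 0)) rlang::abort("counts must be non-negative.")
  if (!all(is_whole_number(counts))) {
    rlang::abort(
      "counts must be integers; floating-point abundances are not rounded.")
  }
  if (any(rowSums(counts) == 0)) {
    bad <- sids[rowSums(counts) == 0]
    rlang::abort(paste0("sample(s) with no reads: ",
                        paste(bad, collapse = ", ")))
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("otu_table", class(matrix()))
  counts
}

#' @rdname otu_table
#' @param x A data frame (first column sample ids, remaining columns OTU
#'   counts) or a matrix.
#' @param ... Unused.
#' @export
as_otu_table <- function(x, ...) UseMethod("as_otu_table")

#' @export
as_otu_table.otu_table <- function(x, ...) x

#' @export
as_otu_table.matrix <- function(x, ...) otu_table(x)

#' @export
as_otu_table.data.frame <- function(x, ...) {
  if (ncol(x) < 2) rlang::abort("need at least one OTU column.")
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) rlang::abort("non-numeric count cell(s) found.")
  rownames(m) <- ids
  otu_table(m)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d samples x %d OTUs, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Tidy an OTU table into long format
#'
#' @param x An `otu_table`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `otu_id`, `count`.
#' @export
tidy.otu_table <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    otu_id = rep(colnames(x), each = nrow(x)),
    count = as.integer(x)
  )
}

sample_ids <- function(table) rownames(table)
otu_ids <- function(table) colnames(table)
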