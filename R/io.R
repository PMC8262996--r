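#' Read an OTU count table from TSV or BIOM-JSON
#'
#' TSV dialect: a header row plus one row per sample, first column holding
#' sample ids (or OTU ids when the file is transposed). Orientation can be
#' forced with `transpose`, or auto-detected by matching header tokens
#' against `meta$sample_id` when metadata are supplied: if the header looks
#' like sample ids the file is OTU x sample and is transposed on read.
#' BIOM-JSON files are parsed with the biomformat package.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom-json"`.
#' @param transpose `NULL` (auto/default), or logical: `TRUE` means the file
#'   is OTUs x samples.
#' @param meta Optional sample metadata (see [read_sample_meta()]) used for
#'   orientation auto-detection.
#' @return A validated [otu_table()].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json"),
                           transpose = NULL, meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      rlang::abort("reading BIOM files requires the 'biomformat' package.")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # taxa x samples
    return(otu_table(t(m)))
  }
  raw <- suppressMessages(
    readr::read_tsv(path, col_types = readr::cols(), progress = FALSE))
  first <- as.character(raw[[1]])
  body <- raw[, -1, drop = FALSE]
  if (!all(vapply(body, is.numeric, logical(1)))) {
    bad <- names(body)[!vapply(body, is.numeric, logical(1))]
    rlang::abort(paste0("non-numeric count column(s): ",
                        paste(bad, collapse = ", ")))
  }
  m <- as.matrix(body)
  rownames(m) <- first
  if (is.null(transpose)) {
    transpose <- FALSE
    if (!is.null(meta)) {
      header_hits <- mean(colnames(m) %in% meta$sample_id)
      column_hits <- mean(first %in% meta$sample_id)
      if (header_hits > column_hits) transpose <- TRUE
    }
  }
  if (transpose) m <- t(m)
  otu_table(m)
}

#' Write an OTU table
#'
#' @param table An [otu_table()].
#' @param path Output path.
#' @param format `"tsv"` (samples in rows, first column `sample_id`) or
#'   `"biom-json"`.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  table <- as_otu_table(table)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      rlang::abort("writing BIOM files requires the 'biomformat' package.")
    }
    b <- biomformat::make_biom(t(unclass(table)))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- tibble::as_tibble(unclass(table), rownames = "sample_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a newick file
#'
#' Square-bracket comments are stripped before parsing; quoted labels follow
#' the common newick dialect handled by \pkg{ape}. Trees must be rooted, have
#' unique tip labels, and carry a branch length on every edge unless
#' `missing_as_zero = TRUE` (which substitutes 0 with a warning).
#'
#' @param path Path to a newick file containing a single tree.
#' @param missing_as_zero Treat absent branch lengths as 0 instead of erroring.
#' @return An \pkg{ape} `phylo` object.
#' @export
read_tree <- function(path, missing_as_zero = FALSE) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\[[^]]*\\]", "", txt)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL)
  if (is.null(tree)) rlang::abort("unparsable newick.")
  if (inherits(tree, "multiPhylo")) {
    rlang::abort("file contains more than one tree.")
  }
  validate_tree(tree, missing_as_zero = missing_as_zero)
}

validate_tree <- function(tree, missing_as_zero = FALSE) {
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    rlang::abort(paste0("duplicated tip label(s): ",
                        paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (missing_as_zero) {
      rlang::warn("missing branch lengths treated as 0.")
      if (is.null(tree$edge.length)) {
        tree$edge.length <- rep(0, nrow(tree$edge))
      } else {
        tree$edge.length[is.na(tree$edge.length)] <- 0
      }
    } else {
      rlang::abort("tree has missing branch lengths.")
    }
  }
  if (any(tree$edge.length < 0)) rlang::abort("negative branch length(s).")
  if (!ape::is.rooted(tree)) rlang::abort("tree must be rooted.")
  tree
}

#' Read or write the sample metadata table
#'
#' The CSV must carry the header columns `sample_id`, `host_species`, `site`,
#' `latitude`, `longitude`, `mat` (mean annual temperature, degrees C) and
#' `map_mm` (mean annual precipitation, mm/yr); `haplotype` is optional.
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per sample.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  meta <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  validate_sample_meta(meta)
}

validate_sample_meta <- function(meta) {
  required <- c("sample_id", "host_species", "site",
                "latitude", "longitude", "mat", "map_mm")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    rlang::abort(paste0("metadata missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  meta$sample_id <- as.character(meta$sample_id)
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) {
    rlang::abort(paste0("duplicated sample id(s): ",
                        paste(dup, collapse = ", ")))
  }
  if (any(!is.na(meta$latitude) & abs(meta$latitude) > 90)) {
    rlang::abort("latitude outside [-90, 90].")
  }
  if (any(!is.na(meta$longitude) & abs(meta$longitude) > 180)) {
    rlang::abort("longitude outside [-180, 180].")
  }
  tibble::as_tibble(meta)
}

#' @rdname read_sample_meta
#' @param meta A metadata tibble.
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_csv(validate_sample_meta(meta), path, progress = FALSE)
  invisible(path)
}

#' Align an OTU table, tree, and metadata to a common id universe
#'
#' Restricts the table to samples present in the metadata (and vice versa,
#' preserving table order), prunes the tree to the OTUs present in the table,
#' and checks that every analyzed OTU has a tip. OTUs missing from the tree
#' are an error unless `allow_missing_tips = TRUE`, in which case they are
#' dropped from the table with a message reporting how many.
#'
#' The operation is idempotent: aligning aligned inputs is a no-op.
#'
#' @param table An [otu_table()].
#' @param tree A `phylo` whose tips cover the table's OTUs.
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @param allow_missing_tips Drop table OTUs absent from the tree instead of
#'   erroring.
#' @return A list with elements `table`, `tree`, `meta`.
#' @export
align_inputs <- function(table, tree, meta, allow_missing_tips = FALSE) {
  table <- as_otu_table(table)
  meta <- validate_sample_meta(meta)
  keep_samples <- intersect(sample_ids(table), meta$sample_id)
  if (!length(keep_samples)) {
    rlang::abort("no sample ids shared between table and metadata.")
  }
  table <- unclass(table)[keep_samples, , drop = FALSE]
  missing_tips <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_tips)) {
    if (!allow_missing_tips) {
      rlang::abort(paste0("OTU(s) absent from tree: ",
                          paste(missing_tips, collapse = ", ")))
    }
    rlang::inform(paste0("dropping ", length(missing_tips),
                         " OTU(s) absent from the tree."))
    table <- table[, setdiff(colnames(table), missing_tips), drop = FALSE]
  }
  table <- otu_table(table)
  if (length(setdiff(tree$tip.label, otu_ids(table)))) {
    tree <- ape::keep.tip(tree, otu_ids(table))
  }
  meta <- meta[match(sample_ids(table), meta$sample_id), , drop = FALSE]
  list(table = table, tree = tree, meta = meta)
}
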