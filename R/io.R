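#' Read and write the package's tabular formats
#'
#' The pipeline exchanges four plain-text formats: a genes-by-arrays log2
#' expression matrix (TSV with a header row of array ids and gene ids in the
#' first column), a sample sheet (TSV: `array_id`, `tissue`, `stage`,
#' `replicate`), a truth table (TSV, see [simulate_truth()]), and gene-set
#' annotation in GMT (one set per line: name, description, then tab-separated
#' gene ids). All writers and readers round-trip losslessly on the decimal
#' text representation.
#'
#' @param path File path.
#' @param matrix Genes x arrays numeric matrix with dimnames.
#' @param sheet,truth Data frames as produced by [build_design()] and
#'   [simulate_truth()].
#' @return Readers return the corresponding object; writers return the path
#'   invisibly.
#' @name limbtempo-io
NULL

#' @rdname limbtempo-io
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >=1 array column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate array ids in ", path)
  m
}

#' @rdname limbtempo-io
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  df <- data.frame(gene = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname limbtempo-io
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("array_id", "tissue", "stage", "replicate")
  missing <- setdiff(required, names(sheet))
  if (length(missing)) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(sheet$tissue), TISSUES)
  if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(sheet$array_id)) stop("duplicate array ids in sample sheet")
  sheet
}

#' @rdname limbtempo-io
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname limbtempo-io
#' @export
read_truth <- function(path) {
  truth <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(fl_pattern = "character",
                                     hl_pattern = "character"))
  class(truth) <- c("truth_table", "data.frame")
  truth
}

#' @rdname limbtempo-io
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-set annotation container
#'
#' A validated collection of gene sets over a fixed gene universe (the genes
#' present on the array). Invariants: every category is a non-empty subset of
#' the universe; duplicate genes within a category are removed with a
#' warning.
#'
#' @param sets Named list of character vectors (category id -> gene ids).
#' @param description Optional named character vector of category
#'   descriptions; defaults to empty strings.
#' @param universe Character vector of all annotated gene ids on the array.
#' @return An object of class `"annotation_set"`: a list with elements
#'   `sets`, `description`, `universe`.
#' @export
annotation_set <- function(sets, description = NULL, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  if (!length(universe)) stop("annotation universe is empty")
  if (is.null(description)) {
    description <- setNames(rep("", length(sets)), names(sets))
  }
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (!length(g)) stop("empty category: ", nm)
    if (anyDuplicated(g)) {
      warning("duplicate gene ids in category ", nm, "; deduplicated")
      g <- unique(g)
    }
    outside <- setdiff(g, universe)
    if (length(outside)) {
      stop("category ", nm, " contains gene(s) outside the universe: ",
           paste(utils::head(outside, 3), collapse = ", "))
    }
    sets[[nm]] <- g
  }
  structure(list(sets = sets, description = description[names(sets)],
                 universe = universe),
            class = "annotation_set")
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one category per line; tab-separated fields are the category
#' id, a free-text description, then the member gene ids.
#'
#' @param path GMT file path.
#' @param universe Gene universe for the resulting [annotation_set()];
#'   defaults to the union of all member genes.
#' @return An [annotation_set()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": need name, description and >=1 gene")
    }
    nm <- fields[1]
    if (nm %in% names(sets)) stop("duplicate category id at GMT line ", i, ": ", nm)
    sets[[nm]] <- fields[-(1:2)]
    desc[nm] <- fields[2]
  }
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  annotation_set(sets, desc, universe)
}

#' Write an annotation set as GMT
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  lines <- vapply(names(ann$sets), function(nm) {
    paste(c(nm, ann$description[[nm]], ann$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname limbtempo-io
#' @export
read_probe_map <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(map))) {
    stop("probe map needs columns 'probe' and 'gene'")
  }
  if (anyDuplicated(map$probe)) stop("probe map is not many-to-one: duplicate probes")
  map
}

#' Write a differential-expression or enrichment table as TSV
#'
#' @param table A data.frame (e.g. from [run_all_contrasts()] or
#'   [enrich_cluster()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_result_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
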