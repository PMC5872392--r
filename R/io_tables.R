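#' Association tables
#'
#' An association table is a binary bipartite incidence between entities
#' (herbs or proteins) and attributes (efficacies, pathways, or protein
#' targets). It is the common input container of the pipeline: herb-target,
#' herb-efficacy and protein-pathway tables all use it. Rows and columns are
#' kept in lexicographic order so that every downstream matrix has a stable,
#' input-order-independent indexing.
#'
#' @param entity character vector of entity ids.
#' @param attribute character vector of attribute ids, same length.
#' @return An object of class `assoc_table` with fields `entities`
#'   (sorted unique entity ids), `attributes` (sorted unique attribute ids)
#'   and `pairs` (deduplicated two-column data frame of links).
#' @examples
#' tab <- association_table(c("h1", "h1", "h2"), c("e1", "e2", "e2"))
#' association_stats(tab)
#' @export
association_table <- function(entity, attribute) {
  stopifnot(length(entity) == length(attribute))
  if (length(entity) == 0L) {
    stop("association table has no pairs")
  }
  entity <- as.character(entity)
  attribute <- as.character(attribute)
  if (anyNA(entity) || anyNA(attribute) ||
      any(entity == "") || any(attribute == "")) {
    stop("entity and attribute ids must be non-empty strings")
  }
  pairs <- unique(data.frame(entity = entity, attribute = attribute,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$entity, pairs$attribute), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(
      entities = sort(unique(pairs$entity)),
      attributes = sort(unique(pairs$attribute)),
      pairs = pairs
    ),
    class = "assoc_table"
  )
}

#' Read an association table from delimited text
#'
#' Reads a two-column delimited file (entity, attribute). Extra columns are
#' ignored; duplicate pairs collapse to one. Lines with fewer than two fields
#' abort with the offending line number.
#'
#' @param path path to the file.
#' @param delimiter field delimiter, default tab.
#' @param header logical; if `TRUE` the first line is discarded.
#' @return An [association_table()] object.
#' @export
read_association_table <- function(path, delimiter = "\t", header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines) >= 1L) lines <- lines[-1L]
  if (length(lines) == 0L) stop("empty association file: ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L] + if (header) 1L else 0L
    stop("malformed line ", bad, " in ", path, ": expected >= 2 fields")
  }
  association_table(
    entity = vapply(fields, `[[`, character(1), 1L),
    attribute = vapply(fields, `[[`, character(1), 2L)
  )
}

#' Write an association table as two-column delimited text
#'
#' @param t an `assoc_table`.
#' @param path output file path.
#' @param delimiter field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(t, path, delimiter = "\t") {
  stopifnot(inherits(t, "assoc_table"))
  writeLines(paste(t$pairs$entity, t$pairs$attribute, sep = delimiter), path)
  invisible(path)
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("<assoc_table> %d entities x %d attributes, %d pairs\n",
              length(x$entities), length(x$attributes), nrow(x$pairs)))
  invisible(x)
}

#' Sparse binary incidence matrix of an association table
#'
#' @param t an `assoc_table`.
#' @return A `dgCMatrix` with entities as rows and attributes as columns.
#' @export
as_incidence <- function(t) {
  stopifnot(inherits(t, "assoc_table"))
  Matrix::sparseMatrix(
    i = match(t$pairs$entity, t$entities),
    j = match(t$pairs$attribute, t$attributes),
    x = 1,
    dims = c(length(t$entities), length(t$attributes)),
    dimnames = list(t$entities, t$attributes)
  )
}

#' Restrict an association table to a subset of entities
#'
#' Attributes that lose all links are dropped from the column index; the
#' attribute universe can be kept with `keep_attributes = TRUE` (used by the
#' shuffle null, which draws from the full attribute universe).
#'
#' @param t an `assoc_table`.
#' @param entities entity ids to keep.
#' @param keep_attributes keep the original attribute universe even if some
#'   attributes end up unlinked.
#' @return An `assoc_table`.
#' @export
subset_table <- function(t, entities, keep_attributes = FALSE) {
  stopifnot(inherits(t, "assoc_table"))
  keep <- t$pairs$entity %in% entities
  if (!any(keep)) stop("no pairs left after subsetting")
  out <- association_table(t$pairs$entity[keep], t$pairs$attribute[keep])
  if (keep_attributes) out$attributes <- t$attributes
  out
}

#' Degree summary of an association table
#'
#' Reports the mean number of links per entity and per attribute, and the
#' fraction of entities whose degree exceeds a threshold (e.g. the share of
#' herbs with more than ten known targets).
#'
#' @param t an `assoc_table`.
#' @param degree_threshold threshold k for the `frac_entities_above` field.
#' @return A list with `n_entities`, `n_attributes`, `n_pairs`,
#'   `mean_per_entity`, `mean_per_attribute`, `frac_entities_above`.
#' @export
association_stats <- function(t, degree_threshold = 10) {
  stopifnot(inherits(t, "assoc_table"))
  deg <- table(t$pairs$entity)
  list(
    n_entities = length(t$entities),
    n_attributes = length(t$attributes),
    n_pairs = nrow(t$pairs),
    mean_per_entity = nrow(t$pairs) / length(t$entities),
    mean_per_attribute = nrow(t$pairs) / length(t$attributes),
    frac_entities_above = mean(deg > degree_threshold)
  )
}
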