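#' Cosine similarity of binary annotation profiles
#'
#' Every entity is represented by a binary vector over the attribute
#' universe (1 if the attribute is annotated to the entity). The similarity
#' of two entities x and y is the cosine of their vectors,
#' \deqn{S_{xy} = |A_x \cap A_y| / (\sqrt{|A_x|}\,\sqrt{|A_y|}),}
#' where A_x is the attribute set of x. This is the single similarity used
#' throughout: efficacy- and target-based similarity of herb pairs, and
#' pathway- and herb-based similarity of protein pairs, differing only in
#' which association table is supplied.
#'
#' Entities with zero annotations cannot occur when the matrix is built from
#' an association table (every row has at least one link) but are tolerated
#' when matrices are subset downstream: such rows are all-zero, including the
#' diagonal, and are listed in the `zero_annotation` field.
#'
#' @param t an [association_table()].
#' @return An object of class `similarity_matrix`: list with `ids` (entity
#'   ids, lexicographic), `S` (sparse symmetric matrix of cosines in [0,1]
#'   with unit diagonal for annotated entities) and `zero_annotation`
#'   (character vector of unannotated ids).
#' @examples
#' tab <- association_table(c("x", "x", "y", "y"), c("e1", "e2", "e2", "e3"))
#' cosine_similarity(tab)$S["x", "y"]  # 1 / (sqrt(2) * sqrt(2)) = 0.5
#' @export
cosine_similarity <- function(t) {
  stopifnot(inherits(t, "assoc_table"))
  M <- as_incidence(t)
  deg <- Matrix::rowSums(M)
  inv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  S <- Matrix::Diagonal(x = inv) %*% Matrix::tcrossprod(M) %*%
    Matrix::Diagonal(x = inv)
  S <- methods::as(S, "generalMatrix")
  # co-membership counts are integers, so the diagonal is exactly 1 up to
  # floating error; pin it
  Matrix::diag(S)[deg > 0] <- 1
  dimnames(S) <- list(t$entities, t$entities)
  structure(
    list(ids = t$entities, S = Matrix::drop0(S),
         zero_annotation = t$entities[deg == 0]),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d entities, %d positive pairs\n",
              length(x$ids),
              (Matrix::nnzero(x$S) - sum(Matrix::diag(x$S) > 0)) / 2))
  invisible(x)
}

#' Restrict a similarity matrix to a subset of entities
#'
#' @param sim a `similarity_matrix`.
#' @param ids entity ids to keep (order is re-sorted lexicographically).
#' @return A `similarity_matrix` over `ids`.
#' @export
subset_similarity <- function(sim, ids) {
  stopifnot(inherits(sim, "similarity_matrix"))
  ids <- sort(ids)
  missing <- setdiff(ids, sim$ids)
  if (length(missing)) stop("unknown ids: ", paste(missing, collapse = ", "))
  S <- sim$S[ids, ids, drop = FALSE]
  structure(
    list(ids = ids, S = S,
         zero_annotation = ids[Matrix::diag(S) == 0]),
    class = "similarity_matrix"
  )
}

#' Dump positive similarity pairs to delimited text
#'
#' Writes one line per unordered pair with positive similarity:
#' entity_i, entity_j, similarity.
#'
#' @param sim a `similarity_matrix`.
#' @param path output path.
#' @param delimiter field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_similarity_pairs <- function(sim, path, delimiter = "\t") {
  stopifnot(inherits(sim, "similarity_matrix"))
  tri <- Matrix::triu(sim$S, k = 1)
  sm <- Matrix::summary(methods::as(tri, "TsparseMatrix"))
  writeLines(paste(sim$ids[sm$i], sim$ids[sm$j],
                   format(sm$x, digits = 15, trim = TRUE),
                   sep = delimiter), path)
  invisible(path)
}
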