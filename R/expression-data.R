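#' Construct an expression matrix
#'
#' Wraps a numeric P x M matrix (genes in rows, samples in columns) after
#' validating the invariants every classifier in this package relies on:
#' unique gene and sample identifiers, finite values, and at least two genes
#' and two samples.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids Character vector of P unique gene identifiers. Defaults to
#'   `rownames(values)`.
#' @param sample_ids Character vector of M unique sample identifiers. Defaults
#'   to `colnames(values)`.
#' @return An object of class `expr_matrix`: the numeric matrix with
#'   `dimnames` set to the identifiers.
#' @examples
#' x <- expr_matrix(matrix(1:6, 2, 3), c("g1", "g2"), c("s1", "s2", "s3"))
#' dim(x)
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 genes and 2 samples")
  if (length(gene_ids) != nrow(values))
    stop("length of `gene_ids` does not match the number of rows")
  if (length(sample_ids) != ncol(values))
    stop("length of `sample_ids` does not match the number of columns")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]))
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  cat("genes:  ", paste(utils::head(rownames(x), 4L), collapse = ", "),
      if (nrow(x) > 4L) ", ..." else "", "\n", sep = "")
  cat("samples:", paste(utils::head(colnames(x), 4L), collapse = ", "),
      if (ncol(x) > 4L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Construct a binary class-label vector
#'
#' @param labels Character (or factor) vector of per-sample class symbols,
#'   aligned with the sample columns of the matching expression matrix.
#'   Exactly two distinct symbols must be present.
#' @param class_order Optional length-2 character vector fixing which class is
#'   treated as the first class C1. Defaults to order of first appearance.
#' @return An object of class `class_labels`: a list with elements `labels`
#'   (character vector) and `class_order` (length-2 character).
#' @examples
#' y <- class_labels(c("tumour", "normal", "tumour", "normal"))
#' y$class_order
#' @export
class_labels <- function(labels, class_order = NULL) {
  labels <- as.character(labels)
  present <- unique(labels)
  if (length(present) != 2L)
    stop("exactly two classes are required, found: ",
         paste(present, collapse = ", "))
  if (is.null(class_order)) {
    class_order <- present
  } else {
    class_order <- as.character(class_order)
    if (length(class_order) != 2L || !setequal(class_order, present))
      stop("`class_order` must be a permutation of the two classes present")
  }
  structure(list(labels = labels, class_order = class_order),
            class = "class_labels")
}

#' @export
print.class_labels <- function(x, ...) {
  n <- table(factor(x$labels, levels = x$class_order))
  cat(sprintf("class labels: %d samples (%s: %d, %s: %d)\n",
              length(x$labels),
              x$class_order[1L], n[1L], x$class_order[2L], n[2L]))
  invisible(x)
}

# integer class index (1 or 2) per sample, following class_order
label_index <- function(labels) {
  match(labels$labels, labels$class_order)
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers, gene identifiers in the first
#' column, and finite numeric cells; the canonical on-disk format of this
#' package. Row and column order is preserved.
#'
#' @param path Path to a TSV file.
#' @return An [expr_matrix].
#' @seealso [write_expression_tsv()]
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("expression file needs a header and >= 2 gene rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  ncol_expected <- length(header)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != ncol_expected))
    stop(sprintf("ragged row %d: expected %d fields, found %d",
                 which(widths != ncol_expected)[1L] + 1L, ncol_expected,
                 widths[widths != ncol_expected][1L]))
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  values <- suppressWarnings(as.numeric(cells))
  if (anyNA(values) || !all(is.finite(values))) {
    bad <- which(!is.finite(values) | is.na(values))[1L]
    r <- (bad - 1L) %/% length(sample_ids) + 1L
    c_ <- (bad - 1L) %% length(sample_ids) + 1L
    stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s'",
                 cells[bad], gene_ids[r], sample_ids[c_]))
  }
  mat <- matrix(values, nrow = length(gene_ids), byrow = TRUE)
  expr_matrix(mat, gene_ids, sample_ids)
}

#' Write an expression matrix as tab-separated text
#'
#' @param expr An [expr_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  header <- paste(c("gene_id", colnames(expr)), collapse = "\t")
  rows <- vapply(seq_len(nrow(expr)), function(r) {
    paste(c(rownames(expr)[r],
            format(expr[r, ], trim = TRUE, digits = 15, scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read sample class labels from a two-column TSV
#'
#' The file holds one `sample_id<TAB>class` row per sample (an optional header
#' is detected by its first field `sample_id`). Labels are reordered to match
#' `sample_ids`; every sample in the matrix must be present.
#'
#' @param path Path to the label TSV.
#' @param sample_ids Character vector of sample identifiers (usually
#'   `colnames` of the expression matrix) defining the output order.
#' @param class_order Optional override of which class is C1 (see
#'   [class_labels()]); defaults to order of first appearance in the file.
#' @return A [class_labels] object aligned with `sample_ids`.
#' @export
read_labels_tsv <- function(path, sample_ids, class_order = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L))
    stop("label file must have exactly two tab-separated columns")
  ids <- vapply(fields, `[[`, character(1L), 1L)
  cls <- vapply(fields, `[[`, character(1L), 2L)
  if (ids[1L] == "sample_id") {
    ids <- ids[-1L]
    cls <- cls[-1L]
  }
  if (anyDuplicated(ids))
    stop("duplicate sample id(s) in label file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing <- setdiff(sample_ids, ids)
  if (length(missing))
    stop("sample(s) missing from label file: ", paste(missing, collapse = ", "))
  cls <- cls[match(sample_ids, ids)]
  class_labels(cls, class_order = class_order)
}

#' Write sample class labels as a two-column TSV
#'
#' @param labels A [class_labels] object.
#' @param sample_ids Sample identifiers, aligned with `labels$labels`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, sample_ids, path) {
  writeLines(c("sample_id\tclass",
               paste(sample_ids, labels$labels, sep = "\t")), path)
  invisible(path)
}

#' Cross-validation folds, stratified by class
#'
#' Partitions the M samples into `n_folds` test sets whose per-class counts
#' differ by at most one from proportional allocation. With
#' `stratify = FALSE` a plain random partition (balanced in size only) is
#' produced instead.
#'
#' @param labels A [class_labels] object.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed; the same seed always yields the same folds.
#' @param stratify Stratify the partition by class (default `TRUE`).
#' @return A list of `n_folds` lists, each with integer vectors `train` and
#'   `test` indexing samples.
#' @examples
#' y <- class_labels(rep(c("A", "B"), each = 10))
#' folds <- stratified_kfold(y, n_folds = 5, seed = 1)
#' lengths(lapply(folds, `[[`, "test"))
#' @export
stratified_kfold <- function(labels, n_folds, seed, stratify = TRUE) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("`n_folds` must be at least 2")
  m <- length(labels$labels)
  idx <- label_index(labels)
  if (stratify) {
    counts <- tabulate(idx, 2L)
    if (any(counts < n_folds))
      stop(sprintf("class '%s' has %d samples, fewer than %d folds",
                   labels$class_order[which.min(counts)], min(counts), n_folds))
    assignment <- integer(m)
    with_seed(seed, {
      for (cl in 1:2) {
        members <- sample(which(idx == cl))
        assignment[members] <- rep_len(seq_len(n_folds), length(members))
      }
    })
  } else {
    if (m < n_folds) stop("more folds than samples")
    assignment <- integer(m)
    with_seed(seed, {
      assignment[sample.int(m)] <- rep_len(seq_len(n_folds), m)
    })
  }
  lapply(seq_len(n_folds), function(f) {
    list(train = which(assignment != f), test = which(assignment == f))
  })
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
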