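# JSON serialization of fitted models. All model types share a schema core
# (`type`, `class_order`, `pairs` with gene ids, signs and weights) so that
# the baselines and the evolved models are diffable in the same format; the
# triplet model adds its ordering distributions. Field order is fixed and
# numbers are written at full precision, so identical models serialize to
# identical bytes.

#' Write a fitted model to JSON
#'
#' @param model A fitted `tsp_model`, `ktsp_model`, `tst_model` or
#'   `evotsp_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

model_to_list <- function(model) UseMethod("model_to_list")

#' @export
model_to_list.tsp_model <- function(model) {
  list(type = "tsp",
       class_order = model$class_order,
       pairs = list(list(gene_i = model$pair$gene_i,
                         gene_j = model$pair$gene_j,
                         sign = if (model$vote_lt == 1L) 1L else -1L,
                         weight = 1)),
       vote_lt = model$vote_lt,
       delta = model$pair$delta,
       secondary = model$pair$secondary)
}

#' @export
model_to_list.ktsp_model <- function(model) {
  list(type = "ktsp",
       class_order = model$class_order,
       pairs = lapply(seq_len(nrow(model$pairs)), function(r)
         list(gene_i = model$pairs$gene_i[r],
              gene_j = model$pairs$gene_j[r],
              sign = if (model$vote_lt[r] == 1L) 1L else -1L,
              weight = 1)),
       vote_lt = model$vote_lt,
       delta = model$pairs$delta,
       k = model$k)
}

#' @export
model_to_list.tst_model <- function(model) {
  list(type = "tst",
       class_order = model$class_order,
       genes = model$gene_ids,
       ordering_p1 = as.list(model$ordering_p1),
       ordering_p2 = as.list(model$ordering_p2),
       class_sizes = model$class_sizes,
       score = model$score)
}

#' @export
model_to_list.evotsp_model <- function(model) {
  list(type = "evotsp",
       class_order = model$class_order,
       pairs = lapply(seq_len(nrow(model$pairs)), function(r)
         list(gene_i = model$pairs$gene_i[r],
              gene_j = model$pairs$gene_j[r],
              sign = model$pairs$sign[r],
              weight = model$pairs$weight[r])),
       alpha = model$alpha,
       seed = model$seed,
       training_summary = model$training)
}

#' Read a fitted model back from JSON
#'
#' Reconstructs a model written by [write_model()] with enough state to
#' [predict()] on new expression data.
#'
#' @param path Path to a model JSON file.
#' @return A fitted model object of the class recorded in the file.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (is.null(obj$type)) stop("not a model file (missing 'type'): ", path)
  switch(obj$type,
    tsp = structure(list(
      pair = data.frame(gene_i = obj$pairs$gene_i[1L],
                        gene_j = obj$pairs$gene_j[1L],
                        delta = obj$delta, secondary = obj$secondary,
                        stringsAsFactors = FALSE),
      vote_lt = as.integer(obj$vote_lt),
      class_order = obj$class_order), class = "tsp_model"),
    ktsp = structure(list(
      pairs = data.frame(gene_i = obj$pairs$gene_i,
                         gene_j = obj$pairs$gene_j,
                         delta = obj$delta, stringsAsFactors = FALSE),
      vote_lt = as.integer(obj$vote_lt),
      k = as.integer(obj$k),
      class_order = obj$class_order), class = "ktsp_model"),
    tst = structure(list(
      gene_ids = obj$genes,
      ordering_p1 = stats::setNames(unlist(obj$ordering_p1),
                                    tst_ordering_names),
      ordering_p2 = stats::setNames(unlist(obj$ordering_p2),
                                    tst_ordering_names),
      class_sizes = unlist(obj$class_sizes),
      score = obj$score,
      class_order = obj$class_order), class = "tst_model"),
    evotsp = structure(list(
      individual = list(i = NA_integer_, j = NA_integer_,
                        sign = as.integer(obj$pairs$sign),
                        w = as.numeric(obj$pairs$weight),
                        fitness = obj$training_summary$fitness),
      pairs = data.frame(gene_i = obj$pairs$gene_i,
                         gene_j = obj$pairs$gene_j,
                         sign = as.integer(obj$pairs$sign),
                         weight = as.numeric(obj$pairs$weight),
                         stringsAsFactors = FALSE),
      class_order = obj$class_order,
      alpha = obj$alpha,
      seed = obj$seed,
      training = lapply(obj$training_summary, identity)),
      class = "evotsp_model"),
    stop("unknown model type: ", obj$type))
}
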