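#' Read a gene-by-sample expression table
#'
#' Expects genes as rows and samples as columns, with gene identifiers in the
#' first column and sample identifiers in the header. The orientation is not
#' guessed: a table whose first column is not unique fails loudly.
#'
#' @param path TSV or CSV file (delimiter inferred from the extension).
#' @param scale_tag scale of the stored values, see [expression_matrix()].
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, scale_tag = "normalized") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs >=1 sample column")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("first column of ", path, " is not a unique gene identifier; ",
         "expected genes as rows, samples as columns")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, scale_tag = scale_tag)
}

#' Write an expression matrix as TSV (genes as rows)
#' @param expr an [expression_matrix()] or plain matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), unclass(expr),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical/survival table
#'
#' A TSV with one row per sample; must contain `sample_id`, and for survival
#' analyses `time` (positive, consistent units across the cohort) and `event`
#' (0/1, 1 = death). Extra columns (tissue, metastasis, stage, ...) are
#' passed through.
#' @param path TSV path.
#' @return data.frame keyed by `sample_id`.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("clinical table must contain a 'sample_id' column")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in ", path)
  tab
}

#' Write a clinical table as TSV
#' @param clinical data.frame with a `sample_id` column.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated `name <tab> description <tab>
#' gene1 <tab> gene2 ...`.
#' @param path GMT path.
#' @return named list of character vectors; descriptions kept as an attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- description %||% attr(sets, "description") %||%
    rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a signature model to JSON
#' @param model a `signature_model`, see [fit_final_model()].
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  obj <- list(
    pairs = model$pairs,
    coefficients = model$coefficients,
    table = model$table,
    cutoff = model$cutoff,
    provenance = model$provenance,
    pipeline_version = as.character(utils::packageVersion("pairsig")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Load a signature model from JSON
#' @param path JSON produced by [write_model_json()].
#' @return a `signature_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_signature_model(
    pairs = as.character(obj$pairs),
    coefficients = as.numeric(obj$coefficients),
    table = as.data.frame(obj$table),
    cutoff = if (is.null(obj$cutoff)) NA_real_ else as.numeric(obj$cutoff),
    provenance = as.character(obj$provenance))
}
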