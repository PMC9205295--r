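#' Read / write a marker matrix
#'
#' CSV or TSV with a header row of marker names and the line identifier
#' in the first column.
#'
#' @param path file path (delimiter inferred from the extension; `.tsv`
#'   is tab-separated, anything else comma-separated).
#' @return numeric matrix with line-id row names.
#' @export
read_markers <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("marker file needs a line-id column and markers")
  ids <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(X)) stop("non-numeric marker entries in ", path)
  rownames(X) <- ids
  X
}

#' @rdname read_markers
#' @param X numeric matrix with line-id row names.
#' @export
write_markers <- function(X, path) {
  df <- data.frame(Line = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with header columns `Line`, `Env` and exactly one trait column.
#' The trait type is inferred with [infer_response_type()] and attached
#' as attribute `response_spec`. Duplicate (Line, Env) keys are an error.
#'
#' @param path CSV file path.
#' @return data frame with columns `Line`, `Env` and the trait.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("Line", "Env")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns 'Line' and 'Env'")
  }
  traits <- setdiff(names(df), need)
  if (length(traits) == 0) stop("phenotype file has no trait column")
  df <- df[, c(need, traits[1])]
  key <- paste(df$Line, df$Env, sep = " / ")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    stop("duplicated (Line, Env) records: ",
         paste(utils::head(dup, 5), collapse = "; "))
  }
  attr(df, "response_spec") <- infer_response_type(df[[traits[1]]])
  df
}

#' Read / write a kernel matrix as labelled CSV
#'
#' Square CSV with line ids both as first column and as header.
#'
#' @param path CSV file path.
#' @return symmetric numeric matrix with line-id dimnames.
#' @export
read_kernel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- as.character(df[[1]])
  check_symmetric(K)
}

#' @rdname read_kernel
#' @param K kernel matrix with line-id dimnames.
#' @export
write_kernel <- function(K, path) {
  df <- data.frame(Line = rownames(K), K, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load and save run configurations
#'
#' YAML round-trip for the benchmark/kernelize workflows; values load
#' back exactly as saved.
#'
#' @param path YAML file path.
#' @return named list (reader); `path` invisibly (writer).
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
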