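#' Expression matrix with sample metadata
#'
#' Transcript-by-sample FPKM values plus a sample sheet assigning each
#' column a genotype (`tolerant`/`sensitive`), condition
#' (`control`/`salt`) and replicate index.
#'
#' @param values Numeric matrix, rows = transcripts (unique rownames),
#'   columns = samples; all values `>= 0`.
#' @param samples `data.frame` with columns `sample`, `genotype`,
#'   `condition`, `replicate`; `sample` must match `colnames(values)`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique rownames (transcript ids)")
  if (any(values < 0)) stop("FPKM values must be non-negative")
  need <- c("sample", "genotype", "condition", "replicate")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "))
  if (!identical(as.character(samples$sample), colnames(values)))
    stop("samples$sample must match colnames(values) in order")
  for (g in unique(samples$genotype)) {
    cond <- samples$condition[samples$genotype == g]
    if (!all(c("control", "salt") %in% cond))
      stop("genotype ", g, " needs at least one control and one salt sample")
  }
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d transcripts x %d samples (%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$genotype), collapse = ", ")))
  invisible(x)
}

#' Read/write an expression matrix as TSV
#'
#' Layout: first column `transcript_id`, remaining columns named
#' `<genotype>_<condition>_<replicate>` (e.g. `tolerant_salt_2`), from
#' which the sample sheet is reconstructed on read.
#'
#' @param path File path.
#' @return `read_expression_tsv()`: an [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_table(path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  parts <- strsplit(colnames(values), "_", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("sample columns must be named <genotype>_<condition>_<replicate>")
  samples <- data.frame(
    sample = colnames(values),
    genotype = vapply(parts, `[`, character(1), 1),
    condition = vapply(parts, `[`, character(1), 2),
    replicate = as.integer(vapply(parts, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  expression_matrix(values, samples)
}

#' @rdname read_expression_tsv
#' @param matrix An `expression_matrix`.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(transcript_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

fpkm_row <- function(matrix, transcript_id) {
  if (!transcript_id %in% rownames(matrix$values))
    stop("transcript not in expression matrix: ", transcript_id)
  matrix$values[transcript_id, ]
}
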