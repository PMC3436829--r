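# Cohort matrices, mutation tables and the global rank-ratio transform.

#' Global rank-ratio transform
#'
#' All finite values of the matrix are ranked jointly across every gene and
#' sample, smallest to largest, and rank r is mapped to (r - 1) / (N*G - 1)
#' where N*G is the number of ranked values; the result lies in \[0, 1\].
#' Ties receive average ranks.  Missing values are excluded from ranking and
#' re-emitted as `NA`.
#'
#' @param m numeric gene-by-sample matrix.
#' @return A matrix of the same shape with values in \[0, 1\].
#' @export
rank_ratio_transform <- function(m) {
  m <- as.matrix(m)
  x <- as.vector(m)
  n_eff <- sum(!is.na(x))
  if (n_eff < 2)
    stop("rank-ratio transform needs at least 2 non-missing values")
  r <- rank(x, ties.method = "average", na.last = "keep")
  out <- (r - 1) / (n_eff - 1)
  matrix(out, nrow = nrow(m), dimnames = dimnames(m))
}

#' Read a gene-by-sample TSV matrix
#'
#' Expects a header row of sample ids and gene ids in the first column.
#'
#' @param path TSV file path.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  m
}

#' Read a MAF-lite mutation table
#'
#' Accepts either the MAF-lite header (`Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, optional `Variant_Classification`) or plain
#' `gene` / `sample` columns.
#'
#' @param path TSV file path.
#' @param non_silent_only drop records classified `Silent` (default `FALSE`;
#'   most call sets arrive pre-filtered).
#' @return A `pshift_mutations` data.frame with columns `gene`, `sample`
#'   and (possibly `NA`) `variant`.
#' @export
read_mutations <- function(path, non_silent_only = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  gene_col <- intersect(c("Hugo_Symbol", "gene"), nm)[1]
  samp_col <- intersect(c("Tumor_Sample_Barcode", "sample"), nm)[1]
  if (is.na(gene_col) || is.na(samp_col))
    stop("mutation table needs Hugo_Symbol/gene and Tumor_Sample_Barcode/sample columns")
  var_col <- intersect(c("Variant_Classification", "variant"), nm)[1]
  out <- data.frame(gene = df[[gene_col]], sample = df[[samp_col]],
                    variant = if (!is.na(var_col)) df[[var_col]] else
                      NA_character_,
                    stringsAsFactors = FALSE)
  if (non_silent_only)
    out <- out[is.na(out$variant) | out$variant != "Silent", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pshift_mutations", "data.frame")
  out
}

#' Construct a mutation table in code
#' @param gene,sample character vectors of equal length.
#' @param variant optional variant annotations.
#' @return A `pshift_mutations` data.frame.
#' @export
mutation_table <- function(gene, sample, variant = NA_character_) {
  out <- data.frame(gene = as.character(gene), sample = as.character(sample),
                    variant = variant, stringsAsFactors = FALSE)
  class(out) <- c("pshift_mutations", "data.frame")
  out
}

#' Assemble a multi-omics dataset
#'
#' Applies the global rank-ratio transform to expression and copy number
#' separately (each data type is ranked on its own), intersects the sample
#' sets, and attaches mutation calls (records for samples outside the
#' intersection are dropped with a warning).
#'
#' @param expression raw gene-by-sample expression matrix.
#' @param copy_number raw gene-by-sample copy-number matrix (optional).
#' @param mutations a `pshift_mutations` table (optional).
#' @param transformed set `TRUE` if the matrices are already rank-ratios.
#' @return A `pshift_omics` object with elements `expression`,
#'   `copy_number`, `sample_ids`, `gene_ids`, `mutations`.
#' @export
omics_dataset <- function(expression, copy_number = NULL, mutations = NULL,
                          transformed = FALSE) {
  expression <- as.matrix(expression)
  samples <- colnames(expression)
  if (is.null(samples)) stop("expression matrix needs sample column names")
  if (!is.null(copy_number)) {
    copy_number <- as.matrix(copy_number)
    samples <- intersect(samples, colnames(copy_number))
    if (!length(samples))
      stop("no samples shared between expression and copy number")
    copy_number <- copy_number[, samples, drop = FALSE]
  }
  expression <- expression[, samples, drop = FALSE]
  if (!transformed) {
    expression <- rank_ratio_transform(expression)
    if (!is.null(copy_number)) copy_number <- rank_ratio_transform(copy_number)
  }
  if (!is.null(mutations)) {
    unknown <- !(mutations$sample %in% samples)
    if (any(unknown)) {
      warning(sum(unknown), " mutation record(s) in samples absent from the ",
              "dataset were dropped")
      mutations <- mutations[!unknown, , drop = FALSE]
    }
  }
  structure(list(expression = expression,
                 copy_number = copy_number,
                 sample_ids = samples,
                 gene_ids = rownames(expression),
                 mutations = mutations),
            class = "pshift_omics")
}

#' @export
print.pshift_omics <- function(x, ...) {
  cat(sprintf(
    "pshift omics dataset: %d genes x %d samples (expression%s), %d mutation records\n",
    length(x$gene_ids), length(x$sample_ids),
    if (is.null(x$copy_number)) "" else " + copy number",
    if (is.null(x$mutations)) 0L else nrow(x$mutations)))
  invisible(x)
}

# logical: which of `samples` carry a mutation in `gene`
mutated_in <- function(data, gene, samples = data$sample_ids) {
  if (is.null(data$mutations)) return(rep(FALSE, length(samples)))
  samples %in% data$mutations$sample[data$mutations$gene == gene]
}
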