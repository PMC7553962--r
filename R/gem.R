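#' Gene expression matrix (GEM) container
#'
#' A GEM bundles a genes-by-samples value matrix with optional sample
#' region labels and gene lengths.  Values may be on the linear
#' (TPM-like) scale or log2 scale depending on the preprocessing stage;
#' missing values are allowed.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples
#'   in columns (unique colnames).
#' @param labels Optional named character vector mapping every sample id
#'   to a region label.
#' @param gene_lengths Optional named numeric vector of gene lengths in bp.
#' @param scale Either `"linear"` or `"log2"`; bookkeeping only.
#' @return An object of class `gem`.
#' @export
gem <- function(values, labels = NULL, gene_lengths = NULL,
                scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g) > 0)
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s) > 0)
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  if (!is.null(labels)) {
    missing_lab <- setdiff(colnames(values), names(labels))
    if (length(missing_lab) > 0)
      stop("labels missing for sample(s): ",
           paste(head(missing_lab, 5), collapse = ", "), call. = FALSE)
    labels <- labels[colnames(values)]
  }
  structure(
    list(values = values, labels = labels, gene_lengths = gene_lengths,
         scale = scale),
    class = "gem")
}

#' @export
print.gem <- function(x, ...) {
  cat("<gem> ", nrow(x$values), " genes x ", ncol(x$values), " samples (",
      x$scale, " scale)\n", sep = "")
  if (!is.null(x$labels))
    cat("  regions: ", paste(names(table(x$labels)), collapse = ", "), "\n",
        sep = "")
  if (!is.null(x$gene_lengths))
    cat("  gene lengths: ", sum(!is.na(x$gene_lengths)), " genes\n", sep = "")
  invisible(x)
}

#' @export
dim.gem <- function(x) dim(x$values)

#' @rdname gem
#' @param x A `gem` object.
#' @param ... Unused.
#' @export
as_tibble.gem <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value")
}

#' Read / write a GEM as TSV
#'
#' The exchange format is tab-separated with the gene id in the first
#' column (header `gene`) and one column per sample; empty cells are
#' missing values.
#'
#' @param path File path.
#' @param labels,gene_lengths Optional paths to a labels TSV
#'   (`sample_id`, `region`) and gene-length TSV (`gene_id`, `length_bp`)
#'   attached to the returned object.
#' @return `read_gem()` returns a [gem]; `write_gem()` returns `path`
#'   invisibly.
#' @export
read_gem <- function(path, labels = NULL, gene_lengths = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    gene = readr::col_character()))
  prob <- readr::problems(df)
  if (nrow(prob) > 0)
    stop("malformed GEM file (", nrow(prob),
         " parsing problem(s), first at row ", prob$row[1],
         "): expected numeric cells and rectangular rows", call. = FALSE)
  if (names(df)[1] != "gene") names(df)[1] <- "gene"
  m <- as.matrix(df[-1])
  rownames(m) <- df$gene
  lab <- if (!is.null(labels)) read_labels(labels) else NULL
  gl <- if (!is.null(gene_lengths)) read_gene_lengths(gene_lengths) else NULL
  g <- gem(m, labels = lab, gene_lengths = gl)
  g
}

#' @rdname read_gem
#' @param x A `gem` object.
#' @export
write_gem <- function(x, path) {
  df <- tibble::as_tibble(x$values, rownames = "gene")
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' @rdname read_gem
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc")
  setNames(df[[2]], df[[1]])
}

#' @rdname read_gem
#' @param labels_named Named character vector (sample id -> region).
#' @export
write_labels <- function(labels_named, path) {
  readr::write_tsv(
    tibble::tibble(sample_id = names(labels_named), region = unname(labels_named)),
    path)
  invisible(path)
}

#' @rdname read_gem
#' @export
read_gene_lengths <- function(path) {
  df <- readr::read_tsv(path, col_types = "cd")
  setNames(df[[2]], df[[1]])
}

#' @rdname read_gem
#' @param lengths_named Named numeric vector (gene id -> length in bp).
#' @export
write_gene_lengths <- function(lengths_named, path) {
  readr::write_tsv(
    tibble::tibble(gene_id = names(lengths_named), length_bp = unname(lengths_named)),
    path)
  invisible(path)
}
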