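#' Gene-by-sample omics matrix
#'
#' The common currency of all stages: a numeric matrix with gene row names and
#' sample column names, tagged with the layer it carries
#' (`"expression_log10"`, `"methylation_beta"` or `"centered"`). Methylation
#' beta values are fractional methylation and must lie in \[0, 1\].
#'
#' @param values numeric matrix, genes in rows, samples in columns; complete
#'   (no missing values), with unique row and column names.
#' @param layer one of `"expression_log10"`, `"methylation_beta"`,
#'   `"centered"`.
#' @return the matrix with a `layer` attribute, validated.
#' @export
omics_matrix <- function(values,
                         layer = c("expression_log10", "methylation_beta",
                                   "centered")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("omics matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in omics matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in omics matrix")
  if (anyNA(values))
    stop("omics matrix contains missing values; impute or filter upstream")
  if (!all(is.finite(values)))
    stop("omics matrix contains non-finite values")
  if (layer == "methylation_beta" &&
      (min(values) < 0 || max(values) > 1))
    stop("methylation beta values must lie in [0, 1]")
  attr(values, "layer") <- layer
  values
}

omics_layer <- function(m) attr(m, "layer") %||% "expression_log10"

#' Read / write an omics matrix as TSV
#'
#' Tab-separated with a header row of sample ids; the first column holds
#' gene (or CpG) ids.
#'
#' @param path file path.
#' @param layer layer tag passed to [omics_matrix()].
#' @return `read_omics_tsv`: a validated omics matrix.
#' @export
read_omics_tsv <- function(path, layer = "expression_log10") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  omics_matrix(m, layer)
}

#' @rdname read_omics_tsv
#' @param m omics matrix.
#' @param id_col name for the identifier column.
#' @export
write_omics_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene annotation table
#'
#' @param gene_id character gene identifiers.
#' @param chromosome chromosome names (e.g. `"chr7"`, `"chrX"`).
#' @param tss 1-based transcription start sites.
#' @param strand `"+"` or `"-"`.
#' @return a validated `data.frame`.
#' @export
gene_annotation <- function(gene_id, chromosome, tss, strand) {
  ann <- data.frame(gene_id = as.character(gene_id),
                    chromosome = as.character(chromosome),
                    tss = as.integer(tss),
                    strand = as.character(strand),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids in annotation")
  if (any(ann$tss < 1L)) stop("tss must be >= 1 (1-based coordinates)")
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  ann
}

#' @rdname gene_annotation
#' @param path TSV with columns gene_id, chrom/chromosome, tss, strand.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  chrom <- df$chromosome %||% df$chrom
  gene_annotation(df$gene_id, chrom, df$tss, df$strand)
}

#' CpG methylation table
#'
#' Per-CpG beta values with genomic coordinates. Betas live in \[0, 1\];
#' missing betas are allowed here (they are dropped pairwise during promoter
#' aggregation).
#'
#' @param cpg_id,chromosome,position CpG identifiers and 1-based coordinates.
#' @param betas numeric matrix CpG x sample.
#' @return list with `info` (data.frame) and `betas` (matrix), class
#'   `cpg_table`.
#' @export
cpg_table <- function(cpg_id, chromosome, position, betas) {
  if (!is.matrix(betas)) stop("'betas' must be a matrix")
  if (length(cpg_id) != nrow(betas))
    stop("cpg_id length must match beta rows")
  rng <- range(betas, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("beta values must lie in [0, 1]")
  rownames(betas) <- as.character(cpg_id)
  structure(list(
    info = data.frame(cpg_id = as.character(cpg_id),
                      chromosome = as.character(chromosome),
                      position = as.integer(position),
                      stringsAsFactors = FALSE),
    betas = betas), class = "cpg_table")
}

#' @rdname cpg_table
#' @param path TSV with columns cpg_id, chrom, pos, then one column per sample.
#' @export
read_cpg_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  b <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(b) <- "double"
  cpg_table(df[[1L]], df[[2L]], df[[3L]], b)
}

#' @rdname cpg_table
#' @param x a `cpg_table`.
#' @export
write_cpg_tsv <- function(x, path) {
  df <- data.frame(x$info$cpg_id, x$info$chromosome, x$info$position,
                   x$betas, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("cpg_id", "chrom", "pos")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors (unique gene ids per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene id vectors.
#' @param description optional per-set description.
#' @export
write_gmt <- function(sets, path, description = names(sets)) {
  lines <- mapply(function(nm, ds, gg) paste(c(nm, ds, gg), collapse = "\t"),
                  names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with columns sample_id, subtype, age, sex (F/M), tlr, surv_time,
#' surv_event.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subtype", "age", "sex", "tlr",
            "surv_time", "surv_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  df
}
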