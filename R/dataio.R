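# Reading, merging and filtering of the three input sources (two IC50
# tables, a count matrix, a log TPM matrix) into one analysis-ready
# dataset keyed by shared cell-line ids.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a two-column IC50 table
#'
#' Expects a delimited file (comma for `.csv`, tab otherwise) with a
#' header and columns id, value. Empty fields and the sentinel tokens
#' `NA`, `NaN`, `` are treated as missing and dropped.
#'
#' @param path File path.
#' @return Data frame with columns `id` (character) and `ic50` (numeric).
#' @export
read_ic50 <- function(path) {
  df <- read.delim(path, sep = delim_for(path), header = TRUE,
                   stringsAsFactors = FALSE,
                   na.strings = c("", "NA", "NaN", "na"))
  if (ncol(df) < 2) stop("IC50 table must have two columns (id, value): ", path)
  out <- data.frame(id = as.character(df[[1]]),
                    ic50 = as.numeric(df[[2]]))
  out[!is.na(out$id) & !is.na(out$ic50), , drop = FALSE]
}

#' Read a gene x sample expression matrix
#'
#' Genes in rows (first column = gene id), header row of sample ids.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, sep = delim_for(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write a gene x sample matrix as delimited text
#'
#' @param m Matrix with gene rownames and sample colnames.
#' @param path Output path (comma-delimited for `.csv`, tab otherwise).
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = delim_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Merge IC50 and expression sources into one dataset
#'
#' Retains exactly the cell lines with non-missing values in all four
#' sources, in lexicographic id order, so the result is independent of
#' input file order. Idempotent: merging the output with itself changes
#' nothing.
#'
#' @param ic50_a,ic50_b Data frames `id`, `ic50` (or named numeric
#'   vectors).
#' @param counts Gene x sample count matrix.
#' @param log_tpm Gene x sample log10(TPM+1) matrix, same genes as
#'   `counts`.
#' @return An object of class `integrated_dataset`: list with
#'   `sample_ids`, `gene_ids`, `ic50_a`, `ic50_b` (named numeric vectors
#'   over `sample_ids`), `counts`, `log_tpm`.
#' @export
merge_cohort <- function(ic50_a, ic50_b, counts, log_tpm) {
  as_tab <- function(x, nm) {
    if (is.data.frame(x)) {
      v <- x[[2]]
      names(v) <- as.character(x[[1]])
    } else {
      v <- x
    }
    v <- v[!is.na(v) & is.finite(v)]
    if (anyDuplicated(names(v))) stop("duplicated ids in ", nm)
    v
  }
  a <- as_tab(ic50_a, "ic50_a")
  b <- as_tab(ic50_b, "ic50_b")
  if (!identical(rownames(counts), rownames(log_tpm))) {
    stop("counts and log_tpm must share the same gene rows")
  }
  expr_ok_a <- colnames(counts)[colSums(is.na(counts)) == 0]
  expr_ok_b <- colnames(log_tpm)[colSums(is.na(log_tpm)) == 0]
  common <- Reduce(intersect, list(names(a), names(b), expr_ok_a, expr_ok_b))
  if (length(common) == 0) {
    stop(sprintf(paste0("no cell lines shared by all sources ",
                        "(ic50_a: %d, ic50_b: %d, counts: %d, log_tpm: %d, ",
                        "overlap: 0)"),
                 length(a), length(b), ncol(counts), ncol(log_tpm)))
  }
  common <- sort(common)
  structure(list(sample_ids = common,
                 gene_ids = rownames(counts),
                 ic50_a = a[common],
                 ic50_b = b[common],
                 counts = counts[, common, drop = FALSE],
                 log_tpm = log_tpm[, common, drop = FALSE]),
            class = "integrated_dataset")
}

#' @export
print.integrated_dataset <- function(x, ...) {
  cat("Integrated pharmacogenomic dataset:",
      length(x$sample_ids), "cell lines x", length(x$gene_ids), "genes\n")
  invisible(x)
}

#' Remove low-expression genes
#'
#' Keeps genes whose total count across samples is at least `min_total`;
#' gene order is preserved.
#'
#' @param counts Nonnegative integer gene x sample matrix.
#' @param min_total Minimum row total (default 10).
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_total = 10) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Read a cohort named by a manifest file
#'
#' The manifest is a flat `key = value` (or `key: value`) text file with
#' keys `ic50_a`, `ic50_b`, `counts`, `log_tpm`; relative paths resolve
#' against the manifest's directory.
#'
#' @param path Manifest path.
#' @return An `integrated_dataset` (see [merge_cohort()]).
#' @export
read_cohort <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "[=:]", fixed = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  names(vals) <- keys
  need <- c("ic50_a", "ic50_b", "counts", "log_tpm")
  miss <- setdiff(need, keys)
  if (length(miss) > 0) stop("manifest missing keys: ", paste(miss, collapse = ", "))
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  merge_cohort(read_ic50(resolve(vals["ic50_a"])),
               read_ic50(resolve(vals["ic50_b"])),
               read_matrix(resolve(vals["counts"])),
               read_matrix(resolve(vals["log_tpm"])))
}
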