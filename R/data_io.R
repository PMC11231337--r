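#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of log2-scale abundances with
#' unique gene symbols as row names and unique sample identifiers as column
#' names. All values must be finite and the matrix must contain at least two
#' genes and two samples.
#'
#' @param mat numeric matrix, genes x samples.
#' @return The validated matrix, invisibly usable downstream.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must have gene row names and sample column names")
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("expression matrix must have at least 2 genes and 2 samples")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  if (!all(is.finite(mat)))
    stop("expression matrix contains non-finite values")
  mat
}

#' Read a gene x sample expression matrix
#'
#' Expects a delimited text file with gene identifiers in the first column
#' and sample identifiers in the header row. Values are log2-scale by
#' convention (log2 of a normalized quantity plus one); set
#' \code{log2_input = FALSE} to log2(x+1)-transform linear-scale input.
#'
#' @param path file path.
#' @param delimiter field delimiter, default tab.
#' @param log2_input logical; if \code{FALSE} the values are linear scale and
#'   are transformed with log2(x+1).
#' @return validated numeric matrix (genes x samples).
#' @export
read_expression <- function(path, delimiter = "\t", log2_input = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("expression file needs a gene column plus >= 1 sample column")
  genes <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) & !is.na(body[[j]]))
      stop(sprintf("non-numeric value in column '%s', row %d (gene '%s')",
                   names(body)[j], bad[1L], genes[bad[1L]]))
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- genes
  if (!log2_input) mat <- log2(mat + 1)
  validate_expression_matrix(mat)
}

#' Write an expression matrix as TSV
#'
#' @param mat validated expression matrix.
#' @param path output path.
#' @param delimiter field delimiter.
#' @export
write_expression <- function(mat, path, delimiter = "\t") {
  validate_expression_matrix(mat)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load gene sets from a GMT file
#'
#' Standard GMT dialect: one tab-separated line per set, fields are set name,
#' description, then gene symbols. Empty trailing fields are dropped;
#' duplicate genes within a line are removed with a warning.
#'
#' @param path file path.
#' @return named list of character vectors of gene symbols; descriptions are
#'   kept in the \code{"description"} attribute.
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT format error at line %d: fewer than 3 fields", i))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes in set '%s' deduplicated", fields[1L]))
      genes <- unique(genes)
    }
    if (length(genes) == 0L)
      stop(sprintf("GMT format error at line %d: set '%s' has no genes", i, fields[1L]))
    sets[[fields[1L]]] <- genes
    descs[fields[1L]] <- fields[2L]
  }
  attr(sets, "description") <- descs
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load a paired epithelial/mesenchymal EMT signature from GMT
#'
#' Looks up the two entries \code{<name>_EPI} and \code{<name>_MES}. Genes
#' shared between the two arms are removed from both with a warning so the
#' arms are disjoint.
#'
#' @param path GMT file path.
#' @param name signature base name.
#' @return object of class \code{emt_signature} with elements \code{name},
#'   \code{epithelial} and \code{mesenchymal}.
#' @export
load_emt_signature <- function(path, name) {
  sets <- load_gmt(path)
  epi_key <- paste0(name, "_EPI")
  mes_key <- paste0(name, "_MES")
  if (!epi_key %in% names(sets)) stop("GMT entry not found: ", epi_key)
  if (!mes_key %in% names(sets)) stop("GMT entry not found: ", mes_key)
  emt_signature(name, sets[[epi_key]], sets[[mes_key]])
}

#' Construct an EMT signature
#'
#' @param name signature name.
#' @param epithelial character vector of epithelial-arm gene symbols.
#' @param mesenchymal character vector of mesenchymal-arm gene symbols.
#' @return object of class \code{emt_signature}.
#' @export
emt_signature <- function(name, epithelial, mesenchymal) {
  epithelial <- unique(as.character(epithelial))
  mesenchymal <- unique(as.character(mesenchymal))
  shared <- intersect(epithelial, mesenchymal)
  if (length(shared) > 0L) {
    warning(sprintf("signature '%s': %d gene(s) in both arms removed from both: %s",
                    name, length(shared), paste(shared, collapse = ", ")))
    epithelial <- setdiff(epithelial, shared)
    mesenchymal <- setdiff(mesenchymal, shared)
  }
  if (length(epithelial) == 0L || length(mesenchymal) == 0L)
    stop("both signature arms must be non-empty")
  structure(list(name = name, epithelial = epithelial, mesenchymal = mesenchymal),
            class = "emt_signature")
}

#' @export
print.emt_signature <- function(x, ...) {
  cat(sprintf("EMT signature '%s': %d epithelial + %d mesenchymal = %d genes\n",
              x$name, length(x$epithelial), length(x$mesenchymal),
              length(x$epithelial) + length(x$mesenchymal)))
  invisible(x)
}

#' Split signature genes into present/missing against a matrix
#'
#' Matching is case-sensitive exact symbol match against the matrix row names.
#'
#' @param genes character vector of gene symbols.
#' @param mat expression matrix.
#' @return list with elements \code{present} and \code{missing}.
#' @export
resolve_genes <- function(genes, mat) {
  genes <- as.character(genes)
  present <- genes[genes %in% rownames(mat)]
  list(present = present, missing = setdiff(genes, present))
}

#' Path to a bundled signature fixture
#'
#' The bundled EMT and immune gene sets are synthetic placeholders that
#' reproduce the arm sizes of the published tumor-tissue (145 epithelial +
#' 170 mesenchymal) and cell-line (170 + 48) EMT signatures; see the files'
#' descriptions. They are seeded with canonical marker genes and padded with
#' clearly synthetic symbols.
#'
#' @param which one of \code{"emt"} or \code{"immune"}.
#' @return file path inside the installed package.
#' @export
bundled_signature_path <- function(which = c("emt", "immune")) {
  which <- match.arg(which)
  fn <- switch(which,
               emt = "emt_signatures_synthetic.gmt",
               immune = "immune_signatures_synthetic.gmt")
  path <- system.file("extdata", fn, package = "emtici")
  if (!nzchar(path)) stop("bundled fixture not found: ", fn)
  path
}

#' Read a cohort metadata table
#'
#' CSV with one row per sample. Recognized columns: \code{sample_id},
#' \code{pdl1_expr} (log2 CD274 expression), \code{pdl1_tps} (0-100),
#' \code{response} (CR/PR/SD/PD), \code{pfs_time}/\code{pfs_event},
#' \code{os_time}/\code{os_event}, and optional \code{hscore_<marker>}
#' columns (integer 0-300).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(df)
}

#' Validate a cohort metadata table
#'
#' @param df data.frame with a \code{sample_id} column.
#' @return the validated data.frame.
#' @export
validate_cohort <- function(df) {
  if (!"sample_id" %in% names(df)) stop("cohort table needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in cohort table")
  if ("response" %in% names(df)) {
    bad <- setdiff(stats::na.omit(unique(df$response)), c("CR", "PR", "SD", "PD"))
    if (length(bad) > 0L)
      stop("invalid response labels: ", paste(bad, collapse = ", "))
  }
  for (col in intersect(c("pfs_time", "os_time"), names(df)))
    if (any(df[[col]] < 0, na.rm = TRUE)) stop(col, " must be non-negative")
  for (col in intersect(c("pfs_event", "os_event"), names(df)))
    if (!all(df[[col]] %in% c(0, 1, NA))) stop(col, " must be 0/1")
  if ("pdl1_tps" %in% names(df) &&
      any(df$pdl1_tps < 0 | df$pdl1_tps > 100, na.rm = TRUE))
    stop("pdl1_tps must lie in [0, 100]")
  for (col in grep("^hscore_", names(df), value = TRUE))
    if (any(df[[col]] < 0 | df[[col]] > 300, na.rm = TRUE))
      stop(col, " must lie in [0, 300]")
  df
}
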