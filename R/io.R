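# Readers/writers for the formats the pipeline touches: Matrix Market
# expression triples with name sidecars, dense TSV matrices, tab-separated
# tables, plain key=value configs and serialized models.  All writes are
# atomic: content goes to a temporary file in the target directory which is
# renamed into place only on success.

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("failed to move temporary file into place for ", path, call. = FALSE)
  }
  invisible(path)
}

#' Write a tab-separated table atomically
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  atomic_write(path, function(tmp) {
    utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Read an expression matrix
#'
#' Two formats are supported: a dense tab-separated matrix with a header row
#' of gene names and a first column of cell ids, or a Matrix Market sparse
#' file with sidecar name files `<stem>.genes.txt` and `<stem>.cells.txt`
#' (one name per line).  Matrix Market dumps conventionally store genes as
#' rows; the orientation is normalized to cells x genes (`orientation =
#' "genes_x_cells"`, the default for `.mtx`, transposes on read).  Duplicate
#' names are deduplicated by suffixing (reported via a message).
#'
#' @param path matrix file path.
#' @param format `"auto"` (by extension), `"mtx"` or `"dense"`.
#' @param orientation for `.mtx` files, `"genes_x_cells"` (default) or
#'   `"cells_x_genes"`.
#' @return list with `matrix` (dense, cells x genes), `gene_names`,
#'   `cell_ids`.
#' @export
read_expression <- function(path, format = c("auto", "mtx", "dense"),
                            orientation = c("genes_x_cells",
                                            "cells_x_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    gfile <- paste0(stem, ".genes.txt")
    cfile <- paste0(stem, ".cells.txt")
    if (!file.exists(gfile) || !file.exists(cfile)) {
      stop("missing sidecar name file(s) for ", path, ": expected ",
           gfile, " and ", cfile, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gfile)
    cellids <- readLines(cfile)
    if (orientation == "genes_x_cells") m <- t(m)
    if (nrow(m) != length(cellids) || ncol(m) != length(genes)) {
      stop(path, ": matrix is ", nrow(m), " x ", ncol(m),
           " after orientation but sidecars name ", length(cellids),
           " cells and ", length(genes), " genes", call. = FALSE)
    }
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    cellids <- as.character(tab[[1]])
    genes <- names(tab)[-1]            # before as.matrix uniquifies them
    m <- as.matrix(tab[, -1, drop = FALSE])
  }
  genes <- dedup_names(genes, "gene")
  cellids <- dedup_names(cellids, "cell")
  dimnames(m) <- list(cellids, genes)
  list(matrix = m, gene_names = genes, cell_ids = cellids)
}

dedup_names <- function(x, what) {
  if (anyDuplicated(x)) {
    message("deduplicating ", sum(duplicated(x)), " ", what,
            " name(s) by suffixing")
    x <- make.unique(x, sep = ".")
  }
  x
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: Matrix Market triples (written genes x
#' cells by convention) with name sidecars, or a dense TSV.
#'
#' @param matrix cells x genes matrix.
#' @param gene_names,cell_ids dimension names.
#' @param path output path (`.mtx` selects Matrix Market).
#' @param orientation orientation of the written `.mtx` file.
#' @export
write_expression <- function(matrix, gene_names, cell_ids, path,
                             orientation = c("genes_x_cells",
                                             "cells_x_genes")) {
  orientation <- match.arg(orientation)
  if (grepl("\\.mtx$", path)) {
    m <- Matrix::Matrix(matrix, sparse = TRUE)
    if (orientation == "genes_x_cells") m <- Matrix::t(m)
    atomic_write(path, function(tmp) Matrix::writeMM(m, tmp))
    stem <- sub("\\.mtx$", "", path)
    atomic_write(paste0(stem, ".genes.txt"),
                 function(tmp) writeLines(gene_names, tmp))
    atomic_write(paste0(stem, ".cells.txt"),
                 function(tmp) writeLines(cell_ids, tmp))
  } else {
    df <- data.frame(cell_id = cell_ids, matrix, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("cell_id", gene_names)
    write_tsv(df, path)
  }
  invisible(path)
}

#' Write clonality assignments
#'
#' Tab-separated `cell_id`, `donor_id`, `label`, `malignancy_target`,
#' `dominant_alpha`, `dominant_beta`.
#'
#' @param assignments data.frame from [assign_clonality()].
#' @param path output path.
#' @export
write_assignments <- function(assignments, path) {
  write_tsv(assignments, path)
}

#' Write a long-format TCR table
#'
#' One row per recombinant, the format read back by [read_tcr_table()].
#'
#' @param cells a `cell_records` data.frame.
#' @param path output path.
#' @export
write_tcr_table <- function(cells, path) {
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    recs <- c(cells$alpha[[i]], cells$beta[[i]])
    if (!length(recs)) return(NULL)
    data.frame(cell_id = cells$cell_id[i], donor_id = cells$donor_id[i],
               tissue = cells$tissue[i],
               chain = c(rep("A", length(cells$alpha[[i]])),
                         rep("B", length(cells$beta[[i]]))),
               recombinant = recs, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are coerced to numeric or logical where possible; comma-separated
#' values become vectors.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_kv_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config line without '=': ", sQuote(ln), call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(toupper(parts) %in% c("TRUE", "FALSE")))
        as.logical(toupper(parts))
      else if (length(parts)) parts else val
  }
  out
}

#' Serialize a trained model
#'
#' Writes a single archive holding all parameter arrays plus dimensions, gene
#' names and the training config.
#'
#' @param model an `nnlogreg_model` or `standard_ann_model`.
#' @param path output path (`.rds`).
#' @export
write_model <- function(model, path) {
  atomic_write(path, function(tmp) saveRDS(model, tmp))
}

#' @rdname write_model
#' @param path path written by `write_model`.
#' @export
read_model <- function(path) readRDS(path)
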