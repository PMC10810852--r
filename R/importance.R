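# Feature importance from the adaptive weights: per correctly classified
# cell, the genes in the top fraction of its adaptive-weight vector are
# "important" for that cell; aggregation reports, per gene, the percentage of
# correctly classified cells for which this holds.

#' Cells the model classifies correctly
#'
#' @param model a trained `nnlogreg_model` (or any object with a `predict`
#'   method returning probabilities).
#' @param dataset a `labeled_dataset`.
#' @param threshold probability cut: predicted class is 1 when p > threshold.
#' @return character vector of the correctly classified cell ids.
#' @export
correctly_classified <- function(model, dataset, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  p <- predict(model, dataset)
  dataset$cell_ids[as.integer(p > threshold) == dataset$targets]
}

#' Top-fraction genes of one adaptive-weight vector
#'
#' The `k = ceiling(fraction * G)` genes with the largest adaptive weights;
#' ties at the cutoff are broken by gene (column) order so the result is
#' deterministic.
#'
#' @param weights numeric vector of length G (one cell's adaptive weights),
#'   named by gene, or unnamed with `gene_names` supplied.
#' @param fraction top fraction of genes to keep (default 0.005, i.e. the
#'   top 0.5 percent).
#' @param gene_names optional gene names when `weights` is unnamed.
#' @return character vector of the k selected gene names, in decreasing
#'   weight order.
#' @export
top_fraction_genes <- function(weights, fraction = 0.005, gene_names = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.null(gene_names)) gene_names <- names(weights)
  G <- length(weights)
  stopifnot(length(gene_names) == G)
  k <- ceiling(fraction * G)
  gene_names[order(-weights)[seq_len(k)]]   # order() breaks ties by position
}

#' Aggregate per-cell importance to per-gene percentages
#'
#' For every gene, the percentage of correctly classified cells whose
#' top-fraction adaptive-weight set contains it.  A value of 100 means the
#' gene is among the top `fraction` of genes for every correctly classified
#' cell.
#'
#' @param model a trained `nnlogreg_model`.
#' @param dataset a `labeled_dataset` (typically the training or the test
#'   split).
#' @param fraction per-cell top fraction (default 0.005).
#' @param threshold correct-classification probability cut.
#' @param set_tag label recorded with the summary (e.g. `"TRAIN"`/`"TEST"`).
#' @return object of class `importance_summary`: `per_gene_percent` (named
#'   numeric, percent of cells per gene), `n_cells` (number of correctly
#'   classified cells), `fraction`, `set_tag`, and `top_sets` (list of
#'   per-cell top gene sets, named by cell id).
#' @export
gene_importance <- function(model, dataset, fraction = 0.005,
                            threshold = 0.5, set_tag = "TRAIN") {
  keep <- correctly_classified(model, dataset, threshold)
  if (!length(keep)) {
    stop("no correctly classified cells; importance is undefined",
         call. = FALSE)
  }
  rows <- match(keep, dataset$cell_ids)
  X <- if (model$config$log1p) log1p(dataset$matrix) else dataset$matrix
  A <- hypernet_forward(model$params, X[rows, , drop = FALSE])
  top_sets <- lapply(seq_len(nrow(A)), function(i) {
    top_fraction_genes(A[i, ], fraction, gene_names = model$gene_names)
  })
  names(top_sets) <- keep
  tally <- table(factor(unlist(top_sets), levels = model$gene_names))
  pct <- stats::setNames(100 * as.numeric(tally) / length(keep),
                         model$gene_names)
  structure(list(per_gene_percent = pct, n_cells = length(keep),
                 fraction = fraction, set_tag = set_tag,
                 top_sets = top_sets),
            class = "importance_summary")
}

#' @export
print.importance_summary <- function(x, ...) {
  cat("importance_summary [", x$set_tag, "]: ", x$n_cells,
      " correctly classified cells, top fraction ", x$fraction, "\n", sep = "")
  top <- sort(x$per_gene_percent, decreasing = TRUE)
  top <- top[top > 0]
  print(utils::head(top, 10))
  invisible(x)
}

#' Significant genes from an importance summary
#'
#' Genes important (in the per-cell top fraction) for at least
#' `min_cell_fraction` of the correctly classified cells, ordered by
#' decreasing percentage.
#'
#' @param summary an `importance_summary`.
#' @param min_cell_fraction minimum fraction of cells (default 0.5).
#' @return named numeric vector: percentages, named by gene, in decreasing
#'   order; names are the significant-gene list.
#' @export
significant_genes <- function(summary, min_cell_fraction = 0.5) {
  stopifnot(min_cell_fraction > 0, min_cell_fraction <= 1)
  pct <- summary$per_gene_percent
  sel <- pct[pct >= 100 * min_cell_fraction]
  sel[order(-sel)]
}

#' Overlap of two significant-gene lists
#'
#' Intersection of (typically) the training- and test-set significant genes,
#' ordered by decreasing mean percentage across the two sets when both inputs
#' carry percentages.
#'
#' @param train_genes,test_genes named numeric vectors from
#'   [significant_genes()] (or bare character vectors).
#' @return character vector of the overlapping gene names.
#' @export
overlap_genes <- function(train_genes, test_genes) {
  a <- if (is.character(train_genes)) stats::setNames(rep(NA_real_,
        length(train_genes)), train_genes) else train_genes
  b <- if (is.character(test_genes)) stats::setNames(rep(NA_real_,
        length(test_genes)), test_genes) else test_genes
  common <- intersect(names(a), names(b))
  if (!length(common)) return(character(0))
  score <- (a[common] + b[common]) / 2
  if (anyNA(score)) common else common[order(-score)]
}

#' Tabulate train/test importance side by side
#'
#' @param train_summary,test_summary `importance_summary` objects for the
#'   training and test splits.
#' @param min_cell_fraction threshold passed to [significant_genes()].
#' @return data.frame with columns `gene`, `percent_train`, `percent_test`,
#'   `in_overlap`, covering every gene significant in either set.
#' @export
importance_table <- function(train_summary, test_summary,
                             min_cell_fraction = 0.5) {
  tr <- significant_genes(train_summary, min_cell_fraction)
  te <- significant_genes(test_summary, min_cell_fraction)
  ov <- overlap_genes(tr, te)
  genes <- union(names(tr), names(te))
  genes <- genes[order(-pmax(train_summary$per_gene_percent[genes],
                             test_summary$per_gene_percent[genes]))]
  data.frame(gene = genes,
             percent_train = unname(train_summary$per_gene_percent[genes]),
             percent_test = unname(test_summary$per_gene_percent[genes]),
             in_overlap = genes %in% ov,
             stringsAsFactors = FALSE)
}
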