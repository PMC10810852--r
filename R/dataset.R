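#' Labeled expression dataset
#'
#' Container for the classifier input: a cells x genes matrix of non-negative
#' normalized expression values (RPKM-style) with per-cell donor ids and 0/1
#' malignancy targets.
#'
#' @param matrix cells x genes numeric matrix, finite and non-negative.
#' @param gene_names character vector, one per column, unique.
#' @param cell_ids,donor_ids character vectors, one per row.
#' @param targets integer 0/1 vector, one per row (1 = clonal/malignant).
#' @return object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(matrix, gene_names, cell_ids, donor_ids, targets) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == length(gene_names),
            nrow(matrix) == length(cell_ids),
            nrow(matrix) == length(donor_ids),
            nrow(matrix) == length(targets))
  if (anyDuplicated(gene_names)) stop("gene_names must be unique")
  if (any(!is.finite(matrix)) || any(matrix < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  if (!all(targets %in% c(0L, 1L))) stop("targets must be 0/1")
  dimnames(matrix) <- list(as.character(cell_ids), gene_names)
  structure(list(matrix = matrix, gene_names = gene_names,
                 cell_ids = as.character(cell_ids),
                 donor_ids = as.character(donor_ids),
                 targets = as.integer(targets)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", length(x$cell_ids), "cells x",
      length(x$gene_names), "genes;",
      length(unique(x$donor_ids)), "donors;",
      sum(x$targets), "malignant /", sum(1 - x$targets), "bystander\n")
  invisible(x)
}

#' @export
`[.labeled_dataset` <- function(x, i) {
  labeled_dataset(x$matrix[i, , drop = FALSE], x$gene_names,
                  x$cell_ids[i], x$donor_ids[i], x$targets[i])
}

#' Drop TCR variable-region genes
#'
#' Clonality labels are derived from TCR sequences, so every gene belonging to
#' the variable parts of the TCR (names starting with `TRAV`, `TRAJ`, `TRBV`
#' or `TRBJ`, case-insensitively) is removed before training to avoid label
#' leakage.  Column order of the remaining genes is preserved.
#'
#' @param x a `labeled_dataset`, or a cells x genes matrix.
#' @param gene_names required when `x` is a bare matrix.
#' @return the same type as `x`, with TCR gene columns removed.
#' @export
exclude_tcr_genes <- function(x, gene_names = NULL) {
  if (inherits(x, "labeled_dataset")) {
    keep <- !is_tcr_gene(x$gene_names)
    return(labeled_dataset(x$matrix[, keep, drop = FALSE], x$gene_names[keep],
                           x$cell_ids, x$donor_ids, x$targets))
  }
  stopifnot(!is.null(gene_names), ncol(x) == length(gene_names))
  keep <- !is_tcr_gene(gene_names)
  list(matrix = x[, keep, drop = FALSE], gene_names = gene_names[keep])
}

is_tcr_gene <- function(gene_names) {
  grepl("^(TRAV|TRAJ|TRBV|TRBJ)", gene_names, ignore.case = TRUE)
}

#' Training configuration
#'
#' Collects every tunable of the NN-log-reg and standard-ANN training loops.
#' Cells are split by donor, not individually, so evaluation donors are never
#' seen during training.
#'
#' @param split named fractions `c(train=, validation=, test=)`, positive,
#'   summing to 1 (donors are partitioned at these proportions).
#' @param hidden hidden width(s): a single width for the hypernetwork (its
#'   three hidden layers share it) or a vector of layer widths for the
#'   standard ANN.
#' @param epochs maximum training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size rows per gradient step; `Inf` (default) = full batch.
#' @param patience early-stopping patience, in epochs without improvement of
#'   the validation loss; the returned parameters are those of the best
#'   validation epoch.
#' @param seed integer seed fixing initialization, donor shuffling and any
#'   batch shuffling.
#' @param log1p if `TRUE`, apply `log1p` to expression values before the
#'   model sees them (off by default; values are used as given).
#' @param clamp probability clamp for the cross-entropy loss.
#' @param attention_l1 sparsity of the attention logits during NN-log-reg
#'   training, as a fraction of the largest standardized logit gradient at
#'   initialization (0 disables the penalty; see [nn_logreg_train()]).
#' @param gain_release number of initial epochs during which the head gain
#'   `w_D` is held fixed while attention forms.
#' @return list of class `train_config`.
#' @export
train_config <- function(split = c(train = 0.6, validation = 0.2, test = 0.2),
                         hidden = 1000L, epochs = 500L, learning_rate = 1e-2,
                         batch_size = Inf, patience = 50L, seed = 1L,
                         log1p = FALSE, clamp = 1e-12, attention_l1 = 0.3,
                         gain_release = 200L) {
  stopifnot(length(split) == 3L, all(split > 0), abs(sum(split) - 1) < 1e-8,
            epochs >= 1L, learning_rate > 0, patience >= 1L,
            attention_l1 >= 0, gain_release >= 0L)
  structure(list(split = split, hidden = hidden, epochs = as.integer(epochs),
                 learning_rate = learning_rate, batch_size = batch_size,
                 patience = as.integer(patience), seed = as.integer(seed),
                 log1p = isTRUE(log1p), clamp = clamp,
                 attention_l1 = attention_l1,
                 gain_release = as.integer(gain_release)),
            class = "train_config")
}

#' Split a dataset into train/validation/test by donor
#'
#' Whole donors, never individual cells, are assigned to the three splits so
#' that the test set consists of cells from donors unseen during training and
#' validation.  Donor order is shuffled with the config seed; the number of
#' test and validation donors is `max(1, round(fraction * n_donors))` each,
#' the remainder trains.
#'
#' @param dataset a `labeled_dataset`.
#' @param config a [train_config()] (uses `split` and `seed`).
#' @return list with `labeled_dataset` elements `train`, `validation`,
#'   `test`, and `donors`, a list of the donor ids per split.
#' @export
split_by_donor <- function(dataset, config = train_config()) {
  donors <- sort(unique(dataset$donor_ids))
  if (length(donors) < 3L) {
    stop("need at least 3 donors to split by donor; got ", length(donors),
         call. = FALSE)
  }
  ord <- local_seed(config$seed, sample(donors))
  n <- length(donors)
  n_test <- max(1L, round(config$split[["test"]] * n))
  n_val <- max(1L, round(config$split[["validation"]] * n))
  if (n_test + n_val >= n) stop("split leaves no training donor", call. = FALSE)
  assign <- list(test = ord[seq_len(n_test)],
                 validation = ord[n_test + seq_len(n_val)],
                 train = ord[(n_test + n_val + 1L):n])
  pick <- function(ds, who) ds[ds$donor_ids %in% who]
  list(train = pick(dataset, assign$train),
       validation = pick(dataset, assign$validation),
       test = pick(dataset, assign$test),
       donors = assign[c("train", "validation", "test")])
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
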