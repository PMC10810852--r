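#' Clonality label levels
#'
#' Order matters: labels are assigned in this priority within each donor.
#' @keywords internal
clonality_levels <- c("MAIN_CLONE", "RELATED_TO_MAIN_CLONE",
                      "BYSTANDER_GROUP", "SINGLE_BYSTANDER", "EXCLUDED")

#' Admit cells to the clonality / classification analysis
#'
#' A cell enters the analysis only if at least one TCR chain was reconstructed
#' for it and it does not carry the CD8 phenotype (the malignant clone in
#' mycosis fungoides is CD4+; CD8 cells are removed up front).  The CD8 rule
#' is either the `cd8_positive` metadata flag or, when an expression matrix is
#' supplied, a threshold on summed CD8A + CD8B normalized expression.
#'
#' @param cells a `cell_records` data.frame (see [cell_records()]).
#' @param expr optional cells x genes expression matrix with rownames matching
#'   `cells$cell_id`; when given, CD8 status is derived from expression
#'   instead of the metadata flag.
#' @param cd8_genes gene names summed for the expression rule.
#' @param cd8_threshold a cell with summed CD8 expression strictly above this
#'   value is treated as CD8-positive (default 1.0 normalized units).
#' @return the admitted subset of `cells`, original order preserved.
#' @export
admit_cells <- function(cells, expr = NULL, cd8_genes = c("CD8A", "CD8B"),
                        cd8_threshold = 1.0) {
  has_chain <- vapply(seq_len(nrow(cells)), function(i) {
    length(cells$alpha[[i]]) + length(cells$beta[[i]]) > 0L
  }, logical(1))
  if (is.null(expr)) {
    cd8 <- cells$cd8_positive
  } else {
    cols <- intersect(cd8_genes, colnames(expr))
    tot <- if (length(cols)) {
      rowSums(expr[match(cells$cell_id, rownames(expr)), cols, drop = FALSE])
    } else rep(0, nrow(cells))
    cd8 <- tot > cd8_threshold
  }
  out <- cells[has_chain & !cd8, , drop = FALSE]
  class(out) <- c("cell_records", "data.frame")
  out
}

pair_key <- function(alpha, beta) paste(alpha, beta, sep = "\t")

#' Find a donor's dominant alpha/beta chain combination
#'
#' The largest group of a donor's cells sharing the same combination of alpha
#' and beta chains defines the (putatively malignant) main clone.  A cell
#' carrying several recombinants per chain contributes every distinct
#' alpha x beta pair it carries.  Ties are broken by the pair's total
#' single-chain support (number of the donor's cells carrying the alpha or
#' the beta), then lexicographically, so the result is deterministic and
#' independent of input order.
#'
#' @param cells admitted `cell_records`.
#' @param donor_id donor to analyse.
#' @return named character vector `c(alpha = ..., beta = ...)`.
#' @export
dominant_pair <- function(cells, donor_id) {
  d <- cells[cells$donor_id == donor_id, , drop = FALSE]
  pairs <- character(0)
  for (i in seq_len(nrow(d))) {
    a <- d$alpha[[i]]; b <- d$beta[[i]]
    if (length(a) && length(b)) {
      pairs <- c(pairs, pair_key(rep(a, each = length(b)), rep(b, length(a))))
    }
  }
  if (!length(pairs)) {
    stop("no dominant pair: no cell of donor ", sQuote(donor_id),
         " carries both an alpha and a beta chain", call. = FALSE)
  }
  counts <- table(pairs)
  cand <- names(counts)[counts == max(counts)]
  if (length(cand) > 1L) {
    support <- vapply(cand, function(k) {
      ab <- strsplit(k, "\t", fixed = TRUE)[[1]]
      sum(vapply(seq_len(nrow(d)), function(i) {
        ab[1] %in% d$alpha[[i]] || ab[2] %in% d$beta[[i]]
      }, logical(1)))
    }, numeric(1))
    cand <- cand[support == max(support)]
    cand <- sort(cand)[1]
  }
  ab <- strsplit(cand, "\t", fixed = TRUE)[[1]]
  c(alpha = ab[1], beta = ab[2])
}

#' Partition a donor's T cells by clonality
#'
#' For each donor independently, admitted cells are labeled in four groups:
#'
#' 1. `MAIN_CLONE` - cells carrying the dominant alpha or the dominant beta
#'    chain (see [dominant_pair()]).
#' 2. `RELATED_TO_MAIN_CLONE` - remaining cells with at least one chain
#'    associated with the main clone through chain co-occurrence: an
#'    undirected graph joins two recombinant identifiers whenever they occur
#'    in the same cell, and a chain is "associated" if it lies in the
#'    connected component of the dominant chains (`related = "transitive"`,
#'    the default) or is directly adjacent to a dominant chain
#'    (`related = "one-step"`).
#' 3. `BYSTANDER_GROUP` - remaining cells in a group of at least two cells
#'    with an identical (alpha-set, beta-set) signature.
#' 4. `SINGLE_BYSTANDER` - all remaining cells (in typical repertoires these
#'    share no chain with any other cell of the donor).
#'
#' Malignancy targets are 1 for the two clone-linked labels and 0 for the two
#' bystander labels.  A donor in which no cell carries both chains has no
#' dominant pair; its cells are labeled through steps 3-4 only.
#'
#' @param cells admitted `cell_records` (use [admit_cells()] first).
#' @param related `"transitive"` or `"one-step"` association rule.
#' @return data.frame with columns `cell_id`, `donor_id`, `label` (factor),
#'   `malignancy_target`, `dominant_alpha`, `dominant_beta` (NA when the donor
#'   has no dominant pair), one row per input cell, in input order.
#' @export
assign_clonality <- function(cells, related = c("transitive", "one-step")) {
  related <- match.arg(related)
  res <- lapply(unique(cells$donor_id), function(don) {
    assign_clonality_donor(cells[cells$donor_id == don, , drop = FALSE], related)
  })
  out <- do.call(rbind, res)
  out <- out[match(cells$cell_id, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

assign_clonality_donor <- function(d, related) {
  n <- nrow(d)
  chains <- lapply(seq_len(n), function(i) c(d$alpha[[i]], d$beta[[i]]))
  if (any(lengths(chains) == 0L)) {
    stop("cell(s) without any reconstructed chain passed to assign_clonality; ",
         "run admit_cells() first", call. = FALSE)
  }
  label <- rep(NA_character_, n)

  dom <- tryCatch(dominant_pair(d, d$donor_id[1]), error = function(e) NULL)
  if (!is.null(dom)) {
    is_mc <- vapply(seq_len(n), function(i) {
      dom[["alpha"]] %in% d$alpha[[i]] || dom[["beta"]] %in% d$beta[[i]]
    }, logical(1))
    label[is_mc] <- "MAIN_CLONE"

    assoc <- associated_chains(chains, dom, related)
    is_rel <- !is_mc & vapply(chains, function(ch) any(ch %in% assoc), logical(1))
    label[is_rel] <- "RELATED_TO_MAIN_CLONE"
  }

  rest <- which(is.na(label))
  sig <- vapply(rest, function(i) {
    paste(paste(d$alpha[[i]], collapse = ","),
          paste(d$beta[[i]], collapse = ","), sep = "|")
  }, character(1))
  grp <- rest[sig %in% names(which(table(sig) >= 2L))]
  label[grp] <- "BYSTANDER_GROUP"
  label[is.na(label)] <- "SINGLE_BYSTANDER"

  data.frame(cell_id = d$cell_id, donor_id = d$donor_id,
             label = factor(label, levels = clonality_levels),
             malignancy_target =
               as.integer(label %in% c("MAIN_CLONE", "RELATED_TO_MAIN_CLONE")),
             dominant_alpha = if (is.null(dom)) NA_character_ else dom[["alpha"]],
             dominant_beta = if (is.null(dom)) NA_character_ else dom[["beta"]],
             stringsAsFactors = FALSE)
}

# Chains associated with the dominant pair in the co-occurrence graph.
associated_chains <- function(chains, dom, related) {
  edges <- unlist(lapply(chains, function(ch) {
    ch <- unique(ch)
    if (length(ch) < 2L) return(NULL)
    cmb <- utils::combn(ch, 2L)
    as.vector(cmb)
  }))
  verts <- unique(c(unlist(chains), dom))
  g <- igraph::make_graph(edges = match(edges, verts), n = length(verts),
                          directed = FALSE)
  if (related == "transitive") {
    comp <- igraph::components(g)
    keep <- comp$membership %in%
      comp$membership[match(c(dom[["alpha"]], dom[["beta"]]), verts)]
    verts[keep]
  } else {
    nb <- unlist(igraph::adjacent_vertices(
      g, match(c(dom[["alpha"]], dom[["beta"]]), verts)))
    unique(c(dom, verts[nb]))
  }
}

#' Fractions of cells per clonality label
#'
#' @param assignments data.frame from [assign_clonality()] (rows labeled
#'   `EXCLUDED` are ignored).
#' @return named numeric vector over the four clonality labels, summing to 1.
#' @export
clonality_fractions <- function(assignments) {
  lab <- assignments$label[assignments$label != "EXCLUDED"]
  if (!length(lab)) stop("no non-excluded assignments", call. = FALSE)
  tab <- table(factor(lab, levels = clonality_levels[1:4]))
  fr <- as.numeric(tab) / length(lab)
  names(fr) <- names(tab)
  fr
}
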