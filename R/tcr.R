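#' Parse a reconstructed TCR recombinant identifier
#'
#' Recombinants reconstructed from single-cell reads are identified by the
#' canonical string `"<V locus>_<junction sequence>_<J locus>"`, where the
#' gene loci are given by their names (e.g. `TRBV20-1`) and the junction is a
#' short nucleotide sequence.  Locus names never contain an underscore, so the
#' junction is everything between the first and the last underscore-delimited
#' segment.
#'
#' @param identifier character vector of recombinant identifiers.
#' @return A data.frame with columns `v_locus`, `junction`, `j_locus`,
#'   `chain` (`"ALPHA"` or `"BETA"`, inferred from the `TRAV`/`TRAJ` vs
#'   `TRBV`/`TRBJ` locus prefixes) and `identifier`.
#' @examples
#' parse_recombinant("TRBV20-1_TGTAGC_TRBJ2-7")
#' @seealso [format_recombinant()], [recombinant_chain()]
#' @export
parse_recombinant <- function(identifier) {
  stopifnot(is.character(identifier))
  parts <- strsplit(identifier, "_", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 3L || any(!nzchar(p)), logical(1))
  if (any(bad)) {
    stop("malformed recombinant identifier(s): ",
         paste(sQuote(identifier[bad]), collapse = ", "),
         " (expected '<V locus>_<junction>_<J locus>')", call. = FALSE)
  }
  v <- vapply(parts, `[`, character(1), 1L)
  j <- vapply(parts, function(p) p[length(p)], character(1))
  junction <- vapply(parts, function(p) {
    paste(p[2:(length(p) - 1L)], collapse = "_")
  }, character(1))
  badj <- grepl("[^ACGTN]", junction)
  if (any(badj)) {
    stop("junction sequence of ", paste(sQuote(identifier[badj]), collapse = ", "),
         " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  data.frame(v_locus = v, junction = junction, j_locus = j,
             chain = recombinant_chain(v, j),
             identifier = identifier, stringsAsFactors = FALSE)
}

#' Format a TCR recombinant back into its canonical identifier
#'
#' Inverse of [parse_recombinant()]: `format_recombinant(parse_recombinant(x))`
#' returns `x`.
#'
#' @param rec a data.frame with columns `v_locus`, `junction`, `j_locus` (as
#'   returned by [parse_recombinant()]).
#' @return character vector of identifiers.
#' @export
format_recombinant <- function(rec) {
  paste(rec$v_locus, rec$junction, rec$j_locus, sep = "_")
}

#' Infer TCR chain from locus names
#'
#' Alpha-chain recombinants use `TRAV`/`TRAJ` loci, beta-chain recombinants
#' `TRBV`/`TRBJ`.
#'
#' @param v_locus,j_locus character vectors of locus names.
#' @return character vector, `"ALPHA"` or `"BETA"`.
#' @export
recombinant_chain <- function(v_locus, j_locus) {
  from_v <- ifelse(startsWith(v_locus, "TRAV"), "ALPHA",
            ifelse(startsWith(v_locus, "TRBV"), "BETA", NA_character_))
  from_j <- ifelse(startsWith(j_locus, "TRAJ"), "ALPHA",
            ifelse(startsWith(j_locus, "TRBJ"), "BETA", NA_character_))
  chain <- ifelse(is.na(from_v), from_j, from_v)
  disagree <- !is.na(from_v) & !is.na(from_j) & from_v != from_j
  if (any(disagree)) {
    stop("V and J loci disagree on chain for: ",
         paste(paste(v_locus[disagree], j_locus[disagree], sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(chain)) {
    stop("cannot infer chain from locus names: ",
         paste(paste(v_locus[is.na(chain)], j_locus[is.na(chain)], sep = "/"),
               collapse = ", "), call. = FALSE)
  }
  chain
}

#' Read a long-format TCR recombinant table
#'
#' The on-disk interchange format is tab-separated with a header and one row
#' per reconstructed recombinant: columns `cell_id`, `donor_id`, `tissue`,
#' `chain` (`A` or `B`) and `recombinant` (the canonical underscore
#' identifier).
#'
#' @param path path to the TSV file.
#' @return data.frame with the five columns above; `chain` normalized to
#'   `"ALPHA"`/`"BETA"` and checked against the locus prefixes.
#' @export
read_tcr_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "donor_id", "tissue", "chain", "recombinant")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("TCR table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  chain <- toupper(tab$chain)
  chain[chain == "A"] <- "ALPHA"
  chain[chain == "B"] <- "BETA"
  if (!all(chain %in% c("ALPHA", "BETA"))) {
    stop("chain column must be A/B (or ALPHA/BETA)", call. = FALSE)
  }
  parsed <- parse_recombinant(tab$recombinant)
  if (!all(parsed$chain == chain)) {
    k <- which(parsed$chain != chain)[1]
    stop("chain column disagrees with locus prefixes for ",
         sQuote(tab$recombinant[k]), call. = FALSE)
  }
  tab$chain <- chain
  tab[need]
}

#' Assemble per-cell records from a long TCR table
#'
#' Collapses one-row-per-recombinant data into one record per cell, with the
#' cell's sets of alpha and beta recombinant identifiers as list columns.
#' Cells present in `meta` but absent from `tcr` get empty chain sets (they
#' are the non-TCR-reconstructed cells later removed by [admit_cells()]).
#'
#' @param tcr long-format data.frame as returned by [read_tcr_table()].
#' @param meta optional per-cell metadata data.frame with columns `cell_id`
#'   and any of `donor_id`, `tissue`, `cd8_positive`.  When `NULL`, donor and
#'   tissue are taken from `tcr` and `cd8_positive` defaults to `FALSE`.
#' @return a `cell_records` data.frame with columns `cell_id`, `donor_id`,
#'   `tissue`, `cd8_positive` and list columns `alpha`, `beta` (character
#'   vectors of recombinant identifiers, duplicates removed).
#' @export
cell_records <- function(tcr, meta = NULL) {
  if (is.null(meta)) {
    meta <- unique(tcr[c("cell_id", "donor_id", "tissue")])
    if (anyDuplicated(meta$cell_id)) {
      stop("inconsistent donor_id/tissue for one cell_id in TCR table",
           call. = FALSE)
    }
    meta$cd8_positive <- FALSE
  } else {
    if (!"cell_id" %in% names(meta)) stop("meta needs a cell_id column")
    if (anyDuplicated(meta$cell_id)) stop("duplicated cell_id in meta")
    if (!"cd8_positive" %in% names(meta)) meta$cd8_positive <- FALSE
    if (!"tissue" %in% names(meta)) meta$tissue <- "OTHER"
    if (!"donor_id" %in% names(meta)) {
      don <- unique(tcr[c("cell_id", "donor_id")])
      meta$donor_id <- don$donor_id[match(meta$cell_id, don$cell_id)]
    }
  }
  extra <- setdiff(tcr$cell_id, meta$cell_id)
  if (length(extra)) {
    stop("TCR rows for cell(s) absent from metadata: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  pick <- function(chain) {
    sub <- tcr[tcr$chain == chain, c("cell_id", "recombinant")]
    sets <- split(sub$recombinant, factor(sub$cell_id, levels = meta$cell_id))
    lapply(sets, function(x) sort(unique(x)))
  }
  out <- data.frame(cell_id = meta$cell_id,
                    donor_id = as.character(meta$donor_id),
                    tissue = as.character(meta$tissue),
                    cd8_positive = as.logical(meta$cd8_positive),
                    stringsAsFactors = FALSE)
  out$alpha <- unname(pick("ALPHA"))
  out$beta <- unname(pick("BETA"))
  class(out) <- c("cell_records", "data.frame")
  out
}

#' Build cell records directly from chain sets
#'
#' Programmatic constructor used by the simulator and in tests; takes the
#' chain identifier sets as list columns instead of a long table.
#'
#' @param cell_id,donor_id character vectors.
#' @param alpha,beta lists of character vectors of recombinant identifiers.
#' @param tissue,cd8_positive optional per-cell annotations.
#' @return a `cell_records` data.frame (see [cell_records()]).
#' @export
new_cell_records <- function(cell_id, donor_id, alpha, beta,
                             tissue = "SKIN", cd8_positive = FALSE) {
  n <- length(cell_id)
  donor_id <- rep_len(as.character(donor_id), n)
  stopifnot(length(alpha) == n, length(beta) == n)
  if (anyDuplicated(cell_id)) stop("cell_id must be unique")
  out <- data.frame(cell_id = as.character(cell_id),
                    donor_id = as.character(donor_id),
                    tissue = rep_len(as.character(tissue), n),
                    cd8_positive = rep_len(as.logical(cd8_positive), n),
                    stringsAsFactors = FALSE)
  out$alpha <- lapply(alpha, function(x) sort(unique(as.character(x))))
  out$beta <- lapply(beta, function(x) sort(unique(as.character(x))))
  class(out) <- c("cell_records", "data.frame")
  out
}
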