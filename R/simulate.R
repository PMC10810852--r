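# Synthetic generator: TCR repertoires with planted clonal structure and
# matched expression with planted malignancy markers.  Everything is seeded;
# the planted labels are constructed so that assign_clonality() recovers them
# exactly (dominant pair strictly most frequent, related cells bridged to it
# through shared chains, bystander groups with duplicated signatures, single
# bystanders with globally unique chains).

#' Simulation configuration
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: 5 donors of 100 skin T cells, clonality fractions echoing a
#' dominant malignant clone with a minority of bystanders, 2,000 genes of
#' which 10 are informative at a 2-fold effect (half up-, half down-shifted,
#' echoing an MHC-I-up / IL7R-down style malignancy signature), negative
#' binomial counts with dropout, plus decoy TCR-named genes to exercise the
#' TCR-gene exclusion.
#'
#' @param n_donors number of donors.
#' @param cells_per_donor admitted cells per donor.
#' @param fractions named fractions over the four clonality labels
#'   (`main`, `related`, `group`, `single`), summing to 1.
#' @param n_genes number of non-TCR genes.
#' @param n_informative number of informative (malignancy-associated) genes.
#' @param effect_log2 signed log2 effect per informative gene, recycled to
#'   `n_informative`; default half +1 (2-fold up in malignant cells) and half
#'   -1 (2-fold down).
#' @param nb_mean average negative-binomial baseline mean per gene (per-gene
#'   means vary log-normally around it, sdlog 0.5).
#' @param nb_dispersion negative-binomial size parameter.
#' @param dropout probability that an entry is zeroed (technical dropout).
#' @param n_decoy_tcr number of extra TCR-named decoy genes appended to the
#'   matrix.
#' @param junction_length nucleotides per simulated junction sequence.
#' @param seed integer seed fixing every draw.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 5L, cells_per_donor = 100L,
                       fractions = c(main = 0.6, related = 0.15,
                                     group = 0.1, single = 0.15),
                       n_genes = 2000L, n_informative = 10L,
                       effect_log2 = NULL, nb_mean = 20, nb_dispersion = 5,
                       dropout = 0.1, n_decoy_tcr = 12L,
                       junction_length = 12L, seed = 1L) {
  stopifnot(length(fractions) == 4L, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8,
            n_donors >= 1L, cells_per_donor >= 1L,
            n_informative <= n_genes, nb_mean > 0, nb_dispersion > 0,
            dropout >= 0, dropout < 1)
  names(fractions) <- c("main", "related", "group", "single")
  if (is.null(effect_log2)) {
    n_up <- ceiling(n_informative / 2)
    effect_log2 <- c(rep(1, n_up), rep(-1, n_informative - n_up))
  }
  effect_log2 <- rep_len(effect_log2, n_informative)
  structure(list(n_donors = as.integer(n_donors),
                 cells_per_donor = as.integer(cells_per_donor),
                 fractions = fractions, n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 effect_log2 = effect_log2, nb_mean = nb_mean,
                 nb_dispersion = nb_dispersion, dropout = dropout,
                 n_decoy_tcr = as.integer(n_decoy_tcr),
                 junction_length = as.integer(junction_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Fresh recombinant identifiers with realistic locus names and random
# junctions; an environment tracks used identifiers so every draw is unique.
make_chain_factory <- function(junction_length) {
  used <- new.env(parent = emptyenv())
  trav <- paste0("TRAV", 1:40)
  traj <- paste0("TRAJ", 1:58)
  trbv <- c(paste0("TRBV", 1:30),
            paste0("TRBV", rep(c(4, 6, 7, 20), each = 3), "-", 1:3))
  trbj <- paste0("TRBJ", rep(1:2, each = 7), "-", 1:7)
  function(chain) {
    repeat {
      v <- if (chain == "ALPHA") sample(trav, 1) else sample(trbv, 1)
      j <- if (chain == "ALPHA") sample(traj, 1) else sample(trbj, 1)
      junc <- paste(sample(c("A", "C", "G", "T"), junction_length,
                           replace = TRUE), collapse = "")
      id <- paste(v, junc, j, sep = "_")
      if (is.null(used[[id]])) {
        used[[id]] <- TRUE
        return(id)
      }
    }
  }
}

label_counts <- function(n, fractions) {
  raw <- fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  cnt <- as.integer(cnt)
  names(cnt) <- names(fractions)
  cnt
}

#' Simulate TCR repertoires with planted clonal structure
#'
#' Per donor: the main clone carries a dominant (alpha1, beta1) pair, with a
#' minority of main-clone cells pairing a dominant chain with a fresh
#' partner; related cells carry a fresh chain plus one of those partner
#' chains (one co-occurrence step from the dominant pair); bystander groups
#' come in duplicated exact chain-set signatures of size 2-3; single
#' bystanders carry globally unique chains (cycling through
#' alpha+beta, alpha-only and beta-only cells).  [assign_clonality()] applied
#' to the output reproduces the planted labels exactly.
#'
#' @param config a [sim_config()].
#' @return list with `cells` (a `cell_records` data.frame) and `truth`, a
#'   list holding `labels` (data.frame `cell_id`, `donor_id`, `label`,
#'   `malignancy_target`) and `dominant` (data.frame `donor_id`, `alpha`,
#'   `beta`).
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    fresh <- make_chain_factory(config$junction_length)
    cells <- list(); labels <- list(); dominants <- list()
    for (don in seq_len(config$n_donors)) {
      donor_id <- sprintf("donor%02d", don)
      cnt <- label_counts(config$cells_per_donor, config$fractions)
      if (cnt[["group"]] == 1L) {
        stop("infeasible fractions: a bystander group needs at least 2 cells ",
             "(donor ", donor_id, " got 1); adjust fractions or cell count",
             call. = FALSE)
      }
      if (cnt[["related"]] > 0L && cnt[["main"]] < 3L) {
        stop("infeasible fractions: related-to-main-clone cells require a ",
             "main clone of at least 3 cells", call. = FALSE)
      }
      alpha <- list(); beta <- list(); lab <- character(0)

      bridges <- character(0)
      if (cnt[["main"]] > 0L) {
        a1 <- fresh("ALPHA"); b1 <- fresh("BETA")
        dominants[[donor_id]] <- c(alpha = a1, beta = b1)
        n_mc <- cnt[["main"]]
        # variant main-clone cells pair a dominant chain with a fresh partner
        n_var <- min(n_mc - 1L, floor(0.3 * n_mc))
        if (cnt[["related"]] > 0L) n_var <- max(1L, n_var)
        n_exact <- n_mc - n_var
        if (cnt[["group"]] > 0L && n_exact < 4L) {
          stop("infeasible fractions: the exact dominant pair must outnumber ",
               "every bystander group (donor ", donor_id, ")", call. = FALSE)
        }
        for (i in seq_len(n_exact)) {
          alpha <- c(alpha, list(a1)); beta <- c(beta, list(b1))
        }
        for (i in seq_len(n_var)) {
          if (i %% 2L == 1L) {           # alpha1 with a fresh beta partner
            bpart <- fresh("BETA"); bridges <- c(bridges, bpart)
            alpha <- c(alpha, list(a1)); beta <- c(beta, list(bpart))
          } else {                       # fresh alpha partner with beta1
            apart <- fresh("ALPHA"); bridges <- c(bridges, apart)
            alpha <- c(alpha, list(apart)); beta <- c(beta, list(b1))
          }
        }
        lab <- c(lab, rep("MAIN_CLONE", n_mc))
      }

      if (cnt[["related"]] > 0L) {
        for (i in seq_len(cnt[["related"]])) {
          bridge <- bridges[1L + (i - 1L) %% length(bridges)]
          if (startsWith(bridge, "TRAV")) {
            alpha <- c(alpha, list(bridge)); beta <- c(beta, list(fresh("BETA")))
          } else {
            alpha <- c(alpha, list(fresh("ALPHA"))); beta <- c(beta, list(bridge))
          }
        }
        lab <- c(lab, rep("RELATED_TO_MAIN_CLONE", cnt[["related"]]))
      }

      n_bg <- cnt[["group"]]
      while (n_bg > 0L) {
        size <- if (n_bg %in% c(2L, 3L)) n_bg else 2L
        ga <- fresh("ALPHA"); gb <- fresh("BETA")
        for (i in seq_len(size)) {
          alpha <- c(alpha, list(ga)); beta <- c(beta, list(gb))
        }
        lab <- c(lab, rep("BYSTANDER_GROUP", size))
        n_bg <- n_bg - size
      }

      if (cnt[["single"]] > 0L) {
        for (i in seq_len(cnt[["single"]])) {
          kind <- i %% 3L
          alpha <- c(alpha, list(if (kind == 2L) character(0) else fresh("ALPHA")))
          beta <- c(beta, list(if (kind == 1L) character(0) else fresh("BETA")))
        }
        lab <- c(lab, rep("SINGLE_BYSTANDER", cnt[["single"]]))
      }

      ids <- sprintf("%s_cell%03d", donor_id, seq_along(lab))
      cells[[donor_id]] <- new_cell_records(ids, donor_id, alpha, beta)
      labels[[donor_id]] <- data.frame(
        cell_id = ids, donor_id = donor_id,
        label = factor(lab, levels = clonality_levels),
        malignancy_target =
          as.integer(lab %in% c("MAIN_CLONE", "RELATED_TO_MAIN_CLONE")),
        stringsAsFactors = FALSE)
    }
    cells <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
    class(cells) <- c("cell_records", "data.frame")
    dom <- if (length(dominants)) {
      data.frame(donor_id = names(dominants),
                 alpha = vapply(dominants, `[[`, "", "alpha"),
                 beta = vapply(dominants, `[[`, "", "beta"),
                 row.names = NULL, stringsAsFactors = FALSE)
    } else {
      data.frame(donor_id = character(0), alpha = character(0),
                 beta = character(0))
    }
    list(cells = cells,
         truth = list(labels = do.call(rbind, c(unname(labels),
                                                list(make.row.names = FALSE))),
                      dominant = dom))
  })
}

#' Simulate a matched expression matrix with planted marker genes
#'
#' Baseline counts are negative binomial with per-gene means varying
#' log-normally around `nb_mean`; informative genes are shifted by their
#' signed log2 effect in malignant cells only; entries are then zeroed with
#' the dropout probability and each cell is scaled to a fixed total of 1e6,
#' following the per-million convention of RPKM-style normalization.  Decoy
#' genes
#' with TCR-variable-region names are appended so the TCR-gene exclusion is
#' exercised end to end.
#'
#' @param cells `cell_records` from [simulate_repertoire()].
#' @param truth the matching ground truth.
#' @param config the same [sim_config()].
#' @return list with `dataset` (a [labeled_dataset()], including decoy TCR
#'   genes) and `informative` (data.frame `gene`, `effect_log2`).
#' @export
simulate_expression <- function(cells, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_informative > config$n_genes) {
    stop("n_informative exceeds n_genes", call. = FALSE)
  }
  local_seed(config$seed + 1L, {
    n <- nrow(cells)
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    fresh <- make_chain_factory(config$junction_length)
    decoys <- if (config$n_decoy_tcr > 0L) {
      vapply(seq_len(config$n_decoy_tcr), function(i) {
        id <- fresh(if (i %% 2L) "ALPHA" else "BETA")
        parts <- strsplit(id, "_")[[1]]
        paste0(parts[if (i %% 4L < 2L) 1L else 3L], ".", i)  # TRAVx.i etc.
      }, character(1))
    } else character(0)
    gene_names <- c(genes, decoys)
    G <- length(gene_names)
    target <- truth$labels$malignancy_target[match(cells$cell_id,
                                                   truth$labels$cell_id)]
    inf_idx <- sort(sample.int(config$n_genes, config$n_informative))
    mu_g <- config$nb_mean * exp(stats::rnorm(G, 0, 0.5) - 0.5^2 / 2)
    M <- matrix(rep(mu_g, each = n), n, G)
    if (config$n_informative > 0L) {
      shift <- matrix(1, n, config$n_informative)
      shift[target == 1L, ] <- rep(2^config$effect_log2,
                                   each = sum(target == 1L))
      M[, inf_idx] <- M[, inf_idx] * shift
    }
    counts <- matrix(stats::rnbinom(n * G, mu = as.vector(M),
                                    size = config$nb_dispersion), n, G)
    if (config$dropout > 0) {
      keep <- matrix(stats::rbinom(n * G, 1L, 1 - config$dropout), n, G)
      counts <- counts * keep
    }
    tot <- rowSums(counts)
    scale <- ifelse(tot > 0, 1e6 / tot, 0)
    values <- counts * scale
    list(dataset = labeled_dataset(values, gene_names, cells$cell_id,
                                   cells$donor_id, target),
         informative = data.frame(gene = genes[inf_idx],
                                  effect_log2 = config$effect_log2,
                                  stringsAsFactors = FALSE))
  })
}

#' Simulate a complete labeled study
#'
#' Convenience wrapper: [simulate_repertoire()] then [simulate_expression()].
#'
#' @param config a [sim_config()].
#' @return list with `cells`, `truth`, `dataset` and `informative`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  rep <- simulate_repertoire(config)
  expr <- simulate_expression(rep$cells, rep$truth, config)
  c(rep, expr)
}
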