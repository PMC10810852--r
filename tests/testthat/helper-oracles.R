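# Independent reference implementations used as oracles.  These deliberately
# avoid the package's code paths: the clonality reference enumerates by
# repeated set expansion, the forward-pass reference evaluates the model
# equations term by term, and the AUC reference counts concordant pairs.

# Build cell_records from a compact description: a list of donors, each a
# list of cells, each cell a character vector of chain ids where alpha ids
# start with "a" and beta ids with "b" (mapped onto valid identifiers).
make_cells <- function(donors) {
  chain_id <- function(x) {
    if (startsWith(x, "a")) paste0("TRAV", sub("^a", "", x), "_ACGT_TRAJ1")
    else paste0("TRBV", sub("^b", "", x), "_ACGT_TRBJ1-1")
  }
  cell_id <- character(0); donor_id <- character(0)
  alpha <- list(); beta <- list()
  k <- 0L
  for (don in names(donors)) {
    for (cell in donors[[don]]) {
      k <- k + 1L
      cell_id <- c(cell_id, sprintf("c%03d", k))
      donor_id <- c(donor_id, don)
      alpha <- c(alpha, list(vapply(cell[startsWith(cell, "a")], chain_id, "",
                                    USE.NAMES = FALSE)))
      beta <- c(beta, list(vapply(cell[startsWith(cell, "b")], chain_id, "",
                                  USE.NAMES = FALSE)))
    }
  }
  new_cell_records(cell_id, donor_id, alpha, beta)
}

# Exhaustive clonality reference for one donor's cells.
brute_clonality <- function(cells) {
  out <- lapply(split(seq_len(nrow(cells)), cells$donor_id), function(rows) {
    d <- cells[rows, , drop = FALSE]
    n <- nrow(d)
    chains <- lapply(seq_len(n), function(i) c(d$alpha[[i]], d$beta[[i]]))
    # dominant pair by explicit enumeration over all alpha x beta pairs
    tallies <- list()
    for (i in seq_len(n)) {
      for (a in d$alpha[[i]]) for (b in d$beta[[i]]) {
        key <- paste(a, b, sep = "\t")
        tallies[[key]] <- (tallies[[key]] %||% 0L) + 1L
      }
    }
    lab <- rep(NA_character_, n)
    if (length(tallies)) {
      cnt <- unlist(tallies)
      top <- names(cnt)[cnt == max(cnt)]
      if (length(top) > 1L) {
        supp <- vapply(top, function(key) {
          ab <- strsplit(key, "\t")[[1]]
          sum(vapply(seq_len(n), function(i) {
            ab[1] %in% d$alpha[[i]] || ab[2] %in% d$beta[[i]]
          }, logical(1)))
        }, integer(1))
        top <- sort(top[supp == max(supp)])[1]
      }
      dom <- strsplit(top, "\t")[[1]]
      is_mc <- vapply(seq_len(n), function(i) {
        dom[1] %in% d$alpha[[i]] || dom[2] %in% d$beta[[i]]
      }, logical(1))
      lab[is_mc] <- "MAIN_CLONE"
      # component of the dominant chains by repeated set expansion
      comp <- dom
      repeat {
        grown <- comp
        for (ch in chains) if (any(ch %in% grown)) grown <- union(grown, ch)
        if (length(grown) == length(comp)) break
        comp <- grown
      }
      rel <- !is_mc & vapply(chains, function(ch) any(ch %in% comp), logical(1))
      lab[rel] <- "RELATED_TO_MAIN_CLONE"
    }
    rest <- which(is.na(lab))
    sig <- vapply(rest, function(i) {
      paste(paste(sort(d$alpha[[i]]), collapse = ","),
            paste(sort(d$beta[[i]]), collapse = ","), sep = "|")
    }, character(1))
    for (i in seq_along(rest)) {
      lab[rest[i]] <- if (sum(sig == sig[i]) >= 2L) "BYSTANDER_GROUP"
                      else "SINGLE_BYSTANDER"
    }
    data.frame(cell_id = d$cell_id, label = lab, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[match(cells$cell_id, res$cell_id), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random repertoire generator independent of the package simulator: draws
# chains from small pools so sharing patterns arise by chance.
random_repertoire <- function(n_cells, n_alpha = 6, n_beta = 6) {
  alphas <- paste0("TRAV", seq_len(n_alpha), "_AC_TRAJ1")
  betas <- paste0("TRBV", seq_len(n_beta), "_AC_TRBJ1-1")
  alpha <- list(); beta <- list()
  for (i in seq_len(n_cells)) {
    na <- sample(0:2, 1, prob = c(0.2, 0.6, 0.2))
    nb <- if (na == 0L) sample(1:2, 1) else sample(0:2, 1, prob = c(0.2, 0.6, 0.2))
    alpha <- c(alpha, list(sample(alphas, na)))
    beta <- c(beta, list(sample(betas, nb)))
  }
  new_cell_records(sprintf("r%03d", seq_len(n_cells)), "donorR", alpha, beta)
}

# Direct, scalar-level evaluation of the two model equations.
direct_hypernet <- function(params, x) {
  pre_a <- as.numeric(params$W_A %*% x) + params$b_A
  h1 <- tanh(pre_a)
  pre_b <- as.numeric(params$W_B %*% h1) + params$b_B
  h2 <- tanh(pre_b)
  s <- 1 / (1 + exp(-(as.numeric(params$W_C %*% h2) + params$b_C)))
  exp(s) / sum(exp(s))
}

direct_output <- function(params, x) {
  a <- direct_hypernet(params, x)
  1 / (1 + exp(-(params$b_D + params$w_D * sum(a * x))))
}

# Probability that a random positive outscores a random negative, ties 1/2.
pairwise_auc <- function(scores, targets) {
  pos <- scores[targets == 1]; neg <- scores[targets == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

random_params <- function(G, H, seed) {
  set.seed(seed)
  structure(list(W_A = matrix(rnorm(H * G), H, G), b_A = rnorm(H),
                 W_B = matrix(rnorm(H * H), H, H), b_B = rnorm(H),
                 W_C = matrix(rnorm(G * H), G, H), b_C = rnorm(G),
                 w_D = rnorm(1), b_D = rnorm(1)),
            G = G, H = H, class = "hypernet_params")
}

# A linearly separable two-gene toy dataset: clonal cells high in gene 1.
separable_dataset <- function(n = 40, donors = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  g1 <- ifelse(y == 1, 10, 1) + runif(n, 0, 0.5)
  g2 <- ifelse(y == 1, 1, 10) + runif(n, 0, 0.5)
  labeled_dataset(cbind(g1, g2), c("GENEUP", "GENEDN"),
                  sprintf("s%03d", seq_len(n)),
                  rep(sprintf("d%d", seq_len(donors)), length.out = n), y)
}
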