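test_that("TCR variable-region genes are excluded, others kept in order", {
  m <- matrix(1:8, 2, 4)
  out <- exclude_tcr_genes(m, c("TRAV12-1", "TRBJ2-7", "HLA-A", "IL32"))
  expect_equal(out$gene_names, c("HLA-A", "IL32"))
  expect_equal(out$matrix, m[, 3:4])

  out2 <- exclude_tcr_genes(m, c("A", "B", "C", "D"))
  expect_equal(out2$gene_names, c("A", "B", "C", "D"))

  set.seed(5)
  names100 <- c(sprintf("G%03d", 1:93),
                c("TRAV3", "TRAJ12", "TRBV20-1", "TRBJ1-2", "trav9",
                  "TRBV7", "TRAJ1"))[sample(100)]
  kept <- exclude_tcr_genes(matrix(0, 1, 100), names100)$gene_names
  expect_length(kept, 93L)
  expect_false(any(grepl("^(TRAV|TRAJ|TRBV|TRBJ)", kept, ignore.case = TRUE)))
})

test_that("donor splits partition donors, never cells", {
  ds <- simulate_dataset(sim_config(n_donors = 10, cells_per_donor = 50,
                                    n_genes = 20, n_decoy_tcr = 0,
                                    seed = 4))$dataset
  tc <- train_config(split = c(train = 0.8, validation = 0.1, test = 0.1),
                     seed = 9)
  sp <- split_by_donor(ds, tc)
  expect_length(sp$donors$test, 1L)
  expect_length(sp$donors$validation, 1L)
  expect_length(intersect(sp$donors$train,
                          c(sp$donors$validation, sp$donors$test)), 0L)
  expect_setequal(unlist(sp$donors), unique(ds$donor_ids))
  expect_equal(length(sp$test$cell_ids), 50L)
  expect_setequal(unique(sp$test$donor_ids), sp$donors$test)
  # same seed, same split
  sp2 <- split_by_donor(ds, tc)
  expect_identical(sp$donors, sp2$donors)

  two <- ds[ds$donor_ids %in% c("donor01", "donor02")]
  expect_error(split_by_donor(two, tc), "at least 3 donors")
})

test_that("zero parameters give uniform weights and output exactly 0.5", {
  p <- zero_hypernet_params(4, 3)
  for (x in list(c(0, 0, 0, 0), c(1, 2, 3, 4), runif(4, 0, 100))) {
    expect_equal(hypernet_forward(p, x), rep(0.25, 4))
    expect_identical(model_forward(p, x), 0.5)
  }
})

test_that("a uniform-attention model reduces to plain logistic regression", {
  p <- zero_hypernet_params(4, 2)
  p$w_D <- 1
  expect_equal(model_forward(p, c(4, 0, 0, 0)), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
})

test_that("forward passes match the direct equation evaluation", {
  for (i in 1:25) {
    params <- random_params(G = 5, H = 3, seed = i)
    x <- abs(rnorm(5, sd = 2))
    expect_equal(hypernet_forward(params, x), direct_hypernet(params, x),
                 tolerance = 1e-6)
    expect_equal(model_forward(params, x), direct_output(params, x),
                 tolerance = 1e-6)
  }
})

test_that("adaptive weights are a strictly positive distribution per cell", {
  for (i in 1:10) {
    params <- random_params(G = 30, H = 5, seed = 100 + i)
    X <- matrix(abs(rnorm(8 * 30, sd = 3)), 8, 30)
    A <- hypernet_forward(params, X)
    expect_true(all(A > 0))
    expect_equal(rowSums(A), rep(1, 8), tolerance = 1e-9)
  }
})

test_that("the large published gene dimension is supported", {
  p <- zero_hypernet_params(44782, 2)
  a <- hypernet_forward(p, numeric(44782))
  expect_length(a, 44782L)
  expect_equal(sum(a), 1, tolerance = 1e-9)
})

test_that("binary cross-entropy matches hand arithmetic and handles limits", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)),
               mean(c(-log(0.9), -log(0.8))), tolerance = 1e-12)
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-10)
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))  # clamped, not Inf
  expect_error(bce_loss(c(0.5, 0.5), 1), "length mismatch")
})

test_that("shape mismatches are rejected", {
  p <- zero_hypernet_params(4, 2)
  expect_error(hypernet_forward(p, 1:3), "G = 4")
  expect_error(model_forward(p, matrix(1, 2, 5)), "G = 4")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(31)
  for (rep in 1:3) {
    params <- clonoreg:::init_hypernet_params(10, 4, seed = rep)
    X <- matrix(runif(6 * 10, 0, 3), 6, 10)
    y <- rep(c(1, 0), 3)
    gr <- clonoreg:::nnlogreg_gradients(params, X, y)
    eps <- 1e-5
    for (nm in names(gr)) {
      idx <- sample(seq_along(gr[[nm]]), min(5, length(gr[[nm]])))
      for (i in idx) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (bce_loss(model_forward(pp, X), y) -
                bce_loss(model_forward(pm, X), y)) / (2 * eps)
        ana <- gr[[nm]][i]
        expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-8), 1e-4)
      }
    }
  }
})

test_that("separable data trains to perfect AUC with decreasing loss", {
  toy <- separable_dataset(n = 40, seed = 1)
  tc <- train_config(hidden = 8L, epochs = 150, seed = 2)
  m <- nn_logreg_train(toy, toy, tc)
  expect_true(all(diff(m$history$train_loss[1:10]) < 0))
  expect_equal(roc_curve(predict(m, toy), toy$targets)$auc, 1.0)
})

test_that("training is bitwise reproducible for a fixed seed and config", {
  toy <- separable_dataset(n = 30, seed = 3)
  tc <- train_config(hidden = 8L, epochs = 40, seed = 7)
  m1 <- nn_logreg_train(toy, toy, tc)
  m2 <- nn_logreg_train(toy, toy, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("single-class training sets are rejected", {
  toy <- separable_dataset(n = 20, seed = 4)
  toy$targets <- rep(1L, 20)
  expect_error(nn_logreg_train(toy, toy, train_config(hidden = 4L)),
               "single class")
})

test_that("predict is the row-wise model forward pass", {
  params <- random_params(G = 12, H = 4, seed = 5)
  X <- matrix(abs(rnorm(100 * 12)), 100, 12)
  batch <- model_forward(params, X)
  looped <- vapply(seq_len(100), function(i) model_forward(params, X[i, ]),
                   numeric(1))
  expect_equal(batch, looped, tolerance = 1e-9)
  p <- zero_hypernet_params(12, 4)
  expect_equal(model_forward(p, X), rep(0.5, 100))
})
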