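test_that("one-component weights have the sign of the gene-response covariance", {
  expr <- tiny_expr(n_genes = 6, n1 = 6, n2 = 6, seed = 12,
                    effect_genes = c("g1", "g2"), effect = 2)
  vals <- expr$values
  vals["g3", expr$labels == "responder"] <-
    vals["g3", expr$labels == "responder"] - 2   # down-regulated gene
  expr <- expression_matrix(vals, expr$labels)
  model <- fit_pls(expr)
  y <- ifelse(expr$labels == "responder", 1, -1)
  covs <- apply(expr$values, 1, function(v) cov(v, y))
  expect_equal(sign(model$weights), sign(covs)[names(model$weights)])
  expect_equal(sum(model$weights^2), 1, tolerance = 1e-12)

  single <- fit_pls(expr, genes = "g1")
  expect_identical(unname(sign(single$weights)), 1)
})

test_that("the fitted weight maximizes squared covariance against random unit vectors", {
  set.seed(33)
  expr <- tiny_expr(n_genes = 6, n1 = 6, n2 = 6, seed = 44,
                    effect_genes = "g1", effect = 1)
  model <- fit_pls(expr)
  X <- scale(t(expr$values))
  y <- ifelse(expr$labels == "responder", 1, -1); y <- y - mean(y)
  cov_sq <- function(w) (sum((X %*% w) * y) / (nrow(X) - 1))^2
  fitted_obj <- cov_sq(model$weights)
  V <- matrix(rnorm(6 * 1e5), 6)
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  rand_obj <- (drop(crossprod(y, X %*% V)) / (nrow(X) - 1))^2
  expect_gte(fitted_obj + 1e-12, max(rand_obj))
})

test_that("degenerate candidate genes are rejected by name", {
  expr <- tiny_expr(n_genes = 4, seed = 3)
  vals <- expr$values
  vals["g2", ] <- 1
  expect_error(fit_pls(expression_matrix(vals, expr$labels)), "g2")
})

test_that("scoring is the stated linear functional of standardized expression", {
  model <- tg_signature_model()
  genes <- model$gene_ids
  labels <- stats::setNames(c("responder", "non_responder"), c("S1", "S2"))

  zero <- matrix(0, 6, 2, dimnames = list(genes, names(labels)))
  sc <- score_samples(model, expression_matrix(zero, labels))
  expect_equal(sc$score, c(0, 0))
  expect_identical(sc$predicted, c("responder", "responder"))  # 0 > -0.03

  # perturbing one standardized gene moves the score by exactly W * delta
  pert <- zero; pert["CRK", "S1"] <- 1.7
  sc2 <- score_samples(model, expression_matrix(pert, labels))
  expect_equal(sc2$score[1] - sc$score[1],
               unname(model$weights["CRK"]) * 1.7, tolerance = 1e-12)

  # dot-product oracle on random samples
  set.seed(9)
  mat <- matrix(rnorm(6 * 100), 6, 100,
                dimnames = list(genes, sprintf("P%03d", 1:100)))
  labs <- stats::setNames(rep(c("responder", "non_responder"), 50),
                          colnames(mat))
  sc3 <- score_samples(model, expression_matrix(mat, labs))
  expect_equal(sc3$score, unname(drop(crossprod(mat, model$weights))),
               tolerance = 1e-12)

  expect_error(score_samples(model, tiny_expr(n_genes = 3)), "MX1")
})

test_that("threshold choice maximizes Youden's J over every cutoff position", {
  labs <- rep(c("responder", "non_responder"), each = 5)
  sep <- c(6:10, 1:5)
  ch <- choose_threshold(sep, labs)
  expect_equal(ch$threshold, 5.5)           # midpoint of the separating gap
  expect_equal(ch$accuracy, 1)
  expect_false(ch$degenerate)

  flat <- choose_threshold(rep(2, 10), labs)
  expect_true(flat$degenerate)
  expect_equal(flat$youden_j, 0)
  expect_equal(flat$threshold, 1)           # lowest candidate cutoff

  set.seed(55)
  for (i in 1:25) {
    sc <- round(rnorm(14), 1)               # ties likely
    lab <- sample(rep(c("responder", "non_responder"), 7))
    got <- choose_threshold(sc, lab)
    d <- sort(unique(sc))
    cuts <- c(d[1] - 1, (d[-1] + d[-length(d)]) / 2, d[length(d)] + 1)
    brute <- max(vapply(cuts, function(cut) {
      sens <- mean(sc[lab == "responder"] > cut)
      spec <- mean(sc[lab == "non_responder"] <= cut)
      sens + spec - 1
    }, numeric(1)))
    expect_equal(got$youden_j, brute, tolerance = 1e-12)
  }

  expect_error(choose_threshold(1:4, rep("responder", 4)), "both classes")
})

test_that("model JSON serialization round-trips at full precision", {
  expr <- tiny_expr(n_genes = 6, n1 = 5, n2 = 5, seed = 77,
                    effect_genes = "g1", effect = 2)
  model <- train_classifier(expr)
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(model, path)
  back <- read_pls_model(path)
  expect_identical(back$gene_ids, model$gene_ids)
  expect_equal(back$weights, model$weights, tolerance = 0)
  expect_equal(back$center, model$center, tolerance = 0)
  expect_equal(back$scale, model$scale, tolerance = 0)
  expect_equal(back$threshold, model$threshold, tolerance = 0)
  expect_equal(score_samples(back, expr)$score,
               score_samples(model, expr)$score, tolerance = 0)
})

test_that("fitted weight signs reproduce the published signature directions", {
  # synthetic cohort with the published regulation directions:
  # MX1/OASL/SPINK1 lower in responders, CRK/GRAPL/RNF2 higher
  genes <- c("MX1", "OASL", "SPINK1", "CRK", "GRAPL", "RNF2")
  dirs <- c(-1, -1, -1, 1, 1, 1)
  set.seed(101)
  labels <- stats::setNames(rep(c("responder", "non_responder"), each = 6),
                            sprintf("S%02d", 1:12))
  vals <- matrix(rnorm(6 * 12, 7, 0.5), 6, 12,
                 dimnames = list(genes, names(labels)))
  vals[, labels == "responder"] <- vals[, labels == "responder"] + dirs
  model <- fit_pls(expression_matrix(vals, labels))
  expect_equal(unname(sign(model$weights[genes])), dirs)
  expect_equal(sign(tg_signature_model()$weights[genes]), sign(model$weights[genes]))
})
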