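test_that("rho implements the capacity formula", {
  expect_equal(round(rho(4108, 20, 50, 2), 2), 3.57)
  expect_equal(rho((10 + 1) * 5 + (5 + 1) * 2, 10, 5, 2), 1.0)
  expect_equal(rho(1000, 10, 10, 2), 1000 / 132)
  expect_error(rho(0, 10, 10, 2), ">= 1")
  expect_error(rho(100, -1, 10, 2), ">= 1")
})

test_that("a linearly separable table is fit to perfection", {
  set.seed(5)
  n <- 120
  cls <- rep(c(1L, -1L), n / 2)
  tb <- tibble::tibble(ACRC = cls,
                       `D[x]dt` = cls * 2 + rnorm(n, sd = 0.1),
                       `D[y]dt` = rnorm(n))
  cfg <- ptml_config(h_range = c(20, 25), restarts = 2, retained = 1,
                     maxit = 200, seed = 42)
  m <- suppressWarnings(ptml_train(tb, config = cfg))
  pr <- predict(m, tb)
  perf <- sn_sp(confusion_counts(pr$pacrc, tb$ACRC))
  expect_equal(perf$sn, 100)
  expect_equal(perf$sp, 100)
})

test_that("training is deterministic for identical seed, config and data", {
  s <- small_sim()
  cols <- grep("^D\\[", names(s$ftr), value = TRUE)[1:8]
  cfg <- ptml_config(restarts = 2, retained = 1, maxit = 40, seed = 31)
  m1 <- suppressWarnings(ptml_train(s$ftr[c("ACRC", cols)], config = cfg))
  m2 <- suppressWarnings(ptml_train(s$ftr[c("ACRC", cols)], config = cfg))
  expect_identical(m1$wts, m2$wts)
  expect_identical(m1$n, m2$n)
})

test_that("stored rho matches the stored topology and T", {
  mm <- small_model()
  m <- mm$model
  expect_equal(m$rho, rho(m$T, m$n[1], m$n[2], m$n[3]))
})

test_that("the forward pass reproduces the reference implementation", {
  set.seed(8)
  X <- matrix(rnorm(50 * 4), 50)
  Y <- cbind(as.integer(X[, 1] < 0), as.integer(X[, 1] >= 0))
  fit <- nnet::nnet(x = X, y = Y, size = 6, softmax = TRUE, maxit = 60,
                    trace = FALSE)
  ours <- ptmlfbtd:::.mlp_forward(fit$wts, fit$n, X)
  ref <- predict(fit, X)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("the JSON bundle round-trips predictions bit-for-bit", {
  mm <- small_model()
  s <- small_sim()
  tf <- withr::local_tempfile(fileext = ".json")
  ptml_save(mm$model, tf)
  m2 <- ptml_load(tf)
  p1 <- predict(mm$model, s$fte)
  p2 <- predict(m2, s$fte)
  expect_identical(p1$prob_act, p2$prob_act)
  expect_identical(p1$tsad, p2$tsad)
})

test_that("ProbAct and the predicted class never disagree with the 0.5 rule", {
  mm <- small_model()
  m <- mm$model
  set.seed(77)
  X <- matrix(rnorm(10000 * m$n[1], sd = 3), ncol = m$n[1])
  p <- ptmlfbtd:::.mlp_forward(m$wts, m$n, X)[, 2]
  pacrc <- ifelse(p > 0.5, 1L, -1L)
  expect_true(all((p > 0.5) == (pacrc == 1L)))
  # exact 0.5 maps to inactive (strict inequality): zero weights give 0.5
  wts0 <- rep(0, length(m$wts))
  p0 <- ptmlfbtd:::.mlp_forward(wts0, m$n, X[1:3, , drop = FALSE])[, 2]
  expect_equal(p0, rep(0.5, 3))
  expect_equal(ifelse(p0 > 0.5, 1L, -1L), rep(-1L, 3))
})

test_that("prediction from SMILES runs the stored pipeline end to end", {
  mm <- small_model()
  s <- small_sim()
  mol <- s$sim$molecules[1:2, ]
  cases <- tidyr::crossing(mol[c("molecule_id", "smiles")],
                           condition_id = c("ej01", "ej05"))
  pr <- predict(mm$model, cases)
  expect_equal(nrow(pr), 4L)
  expect_true(all(pr$prob_act >= 0 & pr$prob_act <= 1))
  expect_true(all(pr$pacrc %in% c(-1L, 1L)))
  expect_error(predict(mm$model,
                       dplyr::mutate(cases, condition_id = "ej99")),
               "registry")
})

test_that("tidy and glance summarise the fitted bundle", {
  mm <- small_model()
  td <- tidy(mm$model)
  expect_equal(td$term, mm$model$feature_ids)
  expect_true(all(td$ad_min <= td$ad_max))
  gl <- glance(mm$model)
  expect_equal(gl$i, mm$model$n[1])
  expect_equal(gl$rho, mm$model$rho)
})
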