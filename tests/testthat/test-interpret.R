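test_that("sensitivity values flag uninformative inputs with SV = 1", {
  mm <- small_model()
  s <- small_sim()
  m <- mm$model
  # zero all weights leaving the first input: remaining inputs have SV = 1
  I <- m$n[1]; H <- m$n[2]
  W1 <- matrix(m$wts[seq_len((I + 1) * H)], nrow = I + 1)
  W1[3:(I + 1), ] <- 0   # keep bias + inputs 1-2 only
  m0 <- m
  m0$wts[seq_len((I + 1) * H)] <- as.vector(W1)
  sv <- sensitivity_values(m0, s$ftr)
  dead <- m$feature_ids[-(1:2)]
  expect_equal(sv$sv[match(dead, sv$term)], rep(1, length(dead)))
  # constant input column: substitution is the identity
  ftr2 <- s$ftr
  ftr2[[m$feature_ids[1]]] <- 1.7
  sv2 <- sensitivity_values(m, ftr2)
  expect_equal(sv2$sv[sv2$term == m$feature_ids[1]], 1)
})

test_that("sensitivity ranking is deterministic and column-order invariant", {
  mm <- small_model()
  s <- small_sim()
  sv1 <- sensitivity_values(mm$model, s$ftr)
  shuffled <- s$ftr[sample(names(s$ftr))]
  sv2 <- sensitivity_values(mm$model, shuffled)
  expect_identical(sv1, sv2)
})

test_that("tendency classification follows the mean comparison", {
  expect_equal(classify_tendency(1.481e-2, 8.723e-2), "Decrease")
  expect_equal(classify_tendency(-9.067e-3, -4.975e-2), "Increase")
  expect_equal(classify_tendency(1, 1), "Indeterminate")
  # antisymmetry under class-label swap
  a <- rnorm(10); b <- rnorm(10)
  swap <- c(Increase = "Decrease", Decrease = "Increase",
            Indeterminate = "Indeterminate")
  expect_equal(unname(swap[classify_tendency(a, b)]),
               classify_tendency(b, a))
})

test_that("tendency table restricts means to correctly classified cases", {
  mm <- small_model()
  s <- small_sim()
  tt <- tendency_table(mm$model, s$ftr)
  expect_equal(nrow(tt), length(mm$model$feature_ids))
  pr <- predict(mm$model, s$ftr)
  corr_act <- pr$pacrc == 1 & s$ftr$ACRC == 1
  id1 <- mm$model$feature_ids[1]
  expect_equal(tt$active_mean[tt$term == id1],
               mean(s$ftr[[id1]][corr_act]))
})

test_that("multi-cell verdict applies the 4-of-7 rule", {
  probs <- c(43.43, 58.41, 55.23, 66.49, 56.13, 42.44, 46.02) / 100
  v <- multicell_verdict(probs)
  expect_equal(v$n_active, 4L)
  expect_equal(v$min_active, 4L)
  expect_true(v$multicell)
  expect_true(multicell_verdict(rep(0.9, 7))$multicell)
  expect_false(multicell_verdict(rep(0.1, 7))$multicell)
  expect_equal(multicell_verdict(rep(0.9, 5))$min_active, 3L)
})

test_that("druglikeness boundary semantics are exact", {
  base <- tibble::tibble(mw = 400, hba = 10, hbd = 5, mlogp = 2, alogp = 2,
                         rbn = 10, psa = 139.9)
  ok <- druglikeness(base)
  expect_equal(ok$n_lipinski_violations, 0L)
  expect_true(ok$lipinski_ok && ok$veber_ok)
  # MW = 500 violates (strict <); HBA = 10 passes (<=)
  mw500 <- druglikeness(dplyr::mutate(base, mw = 500))
  expect_equal(mw500$violations[[1]], "MW")
  hba11 <- druglikeness(dplyr::mutate(base, hba = 11))
  expect_equal(hba11$violations[[1]], "HBA")
  veber <- druglikeness(dplyr::mutate(base, psa = 140))
  expect_false(veber$veber_ok)
  zero <- druglikeness(tibble::tibble(mw = 0, hba = 0, hbd = 0, mlogp = 0,
                                      alogp = 0, rbn = 0, psa = 0))
  expect_true(zero$lipinski_ok && zero$veber_ok)
})

test_that("properties computed from SMILES are chemically sensible", {
  pr <- molecular_properties(tibble::tibble(molecule_id = "aspirin",
                                            smiles = "CC(=O)Oc1ccccc1C(=O)O"))
  expect_equal(pr$mw, 180.157, tolerance = 1e-3)
  expect_equal(pr$hba, 4L)
  expect_equal(pr$hbd, 1L)
  expect_equal(pr$psa, 63.6, tolerance = 1e-6)
  caffeine <- molecular_properties(
    tibble::tibble(smiles = "Cn1cnc2c1c(=O)n(C)c(=O)n2C"))
  expect_equal(caffeine$hba, 6L)
  expect_equal(caffeine$hbd, 0L)
})

test_that("multicell report scores every registry condition", {
  mm <- small_model()
  s <- small_sim()
  rep_ <- multicell_report(mm$model, s$sim$molecules[1:2, ])
  expect_equal(nrow(rep_), 14L)
  summ <- attr(rep_, "summary")
  expect_equal(nrow(summ), 2L)
  expect_equal(summ$min_active, c(4, 4))
})
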