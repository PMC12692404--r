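make_raw <- function(...) {
  tibble::tibble(...)
}

test_that("curation applies threshold, minimum rule and mass filter", {
  raw <- make_raw(
    molecule_id = c("m1", "m2", "m3", "m3", "m4"),
    smiles = c("CCCCCCc1ccccc1O", "CCCCCCc1ccccc1N", "CCCCCCCCc1ccccc1",
               "CCCCCCCCc1ccccc1", "c1ccccc1"),
    gi50_nm = c(1900, 1901, 500, 200, 100),
    condition_id = c("ej01", "ej01", "ej02", "ej02", "ej03")
  )
  cur <- suppressMessages(curate_assays(raw))
  expect_equal(cur$ACRC[cur$molecule_id == "m1"], 1L)
  expect_equal(cur$ACRC[cur$molecule_id == "m2"], -1L)
  m3 <- cur[cur$molecule_id == "m3", ]
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$gi50_nm, 200)
  # benzene (78 g/mol) falls below the 130 g/mol window
  expect_false("m4" %in% cur$molecule_id)
  rej <- attr(cur, "rejected")
  expect_true("molar mass outside window" %in% rej$reason)
})

test_that("curation rejects bad records with typed reasons", {
  raw <- make_raw(
    molecule_id = c("a", "b", "c", "d"),
    smiles = c("", "CC(=O)O.[Na+]", "CCCCCCCCc1ccccc1", "CCCCCCCCc1ccccc1"),
    gi50_nm = c(100, 100, NA, -5),
    condition_id = rep("ej01", 4)
  )
  cur <- suppressMessages(curate_assays(raw))
  expect_equal(nrow(cur), 0L)
  rej <- attr(cur, "rejected")
  expect_setequal(rej$reason,
                  c("missing SMILES", "multi-component SMILES",
                    "missing activity value", "non-positive activity value"))
  expect_error(curate_assays(make_raw(molecule_id = "a", smiles = "CC",
                                      gi50_nm = 1, condition_id = "ej99")),
               "registry")
})

test_that("units are harmonized to nM when a unit column is present", {
  raw <- make_raw(molecule_id = c("a", "b"),
                  smiles = rep("CCCCCCCCc1ccccc1", 2),
                  gi50_nm = c(1.5, 1900),
                  gi50_unit = c("uM", "nM"),
                  condition_id = c("ej01", "ej02"))
  cur <- suppressMessages(curate_assays(raw))
  expect_equal(sort(cur$gi50_nm), c(1500, 1900))
  expect_equal(cur$ACRC, c(1L, 1L))
})

test_that("split follows the sorted 3:1 block rule", {
  cases <- make_raw(molecule_id = sprintf("m%02d", 1:8),
                    smiles = "CC", gi50_nm = 1:8,
                    condition_id = "ej01")
  spl <- split_assays(cases)
  expect_equal(spl$partition, rep(c("train", "train", "train", "test"), 2))
  # trailing partial block goes to training
  spl3 <- suppressWarnings(split_assays(cases[1:3, ]))
  expect_equal(spl3$partition, rep("train", 3))
  big <- make_raw(molecule_id = sprintf("m%03d", 1:40), smiles = "CC",
                  gi50_nm = stats::runif(40), condition_id = "ej01")
  expect_equal(sum(split_assays(big)$partition == "test"), 10L)
  # determinism under re-run
  expect_identical(split_assays(big), split_assays(big))
})

test_that("condition labels expand from the registry", {
  reg <- default_condition_registry()
  x <- expand_labels(make_raw(condition_id = c("ej05", "ej02")), reg)
  expect_equal(x$dt, c("Intermediate growth", "Fast growth"))
  expect_equal(x$ct, c("KM12", "HT-29"))
  expect_equal(x$mc, c("MSI", "MSS"))
  expect_error(expand_labels(make_raw(condition_id = "ej99"), reg),
               "not in registry")
})

test_that("train fraction stays within the 3:1 band", {
  for (n in c(8, 30, 101)) {
    cases <- make_raw(molecule_id = sprintf("m%03d", 1:n), smiles = "CC",
                      gi50_nm = seq_len(n), condition_id = "ej01")
    fr <- mean(split_assays(cases)$partition == "train")
    expect_gte(fr, 0.75)
    expect_lte(fr, 0.75 + 3 / n)
  }
})
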