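toy_train <- function() {
  tibble::tibble(
    molecule_id = paste0("m", 1:8),
    dt = rep(c("Fast", "Slow"), 4),
    ct = rep(c("A", "B"), each = 4),
    mc = "MSS",
    ACRC = c(1L, 1L, 1L, -1L, 1L, -1L, -1L, -1L),
    `SM(Std)1` = c(1, 2, 3, 4, 5, 6, 7, 8),
    `SM(Std)2` = c(2, 4, 6, 8, 10, 12, 14, 16)
  )
}

test_that("fusion statistics implement the moving-average definitions", {
  tr <- toy_train()
  fs <- fit_fusion(tr, descriptor_cols = c("SM(Std)1", "SM(Std)2"))
  expect_equal(fs$T, 8L)
  # n and p per dt label over active cases only
  dt <- fs$elements$dt$labels
  expect_equal(dt$n[dt$label == "Fast"], 3L)  # m1, m3, m5
  expect_equal(dt$p[dt$label == "Fast"], 3 / 8)
  expect_equal(fs$elements$dt$avg["Fast", "SM(Std)1"], mean(c(1, 3, 5)))
  # population standard deviation over all training cases
  v <- tr$`SM(Std)1`
  expect_equal(unname(fs$sdv["SM(Std)1"]), sqrt(mean((v - mean(v))^2)))
})

test_that("a single active case defines the reference and fuses to zero", {
  tr <- toy_train()
  tr$ACRC <- c(1L, rep(-1L, 7))
  fs <- fit_fusion(tr, descriptor_cols = "SM(Std)1")
  fz <- fuse_descriptors(tr[1, ], fs)
  expect_equal(fz$`D[SM(Std)1]dt`, 0)
  expect_equal(fz$`D[SM(Std)1]ct`, 0)
})

test_that("p(ej) reaches 1 when every training case is active on one label", {
  tr <- toy_train()
  tr$ACRC <- 1L
  fs <- fit_fusion(tr, descriptor_cols = "SM(Std)1")
  expect_equal(fs$elements$mc$labels$p, 1)
})

test_that("degenerate descriptors are excluded with a message", {
  tr <- toy_train()
  tr$const <- 5
  expect_message(fs <- fit_fusion(tr, descriptor_cols = c("SM(Std)1", "const")),
                 "degenerate")
  expect_false("const" %in% fs$descriptor_cols)
})

test_that("the perturbation formula matches direct substitution", {
  # GTI = 2, avg = 1, sdv = 0.5, p = 0.25 -> D = 8
  fs <- structure(list(
    elements = list(
      dt = list(labels = tibble::tibble(label = "x", n = 2L, p = 0.25),
                avg = matrix(1, 1, 1, dimnames = list("x", "g"))),
      ct = list(labels = tibble::tibble(label = "y", n = 2L, p = 0.5),
                avg = matrix(2, 1, 1, dimnames = list("y", "g"))),
      mc = list(labels = tibble::tibble(label = "z", n = 2L, p = 1),
                avg = matrix(2, 1, 1, dimnames = list("z", "g")))),
    sdv = c(g = 0.5), T = 8L, descriptor_cols = "g",
    degenerate = character(0)), class = "fusion_stats")
  case <- tibble::tibble(dt = "x", ct = "y", mc = "z", g = 2)
  fz <- fuse_descriptors(case, fs)
  expect_equal(fz$`D[g]dt`, 8)
  expect_equal(fz$`D[g]ct`, 0)   # centered value is zero regardless of p
  expect_error(fuse_descriptors(tibble::tibble(dt = "q", ct = "y",
                                               mc = "z", g = 1), fs),
               "absent from fusion")
})

test_that("centering identity holds on the simulated study", {
  s <- small_sim()
  ftr <- s$ftr
  act <- ftr$ACRC == 1
  for (el in c("dt", "ct", "mc")) {
    cols <- grep(paste0("\\]", el, "$"), names(ftr), value = TRUE)[1:5]
    for (lb in unique(ftr[[el]][act])) {
      sel <- act & ftr[[el]] == lb
      expect_equal(unname(colMeans(ftr[sel, cols])), rep(0, length(cols)),
                   tolerance = 1e-9)
    }
  }
})

test_that("fused values are invariant to a common rescaling of the raw pool", {
  tr <- toy_train()
  fs1 <- fit_fusion(tr, descriptor_cols = "SM(Std)1")
  tr2 <- tr
  tr2$`SM(Std)1` <- tr2$`SM(Std)1` * 37
  fs2 <- fit_fusion(tr2, descriptor_cols = "SM(Std)1")
  expect_equal(unname(fs2$sdv), unname(fs1$sdv) * 37)
  expect_equal(fuse_descriptors(tr2, fs2)$`D[SM(Std)1]dt`,
               fuse_descriptors(tr, fs1)$`D[SM(Std)1]dt`)
})

test_that("fusion statistics survive JSON persistence bit-for-bit", {
  s <- small_sim()
  tf <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::serializeJSON(s$fus, digits = I(17)), tf)
  fs2 <- jsonlite::unserializeJSON(paste(readLines(tf), collapse = "\n"))
  f1 <- fuse_descriptors(s$train[1:5, ], s$fus)
  f2 <- fuse_descriptors(s$train[1:5, ], fs2)
  expect_identical(f1, f2)
})
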