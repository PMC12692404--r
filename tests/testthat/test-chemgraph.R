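test_that("SMILES parse to hydrogen-suppressed graphs with correct topology", {
  g <- parse_smiles("CC")
  expect_equal(nrow(g$atoms), 2L)
  expect_equal(g$L, 1L)
  expect_equal(g$atoms$degree, c(1L, 1L))
  expect_equal(g$atoms$h, c(3L, 3L))

  g2 <- parse_smiles("C1CC1")
  expect_equal(nrow(g2$atoms), 3L)
  expect_equal(g2$L, 3L)
  expect_equal(g2$atoms$degree, c(2L, 2L, 2L))

  expect_error(parse_smiles("CC(=O)O.[Na+]"), "multi-component")
  expect_error(parse_smiles("not-a-smiles"), "unparsable")
})

test_that("degree equals incident bond count and mass includes hydrogens", {
  for (g in fixture_graphs()) {
    deg <- tabulate(c(g$bonds$i, g$bonds$j), nbins = nrow(g$atoms))
    expect_equal(g$atoms$degree, deg)
    expect_gte(g$L, 1L)
  }
  # aspirin: C9H8O4 = 180.16
  expect_equal(parse_smiles("CC(=O)Oc1ccccc1C(=O)O")$molar_mass, 180.157,
               tolerance = 1e-3)
})

test_that("atom and bond counts agree with an independent parser", {
  oracle <- tryCatch(system2("python", c("-c", shQuote(paste0(
    "from rdkit import Chem\n",
    "import sys\n",
    "for s in sys.argv[1:]:\n",
    "    m = Chem.MolFromSmiles(s)\n",
    "    degs = sorted(a.GetDegree() for a in m.GetAtoms())\n",
    "    print(m.GetNumAtoms(), m.GetNumBonds(), *degs)\n")),
    shQuote(unname(fixture_smiles()))),
    stdout = TRUE, stderr = FALSE), error = function(e) NULL)
  skip_if(is.null(oracle) || length(oracle) != length(fixture_smiles()),
          "independent parser unavailable")
  graphs <- fixture_graphs()
  for (k in seq_along(graphs)) {
    ref <- as.integer(strsplit(oracle[k], " ")[[1]])
    g <- graphs[[k]]
    expect_equal(nrow(g$atoms), ref[1], info = g$smiles)
    expect_equal(g$L, ref[2], info = g$smiles)
    expect_equal(sort(g$atoms$degree), ref[-(1:2)], info = g$smiles)
  }
})

test_that("Gasteiger charges respect symmetry, conservation and determinism", {
  q <- gasteiger_charges(parse_smiles("CC"))
  expect_equal(q[1], q[2])
  for (g in fixture_graphs()) {
    expect_equal(sum(gasteiger_charges(g)), sum(g$atoms$charge),
                 tolerance = 1e-6)
  }
  m <- parse_smiles("CO")
  q <- gasteiger_charges(m)
  o <- which(m$atoms$element == "O")
  expect_lt(q[o], 0)
  expect_gt(q[-o], 0)
  expect_identical(gasteiger_charges(parse_smiles("c1ccncc1")),
                   gasteiger_charges(parse_smiles("c1ccncc1")))
})

test_that("Gasteiger charges match a hand iteration of the update rule", {
  # independent re-implementation for methanol (heavy atoms + explicit H)
  par <- contribution_table("gasteiger")
  row <- function(el) which(par$element == el & par$hyb == "sp3")
  els <- c("C", "O", rep("H", 4))
  a <- par$a[vapply(els, row, 1L)]
  b <- par$b[vapply(els, row, 1L)]
  cc <- par$c[vapply(els, row, 1L)]
  chip <- ifelse(els == "H", 20.02, a + b + cc)
  bonds <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 6))
  q <- numeric(6)
  for (it in 1:8) {
    chi <- a + b * q + cc * q^2
    dq <- numeric(6)
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      lo <- if (chi[i] < chi[j]) i else j
      hi <- if (chi[i] < chi[j]) j else i
      tr <- (chi[hi] - chi[lo]) / chip[lo] * 0.5^it
      dq[lo] <- dq[lo] + tr
      dq[hi] <- dq[hi] - tr
    }
    q <- q + dq
  }
  expected <- c(q[1] + sum(q[3:5]), q[2] + q[6])
  expect_equal(gasteiger_charges(parse_smiles("CO")), expected,
               tolerance = 1e-10)
})

test_that("atomic contributions follow the published tables", {
  g <- parse_smiles("CC")
  expect_equal(atomic_contributions(g, "Ato"), c(12.011, 12.011))
  an <- parse_smiles("COc1ccccc1")  # anisole: ether O, plain carbons
  psa <- atomic_contributions(an, "Psa")
  expect_equal(psa[an$atoms$element == "C"], rep(0, 7))
  tp <- contribution_table("tpsa")
  ether <- tp$value[tp$element == "O" & tp$aromatic == 0 & tp$h == 0 &
                      tp$nsingle == 2 & tp$in3ring == 0]
  expect_equal(psa[an$atoms$element == "O"], ether)
  expect_error(atomic_contributions(g, "Std"), "atomic contributions")
})

test_that("bond weights: table lookups and the atom-to-bond rule", {
  g <- parse_smiles("CC")
  expect_equal(bond_weights(g, "Ato"), 12.011 / 1 + 12.011 / 1)
  expect_equal(bond_weights(g, "Std"), 1.54)
  # summing w(i,j) over bonds equals summing p_i over atoms
  for (g in fixture_graphs()) {
    for (sc in c("Ato", "Psa", "Hyd", "Mol", "Gas")) {
      expect_equal(sum(bond_weights(g, sc)),
                   sum(atomic_contributions(g, sc)),
                   tolerance = 1e-9, info = paste(g$smiles, sc))
    }
  }
})

test_that("weight scheme registry partitions codes by kind", {
  ws <- weight_schemes()
  expect_setequal(ws$code, c("Std", "Dip", "Hyd", "Psa", "Mol", "Gas", "Ato"))
  expect_equal(ws$kind[ws$code %in% c("Std", "Dip")],
               rep("bond-table", 2))
  expect_equal(ws$kind[ws$code == "Gas"], "computed-charge")
})
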