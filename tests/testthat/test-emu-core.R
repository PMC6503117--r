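test_that("EMU names are canonical and parse back", {
  expect_equal(emuName("OAA", c(4, 2, 3)), "OAA_234")
  e <- parseEMU("Glu_12345")
  expect_equal(e$met, "Glu")
  expect_equal(e$atoms, 1:5)
  expect_equal(e$size, 5L)
  expect_error(parseEMU("Glu_321"), "ascending")
  expect_error(parseEMU("Glu"), "not a valid EMU")
})

test_that("precursor tracing follows the atom maps", {
  tca <- tcaNet()
  p <- emuPrecursors(tca, "Glu_12345", "v3")
  expect_length(p, 1)
  expect_equal(p[[1]]$factors, "AKG_12345")
  expect_equal(p[[1]]$coeff, 1)

  # condensation: citrate carbons 1-5 come from OAA C2-C4 plus AcCoA C1-C2
  p <- emuPrecursors(tca, "Cit_12345", "v1")
  expect_length(p, 1)
  expect_equal(p[[1]]$factors, c("AcCoA_12", "OAA_234"))
})

test_that("symmetric sources split into equally weighted orientations", {
  tca <- tcaNet()
  p <- emuPrecursors(tca, "OAA_2", "v6f")
  got <- sort(vapply(p, function(x) paste(x$factors, collapse = "*"), ""))
  expect_equal(got, c("Fum_2", "Fum_3"))
  expect_equal(vapply(p, `[[`, 0, "coeff"), c(0.5, 0.5))

  # orientation weights always sum to the unsplit coefficient
  for (emu in c("OAA_2", "OAA_23", "OAA_234", "OAA_1234"))
    expect_equal(sum(vapply(emuPrecursors(tca, emu, "v6f"), `[[`, 0,
                            "coeff")), 1)
  # positions fixed by the rotation axis collapse back to one term
  p <- emuPrecursors(tca, "OAA_23", "v6f")
  expect_length(p, 1)
  expect_equal(p[[1]]$factors, "Fum_23")
  expect_equal(p[[1]]$coeff, 1)
})

test_that("decomposition from glutamate spans sizes 1, 2, 3 and 5", {
  dec <- decomposeEMU(tcaNet(), "Glu_12345")
  expect_equal(names(dec@eams), c("1", "2", "3", "5"))
  expect_true("Glu_12345" %in% dec@eams[["5"]]@columns)
  # condensation factors restart the search at their own sizes
  expect_true("AcCoA_12*OAA_234" %in% dec@eams[["5"]]@knowns)
  expect_true("OAA_234" %in% dec@eams[["3"]]@columns)
})

test_that("a substrate target decomposes to nothing", {
  dec <- decomposeEMU(tcaNet(), "Asp_12")
  expect_length(dec@eams, 0)
  expect_equal(countVariables(dec), 0L)
})

test_that("a linear chain gives one size-1 EAM with two EMU reactions", {
  dec <- decomposeEMU(chainNet(), "C_1")
  expect_equal(names(dec@eams), "1")
  eam <- dec@eams[["1"]]
  expect_setequal(eam@columns, c("C_1", "B_1"))
  expect_equal(nrow(eam@entries), 2)
})

test_that("decomposition is deterministic", {
  d1 <- decomposeEMU(xylNet(), acReadouts)
  d2 <- decomposeEMU(xylNet(), acReadouts)
  for (s in names(d1@eams)) {
    expect_identical(d1@eams[[s]]@columns, d2@eams[[s]]@columns)
    expect_identical(d1@eams[[s]]@entries, d2@eams[[s]]@entries)
  }
})

test_that("EAM cells only reference fluxes of the network", {
  for (net in list(tcaNet(), xylNet())) {
    ids <- vapply(net@reactions, `[[`, "", "id")
    dec <- decomposeEMU(net, if (length(net@reactions) == 8) "Glu_12345"
                        else acReadouts)
    for (e in dec@eams) expect_true(all(e@entries$flux %in% ids))
  }
})

test_that("unimolecular lumping renames rows to their precursors", {
  dec <- reduceUnimolecular(decomposeEMU(tcaNet(), "Glu_12345"))
  e1 <- dec@eams[["1"]]
  # AKG_3 and Cit_3 chains collapse: OAA_2 is now fed straight from Fum
  expect_false("AKG_3" %in% e1@columns)
  expect_false("Cit_3" %in% e1@columns)
  expect_setequal(e1@columns, c("OAA_2", "OAA_3", "Fum_2", "Fum_3"))
  # Suc (single influx reaction v4) lumped through to OAA_2 / AcCoA_2
  fum2 <- e1@entries[e1@entries$col == "Fum_2" & e1@entries$flux == "v5", ]
  expect_setequal(fum2$row, c("OAA_2", "AcCoA_2"))
  expect_equal(sum(fum2$coeff), 1)
})

test_that("reduction reaches a fixed point and is idempotent", {
  dec <- reduceUnimolecular(decomposeEMU(tcaNet(), "Glu_12345"))
  again <- reduceUnimolecular(dec)
  for (s in names(dec@eams))
    expect_equal(again@eams[[s]]@entries, dec@eams[[s]]@entries)
})

test_that("a fully unimolecular chain collapses onto the substrate", {
  dec <- reduceUnimolecular(decomposeEMU(chainNet(), "D_1"))
  eam <- dec@eams[["1"]]
  expect_equal(eam@columns, "D_1")
  expect_equal(eam@entries$row, "A_1")
  expect_equal(eam@entries$flux, "v3")
  expect_equal(eam@entries$coeff, 1)
})

test_that("equivalent EMUs merge under the declared symmetry", {
  dec <- fullDecompose(tcaNet(), "Glu_12345")
  e1 <- dec@eams[["1"]]
  expect_setequal(e1@columns, c("Fum_2", "OAA_2", "OAA_3"))
  expect_false("Fum_3" %in% e1@columns)
  expect_equal(unname(dec@equivalents["Fum_3"]), "Fum_2")
  e3 <- dec@eams[["3"]]
  expect_setequal(e3@columns, c("Fum_123", "OAA_123", "OAA_234"))
})

test_that("combining is the identity without symmetric metabolites", {
  red <- reduceUnimolecular(decomposeEMU(xylNet(), "AC_12"))
  comb <- combineEquivalents(red)
  for (s in names(red@eams)) {
    expect_identical(comb@eams[[s]]@columns, red@eams[[s]]@columns)
    expect_equal(comb@eams[[s]]@entries$coeff, red@eams[[s]]@entries$coeff)
  }
})

test_that("variable counting collapses equivalence classes, not columns", {
  dec <- decomposeEMU(tcaNet(), "Glu_12345")
  expect_equal(countVariables(dec), 24L)
  # both orientations are present as columns before combining
  expect_true(all(c("Fum_2", "Fum_3") %in% dec@eams[["1"]]@columns))
  expect_gt(sum(vapply(dec@eams, function(e) length(e@columns), 0L)), 24L)
  red <- combineEquivalents(reduceUnimolecular(dec))
  expect_equal(countVariables(red), 9L)
  expect_equal(countVariablesBySize(red),
               c(`1` = 3L, `2` = 2L, `3` = 3L, `5` = 1L))
})

test_that("simulated MDVs are invariant under reduction and combination", {
  tca <- tcaNet()
  raw <- decomposeEMU(tca, "Glu_12345")
  red <- reduceUnimolecular(raw)
  comb <- combineEquivalents(red)
  set.seed(42)
  for (i in 1:5) {
    fl <- tcaFluxes(x = runif(1), e = 10^runif(1, -3, 1))
    tr <- "AcCoA:12@0.7,0@0.3"
    m0 <- solveCascade(raw, fl, tr)[["Glu_12345"]]
    m1 <- solveCascade(red, fl, tr)[["Glu_12345"]]
    m2 <- solveCascade(comb, fl, tr)[["Glu_12345"]]
    expect_lt(max(abs(m1 - m0)), 1e-10)
    expect_lt(max(abs(m2 - m0)), 1e-10)
  }
})

test_that("EAMs export as a JSON report", {
  dec <- fullDecompose(tcaNet(), "Glu_12345")
  rep <- jsonlite::fromJSON(exportEAMs(dec), simplifyVector = FALSE)
  expect_equal(rep[["5"]]$columns, "Glu_12345")
  expect_equal(rep[["5"]]$cells[[1]]$flux, "v3")
})
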