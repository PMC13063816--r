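test_that("standardization canonicalizes, strips salts and is idempotent", {
  out <- standardizeSmiles("c1ccccc1")
  expect_identical(out$canonical, "c1ccccc1")
  expect_identical(out$formula, "C6H6")

  # glycine hydrochloride: HCl counter-ion dropped, glycine kept
  gly <- standardizeSmiles("C(C(=O)O)N.Cl")
  expect_identical(gly$formula, "C2H5NO2")
  expect_false(grepl("Cl", gly$canonical))

  # idempotence on a mixed batch
  batch <- c("C(C(=O)O)N.Cl", "O=[N+]([O-])c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
             "CCN(CC)CC", "c1ccc2[nH]ccc2c1")
  first <- standardizeSmiles(batch)
  second <- standardizeSmiles(first$canonical)
  expect_identical(second$canonical, first$canonical)
})

test_that("standardization reports parse and empty-structure errors", {
  expect_error(standardizeSmiles("not_a_smiles"), "unparseable.*not_a_smiles")
  expect_error(standardizeSmiles(""), "empty")
  res <- standardizeSmiles(c("c1ccccc1", "not_a_smiles"), onError = "na")
  expect_identical(is.na(res$error), c(TRUE, FALSE))
  expect_true(is.na(res$canonical[2]))
})

test_that("charge neutralization is a proton-transfer flag", {
  neut <- standardizeSmiles("CC(=O)[O-]", neutralize = TRUE)
  expect_identical(neut$formula, "C2H4O2")
  kept <- standardizeSmiles("CC(=O)[O-]", neutralize = FALSE)
  expect_true(grepl("-", kept$canonical, fixed = TRUE))
})

test_that("elemental profiles reproduce the DBE formula on known formulas", {
  prof <- elementalProfile(c("c1ccccc1", "C", "Cn1cnc2c1c(=O)n(C)c(=O)n2C"),
                           strict = FALSE)
  # benzene: DBE 4, H/C 1, DBE/C 2/3
  expect_equal(prof$dbe[1], 4)
  expect_equal(prof$h_c[1], 1)
  expect_equal(prof$dbe_c[1], 2 / 3)
  # methane: saturated single carbon
  expect_equal(prof$dbe[2], 0)
  expect_equal(prof$h_c[2], 4)
  # caffeine C8H10N4O2: 8 - 5 + 2 + 1 = 6
  expect_identical(prof$formula[3], "C8H10N4O2")
  expect_equal(prof$dbe[3], 6)
  expect_error(elementalProfile("O", strict = TRUE), "without carbon")
})

test_that("DBE agrees with ring + pi-bond enumeration on random molecules", {
  pop <- generateCompounds(syntheticConfig(n = 50, seed = 404))
  smiles <- standardizeSmiles(pop$smiles)$canonical
  prof <- elementalProfile(smiles)
  # independent oracle: rings + double bonds + 2 * triple bonds, by RDKit
  script <- tempfile(fileext = ".py")
  out <- tempfile(fileext = ".json")
  writeLines(c(
    "import sys, json",
    "from rdkit import Chem",
    "smis = json.load(open(sys.argv[1]))",
    "res = []",
    "for s in smis:",
    "    m = Chem.MolFromSmiles(s)",
    "    rings = len(Chem.GetSymmSSSR(m))",
    "    Chem.Kekulize(m, clearAromaticFlags=True)",
    "    pi = sum({Chem.BondType.DOUBLE: 1, Chem.BondType.TRIPLE: 2}",
    "             .get(b.GetBondType(), 0) for b in m.GetBonds())",
    "    res.append(rings + pi)",
    "json.dump(res, open(sys.argv[2], 'w'))"), script)
  smifile <- tempfile(fileext = ".json")
  jsonlite::write_json(smiles, smifile)
  expect_identical(system2("python", c(script, smifile, out),
                           stdout = FALSE, stderr = FALSE), 0L)
  oracle <- unlist(jsonlite::read_json(out, simplifyVector = TRUE))
  expect_equal(prof$dbe, oracle)
})

test_that("applicability domain flags every failed rule", {
  ad <- ApplicabilityDomain()
  prof <- elementalProfile(c("c1ccccc1", "C", "Fc1ccccc1", "CP(C)C"),
                           strict = FALSE)
  dom <- inDomain(prof, ad)
  expect_true(dom$in_domain[1])
  expect_identical(dom$violations[[1]], character(0))
  # methane: below the mass window AND H/C above 3
  expect_false(dom$in_domain[2])
  expect_identical(sort(dom$violations[[2]]), c("h_c", "mw_min"))
  # non-CHONS elements
  expect_identical(dom$violations[[3]], "elements")
  # trimethylphosphine: disallowed element, and its formula-based DBE/C
  # (undefined for P-organics) also falls outside the ratio window
  expect_true("elements" %in% dom$violations[[4]])
})

test_that("domain bounds are closed intervals", {
  ad <- ApplicabilityDomain(mwRange = c(78.11184, 900))
  prof <- elementalProfile("c1ccccc1")
  expect_true(inDomain(prof, ad)$in_domain)
  # DBE/C exactly 1.0 passes (closed upper bound)
  prof2 <- elementalProfile("O=[N+]([O-])c1ccc(cc1)[N+](=O)[O-]",
                            strict = FALSE)
  expect_equal(prof2$dbe_c, 1.0)
  expect_true(inDomain(prof2, ApplicabilityDomain())$in_domain)
})

test_that("invalid domain definitions are rejected", {
  expect_error(ApplicabilityDomain(mwRange = c(900, 50)), "min < max")
  rb <- rbind(h_c = c(3, 0.3), o_c = c(0, 3), n_c = c(0, 1.3),
              s_c = c(0, 0.8), dbe_c = c(0, 1))
  expect_error(ApplicabilityDomain(ratioBounds = rb), "lower <= upper")
})

test_that("compound tables round-trip through delimited text and SDF", {
  tab <- data.frame(id = c("a", "b"), smiles = c("c1ccccc1", "CCO"),
                    ic50_nM = c(100, 2e4))
  csv <- tempfile(fileext = ".csv")
  writeCompounds(tab, csv)
  back <- readCompounds(csv)
  expect_equal(back$ic50_nM, tab$ic50_nM)
  expect_identical(back$smiles, tab$smiles)

  # micromolar units are converted to nM
  back_uM <- readCompounds(csv, units = "uM")
  expect_equal(back_uM$ic50_nM, tab$ic50_nM * 1e3)

  # SDF input via the structure converter
  sdf <- tempfile(fileext = ".sdf")
  writeLines(ChemmineOB::convertFormat(
    "SMI", "SDF", "c1ccccc1 benz\n",
    options = data.frame(names = character(0), args = character(0))), sdf)
  sdf_tab <- readCompounds(sdf)
  expect_identical(nrow(sdf_tab), 1L)
  expect_identical(standardizeSmiles(sdf_tab$smiles)$formula, "C6H6")
})
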