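test_that("an all-zero cofactor table is the identity on the group table", {
  for (s in c("SAMPLER", "DKEGR", "GDG")) {
    expect_identical(cofactor_pkas(s, "emboss", zero_cofactor()),
                     enumerate_groups(s, "emboss"), info = s)
    expect_identical(solve_pi_cofactor(s, "emboss", zero_cofactor()),
                     solve_pi(s, "emboss"), info = s)
  }
})

test_that("cofactor corrections target carboxyl groups with bounds clipping", {
  # single-entry table: any G neighbor at +/-1..3 shifts a target by -0.1 each
  tab <- correction_table("cofactor", data.frame(
    residue = "G", offset = c(-3, -2, -1, 1, 2, 3), delta = -0.1))
  base <- get_pka_set("emboss")

  # D at position 2 of a length-3 peptide: only offsets -1 and +1 exist
  g <- cofactor_pkas("GDG", base, tab)
  d_row <- g$kind == "sidechain" & g$residue == "D"
  expect_equal(g$pka[d_row], base$sidechain[["D"]] - 0.2)
  # the C-terminus (position 3) sees neighbors at -2 and -1... but -1 is D
  expect_equal(g$pka[g$kind == "c_term"], base$c_term - 0.1)

  # a K group is never altered, whatever the table says
  tabk <- correction_table("cofactor", data.frame(
    residue = "G", offset = 1, delta = -2))
  gk <- cofactor_pkas("KGD", base, tabk)
  expect_equal(gk$pka[gk$residue == "K" & gk$kind == "sidechain"],
               base$sidechain[["K"]])

  # D at position 4 of a length-7 peptide sums all six offsets
  g7 <- cofactor_pkas("GGGDGGG", base, tab)
  expect_equal(g7$pka[g7$kind == "sidechain"], base$sidechain[["D"]] - 0.6)
})

test_that("a negative delta on D strictly lowers the solved pI", {
  # acidic peptide (pI ~ 4) whose D at position 2 has the G neighbor at -1
  tab <- correction_table("cofactor",
                          data.frame(residue = "G", offset = -1, delta = -0.8))
  s <- "GDDDGK"
  before <- solve_pi(s, "emboss")
  after <- solve_pi_cofactor(s, "emboss", tab)
  expect_lt(after, before)
  expect_equal(after, oracle_grid_pi(cofactor_pkas(s, "emboss", tab)),
               tolerance = 1e-4)
})

test_that("cofactor corrections are local to the window", {
  tab <- get_correction_table("cofactor")
  # editing a residue more than 3 positions from every D/E and the C-terminus
  a <- "DGGGGAGGGGGK"
  b <- "DGGGGWGGGGGK"   # position 6 is > 3 from D (pos 1) and c_term (pos 12)
  ga <- cofactor_pkas(a, "emboss", tab)
  gb <- cofactor_pkas(b, "emboss", tab)
  expect_equal(ga$pka[ga$kind == "c_term"], gb$pka[gb$kind == "c_term"])
  expect_equal(ga$pka[ga$residue == "D"], gb$pka[gb$residue == "D"])
})

test_that("correction tables are validated against the method they parameterize", {
  expect_error(cofactor_pkas("GDGK", "emboss", zero_branca()),
               class = "ampholyte_error_validation")
  expect_error(solve_pi_branca("GDGK", "emboss", zero_cofactor()),
               class = "ampholyte_error_validation")
})

test_that("a zero table and zero carboxyl correction reduce branca to the iterative pI", {
  for (s in c("SAMPLER", "DKEGR", "GGGK")) {
    expect_identical(solve_pi_branca(s, "emboss", zero_branca()),
                     solve_pi(s, "emboss"), info = s)
  }
})

test_that("branca rejects sequences without a basic C-terminus", {
  err <- expect_error(solve_pi_branca("SAMPLEG", "emboss", zero_branca()),
                      class = "ampholyte_error_not_applicable")
  expect_match(conditionMessage(err), "K or R")
})

test_that("branca weights corrections by the neighbor's charged fraction", {
  base <- register_pka_set(
    pka_set("branca-weight-test", c(D = 4.0, K = 10.5, H = 6.0),
            n_term = 9, c_term = 2.5), overwrite = TRUE)
  # acidic peptide (pI ~ 4) where only the D at position 4 has a K at +1;
  # K is essentially fully protonated there, so nearly the full -0.6 applies
  tab_k <- correction_table("branca",
                            data.frame(residue = "K", offset = 1, delta = -0.6))
  s <- "GDDDKGGK"
  plain <- solve_pi(s, base)
  corrected <- solve_pi_branca(s, base, tab_k)
  expect_lt(corrected, plain - 0.01)
  groups_full <- enumerate_groups(s, base)
  target <- groups_full$kind == "sidechain" & groups_full$position == 4L
  groups_full$pka[target] <- groups_full$pka[target] - 0.6
  expect_equal(corrected, oracle_grid_pi(groups_full), tolerance = 1e-3)

  # a neutral neighbor applies (almost) no correction: H carries ~no charge
  # at the basic pI (~12) of this peptide, so the K group it neighbors is
  # left essentially unshifted
  tab_h <- correction_table("branca",
                            data.frame(residue = "H", offset = 1, delta = -0.6))
  s2 <- "GKHGGK"
  expect_equal(solve_pi_branca(s2, base, tab_h), solve_pi(s2, base),
               tolerance = 0.01)
})

test_that("the branca fixed point is stable and matches the grid oracle at convergence", {
  tab <- get_correction_table("branca")
  for (s in test_peptides(10, seed = 707)) {
    p1 <- solve_pi_branca(s, "emboss", tab)
    p2 <- solve_pi_branca(s, "emboss", tab)
    expect_identical(p1, p2, info = s)
    expect_true(p1 > 0 && p1 < 14)
  }
})

test_that("the branca carboxyl-count term shifts acid pKas additively", {
  tab <- correction_table(
    "branca", carboxyl = data.frame(n_d = 1, n_e = 0, delta = 0.5))
  s <- "GDGGK"
  groups <- enumerate_groups(s, "emboss")
  d_row <- groups$kind == "sidechain" & groups$residue == "D"
  groups$pka[d_row] <- groups$pka[d_row] + 0.5
  expect_equal(solve_pi_branca(s, "emboss", tab), oracle_grid_pi(groups),
               tolerance = 1e-3)
  # a pattern absent from the table contributes zero
  s2 <- "GDDGK"  # n_d = 2 not in table
  expect_identical(solve_pi_branca(s2, "emboss", tab), solve_pi(s2, "emboss"))
})
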