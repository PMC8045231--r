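test_that("fatty-acid labels parse into chain, bonds, omega and class", {
  d <- parse_fa_label(c("C16:0", "C22:6n3", "C18:1n9", "C18:2n6"))
  expect_equal(d$chain_length, c(16L, 22L, 18L, 18L))
  expect_equal(d$n_double_bonds, c(0L, 6L, 1L, 2L))
  expect_equal(d$omega_class, c("none", "n3", "n9", "n6"))
  expect_equal(d$sat_class, c("SFA", "PUFA", "MUFA", "PUFA"))
})

test_that("malformed or inconsistent labels are rejected by name", {
  expect_error(parse_fa_label("16:0"), "16:0")
  expect_error(parse_fa_label("C18-1n9"), "C18-1n9")
  expect_error(parse_fa_label("C18:1"), "omega")
  expect_error(parse_fa_label("C16:0n7"), "omega suffix")
  expect_error(parse_fa_label("C18:1n5"), "omega class")
  expect_error(parse_fa_label("C2:0"), "chain length")
})

test_that("composition tables enforce closure, uniqueness and coverage", {
  m <- random_composition(4, c("C16:0", "C18:1n9", "C18:2n6"), seed = 1)
  comp <- composition_table(m)
  expect_s3_class(comp, "composition_table")
  m_bad <- m; m_bad[1, 1] <- m_bad[1, 1] + 2
  expect_error(composition_table(m_bad), "deviate from 100")
  # renormalization restores exact closure
  renorm <- composition_table(m_bad, closure_tol = 3, renormalize = TRUE)
  expect_equal(unname(rowSums(renorm$proportions)), rep(100, 4))
  m_dup <- m; rownames(m_dup)[2] <- rownames(m_dup)[1]
  expect_error(composition_table(m_dup), "duplicated species")
  m_neg <- m; m_neg[1, 1:2] <- c(-1, m[1, 1] + m[1, 2] + 1)
  expect_error(composition_table(m_neg), "non-negative")
})

test_that("class sums match hand-derived compositions", {
  comp <- one_species_comp("C16:0" = 25, "C18:1n9" = 25,
                           "C18:2n6" = 30, "C20:5n3" = 20)
  cs <- class_sums(comp)
  expect_equal(cs$sfa, 25)
  expect_equal(cs$mufa, 25)
  expect_equal(cs$pufa, 50)
  expect_equal(cs$n3_over_total_pufa, 0.4)

  half <- one_species_comp("C18:2n6" = 50, "C22:6n3" = 50)
  expect_equal(class_sums(half)$pufa, 100)
  expect_equal(class_sums(half)$n3_over_total_pufa, 0.5)

  pure <- one_species_comp("C16:0" = 100)
  expect_warning(cs0 <- class_sums(pure), "total PUFA is zero")
  expect_equal(cs0$sfa, 100)
  expect_true(is.na(cs0$n3_over_total_pufa))
})

test_that("average chain length is the mol-fraction-weighted mean", {
  expect_equal(unname(average_chain_length(one_species_comp("C18:0" = 100))), 18)
  expect_equal(unname(average_chain_length(
    one_species_comp("C16:0" = 50, "C18:0" = 50))), 17)
  expect_equal(unname(average_chain_length(
    one_species_comp("C14:0" = 25, "C16:0" = 25, "C22:6n3" = 50))), 18.5)
})

test_that("double bond index counts bonds per 100 fatty acids", {
  expect_equal(unname(double_bond_index(one_species_comp("C16:0" = 100))), 0)
  expect_equal(unname(double_bond_index(one_species_comp("C18:1n9" = 100))), 100)
  expect_equal(unname(double_bond_index(
    one_species_comp("C16:0" = 50, "C22:6n3" = 50))), 300)
})

test_that("peroxidizability index applies the printed coefficients exactly", {
  expect_equal(unname(peroxidizability_index(
    one_species_comp("C18:1n9" = 100))), 2.5)
  expect_equal(unname(peroxidizability_index(
    one_species_comp("C16:0" = 100))), 0)
  expect_equal(unname(peroxidizability_index(
    one_species_comp("C18:2n6" = 50, "C20:4n6" = 25, "C16:0" = 25))), 150)
})

test_that("anti-inflammatory index is the enumerated percentage ratio", {
  comp <- one_species_comp("C20:3n6" = 1, "C20:5n3" = 2, "C22:6n3" = 3,
                           "C20:4n6" = 2, "C16:0" = 92)
  expect_equal(unname(anti_inflammatory_index(comp)), 300)
  comp0 <- one_species_comp("C20:4n6" = 5, "C16:0" = 95)
  expect_equal(unname(anti_inflammatory_index(comp0)), 0)
  eqc <- one_species_comp("C22:6n3" = 4, "C20:4n6" = 4, "C16:0" = 92)
  expect_equal(unname(anti_inflammatory_index(eqc)), 100)
  noden <- one_species_comp("C22:6n3" = 4, "C16:0" = 96)
  expect_error(anti_inflammatory_index(noden), "arachidonic")
  zeroden <- one_species_comp("C22:6n3" = 4, "C20:4n6" = 0, "C16:0" = 96)
  expect_warning(ai <- anti_inflammatory_index(zeroden), "zero")
  expect_true(is.na(ai))
})

test_that("indices are invariant to column permutation and closure holds", {
  labels <- names(default_fa_panel())
  m <- random_composition(8, labels, seed = 42)
  comp <- composition_table(m)
  perm <- composition_table(m[, sample(ncol(m))])
  t1 <- fa_index_table(comp)
  t2 <- fa_index_table(perm)
  expect_equal(t1, t2)
  cs <- class_sums(comp)
  expect_equal(cs$sfa + cs$mufa + cs$pufa, unname(rowSums(m)),
               tolerance = 1e-12)
})

test_that("moving mass from saturated to hexaenoic acid raises DBI and PI", {
  base <- one_species_comp("C16:0" = 60, "C22:6n3" = 40)
  shifted <- one_species_comp("C16:0" = 50, "C22:6n3" = 50)
  expect_gt(unname(double_bond_index(shifted)), unname(double_bond_index(base)))
  expect_gt(unname(peroxidizability_index(shifted)),
            unname(peroxidizability_index(base)))
})

test_that("index table bounds hold on random compositions", {
  labels <- names(default_fa_panel())
  fa <- parse_fa_label(labels)
  m <- random_composition(20, labels, seed = 7)
  idx <- fa_index_table(composition_table(m))
  expect_true(all(idx$acl >= min(fa$chain_length) &
                  idx$acl <= max(fa$chain_length)))
  expect_true(all(idx$dbi >= 0 & idx$dbi <= 600))
  expect_true(all(idx$pi_index >= 0 & idx$pi_index <= 800))
  expect_true(all(idx$n3_over_total_pufa >= 0 & idx$n3_over_total_pufa <= 1))
  expect_true(all(idx$ai >= 0))
})

test_that("composition CSV reader and index writer round-trip", {
  labels <- c("C16:0", "C18:1n9", "C20:4n6", "C22:6n3")
  m <- random_composition(5, labels, seed = 3)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(species = rownames(m), m, check.names = FALSE),
                   f, row.names = FALSE)
  comp <- read_composition_csv(f)
  expect_equal(comp$proportions, m)
  out <- tempfile(fileext = ".csv")
  write_index_csv(fa_index_table(comp), out)
  back <- utils::read.csv(out)
  expect_equal(back$acl, unname(average_chain_length(comp)), tolerance = 1e-8)
})
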