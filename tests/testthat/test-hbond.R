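test_that("bond energy hits -epsilon at the optimum and vanishes at 90 degrees", {
  p <- default_hbond_params()
  # at d = d_opt, theta = 0 the radial term is 3 - 4 = -1, so dG = -epsilon
  expect_equal(hbond_energy("N", "N", 3.2, 0), -2.0)
  expect_equal(hbond_energy("N", "O", 3.0, 0), -2.8)
  expect_equal(hbond_energy("O", "N", 3.0, 0), -2.8)  # pair class is unordered
  expect_equal(hbond_energy("O", "O", 2.8, 0), -4.0)
  for (pair in list(c("N", "N"), c("N", "O"), c("O", "O"))) {
    expect_equal(hbond_energy(pair[1], pair[2], 3.1, 90), 0)
  }
})

test_that("bond energy matches independent step-by-step evaluation", {
  # N-O at 3.5 A, 20 deg off linear, evaluated term by term
  r <- 3.0 / 3.5
  radial <- 3 * r^8 - 4 * r^6
  angular <- cos(20 * pi / 180)^4
  expected <- 2.8 * radial * angular
  expect_equal(hbond_energy("N", "O", 3.5, 20), expected)
  expect_equal(round(expected, 3), -1.555)
})

test_that("energy is minimised at d_opt, repulsive near zero, vanishing far away", {
  p <- default_hbond_params()
  for (i in seq_len(nrow(p))) {
    el <- strsplit(p$pair_class[i], "-")[[1L]]
    at_opt <- hbond_energy(el[1], el[2], p$d_opt[i], 0)
    expect_equal(at_opt, -p$epsilon[i])
    for (d in seq(1.5, 6, by = 0.1)) {
      expect_gte(hbond_energy(el[1], el[2], d, 0), at_opt - 1e-12)
    }
    expect_gt(hbond_energy(el[1], el[2], 0.5, 0), 0)      # repulsive core
    far <- hbond_energy(el[1], el[2], 50, 0)
    expect_lt(far, 0)
    expect_gt(far, -1e-4)                                  # -> 0 from below
  }
  # attractive bond weakens monotonically as theta grows on [0, 90]
  e <- vapply(seq(0, 90, by = 5), function(th) hbond_energy("N", "O", 3.0, th),
              numeric(1))
  expect_true(all(diff(e) >= 0))
})

test_that("geometry records parse with line-numbered validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("donor_element\tacceptor_element\tdistance\tangle",
               "N\tO\t3.0\t0",
               "N\tN\t3.2\t10",
               "O\tO\t2.9\t25"), path)
  rec <- parse_hbond_records(path)
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$line, 2:4)

  writeLines(c("donor_element\tacceptor_element\tdistance\tangle",
               "N\tO\t-1.0\t0"), path)
  expect_error(parse_hbond_records(path), "line 2.*positive")
  writeLines(c("donor_element\tacceptor_element\tdistance\tangle",
               "N\tX\t3.0\t0"), path)
  expect_error(parse_hbond_records(path), "line 2.*unknown element")

  writeLines(character(0), path)
  empty <- parse_hbond_records(path)
  expect_identical(nrow(empty), 0L)
  expect_equal(complex_energy(empty)$total_energy, 0)
})

test_that("complex energy is the sum of per-bond energies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("donor_element\tacceptor_element\tdistance\tangle",
               "N\tO\t3.0\t0",
               "N\tO\t3.0\t0"), path)
  two <- complex_energy(parse_hbond_records(path))
  expect_equal(two$total_energy, -5.6)

  writeLines(c("donor_element\tacceptor_element\tdistance\tangle",
               "N\tO\t3.1\t12",
               "N\tN\t3.4\t33",
               "O\tO\t2.8\t5",
               "O\tN\t2.7\t48",
               "N\tN\t3.2\t0"), path)
  bonds <- parse_hbond_records(path)
  ce <- complex_energy(bonds)
  oracle <- sum(vapply(seq_len(nrow(bonds)), function(i) {
    hbond_energy(bonds$donor_element[i], bonds$acceptor_element[i],
                 bonds$distance[i], bonds$angle[i])
  }, numeric(1)))
  expect_equal(ce$total_energy, oracle)
  # permutation invariance
  perm <- bonds[c(3, 1, 5, 2, 4), ]
  expect_equal(complex_energy(perm)$total_energy, ce$total_energy)
})

test_that("designs rank by ascending energy with stable ties and a min oracle", {
  mk <- function(id, e) structure(list(design_id = id, bond_energies = numeric(0),
                                       total_energy = e), class = "complex_energy")
  ranked <- rank_designs(list(mk("a", -6.8), mk("b", -2.1), mk("c", -9.0)))
  expect_identical(ranked$design_id, c("c", "a", "b"))
  expect_equal(ranked$total_energy, c(-9.0, -6.8, -2.1))

  ties <- rank_designs(list(mk("first", -1), mk("second", -1), mk("third", -1)))
  expect_identical(ties$design_id, c("first", "second", "third"))

  set.seed(8)
  energies <- runif(448, -12, 0)
  cx <- lapply(seq_along(energies), function(i) mk(sprintf("h%03d", i), energies[i]))
  ranked <- rank_designs(cx)
  expect_identical(ranked$design_id[1L], sprintf("h%03d", which.min(energies)))
  expect_equal(ranked$total_energy[1L], min(energies))
})
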