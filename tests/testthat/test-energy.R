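# hand-summed expectations from the packaged stack table:
#   ACTAACTTT: steps AC/UG -2.2, CT/GA -2.1, TA/AU -1.3, AC/UG -2.2,
#   bulge +0.5 -> -7.3

test_that("duplex energy matches hand-summed stack/penalty arithmetic", {
  p <- duplex_params()
  expect_equal(duplex_energy("ACTAACTTT", p), -7.3)
  # -1 variant keeps the helix but pays the full -1 penalty in WT mode
  expect_equal(duplex_energy("ACTGACTTT", p), -7.3 + 6)
  # -2 variant breaks the two stacks flanking -2 and pays its penalty
  expect_equal(duplex_energy("ACCAACTTT", p), -7.3 + 2.1 + 1.3 + 2)
  # wobble at -3 swaps in the weaker stacks
  expect_equal(duplex_energy("ATTAACTTT", p), -1.4 - 0.6 - 1.3 - 2.2 + 0.5)
})

test_that("non-binding windows clamp to zero", {
  p <- duplex_params()
  expect_equal(duplex_energy("GGGGAGGGG", p), 0)
  expect_gt(duplex_energy("GGGGAGGGG", p, clamp = FALSE), 0)
})

test_that("malformed windows are rejected", {
  expect_error(duplex_energy("ACTAAC"), "9-mer")
  expect_error(duplex_energy("ACTANCTTT"), "non-ACGT")
  expect_error(duplex_energy("ACTACCTTT"), "branch adenosine")
})

test_that("K700E mode stabilizes -1 variants, scaled by lambda", {
  p1 <- duplex_params(lambda_minus1 = 1)
  p04 <- duplex_params(lambda_minus1 = 0.4)
  w <- "ACTGACTTT"
  expect_equal(duplex_energy(w, p1, mode = "K700E"),
               duplex_energy(w, p1, mode = "WT"))
  expect_equal(duplex_energy(w, p04, mode = "K700E"), -7.3 + 0.4 * 6)
  # canonical -1 base: modes agree regardless of lambda
  expect_equal(duplex_energy("ACTAACTTT", p04, mode = "K700E"),
               duplex_energy("ACTAACTTT", p04, mode = "WT"))
})

test_that("mode ordering and mismatch monotonicity hold on random windows", {
  set.seed(42)
  wins <- replicate(500, paste0(
    paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = ""), "A",
    paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")
  ))
  p <- duplex_params(lambda_minus1 = 0.4)
  e_wt <- duplex_energy(wins, p, "WT", clamp = FALSE)
  e_ke <- duplex_energy(wins, p, "K700E", clamp = FALSE)
  expect_true(all(e_ke <= e_wt + 1e-12))
  minus1 <- substr(wins, 4, 4) != "A"
  expect_true(all(e_ke[minus1] < e_wt[minus1]))
  expect_true(all(e_ke[!minus1] == e_wt[!minus1]))
  # degrading any one duplex position never stabilizes the window
  for (col in c(1, 2, 3, 4, 6)) {
    bad <- c("C", "A", "G", "G", "A")[match(col, c(1, 2, 3, 4, 6))]
    mut <- wins
    substr(mut, col, col) <- bad
    expect_true(all(duplex_energy(mut, p, "WT", clamp = FALSE) >=
                      e_wt - 1e-12))
  }
})

test_that("predict_bp returns the minimum-energy adenosine, proximal on ties", {
  up <- paste0(strrep("GC", 15), "CTAAC", strrep("GC", 10))
  hit <- predict_bp(up)
  expect_equal(hit$position, 33)  # the adenosine of the single CTAAC
  expect_equal(hit$offset_to_acceptor, -22)
  # two identical competitive windows: the acceptor-proximal one wins
  up2 <- paste0("GC", "ACTAACT", strrep("GC", 4), "ACTAACT", strrep("GC", 8))
  two <- gregexpr("CTAAC", up2)[[1]]
  hit2 <- predict_bp(up2)
  expect_equal(hit2$position, max(two) - 1 + 3)
  # no adenosine in the window
  expect_null(predict_bp(strrep("GC", 30)))
})

test_that("compare_energies reports means, direction, and sane p-values", {
  x <- c(-5, -4.2, -6.1, -3.3)
  expect_error(compare_energies(numeric(0), x), "nonempty")
  same <- compare_energies(x, x)
  expect_equal(same$mean_a, same$mean_b)
  expect_gt(same$p_value, 0.9)
  cmp <- compare_energies(c(-1, -0.5, -0.2), c(-7, -6, -5.5),
                          labels = c("weak", "strong"))
  expect_identical(cmp$less_stable, "weak")
})

test_that("rank-sum p agrees with an exhaustive permutation oracle on small sets", {
  set.seed(7)
  for (i in 1:5) {
    a <- round(rnorm(5, -3, 1), 3)
    b <- round(rnorm(6, -5, 1), 3)
    cmp <- compare_energies(a, b)
    expect_equal(cmp$p_value, oracle_permutation_p(a, b), tolerance = 1e-10)
  }
})
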