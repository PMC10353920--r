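test_that("vital-rate set enforces its invariants", {
  expect_error(vital_rate_set(s1h = 0.37, s2 = 0.87, sa = 0.86, BP2 = 0.17,
                              BP3 = 0.58, BP4 = 0.71, BP5 = 0.9, BPeb = 0.72,
                              CS = 4.08, HS = 0.61),
               "BP5")
  expect_error(vital_rate_set(s2 = 0.87, sa = 0.86, BP2 = 0.17, BP3 = 0.58,
                              BP4 = 0.71, BPeb = 0.72, CS = 4.08, HS = 0.61),
               "first-year survival")
  expect_error(vital_rate_set(s1h = 1.2, s2 = 0.87, sa = 0.86, BP2 = 0.17,
                              BP3 = 0.58, BP4 = 0.71, BPeb = 0.72, CS = 4.08,
                              HS = 0.61),
               "s1h")
  # s1f + FS without s1h is a legal parameterisation
  ok <- vital_rate_set(s1f = 0.75, FS = 0.22, s2 = 0.87, sa = 0.86,
                       BP2 = 0.17, BP3 = 0.58, BP4 = 0.71, BPeb = 0.72,
                       CS = 4.08, HS = 0.61)
  expect_s3_class(ok, "vital_rate_set")
})

test_that("effective first-year survival follows the requested pathway", {
  rates <- eider_vital_rates()
  expect_equal(effective_first_year_survival(rates, "fledging_product"),
               0.165)
  expect_equal(effective_first_year_survival(rates, "direct"), 0.37)
  expect_equal(effective_first_year_survival(rates, "pooled"), 0.2675)
  only_fledging <- vital_rate_set(s1f = 0.75, FS = 0.22, s2 = 0.87,
                                  sa = 0.86, BP2 = 0.17, BP3 = 0.58,
                                  BP4 = 0.71, BPeb = 0.72, CS = 4.08,
                                  HS = 0.61)
  expect_error(effective_first_year_survival(only_fledging, "direct"),
               "s1h")
})

test_that("fertility composes clutch size, hatching success, first-year survival and the sex ratio", {
  rates <- eider_vital_rates()
  expect_equal(fertility(rates, "fledging_product",
                         propensity_adjust = FALSE),
               0.5 * 4.08 * 0.61 * 0.165)
  expect_equal(fertility(rates, "direct", propensity_adjust = FALSE),
               0.460428)
  expect_equal(fertility(rates, "pooled"),
               0.5 * 4.08 * 0.61 * 0.2675 * 0.72)
  zero_hs <- vital_rate_set(s1h = 0.37, s2 = 0.87, sa = 0.86, BP2 = 0.17,
                            BP3 = 0.58, BP4 = 0.71, BPeb = 0.72, CS = 4.08,
                            HS = 0)
  expect_equal(fertility(zero_hs, "direct"), 0)
})

test_that("matrix entries match the life-cycle formulation", {
  A <- build_matrix(eider_vital_rates())
  expect_equal(A["NB", "B"], 0.86 * 0.28)
  expect_equal(A["PB2", "1yo"], 0.87 * 0.83)
  expect_equal(A["B", "1yo"], 0.87 * 0.17)
  expect_equal(A["B", "PB4"], 0.86)
  expect_equal(A["B", "B"], A["B", "NB"])
  expect_equal(A["NB", "B"], A["NB", "NB"])
  # structural zeros exactly where transitions are impossible
  possible <- rbind(c(1, 5), c(2, 1), c(3, 2), c(4, 3),
                    c(5, 1), c(5, 2), c(5, 3), c(5, 4), c(5, 5), c(5, 6),
                    c(6, 5), c(6, 6))
  mask <- matrix(FALSE, 6, 6)
  mask[possible] <- TRUE
  expect_true(all(unclass(A)[!mask] == 0))
  expect_true(all(unclass(A)[mask] > 0))
})

test_that("non-fertility column sums equal each column's survival rate", {
  for (seed in 1:20) {
    rates <- generate_vital_rate_set(seed, jitter = 0.1)
    A <- unclass(build_matrix(rates))
    A[1, 5] <- 0  # remove fertility
    sums <- colSums(A)
    expect_equal(sums[["1yo"]], rates$s2, tolerance = 1e-12)
    expect_equal(unname(sums[2:6]), rep(rates$sa, 5), tolerance = 1e-12)
  }
})

test_that("full breeding propensity collapses the nonbreeder stage", {
  rates <- vital_rate_set(s1h = 0.37, s2 = 0.87, sa = 0.86, BP2 = 0.17,
                          BP3 = 0.58, BP4 = 0.71, BPeb = 1, CS = 4.08,
                          HS = 0.61)
  A <- build_matrix(rates, mode = "direct")
  expect_equal(A["B", "NB"], 0.86)
  expect_equal(A["NB", "B"], 0)   # nonbreeder stage unreachable
  expect_equal(A["NB", "NB"], 0)
})

test_that("with fertility zero the growth rate equals adult survival", {
  rates <- vital_rate_set(s1h = 0.37, s2 = 0.87, sa = 0.86, BP2 = 0.17,
                          BP3 = 0.58, BP4 = 0.71, BPeb = 0.72, CS = 0,
                          HS = 0.61)
  A <- build_matrix(rates)
  expect_equal(growth_rate(A), 0.86, tolerance = 1e-10)
})

test_that("the matrix edge list mirrors the nonzero structure", {
  A <- build_matrix(eider_vital_rates())
  edges <- matrix_edges(A)
  expect_equal(nrow(edges), 12)
  expect_equal(edges$value[edges$from == "B" & edges$to == "1yo"],
               A["1yo", "B"])
})

test_that("jittered vital-rate sets build valid matrices with unit elasticity mass", {
  for (seed in 1:100) {
    rates <- generate_vital_rate_set(seed, jitter = 0.1)
    A <- build_matrix(rates)
    res <- elasticity_matrix(A)
    expect_equal(sum(res$elasticity), 1, tolerance = 1e-10)
  }
})
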