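test_that("assembly assignment follows argmax with a selectivity gate", {
  asg <- assign_assemblies(rbind(c(40, 2, 2), c(10, 10, 10), c(1, 1, 30)))
  expect_equal(as.integer(asg), c(1L, NA, 3L))
  # tie with high rates but no selectivity stays unassigned at 0.3
  expect_true(is.na(assign_assemblies(rbind(c(10, 10), c(0, 20)))[1]))
  # ties resolve to the lowest stimulus id when above threshold
  asg2 <- assign_assemblies(rbind(c(30, 30, 1), c(30, 1, 1)),
                            threshold = 0)
  expect_equal(as.integer(asg2), c(1L, 1L))
  expect_warning(assign_assemblies(matrix(0, 3, 2)), "zero")
})

test_that("ratio metrics match their closed forms on synthetic reports", {
  asg <- synthetic_assignment(c(2, 1, 1, 1, 1))
  # equal per-neuron rates everywhere -> firing-rate ratio 1, size ratio 2
  rates <- rep(3, 6)
  expect_equal(firing_rate_ratio(rates, asg), 1)
  expect_equal(assembly_size_ratio(rates, asg), 2)
  # per-neuron rates (2,1,1,1,1) by assembly -> firing-rate ratio 2
  asg5 <- synthetic_assignment(rep(1, 5))
  expect_equal(firing_rate_ratio(c(2, 1, 1, 1, 1), asg5), 2)
  # population rates (4,2,2,2,2) -> activity ratio 2
  expect_equal(assembly_activity_ratio(c(4, 2, 2, 2, 2), asg5), 2)
  expect_equal(assembly_activity_ratio(rep(1, 5), asg5), 1)
  # empty competitor -> undefined
  er <- rbind(c(40, 1), c(35, 2))
  asg_missing <- assign_assemblies(er)
  expect_true(is.na(assembly_activity_ratio(c(3, 3), asg_missing)))
})

test_that("ratio metrics ignore how non-target assemblies are labeled", {
  set.seed(10)
  rates <- runif(12, 1, 5)
  asg <- structure(rep(1:4, each = 3), n_assemblies = 4L,
                   class = "assembly_assignment")
  perm <- structure(c(rep(1L, 3), rep(c(4L, 2L, 3L), each = 3)),
                    n_assemblies = 4L, class = "assembly_assignment")
  rates_perm <- rates  # members unchanged, only labels 2..4 permuted
  expect_equal(assembly_activity_ratio(rates, asg),
               assembly_activity_ratio(rates_perm, perm))
  expect_equal(firing_rate_ratio(rates, asg),
               firing_rate_ratio(rates_perm, perm))
})

test_that("activity ratio and choices-to-right follow their definitions", {
  expect_equal(activity_ratio_AR(1, 1), 0.5)
  expect_equal(activity_ratio_AR(4, 1), 0.8)
  expect_equal(activity_ratio_AR(1, 0), 1)
  expect_true(is.na(activity_ratio_AR(0, 0)))
  expect_equal(choices_to_right(0.5), 50)
  expect_equal(choices_to_right(0.8), 80)
  expect_equal(choices_to_right(0), 0)
  # swapping R and L mirrors the percentage
  r <- 3.7; l <- 1.2
  expect_equal(choices_to_right(activity_ratio_AR(l, r)),
               100 - choices_to_right(activity_ratio_AR(r, l)))
})

test_that("normalized excitatory incoming weights sum the positive
           within-assembly entries", {
  asg <- synthetic_assignment(c(2, 2))
  M <- matrix(0, 4, 4)
  M[1:2, 1:2] <- 1.5   # block sums 6 and 14 -> fractions 0.3 / 0.7
  M[3:4, 3:4] <- 3.5
  expect_equal(normalized_excitatory_incoming_weights(M, asg),
               c(0.3, 0.7))
  # symmetric blocks -> 0.5 each; negative entries are ignored
  M2 <- matrix(-1, 4, 4)
  M2[1:2, 1:2] <- 2; M2[3:4, 3:4] <- 2
  expect_equal(normalized_excitatory_incoming_weights(M2, asg),
               c(0.5, 0.5))
  expect_warning(
    out <- normalized_excitatory_incoming_weights(-M2 - 3, asg))
  expect_true(all(is.na(out)))
})

test_that("lateral inhibition is the G-path / M_IE matrix product", {
  G <- diag(c(1, 1)); M <- diag(c(2, 3))
  expect_equal(lateral_inhibition_matrix(G, M), diag(c(2, 3)))
  expect_equal(lateral_inhibition_matrix(matrix(0, 2, 3), matrix(1, 3, 2)),
               matrix(0, 2, 2))
  expect_error(lateral_inhibition_matrix(matrix(1, 2, 3), matrix(1, 2, 2)),
               "shapes")
})

test_that("pairwise correlations: unit diagonal, zero-variance flags, and
           independence", {
  set.seed(11)
  bins <- matrix(rpois(5 * 500, 2), 5, 500)
  bins[5, ] <- 0
  cc <- pairwise_correlations(bins)
  expect_equal(diag(cc), rep(1, 5))
  expect_equal(attr(cc, "zero_variance"), 5L)
  expect_equal(unname(cc[5, 1]), 0)
  off <- cc[upper.tri(cc)][1:6]
  expect_lt(max(abs(off)), 0.15)  # independent Poisson trains
  expect_error(pairwise_correlations(bins[, 1:50]))
})

test_that("within/between summaries exclude the diagonal and unassigned
           neurons", {
  asg <- c(1L, 1L, 2L, NA)
  mat <- matrix(1, 4, 4)
  mat[1, 2] <- 5; mat[2, 1] <- 5   # within pair
  mat[4, ] <- 100; mat[, 4] <- 100 # unassigned: must be ignored
  s <- within_between_summary(mat, asg)
  expect_equal(s$median[s$class == "within"], 5)
  expect_equal(s$median[s$class == "between"], 1)
})

test_that("closed-form activity ratio holds on rasters with known rates", {
  # build binned counts with per-assembly rates fixed by construction
  set.seed(12)
  asg <- synthetic_assignment(c(3, 3))
  bins <- rbind(matrix(rpois(3 * 5000, 0.08), 3),   # 4 Hz at 20-ms bins
                matrix(rpois(3 * 5000, 0.04), 3))   # 2 Hz
  rates <- rowSums(bins) / (5000 * 0.02)
  ar <- assembly_activity_ratio(rates, asg)
  expect_equal(ar, sum(rates[1:3]) / sum(rates[4:6]))
  expect_equal(ar, 2, tolerance = 0.1)
})
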