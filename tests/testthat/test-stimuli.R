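test_that("pattern specs validate probabilities and build memberships", {
  expect_error(pattern_spec(2, probabilities = c(0.5, 0.6)), "sum")
  expect_error(pattern_spec(2, probabilities = c(-0.1, 1.1)))
  spec <- pattern_spec(3, group_size = 10)
  expect_equal(spec$n_inputs, 30)
  expect_equal(colSums(spec$membership), rep(10, 3))
  expect_equal(sum(rowSums(spec$membership) > 1), 0)  # non-overlapping
  # half-overlapping pair shares exactly half of its members
  ov <- pattern_spec(2, group_size = 10, overlap_fraction = 0.5)
  expect_equal(ov$n_inputs, 15)
  expect_equal(sum(ov$membership[, 1] & ov$membership[, 2]), 5)
})

test_that("random schedules hit the configured probabilities", {
  set.seed(1)
  spec <- pattern_spec(2, group_size = 5)
  sched <- build_schedule(spec, 1000 * 200)  # 1000 events
  counts <- table(factor(sched$events$pattern_id, levels = 1:2))
  expect_lt(abs(counts[[1]] - 500), 3 * sqrt(250))

  # goodness of fit at alpha = 0.01 for a 30/70 protocol
  set.seed(2)
  spec2 <- pattern_spec(2, group_size = 5, probabilities = c(0.3, 0.7))
  sched2 <- build_schedule(spec2, 1500 * 200)
  tab <- table(factor(sched2$events$pattern_id, levels = 1:2))
  gof <- chisq.test(tab, p = c(0.3, 0.7))
  expect_gt(gof$p.value, 0.01)
  expect_equal(sum(empirical_frequencies(sched2)), 1)
})

test_that("fixed sequences cycle and events never overlap", {
  spec <- pattern_spec(3, group_size = 4, order = "fixed_sequence")
  sched <- build_schedule(spec, 12 * 200)
  expect_equal(sched$events$pattern_id, rep(1:3, 4))
  ev <- sched$events[order(sched$events$onset_ms), ]
  expect_true(all(diff(ev$onset_ms) >= spec$duration_ms))
  expect_equal(ev$offset_ms - ev$onset_ms, rep(spec$duration_ms, 12))
})

test_that("rate programs put members at the pattern rate and everyone else
           at background", {
  set.seed(3)
  spec <- pattern_spec(2, group_size = 5)
  sched <- build_schedule(spec, 2000)
  prog <- schedule_to_rates(sched)
  ev <- sched$events[1, ]
  step_on <- ev$onset_ms + 50
  col <- prog$rates[, prog$program[step_on]]
  expect_equal(unname(col[spec$membership[, ev$pattern_id]]), rep(50, 5))
  expect_equal(unname(col[!spec$membership[, ev$pattern_id]]), rep(2, 5))
  # gap steps: all at background
  gap_col <- prog$rates[, prog$program[50]]
  expect_equal(unname(gap_col), rep(2, 10))
  # overlapping groups: shared members fire at the pattern rate under
  # either pattern
  ospec <- pattern_spec(2, group_size = 4, overlap_fraction = 0.5)
  osched <- build_schedule(ospec, 2000)
  oprog <- schedule_to_rates(osched)
  shared <- which(ospec$membership[, 1] & ospec$membership[, 2])
  for (pid in 1:2) {
    colp <- oprog$rates[, pid + 1]
    expect_equal(unname(colp[shared]), rep(50, length(shared)))
  }
})

test_that("coherence rates split r_max by the signed coherence", {
  expect_equal(coherence_rates(0.5), c(R = 50, L = 0))
  expect_equal(coherence_rates(0), c(R = 25, L = 25))
  expect_equal(coherence_rates(-0.5), c(R = 0, L = 50))
  expect_error(coherence_rates(0.6), "coherence")
  # training columns of the coherence protocol silence the opposite pool
  spec <- coherence_spec(group_size = 4)
  sched <- build_schedule(spec, 1000)
  prog <- schedule_to_rates(sched)
  expect_equal(unname(prog$rates[, 2]), c(rep(50, 4), rep(0, 4)))
  expect_equal(unname(prog$rates[, 3]), c(rep(0, 4), rep(50, 4)))
})

test_that("conditioned schedules follow the conditional table and stay
           time-aligned", {
  expect_error(conditioned_spec(matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2)),
               "sum")
  set.seed(4)
  spec <- conditioned_spec(group_size = 4)
  sched <- build_schedule(spec, 3000 * 200)
  ev <- sched$events
  a <- ev[ev$pattern_id <= 2, ]
  b <- ev[ev$pattern_id >= 3, ]
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$onset_ms, b$onset_ms)  # simultaneous pairs
  # conditional frequencies close to (1/3, 2/3) given S1
  s1 <- b$pattern_id[a$pattern_id == 1]
  p_s4_given_s1 <- mean(s1 == 4)
  expect_lt(abs(p_s4_given_s1 - 2 / 3), 3 * sqrt(2 / 9 / length(s1)))
  s2 <- b$pattern_id[a$pattern_id == 2]
  expect_lt(abs(mean(s2 == 4) - 1 / 3), 3 * sqrt(2 / 9 / length(s2)))
  # degenerate table: B deterministically follows A
  set.seed(5)
  dspec <- conditioned_spec(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
                            group_size = 4)
  dsched <- build_schedule(dspec, 200 * 200)
  dev <- dsched$events
  da <- dev$pattern_id[dev$pattern_id <= 2]
  db <- dev$pattern_id[dev$pattern_id >= 3]
  expect_equal(db, da + 2L)
  # at most one A-pattern and one B-pattern active at any time
  expect_true(all(table(dev$onset_ms) <= 2))
})

test_that("Poisson rasters are seeded, empty at zero rate, and hit the
           requested rate", {
  spec <- pattern_spec(1, group_size = 3)
  expect_equal(sum(rates_to_spikes(blank_program(3, 1000))), 0)
  prog <- constant_program(50, 1, 1e5)
  set.seed(6)
  r1 <- rates_to_spikes(prog)
  set.seed(6)
  r2 <- rates_to_spikes(prog)
  expect_identical(r1, r2)
  rate <- mean(r1) * 1000
  expect_lt(abs(rate - 50), 3 * sqrt(0.05 * 0.95 / 1e5) * 1000)
})

test_that("schedules and rasters round-trip through their CSV formats", {
  set.seed(7)
  spec <- pattern_spec(2, group_size = 3)
  sched <- build_schedule(spec, 5000)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_schedule_csv(sched, csv, json = js)
  back <- read_schedule_csv(csv)
  expect_equal(back$pattern_id, sched$events$pattern_id)
  expect_equal(back$onset_ms, sched$events$onset_ms)
  expect_equal(back$offset_ms, sched$events$offset_ms)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$n_patterns, 2)

  ras <- data.frame(neuron = c(1L, 5L, 2L), time_ms = c(1.5, 2, 3.5))
  rcsv <- tempfile(fileext = ".csv")
  write_raster_csv(ras, rcsv, population = "net")
  rback <- read_raster_csv(rcsv)
  expect_equal(rback$neuron_id, ras$neuron)
  expect_equal(rback$time_ms, ras$time_ms)
  expect_equal(unique(rback$population), "net")
})
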