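# Fast, down-scaled experiment runs: tiny networks and short phases keep
# these under a few seconds each while still exercising the full pipeline.

tiny_config <- function(seed = 1, ...) {
  experiment_config(pattern_spec(2, group_size = 10),
                    n_neurons = 24, learn_ms = 2e4, recover_ms = 2e3,
                    spont_ms = 4e3, probe_presentations = 5,
                    seed = seed, ...)
}

test_that("experiment configs round-trip through JSON", {
  cfg <- tiny_config(seed = 7, fixed_h = TRUE,
                     spont_plastic = c("W", "M"))
  f <- tempfile(fileext = ".json")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$fixed_h, TRUE)
  expect_equal(back$spont_plastic, c("W", "M"))
  expect_equal(back$stimulus$probabilities, cfg$stimulus$probabilities)
  expect_equal(back$stimulus$membership, cfg$stimulus$membership)
  expect_equal(as_params_list(back$params), as_params_list(cfg$params))

  # coherence and conditioned specs keep their subclass
  ccfg <- experiment_config(coherence_spec(group_size = 5), seed = 2)
  write_config(ccfg, f)
  expect_s3_class(read_config(f)$stimulus, "coherence_spec")
  dcfg <- experiment_config(conditioned_spec(group_size = 5), seed = 3)
  write_config(dcfg, f)
  dback <- read_config(f)$stimulus
  expect_s3_class(dback, "conditioned_spec")
  expect_equal(dback$cond_table, conditioned_spec(group_size = 5)$cond_table)
})

test_that("an experiment is deterministic given its seed", {
  cfg <- tiny_config(seed = 42)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$report$pops, r2$report$pops)
  expect_identical(r1$fit$weights$M, r2$fit$weights$M)
  expect_identical(as.integer(r1$fit$assignment),
                   as.integer(r2$fit$assignment))
  r3 <- run_experiment(tiny_config(seed = 43))
  expect_false(identical(r1$fit$weights$M, r3$fit$weights$M))
})

test_that("the experiment pipeline keeps plasticity off outside learning", {
  cfg <- tiny_config(seed = 5)
  res <- run_experiment(cfg)
  # recovery and spontaneous phases ran with frozen weights: re-simulating
  # the spontaneous epoch from the stored post-recovery state with
  # plasticity off must leave the fitted weights untouched
  expect_identical(res$spont$plastic, character(0))
  w_before <- res$fit$weights$M
  sim <- simulate(res$fit, duration_ms = 2e3)
  expect_identical(res$fit$weights$M, w_before)
  expect_s3_class(res$report, "metrics_report")
  expect_length(res$report$pops, 2)
})

test_that("the between-assembly excitation ablation zeroes exactly the
           positive crossing entries", {
  cfg <- tiny_config(seed = 9)
  res <- run_experiment(cfg)
  fit <- res$fit
  ab <- remove_between_assembly_excitation(fit)
  asg <- as.integer(fit$assignment)
  cross <- outer(asg, asg, "!=")
  cross[is.na(cross)] <- TRUE
  expect_true(all(ab$weights$M[cross] <= 0))
  same <- !cross
  expect_identical(ab$weights$M[same], fit$weights$M[same])
})

test_that("resuming from a checkpoint reproduces the original
           trajectory", {
  net <- tiny_net("nDL", N = 10, K = 8, seed = 200)
  net$state$h <- rep(0.1, 10)
  prog <- constant_program(30, 8, 200)
  set.seed(201)
  mid <- run_phase(net, prog)$net
  d <- file.path(tempdir(), "ckpt")
  write_checkpoint(mid, d)
  cont1 <- run_phase(mid, prog)
  restored <- read_checkpoint(d)   # also restores the RNG state
  cont2 <- run_phase(restored, prog)
  expect_identical(cont1$rec$counts, cont2$rec$counts)
  expect_equal(cont1$net$weights$M, cont2$net$weights$M, tolerance = 0)
  expect_equal(cont1$net$state$y, cont2$net$state$y, tolerance = 0)
  expect_equal(restored$state$t, mid$state$t)
})

test_that("probability sweep aggregates ratio metrics across trials", {
  base <- experiment_config(pattern_spec(2, group_size = 8),
                            n_neurons = 20, learn_ms = 1e4,
                            recover_ms = 1e3, spont_ms = 2e3,
                            probe_presentations = 3)
  out <- suppressWarnings(
    run_probability_sweep(c(1, 2), n_patterns = 2, n_trials = 2,
                          base_config = base, seed = 11))
  expect_equal(nrow(out), 4)
  expect_setequal(unique(out$ratio), c(1, 2))
  agg <- attr(out, "summary")
  expect_equal(nrow(agg), 2)
})
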