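test_that("grid enumeration is the exact Cartesian product in declared order", {
  g <- parameter_grid(a = c(1, 2), b = c(10, 20, 30))
  combos <- enumerate_grid(g)
  expect_equal(nrow(combos), 6L)
  expect_equal(combos$a, rep(c(1, 2), each = 3))
  expect_equal(combos$b, rep(c(10, 20, 30), 2))
  expect_equal(nrow(enumerate_grid(parameter_grid(x = 5))), 1L)
  # random grids against a nested-loop count
  set.seed(4)
  for (i in 1:20) {
    k <- sample(1:4, 1)
    vals <- lapply(seq_len(k), function(j) sort(sample(100, sample(1:5, 1))))
    names(vals) <- paste0("p", seq_len(k))
    n <- 0L
    idx <- rep(1L, k)
    sizes <- lengths(vals)
    repeat {
      n <- n + 1L
      j <- k
      while (j >= 1L && idx[j] == sizes[j]) { idx[j] <- 1L; j <- j - 1L }
      if (j < 1L) break
      idx[j] <- idx[j] + 1L
    }
    expect_equal(nrow(enumerate_grid(do.call(parameter_grid, vals))), n)
  }
})

test_that("the published refinement grids enumerate to their stated sizes", {
  round2 <- parameter_grid(c = c(1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5),
                           g = c(30, 40, 50, 60, 70),
                           f = c(0.005, 0.01, 0.015, 0.02, 0.025, 0.03),
                           j = c(1, 2, 3, 4, 5),
                           a = c(5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15),
                           M = c(0.7, 0.75, 0.8, 0.85, 0.9, 0.95))
  expect_equal(nrow(enumerate_grid(round2)), 89100L)
  round3 <- parameter_grid(c = seq(1, 2, by = 0.1),
                           g = 40:60,
                           f = seq(0.01, 0.02, by = 0.001),
                           j = c(1, 2),
                           a = c(13, 14, 15),
                           M = seq(0.9, 0.99, by = 0.01))
  expect_equal(nrow(enumerate_grid(round3)), 152460L)
  # the first-round grid: its true product (the j list has six values)
  round1 <- parameter_grid(c = c(1, 3, 5, 7, 9), g = c(10, 30, 50, 70, 90),
                           f = c(0.01, 0.03, 0.05, 0.07, 0.09),
                           j = c(1, 2, 3, 5, 7, 9), a = c(5, 10, 15, 20, 25),
                           M = c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(nrow(enumerate_grid(round1)), 18750L)
})

test_that("grid validation rejects malformed inputs", {
  expect_error(parameter_grid(a = c(3, 1)), "strictly increasing")
  expect_error(parameter_grid(c(1, 2)), "unique non-empty names")
  expect_error(parameter_grid(a = numeric(0)), "non-empty")
})

test_that("grid refinement brackets the incumbent at finer spacing", {
  g <- parameter_grid(c = c(1, 3, 5, 7, 9))
  r <- refine_grid(g, list(c = 3), list(c = list(radius = 2, step = 0.5)))
  expect_equal(r$c, c(1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5))
  # boundary optimum with hard bounds -> one-sided, incumbent kept
  g2 <- parameter_grid(M = c(0.1, 0.5, 0.9))
  expect_message(
    r2 <- refine_grid(g2, list(M = 0.9), list(M = list(radius = 0.1, step = 0.05)),
                      bounds = list(M = c(0, 1))),
    NA)
  expect_true(0.9 %in% r2$M)
  expect_message(
    r3 <- refine_grid(g2, list(M = 0.9), list(M = list(radius = 0.2, step = 0.05)),
                      bounds = list(M = c(0, 0.95))),
    "clipped")
  expect_true(all(r3$M <= 0.95))
  expect_error(refine_grid(g, list(c = 4), list(c = list(radius = 1, step = 1))),
               "not in the previous grid")
})

test_that("a sweep recovers a planted optimum and reports failures as NA", {
  sim <- shared_sim()
  cfg <- sim$config
  opt <- list(c = 3, g = 50)
  asm <- make_synthetic_assembler(sim$annotation, opt,
                                  list(c = c(1, 9), g = c(10, 90)), cfg)
  res <- run_sweep(asm, NULL, parameter_grid(c = c(1, 3, 5), g = c(30, 50, 70)),
                   sim$annotation)
  expect_equal(res$best, list(c = 3, g = 50))
  expect_equal(res$best_objective, 1)
  # the reference against itself scores exactly 1 for every combination
  ref_asm <- function(reads, params) sim$annotation
  res_ref <- run_sweep(ref_asm, NULL, parameter_grid(c = c(1, 2)), sim$annotation)
  expect_true(all(res_ref$results$objective == 1))
  # failing combinations leave NA but the sweep continues
  flaky <- function(reads, params) {
    if (params$c == 1) stop("boom")
    asm(reads, params)
  }
  suppressMessages(
    res_f <- run_sweep(flaky, NULL, parameter_grid(c = c(1, 3), g = c(50)),
                       sim$annotation))
  expect_true(is.na(res_f$results$objective[1]))
  expect_equal(res_f$best, list(c = 3, g = 50))
  all_fail <- function(reads, params) stop("boom")
  suppressMessages(expect_error(
    run_sweep(all_fail, NULL, parameter_grid(c = c(1, 2)), sim$annotation),
    "no successful evaluation"))
})

test_that("refinement rounds never regress and find an off-grid optimum", {
  sim <- shared_sim()
  opt <- list(c = 2.5)
  asm <- make_synthetic_assembler(sim$annotation, opt, list(c = c(1, 9)),
                                  sim$config)
  rounds <- run_refinement_schedule(
    asm, NULL, parameter_grid(c = c(1, 3, 5, 7, 9)), sim$annotation,
    schedule = list(list(c = list(radius = 2, step = 0.5)),
                    list(c = list(radius = 0.5, step = 0.1))))
  objs <- vapply(rounds, function(r) r$best_objective, numeric(1))
  expect_true(all(diff(objs) >= 0))
  expect_equal(rounds[[3]]$best$c, 2.5)
  expect_equal(rounds[[3]]$best_objective, 1)
})

test_that("the merge contract is idempotent and honors its thresholds", {
  sim <- shared_sim()
  asm <- make_synthetic_assembler(sim$annotation, list(c = 3),
                                  list(c = c(1, 9)), sim$config)
  a1 <- asm(NULL, list(c = 3))   # truth with abundances
  merged <- merge_annotations(list(a1, a1))
  expect_equal(exon_jaccard(merged, a1), 1)
  expect_equal(n_transcripts(merged), n_transcripts(a1))
  expect_error(merge_annotations(list(a1), min_tpm = 1e9),
               "no transcript passes")
  mg <- parameter_grid(F = c(0, 1e9), T = c(0))
  suppressMessages(res <- optimize_merge_params(list(a1, a1), mg, sim$annotation))
  expect_equal(res$results$objective[1], 1)
  expect_true(is.na(res$results$objective[2]))
  expect_equal(res$best$F, 0)
})
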