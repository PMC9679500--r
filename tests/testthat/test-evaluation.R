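test_that("grouped_split samples genotypes, not plots", {
  groups <- rep(sprintf("g%02d", 1:10), each = 3)  # 3 replicate plots each
  sp <- grouped_split(groups, 0.7, seed = 1)
  expect_length(sp$train_groups, 7L)
  expect_length(sp$test_groups, 3L)
  for (i in 1:20) {
    spi <- grouped_split(groups, 0.7, seed = i)
    sides <- tapply(seq_along(groups) %in% spi$train_idx, groups,
                    function(v) length(unique(v)))
    expect_true(all(sides == 1))  # replicates never straddle the split
  }
  plans <- lapply(1:50, function(i) grouped_split(groups, 0.7, seed = i))
  expect_gt(length(unique(lapply(plans, `[[`, "test_groups"))), 1L)
  frac <- mean(vapply(plans, function(p) length(p$test_idx) / 30,
                      numeric(1)))
  expect_equal(frac, 0.3, tolerance = 1e-9)
  expect_error(grouped_split(rep("g1", 5)), "at least 2 groups")
})

test_that("compute_metrics matches its definitions", {
  obs <- c(5, 7, 9, 11)
  m <- compute_metrics(obs, obs)
  expect_equal(m$r2p, 1); expect_equal(m$rmsep, 0)
  expect_equal(m$bias, 0); expect_equal(m$ccc, 1)
  expect_true(is.na(m$rpd) && is.na(m$rpiq))
  # location shift: r2p stays 1, CCC is penalised, bias is the shift
  m2 <- compute_metrics(obs, obs + 2)
  expect_equal(m2$r2p, 1)
  expect_lt(m2$ccc, 1)
  expect_equal(m2$bias, 2)
  expect_error(compute_metrics(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(compute_metrics(1:2, 1:2), "at least 3")
})

test_that("compute_metrics reproduces the frozen hand oracle", {
  m <- compute_metrics(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(m$r2p, 0.9817777777777775, tolerance = 1e-10)
  expect_equal(m$rmsep, 0.1581138830084191, tolerance = 1e-10)
  expect_equal(m$bias, 0, tolerance = 1e-10)
  expect_equal(m$sep, 0.1825741858350555, tolerance = 1e-10)
  expect_equal(m$rpd, 8.1649658092772519, tolerance = 1e-10)
  expect_equal(m$rpiq, 9.4868329805051292, tolerance = 1e-10)
  expect_equal(m$ccc, 0.9894736842105262, tolerance = 1e-10)
})

test_that("metric identities hold on random pairs", {
  set.seed(20)
  for (i in 1:50) {
    obs <- rnorm(20, 25, 5)
    pred <- obs * runif(1, 0.3, 1.5) + rnorm(20, 0, 3) + runif(1, -2, 2)
    m <- compute_metrics(obs, pred)
    expect_equal(m$rpiq / m$rpd, unname(IQR(obs) / sd(obs)),
                 tolerance = 1e-12)
    expect_lte(m$ccc, abs(cor(obs, pred)) + 1e-12)
    expect_gte(m$rmsep, 0)
    expect_true(m$r2p >= 0 && m$r2p <= 1)
    expect_true(m$ccc >= -1 && m$ccc <= 1)
  }
})

test_that("within_trial_evaluate recovers planted signal, not permuted labels", {
  fx <- make_samples(tiny_config(genotypes_per_trial = 40))
  d <- assemble_dataset(fx$samples, fx$reference, average = FALSE)
  ev <- within_trial_evaluate(d$X, d$y, d$genotype, "PLSR", niter = 3,
                              seed = 5)
  expect_gt(mean(ev$iterations$r2p), 0.9)
  expect_equal(nrow(ev$iterations), 3L)
  # determinism
  ev2 <- within_trial_evaluate(d$X, d$y, d$genotype, "PLSR", niter = 3,
                               seed = 5)
  expect_equal(ev$iterations, ev2$iterations)
  # permuted labels: no skill
  set.seed(99)
  ev_null <- within_trial_evaluate(d$X, sample(d$y), d$genotype, "PLSR",
                                   niter = 3, seed = 5)
  expect_lt(mean(ev_null$iterations$r2p), 0.2)
})

test_that("CV schemes satisfy their set relations", {
  fx <- make_samples(multi_trial_config())
  ref <- fx$reference
  geno <- ref$genotype_id; trial <- ref$trial_id
  focal <- "T02"
  focal_geno <- unique(geno[trial == focal])
  # CV0: test = entire focal trial, train = everything else
  p0 <- build_cv_scheme("CV0", geno, trial, focal)[[1]]
  expect_setequal(p0$test_idx, which(trial == focal))
  expect_setequal(p0$train_idx, which(trial != focal))
  # CV00: focal-trial genotypes absent from training
  p00 <- build_cv_scheme("CV00", geno, trial, focal)[[1]]
  expect_setequal(p00$test_idx, which(trial == focal))
  expect_length(intersect(geno[p00$train_idx], focal_geno), 0L)
  # a genotype shared across trials is excluded from CV00 training
  shared <- intersect(focal_geno, geno[trial != focal])
  expect_gt(length(shared), 0L)
  expect_false(any(shared %in% geno[p00$train_idx]))
  for (seed in 1:10) {
    p2 <- build_cv_scheme("CV2", geno, trial, focal, seed = seed,
                          niter = 2)
    p1 <- build_cv_scheme("CV1", geno, trial, focal, seed = seed,
                          niter = 2)
    for (i in 1:2) {
      expect_identical(p2[[i]]$test_idx, p1[[i]]$test_idx)
      expect_true(all(p1[[i]]$train_idx %in% p2[[i]]$train_idx))
      expect_length(intersect(geno[p1[[i]]$train_idx],
                              geno[p1[[i]]$test_idx]), 0L)
      expect_equal(length(unique(geno[p2[[i]]$test_idx])),
                   round(0.3 * length(focal_geno)))
      expect_length(intersect(p2[[i]]$train_idx, p2[[i]]$test_idx), 0L)
      expect_true(all(trial[p2[[i]]$test_idx] == focal))
    }
  }
  expect_error(build_cv_scheme("CV2", geno, rep("T01", length(geno)),
                               "T01"), "at least 2 trials")
  expect_error(build_cv_scheme("CV0", geno, trial, "T99"), "not present")
})

test_that("run_cv_schemes emits a tidy deterministic table", {
  fx <- make_samples(multi_trial_config())
  tab <- run_cv_schemes(fx$samples, fx$reference, pretreatments = "RAW",
                        algorithms = "PLSR", schemes = c("CV2", "CV00"),
                        focal_trials = "T01", niter = 2, seed = 3,
                        max_rank = 6)
  expect_equal(sort(unique(tab$scheme)), c("CV00", "CV2"))
  expect_equal(sum(tab$scheme == "CV2"), 2L)   # niter plans
  expect_equal(sum(tab$scheme == "CV00"), 1L)  # single plan
  expect_true(all(c("r2p", "rmsep", "rpd", "rpiq", "ccc") %in% names(tab)))
  tab2 <- run_cv_schemes(fx$samples, fx$reference, pretreatments = "RAW",
                         algorithms = "PLSR", schemes = c("CV2", "CV00"),
                         focal_trials = "T01", niter = 2, seed = 3,
                         max_rank = 6)
  expect_equal(tab, tab2)
})
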