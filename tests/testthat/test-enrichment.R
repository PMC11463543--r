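test_that("median-centering normalization removes per-channel scale", {
  d <- tiny_design()
  base <- withr::with_seed(3, matrix(2^rnorm(120, 20, 2), 20, 6))
  dimnames(base) <- list(sprintf("P%02d", 1:20), d$channel_id)
  base[, 3] <- base[, 2]  # two identical channels
  m1 <- normalize_log2(intensity_matrix(base, d))
  scaled <- base
  scaled[, 2] <- scaled[, 2] * 8  # constant log2 shift of 3
  m2 <- normalize_log2(intensity_matrix(scaled, d))
  # the scaled channel lands back on its unscaled twin
  expect_equal(m2$values[, 2], m2$values[, 3], tolerance = 1e-12)
  # and the whole matrix differs from the unscaled run only by the
  # grand-median anchor, a single constant
  shift <- m2$values - m1$values
  expect_lt(diff(range(shift)), 1e-12)

  # identical columns: normalization is a no-op beyond the transform
  same <- matrix(rep(2^seq(10, 19.5, by = 0.5), 6), 20, 6,
                 dimnames = dimnames(base))
  mm <- normalize_log2(intensity_matrix(same, d))
  expect_equal(mm$values, log2(same), tolerance = 1e-12)

  # every channel median equals the grand median
  meds <- apply(m1$values, 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(median(meds), 6), tolerance = 1e-9)
})

test_that("normalization flags sparse channels and rejects empty ones", {
  d <- tiny_design()
  v <- matrix(2^20, 12, 6, dimnames = list(sprintf("P%02d", 1:12),
                                           d$channel_id))
  v[4:12, 1] <- NA
  expect_warning(normalize_log2(intensity_matrix(v, d)), "< 10 finite")
  v[, 1] <- NA
  expect_error(normalize_log2(intensity_matrix(v, d)), "all-missing")
})

test_that("BH adjustment matches hand and brute-force oracles", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA propagation: missing p-values do not count as tests
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_adjust(c(0.01, 0.04)))

  withr::with_seed(11, {
    for (i in 1:25) {
      p <- runif(sample(3:60, 1))^sample(1:3, 1)
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
      expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    }
  })
})

test_that("q >= p and q is monotone along the p-ordering", {
  withr::with_seed(4, {
    p <- runif(200)
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  })
})

test_that("variance prior recovery from a scaled-F simulation", {
  d0_true <- 4; s0_true <- 0.09; dg <- 4
  d <- tiny_design()
  # per-protein true variances drawn from the scaled inverse-chi-square
  # prior, then normal observations around a flat mean: the pooled
  # variances are marginally s0 * F(dg, d0) as the model assumes
  s2 <- withr::with_seed(17, s0_true * d0_true /
                           stats::rchisq(2000, d0_true))
  n <- 2000
  sds <- sqrt(s2)
  v <- matrix(NA_real_, n, 6,
              dimnames = list(sprintf("P%04d", 1:n), d$channel_id))
  v <- withr::with_seed(18, {
    for (i in 1:n) v[i, ] <- 20 + rnorm(6, sd = sds[i])
    v
  })
  m <- intensity_matrix(v, d, log2_scale = TRUE)
  fit <- fit_ebayes(m)
  expect_gt(fit$d0, 2.5)
  expect_lt(fit$d0, 6.5)
  expect_lt(abs(fit$s0_sq - s0_true) / s0_true, 0.2)
})

test_that("equal variances drive the prior df to infinity", {
  d <- tiny_design()
  n <- 50
  v <- matrix(20, n, 6, dimnames = list(sprintf("P%02d", 1:n),
                                        d$channel_id))
  v[, c(1, 4)] <- 19   # every row sees (19, 20, 21) in each group
  v[, c(3, 6)] <- 21
  m <- intensity_matrix(v, d, log2_scale = TRUE)
  fit <- fit_ebayes(m)
  expect_true(is.infinite(fit$d0))
  expect_equal(fit$s0_sq, 1, tolerance = 1e-6)  # pooled var of (-1,0,1) x2
})

test_that("prior fit is invariant to protein order", {
  sim <- simulate_ip_experiment(sim_config(n_proteins = 120, seed = 5))
  m <- normalize_log2(sim$matrix)
  fit1 <- fit_ebayes(m)
  perm <- withr::with_seed(1, sample(nrow(m$values)))
  m2 <- m
  m2$values <- m$values[perm, ]
  fit2 <- fit_ebayes(m2)
  expect_equal(fit1$d0, fit2$d0, tolerance = 1e-9)
  expect_equal(fit1$s0_sq, fit2$s0_sq, tolerance = 1e-12)
})

test_that("prior fit agrees with an independent moderated-variance fit", {
  sim <- simulate_ip_experiment(sim_config(n_proteins = 800, seed = 31,
                                           missing_rate = 0))
  m <- normalize_log2(sim$matrix)
  fit <- fit_ebayes(m)
  gs <- endocargo:::group_stats(m)
  sq <- limma::squeezeVar(gs$s2, gs$df)
  expect_equal(fit$s0_sq, sq$var.prior, tolerance = 0.05)
  expect_equal(fit$d0, sq$df.prior, tolerance = 0.15)
})

test_that("d0 = 0 reduces the moderated t to the ordinary pooled t", {
  sim <- simulate_ip_experiment(sim_config(n_proteins = 40, seed = 13,
                                           missing_rate = 0))
  m <- normalize_log2(sim$matrix)
  et <- test_enrichment(m, ebayes_model(0, 1))
  for (i in c(1, 7, 25)) {
    tt <- t.test(m$values[i, 1:3], m$values[i, 4:6], var.equal = TRUE)
    expect_equal(et$t_mod[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(et$p[i], tt$p.value, tolerance = 1e-9)
  }
})

test_that("closed-form single-protein case with a fixed prior", {
  d <- tiny_design()
  v <- matrix(c(8, 8, 8, 4, 4, 4), 1, 6,
              dimnames = list("P1", d$channel_id))
  m <- intensity_matrix(v, d, log2_scale = TRUE)
  s0 <- 0.36
  et <- test_enrichment(m, ebayes_model(Inf, s0))
  expect_equal(et$log2FC, 4)
  t_expected <- 4 / sqrt(s0 * (1 / 3 + 1 / 3))
  expect_equal(et$t_mod, t_expected)
  expect_equal(et$p, 2 * pnorm(-t_expected))
  expect_true(et$enriched)
})

test_that("enrichment calling is monotone in both cutoffs", {
  sim <- simulate_ip_experiment(sim_config(n_proteins = 300, seed = 19))
  m <- normalize_log2(sim$matrix)
  fit <- fit_ebayes(m)
  loose <- test_enrichment(m, fit, run_config(lfc_cutoff = 0.5,
                                              q_cutoff = 0.05))
  tight <- test_enrichment(m, fit, run_config(lfc_cutoff = 1.5,
                                              q_cutoff = 0.005))
  expect_true(all(tight$enriched <= loose$enriched))
})

test_that("zero-noise planted effects give perfect calls", {
  cfg <- sim_config(n_proteins = 250, noise_sd = 1e-6, missing_rate = 0,
                    seed = 23)
  sim <- simulate_ip_experiment(cfg, ip_type = "lyso")
  m <- normalize_log2(sim$matrix)
  et <- test_enrichment(m, fit_ebayes(m))
  pos <- sim$truth$effect_lyso >= 1
  expect_equal(mean(et$enriched[pos]), 1)
  expect_equal(sum(et$enriched[!pos]), 0L)
})

test_that("proteins with too few observations are reported untested", {
  d <- tiny_design()
  v <- matrix(rep(c(8, 8, 8, 4, 4, 4), each = 2), 2, 6, byrow = FALSE,
              dimnames = list(c("P1", "P2"), d$channel_id))
  v[2, 2:3] <- NA  # one tagged observation left
  m <- intensity_matrix(v, d, log2_scale = TRUE)
  et <- test_enrichment(m, ebayes_model(Inf, 0.1))
  expect_true(is.na(et$p[et$protein == "P2"]))
  expect_false(et$enriched[et$protein == "P2"])
})

test_that("replicate-dataset comparison: identity, disjoint, simulated", {
  sim <- simulate_ip_experiment(sim_config(n_proteins = 500, seed = 29))
  m <- normalize_log2(sim$matrix)
  et <- test_enrichment(m, fit_ebayes(m))
  same <- compare_replicate_datasets(et, et)
  expect_equal(same$jaccard, 1)
  expect_equal(same$pearson_r, 1)

  other <- et
  other$protein <- paste0("X", other$protein)
  expect_warning(dis <- compare_replicate_datasets(et, other), "shared")
  expect_equal(dis$jaccard, 0)
  expect_true(is.na(dis$pearson_r))

  # independent measurement noise over one biological truth
  cfg <- sim_config(n_proteins = 500, seed = 29)
  rep2 <- simulate_ip_experiment(cfg, noise_stream = "ip_noise_rep2")
  m2 <- normalize_log2(rep2$matrix)
  et2 <- test_enrichment(m2, fit_ebayes(m2))
  rep_cmp <- compare_replicate_datasets(et, et2)
  expect_gte(rep_cmp$pearson_r, 0.9)
  expect_gt(rep_cmp$jaccard, 0.5)
})
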