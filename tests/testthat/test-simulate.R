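test_that("fixed spacing lays probes at exact positions and runs are reproducible", {
  cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 5,
                    spacing_model = "fixed", spacing_bp = 100,
                    n_pairs = 2, seed = 7)
  mf <- simulate_manifest(cfg)
  expect_equal(mf$pos, c(1L, 101L, 201L, 301L, 401L))
  expect_identical(simulate_manifest(cfg), mf)

  sim1 <- simulate_psdmr(sim_config(n_chromosomes = 1, cpgs_per_chromosome = 200,
                                    n_pairs = 3, seed = 7))
  sim2 <- simulate_psdmr(sim_config(n_chromosomes = 1, cpgs_per_chromosome = 200,
                                    n_pairs = 3, seed = 7))
  expect_identical(serialize(sim1, NULL), serialize(sim2, NULL))
})

test_that("geometric spacing attains the configured mean gap", {
  cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 10000,
                    spacing_bp = 100, n_pairs = 2, seed = 11)
  mf <- simulate_manifest(cfg)
  expect_true(all(diff(mf$pos) >= 1))
  expect_lt(abs(mean(diff(mf$pos)) - 100) / 100, 0.05)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(n_pairs = 1), class = "psdmr_config_error")
  expect_error(sim_config(noise_sd_m = -1), class = "psdmr_config_error")
  expect_error(sim_config(cpgs_per_chromosome = 0), class = "psdmr_config_error")
  bad <- tibble::tibble(chromosome = "chr1", start_probe_index = 95L,
                        n_probes = 10L, delta_m = 1)
  cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 100,
                    n_pairs = 2, spikes = bad, seed = 1)
  expect_error(simulate_psdmr(cfg), class = "psdmr_config_error")
  overlapping <- tibble::tibble(chromosome = "chr1",
                                start_probe_index = c(10L, 15L),
                                n_probes = c(10L, 10L), delta_m = c(1, -1))
  cfg2 <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 100,
                     n_pairs = 2, spikes = overlapping, seed = 1)
  expect_error(simulate_psdmr(cfg2), class = "psdmr_config_error")
})

test_that("null simulation is symmetric and betas stay inside (0, 1)", {
  cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 2000,
                    n_pairs = 30, seed = 21)
  sim <- simulate_psdmr(cfg)
  b <- as.matrix(sim$betas[-1])
  expect_true(all(b > 0 & b < 1))

  idx <- psdmr:::pair_columns(colnames(b), sim$design)
  m <- beta_to_m(b)
  d <- m[, idx$tumor] - m[, idx$normal]
  z <- rowMeans(d) / (apply(d, 1, sd) / sqrt(ncol(d)))
  ## per-probe mean difference should be null: ~0.3% of |z| > 3 expected
  expect_lt(mean(abs(z) > 3), 0.02)
})

test_that("spiked effects are recovered on the M scale at the configured size", {
  mf <- simulate_manifest(sim_config(n_chromosomes = 1,
                                     cpgs_per_chromosome = 500,
                                     n_pairs = 40, seed = 3))
  sp <- tibble::tibble(chromosome = "chr1", start_probe_index = 100L,
                       n_probes = 10L, delta_m = 1.0)
  cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 500,
                    n_pairs = 40, spikes = sp, seed = 3)
  sim <- simulate_paired_betas(mf, cfg)
  expect_equal(sim$truth$true_state, "Hyper")
  expect_equal(sim$truth$n_probes, 10L)

  m <- beta_to_m(as.matrix(sim$betas[-1]))
  idx <- psdmr:::pair_columns(colnames(m), sim$design)
  d <- (m[, idx$tumor] - m[, idx$normal])[100:109, ]
  pair_means <- colMeans(d)  # pairs are the independent replication units
  est <- mean(pair_means)
  se <- sd(pair_means) / sqrt(length(pair_means))
  expect_lt(abs(est - 1.0), 3 * se)
})

test_that("normal-tissue M variance decomposes into baseline plus noise", {
  cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 3000,
                    n_pairs = 30, baseline_sd_m = 1.5, noise_sd_m = 0.5,
                    seed = 5)
  sim <- simulate_psdmr(cfg)
  m <- beta_to_m(as.matrix(sim$betas[-1]), epsilon = 1e-6)
  normals <- m[, sim$design$sample_id[sim$design$phenotype == "Normal"]]
  v <- mean(apply(normals, 1, stats::var))
  expect_lt(abs(v - (1.5^2 + 0.5^2)) / (1.5^2 + 0.5^2), 0.05)
})

test_that("place_spikes yields in-cluster windows with alternating signs", {
  mf <- simulate_manifest(sim_config(n_chromosomes = 2,
                                     cpgs_per_chromosome = 2000,
                                     n_pairs = 2, seed = 9))
  sp <- place_spikes(mf, n_spikes = 6, n_probes = 8, delta_m = 1.2,
                     max_gap = 300)
  expect_equal(nrow(sp), 6)
  expect_equal(sort(unique(sp$delta_m)), c(-1.2, 1.2))
  cl <- make_clusters(mf, 300)
  for (i in seq_len(nrow(sp))) {
    rows <- which(cl$chrom == sp$chromosome[i])
    ids <- cl$cluster_id[rows][sp$start_probe_index[i]:(sp$start_probe_index[i] + sp$n_probes[i] - 1)]
    expect_length(unique(ids), 1)
  }
})

test_that("ROI counts are NB-distributed with recoverable dispersion and null symmetry", {
  sim <- simulate_roi_counts(n_rois = 50, n_case = 100, n_control = 100,
                             base_mean = 100, dispersion = 0.1, seed = 13)
  cnt <- as.matrix(sim$counts[-1])
  expect_true(all(cnt >= 0))
  expect_true(all(cnt == round(cnt)))

  ## null: group means agree within 3 SE per ROI (allow rare excursions)
  grp <- sim$samples$group[match(colnames(cnt), sim$samples$sample_id)]
  lib <- sim$samples$library_size[match(colnames(cnt), sim$samples$sample_id)]
  y <- sweep(cnt, 2, mean(lib) / lib, `*`)
  z <- apply(y, 1, function(r) {
    a <- r[grp == "case"]; b <- r[grp == "control"]
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  })
  expect_lt(mean(abs(z) > 3), 0.05)

  est <- estimate_dispersion(sim$counts, sim$samples)
  expect_lt(abs(est$common - 0.1) / 0.1, 0.3)

  ## determinism
  sim2 <- simulate_roi_counts(n_rois = 50, n_case = 100, n_control = 100,
                              base_mean = 100, dispersion = 0.1, seed = 13)
  expect_identical(serialize(unclass(sim), NULL), serialize(unclass(sim2), NULL))
})
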