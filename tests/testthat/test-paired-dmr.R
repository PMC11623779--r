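test_that("paired t handles zero-mean and zero-variance probes", {
  d <- toy_design(2)
  m <- wide_from_matrix(matrix(c(2, 0, 1, 1,   # d = (1, -1) -> t = 0
                                 5, 5, 2, 2,   # d = (3, 3): sd 0 -> capped
                                 1, 1, 1, 1),  # d = (0, 0) -> t = 0
                               nrow = 3, byrow = TRUE,
                               dimnames = list(NULL, d$sample_id)))
  t <- paired_t_statistics(m, d, t_cap = 100)$t
  expect_equal(t, c(0, 100, 0))
})

test_that("paired and Welch t match the textbook formulas via t.test", {
  set.seed(31)
  for (rep in 1:50) {
    np <- sample(3:12, 1)
    des <- toy_design(np)
    m <- toy_paired_matrix(5, np, seed = rep)
    tp <- paired_t_statistics(wide_from_matrix(m), des)$t
    tu <- unpaired_t_statistics(wide_from_matrix(m), des)$t
    for (i in 1:5) {
      x <- m[i, 1:np]; y <- m[i, np + 1:np]
      expect_equal(tp[i], unname(t.test(x, y, paired = TRUE)$statistic),
                   tolerance = 1e-10)
      expect_equal(tu[i], unname(t.test(x, y)$statistic), tolerance = 1e-10)
    }
  }
})

test_that("swapping tumor and normal labels negates every t", {
  des <- toy_design(6)
  m <- wide_from_matrix(toy_paired_matrix(40, 6, seed = 4))
  swapped <- des
  swapped$phenotype <- ifelse(des$phenotype == "Tumor", "Normal", "Tumor")
  expect_equal(paired_t_statistics(m, des)$t,
               -paired_t_statistics(m, swapped)$t, tolerance = 1e-12)
  expect_equal(unpaired_t_statistics(m, des)$t,
               -unpaired_t_statistics(m, swapped)$t, tolerance = 1e-12)
})

test_that("stage errors: unknown samples and undersized groups", {
  des <- toy_design(3)
  m <- wide_from_matrix(matrix(rnorm(12), 2,
                               dimnames = list(NULL, c(des$sample_id[-1], "ghost"))))
  expect_error(paired_t_statistics(m, des), class = "psdmr_data_error")
  m2 <- wide_from_matrix(matrix(rnorm(10, 1), 2))
  m2[2, 2] <- NA
  expect_error(paired_t_statistics(m2, des), class = "psdmr_data_error")
})

test_that("candidate regions match closed forms and the exhaustive-run oracle", {
  ## a plateau of 10 probes at c among 100: tau = c, value = c, area = 10|c|
  pos <- cumsum(c(1, rep(50, 99)))
  s <- rep(0.01, 100); s[41:50] <- 5
  mf <- toy_manifest(pos)
  cl <- make_clusters(mf, 300)
  sm <- dplyr::mutate(cl, t = s, smoothed_t = s)
  cand <- find_candidate_regions(sm, cutoff_quantile = 0.99, min_probes = 7)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$value, 5)
  expect_equal(cand$area, 50)
  expect_equal(cand$n_cpgs, 10L)
  expect_equal(attr(cand, "tau"), 5)

  ## random smoothed vectors against the brute-force enumeration
  set.seed(17)
  for (rep in 1:20) {
    n <- 400
    pos <- cumsum(1 + rgeom(n, 1 / 100))
    mf <- toy_manifest(pos)
    cl <- make_clusters(mf, 300)
    s <- rnorm(n) + rep(rnorm(ceiling(n / 8), sd = 2), each = 8)[1:n]
    sm <- dplyr::mutate(cl, t = s, smoothed_t = s)
    got <- find_candidate_regions(sm, cutoff_quantile = 0.9, min_probes = 3)
    tau <- attr(got, "tau")
    want <- oracle_regions(s, cl$cluster_id, cl$pos, cl$chrom, tau, 3)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$value, want$value, tolerance = 1e-12)
      expect_equal(got$area, want$area, tolerance = 1e-12)
    }
  }
})

test_that("plus-one FWER counting follows the stated conventions", {
  null <- list(areas = tibble::tibble(iteration = 1:4, size = 10L,
                                      area = c(1, 2, 3, 4)),
               max_area = c(1, 2, 3, 4), method = "windows",
               n_iterations = 4L)
  cand <- tibble::tibble(chrom = "chr1", start = 1L, end = 500L,
                         n_cpgs = 10L, value = 1, area = 2.5)
  got <- assign_fwer(cand, null)
  expect_equal(got$fwer, 3 / 5)
  expect_equal(got$p, 3 / 5)
  expect_equal(got$fwer_area, 3 / 5)

  ## observed above every maximum with B = 999 -> fwer = 1/1000
  null2 <- list(areas = tibble::tibble(iteration = 1:999, size = 10L,
                                       area = runif(999, 0, 1)),
                max_area = runif(999, 0, 1), method = "windows",
                n_iterations = 999L)
  top <- dplyr::mutate(cand, area = 2)
  expect_equal(assign_fwer(top, null2)$fwer, 1 / 1000)
  ## observed below every null value -> fwer = 1
  bottom <- dplyr::mutate(cand, area = -1)
  expect_equal(assign_fwer(bottom, null2)$fwer, 1)
})

test_that("the resampling null is deterministic given the seed", {
  sim <- simulate_psdmr(sim_config(n_chromosomes = 1,
                                   cpgs_per_chromosome = 600,
                                   n_pairs = 6, seed = 2))
  m <- dplyr::mutate(sim$betas,
                     dplyr::across(-probe_id, ~beta_to_m(.x)))
  cl <- filter_clusters(make_clusters(sim$manifest, 300), 7)
  for (method in c("regions", "windows")) {
    n1 <- suppressWarnings(null_distribution(m, sim$design, cl,
                                             candidate_sizes = c(7L, 9L),
                                             n_iterations = 20, seed = 77,
                                             method = method))
    n2 <- suppressWarnings(null_distribution(m, sim$design, cl,
                                             candidate_sizes = c(7L, 9L),
                                             n_iterations = 20, seed = 77,
                                             method = method))
    expect_identical(n1, n2)
  }
  ## windows null: one window per requested size per iteration
  nw <- suppressWarnings(null_distribution(m, sim$design, cl,
                                           candidate_sizes = c(7L, 9L),
                                           n_iterations = 20, seed = 1,
                                           method = "windows"))
  expect_equal(nrow(nw$areas), 40)
  expect_equal(sort(unique(nw$areas$size)), c(7L, 9L))
  expect_equal(nw$max_area,
               tapply(nw$areas$area, nw$areas$iteration, max),
               ignore_attr = TRUE)
})

test_that("null region areas are exchangeable with observed candidate areas under the null", {
  ## pooled over pure-noise datasets, observed candidates and resampled null
  ## regions should follow the same area distribution (KS, alpha = 0.01)
  obs <- c(); nul <- c()
  for (i in 1:12) {
    sim <- simulate_psdmr(sim_config(n_chromosomes = 2,
                                     cpgs_per_chromosome = 1500,
                                     n_pairs = 10, seed = 400 + i))
    m <- dplyr::mutate(sim$betas, dplyr::across(-probe_id, ~beta_to_m(.x)))
    cl <- filter_clusters(make_clusters(sim$manifest, 300), 3)
    st <- paired_t_statistics(m, sim$design)
    sm <- smooth_statistics(st, cl, 0.75)
    cand <- find_candidate_regions(sm, cutoff_quantile = 0.9, min_probes = 3)
    nd <- suppressWarnings(null_distribution(m, sim$design, cl,
                                             n_iterations = 15, seed = 500 + i,
                                             cutoff_quantile = 0.9,
                                             min_probes = 3,
                                             method = "regions"))
    obs <- c(obs, cand$area)
    nul <- c(nul, nd$areas$area)
  }
  expect_gt(length(obs), 100)
  set.seed(1)
  nul <- sample(nul, min(length(nul), 500))
  ks <- suppressWarnings(stats::ks.test(obs, nul))
  expect_gt(ks$p.value, 0.01)
})

test_that("region state follows the sign of the mean paired beta difference", {
  des <- toy_design(4)
  mf <- toy_manifest(c(100, 150, 200))
  b <- matrix(0.5, 3, 8, dimnames = list(NULL, des$sample_id))
  b[1:2, 1:4] <- 0.65   # tumors up on probes 1-2
  b[3, 1:4] <- 0.40     # tumor down on probe 3
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(100L, 200L), end = c(150L, 200L))
  got <- call_state(regions, wide_from_matrix(b), des, mf)
  expect_equal(got$state, c("Hyper", "Hypo"))
  expect_equal(got$mean_beta_diff, c(0.15, -0.10), tolerance = 1e-12)
  expect_true(all(got$state %in% c("Hyper", "Hypo")))
})

test_that("under per-pair baseline shifts the Welch t is weaker than the paired t on spiked probes", {
  mf <- simulate_manifest(sim_config(n_chromosomes = 1,
                                     cpgs_per_chromosome = 1000,
                                     n_pairs = 20, seed = 6))
  sp <- tibble::tibble(chromosome = "chr1", start_probe_index = 300L,
                       n_probes = 50L, delta_m = 1.0)
  cfg <- sim_config(n_chromosomes = 1, cpgs_per_chromosome = 1000,
                    n_pairs = 20, baseline_sd_m = 1.5, spikes = sp, seed = 6)
  sim <- simulate_paired_betas(mf, cfg)
  m <- dplyr::mutate(sim$betas, dplyr::across(-probe_id, ~beta_to_m(.x)))
  tp <- paired_t_statistics(m, sim$design)$t[300:349]
  tu <- unpaired_t_statistics(m, sim$design)$t[300:349]
  expect_lt(median(abs(tu)), median(abs(tp)))
})

test_that("the full paired run is deterministic and records its parameters", {
  sim <- simulate_psdmr(sim_config(n_chromosomes = 1,
                                   cpgs_per_chromosome = 800,
                                   n_pairs = 6, seed = 12))
  r1 <- run_paired_dmr(sim$betas, sim$design, sim$manifest, B = 100, seed = 3)
  r2 <- run_paired_dmr(sim$betas, sim$design, sim$manifest, B = 100, seed = 3)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  expect_equal(r1$metadata$min_probes, 7)
  expect_equal(r1$metadata$B, 100)
  expect_equal(r1$metadata$seed, 3)
  expect_equal(r1$metadata$engine, "paired")
  ## sorted by fwer then area descending
  if (nrow(r1$regions) > 1) {
    expect_true(!is.unsorted(r1$regions$fwer))
  }
})

test_that("spiked regions are found with correct states", {
  mf <- simulate_manifest(sim_config(n_chromosomes = 2,
                                     cpgs_per_chromosome = 1500,
                                     n_pairs = 20, seed = 14))
  sp <- place_spikes(mf, n_spikes = 4, n_probes = 10, delta_m = 1.5)
  cfg <- sim_config(n_chromosomes = 2, cpgs_per_chromosome = 1500,
                    n_pairs = 20, spikes = sp, seed = 14)
  sim <- simulate_psdmr(cfg)
  res <- run_paired_dmr(sim$betas, sim$design, sim$manifest, B = 120, seed = 8)
  rec <- count_recovered(res, sim$truth)
  expect_gte(rec$n, 3)
  found <- !is.na(rec$states)
  expect_equal(rec$states[found], sim$truth$true_state[found])
})
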