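## fixtures and independent oracles, built in code at test time

## a tiny manifest on one or more chromosomes
toy_manifest <- function(pos, chrom = "chr1") {
  tibble::tibble(probe_id = sprintf("cg%05d", seq_along(pos)),
                 chrom = rep_len(chrom, length(pos)),
                 pos = as.integer(pos))
}

## wide beta/M tibble from a plain matrix
wide_from_matrix <- function(m, ids = sprintf("cg%05d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("S%02d", seq_len(ncol(m)))
  out <- tibble::as_tibble(m)
  out$probe_id <- ids
  dplyr::relocate(out, "probe_id")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_design <- function(n_pairs) {
  tibble::tibble(
    sample_id = c(sprintf("P%02d_T", 1:n_pairs), sprintf("P%02d_N", 1:n_pairs)),
    pair_id = rep(sprintf("P%02d", 1:n_pairs), 2),
    phenotype = rep(c("Tumor", "Normal"), each = n_pairs))
}

## paired data: tumor columns first, then normal, matching toy_design
toy_paired_matrix <- function(n_probes, n_pairs, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * 2 * n_pairs), n_probes)
  colnames(m) <- toy_design(n_pairs)$sample_id
  m
}

## O(n^2) clustering oracle: merge probes by pairwise adjacency, then take
## the transitive closure
oracle_clusters <- function(manifest, max_gap) {
  n <- nrow(manifest)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && manifest$chrom[i] == manifest$chrom[j] &&
        abs(manifest$pos[i] - manifest$pos[j]) <= max_gap) {
      ## adjacency is only between consecutive probes
      if (j == i + 1) parent[find(j)] <- find(i)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

## direct weighted-least-squares local-quadratic oracle with tricube
## weights over the k nearest probes (window = contiguous block containing
## the target with minimal maximum distance)
oracle_local_quadratic <- function(x, y, span) {
  n <- length(x)
  if (n < 4) { # centred 3-point running mean
    return(vapply(seq_len(n), function(i) {
      mean(y[max(1, i - 1):min(n, i + 1)])
    }, numeric(1)))
  }
  k <- max(4, ceiling(span * n))
  k <- min(k, n)
  vapply(seq_len(n), function(i) {
    ls <- max(1, i - k + 1):min(i, n - k + 1)
    dmaxs <- vapply(ls, function(l) max(x[i] - x[l], x[l + k - 1] - x[i]),
                    numeric(1))
    l <- ls[which.min(dmaxs)]
    idx <- l:(l + k - 1)
    dmax <- max(abs(x[idx] - x[i]))
    w <- (1 - (abs(x[idx] - x[i]) / dmax)^3)^3
    z <- (x[idx] - x[i]) / dmax
    X <- cbind(1, z, z^2)
    keep <- w > 0
    b <- solve(t(X[keep, ]) %*% (w[keep] * X[keep, ]),
               t(X[keep, ]) %*% (w[keep] * y[idx][keep]))
    b[1]
  }, numeric(1))
}

## exhaustive scan oracle enumerating all maximal same-sign exceedance runs
oracle_regions <- function(s, cluster_id, pos, chrom, tau, min_probes) {
  out <- list()
  i <- 1
  n <- length(s)
  while (i <= n) {
    if (abs(s[i]) >= tau && s[i] != 0) {
      j <- i
      while (j < n && cluster_id[j + 1] == cluster_id[i] &&
             abs(s[j + 1]) >= tau && sign(s[j + 1]) == sign(s[i])) {
        j <- j + 1
      }
      if (j - i + 1 >= min_probes) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = chrom[i], start = pos[i], end = pos[j],
          n_cpgs = j - i + 1L, value = mean(s[i:j]), area = sum(abs(s[i:j])))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   n_cpgs = integer(), value = numeric(), area = numeric())
  } else {
    dplyr::bind_rows(out)
  }
}

## all-pairs interval-overlap oracle (1-based inclusive)
oracle_overlaps <- function(a, b) {
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] && a$start[i] <= b$end[j] &&
        a$end[i] >= b$start[j]) {
      hits[[length(hits) + 1]] <- c(i, j)
    }
  }
  if (length(hits) == 0) matrix(integer(), ncol = 2) else do.call(rbind, hits)
}

## NB log-likelihood at fixed dispersion for a two-group log-linear model
nb_loglik <- function(y, mu, phi) {
  sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

## refining grid-search oracle maximizing the NB likelihood over
## (log2 baseline, log2 fold change)
oracle_nb_grid <- function(y, is_case, lib, phi) {
  obj <- function(b, f) {
    mu <- lib * 2^(b + f * is_case)
    nb_loglik(y, mu, phi)
  }
  b0 <- log2(mean(y / lib))
  brange <- b0 + c(-3, 3); frange <- c(-6, 6)
  for (step in 1:6) {
    bs <- seq(brange[1], brange[2], length.out = 41)
    fs <- seq(frange[1], frange[2], length.out = 41)
    ll <- outer(bs, fs, Vectorize(obj))
    best <- arrayInd(which.max(ll), dim(ll))
    db <- diff(brange) / 40; df <- diff(frange) / 40
    brange <- bs[best[1]] + c(-db, db)
    frange <- fs[best[2]] + c(-df, df)
  }
  list(logFC = mean(frange), loglik = obj(mean(brange), mean(frange)))
}

## truth-region recovery against a significant-region table
count_recovered <- function(result, truth, fwer_threshold = 0.05) {
  sig <- result$regions[result$regions$fwer < fwer_threshold, ]
  states <- vapply(seq_len(nrow(truth)), function(i) {
    hit <- sig$chrom == truth$chrom[i] & sig$start <= truth$end[i] &
      sig$end >= truth$start[i]
    if (!any(hit)) NA_character_ else
      sig$state[which(hit)[which.max(sig$area[hit])]]
  }, character(1))
  list(n = sum(!is.na(states)), states = states)
}
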