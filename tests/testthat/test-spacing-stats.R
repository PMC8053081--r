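test_that("spacing histogram uses half-open reporting bins", {
  h <- spacing_histogram(c(2, 5, 25))
  expect_equal(h$bin_edges_kb, c(0, 1.5, 4, 10, 20, Inf))
  expect_equal(h$fractions, c(0, 1 / 3, 1 / 3, 0, 1 / 3))
  expect_equal(sum(h$counts), 3L)

  h2 <- spacing_histogram(c(1.5, 2, 3.999))  # left-closed, right-open
  expect_equal(h2$counts, c(0L, 3L, 0L, 0L, 0L))
  expect_equal(h2$fractions[2], 1)

  h0 <- spacing_histogram(numeric(0))
  expect_equal(h0$counts, rep(0L, 5))
  expect_length(h0$fractions, 0)
  expect_error(spacing_histogram(1, edges = c(0, 1, 1)), "increasing")
})

test_that("histogram fractions match the shifted-exponential closed form", {
  r <- 1.0; lambda <- 0.2; n <- 1e4
  set.seed(202)
  gaps <- r + stats::rexp(n, lambda)
  h <- spacing_histogram(gaps)
  edges <- h$bin_edges_kb
  analytic <- vapply(seq_len(length(edges) - 1), function(i) {
    lo <- max(edges[i], r); hi <- max(edges[i + 1], r)
    exp(-lambda * (lo - r)) - exp(-lambda * (hi - r))
  }, numeric(1))
  expect_equal(sum(analytic), 1, tolerance = 1e-12)
  for (i in seq_along(analytic)) {
    se <- sqrt(analytic[i] * (1 - analytic[i]) / n)
    expect_lt(abs(h$fractions[i] - analytic[i]), 3 * se + 1e-9)
  }
})

test_that("pattern dissimilarity is a Jaccard distance on occupied bins", {
  expect_equal(pattern_dissimilarity(c(1, 5, 9), c(1, 5, 9)), 0)
  expect_equal(pattern_dissimilarity(c(1, 3), c(11, 13)), 1)
  expect_equal(pattern_dissimilarity(numeric(0), numeric(0)), 0)
  # same bin, different exact positions
  expect_equal(pattern_dissimilarity(c(1.1), c(1.9), bin_kb = 2), 0)
  expect_error(pattern_dissimilarity(1, 2, oriented_b = FALSE),
               "unoriented")

  set.seed(301)
  for (rep in 1:50) {
    a <- stats::runif(sample(0:12, 1), 0, 48)
    b <- stats::runif(sample(0:12, 1), 0, 48)
    got <- pattern_dissimilarity(a, b, bin_kb = 2)
    # brute-force set computation
    ba <- unique(floor(a / 2)); bb <- unique(floor(b / 2))
    want <- if (length(union(ba, bb)) == 0) 0 else
      1 - sum(ba %in% bb) / length(unique(c(ba, bb)))
    expect_equal(got, want)
    expect_equal(got, pattern_dissimilarity(b, a, bin_kb = 2))
    expect_true(got >= 0 && got <= 1)
  }
})

test_that("density estimator inverts the shifted-exponential mean", {
  d <- rep(1.0 + 5, 50)
  est <- estimate_density(d, 1.0, 30, 1, B = 0)
  expect_equal(est$lambda_eff, 0.2)
  expect_true(is.na(est$ci_low))
  expect_error(estimate_density(rep(0.5, 10), 1.0, 30, 1),
               "saturated")
  # invariance to shuffling
  set.seed(1)
  d2 <- 1 + stats::rexp(500, 0.3)
  e1 <- estimate_density(d2, 1, 30, 1, B = 0)
  e2 <- estimate_density(sample(d2), 1, 30, 1, B = 0)
  expect_equal(e1$lambda_eff, e2$lambda_eff)
})

test_that("density recovery on finite molecules matches size-biased theory", {
  # Labels as a Poisson process on 500 x 48.5-kb molecules, dead-time
  # merged at resolution r, then re-estimated. Finite molecules censor
  # long gaps: a gap of length g is observed with probability
  # proportional to (W - g), so the expected observed mean is
  # (W E[g] - E[g^2]) / (W - E[g]) rather than E[g] = r + 1/lambda,
  # and the moment estimator converges to the size-biased value.
  lambda <- 0.2; r <- 1.0; W <- 48.5
  set.seed(404)
  gaps <- unlist(lapply(1:500, function(i) {
    x <- cumsum(stats::rexp(40, lambda))
    x <- x[x < W]
    if (length(x) < 2) return(NULL)
    # dead-time merging: a label within r of the last kept one fuses
    merged <- x[1]
    for (p in x[-1]) if (p - merged[length(merged)] >= r)
      merged <- c(merged, p)
    if (length(merged) < 2) NULL else diff(merged)
  }))
  Eg <- r + 1 / lambda
  Eg2 <- 1 / lambda^2 + Eg^2
  mean_censored <- (W * Eg - Eg2) / (W - Eg)
  lambda_censored <- 1 / (mean_censored - r)
  est <- estimate_density(gaps, r, 33.3, 1, B = 200, seed = 9)
  se <- stats::sd(gaps) / sqrt(length(gaps)) / (mean(gaps) - r)^2
  expect_lt(abs(est$lambda_eff - lambda_censored), 3 * se)
  expect_true(est$ci_low <= est$f_hat && est$f_hat <= est$ci_high)
  # fixed seed -> identical bootstrap interval
  est2 <- estimate_density(gaps, r, 33.3, 1, B = 200, seed = 9)
  expect_identical(est, est2)

  # without censoring (gaps drawn from the model itself), recovery is
  # within 10%
  set.seed(405)
  direct <- r + stats::rexp(1e4, lambda)
  est3 <- estimate_density(direct, r, 33.3, 1, B = 0)
  expect_lt(abs(est3$lambda_eff - lambda) / lambda, 0.1)
})

test_that("occupancy recovery at f = 0.12 with merging disabled", {
  f <- 0.12; spacing_bp <- 30; n_sites <- 1e4
  set.seed(505)
  modified <- which(stats::runif(n_sites) < f)
  pos_kb <- modified * spacing_bp / 1000
  d <- diff(pos_kb)
  est <- estimate_density(d, 0, 1000 / spacing_bp, 1, B = 0)
  se <- f / sqrt(length(d))
  expect_lt(abs(est$f_hat - f), 3 * se)
})

test_that("spots-per-molecule report captures count spread and heterogeneity", {
  cal <- calibrate(15.53, 48502)
  mk <- function(id, end, pos) {
    rows <- data.frame(molecule_id = id, backbone_um = 15.53,
                       end_labeled = end, spot_position_um = pos,
                       channel = "PT", stringsAsFactors = FALSE)
    if (end) rows <- rbind(rows, data.frame(
      molecule_id = id, backbone_um = 15.53, end_labeled = TRUE,
      spot_position_um = 0.01, channel = "end"))
    rows
  }
  spots <- rbind(mk("m1", TRUE, c(1, 2, 3, 4, 5)),
                 mk("m2", TRUE, c(1, 2)),
                 mk("m3", FALSE, c(3, 9)))
  recs <- select_molecules(molecule_records(spots, cal), 48.502, 0.05)
  rep <- spots_per_molecule(recs, bin_kb = 2)
  expect_equal(as.integer(rep$spots_per_molecule[c("2", "5")]), c(2L, 1L))
  expect_equal(rep$n_molecules, 3L)
  expect_equal(rep$n_oriented, 2L)
  # one oriented pair: positions kb m1 vs m2
  p1 <- recs$positions$position_kb[recs$positions$molecule_id == "m1"]
  p2 <- recs$positions$position_kb[recs$positions$molecule_id == "m2"]
  expect_equal(rep$mean_pairwise_dissimilarity,
               pattern_dissimilarity(p1, p2, 2))

  # single molecule: dissimilarity undefined, reported absent
  one <- select_molecules(molecule_records(mk("m1", TRUE, c(1, 5)), cal),
                          48.502, 0.05)
  expect_true(is.na(spots_per_molecule(one)$mean_pairwise_dissimilarity))
})
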