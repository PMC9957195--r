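test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_burst_family(1.5, 100, seed = 9)
  s2 <- simulate_burst_family(1.5, 100, seed = 9)
  expect_identical(s1$hits, s2$hits)
  expect_identical(vapply(s1$monomers, `[[`, character(1), "sequence"),
                   vapply(s2$monomers, `[[`, character(1), "sequence"))
  # hit table identical with and without sequence materialization
  s3 <- simulate_burst_family(1.5, 100, seed = 9, emit_sequences = FALSE)
  expect_identical(s1$hits, s3$hits)
  expect_null(s3$monomers)

  l1 <- simulate_library(seed = 5)
  l2 <- simulate_library(seed = 5)
  expect_identical(vapply(l1$members, `[[`, character(1), "sequence"),
                   vapply(l2$members, `[[`, character(1), "sequence"))

  t1 <- simulate_transect(4, 1, seed = 3)
  t2 <- simulate_transect(4, 1, seed = 3)
  expect_identical(t1, t2)
  # the generator does not disturb the ambient RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_burst_family(1, 10, seed = 2)); after <- runif(1)
  expect_identical(before, after)
})

test_that("burst at time zero yields identical copies and time zero", {
  sim <- simulate_burst_family(0, 50, seed = 10)
  expect_true(all(sim$hits$divergence_pct == 0))
  seqs <- vapply(sim$monomers, `[[`, character(1), "sequence")
  expect_equal(length(unique(seqs)), 1L)
  expect_equal(unique(seqs), sim$ancestor$sequence)
  ls <- compute_landscape(sim$hits)
  expect_equal(divpeak(ls), 0)
  expect_equal(amplification_time(divpeak(ls)), 0)
})

test_that("realized divergence matches the sequences and converges to 2*rate*t", {
  sim <- simulate_burst_family(2, 200, seed = 11, monomer_len = 150L)
  # hit divergence equals the actual mismatch fraction of each copy
  anc <- strsplit(sim$ancestor$sequence, "")[[1]]
  mism <- vapply(sim$monomers, function(m)
    sum(strsplit(m$sequence, "")[[1]] != anc), numeric(1))
  expect_equal(sim$hits$divergence_pct, 100 * mism / 150)

  # law of large numbers at 10k copies: mean divergence near 2 * rate * t
  big <- simulate_burst_family(1.5, 10000, seed = 12, emit_sequences = FALSE)
  p <- 2 * 1.11 * 1.5 / 100
  se3 <- 3 * 100 * sqrt(p * (1 - p) / 300) / sqrt(10000)
  expect_lt(abs(mean(big$hits$divergence_pct) - 100 * p), se3)
})

test_that("planted burst times are recovered through the full pipeline", {
  # generator -> hits TSV -> landscape -> dating, t = 1.5 Mya regime
  err <- vapply(1:100, function(s) {
    sim <- simulate_burst_family(1.5, 500, seed = 1000 + s,
                                 emit_sequences = FALSE)
    tsv <- tempfile(fileext = ".tsv")
    on.exit(unlink(tsv), add = TRUE)
    write_hits_tsv(sim$hits, tsv)
    hits <- read_repeatmasker_hits(tsv, "tsv")
    abs(amplification_time(divpeak(compute_landscape(hits))) - 1.5)
  }, numeric(1))
  expect_lt(median(err), 0.15)
})

test_that("two-burst families produce a bimodal landscape peaking recently", {
  old <- simulate_burst_family(3.5, 150, seed = 13, family = "f",
                               emit_sequences = FALSE)
  rec <- simulate_burst_family(0.5, 500, seed = 14, family = "f",
                               emit_sequences = FALSE)
  ls <- compute_landscape(rbind(old$hits, rec$hits))
  dp <- divpeak(ls)
  expect_lt(dp, 2)                       # peak at the recent mode
  # old mode still visible: abundance beyond 5% divergence
  expect_gt(sum(ls$bins$abundance_bp[ls$bins$bin_lower > 5]), 0)
})

test_that("simulate_library plants the advertised nested structure", {
  lib <- simulate_library(seed = 15)
  expect_length(lib$members, 60)          # 5 families x (2|3) variants x 5
  expect_equal(max(lib$truth$family), 5L)
  expect_equal(max(lib$truth$subfamily), 12L)
  # one-variant families collapse subfamilies onto families
  lib1 <- simulate_library(variants_per_family = 1, seed = 16)
  expect_true(same_partition(lib1$truth$subfamily, lib1$truth$family))
  # zero variant divergence: members of a variant are identical
  lib0 <- simulate_library(variant_divergence = 0, seed = 17)
  seqs <- vapply(lib0$members, `[[`, character(1), "sequence")
  expect_true(all(tapply(seqs, lib0$truth$subfamily,
                         function(v) length(unique(v)) == 1)))
})

test_that("simulate_transect respects linkage and the planted cline", {
  # q = 0 everywhere: all NN / all N
  t0 <- simulate_transect(center = 1000, width = 1, n_per_site = 20,
                          linkage = "autosomal", seed = 18)
  expect_true(all(t0$NN == 20 & t0$NB == 0 & t0$BB == 0))
  x0 <- simulate_transect(center = 1000, width = 1, linkage = "x_linked",
                          seed = 18)
  expect_true(all(x0$B == 0))
  expect_true(all(is.na(x0$NN)))          # hemizygous: no genotype counts

  tt <- simulate_transect(4, 0.5, n_per_site = c(41, 7, 7, 12, 8, 10, 42),
                          linkage = "autosomal", seed = 19)
  expect_equal(tt$NN + tt$NB + tt$BB, c(41L, 7L, 7L, 12L, 8L, 10L, 42L))
  expect_true(all(diff(tt$true_q) > 0))   # monotone sigmoid
  expect_true(all(tt$true_q >= 0 & tt$true_q <= 1))
})

test_that("transect sampling at Table 4 frequencies mirrors the empirical data", {
  # planted frequencies = exact Table 4 fractions, n from Table 1; the
  # expected genotype counts then match Table 4 within binomial noise
  sites <- table1_sites()
  set.seed(20)
  q <- q_autosomal_exact
  draws <- replicate(200, {
    g <- vapply(seq_along(q), function(i) {
      probs <- c((1 - q[i])^2, 2 * q[i] * (1 - q[i]), q[i]^2)
      as.integer(rmultinom(1, sites$n_males[i], probs))
    }, integer(3))
    (g[2, ] + 2 * g[3, ]) / (2 * sites$n_males)
  })
  # mean sampled frequency converges on the planted (= printed) values
  expect_lt(max(abs(rowMeans(draws) - q)), 0.03)
})
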