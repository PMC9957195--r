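test_that("dimerize repeats the monomer to at least 200 nt and two units", {
  expect_equal(nchar(dimerize(tr_consensus("a-7", strrep("AACCTGG", 1)))), 203)  # k = 29
  expect_equal(nchar(dimerize(paste(rep("ACGTA", 30), collapse = ""))), 300)     # 150 bp: dimer
  long <- random_dna(405)
  expect_equal(nchar(dimerize(long)), 810)  # dimer rule overrides min_len
  expect_equal(dimerize("ACG", min_len = 1), "ACGACG")
  expect_error(dimerize(""), "empty")
})

test_that("monomer_identity is rotation- and strand-invariant", {
  set.seed(101)
  for (len in c(11, 37, 120)) {
    a <- random_dna(len)
    for (k in c(1, 3, len - 1)) {
      r <- monomer_identity(a, rotate_seq(a, k))
      expect_equal(r$identity_pct, 100)
    }
    rc <- monomer_identity(a, revcomp(a))
    expect_equal(rc$identity_pct, 100)
    expect_equal(rc$strand, "reverse")
  }
  self <- monomer_identity("ACGTACGTTT", "ACGTACGTTT")
  expect_equal(self$identity_pct, 100)
  expect_equal(self$strand, "forward")
  expect_equal(self$rotation_offset, 0L)
})

test_that("monomer_identity is symmetric and near the planted divergence", {
  set.seed(102)
  for (r in 1:8) {
    a <- random_dna(100)
    b <- mutate_dna(a, 10)
    i_ab <- monomer_identity(a, b)$identity_pct
    i_ba <- monomer_identity(b, a)$identity_pct
    expect_equal(i_ab, i_ba, tolerance = 1e-9)
    expect_lt(abs(i_ab - 90), 1.5)  # 10 substitutions on a 100-mer
  }
})

test_that("monomer_identity agrees with the brute-force DP oracle", {
  # full sweep over all pairs <= 60 bp runs in test-acceptance.R; here a
  # quick related/unrelated spot check
  set.seed(103)
  a <- random_dna(24)
  cases <- list(c(a, mutate_dna(a, 3)),
                c(a, rotate_seq(mutate_dna(a, 2), 7)),
                c(a, oracle_revcomp(mutate_dna(a, 4))),
                c(a, random_dna(31)))
  for (cs in cases) {
    expect_equal(monomer_identity(cs[1], cs[2])$identity_pct,
                 oracle_monomer_identity(cs[1], cs[2]),
                 tolerance = 0.5)
  }
})

test_that("build_catalog nests partitions and recovers planted structure", {
  trs <- lapply(1:3, function(i) tr_consensus(paste0("s", i), "ACGTTGCAAC"))
  ct <- build_catalog(trs)
  expect_equal(ct$assignments$subfamily, rep(1L, 3))
  expect_equal(ct$assignments$family, rep(1L, 3))
  expect_equal(ct$assignments$superfamily, rep(1L, 3))

  lib <- simulate_library(seed = 21)
  ct <- build_catalog(lib$members)
  a <- merge(ct$assignments, lib$truth, by = "name")
  expect_true(same_partition(a$family.x, a$family.y))
  expect_true(same_partition(a$subfamily.x, a$subfamily.y))
  # nesting: same subfamily => same family => same superfamily
  expect_true(all(tapply(a$family.x, a$subfamily.x,
                         function(v) length(unique(v)) == 1)))
  expect_true(all(tapply(a$superfamily, a$family.x,
                         function(v) length(unique(v)) == 1)))
  # ids dense from 1, first-seen order
  expect_equal(sort(unique(ct$assignments$family)),
               seq_len(max(ct$assignments$family)))
  expect_equal(ct$assignments$subfamily[1], 1L)
})

test_that("unrelated sequences fall into distinct superfamilies", {
  set.seed(104)
  trs <- list(tr_consensus("u1", random_dna(120)),
              tr_consensus("u2", random_dna(90)))
  ct <- build_catalog(trs)
  expect_equal(max(ct$assignments$superfamily), 2L)
  expect_equal(max(ct$assignments$family), 2L)
})

test_that("family threshold is monotone: raising it never merges families", {
  lib <- simulate_library(seed = 22, family_divergence = 14)
  ct80 <- build_catalog(lib$members, list(subfamily = 95, family = 80))
  ct90 <- build_catalog(lib$members, list(subfamily = 95, family = 90))
  # every 90%-family lies inside a single 80%-family
  expect_true(all(tapply(ct80$assignments$family, ct90$assignments$family,
                         function(v) length(unique(v)) == 1)))
})

test_that("catalog thresholds and abundance ordering are validated", {
  trs <- list(tr_consensus("a", "ACGTACGTAC"))
  expect_error(build_catalog(trs, list(subfamily = 80, family = 95)), "thresholds")
  expect_error(build_catalog(trs, list(subfamily = 101, family = 80)), "thresholds")
  expect_error(build_catalog(list()), "no members")

  set.seed(105)
  lib <- simulate_library(n_families = 3, variants_per_family = 1,
                          members_per_variant = 1, seed = 23)
  ab <- c(fam01_var01_m01 = 10, fam02_var01_m01 = 500, fam03_var01_m01 = 50)
  ct <- build_catalog(lib$members, abundance = ab)
  # most abundant member gets family id 1
  expect_equal(ct$assignments$family[ct$assignments$name == "fam02_var01_m01"], 1L)
  expect_equal(ct$assignments$family[ct$assignments$name == "fam01_var01_m01"], 3L)
})

test_that("subfamily_consensus picks the medoid member", {
  base <- strrep("ACGTTACGGA", 10)
  set.seed(106)
  trs <- list(tr_consensus("central", base),
              tr_consensus("off1", mutate_dna(base, 3)),
              tr_consensus("off2", mutate_dna(base, 3)))
  ct <- build_catalog(trs)
  expect_equal(max(ct$assignments$subfamily), 1L)
  expect_equal(subfamily_consensus(ct), "central")
})

test_that("catalog TSV writer emits the assignment table", {
  lib <- simulate_library(n_families = 2, variants_per_family = 1,
                          members_per_variant = 2, seed = 24)
  ct <- build_catalog(lib$members)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_tsv(ct, tsv)
  back <- read.delim(tsv)
  expect_equal(back, ct$assignments)
})
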