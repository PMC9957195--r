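# Independent oracles and fixture builders shared across test files.
# The alignment oracle is a pure-R DP, deliberately separate from the
# package's C++ aligner and from Biostrings.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# substitute exactly k distinct positions to a different base
mutate_dna <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  for (p in sample.int(length(ch), k))
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

oracle_rotate <- function(seq, o) {
  n <- nchar(seq); o <- o %% n
  if (o == 0) return(seq)
  paste0(substring(seq, o + 1, n), substring(seq, 1, o))
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

oracle_dimerize <- function(seq, min_len = 200) {
  strrep(seq, max(2, ceiling(min_len / nchar(seq))))
}

# Global alignment identity, pure-R anti-diagonal DP. Same objective as
# the package aligner: match +1 / mismatch -1 / gap -1, lexicographically
# maximizing (score, matches, -columns) via scalarized weights; identity
# is 100 * matches / columns. Returns the identity only.
oracle_nw_identity <- function(a, b) {
  W1 <- 1e9; W2 <- 1e5
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0 || m == 0) stop("empty")
  gap <- -W1 - 1
  ## diagonals d = i + j, stored as vectors over i = 0..n at index i + 1;
  ## cells on one diagonal are mutually independent, so each diagonal is
  ## one vectorized sweep
  d2 <- c(0, rep(NA_real_, n))              # d = 0: cell (0,0)
  d1 <- c(gap, gap, rep(NA_real_, max(0, n - 1)))  # d = 1: (0,1), (1,0)
  for (d in 2:(n + m)) {
    cur <- rep(NA_real_, n + 1)
    i_int <- max(1, d - m):min(n, d - 1)    # interior cells (i >= 1, j >= 1)
    if (i_int[1] <= i_int[length(i_int)]) {
      j_int <- d - i_int
      sub <- d2[i_int] +
        ifelse(av[i_int] == bv[j_int], W1 + W2 - 1, -W1 - 1)
      cur[i_int + 1] <- pmax(sub, d1[i_int] + gap, d1[i_int + 1] + gap)
    }
    if (d <= m) cur[1] <- d * gap           # boundary (0, d)
    if (d <= n) cur[d + 1] <- d * gap       # boundary (d, 0)
    d2 <- d1; d1 <- cur
  }
  total <- d1[n + 1]
  score <- round(total / W1)
  matches <- round((total - score * W1) / W2)
  columns <- -(total - score * W1 - matches * W2)
  100 * matches / columns
}

# Brute-force rotation x strand scan with the pure-R DP aligner.
oracle_monomer_identity <- function(a, b, min_len = 200) {
  da <- oracle_dimerize(a, min_len)
  best <- -Inf
  for (sb in c(b, oracle_revcomp(b)))
    for (o in 0:(nchar(b) - 1))
      best <- max(best, oracle_nw_identity(
        da, oracle_dimerize(oracle_rotate(sb, o), min_len)))
  best
}

# partitions equal up to label renaming
same_partition <- function(p, q) {
  length(p) == length(q) &&
    !anyDuplicated(unique(data.frame(p = p, q = q))[["p"]]) &&
    !anyDuplicated(unique(data.frame(p = p, q = q))[["q"]])
}

fixture_path <- function(f) satzone_example(f)

table4_genotypes <- function() read_genotype_table(fixture_path("genotypes_transect.csv"))
table1_sites <- function() read_transect_sites(fixture_path("transect_sites.csv"))
cpp_bands <- function() read_band_table(fixture_path("bands_cpp.csv"), "CPP")
cpe_bands <- function() read_band_table(fixture_path("bands_cpe.csv"), "CPE")

# exact Table 4 allele frequencies used by several tests
q_autosomal_exact <- c(0, 0, 1/14, 3/24, 5/16, 1, 1)
q_xlinked_exact <- c(0, 0, 0, 0, 4/10, 1, 7/9)
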