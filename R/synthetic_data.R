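## Generators for every input the pipeline consumes, with known ground
## truth: monomer libraries with planted subfamily/family structure,
## divergence-hit sets produced by amplification-burst evolution, tandem
## array contexts for TSI, and transect genotype samples under a planted
## sigmoid cline. All generators are deterministic under a fixed seed.

.BASES <- c("A", "C", "G", "T")

# run code under a local RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

.random_monomer <- function(len)
  paste(sample(.BASES, len, replace = TRUE), collapse = "")

# substitute exactly k random positions to a different base
.mutate_k <- function(seq, k) {
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), k)
  for (p in pos)
    chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Simulate a TR family produced by an amplification burst
#'
#' An amplification burst at time \code{burst_time_mya} copies one
#' ancestral monomer \code{copies} times; each copy then accumulates
#' substitutions independently so that its expected divergence from the
#' ancestor is \code{2 * sub_rate_pct_per_mya * burst_time_mya} percent
#' (per-copy substitution counts are binomial over sites, Jukes-Cantor
#' style: uniform across sites and bases, no indels). The factor 2 makes
#' the dating estimator \code{t = DIVPEAK / (2 * rate)} unbiased for this
#' process. One divergence hit is emitted per copy with its realized
#' divergence and length.
#'
#' @param burst_time_mya Burst age in Mya (>= 0).
#' @param copies Number of copies amplified.
#' @param sub_rate_pct_per_mya Turnover rate in percent per Myr (default
#'   1.11, the grasshopper satDNA average used for dating).
#' @param monomer_len Monomer length in bp (default 300).
#' @param seed Integer seed.
#' @param family,library_id Labels stamped on the emitted hits.
#' @param emit_sequences If \code{FALSE}, skip materializing the mutated
#'   copy sequences (the hit table is identical either way under the same
#'   seed; sequence realization consumes additional random draws).
#' @return List with \code{ancestor} (a \code{\link{tr_consensus}}),
#'   \code{monomers} (list of \code{tr_consensus}, or \code{NULL}),
#'   \code{hits} (divergence-hit \code{data.frame}) and the model
#'   parameters.
#' @export
simulate_burst_family <- function(burst_time_mya, copies,
                                  sub_rate_pct_per_mya = 1.11,
                                  monomer_len = 300L, seed,
                                  family = "simfam", library_id = "sim",
                                  emit_sequences = TRUE) {
  stopifnot(burst_time_mya >= 0, copies >= 1L, sub_rate_pct_per_mya > 0,
            monomer_len >= 1L)
  if (missing(seed)) stop("simulate_burst_family: seed is required")
  p_sub <- 2 * sub_rate_pct_per_mya * burst_time_mya / 100
  if (p_sub > 1) stop("simulate_burst_family: expected divergence > 100%")
  .with_seed(seed, {
    anc <- .random_monomer(monomer_len)
    k <- rbinom(copies, monomer_len, p_sub)
    monomers <- NULL
    if (emit_sequences)
      monomers <- lapply(seq_len(copies), function(i)
        tr_consensus(sprintf("%s_copy%04d", family, i),
                     .mutate_k(anc, k[i])))
    hits <- data.frame(family = family,
                       divergence_pct = 100 * k / monomer_len,
                       length_bp = as.integer(monomer_len),
                       library_id = library_id,
                       provenance = "simulated",
                       stringsAsFactors = FALSE)
    list(ancestor = tr_consensus(paste0(family, "_ancestor"), anc),
         monomers = monomers, hits = hits,
         burst_time_mya = burst_time_mya,
         sub_rate_pct_per_mya = sub_rate_pct_per_mya, seed = seed)
  })
}

#' Simulate a TR library with planted subfamily/family structure
#'
#' Draws \code{n_families} unrelated ancestral monomers; each family
#' diversifies into variants (subfamilies) whose pairwise divergence is
#' about \code{family_divergence} percent (each variant moves
#' \code{family_divergence / 2} percent away from the family ancestor),
#' and each variant is emitted as \code{members_per_variant} member
#' sequences at about \code{variant_divergence} percent pairwise
#' divergence. With the default 10\% / 2\% settings, members of one
#' variant stay above the 95\% subfamily threshold and variants of one
#' family above the 80\% family threshold, while unrelated families fall
#' far below it.
#'
#' @param n_families Number of planted families.
#' @param variants_per_family Integer vector (recycled) of variant counts
#'   per family.
#' @param members_per_variant Member sequences emitted per variant.
#' @param family_divergence Target pairwise percent divergence between
#'   variants of one family (default 10).
#' @param variant_divergence Target pairwise percent divergence between
#'   members of one variant (default 2).
#' @param monomer_len Monomer length in bp (default 100).
#' @param seed Integer seed.
#' @return List with \code{members} (list of \code{\link{tr_consensus}})
#'   and \code{truth} (\code{data.frame} \code{name}, \code{subfamily},
#'   \code{family} ground-truth labels).
#' @export
simulate_library <- function(n_families = 5L, variants_per_family = 2:3,
                             members_per_variant = 5L,
                             family_divergence = 10, variant_divergence = 2,
                             monomer_len = 100L, seed) {
  if (missing(seed)) stop("simulate_library: seed is required")
  stopifnot(n_families >= 1L, all(variants_per_family >= 1L),
            members_per_variant >= 1L,
            family_divergence >= 0, variant_divergence >= 0)
  nv <- rep_len(variants_per_family, n_families)
  .with_seed(seed, {
    members <- list(); truth <- list()
    sub_id <- 0L
    for (f in seq_len(n_families)) {
      anc <- .random_monomer(monomer_len)
      for (v in seq_len(nv[f])) {
        sub_id <- sub_id + 1L
        k_var <- round(monomer_len * family_divergence / 2 / 100)
        var_seq <- .mutate_k(anc, k_var)
        for (m in seq_len(members_per_variant)) {
          k_mem <- round(monomer_len * variant_divergence / 2 / 100)
          nm <- sprintf("fam%02d_var%02d_m%02d", f, v, m)
          members[[length(members) + 1L]] <-
            tr_consensus(nm, .mutate_k(var_seq, k_mem))
          truth[[length(truth) + 1L]] <-
            data.frame(name = nm, subfamily = sub_id, family = f,
                       stringsAsFactors = FALSE)
        }
      }
    }
    list(members = members, truth = do.call(rbind, truth))
  })
}

#' Simulate junction-annotated hit contexts for TSI
#'
#' Plants a known fraction of a family's abundance in tandem arrays of at
#' least two units (every array member has a same-repeat junction) and the
#' rest as dispersed single monomers (no junctions), so the true TSI
#' equals \code{tandem_fraction} exactly.
#'
#' @param n_units Total number of monomer units.
#' @param tandem_fraction Fraction of units placed in arrays (default
#'   0.6).
#' @param monomer_len Unit length in bp.
#' @param seed Integer seed (array sizes are drawn from 2..5).
#' @return \code{data.frame} with columns \code{length_bp},
#'   \code{left_same}, \code{right_same}, \code{array_id}.
#' @export
simulate_array_contexts <- function(n_units = 1000L, tandem_fraction = 0.6,
                                    monomer_len = 300L, seed) {
  if (missing(seed)) stop("simulate_array_contexts: seed is required")
  stopifnot(tandem_fraction >= 0, tandem_fraction <= 1)
  n_tandem <- round(n_units * tandem_fraction)
  if (n_tandem == 1L) n_tandem <- 2L      # arrays need >= 2 units
  .with_seed(seed, {
    rows <- list(); aid <- 0L; left <- n_tandem
    while (left > 0L) {
      aid <- aid + 1L
      size <- min(left, sample(2:5, 1L))
      if (left - size == 1L) size <- size + 1L
      units <- data.frame(length_bp = as.integer(monomer_len),
                          left_same = c(FALSE, rep(TRUE, size - 1L)),
                          right_same = c(rep(TRUE, size - 1L), FALSE),
                          array_id = aid)
      rows[[length(rows) + 1L]] <- units
      left <- left - size
    }
    n_disp <- n_units - sum(vapply(rows, nrow, integer(1)))
    if (n_disp > 0L)
      rows[[length(rows) + 1L]] <-
        data.frame(length_bp = as.integer(monomer_len),
                   left_same = rep(FALSE, n_disp),
                   right_same = rep(FALSE, n_disp),
                   array_id = NA_integer_)
    do.call(rbind, rows)
  })
}

#' Simulate transect genotype samples under a sigmoid cline
#'
#' Site allele frequencies follow a logistic cline,
#' \code{q(site) = plogis((order_index - center) / width)}. At each site,
#' autosomal markers draw \code{n} male genotypes from Hardy-Weinberg
#' proportions \code{(p^2, 2pq, q^2)}; X-linked markers draw \code{n}
#' hemizygous male X chromosomes as Bernoulli(q), so X-linked tables never
#' carry heterozygote counts.
#'
#' @param center Cline centre in \code{order_index} units.
#' @param width Cline width parameter (> 0; smaller is steeper).
#' @param n_per_site Integer vector (recycled) of males sampled per site.
#' @param linkage \code{"autosomal"} or \code{"x_linked"}.
#' @param sites Site \code{data.frame} with \code{population} and
#'   \code{order_index} (default: seven sites labelled S1..S7 at order
#'   1..7, mirroring a seven-population transect).
#' @param seed Integer seed.
#' @param marker Marker label stamped on the rows.
#' @return Genotype \code{data.frame} in \code{\link{read_genotype_table}}
#'   layout, with the planted \code{true_q} per site as an extra column.
#' @export
simulate_transect <- function(center, width, n_per_site = 30L,
                              linkage = c("autosomal", "x_linked"),
                              sites = NULL, seed, marker = "simmarker") {
  linkage <- match.arg(linkage)
  if (missing(seed)) stop("simulate_transect: seed is required")
  stopifnot(width > 0)
  if (is.null(sites))
    sites <- data.frame(population = paste0("S", 1:7), order_index = 1:7,
                        stringsAsFactors = FALSE)
  sites <- sites[order(sites$order_index), , drop = FALSE]
  n <- rep_len(as.integer(n_per_site), nrow(sites))
  q <- plogis((sites$order_index - center) / width)
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(sites)), function(i) {
      if (linkage == "autosomal") {
        probs <- c((1 - q[i])^2, 2 * q[i] * (1 - q[i]), q[i]^2)
        g <- as.integer(rmultinom(1, n[i], probs))
        data.frame(population = sites$population[i], marker = marker,
                   linkage = linkage, NN = g[1], NB = g[2], BB = g[3],
                   N = NA_integer_, B = NA_integer_, true_q = q[i],
                   stringsAsFactors = FALSE)
      } else {
        b <- rbinom(1, n[i], q[i])
        data.frame(population = sites$population[i], marker = marker,
                   linkage = linkage, NN = NA_integer_, NB = NA_integer_,
                   BB = NA_integer_, N = n[i] - b, B = b, true_q = q[i],
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  })
}
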