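## Allele-frequency clines along a hybrid-zone transect, built from
## genotype counts of presence/absence band markers, plus Gardner-Altman
## paired-mean-difference effect sizes with bootstrap confidence
## intervals.

#' Round half away from zero
#'
#' Reporting convention for allele frequencies: round-half-up at
#' \code{digits} decimals (so 0.125 reports as 0.13), unlike base R's
#' banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Allele frequencies from genotype counts
#'
#' Autosomal markers: \code{q_B = (NB + 2 BB) / (2 (NN + NB + BB))}
#' from male meiotic scoring. X-linked markers in an X0-male system are
#' hemizygous: \code{q_B = B / (N + B)}. \code{p_N} is the exact
#' complement, so \code{p_N + q_B == 1} without rounding; rounding happens
#' only at report time (\code{\link{round_half_up}}).
#'
#' @param gt Genotype \code{data.frame} (rows of
#'   \code{\link{read_genotype_table}}).
#' @return \code{data.frame} with columns \code{population},
#'   \code{marker}, \code{linkage}, \code{n_chromosomes}, \code{p_N},
#'   \code{q_B}.
#' @examples
#' gt <- data.frame(population = "CM", marker = "m", linkage = "autosomal",
#'                  NN = 4L, NB = 3L, BB = 1L, N = NA, B = NA)
#' allele_frequencies(gt)$q_B  # 5/16 = 0.3125
#' @export
allele_frequencies <- function(gt) {
  out <- lapply(seq_len(nrow(gt)), function(r) {
    row <- gt[r, ]
    if (row$linkage == "autosomal") {
      tot <- 2L * (row$NN + row$NB + row$BB)
      if (is.na(tot) || tot == 0L)
        stop("allele_frequencies: zero or missing total for population '",
             row$population, "'")
      q <- (row$NB + 2L * row$BB) / tot
    } else if (row$linkage == "x_linked") {
      tot <- row$N + row$B
      if (is.na(tot) || tot == 0L)
        stop("allele_frequencies: zero or missing total for population '",
             row$population, "'")
      q <- row$B / tot
    } else stop("allele_frequencies: unknown linkage '", row$linkage, "'")
    data.frame(population = row$population, marker = row$marker,
               linkage = row$linkage, n_chromosomes = as.integer(tot),
               p_N = 1 - q, q_B = q, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build an allele-frequency cline along the transect
#'
#' Joins one marker's per-population allele frequencies to the ordered
#' transect sites.
#'
#' @param gts Genotype table (all markers;
#'   \code{\link{read_genotype_table}}).
#' @param sites Transect sites (\code{\link{read_transect_sites}}).
#' @param marker Marker name to profile.
#' @return \code{data.frame} of class \code{cline_profile}, one row per
#'   site in transect order, with site columns plus \code{n_chromosomes},
#'   \code{p_N}, \code{q_B} (\code{NA} where a site was not genotyped).
#' @export
build_cline <- function(gts, sites, marker) {
  g <- gts[gts$marker == marker, , drop = FALSE]
  if (!nrow(g)) stop("build_cline: no genotypes for marker '", marker, "'")
  unmatched <- setdiff(g$population, sites$population)
  if (length(unmatched))
    stop("build_cline: populations not on the transect: ",
         paste(unmatched, collapse = ", "))
  freqs <- allele_frequencies(g)
  sites <- sites[order(sites$order_index), , drop = FALSE]
  idx <- match(sites$population, freqs$population)
  out <- cbind(sites,
               marker = marker,
               n_chromosomes = freqs$n_chromosomes[idx],
               p_N = freqs$p_N[idx],
               q_B = freqs$q_B[idx])
  rownames(out) <- NULL
  class(out) <- c("cline_profile", "data.frame")
  out
}

#' Locate the cline centre
#'
#' Finds the first adjacent site pair whose segment crosses allele
#' frequency 0.5 under linear interpolation on \code{order_index}, and
#' reports the endpoint whose frequency is closer to 0.5 as the nearest
#' site (ties to the earlier site). Profiles that never span 0.5 yield a
#' "no crossing" outcome.
#'
#' @param profile A \code{cline_profile} (sites with \code{NA} frequency
#'   are dropped).
#' @return List of class \code{cline_center} with \code{crossing}
#'   (logical), \code{interval} (character vector of the two site names,
#'   or \code{NULL}), \code{nearest_site} and \code{center_order} (the
#'   interpolated \code{order_index} at frequency 0.5).
#' @export
cline_center <- function(profile) {
  p <- profile[!is.na(profile$q_B), , drop = FALSE]
  if (nrow(p) < 2L) stop("cline_center: need at least two genotyped sites")
  q <- p$q_B
  no_cross <- structure(list(crossing = FALSE, interval = NULL,
                             nearest_site = NA_character_,
                             center_order = NA_real_),
                        class = "cline_center")
  if (max(q) < 0.5 || min(q) > 0.5) return(no_cross)
  for (i in seq_len(nrow(p) - 1L)) {
    lo <- min(q[i], q[i + 1L]); hi <- max(q[i], q[i + 1L])
    if (lo <= 0.5 && hi >= 0.5 && !(lo == hi && lo != 0.5)) {
      nearest <- if (abs(q[i] - 0.5) <= abs(q[i + 1L] - 0.5)) i else i + 1L
      center <- if (q[i + 1L] == q[i]) mean(p$order_index[i + 0:1])
                else p$order_index[i] + (0.5 - q[i]) / (q[i + 1L] - q[i]) *
                     (p$order_index[i + 1L] - p$order_index[i])
      return(structure(list(
        crossing = TRUE,
        interval = p$population[i + 0:1],
        nearest_site = p$population[nearest],
        center_order = center), class = "cline_center"))
    }
  }
  no_cross
}

#' @export
print.cline_center <- function(x, ...) {
  if (!x$crossing) cat("<cline_center> no 0.5 crossing\n")
  else cat(sprintf("<cline_center> interval %s-%s, nearest site %s (order %.2f)\n",
                   x$interval[1], x$interval[2], x$nearest_site,
                   x$center_order))
  invisible(x)
}

#' Gardner-Altman paired mean difference with BCa bootstrap CI
#'
#' Effect size for matched pairs: \code{mean(y - x)}, with a 95\%
#' bias-corrected-and-accelerated (BCa) percentile interval of the
#' bootstrap distribution obtained by resampling pairs with replacement.
#' The convention is second argument minus first; put the comparison group
#' in \code{y}. The effect is judged by whether the interval includes
#' zero.
#'
#' @param x,y Equal-length numeric vectors (length >= 2), paired by
#'   position.
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Integer seed; required so the interval is reproducible.
#' @param conf Confidence level (default 0.95).
#' @return List of class \code{paired_effect}: \code{mean_difference},
#'   \code{ci_low}, \code{ci_high}, \code{n_pairs}, \code{n_boot},
#'   \code{seed}, \code{conf}.
#' @examples
#' paired_mean_difference(c(0, 0.1, 0.4, 1), c(0, 0, 0.5, 1), seed = 1)
#' @export
paired_mean_difference <- function(x, y, n_boot = 5000L, seed, conf = 0.95) {
  if (length(x) != length(y))
    stop("paired_mean_difference: length mismatch")
  if (length(x) < 2L) stop("paired_mean_difference: need >= 2 pairs")
  if (missing(seed)) stop("paired_mean_difference: seed is required")
  d <- y - x
  n <- length(d)
  obs <- mean(d)
  boot <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    colMeans(matrix(d[idx], nrow = n))
  })
  if (diff(range(boot)) == 0 && diff(range(d)) == 0) {
    ci <- c(obs, obs)                     # degenerate: identical pairs
  } else {
    z0 <- qnorm((sum(boot < obs) + 0.5 * sum(boot == obs)) / n_boot)
    jack <- (sum(d) - d) / (n - 1)        # leave-one-out means
    jm <- mean(jack)
    num <- sum((jm - jack)^3); den <- 6 * sum((jm - jack)^2)^1.5
    a <- if (den == 0) 0 else num / den
    alpha <- (1 - conf) / 2
    zs <- qnorm(c(alpha, 1 - alpha))
    adj <- pnorm(z0 + (z0 + zs) / (1 - a * (z0 + zs)))
    if (!is.finite(z0)) adj <- c(alpha, 1 - alpha)  # obs outside boot range
    ci <- unname(quantile(boot, adj, type = 7))
  }
  structure(list(mean_difference = obs,
                 ci_low = min(ci[1], obs), ci_high = max(ci[2], obs),
                 n_pairs = n, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), conf = conf),
            class = "paired_effect")
}

#' @export
print.paired_effect <- function(x, ...) {
  cat(sprintf("<paired_effect> mean difference %.4f  (%.0f%% CI: %.4f, %.4f)  n=%d pairs, %d resamples\n",
              x$mean_difference, 100 * x$conf, x$ci_low, x$ci_high,
              x$n_pairs, x$n_boot))
  invisible(x)
}
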