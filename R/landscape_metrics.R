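## Repeat landscapes: the distribution of a family's genomic abundance
## (aligned bp) over divergence-from-consensus bins, and the indices
## derived from them. A leptokurtic peak at low divergence marks a recent
## amplification burst; the peak's position (DIVPEAK) is a degeneration
## index convertible to time, and the abundance concentrated around it
## (RPS) is a homogenization index.

#' Build a repeat landscape from divergence hits
#'
#' Each hit contributes its aligned length to the bin containing its
#' divergence; bins are half-open \code{[edge, edge + bin_width)} with
#' lower-edge labels, so a hit at exactly 0.5\% falls in the 0.5 bin.
#' Zero-abundance bins are retained up to the maximum observed divergence.
#'
#' @param hits Hit \code{data.frame} (see
#'   \code{\link{read_repeatmasker_hits}}).
#' @param family,library_id Optional filters; \code{NULL} keeps all rows
#'   (after filtering the hit set must be non-empty).
#' @param bin_width Bin width in percent divergence (default 0.5).
#' @return Object of class \code{repeat_landscape}: list with
#'   \code{family}, \code{library_id}, \code{bin_width}, \code{bins}
#'   (data.frame \code{bin_lower}, \code{abundance_bp}) and
#'   \code{total_bp}.
#' @examples
#' hits <- data.frame(family = "famA",
#'                    divergence_pct = c(0.2, 0.7, 0.7, 1.3),
#'                    length_bp = 100L, library_id = "CPE")
#' compute_landscape(hits, "famA", "CPE")
#' @export
compute_landscape <- function(hits, family = NULL, library_id = NULL,
                              bin_width = 0.5) {
  if (bin_width <= 0) stop("compute_landscape: bin_width must be > 0")
  keep <- rep(TRUE, nrow(hits))
  if (!is.null(family)) keep <- keep & hits$family == family
  if (!is.null(library_id)) keep <- keep & hits$library_id == library_id
  h <- hits[keep, , drop = FALSE]
  if (!nrow(h))
    stop("compute_landscape: empty landscape (no hits for family='",
         family, "', library='", library_id, "')")
  edges <- floor(h$divergence_pct / bin_width) * bin_width
  all_edges <- seq(0, max(edges), by = bin_width)
  abundance <- vapply(all_edges, function(e)
    sum(as.integer(h$length_bp)[abs(edges - e) < bin_width / 2]), integer(1))
  structure(list(
    family = if (is.null(family)) NA_character_ else family,
    library_id = if (is.null(library_id)) NA_character_ else library_id,
    bin_width = bin_width,
    bins = data.frame(bin_lower = all_edges, abundance_bp = abundance),
    total_bp = sum(as.integer(h$length_bp))), class = "repeat_landscape")
}

#' @export
print.repeat_landscape <- function(x, ...) {
  cat(sprintf("<repeat_landscape> %s / %s: %d bins of %.2f%%, %d bp total\n",
              x$family, x$library_id, nrow(x$bins), x$bin_width,
              x$total_bp))
  invisible(x)
}

#' @describeIn compute_landscape Barplot of a repeat landscape
#'   (abundance fraction per divergence bin).
#' @param x A \code{repeat_landscape}.
#' @param ... Passed to \code{\link[graphics]{barplot}}.
#' @export
plot.repeat_landscape <- function(x, ...) {
  graphics::barplot(x$bins$abundance_bp / x$total_bp,
                    names.arg = format(x$bins$bin_lower),
                    xlab = "divergence from consensus (%)",
                    ylab = "abundance fraction",
                    main = paste(x$family, x$library_id, sep = " / "), ...)
  invisible(x)
}

#' DIVPEAK: divergence bin of maximum abundance
#'
#' The lower-edge label of the maximum-abundance bin; ties break toward
#' lower divergence (the younger interpretation).
#'
#' @param landscape A \code{repeat_landscape}.
#' @return Numeric bin label in percent.
#' @export
divpeak <- function(landscape) {
  b <- landscape$bins
  if (!nrow(b)) stop("divpeak: empty landscape")
  b$bin_lower[which.max(b$abundance_bp)]
}

#' RPS: relative peak size
#'
#' Percentage of total abundance lying in bins whose lower edge is within
#' \code{window_pct} of DIVPEAK (inclusive). A recently amplified,
#' homogenized family concentrates its abundance in the peak and scores
#' near 100; a degenerate family spreads it out.
#'
#' @param landscape A \code{repeat_landscape}.
#' @param window_pct Half-width of the peak window in percent divergence
#'   (default 1.0; must be at least the bin width).
#' @return Numeric in \code{[0, 100]}.
#' @export
rps <- function(landscape, window_pct = 1.0) {
  if (window_pct < landscape$bin_width)
    stop("rps: window_pct must be >= bin width")
  dp <- divpeak(landscape)
  b <- landscape$bins
  eps <- landscape$bin_width * 1e-9
  in_win <- abs(b$bin_lower - dp) <= window_pct + eps
  100 * sum(b$abundance_bp[in_win]) / landscape$total_bp
}

#' TSI: tandem structure index
#'
#' Abundance-weighted fraction of hits with at least one same-repeat
#' junction, i.e. whose flanking sequence on either side is another copy
#' of the same repeat. Hits inside tandem arrays carry junctions; fully
#' dispersed single monomers carry none, so TSI is monotone in how much of
#' the family's abundance sits in arrays.
#'
#' @param hit_contexts \code{data.frame} with columns \code{length_bp},
#'   \code{left_same}, \code{right_same} (logical junction evidence).
#' @return Numeric in \code{[0, 1]}.
#' @export
tsi <- function(hit_contexts) {
  need <- c("length_bp", "left_same", "right_same")
  if (!all(need %in% names(hit_contexts)))
    stop("tsi: hit_contexts must have columns ",
         paste(need, collapse = ", "))
  if (anyNA(hit_contexts$left_same) || anyNA(hit_contexts$right_same))
    stop("tsi: missing junction annotations")
  if (!nrow(hit_contexts)) stop("tsi: no hits")
  junction <- hit_contexts$left_same | hit_contexts$right_same
  sum(hit_contexts$length_bp[junction]) / sum(hit_contexts$length_bp)
}

#' Date an amplification burst from DIVPEAK
#'
#' Converts a degeneration index to time since the last amplification
#' under a constant TR turnover rate: \code{time = divpeak_pct / (2 *
#' rate)} Mya. The default rate of 1.11\% per lineage per Myr is the
#' average satDNA turnover rate measured in grasshoppers; the factor 2
#' accounts for divergence accruing on both the consensus-defining and the
#' copy lineage.
#'
#' @param divpeak_pct DIVPEAK in percent (>= 0).
#' @param rate Turnover rate in percent per Myr (> 0; default 1.11).
#' @return Time in Mya (unrounded; report layers typically round to one
#'   decimal).
#' @examples
#' round(amplification_time(3.3), 1)  # 1.5
#' round(amplification_time(7.8), 1)  # 3.5
#' @export
amplification_time <- function(divpeak_pct, rate = 1.11) {
  if (any(rate <= 0)) stop("amplification_time: rate must be > 0")
  if (any(divpeak_pct < 0)) stop("amplification_time: divpeak_pct must be >= 0")
  divpeak_pct / (2 * rate)
}

#' All landscape metrics at once
#'
#' @param landscape A \code{repeat_landscape}.
#' @param hit_contexts Optional junction-annotated hits for
#'   \code{\link{tsi}} (\code{NA} otherwise).
#' @param window_pct RPS window (see \code{\link{rps}}).
#' @param rate Dating rate (see \code{\link{amplification_time}}).
#' @return List of class \code{landscape_metrics} with \code{divpeak_pct},
#'   \code{rps_pct}, \code{tsi}, \code{time_mya}.
#' @export
landscape_metrics <- function(landscape, hit_contexts = NULL,
                              window_pct = 1.0, rate = 1.11) {
  dp <- divpeak(landscape)
  structure(list(
    divpeak_pct = dp,
    rps_pct = rps(landscape, window_pct),
    tsi = if (is.null(hit_contexts)) NA_real_ else tsi(hit_contexts),
    time_mya = amplification_time(dp, rate)), class = "landscape_metrics")
}

#' @export
print.landscape_metrics <- function(x, ...) {
  cat(sprintf("<landscape_metrics> DIVPEAK=%.2f%%  RPS=%.1f%%  TSI=%s  time=%.1f Mya\n",
              x$divpeak_pct, x$rps_pct,
              if (is.na(x$tsi)) "NA" else sprintf("%.2f", x$tsi),
              x$time_mya))
  invisible(x)
}
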