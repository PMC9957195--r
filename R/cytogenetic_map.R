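## Comparison of chromosome band tables between two taxa. A TR family's
## FISH signal on a karyotype is classified as B (banded), DB
## (dotted-banded), D (dotted) or NS (no signal); only B and DB count as
## "banded". Families banded in exactly one taxon are the differential
## presence/absence markers usable for hybrid-zone analysis.

.banded_patterns <- c("B", "DB")

#' Summarize band records into per-family pattern summaries
#'
#' @param bands Band-record \code{data.frame} (see
#'   \code{\link{read_band_table}}).
#' @param patterns \code{data.frame} with columns \code{family},
#'   \code{pattern} covering every family in \code{bands} (by default
#'   taken from the \code{"patterns"} attribute of \code{bands}).
#' @param taxon Taxon label (default: from the band records).
#' @return \code{data.frame} with columns \code{family}, \code{taxon},
#'   \code{pattern}, \code{chrom_count} (number of distinct chromosomes
#'   carrying at least one band).
#' @export
summarize_patterns <- function(bands, patterns = attr(bands, "patterns"),
                               taxon = NULL) {
  if (is.null(patterns))
    stop("summarize_patterns: no pattern map supplied")
  if (is.null(taxon))
    taxon <- if (nrow(bands)) bands$taxon[1] else NA_character_
  missing_fams <- setdiff(unique(bands$family), patterns$family)
  if (length(missing_fams))
    stop("summarize_patterns: pattern map lacks families: ",
         paste(missing_fams, collapse = ", "))
  counts <- vapply(patterns$family, function(f)
    length(unique(bands$chromosome[bands$family == f])), integer(1))
  bad <- patterns$pattern == "NS" & counts > 0L
  if (any(bad))
    stop("summarize_patterns: NS family with band records: ",
         paste(patterns$family[bad], collapse = ", "))
  data.frame(family = patterns$family, taxon = taxon,
             pattern = patterns$pattern, chrom_count = counts,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Histogram of chromosome spread for banded families
#'
#' How many banded (B/DB) families occupy 1, 2, ... up to all 9
#' chromosomes of the karyotype.
#'
#' @param summaries Pattern summaries for one taxon
#'   (\code{\link{summarize_patterns}}).
#' @return Named integer vector over chromosome counts \code{1..9}.
#' @export
spread_histogram <- function(summaries) {
  if (length(unique(summaries$taxon)) > 1L)
    stop("spread_histogram: summaries mix taxa")
  banded <- summaries[summaries$pattern %in% .banded_patterns, , drop = FALSE]
  counts <- table(factor(banded$chrom_count, levels = seq_along(KARYOTYPE)))
  stats::setNames(as.integer(counts), names(counts))
}

#' Differential presence/absence markers between two taxa
#'
#' Families banded (B/DB) in exactly one of the two taxa and giving no
#' signal (NS) in the other; these are the usable hybrid-zone markers.
#' Swapping the argument order swaps \code{banded_in}/\code{absent_in} and
#' nothing else.
#'
#' @param summaries_a,summaries_b Pattern summaries for the two taxa over
#'   the same family set.
#' @param bands_a,bands_b Optional band records used to list the affected
#'   chromosomes.
#' @return \code{data.frame} with columns \code{family}, \code{banded_in},
#'   \code{absent_in}, \code{chromosomes} (comma-separated).
#' @export
differential_markers <- function(summaries_a, summaries_b,
                                 bands_a = NULL, bands_b = NULL) {
  if (!setequal(summaries_a$family, summaries_b$family))
    stop("differential_markers: taxa cover different family sets")
  taxon_a <- summaries_a$taxon[1]; taxon_b <- summaries_b$taxon[1]
  pat_a <- stats::setNames(summaries_a$pattern, summaries_a$family)
  pat_b <- stats::setNames(summaries_b$pattern, summaries_b$family)
  fams <- summaries_a$family
  chroms_of <- function(bands, fam) {
    if (is.null(bands)) return(NA_character_)
    ch <- unique(bands$chromosome[bands$family == fam])
    paste(ch[order(match(ch, KARYOTYPE))], collapse = ",")
  }
  rows <- lapply(fams, function(f) {
    a_band <- pat_a[[f]] %in% .banded_patterns
    b_band <- pat_b[[f]] %in% .banded_patterns
    if (a_band && pat_b[[f]] == "NS")
      data.frame(family = f, banded_in = taxon_a, absent_in = taxon_b,
                 chromosomes = chroms_of(bands_a, f),
                 stringsAsFactors = FALSE)
    else if (b_band && pat_a[[f]] == "NS")
      data.frame(family = f, banded_in = taxon_b, absent_in = taxon_a,
                 chromosomes = chroms_of(bands_b, f),
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(family = character(), banded_in = character(),
                      absent_in = character(), chromosomes = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-chromosome family counts
#'
#' Number of distinct families with at least one band on each chromosome
#' of the karyotype.
#'
#' @param bands Band records for one taxon.
#' @return Named integer vector over chromosomes \code{1..8, X}.
#' @export
per_chromosome_counts <- function(bands) {
  vapply(KARYOTYPE, function(ch)
    length(unique(bands$family[bands$chromosome == ch])), integer(1))
}

#' Families banded on a chromosome in one taxon but not another
#'
#' Set difference of per-chromosome family sets; the \code{taxon-exclusive}
#' reading of "more TR families on chromosome c in taxon A".
#'
#' @param bands_a,bands_b Band records for the two taxa.
#' @param chromosome Chromosome label (\code{"1"}..\code{"8"},
#'   \code{"X"}).
#' @return Character vector of families with a band on \code{chromosome}
#'   in \code{bands_a} but not in \code{bands_b}.
#' @export
exclusive_families <- function(bands_a, bands_b, chromosome) {
  fa <- unique(bands_a$family[bands_a$chromosome == chromosome])
  fb <- unique(bands_b$family[bands_b$chromosome == chromosome])
  setdiff(fa, fb)
}
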