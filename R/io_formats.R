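## Readers and writers for every external representation the pipeline
## touches: FASTA consensus libraries, RepeatMasker hit tables (.out /
## .align / internal TSV), cytogenetic band tables and genotype tables.

#' TR consensus monomer
#'
#' Container for a single tandem-repeat consensus: one monomer unit of the
#' repeat, its name and its repeat-unit length (RUL). The stored sequence is
#' always exactly one monomer; dimerization for alignment is an operation
#' (\code{\link{dimerize}}), not a storage convention.
#'
#' @param name Sequence name. Names of the form \code{"<stem>-<int>"}
#'   carry the RUL as the trailing integer (e.g. \code{"CpaTR016-7"} has a
#'   7-bp monomer).
#' @param sequence Uppercase DNA string over \code{A,C,G,T,N}; length equals
#'   the RUL.
#' @param rul Repeat-unit length in bp; defaults to \code{nchar(sequence)}.
#' @return An object of class \code{tr_consensus} with fields \code{name},
#'   \code{sequence}, \code{rul}.
#' @examples
#' tr_consensus("CpaTR016-7", "AACCTGG")
#' @export
tr_consensus <- function(name, sequence, rul = nchar(sequence)) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L)
    stop("tr_consensus: empty sequence for '", name, "'")
  if (grepl("[^ACGTN]", sequence))
    stop("tr_consensus: sequence of '", name,
         "' contains characters outside {A,C,G,T,N}")
  rul <- as.integer(rul)
  if (is.na(rul) || rul < 1L)
    stop("tr_consensus: rul must be a positive integer")
  if (rul != nchar(sequence))
    stop("tr_consensus: rul (", rul, ") != monomer length (",
         nchar(sequence), ") for '", name, "'")
  structure(list(name = name, sequence = sequence, rul = rul),
            class = "tr_consensus")
}

#' @export
print.tr_consensus <- function(x, ...) {
  seq_show <- if (x$rul > 40L) paste0(substr(x$sequence, 1L, 37L), "...")
              else x$sequence
  cat(sprintf("<tr_consensus> %s  RUL=%d bp  %s\n", x$name, x$rul, seq_show))
  invisible(x)
}

# RUL implied by a name: trailing "-<int>", else NA.
.rul_from_name <- function(name) {
  m <- regmatches(name, regexpr("-([0-9]+)$", name))
  if (length(m) == 0L) return(NA_integer_)
  as.integer(sub("^-", "", m))
}

#' Read a FASTA file of TR consensus monomers
#'
#' The RUL is taken from a trailing \code{"-<int>"} suffix in the record
#' name when present and consistent with the sequence length is not
#' required; the stored monomer length always wins, but a mismatch between
#' suffix and length triggers a warning so mislabelled libraries surface
#' early.
#'
#' @param path FASTA file. An empty file yields an empty list.
#' @return List of \code{\link{tr_consensus}} objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("read_fasta: malformed FASTA in ", path, ": ",
                         conditionMessage(e)))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    nm <- strsplit(names(set)[i], "[ \t]")[[1]][1]
    sq <- as.character(set[[i]])
    if (nchar(sq) == 0L)
      stop("read_fasta: empty sequence for record '", nm, "'")
    suffix <- .rul_from_name(nm)
    if (!is.na(suffix) && suffix != nchar(sq))
      warning("read_fasta: record '", nm, "' declares RUL ", suffix,
              " but sequence has ", nchar(sq), " bp; using sequence length")
    out[[i]] <- tr_consensus(nm, sq)
  }
  out
}

#' Write TR consensus monomers to FASTA
#'
#' @param consensuses List of \code{\link{tr_consensus}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(consensuses, path) {
  seqs <- vapply(consensuses, `[[`, character(1), "sequence")
  nms <- vapply(consensuses, `[[`, character(1), "name")
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- nms
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read divergence hits from RepeatMasker output or internal TSV
#'
#' A divergence hit is one masked genomic interval: the family it was
#' masked with, its percent divergence from the family consensus, and the
#' number of aligned bases it contributes to abundance.
#'
#' Dialects:
#' \describe{
#'   \item{\code{"out"}}{RepeatMasker \code{.out} table: divergence is
#'     column 2 (\code{perc div.}), the matching repeat is column 10, and
#'     \code{length_bp = query_end - query_begin + 1} (columns 6 and 7 are
#'     1-based inclusive).}
#'   \item{\code{"align"}}{RepeatMasker \code{.align} file: one alignment
#'     block per hit, introduced by a header line with the raw percent
#'     divergence in field 2; a following \code{Kimura (with divCpGMod)}
#'     line, when present, supplies the Kimura-corrected divergence which
#'     is preferred. The \code{provenance} column records which was used.}
#'   \item{\code{"tsv"}}{The package's own tab-separated format with
#'     columns \code{family}, \code{divergence_pct}, \code{length_bp} and
#'     optionally \code{library_id} (header optional).}
#' }
#'
#' @param path Input file.
#' @param dialect One of \code{"out"}, \code{"align"}, \code{"tsv"}.
#' @param library_id Sample/taxon label attached to every hit when the file
#'   itself carries none.
#' @return \code{data.frame} with columns \code{family},
#'   \code{divergence_pct}, \code{length_bp}, \code{library_id},
#'   \code{provenance}.
#' @export
read_repeatmasker_hits <- function(path, dialect = c("tsv", "out", "align"),
                                   library_id = NA_character_) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e)
                        stop("read_repeatmasker_hits: unknown dialect"))
  if (!file.exists(path))
    stop("read_repeatmasker_hits: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  switch(dialect,
         tsv = .parse_hits_tsv(lines, library_id, path),
         out = .parse_hits_out(lines, library_id, path),
         align = .parse_hits_align(lines, library_id, path))
}

.hit_frame <- function(family, divergence_pct, length_bp, library_id,
                       provenance) {
  if (any(divergence_pct < 0 | divergence_pct > 100))
    stop("divergence_pct outside [0, 100]")
  if (any(length_bp < 1L)) stop("length_bp must be >= 1")
  data.frame(family = family, divergence_pct = divergence_pct,
             length_bp = as.integer(length_bp),
             library_id = library_id, provenance = provenance,
             stringsAsFactors = FALSE)
}

.parse_hits_tsv <- function(lines, library_id, path) {
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) && grepl("^family\t", lines[1])) lines <- lines[-1]
  if (!length(lines))
    return(.hit_frame(character(), numeric(), integer(), character(),
                      character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 3L))
    stop("read_repeatmasker_hits: line ", which(n < 3L)[1],
         " of ", path, " has fewer than 3 columns")
  fam <- vapply(parts, `[[`, character(1), 1L)
  div <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(div))
    stop("read_repeatmasker_hits: non-numeric divergence at line ",
         which(is.na(div))[1], " of ", path)
  len <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(len))
    stop("read_repeatmasker_hits: non-numeric length at line ",
         which(is.na(len))[1], " of ", path)
  lib <- ifelse(n >= 4L, vapply(parts, function(p) p[min(4L, length(p))],
                                character(1)), library_id)
  .hit_frame(fam, div, len, lib, "tsv")
}

.parse_hits_out <- function(lines, library_id, path) {
  body <- lines[grepl("^ *[0-9]+ ", lines)]  # data rows start with the SW score
  if (!length(body))
    return(.hit_frame(character(), numeric(), integer(), character(),
                      character()))
  fields <- strsplit(trimws(body), "[ \t]+")
  n <- lengths(fields)
  if (any(n < 10L))
    stop("read_repeatmasker_hits: malformed .out row in ", path)
  div <- suppressWarnings(
    as.numeric(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(div))
    stop("read_repeatmasker_hits: non-numeric divergence in .out row ",
         which(is.na(div))[1], " of ", path)
  qs <- as.integer(vapply(fields, `[[`, character(1), 6L))
  qe <- as.integer(vapply(fields, `[[`, character(1), 7L))
  fam <- vapply(fields, `[[`, character(1), 10L)
  .hit_frame(fam, div, qe - qs + 1L, library_id, "out_raw")
}

.parse_hits_align <- function(lines, library_id, path) {
  ## Header lines look like .out rows ("score div del ins query qbegin qend
  ## ..."); a subsequent "Kimura (with divCpGMod)=x.xx" line overrides the
  ## raw divergence for the preceding block.
  hdr_idx <- grep("^[0-9]+ ", trimws(lines))
  lines_t <- trimws(lines)
  if (!length(hdr_idx))
    return(.hit_frame(character(), numeric(), integer(), character(),
                      character()))
  fam <- character(length(hdr_idx)); div <- numeric(length(hdr_idx))
  len <- integer(length(hdr_idx)); prov <- character(length(hdr_idx))
  bounds <- c(hdr_idx[-1] - 1L, length(lines))
  for (i in seq_along(hdr_idx)) {
    f <- strsplit(lines_t[hdr_idx[i]], "[ \t]+")[[1]]
    if (length(f) < 9L)
      stop("read_repeatmasker_hits: malformed .align header at line ",
           hdr_idx[i], " of ", path)
    raw <- suppressWarnings(as.numeric(f[2]))
    if (is.na(raw))
      stop("read_repeatmasker_hits: non-numeric divergence at line ",
           hdr_idx[i], " of ", path)
    qs <- as.integer(f[6]); qe <- as.integer(f[7])
    ## repeat name: field after the strand marker ("C") if present, else
    ## field 9 for forward alignments
    fam[i] <- if (f[9] == "C") f[10] else f[9]
    block <- lines_t[hdr_idx[i]:bounds[i]]
    kim <- grep("^Kimura", block, value = TRUE)
    if (length(kim)) {
      div[i] <- as.numeric(sub(".*=\\s*", "", kim[1]))
      prov[i] <- "align_kimura"
    } else {
      div[i] <- raw
      prov[i] <- "align_raw"
    }
    len[i] <- qe - qs + 1L
  }
  .hit_frame(fam, div, len, library_id, prov)
}

#' Write divergence hits to the package TSV format
#'
#' @param hits Hit \code{data.frame} as returned by
#'   \code{\link{read_repeatmasker_hits}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("family\tdivergence_pct\tlength_bp\tlibrary_id", con)
  if (nrow(hits))
    writeLines(paste(hits$family,
                     vapply(hits$divergence_pct, format, character(1),
                            digits = 15, trim = TRUE, scientific = FALSE),
                     hits$length_bp, hits$library_id, sep = "\t"), con)
  invisible(path)
}

# ---- cytogenetic band tables -------------------------------------------

# Expand one compact location cell ("p *i *d *", "iii", "id", "pd *", ...)
# into location letters and heterozygosity flags. Whitespace is cosmetic.
.parse_band_cell <- function(cell, family, chromosome) {
  if (is.null(cell) || is.na(cell)) return(NULL)
  code <- gsub("[[:space:]]", "", as.character(cell))
  if (!nzchar(code)) return(NULL)
  chars <- strsplit(code, "")[[1]]
  loc <- character(0); het <- logical(0)
  for (ch in chars) {
    if (ch %in% c("p", "i", "d")) {
      loc <- c(loc, ch); het <- c(het, FALSE)
    } else if (ch == "*") {
      if (!length(loc))
        stop("read_band_table: dangling '*' for family ", family,
             " chromosome ", chromosome)
      het[length(het)] <- TRUE
    } else {
      stop("read_band_table: invalid location character '", ch,
           "' for family ", family, " chromosome ", chromosome)
    }
  }
  list(loc = loc, het = het)
}

#' Read a cytogenetic band table
#'
#' One CSV row per TR family; one column per chromosome of the fixed
#' 9-element karyotype (autosomes 1--8 plus X) holding compact location
#' codes: \code{p} pericentromeric, \code{i} interstitial, \code{d} distal,
#' with \code{*} after a letter flagging a band seen on only one member of
#' the chromosome pair (heterozygous). \code{"iii"} is three interstitial
#' bands; \code{"p*i*d*"} (spaces allowed) is three heterozygous bands.
#' Blank cells mean no band. A \code{pattern} column carries the overall
#' FISH signal class (\code{B}, \code{DB}, \code{D}, \code{NS}).
#'
#' @param path CSV file with columns \code{family}, \code{pattern},
#'   \code{chr1}..\code{chr8}, \code{chrX} (an optional trailing
#'   \code{chrom} count column is ignored by the parser).
#' @param taxon Taxon label attached to every record.
#' @return \code{data.frame} of band records with columns \code{family},
#'   \code{taxon}, \code{chromosome}, \code{location},
#'   \code{heterozygous} (one row per band); the per-family FISH pattern
#'   table is attached as attribute \code{"patterns"} (columns
#'   \code{family}, \code{pattern}).
#' @export
read_band_table <- function(path, taxon) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  chr_cols <- paste0("chr", KARYOTYPE)
  missing_cols <- setdiff(c("family", "pattern", chr_cols), names(tab))
  if (length(missing_cols))
    stop("read_band_table: missing columns: ",
         paste(missing_cols, collapse = ", "))
  recs <- list()
  for (r in seq_len(nrow(tab))) {
    fam <- tab$family[r]
    for (k in seq_along(KARYOTYPE)) {
      parsed <- .parse_band_cell(tab[[chr_cols[k]]][r], fam, KARYOTYPE[k])
      if (is.null(parsed)) next
      recs[[length(recs) + 1L]] <- data.frame(
        family = fam, taxon = taxon, chromosome = KARYOTYPE[k],
        location = parsed$loc, heterozygous = parsed$het,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs)
         else data.frame(family = character(), taxon = character(),
                         chromosome = character(), location = character(),
                         heterozygous = logical(), stringsAsFactors = FALSE)
  attr(out, "patterns") <- data.frame(family = tab$family,
                                      pattern = tab$pattern,
                                      stringsAsFactors = FALSE)
  out
}

#' Write band records back to the compact CSV representation
#'
#' Inverse of \code{\link{read_band_table}}: locations of each (family,
#' chromosome) cell are re-compacted (heterozygous bands get a trailing
#' \code{*}). Reading the written file recovers the same records.
#'
#' @param bands Band records with a \code{"patterns"} attribute (or
#'   supply \code{patterns}).
#' @param path Output CSV.
#' @param patterns Per-family pattern table.
#' @return \code{path}, invisibly.
#' @export
write_band_table <- function(bands, path, patterns = attr(bands, "patterns")) {
  if (is.null(patterns)) stop("write_band_table: no pattern map")
  chr_cols <- paste0("chr", KARYOTYPE)
  out <- data.frame(family = patterns$family, pattern = patterns$pattern,
                    stringsAsFactors = FALSE)
  for (k in seq_along(KARYOTYPE)) {
    out[[chr_cols[k]]] <- vapply(patterns$family, function(f) {
      sel <- bands$family == f & bands$chromosome == KARYOTYPE[k]
      if (!any(sel)) return("")
      paste0(bands$location[sel],
             ifelse(bands$heterozygous[sel], "*", ""), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  out$chrom <- vapply(patterns$family, function(f)
    length(unique(bands$chromosome[bands$family == f])), integer(1),
    USE.NAMES = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype table for presence/absence band markers
#'
#' Autosomal markers are scored in males as \code{NN}/\code{NB}/\code{BB}
#' genotype counts; X-linked markers in X0 males are hemizygous, so only
#' allele counts \code{N}/\code{B} exist and heterozygote columns must be
#' empty.
#'
#' @param path CSV with columns \code{population}, \code{marker},
#'   \code{linkage} (\code{autosomal} or \code{x_linked}), \code{NN},
#'   \code{NB}, \code{BB}, \code{N}, \code{B}.
#' @return \code{data.frame} with those columns, counts as integers
#'   (\code{NA} where not applicable).
#' @export
read_genotype_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "marker", "linkage", "NN", "NB", "BB", "N", "B")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("read_genotype_table: missing columns: ",
         paste(missing_cols, collapse = ", "))
  for (cc in c("NN", "NB", "BB", "N", "B"))
    tab[[cc]] <- as.integer(tab[[cc]])
  bad_link <- !tab$linkage %in% c("autosomal", "x_linked")
  if (any(bad_link))
    stop("read_genotype_table: invalid linkage '",
         tab$linkage[bad_link][1], "'")
  xrows <- tab$linkage == "x_linked"
  if (any(xrows & (!is.na(tab$NN) | !is.na(tab$NB) | !is.na(tab$BB))))
    stop("read_genotype_table: x_linked rows must not carry genotype counts")
  neg <- function(v) any(!is.na(v) & v < 0L)
  if (neg(tab$NN) || neg(tab$NB) || neg(tab$BB) || neg(tab$N) || neg(tab$B))
    stop("read_genotype_table: negative counts")
  tab[need]
}

#' Read the transect site table
#'
#' @param path CSV with columns \code{population}, \code{site_name},
#'   \code{country}, \code{latitude}, \code{longitude}, \code{altitude_m},
#'   \code{n_males}, \code{order_index}.
#' @return \code{data.frame} sorted by \code{order_index}.
#' @export
read_transect_sites <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "country", "latitude", "longitude",
            "altitude_m", "order_index")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("read_transect_sites: missing columns: ",
         paste(missing_cols, collapse = ", "))
  tab <- tab[order(tab$order_index), , drop = FALSE]
  if (any(diff(tab$order_index) <= 0))
    stop("read_transect_sites: order_index must be strictly increasing")
  rownames(tab) <- NULL
  tab
}

#' Path to a bundled example data file
#'
#' The package ships plain-text transcriptions of the study's site,
#' band-pattern and genotype tables as example fixtures.
#'
#' @param file File name under \code{extdata}; with no argument, lists the
#'   available files.
#' @return Full path (or a character vector of file names).
#' @examples
#' satzone_example()
#' head(read_genotype_table(satzone_example("genotypes_transect.csv")))
#' @export
satzone_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "satzone")))
  path <- system.file("extdata", file, package = "satzone")
  if (!nzchar(path)) stop("no such example file: ", file)
  path
}
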