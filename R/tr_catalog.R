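## Classification of TR consensus monomers into nested subfamilies,
## families and superfamilies. Tandem monomers are circular objects: two
## consensuses may be identical up to an arbitrary rotation of the repeat
## phase and/or reverse complementation, so identity is defined as the
## best global-alignment identity over both strands and all rotations.

#' Concatenate a monomer into a dimer or longer multimer
#'
#' Tandem monomers are compared on concatemers so that alignments are not
#' dominated by end effects on short repeat units: the monomer is repeated
#' \code{k = max(2, ceiling(min_len / rul))} times, i.e. at least a dimer
#' and at least \code{min_len} bases.
#'
#' @param x A \code{\link{tr_consensus}} (or a plain DNA string).
#' @param min_len Minimum multimer length in bp (default 200).
#' @return DNA string of length \code{k * rul}.
#' @examples
#' nchar(dimerize(tr_consensus("a-7", "AACCTGG")))  # 29 * 7 = 203
#' @export
dimerize <- function(x, min_len = 200L) {
  seq <- if (inherits(x, "tr_consensus")) x$sequence else toupper(x)
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("dimerize: empty sequence")
  if (min_len < 1L) stop("dimerize: min_len must be >= 1")
  k <- max(2L, as.integer(ceiling(min_len / nchar(seq))))
  paste(rep(seq, k), collapse = "")
}

#' Rotate a monomer sequence
#'
#' Cyclic left rotation by \code{offset} positions: the monomer starting at
#' position \code{offset + 1}.
#'
#' @param seq DNA string.
#' @param offset Integer in \code{[0, nchar(seq))} (taken modulo length).
#' @return Rotated string.
#' @export
rotate_seq <- function(seq, offset) {
  n <- nchar(seq)
  offset <- ((as.integer(offset) %% n) + n) %% n
  if (offset == 0L) return(seq)
  paste0(substr(seq, offset + 1L, n), substr(seq, 1L, offset))
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over \code{A,C,G,T,N}.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", seq))))
}

#' Global-alignment identity of two DNA strings
#'
#' Needleman-Wunsch alignment (match +1, mismatch -1, gap -1, linear gaps)
#' with identity defined as \code{100 * matches / alignment_columns}; gap
#' columns count in the denominator, so length mismatch is penalized.
#' Among score-optimal alignments the one lexicographically maximizing
#' (score, matches, -columns) is reported, making the identity a
#' well-defined function of the sequences. No rotation or strand search is
#' performed here (see \code{\link{monomer_identity}} for the phase-aware
#' comparison).
#'
#' @param a,b DNA strings.
#' @return List with \code{score}, \code{matches}, \code{columns},
#'   \code{identity_pct}.
#' @export
nw_identity <- function(a, b) .nw_align(toupper(a), toupper(b))

#' Rotation- and strand-aware identity between two TR monomers
#'
#' Computes the best global-alignment identity between the multimerized
#' monomers (\code{\link{dimerize}}) over both strands of \code{b} and all
#' cyclic rotations of \code{b}. The rotation phase is found by aligning
#' the monomer of \code{a} against an extended concatemer of \code{b}
#' (pattern-global / subject-local alignment), the standard trick for
#' circular sequences; \code{b} is then rotated to that phase and a strict
#' global alignment of the two multimers yields the identity, with gap
#' columns counted in the denominator.
#'
#' For repeat units up to \code{exhaustive_limit} bp all rotations are
#' evaluated (batched in one alignment call per strand); above it, the
#' phase heuristic keeps the search linear.
#'
#' @param a,b \code{\link{tr_consensus}} objects (or DNA strings).
#' @param min_len Multimer length passed to \code{\link{dimerize}}.
#' @param exhaustive_limit Largest repeat-unit length of \code{b} for
#'   which every rotation is aligned (default 64).
#' @return List of class \code{identity_result} with \code{identity_pct},
#'   \code{strand} (\code{"forward"}/\code{"reverse"}) and
#'   \code{rotation_offset} (in \code{[0, rul_b)}).
#' @examples
#' a <- tr_consensus("a", "ACGTACGTTT")
#' monomer_identity(a, tr_consensus("b", rotate_seq(a$sequence, 3)))
#' @export
monomer_identity <- function(a, b, min_len = 200L, exhaustive_limit = 64L) {
  seq_a <- if (inherits(a, "tr_consensus")) a$sequence else toupper(a)
  seq_b <- if (inherits(b, "tr_consensus")) b$sequence else toupper(b)
  if (!nchar(seq_a) || !nchar(seq_b)) stop("monomer_identity: empty sequence")
  dim_a <- dimerize(seq_a, min_len)
  rul_b <- nchar(seq_b)
  best <- list(identity_pct = -Inf, strand = "forward", rotation_offset = 0L)
  for (strand in c("forward", "reverse")) {
    sb <- if (strand == "forward") seq_b else revcomp(seq_b)
    if (rul_b <= exhaustive_limit) {
      offsets <- 0:(rul_b - 1L)
    } else {
      ## phase heuristic: find where a's monomer best sits in an extended
      ## concatemer of b (one monomer beyond the dimer so every phase of a
      ## full window is available), plus the unrotated fallback
      ext <- paste0(dimerize(sb, min_len), sb)
      off <- (.nw_glocal_start(seq_a, ext) - 1L) %% rul_b
      offsets <- unique(c(off, 0L))
    }
    idn <- vapply(offsets, function(o)
      .nw_align(dim_a, dimerize(rotate_seq(sb, o), min_len))$identity_pct,
      numeric(1))
    k <- which.max(idn)
    if (idn[k] > best$identity_pct)
      best <- list(identity_pct = idn[k], strand = strand,
                   rotation_offset = as.integer(offsets[k]))
  }
  structure(best, class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("<identity_result> %.2f%%  strand=%s  rotation_offset=%d\n",
              x$identity_pct, x$strand, x$rotation_offset))
  invisible(x)
}

#' Detectable sequence homology between two monomers
#'
#' The superfamily rule: two consensuses are homologous when some local
#' alignment covers at least \code{min_coverage} of the shorter multimer
#' with at least \code{min_identity} percent identity, on either strand.
#'
#' @param a,b \code{\link{tr_consensus}} objects (or DNA strings).
#' @param min_identity Local identity threshold in percent (default 70).
#' @param min_coverage Minimum fraction of the shorter multimer covered by
#'   the local alignment (default 0.5).
#' @param min_len Multimer length passed to \code{\link{dimerize}}.
#' @return Logical.
#' @export
is_homologous <- function(a, b, min_identity = 70, min_coverage = 0.5,
                          min_len = 200L) {
  seq_a <- if (inherits(a, "tr_consensus")) a$sequence else toupper(a)
  seq_b <- if (inherits(b, "tr_consensus")) b$sequence else toupper(b)
  dim_a <- dimerize(seq_a, min_len)
  shorter <- min(nchar(dim_a), nchar(dimerize(seq_b, min_len)))
  for (strand in c("forward", "reverse")) {
    sb <- if (strand == "forward") seq_b else revcomp(seq_b)
    loc <- .nw_local(dim_a, dimerize(sb, min_len))
    if (loc$columns >= min_coverage * shorter &&
        loc$identity_pct >= min_identity)
      return(TRUE)
  }
  FALSE
}

# connected components by single linkage over an edge list (i, j);
# returns integer component labels (arbitrary), length n
.components <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(edges_i)) {
    ri <- find(edges_i[e]); rj <- find(edges_j[e])
    if (ri != rj) parent[rj] <- ri
  }
  vapply(seq_len(n), find, integer(1))
}

# relabel component ids densely from 1 in a given member priority order
.dense_ids <- function(labels, priority) {
  first <- vapply(split(priority, labels), min, numeric(1))
  rank_map <- rank(first, ties.method = "first")
  as.integer(rank_map[as.character(labels)])
}

#' Classify TR consensuses into subfamilies, families and superfamilies
#'
#' Single-linkage clustering on the pairwise \code{\link{monomer_identity}}
#' graph: edges at or above the subfamily threshold (default 95\%) define
#' subfamilies (variants); edges at or above the family threshold (default
#' 80\%) define families; pairs below the family threshold but passing the
#' \code{\link{is_homologous}} local-alignment rule join the same
#' superfamily. The three partitions are nested by construction.
#'
#' Group ids are dense from 1 and ordered by decreasing total abundance
#' when \code{abundance} is supplied, else by input order of the first
#' member.
#'
#' @param members List of \code{\link{tr_consensus}}.
#' @param thresholds Named list with elements \code{subfamily} and
#'   \code{family}, identity percentages in \code{(0, 100]} with
#'   \code{subfamily >= family}.
#' @param abundance Optional named numeric vector (bp per member name)
#'   used to order group ids.
#' @param min_len Multimer length passed to \code{\link{dimerize}}.
#' @return Object of class \code{tr_catalog}: list with \code{members},
#'   \code{assignments} (data.frame \code{name}, \code{subfamily},
#'   \code{family}, \code{superfamily}) and the pairwise \code{identity}
#'   matrix.
#' @export
build_catalog <- function(members,
                          thresholds = list(subfamily = 95, family = 80),
                          abundance = NULL, min_len = 200L) {
  if (!length(members)) stop("build_catalog: no members")
  th_sub <- thresholds$subfamily; th_fam <- thresholds$family
  if (is.null(th_sub) || is.null(th_fam) ||
      th_sub <= 0 || th_sub > 100 || th_fam <= 0 || th_fam > 100 ||
      th_sub < th_fam)
    stop("build_catalog: thresholds must lie in (0, 100] with subfamily >= family")
  n <- length(members)
  nms <- vapply(members, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("build_catalog: duplicated member names")
  idn <- matrix(100, n, n, dimnames = list(nms, nms))
  hom <- matrix(TRUE, n, n)
  if (n > 1) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    idn[i, j] <- idn[j, i] <- monomer_identity(members[[i]], members[[j]],
                                               min_len = min_len)$identity_pct
    hom[i, j] <- hom[j, i] <-
      if (idn[i, j] >= th_fam) TRUE
      else is_homologous(members[[i]], members[[j]], min_len = min_len)
  }
  pair_idx <- which(upper.tri(idn), arr.ind = TRUE)
  edge_set <- function(keep) {
    k <- keep[upper.tri(idn)]
    list(i = pair_idx[k, 1], j = pair_idx[k, 2])
  }
  sub_e <- edge_set(idn >= th_sub)
  fam_e <- edge_set(idn >= th_fam)
  sup_e <- edge_set(idn >= th_fam | hom)
  sub_lab <- .components(n, sub_e$i, sub_e$j)
  fam_lab <- .components(n, fam_e$i, fam_e$j)
  sup_lab <- .components(n, sup_e$i, sup_e$j)
  priority <- if (is.null(abundance)) seq_len(n)
              else -as.numeric(abundance[nms])
  assignments <- data.frame(
    name = nms,
    subfamily = .dense_ids(sub_lab, priority),
    family = .dense_ids(fam_lab, priority),
    superfamily = .dense_ids(sup_lab, priority),
    stringsAsFactors = FALSE)
  structure(list(members = members, assignments = assignments,
                 identity = idn, thresholds = thresholds),
            class = "tr_catalog")
}

#' @export
print.tr_catalog <- function(x, ...) {
  a <- x$assignments
  cat(sprintf(paste0("<tr_catalog> %d members: %d subfamilies, ",
                     "%d families, %d superfamilies\n"),
              nrow(a), max(a$subfamily), max(a$family), max(a$superfamily)))
  invisible(x)
}

#' Medoid consensus of each subfamily
#'
#' For each subfamily the member maximizing mean identity to the other
#' members of the subfamily (ties to the first member in input order), the
#' reproducible replacement for manual consensus picking.
#'
#' @param catalog A \code{tr_catalog}.
#' @return Character vector of member names, one per subfamily id.
#' @export
subfamily_consensus <- function(catalog) {
  a <- catalog$assignments
  idn <- catalog$identity
  vapply(sort(unique(a$subfamily)), function(g) {
    idx <- which(a$subfamily == g)
    if (length(idx) == 1L) return(a$name[idx])
    mean_id <- vapply(idx, function(i) mean(idn[i, setdiff(idx, i)]),
                      numeric(1))
    a$name[idx[which.max(mean_id)]]
  }, character(1))
}

#' Write catalog assignments as TSV
#'
#' Columns \code{name}, \code{subfamily}, \code{family},
#' \code{superfamily}.
#'
#' @param catalog A \code{tr_catalog}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(catalog$assignments, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
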