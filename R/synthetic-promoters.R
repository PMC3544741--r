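#' Generate promoter sequences with planted motif sites
#'
#' Produces `n` random promoter-like sequences of which exactly
#' `round(site_fraction * n)` carry at least one planted
#' exact-consensus motif site (degenerate consensus positions pick an
#' allowed base at random).  The remaining records are rejection
#' sampled against [scan_sequence()] itself until they contain no
#' window, on either strand, scoring at or above `threshold` — so the
#' planted site frequency is exact by construction rather than assumed.
#'
#' Records are named `P0001, P0002, ...` and can be used directly as
#' gene ids.  Background composition is uniform over A/C/G/T.
#'
#' @param n number of promoter records.
#' @param length sequence length in bases; defaults to 2,500, the span
#'   of a -1500..+1000 window around a transcription start site.  Must
#'   be at least the matrix width.
#' @param matrix motif matrix to plant and to reject against
#'   (default [build_ere_matrix()]).
#' @param site_fraction proportion of records that must contain a
#'   site.
#' @param threshold similarity threshold defining "contains a site".
#' @param seed integer RNG seed.
#' @param max_tries rejection-sampling cap per negative record.
#' @return named character vector of sequences with a logical
#'   attribute `"has_site"` marking the planted positives.
#' @export
generate_promoters <- function(n, length = 2500,
                               matrix = build_ere_matrix(),
                               site_fraction = 0.627,
                               threshold = 0.80, seed = 1L,
                               max_tries = 1000L) {
  stopifnot(inherits(matrix, "motif_matrix"))
  if (length < matrix$width)
    stop("'length' must be at least the matrix width (", matrix$width, ")")
  if (site_fraction < 0 || site_fraction > 1)
    stop("'site_fraction' must lie in [0, 1]")
  bases <- c("A", "C", "G", "T")
  set.seed(seed)
  n_pos <- round(site_fraction * n)
  is_pos <- logical(n)
  is_pos[sample.int(n, n_pos)] <- TRUE
  rand_seq <- function(L) paste(sample(bases, L, replace = TRUE), collapse = "")
  consensus_instance <- function() {
    paste(apply(matrix$freq, 1L, function(f) {
      top <- names(f)[f == max(f)]
      if (length(top) == 1L) top else sample(top, 1L)
    }), collapse = "")
  }
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (is_pos[i]) {
      s <- rand_seq(length)
      site <- consensus_instance()
      pos <- sample.int(length - matrix$width + 1L, 1L)
      substr(s, pos, pos + matrix$width - 1L) <- site
      seqs[i] <- s
    } else {
      for (try in seq_len(max_tries)) {
        s <- rand_seq(length)
        hits <- scan_sequence(s, matrix, threshold, both_strands = TRUE)
        if (nrow(hits) == 0L) break
        s <- NA_character_
      }
      if (is.na(s))
        stop("could not rejection-sample a motif-free sequence in ",
             max_tries, " tries; lower 'length' or raise 'threshold'")
      seqs[i] <- s
    }
  }
  names(seqs) <- sprintf("P%04d", seq_len(n))
  attr(seqs, "has_site") <- stats::setNames(is_pos, names(seqs))
  seqs
}

#' Write promoters as FASTA
#'
#' @param seqs named character vector, e.g. from
#'   [generate_promoters()].
#' @param path output FASTA path.
#' @export
write_promoters_fasta <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
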