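#' Build a position frequency matrix from an IUPAC consensus
#'
#' Constructs an open position matrix for a motif from its printed
#' consensus.  Every base outside the position's allowed set gets the
#' pseudo-frequency `(1 - consensus_weight) / 3`; the allowed bases
#' split the remaining mass evenly (so a unique consensus base gets
#' `consensus_weight`, and e.g. a two-base degenerate position gives
#' each allele 0.45 at the default).  Per-position conservation
#' weights are the
#' information content in bits,
#' `w_i = 2 + sum_b f(i,b) * log2 f(i,b)` (with `0 * log 0 = 0`), so
#' conserved positions dominate the similarity score.
#'
#' The default consensus `GCGKGGGCG` (IUPAC K = G or T) is the EGR
#' response element, the GC-rich element bound by the EGR zinc-finger
#' transcription factors.
#'
#' @param consensus IUPAC consensus string.
#' @param consensus_weight total frequency mass on the allowed bases
#'   at each position, in (1/4, 1].
#' @param name matrix identifier.
#' @return object of class `"motif_matrix"`: list with `width`,
#'   `freq` (width x 4 matrix, columns A, C, G, T), `weights` (bits)
#'   and `name`.
#' @examples
#' m <- build_ere_matrix()
#' m$freq[4, ]          # the K position splits G and T
#' round(m$weights, 3)
#' @export
build_ere_matrix <- function(consensus = "GCGKGGGCG",
                             consensus_weight = 0.85,
                             name = "ERE") {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  bases <- c("A", "C", "G", "T")
  letters_cons <- strsplit(toupper(consensus), "")[[1]]
  if (!all(letters_cons %in% names(iupac)))
    stop("invalid IUPAC code(s): ",
         paste(setdiff(letters_cons, names(iupac)), collapse = ", "))
  w <- length(letters_cons)
  freq <- matrix(0, w, 4, dimnames = list(NULL, bases))
  mismatch <- (1 - consensus_weight) / 3
  for (i in seq_len(w)) {
    allowed <- iupac[[letters_cons[i]]]
    n_dis <- 4 - length(allowed)
    f <- rep(mismatch, 4)
    names(f) <- bases
    f[allowed] <- (1 - n_dis * mismatch) / length(allowed)
    freq[i, ] <- f
  }
  info <- apply(freq, 1L, function(f) {
    nz <- f[f > 0]
    2 + sum(nz * log2(nz))
  })
  structure(list(width = w, freq = freq, weights = info,
                 name = name, consensus = paste(letters_cons, collapse = "")),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("Motif matrix '", x$name, "' (width ", x$width,
      ", consensus ", x$consensus, ")\n", sep = "")
  tab <- cbind(round(x$freq, 3), bits = round(x$weights, 3))
  rownames(tab) <- seq_len(x$width)
  print(tab)
  invisible(x)
}

#' Conservation-weighted matrix similarity of one window
#'
#' Scores a sequence window against a motif matrix with the
#' matrix-similarity statistic
#' \deqn{\mathrm{sim} = \frac{\sum_i w_i f(i, b_i)}
#'                           {\sum_i w_i \max_b f(i, b)},}
#' where \eqn{w_i} is the information content of position *i*.  The
#' score lies in [0, 1] and equals 1 exactly when every base attains
#' its position's maximum frequency; conserved positions carry the
#' most weight, so mismatches there are penalised hardest.  Ambiguous
#' bases (anything outside A/C/G/T) contribute frequency 0.
#'
#' @param window character string of the matrix's width.
#' @param matrix a [build_ere_matrix()] object.
#' @return similarity score in [0, 1].
#' @examples
#' m <- build_ere_matrix()
#' matrix_similarity("GCGGGGGCG", m)  # consensus: 1
#' matrix_similarity("GCGTGGGCG", m)  # both K alleles score 1
#' @export
matrix_similarity <- function(window, matrix) {
  stopifnot(inherits(matrix, "motif_matrix"))
  b <- strsplit(toupper(window), "")[[1]]
  if (length(b) != matrix$width)
    stop("window length must equal the matrix width")
  idx <- match(b, colnames(matrix$freq))
  f <- numeric(matrix$width)
  known <- !is.na(idx)
  f[known] <- matrix$freq[cbind(which(known), idx[known])]
  denom <- sum(matrix$weights * apply(matrix$freq, 1L, max))
  sum(matrix$weights * f) / denom
}

# vectorized similarity of all windows of a sequence given as an
# integer vector (1=A 2=C 3=G 4=T, NA for ambiguity); returns numeric
# vector of length length(s) - width + 1
.scan_scores <- function(s_int, matrix) {
  w <- matrix$width
  n_win <- length(s_int) - w + 1L
  if (n_win < 1L) return(numeric(0))
  num <- numeric(n_win)
  wts <- matrix$weights
  for (i in seq_len(w)) {
    idx <- s_int[i:(i + n_win - 1L)]
    fi <- matrix$freq[i, ]
    contrib <- fi[idx] * wts[i]
    contrib[is.na(contrib)] <- 0
    num <- num + contrib
  }
  denom <- sum(wts * apply(matrix$freq, 1L, max))
  num / denom
}

.seq_to_int <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
}

.revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Scan a sequence for motif matches
#'
#' Slides the matrix over every window of the forward strand and, if
#' `both_strands`, of the reverse complement, reporting windows whose
#' matrix similarity reaches `threshold`.  Match coordinates are
#' 0-based, half-open on the input sequence's forward strand
#' regardless of the matched strand.
#'
#' @param seq character string of A/C/G/T (ambiguity codes score 0 at
#'   their positions).
#' @param matrix a [build_ere_matrix()] object.
#' @param threshold minimum matrix similarity to report (default
#'   0.80, the published site-calling cutoff).
#' @param both_strands scan the reverse complement too.
#' @param sequence_id id used in the output table.
#' @return data.frame with columns `sequence_id`, `start`, `end`,
#'   `strand`, `similarity`, `matched_window`, ordered by `start`.
#' @export
scan_sequence <- function(seq, matrix, threshold = 0.80,
                          both_strands = TRUE, sequence_id = "seq") {
  stopifnot(inherits(matrix, "motif_matrix"))
  w <- matrix$width
  L <- nchar(seq)
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      similarity = numeric(), matched_window = character(),
                      stringsAsFactors = FALSE)
  if (L < w) {
    warning("sequence '", sequence_id, "' shorter than the matrix width")
    return(empty)
  }
  res <- list()
  s_int <- .seq_to_int(seq)
  sc <- .scan_scores(s_int, matrix)
  hit <- which(sc >= threshold)
  if (length(hit))
    res$fwd <- data.frame(
      sequence_id = sequence_id, start = hit - 1L, end = hit - 1L + w,
      strand = "+", similarity = sc[hit],
      matched_window = substring(seq, hit, hit + w - 1L),
      stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- .revcomp(seq)
    sc_rc <- .scan_scores(.seq_to_int(rc), matrix)
    hit_rc <- which(sc_rc >= threshold)
    if (length(hit_rc)) {
      # offset j (1-based) on the reverse complement covers forward
      # positions [L - j - w + 2, L - j + 1]
      fwd_start <- L - hit_rc - w + 1L
      res$rev <- data.frame(
        sequence_id = sequence_id, start = fwd_start, end = fwd_start + w,
        strand = "-", similarity = sc_rc[hit_rc],
        matched_window = substring(rc, hit_rc, hit_rc + w - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of promoter records containing a motif site
#'
#' Scans every record of a promoter FASTA (or named character vector)
#' and reports the fraction with at least one window at or above the
#' similarity threshold, plus a per-record match count table.
#'
#' @param fasta path to a FASTA file, a `Biostrings::DNAStringSet`, or
#'   a named character vector of sequences.
#' @inheritParams scan_sequence
#' @return list with `fraction` (proportion of records with >= 1
#'   site) and `per_gene` (data.frame `sequence_id`, `n_sites`,
#'   `has_site`).
#' @export
fraction_with_site <- function(fasta, matrix, threshold = 0.80,
                               both_strands = TRUE) {
  seqs <- read_promoters(fasta)
  if (!length(seqs)) stop("no sequences to scan")
  n_sites <- vapply(seq_along(seqs), function(i)
    nrow(scan_sequence(seqs[[i]], matrix, threshold, both_strands,
                       sequence_id = names(seqs)[i])), 0L)
  per_gene <- data.frame(sequence_id = names(seqs),
                         n_sites = n_sites,
                         has_site = n_sites > 0L,
                         stringsAsFactors = FALSE)
  list(fraction = mean(per_gene$has_site), per_gene = per_gene)
}

#' Read promoter sequences
#'
#' Accepts a FASTA path (read via Biostrings), a `DNAStringSet`, or a
#' named character vector, and returns a named list of plain
#' character sequences.
#'
#' @param fasta input as in [fraction_with_site()].
#' @return named list of character sequences.
#' @export
read_promoters <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    fasta <- Biostrings::readDNAStringSet(fasta)
  if (methods::is(fasta, "XStringSet"))
    fasta <- stats::setNames(as.character(fasta), names(fasta))
  if (is.null(names(fasta)))
    names(fasta) <- sprintf("seq%04d", seq_along(fasta))
  as.list(fasta)
}

#' Serialize a motif matrix to JSON
#'
#' @param matrix a [build_ere_matrix()] object.
#' @param path output file.
#' @export
write_motif_matrix <- function(matrix, path) {
  jsonlite::write_json(
    list(name = matrix$name, consensus = matrix$consensus,
         width = matrix$width,
         freq = as.data.frame(matrix$freq),
         weights = matrix$weights),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write motif matches as a BED-like table
#'
#' Tab-delimited `sequence_id`, `start`, `end`, `name`, `score`
#' (similarity scaled to 0-1000), `strand`.
#'
#' @param matches data.frame from [scan_sequence()].
#' @param matrix the matrix scanned with (names the matches).
#' @param path output file.
#' @export
write_matches_bed <- function(matches, matrix, path) {
  bed <- data.frame(matches$sequence_id, matches$start, matches$end,
                    matrix$name, round(matches$similarity * 1000),
                    matches$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
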