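#' Clustering parameters with CD-HIT-compatible semantics
#'
#' `c` is the identity threshold (fraction of identical positions required
#' for a sequence to join a cluster) and `s` the length-difference cutoff
#' (minimum allowed shorter/longer length ratio). Both are normalised to
#' exactly two decimal places on ingest, once, so that a user's `0.9` and
#' `0.90` are the same run and single- versus two-decimal precision can never
#' alter results downstream.
#'
#' @param c identity threshold fraction in `[0, 1]`.
#' @param s length-difference cutoff fraction in `[0, 1]`.
#' @param mode `"dna"` or `"aa"`. In DNA mode both strands are tried and the
#'   member strand is recorded, as with `cd-hit-est`.
#' @param word_size k-mer size for the shared-word prefilter (`NULL`
#'   disables it; it is a pure optimisation, see [greedy_cluster()]).
#' @return a `clustering_params` list with fields `c`, `s` (two-decimal),
#'   `c100`, `s100` (integer hundredths, used for exact threshold tests),
#'   `mode` and `word_size`.
#' @export
clustering_params <- function(c = 0.90, s = 0.80, mode = c("dna", "aa"),
                              word_size = 8L) {
  mode <- match.arg(mode)
  if (c < 0 || c > 1 || s < 0 || s > 1) stop("c and s must lie in [0, 1]")
  c <- round(c, 2)
  s <- round(s, 2)
  if (!is.null(word_size)) {
    word_size <- as.integer(word_size)
    if (word_size < 2L) stop("word_size must be >= 2")
  }
  structure(list(c = c, s = s,
                 c100 = as.integer(round(100 * c)),
                 s100 = as.integer(round(100 * s)),
                 mode = mode, word_size = word_size),
            class = "clustering_params")
}

# +1/-1 substitution matrix over the letters present in the sequences.
identity_submat <- function(letters) {
  letters <- unique(letters)
  mat <- matrix(-1, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(mat) <- 1
  mat
}

#' Best local-alignment identity between two sequences
#'
#' Smith-Waterman local alignment with match +1, mismatch -1, gap opening -2
#' and gap extension -1 (a gap of length L costs 2 + L). The scoring
#' constants are this package's own, centralised here; threshold semantics,
#' not any external tool's internal scores, are what the clusterer depends
#' on.
#'
#' Three identity denominators are available:
#' \describe{
#'   \item{`shorter`}{matches divided by the full length of the shorter
#'     sequence (CD-HIT's default global-identity semantics; the default
#'     here and what [greedy_cluster()] uses).}
#'   \item{`overlap`}{matches divided by the aligned span of the shorter
#'     sequence only - the local-overlap reading under which a shared domain
#'     scores near 100% regardless of what the rest of the sequences do.}
#'   \item{`alignment`}{matches divided by the full alignment length
#'     including gap columns (strict mode, under which gaps do count as
#'     differences).}
#' }
#'
#' @param a,b non-empty sequences over the same alphabet.
#' @param denominator identity denominator, see above.
#' @return list with `identity_pct` (percent, full precision), `overlap_len`
#'   (aligned span of the shorter sequence), `matches`, `score` and
#'   `alignment_len` (columns including gaps).
#' @export
pairwise_identity <- function(a, b,
                              denominator = c("shorter", "overlap",
                                              "alignment")) {
  denominator <- match.arg(denominator)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  letters <- unique(strsplit(paste0(a, b), "")[[1]])
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = identity_submat(letters),
    gapOpening = 2, gapExtension = 1)
  matches <- Biostrings::nmatch(aln)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sbj <- as.character(Biostrings::alignedSubject(aln))
  alignment_len <- nchar(pat)
  shorter_is_a <- nchar(a) <= nchar(b)
  aligned_str <- if (shorter_is_a) pat else sbj
  span <- nchar(gsub("-", "", aligned_str, fixed = TRUE))
  denom <- switch(denominator,
                  shorter = min(nchar(a), nchar(b)),
                  overlap = span,
                  alignment = alignment_len)
  identity_pct <- if (denom == 0L || matches == 0L) 0 else 100 * matches / denom
  list(identity_pct = identity_pct, overlap_len = span, matches = matches,
       score = Biostrings::score(aln), alignment_len = alignment_len)
}

# match count of the best local alignment only - the hot path inside
# greedy_cluster, which does its own exact-integer threshold test
local_match_count <- function(a, b, mat) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln)
}

# distinct-position k-mers of a sequence
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Minimum shared k-mer occurrences implied by identity >= c over the shorter
# length m: exact for ungapped alignments (each of the <= (1-c)m mismatched
# positions destroys at most k k-mers), a heuristic lower bound once gaps are
# involved. Non-positive => the filter cannot be applied safely.
kmer_bound <- function(m, k, c100) {
  (m - k + 1L) - k * ceiling(m * (100L - c100) / 100)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Greedy incremental sequence clustering
#'
#' A transparent re-statement of greedy incremental clustering: sequences are
#' processed longest-first (ties broken lexicographically by ID); each joins
#' the first existing cluster representative that passes both the
#' length-difference cutoff (`length/rep_length >= s`) and the identity
#' threshold (`matches/length >= c`, exact integer comparison), else founds a
#' new cluster. In DNA mode the reverse complement is also tried and the
#' joining strand recorded.
#'
#' The result is a single-threaded, resource-independent function of its
#' inputs: identical sequences and parameters give byte-identical `.clstr`
#' output on every run. A shared-k-mer count prefilter (`word_size`) skips
#' comparisons that cannot reach the identity threshold; it is a pure
#' optimisation and can be disabled with `word_size = NULL`.
#'
#' @param seqs named character vector of sequences (unique IDs).
#' @param params a [clustering_params()].
#' @return a [cluster_set()] with per-member identities (two decimals, as
#'   printed in `.clstr` files) and, in DNA mode, strands.
#' @export
greedy_cluster <- function(seqs, params = clustering_params()) {
  if (length(seqs) == 0L) {
    return(cluster_set(data.frame(
      cluster = integer(0), seq_id = character(0), length = integer(0),
      identity_pct = numeric(0), strand = character(0), is_rep = logical(0)),
      unit = if (params$mode == "dna") "nt" else "aa"))
  }
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("seqs must carry unique non-empty names")
  }
  lens <- nchar(seqs)
  ord <- order(-lens, ids, method = "radix")
  ids <- ids[ord]; seqs <- seqs[ord]; lens <- lens[ord]

  k <- params$word_size
  use_filter <- !is.null(k)
  dna <- params$mode == "dna"
  submat <- identity_submat(unique(unlist(strsplit(unname(seqs), ""))))

  rep_id <- character(0); rep_seq <- character(0); rep_len <- integer(0)
  rep_kmers <- list()
  assign_cluster <- integer(length(ids))
  assign_pid <- rep(NA_real_, length(ids))
  assign_strand <- rep(NA_character_, length(ids))
  is_rep <- logical(length(ids))

  for (i in seq_along(ids)) {
    m <- lens[[i]]
    fwd_kmers <- if (use_filter) seq_kmers(seqs[[i]], k) else NULL
    rev_seq <- NULL; rev_kmers <- NULL
    bound <- if (use_filter) kmer_bound(m, k, params$c100) else 0L
    joined <- FALSE
    if (length(rep_id) > 0L) {
      # length-difference cutoff: member is never longer than the rep
      candidates <- which(100L * m >= params$s100 * rep_len)
      for (j in candidates) {
        strand <- "+"
        matches <- NA_integer_
        pass_fwd <- TRUE
        if (use_filter && bound >= 1L) {
          pass_fwd <- sum(fwd_kmers %in% rep_kmers[[j]]) >= bound
        }
        if (pass_fwd) {
          fwd_matches <- local_match_count(seqs[[i]], rep_seq[[j]], submat)
          if (100L * fwd_matches >= params$c100 * m) matches <- fwd_matches
        }
        if (is.na(matches) && dna) {
          if (is.null(rev_seq)) {
            rev_seq <- revcomp_chr(seqs[[i]])
            if (use_filter) rev_kmers <- seq_kmers(rev_seq, k)
          }
          pass_rev <- TRUE
          if (use_filter && bound >= 1L) {
            pass_rev <- sum(rev_kmers %in% rep_kmers[[j]]) >= bound
          }
          if (pass_rev) {
            rev_matches <- local_match_count(rev_seq, rep_seq[[j]], submat)
            if (100L * rev_matches >= params$c100 * m) {
              matches <- rev_matches
              strand <- "-"
            }
          }
        }
        if (!is.na(matches)) {
          assign_cluster[[i]] <- j - 1L
          assign_pid[[i]] <- round(100 * matches / m, 2)
          assign_strand[[i]] <- if (dna) strand else NA_character_
          joined <- TRUE
          break
        }
      }
    }
    if (!joined) {
      rep_id <- c(rep_id, ids[[i]])
      rep_seq <- c(rep_seq, seqs[[i]])
      rep_len <- c(rep_len, m)
      if (use_filter) rep_kmers[[length(rep_id)]] <- unique(fwd_kmers)
      assign_cluster[[i]] <- length(rep_id) - 1L
      is_rep[[i]] <- TRUE
    }
  }

  members <- data.frame(cluster = assign_cluster, seq_id = ids,
                        length = lens, identity_pct = assign_pid,
                        strand = assign_strand, is_rep = is_rep,
                        stringsAsFactors = FALSE)
  members <- members[order(members$cluster,
                           !members$is_rep,
                           seq_len(nrow(members)), method = "radix"), ]
  rownames(members) <- NULL
  cluster_set(members, unit = if (dna) "nt" else "aa")
}
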