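# Independent oracles used by the property and acceptance tests. These are
# deliberately naive re-derivations (union-find, exhaustive enumeration,
# textbook DP) kept separate from the package's own code paths.

# --- connected components via union-find -------------------------------------

uf_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (length(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges[r, 1L]); rb <- find(edges[r, 2L])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, character(1))
  unname(split(nodes, roots))
}

# canonical form of a partition: sorted members, components sorted by head
canonical_partition <- function(groups) {
  groups <- unname(lapply(groups, sort, method = "radix"))
  groups[order(vapply(groups, `[`, character(1), 1L), method = "radix")]
}

# --- pairwise co-clustering disagreement by exhaustive enumeration -----------

brute_pair_disagreement <- function(assign_a, assign_b) {
  ids <- names(assign_a)
  n <- length(ids)
  count <- 0L
  if (n < 2L) return(0L)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      co_a <- assign_a[[ids[[i]]]] == assign_a[[ids[[j]]]]
      co_b <- assign_b[[ids[[i]]]] == assign_b[[ids[[j]]]]
      if (xor(co_a, co_b)) count <- count + 1L
    }
  }
  count
}

# --- Smith-Waterman local alignment oracle -----------------------------------
# Affine gaps: a gap of length L costs open + ext*L (first gap position costs
# open+ext). Returns the optimal local score and the attainable range of
# match counts over all optimal-scoring local alignments.

sw_local_oracle <- function(a, b, match = 1, mismatch = -1,
                            open = 2, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L) # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1L, m + 1L) # gap in a (consumes b)
  mmx <- matrix(0L, n + 1L, m + 1L); mnx <- matrix(0L, n + 1L, m + 1L)
  mmM <- matrix(0L, n + 1L, m + 1L); mnM <- matrix(0L, n + 1L, m + 1L)
  mmy <- matrix(0L, n + 1L, m + 1L); mny <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (av[[i - 1L]] == bv[[j - 1L]]) match else mismatch
      is_match <- av[[i - 1L]] == bv[[j - 1L]]
      # M: end on an aligned pair; may start fresh (score 0, 0 matches)
      cand <- c(0, M[i - 1L, j - 1L], Ix[i - 1L, j - 1L], Iy[i - 1L, j - 1L])
      cmm <- c(0L, mmM[i - 1L, j - 1L], mmx[i - 1L, j - 1L],
               mmy[i - 1L, j - 1L])
      cmn <- c(0L, mnM[i - 1L, j - 1L], mnx[i - 1L, j - 1L],
               mny[i - 1L, j - 1L])
      best <- max(cand)
      M[i, j] <- best + s
      mmM[i, j] <- max(cmm[cand == best]) + as.integer(is_match)
      mnM[i, j] <- min(cmn[cand == best]) + as.integer(is_match)
      # Ix: gap in b
      cand <- c(M[i - 1L, j] - open - ext, Ix[i - 1L, j] - ext,
                Iy[i - 1L, j] - open - ext)
      cmm <- c(mmM[i - 1L, j], mmx[i - 1L, j], mmy[i - 1L, j])
      cmn <- c(mnM[i - 1L, j], mnx[i - 1L, j], mny[i - 1L, j])
      best <- max(cand)
      Ix[i, j] <- best
      if (best > NEG / 2) {
        mmx[i, j] <- max(cmm[cand == best])
        mnx[i, j] <- min(cmn[cand == best])
      }
      # Iy: gap in a
      cand <- c(M[i, j - 1L] - open - ext, Iy[i, j - 1L] - ext,
                Ix[i, j - 1L] - open - ext)
      cmm <- c(mmM[i, j - 1L], mmy[i, j - 1L], mmx[i, j - 1L])
      cmn <- c(mnM[i, j - 1L], mny[i, j - 1L], mnx[i, j - 1L])
      best <- max(cand)
      Iy[i, j] <- best
      if (best > NEG / 2) {
        mmy[i, j] <- max(cmm[cand == best])
        mny[i, j] <- min(cmn[cand == best])
      }
    }
  }
  score <- max(0, M)
  if (score == 0) {
    return(list(score = 0, max_matches = 0L, min_matches = 0L))
  }
  at <- which(M == score)
  list(score = score,
       max_matches = max(mmM[at]),
       min_matches = min(mnM[at]))
}

# --- random sequences / trees / cluster sets ---------------------------------

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a fuzzed cluster_set with plausible lengths/identities/strands
random_cluster_set <- function(n_clusters, max_size = 5L, unit = "nt",
                               id_prefix = "g") {
  rows <- list()
  counter <- 0L
  for (cl in seq_len(n_clusters) - 1L) {
    size <- sample.int(max_size, 1L)
    rep_at <- sample.int(size, 1L)
    for (k in seq_len(size)) {
      counter <- counter + 1L
      is_rep <- k == rep_at
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl,
        seq_id = sprintf("%s%04d|gene_%04d", id_prefix,
                         sample.int(50L, 1L), counter),
        length = sample(60:900, 1L),
        identity_pct = if (is_rep) NA_real_ else
          round(stats::runif(1, 80, 100), 2),
        strand = if (is_rep) NA_character_ else
          if (unit == "nt") sample(c("+", "-"), 1L) else NA_character_,
        is_rep = is_rep, stringsAsFactors = FALSE)
    }
  }
  cluster_set(do.call(rbind, rows), unit = unit)
}
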