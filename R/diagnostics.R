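#' Per-cluster summary table
#'
#' One row per cluster with sequence and genome counts, length statistics
#' and mean member identity, sorted by descending cluster size. The
#' representative carries no printed identity in `.clstr` files; by default
#' it is counted as 100.00 in the mean (set `include_rep_identity = FALSE`
#' to average over non-representative members only).
#'
#' @param cs a [cluster_set()]; member lengths must be present.
#' @param separator genome tag separator used to count genomes per cluster.
#' @param include_rep_identity count the representative as 100.00 in
#'   `avg_ident` (default) or exclude it.
#' @param path optional TSV output path.
#' @return data.frame with columns `cluster_id`, `n_seqs`, `n_genomes`,
#'   `avg_len`, `len_min`, `len_max`, `avg_ident` (means rounded to two
#'   decimals), sorted by descending `n_seqs` then `cluster_id`.
#' @export
group_summary <- function(cs, separator = "|", include_rep_identity = TRUE,
                          path = NULL) {
  validate_cluster_set(cs)
  m <- cs$members
  if (nrow(m) > 0L && anyNA(m$length)) {
    stop("group_summary requires member lengths")
  }
  genome <- split_tagged_ids(m$seq_id, separator)$genome_id
  rows <- lapply(unique(m$cluster), function(cl) {
    idx <- m$cluster == cl
    ident <- m$identity_pct[idx]
    if (include_rep_identity) {
      ident[m$is_rep[idx]] <- 100
    } else {
      ident <- ident[!m$is_rep[idx]]
    }
    data.frame(cluster_id = cl,
               n_seqs = sum(idx),
               n_genomes = length(unique(genome[idx])),
               avg_len = round(mean(m$length[idx]), 2),
               len_min = min(m$length[idx]),
               len_max = max(m$length[idx]),
               avg_ident = if (length(ident) == 0L) NA_real_ else
                 round(mean(ident), 2))
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), n_seqs = integer(0),
               n_genomes = integer(0), avg_len = numeric(0),
               len_min = integer(0), len_max = integer(0),
               avg_ident = numeric(0))
  out <- out[order(-out$n_seqs, out$cluster_id), ]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

# one finder hit
finder_hit <- function(file, kind, location, role, matched_id, exact) {
  data.frame(file = file, kind = kind, location = location, role = role,
             matched_id = matched_id, exact = exact,
             stringsAsFactors = FALSE)
}

#' Find a sequence ID across pipeline outputs
#'
#' Cross-references a gene ID in any mix of `.clstr` files, presence-absence
#' CSVs and FASTA files, reporting every occurrence with its role. `.clstr`
#' files store IDs as printed by the producer, possibly truncated; a stored
#' ID that is a strict prefix of the query therefore also matches, and is
#' flagged as inexact. A truncated query matching several stored IDs is
#' reported for all of them with an ambiguity warning.
#'
#' @param query_id the gene ID (tagged or not) to look up.
#' @param artifacts character vector of file paths (`.clstr`, `.csv`,
#'   `.fasta`/`.fa`/`.fna`/`.faa`).
#' @return data.frame of hits with columns `file`, `kind`, `location`,
#'   `role`, `matched_id`, `exact`; zero rows when the ID is absent.
#'   Unrecognised file types produce a per-file warning, not an error.
#' @export
find_sequence <- function(query_id, artifacts) {
  hits <- list()
  for (f in artifacts) {
    ext <- tolower(tools::file_ext(f))
    if (ext == "clstr") {
      cs <- parse_clstr(f)
      m <- cs$members
      match_idx <- which(m$seq_id == query_id |
                           (startsWith(query_id, m$seq_id) &
                              m$seq_id != query_id) |
                           (startsWith(m$seq_id, query_id) &
                              m$seq_id != query_id))
      for (i in match_idx) {
        hits[[length(hits) + 1L]] <- finder_hit(
          f, "clstr", paste0("Cluster ", m$cluster[[i]]),
          if (m$is_rep[[i]]) "representative" else "member",
          m$seq_id[[i]], m$seq_id[[i]] == query_id)
      }
    } else if (ext == "csv") {
      lines <- readLines(f)
      if (length(lines) < 1L) next
      for (i in seq_along(lines)[-1]) {
        cells <- scan(text = lines[[i]], what = character(), sep = ",",
                      quote = '"', quiet = TRUE)
        genes <- unlist(strsplit(cells[-(1:6)], "\t", fixed = TRUE))
        matched <- genes[genes == query_id |
                           (startsWith(genes, query_id) & genes != query_id)]
        for (g in unique(matched)) {
          hits[[length(hits) + 1L]] <- finder_hit(
            f, "presence_absence", cells[[1]], "member", g, g == query_id)
        }
      }
    } else if (ext %in% c("fasta", "fa", "fna", "faa")) {
      ids <- names(read_fasta(f))
      matched <- ids[ids == query_id |
                       (startsWith(ids, query_id) & ids != query_id)]
      for (g in unique(matched)) {
        hits[[length(hits) + 1L]] <- finder_hit(
          f, "fasta", basename(f), "record", g, g == query_id)
      }
    } else {
      warning("unrecognised artifact type, skipping: ", f)
    }
  }
  out <- if (length(hits) > 0L) do.call(rbind, hits) else
    finder_hit(character(0), character(0), character(0), character(0),
               character(0), logical(0))
  inexact_ids <- unique(out$matched_id[!out$exact])
  if (length(inexact_ids) > 1L) {
    warning("query '", query_id, "' resolves ambiguously to ",
            length(inexact_ids), " IDs: ",
            paste(utils::head(inexact_ids, 5L), collapse = ", "))
    attr(out, "ambiguous") <- TRUE
  } else {
    attr(out, "ambiguous") <- FALSE
  }
  out
}

choose2 <- function(n) n * (n - 1) / 2

#' Compare two clusterings of the same sequences
#'
#' Quantifies run-to-run clustering differences: which genes changed
#' co-membership, how many unordered gene pairs are co-clustered in exactly
#' one of the two runs, and how clusters split or merge between them.
#' Partitions over different universes are restricted to the intersection
#' with a warning.
#'
#' Split/merge events count fan-out in the bipartite cluster-overlap graph:
#' a cluster of `a` whose members land in two or more clusters of `b` is one
#' split event, and symmetrically for merges. `moved_genes` and
#' `pairwise_disagreement` are symmetric in the two runs by construction.
#'
#' @param a,b [cluster_set()] objects.
#' @return a `partition_diff`: list with `preserved` (clusters with
#'   identical member sets), `split_events`, `merge_events`, `moved_genes`
#'   (character vector of IDs whose co-member set changed) and
#'   `pairwise_disagreement`.
#' @export
compare_partitions <- function(a, b) {
  validate_cluster_set(a); validate_cluster_set(b)
  ua <- a$universe; ub <- b$universe
  common <- intersect(ua, ub)
  if (length(common) != length(ua) || length(common) != length(ub)) {
    warning("universes differ; comparison restricted to ",
            length(common), " shared sequence(s)")
  }
  ma <- a$members[a$members$seq_id %in% common, ]
  mb <- b$members[b$members$seq_id %in% common, ]
  ca <- stats::setNames(ma$cluster, ma$seq_id)[common]
  cb <- stats::setNames(mb$cluster, mb$seq_id)[common]

  groups_a <- split(common, ca)
  groups_b <- split(common, cb)
  key <- function(ids) paste(sort(ids, method = "radix"), collapse = "\r")
  keys_a <- vapply(groups_a, key, character(1))
  keys_b <- vapply(groups_b, key, character(1))
  preserved <- sum(keys_a %in% keys_b)

  # co-member key per gene; differs between runs => the gene moved
  gene_key_a <- stats::setNames(rep(keys_a, lengths(groups_a)),
                                unlist(groups_a, use.names = FALSE))
  gene_key_b <- stats::setNames(rep(keys_b, lengths(groups_b)),
                                unlist(groups_b, use.names = FALSE))
  moved_genes <- sort(common[gene_key_a[common] != gene_key_b[common]],
                      method = "radix")

  tab <- table(ca, cb)
  sizes_a <- rowSums(tab); sizes_b <- colSums(tab)
  pairwise_disagreement <- sum(choose2(sizes_a)) + sum(choose2(sizes_b)) -
    2 * sum(choose2(tab))
  split_events <- sum(rowSums(tab > 0) > 1L)
  merge_events <- sum(colSums(tab > 0) > 1L)

  structure(list(preserved = preserved,
                 split_events = split_events,
                 merge_events = merge_events,
                 moved_genes = moved_genes,
                 pairwise_disagreement = as.numeric(pairwise_disagreement)),
            class = "partition_diff")
}

#' @export
print.partition_diff <- function(x, ...) {
  cat(sprintf(paste0("partition_diff: %d preserved clusters, %d splits, ",
                     "%d merges, %d moved genes, %g disagreeing pairs\n"),
              x$preserved, x$split_events, x$merge_events,
              length(x$moved_genes), x$pairwise_disagreement))
  invisible(x)
}
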