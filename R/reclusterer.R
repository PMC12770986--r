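#' Integrate second-round sequences into an existing pangenome
#'
#' Maps each cluster of a combined (old + new) clustering onto the
#' first-round families its old members came from, and labels it with one of
#' five tracking categories:
#' \describe{
#'   \item{`only_second`}{no first-round sequences at all.}
#'   \item{`combined`}{old members from two or more first-round families,
#'     merged by the new sequences.}
#'   \item{`extended`}{single origin family whose band over all members is
#'     strictly higher than its first-round band - new sequences moved it up.}
#'   \item{`second`}{single (or no whole) origin; the band over this
#'     cluster's old members alone is strictly lower than the band over all
#'     members, i.e. the band is attained only when new-sequence genomes are
#'     counted.}
#'   \item{`first`}{everything else: the cluster reproduces a first-round
#'     family whose band the additions did not change.}
#' }
#' Precedence is `only_second > combined > extended > second > first`.
#' First-round family records are never mutated; bands are recomputed over
#' the union genome set. Origin families whose old members are scattered
#' over more than one combined cluster are additionally reported as
#' fragmented (the failure mode in which added sequences break existing
#' clusters), rather than being silently absorbed.
#'
#' @param first a `pangenome_result` covering exactly the old sequences.
#' @param combined a [cluster_set()] over old + new sequences.
#' @param new_ids character vector of the second-round (new) seq_ids.
#' @param scheme scheme for band computation; defaults to the first round's.
#' @param separator genome tag separator.
#' @return a `recluster_report`: list with `families` (data.frame of
#'   `family_id`, `band`, `track`, `n_old`, `n_new`, `genome_count` plus
#'   list-columns `origin_family_ids`, `old_seq_ids`, `new_seq_ids`),
#'   `totals` (data.frame `track`, `band`, `n`), `fragmentation` (data.frame
#'   `origin_family_id`, `n_clusters`, `fragmented`), `genomes` (union set)
#'   and `scheme`.
#' @export
recluster <- function(first, combined, new_ids, scheme = first$scheme,
                      separator = "|") {
  validate_cluster_set(combined)
  old_universe <- unlist(lapply(first$families, function(f)
    unlist(f$members_by_genome, use.names = FALSE)), use.names = FALSE)
  overlap <- intersect(new_ids, old_universe)
  if (length(overlap) > 0L) {
    stop("new_ids overlap the first-round universe: ",
         paste(utils::head(overlap, 5L), collapse = ", "))
  }
  m <- combined$members
  is_new <- m$seq_id %in% new_ids
  stray <- setdiff(m$seq_id[!is_new], old_universe)
  if (length(stray) > 0L) {
    stop("old sequence(s) in combined clustering absent from first round: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }

  family_of <- stats::setNames(
    rep(vapply(first$families, function(f) f$family_id, character(1)),
        vapply(first$families, function(f) f$gene_count, integer(1))),
    old_universe)
  first_band <- stats::setNames(
    vapply(first$families, function(f) f$category, character(1)),
    vapply(first$families, function(f) f$family_id, character(1)))

  genome_of <- split_tagged_ids(m$seq_id, separator)$genome_id
  genomes <- sort(unique(c(first$genomes, genome_of)), method = "radix")
  n_union <- length(genomes)

  cl_ids <- unique(m$cluster)
  fam_id <- character(0); band <- character(0); track <- character(0)
  n_old <- integer(0); n_new <- integer(0); gcount <- integer(0)
  origin_l <- list(); old_l <- list(); new_l <- list()
  for (cl in cl_ids) {
    idx <- m$cluster == cl
    ids <- m$seq_id[idx]
    gens <- genome_of[idx]
    old_ids <- ids[!ids %in% new_ids]
    new_in <- setdiff(ids, old_ids)
    origins <- sort(unique(family_of[old_ids]), method = "radix")
    band_all <- classify_family(length(unique(gens)), n_union, scheme)
    if (length(old_ids) == 0L) {
      tr <- "only_second"
    } else if (length(origins) >= 2L) {
      tr <- "combined"
    } else {
      orig_band <- first_band[[origins]]
      band_old <- classify_family(
        length(unique(genome_of[idx][!ids %in% new_ids])), n_union, scheme)
      if (band_rank(band_all, scheme) < band_rank(orig_band, scheme)) {
        tr <- "extended"
      } else if (band_rank(band_old, scheme) > band_rank(band_all, scheme)) {
        tr <- "second"
      } else {
        tr <- "first"
      }
    }
    fam_id <- c(fam_id, paste0("regroup_", cl))
    band <- c(band, band_all)
    track <- c(track, tr)
    n_old <- c(n_old, length(old_ids)); n_new <- c(n_new, length(new_in))
    gcount <- c(gcount, length(unique(gens)))
    origin_l <- c(origin_l, list(origins))
    old_l <- c(old_l, list(old_ids)); new_l <- c(new_l, list(new_in))
  }
  families <- data.frame(family_id = fam_id, band = band, track = track,
                         n_old = n_old, n_new = n_new,
                         genome_count = gcount, stringsAsFactors = FALSE)
  families$origin_family_ids <- origin_l
  families$old_seq_ids <- old_l
  families$new_seq_ids <- new_l

  # per-(track, band) totals over the full grid, zeros included
  tracks <- c("first", "extended", "combined", "second", "only_second")
  totals <- expand.grid(track = tracks, band = scheme$name,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  totals$n <- mapply(function(tr, bd) sum(families$track == tr &
                                            families$band == bd),
                     totals$track, totals$band)
  totals <- totals[order(match(totals$track, tracks),
                         match(totals$band, scheme$name)), ]
  rownames(totals) <- NULL

  # fan-out of each origin family over combined clusters (fragmentation)
  origin_all <- family_of[old_universe]
  cluster_of <- stats::setNames(m$cluster, m$seq_id)
  fan <- tapply(cluster_of[old_universe], origin_all,
                function(x) length(unique(x)))
  fragmentation <- data.frame(
    origin_family_id = names(fan),
    n_clusters = as.integer(fan),
    fragmented = as.integer(fan) > 1L,
    stringsAsFactors = FALSE)
  fragmentation <- fragmentation[
    order(fragmentation$origin_family_id, method = "radix"), ]
  rownames(fragmentation) <- NULL

  structure(list(families = families, totals = totals,
                 fragmentation = fragmentation, genomes = genomes,
                 scheme = scheme),
            class = "recluster_report")
}

#' @export
print.recluster_report <- function(x, ...) {
  cat(sprintf("recluster_report: %d families over %d genomes\n",
              nrow(x$families), length(x$genomes)))
  tt <- tapply(rep(1L, nrow(x$families)), x$families$track, sum)
  for (tr in names(tt)) cat(sprintf("  %s: %d\n", tr, tt[[tr]]))
  invisible(x)
}

# "extended" + band "First_core_99" -> "extended_core_99"; the first track
# keeps the first-round band name unchanged.
recluster_label <- function(track, band) {
  stripped <- ifelse(startsWith(band, "First_"),
                     sub("^First_", "", band), band)
  ifelse(track == "first", band, paste(track, stripped, sep = "_"))
}

#' Write the reclustering summary
#'
#' One line per (track, band) combination, `"<label>: <count>"`, zeros
#' included, where the label fuses the track with the band name (e.g.
#' `extended_core_99`); `first`-track families keep their first-round band
#' names. A final line gives the total family count (the per-line counts sum
#' to it).
#'
#' @param rep a `recluster_report`.
#' @param path output path.
#' @return the lines written, invisibly.
#' @export
write_recluster_summary <- function(rep, path) {
  lines <- sprintf("%s: %d",
                   recluster_label(rep$totals$track, rep$totals$band),
                   rep$totals$n)
  lines <- c(lines, sprintf("Total gene groups: %d", nrow(rep$families)))
  writeLines(lines, path)
  invisible(lines)
}
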