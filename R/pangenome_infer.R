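#' Construct a category scheme of presence-percentage bands
#'
#' A scheme is an ordered set of named bands over the percentage of genomes a
#' family is present in. Bands are lower-inclusive, upper-exclusive
#' `[lo, hi)` intervals, except the top band which also includes 100 exactly;
#' the last lower bound must be 0 so the bands cover `[0, 100]`.
#'
#' @param lower_bounds strictly decreasing numeric vector of lower bounds
#'   (percent, at most two decimal places), ending in 0.
#' @param names band names, same length as `lower_bounds`.
#' @return a `category_scheme`: data.frame with columns `name`, `lower`
#'   (percent) and `lower100` (lower bound in hundredths of a percent, used
#'   for exact rational classification), ordered from highest band down.
#' @export
category_scheme <- function(lower_bounds, names) {
  if (length(lower_bounds) != length(names) || length(names) == 0L) {
    stop("lower_bounds and names must be non-empty and of equal length")
  }
  if (any(diff(lower_bounds) >= 0)) {
    stop("lower_bounds must be strictly decreasing")
  }
  if (utils::tail(lower_bounds, 1L) != 0) {
    stop("the last lower bound must be 0 so the bands cover [0,100]")
  }
  if (lower_bounds[[1]] > 100) stop("lower bounds must be <= 100")
  lower100 <- round(lower_bounds * 100)
  if (any(abs(lower100 - lower_bounds * 100) > 1e-9)) {
    stop("lower bounds must have at most two decimal places")
  }
  structure(data.frame(name = as.character(names), lower = lower_bounds,
                       lower100 = as.integer(lower100),
                       stringsAsFactors = FALSE),
            class = c("category_scheme", "data.frame"))
}

#' The default core/soft-core/shell/cloud scheme
#'
#' Bands at 99/95/15/0 percent, matching the conventional pangenome
#' definitions (core `[99,100]`, soft-core `[95,99)`, shell `[15,95)`, cloud
#' `[0,15)`). First-round families are reported with a `First_` prefix so
#' reclustering output can distinguish rounds.
#'
#' @param prefix prefix for the band names (default `"First"`).
#' @return a [category_scheme()] with names `First_core_99`, `First_core_95`,
#'   `First_core_15`, `First_core_0`.
#' @export
default_scheme <- function(prefix = "First") {
  category_scheme(c(99, 95, 15, 0),
                  paste0(prefix, "_core_", c(99, 95, 15, 0)))
}

# Rank of a band name within a scheme: 1 = highest band. Used for
# strictly-higher/lower band comparisons during reclustering.
band_rank <- function(band, scheme) {
  match(band, scheme$name)
}

#' Classify a gene family into a presence band
#'
#' The band whose interval contains `100 * genome_count / total_genomes`.
#' The comparison is exact rational arithmetic (integer cross-multiplication
#' against lower bounds stored in hundredths of a percent), so boundary cases
#' such as 19/20 = 95% land deterministically in the lower-inclusive band and
#' no floating-point rounding can flip them.
#'
#' @param genome_count number of genomes the family is present in (>= 1).
#' @param total_genomes total genomes in the run (> 0).
#' @param scheme a [category_scheme()].
#' @return the band name (character scalar). Vectorised over `genome_count`.
#' @export
classify_family <- function(genome_count, total_genomes,
                            scheme = default_scheme()) {
  if (length(total_genomes) != 1L || is.na(total_genomes) ||
      total_genomes == 0L) {
    stop("total_genomes must be a single positive integer")
  }
  if (any(genome_count < 1L | genome_count > total_genomes)) {
    stop("genome_count must be in 1..total_genomes")
  }
  # 100*k/n >= lo  <=>  10000*k >= lo100*n  (all integers, exact)
  k <- as.numeric(genome_count)
  n <- as.numeric(total_genomes)
  vapply(k, function(ki) {
    hit <- which(10000 * ki >= scheme$lower100 * n)[1]
    scheme$name[[hit]]
  }, character(1))
}

#' Trace clusters back to their source genomes
#'
#' Converts a clustering of genome-tagged gene IDs into (uncategorised) gene
#' families: one family per cluster, with genes grouped by the genome
#' recovered from each tagged ID. Paralogs (several genes of one genome in
#' one cluster) land in the same genome list.
#'
#' @param cs a [cluster_set()] over tagged IDs.
#' @param separator the genome tag separator (must occur in every seq_id).
#' @return list of gene families; each is a list with `family_id`
#'   (`group_<k>` in cluster order), `members_by_genome` (named list of gene
#'   ID vectors, genomes sorted), `genome_count`, `gene_count`,
#'   `representative_id` and `category` (`NA` until classified). The
#'   attribute `genomes` holds the sorted union of observed genomes.
#' @export
trace_genomes <- function(cs, separator = "|") {
  validate_cluster_set(cs)
  m <- cs$members
  split_ids <- split_tagged_ids(m$seq_id, separator)
  m$genome_id <- split_ids$genome_id
  reps <- representatives(cs)
  rep_of <- stats::setNames(reps$representative_id, reps$cluster)
  families <- lapply(unique(m$cluster), function(cl) {
    rows <- m[m$cluster == cl, , drop = FALSE]
    by_genome <- split(rows$seq_id, rows$genome_id)
    by_genome <- by_genome[order(names(by_genome), method = "radix")]
    list(family_id = paste0("group_", cl),
         members_by_genome = by_genome,
         genome_count = length(by_genome),
         gene_count = nrow(rows),
         representative_id = rep_of[[as.character(cl)]],
         category = NA_character_)
  })
  attr(families, "genomes") <- sort(unique(m$genome_id), method = "radix")
  families
}

#' Assemble a pangenome result from traced families
#'
#' Classifies every family under the scheme and collects run-level totals.
#'
#' @param families output of [trace_genomes()].
#' @param scheme a [category_scheme()].
#' @param genomes optional character vector of all genomes in the run;
#'   defaults to the genomes observed in the families. Supply it explicitly
#'   when some genomes contributed no genes.
#' @return a `pangenome_result`: list with `genomes`, `families` (each now
#'   carrying its `category`), `scheme`, `totals` (named family count per
#'   band) and `total_gene_count`.
#' @export
pangenome_result <- function(families, scheme = default_scheme(),
                             genomes = NULL) {
  if (is.null(genomes)) genomes <- attr(families, "genomes")
  genomes <- sort(unique(genomes), method = "radix")
  n <- length(genomes)
  families <- lapply(families, function(f) {
    f$category <- classify_family(f$genome_count, n, scheme)
    f
  })
  cats <- vapply(families, function(f) f$category, character(1))
  totals <- stats::setNames(
    vapply(scheme$name, function(b) sum(cats == b), integer(1)),
    scheme$name)
  structure(
    list(genomes = genomes, families = families, scheme = scheme,
         totals = totals,
         total_gene_count = sum(vapply(families, function(f) f$gene_count,
                                       numeric(1)))),
    class = "pangenome_result")
}

#' @export
print.pangenome_result <- function(x, ...) {
  cat(sprintf("pangenome_result: %d genomes, %d gene families, %d genes\n",
              length(x$genomes), length(x$families), x$total_gene_count))
  for (b in names(x$totals)) cat(sprintf("  %s: %d\n", b, x$totals[[b]]))
  invisible(x)
}

# format a number with up to 2 decimals, dropping trailing zeros ("1.5", "2")
format_avg <- function(x) {
  sub("\\.?0+$", "", sprintf("%.2f", x))
}

quote_csv <- function(x) paste0('"', gsub('"', '""', x), '"')

#' Build the gene presence-absence table (Roary dialect)
#'
#' Fixed leading columns `Gene`, `Non-unique Gene name`, `Annotation`,
#' `No. isolates`, `No. sequences`, `Avg sequences per isolate`, then one
#' column per genome. A genome's cell lists its member gene IDs joined by a
#' tab character inside the quoted field; an empty cell means absent. Rows
#' are sorted by descending `No. isolates`, then `family_id`.
#'
#' @param pr a `pangenome_result`.
#' @param path optional output path; when given the quoted CSV is written.
#' @return character vector of CSV lines (header first), invisibly when
#'   `path` is given.
#' @export
build_presence_absence <- function(pr, path = NULL) {
  genomes <- pr$genomes
  header <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
              "No. sequences", "Avg sequences per isolate", genomes)
  fams <- pr$families
  if (length(fams) > 0L) {
    iso <- vapply(fams, function(f) f$genome_count, numeric(1))
    ids <- vapply(fams, function(f) f$family_id, character(1))
    fams <- fams[order(-iso, ids, method = "radix")]
  }
  rows <- vapply(fams, function(f) {
    cells <- vapply(genomes, function(g) {
      genes <- f$members_by_genome[[g]]
      if (is.null(genes)) "" else paste(genes, collapse = "\t")
    }, character(1))
    paste(quote_csv(c(
      f$family_id, "", "",
      as.character(f$genome_count), as.character(f$gene_count),
      format_avg(f$gene_count / f$genome_count),
      cells)), collapse = ",")
  }, character(1))
  lines <- c(paste(quote_csv(header), collapse = ","), rows)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write Roary-style summary statistics
#'
#' One line per band, `"<name> (<lo>% <= strains < <hi>%): <count>"` (the top
#' band prints `<= 100%`), and a final `"Total genes: <n>"` line giving the
#' total number of gene families (the sum of the band counts).
#'
#' @param pr a `pangenome_result`.
#' @param path output path.
#' @return the lines written, invisibly.
#' @export
write_summary_statistics <- function(pr, path) {
  sc <- pr$scheme
  fmt_pct <- format_avg
  lines <- character(nrow(sc))
  for (i in seq_len(nrow(sc))) {
    upper <- if (i == 1L) "<= 100%" else paste0("< ", fmt_pct(sc$lower[[i - 1L]]), "%")
    lines[[i]] <- sprintf("%s (%s%% <= strains %s): %d",
                          sc$name[[i]], fmt_pct(sc$lower[[i]]), upper,
                          pr$totals[[sc$name[[i]]]])
  }
  lines <- c(lines, sprintf("Total genes: %d", length(pr$families)))
  writeLines(lines, path)
  invisible(lines)
}

#' Write per-family and combined FASTA files
#'
#' One FASTA per gene family (named `<family_id>.fasta`) plus a combined
#' `combined_families.fasta` with every record. Headers keep the tagged IDs;
#' record order follows `members_by_genome` (genomes sorted, genes in member
#' order).
#'
#' @param pr a `pangenome_result`.
#' @param sequences named character vector covering every member ID.
#' @param outdir output directory (created if needed).
#' @return invisible character vector of the per-family file paths.
#' @export
write_family_fastas <- function(pr, sequences, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  all_ids <- unlist(lapply(pr$families, function(f)
    unlist(f$members_by_genome, use.names = FALSE)), use.names = FALSE)
  missing <- setdiff(all_ids, names(sequences))
  if (length(missing) > 0L) {
    stop("missing sequence(s) for member id(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  paths <- character(length(pr$families))
  combined <- character(0)
  for (i in seq_along(pr$families)) {
    f <- pr$families[[i]]
    ids <- unlist(f$members_by_genome, use.names = FALSE)
    paths[[i]] <- file.path(outdir, paste0(f$family_id, ".fasta"))
    write_fasta(sequences[ids], paths[[i]])
    combined <- c(combined, ids)
  }
  write_fasta(sequences[combined], file.path(outdir, "combined_families.fasta"))
  invisible(paths)
}
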