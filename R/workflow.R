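#' Resolved configuration for a pipeline run
#'
#' Collects every knob of a Full, Partial or Recluster run. Clustering
#' thresholds are normalised to exactly two decimal places once, here, so no
#' downstream step ever sees single-decimal precision. Thread and memory
#' settings affect only external-tool invocation - the internal clusterer is
#' single-threaded and ignores them by design - but they are always recorded
#' in the provenance file, because resource allocation is itself a
#' reproducibility-relevant parameter.
#'
#' @param mode `"full"`, `"partial"` or `"recluster"`.
#' @param input_dir directory of GFF3 genomes (full mode).
#' @param clusters_file `.clstr` or edge-list path (partial/recluster).
#' @param first_dir previous output directory (recluster mode).
#' @param new_fasta FASTA of second-round sequences (recluster mode).
#' @param output_dir output directory.
#' @param scheme a [category_scheme()].
#' @param params a [clustering_params()].
#' @param clusterer `"internal"` (the package's deterministic greedy
#'   clusterer) or `"external_cdhit"`.
#' @param aligner optional aligner command for the core gene alignment
#'   (e.g. `"mafft"`); `NULL` skips alignment.
#' @param features feature types to extract from GFF3.
#' @param separator genome tag separator.
#' @param threads,memory_mb resource hints passed to external tools and
#'   recorded in provenance.
#' @param write_fastas write per-family FASTA files (default `TRUE`).
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("full", "partial", "recluster"),
                       input_dir = NULL, clusters_file = NULL,
                       first_dir = NULL, new_fasta = NULL,
                       output_dir, scheme = default_scheme(),
                       params = clustering_params(),
                       clusterer = c("internal", "external_cdhit"),
                       aligner = NULL, features = "CDS", separator = "|",
                       threads = 1L, memory_mb = 800L,
                       write_fastas = TRUE) {
  mode <- match.arg(mode)
  clusterer <- match.arg(clusterer)
  structure(list(mode = mode, input_dir = input_dir,
                 clusters_file = clusters_file, first_dir = first_dir,
                 new_fasta = new_fasta, output_dir = output_dir,
                 scheme = scheme, params = params, clusterer = clusterer,
                 aligner = aligner, features = features,
                 separator = separator, threads = as.integer(threads),
                 memory_mb = as.integer(memory_mb),
                 write_fastas = write_fastas),
            class = "run_config")
}

write_provenance <- function(cfg, path) {
  prov <- list(
    mode = cfg$mode,
    input_dir = cfg$input_dir, clusters_file = cfg$clusters_file,
    first_dir = cfg$first_dir, new_fasta = cfg$new_fasta,
    output_dir = cfg$output_dir,
    scheme = list(names = cfg$scheme$name, lower_bounds = cfg$scheme$lower),
    identity_threshold_c = cfg$params$c,
    length_difference_cutoff_s = cfg$params$s,
    clustering_mode = cfg$params$mode,
    word_size = cfg$params$word_size,
    clusterer = cfg$clusterer, aligner = cfg$aligner,
    features = cfg$features, separator = cfg$separator,
    threads = cfg$threads, memory_mb = cfg$memory_mb,
    write_fastas = cfg$write_fastas,
    panfam_version = as.character(utils::packageVersion("panfam")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}

# serialise a pangenome_result so recluster mode can reload round one
write_pangenome_json <- function(pr, path) {
  fams <- lapply(pr$families, function(f) {
    list(family_id = f$family_id,
         members_by_genome = f$members_by_genome,
         representative_id = f$representative_id,
         category = f$category)
  })
  jsonlite::write_json(
    list(genomes = pr$genomes,
         scheme = list(names = pr$scheme$name,
                       lower_bounds = pr$scheme$lower),
         families = fams),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

read_pangenome_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  scheme <- category_scheme(unlist(x$scheme$lower_bounds),
                            unlist(x$scheme$names))
  families <- lapply(x$families, function(f) {
    mbg <- lapply(f$members_by_genome, function(v) unlist(v))
    list(family_id = f$family_id, members_by_genome = mbg,
         genome_count = length(mbg),
         gene_count = length(unlist(mbg, use.names = FALSE)),
         representative_id = f$representative_id,
         category = f$category)
  })
  attr(families, "genomes") <- unlist(x$genomes)
  pr <- pangenome_result(families, scheme, genomes = unlist(x$genomes))
  pr
}

# shared tail of full/partial mode: classify, write all pangenome outputs
infer_and_write <- function(cs, cfg, sequences = NULL) {
  outdir <- cfg$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  families <- trace_genomes(cs, cfg$separator)
  pr <- pangenome_result(families, cfg$scheme)
  build_presence_absence(pr, file.path(outdir, "gene_presence_absence.csv"))
  write_summary_statistics(pr, file.path(outdir, "summary_statistics.txt"))
  write_pangenome_json(pr, file.path(outdir, "pangenome.json"))
  if (!is.null(sequences) && cfg$write_fastas) {
    write_family_fastas(pr, sequences, file.path(outdir, "family_fastas"))
  }
  if (!is.null(sequences) && !is.null(cfg$aligner)) {
    core_align_and_concat(pr, sequences, cfg, outdir)
  }
  pr
}

# align single-copy core families and write the concatenated alignment
core_align_and_concat <- function(pr, sequences, cfg, outdir) {
  top_band <- pr$scheme$name[[1]]
  core <- Filter(function(f) f$category == top_band &&
                   f$gene_count == f$genome_count, pr$families)
  if (length(core) == 0L) return(invisible(NULL))
  alns <- list()
  for (f in core) {
    picks <- select_family_representatives(f, sequences, "longest")
    ids <- stats::setNames(picks$per_genome$gene_id,
                           picks$per_genome$genome_id)
    aln <- align_family(stats::setNames(sequences[ids], names(ids)),
                        aligner_cmd = cfg$aligner)
    alns[[f$family_id]] <- aln
  }
  super <- concatenate_core_alignment(alns, genomes = pr$genomes)
  write_fasta(super, file.path(outdir, "core_gene_alignment.fasta"))
  invisible(super)
}

#' Run Full Mode: ingest, tag, cluster, infer, write
#'
#' Parses the genome directory, tags every gene with its genome of origin,
#' clusters the combined gene set (internal clusterer; an external CD-HIT
#' can be requested and must then be on `PATH`), and writes the pangenome
#' outputs plus a provenance file recording every resolved parameter.
#' Reruns with an identical configuration produce byte-identical outputs.
#'
#' @param cfg a [run_config()] with `mode = "full"`.
#' @return the `pangenome_result`, invisibly.
#' @export
run_full <- function(cfg) {
  stopifnot(cfg$mode == "full")
  if (cfg$clusterer == "external_cdhit") {
    binary <- if (cfg$params$mode == "dna") "cd-hit-est" else "cd-hit"
    if (Sys.which(binary) == "") {
      stop("external clusterer requested but '", binary,
           "' is not on PATH; no outputs were written")
    }
  }
  anns <- read_genome_dir(cfg$input_dir, feature_types = cfg$features)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  combined <- tag_and_combine(anns, cfg$separator,
                              out_prefix = file.path(cfg$output_dir,
                                                     "genes"))
  seqs <- if (cfg$params$mode == "dna") combined$dna else combined$aa
  cs <- if (cfg$clusterer == "internal") {
    greedy_cluster(seqs, cfg$params)
  } else {
    run_external_cdhit(seqs, cfg)
  }
  write_clstr(cs, file.path(cfg$output_dir, "clusters.clstr"))
  pr <- infer_and_write(cs, cfg, sequences = seqs)
  write_provenance(cfg, file.path(cfg$output_dir, "provenance.json"))
  invisible(pr)
}

run_external_cdhit <- function(seqs, cfg) {
  binary <- if (cfg$params$mode == "dna") "cd-hit-est" else "cd-hit"
  infile <- tempfile(fileext = ".fasta")
  outfile <- tempfile()
  on.exit(unlink(c(infile, outfile, paste0(outfile, ".clstr"))), add = TRUE)
  write_fasta(seqs, infile)
  status <- system2(binary, c(
    "-i", shQuote(infile), "-o", shQuote(outfile),
    "-c", sprintf("%.2f", cfg$params$c), "-s", sprintf("%.2f", cfg$params$s),
    "-d", "0", "-T", cfg$threads, "-M", cfg$memory_mb),
    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop(binary, " exited with status ", status)
  parse_clstr(paste0(outfile, ".clstr"))
}

#' Run Partial Mode: pangenome inference from pre-clustered genes
#'
#' Accepts a CD-HIT `.clstr` file or a two-column edge list and performs the
#' identical downstream inference and output generation as Full Mode, so the
#' two modes agree bit-exactly on all outputs given equivalent clusterings.
#'
#' @param cfg a [run_config()] with `mode = "partial"` and `clusters_file`
#'   set.
#' @param sequences optional named character vector of gene sequences;
#'   required for per-family FASTA output and core alignment, not for
#'   inference.
#' @return the `pangenome_result`, invisibly.
#' @export
run_partial <- function(cfg, sequences = NULL) {
  stopifnot(cfg$mode == "partial")
  if (is.null(cfg$clusters_file)) stop("partial mode requires clusters_file")
  cs <- if (grepl("\\.clstr$", cfg$clusters_file)) {
    parse_clstr(cfg$clusters_file)
  } else {
    el <- parse_edge_list(cfg$clusters_file)
    clusters_from_edges(el$edges, el$nodes,
                        lengths = if (is.null(sequences)) NULL else
                          nchar(sequences))
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  pr <- infer_and_write(cs, cfg, sequences = sequences)
  write_provenance(cfg, file.path(cfg$output_dir, "provenance.json"))
  invisible(pr)
}

#' Run Recluster Mode: integrate new sequences into a previous run
#'
#' Loads the first-round pangenome from a previous output directory, the
#' combined (old + new) clustering, and the new-sequence FASTA; labels every
#' combined cluster with its tracking category; and writes the reclustering
#' summary, the per-track presence-absence table and the origin-family
#' fragmentation table.
#'
#' @param cfg a [run_config()] with `mode = "recluster"`, `first_dir`,
#'   `clusters_file` (the combined clustering) and `new_fasta` set.
#' @return the `recluster_report`, invisibly.
#' @export
run_recluster <- function(cfg) {
  stopifnot(cfg$mode == "recluster")
  prev <- file.path(cfg$first_dir, "pangenome.json")
  if (!file.exists(prev)) {
    stop("first-round output not found: ", prev,
         " (is first_dir a previous panfam output directory?)")
  }
  first <- read_pangenome_json(prev)
  if (!identical(first$scheme$name, cfg$scheme$name) ||
      !isTRUE(all.equal(as.numeric(first$scheme$lower),
                        as.numeric(cfg$scheme$lower)))) {
    stop("category scheme mismatch between first-round output and ",
         "current configuration")
  }
  combined <- if (grepl("\\.clstr$", cfg$clusters_file)) {
    parse_clstr(cfg$clusters_file)
  } else {
    el <- parse_edge_list(cfg$clusters_file)
    clusters_from_edges(el$edges, el$nodes)
  }
  new_ids <- names(read_fasta(cfg$new_fasta))
  rep <- recluster(first, combined, new_ids, scheme = cfg$scheme,
                   separator = cfg$separator)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_recluster_summary(rep, file.path(cfg$output_dir,
                                         "recluster_summary.txt"))
  write_recluster_presence_absence(
    rep, file.path(cfg$output_dir, "gene_presence_absence_recluster.csv"),
    separator = cfg$separator)
  utils::write.table(rep$fragmentation,
                     file.path(cfg$output_dir, "fragmentation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(cfg, file.path(cfg$output_dir, "provenance.json"))
  invisible(rep)
}

# presence-absence table for a recluster report, with a leading Track column
write_recluster_presence_absence <- function(rep, path, separator = "|") {
  genomes <- rep$genomes
  header <- c("Gene", "Track", "Band", "No. isolates", "No. sequences",
              genomes)
  fams <- rep$families
  ord <- order(-fams$genome_count, fams$family_id, method = "radix")
  lines <- paste(quote_csv(header), collapse = ",")
  for (i in ord) {
    ids <- c(fams$old_seq_ids[[i]], fams$new_seq_ids[[i]])
    genome_of <- split_tagged_ids(ids, separator)$genome_id
    cells <- vapply(genomes, function(g)
      paste(ids[genome_of == g], collapse = "\t"), character(1))
    lines <- c(lines, paste(quote_csv(c(
      fams$family_id[[i]], fams$track[[i]], fams$band[[i]],
      as.character(fams$genome_count[[i]]), as.character(length(ids)),
      cells)), collapse = ","))
  }
  writeLines(lines, path)
  invisible(lines)
}
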