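# Small fixture builders shared across test files. Everything is generated
# in code; nothing is read from disk except what a test writes itself.

# point-mutate a sequence at the given per-site rate (test-local copy)
mutate_fixture <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  idx <- which(stats::runif(length(chars)) < rate)
  for (i in idx) {
    chars[[i]] <- sample(setdiff(c("A", "C", "G", "T"), chars[[i]]), 1L)
  }
  paste(chars, collapse = "")
}

# write a minimal GFF3 file with embedded ##FASTA
write_test_gff <- function(path, contigs, features) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    lines <- c(lines, paste(f$contig, "test", f$type, f$start, f$end, ".",
                            f$strand, "0", paste0("ID=", f$id), sep = "\t"))
  }
  lines <- c(lines, "##FASTA")
  for (nm in names(contigs)) {
    lines <- c(lines, paste0(">", nm), contigs[[nm]])
  }
  writeLines(lines, path)
  path
}

gff_feature <- function(id, contig, start, end, strand = "+", type = "CDS") {
  data.frame(id = id, contig = contig, start = start, end = end,
             strand = strand, type = type, stringsAsFactors = FALSE)
}

# a tiny annotation object without touching the GFF parser
make_annotation <- function(genome_id, gene_ids, seqs = NULL) {
  if (is.null(seqs)) seqs <- vapply(gene_ids, function(i) "ATGAAATAA",
                                    character(1))
  structure(list(
    genome_id = genome_id,
    records = data.frame(
      gene_id = gene_ids, genome_id = genome_id, contig_id = "c1",
      start = 1L, end = nchar(seqs), strand = "+", feature_type = "CDS",
      dna = seqs, aa = NA_character_, aa_internal_stop = NA,
      stringsAsFactors = FALSE),
    source_path = ""), class = "genome_annotation")
}

# cluster_set from a list of member-id vectors; first member is the
# representative, lengths default to nchar-free placeholders
make_cluster_set <- function(groups, lengths = NULL, unit = "nt") {
  rows <- list()
  for (k in seq_along(groups)) {
    ids <- groups[[k]]
    for (j in seq_along(ids)) {
      len <- if (is.null(lengths)) 100L else lengths[[ids[[j]]]]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k - 1L, seq_id = ids[[j]], length = as.integer(len),
        identity_pct = if (j == 1L) NA_real_ else 99,
        strand = if (j == 1L) NA_character_ else "+",
        is_rep = j == 1L, stringsAsFactors = FALSE)
    }
  }
  cluster_set(do.call(rbind, rows), unit = unit)
}

# pangenome_result from family member lists: list(family_id = list(genome =
# c(gene ids)))
make_pangenome <- function(families_spec, genomes,
                           scheme = default_scheme()) {
  fams <- lapply(names(families_spec), function(fid) {
    mbg <- families_spec[[fid]]
    mbg <- mbg[order(names(mbg), method = "radix")]
    list(family_id = fid, members_by_genome = mbg,
         genome_count = length(mbg),
         gene_count = length(unlist(mbg, use.names = FALSE)),
         representative_id = unlist(mbg, use.names = FALSE)[[1]],
         category = NA_character_)
  })
  attr(fams, "genomes") <- genomes
  pangenome_result(fams, scheme, genomes = genomes)
}
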