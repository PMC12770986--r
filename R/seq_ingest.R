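#' Translate a coding sequence with a bacterial genetic code
#'
#' Standard table-11 translation of an in-frame CDS. The terminal stop codon
#' is stripped from the returned protein; internal stops are retained as `*`
#' and flagged with a warning so no gene is silently dropped. Sequences whose
#' length is not a multiple of 3 are truncated by the trailing 1-2 nt and
#' flagged the same way.
#'
#' @param dna nucleotide string (A/C/G/T).
#' @param table_id NCBI genetic code table identifier (default 11, the
#'   bacterial/archaeal/plastid code).
#' @return amino-acid string, with attributes `internal_stop` and `truncated`
#'   (logical flags, also raised as warnings).
#' @export
translate_cds <- function(dna, table_id = 11L) {
  if (!nzchar(dna)) stop("cannot translate an empty sequence")
  truncated <- FALSE
  rem <- nchar(dna) %% 3L
  if (rem != 0L) {
    truncated <- TRUE
    warning("CDS length not divisible by 3; truncating ", rem, " trailing nt")
    dna <- substr(dna, 1L, nchar(dna) - rem)
  }
  code <- genetic_code_cached(table_id)
  starts <- seq(1L, nchar(dna), by = 3L)
  codons <- substring(toupper(dna), starts, starts + 2L)
  aas <- unname(code[codons])
  aas[is.na(aas)] <- "X" # ambiguous/unknown codons
  aa <- paste(aas, collapse = "")
  # strip terminal stop, keep (and flag) any internal ones
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  internal_stop <- grepl("*", aa, fixed = TRUE)
  if (internal_stop) {
    warning("internal stop codon(s) retained in translation")
  }
  structure(aa, internal_stop = internal_stop, truncated = truncated)
}

# Genetic code lookup tables are immutable; fetch each from Biostrings once.
.code_cache <- new.env(parent = emptyenv())
genetic_code_cached <- function(table_id) {
  key <- as.character(table_id)
  if (is.null(.code_cache[[key]])) {
    .code_cache[[key]] <- Biostrings::getGeneticCode(key)
  }
  .code_cache[[key]]
}

# Split a GFF3 file into its feature lines and its sequence section.
# Sequences come either from an embedded ##FASTA section or from a sibling
# FASTA file with matching contig IDs.
read_gff_parts <- function(path, fasta_path = NULL) {
  lines <- readLines(path)
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at) > 0L) {
    feature_lines <- lines[seq_len(fasta_at[[1]] - 1L)]
    fasta_lines <- lines[seq(fasta_at[[1]] + 1L, length(lines))]
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(fasta_lines, tmp)
    contigs <- Biostrings::readDNAStringSet(tmp)
  } else {
    if (is.null(fasta_path)) {
      base <- sub("\\.gff3?$", "", path)
      candidates <- paste0(base, c(".fasta", ".fa", ".fna"))
      fasta_path <- candidates[file.exists(candidates)][1]
      if (is.na(fasta_path)) {
        stop("no ##FASTA section in ", path,
             " and no sibling .fasta/.fa/.fna file found")
      }
    }
    feature_lines <- lines
    contigs <- Biostrings::readDNAStringSet(fasta_path)
  }
  # FASTA headers may carry descriptions; contig ID is the first word
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  list(feature_lines = feature_lines, contigs = contigs)
}

gff_attribute <- function(attrs, key) {
  fields <- strsplit(attrs, ";", fixed = TRUE)[[1]]
  hit <- grep(paste0("^", key, "="), fields, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  sub(paste0("^", key, "="), "", hit[[1]])
}

#' Parse an annotated genome from GFF3 (with embedded or sibling FASTA)
#'
#' Extracts the requested feature types from a GFF3 file, pulling each
#' feature's DNA from its contig (reverse-complemented for strand `-`) and
#' translating CDS features with the bacterial code. GFF3 coordinates are
#' 1-based inclusive and are kept as such internally.
#'
#' Multi-span (joined) features are out of scope: when several feature lines
#' share an `ID`, only single-span handling applies and the extra spans are
#' skipped with a warning. Non-CDS features (rRNA, pseudogenes, ...) are
#' extracted as DNA only, with no `aa`.
#'
#' @param path path to the GFF3 file.
#' @param feature_types character vector of feature types to extract
#'   (default `"CDS"`).
#' @param fasta_path optional sibling FASTA; ignored when the GFF embeds a
#'   `##FASTA` section.
#' @param genome_id genome identifier; defaults to the file name without
#'   extension.
#' @param translation_table NCBI genetic code table for CDS translation.
#' @return a `genome_annotation`: list with `genome_id`, `source_path` and
#'   `records`, a data.frame with one row per extracted feature (columns
#'   `gene_id`, `genome_id`, `contig_id`, `start`, `end`, `strand`,
#'   `feature_type`, `dna`, `aa`, `aa_internal_stop`).
#' @export
parse_gff_with_fasta <- function(path, feature_types = "CDS",
                                 fasta_path = NULL, genome_id = NULL,
                                 translation_table = 11L) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.gff3?$", "", basename(path))
  }
  parts <- read_gff_parts(path, fasta_path)
  contigs <- parts$contigs
  contig_seq <- as.character(contigs)
  contig_len <- nchar(contig_seq)

  recs <- list()
  seen_ids <- character(0)
  skipped_multispan <- character(0)
  for (i in seq_along(parts$feature_lines)) {
    line <- parts$feature_lines[[i]]
    if (line == "" || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9L) {
      stop("malformed GFF line ", i, " in ", path,
           " (expected 9 tab-separated fields, got ", length(fields), ")")
    }
    type <- fields[[3]]
    if (!type %in% feature_types) next
    contig <- fields[[1]]
    start <- suppressWarnings(as.integer(fields[[4]]))
    end <- suppressWarnings(as.integer(fields[[5]]))
    strand <- fields[[7]]
    if (is.na(start) || is.na(end) || end < start) {
      stop("malformed GFF line ", i, " in ", path, " (bad coordinates)")
    }
    gene_id <- gff_attribute(fields[[9]], "ID")
    if (is.na(gene_id)) gene_id <- gff_attribute(fields[[9]], "Name")
    if (is.na(gene_id)) {
      stop("feature at line ", i, " in ", path, " has no ID/Name attribute")
    }
    if (gene_id %in% seen_ids) {
      # second span of a joined feature: single-span features only in v1
      skipped_multispan <- c(skipped_multispan, gene_id)
      next
    }
    if (!contig %in% names(contig_seq)) {
      stop("feature '", gene_id, "' references missing contig '", contig,
           "' in ", path)
    }
    if (end > contig_len[[contig]]) {
      stop("feature '", gene_id, "' (", start, "..", end,
           ") extends beyond contig '", contig, "' length ",
           contig_len[[contig]])
    }
    dna <- substr(contig_seq[[contig]], start, end)
    if (strand == "-") {
      dna <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(dna)))
    } else if (strand != "+") {
      stop("feature '", gene_id, "' at line ", i, " has strand '", strand,
           "' (expected + or -)")
    }
    aa <- NA_character_
    internal_stop <- NA
    if (type == "CDS") {
      aa <- suppressWarnings(translate_cds(dna, translation_table))
      internal_stop <- attr(aa, "internal_stop")
      aa <- as.character(aa)
    }
    seen_ids <- c(seen_ids, gene_id)
    recs[[length(recs) + 1L]] <- data.frame(
      gene_id = gene_id, genome_id = genome_id, contig_id = contig,
      start = start, end = end, strand = strand, feature_type = type,
      dna = dna, aa = aa, aa_internal_stop = internal_stop,
      stringsAsFactors = FALSE)
  }
  if (length(skipped_multispan) > 0L) {
    warning("skipped ", length(unique(skipped_multispan)),
            " multi-span feature(s) in ", path, ": ",
            paste(utils::head(unique(skipped_multispan), 3L), collapse = ", "))
  }
  records <- if (length(recs) > 0L) do.call(rbind, recs) else
    data.frame(gene_id = character(0), genome_id = character(0),
               contig_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), feature_type = character(0),
               dna = character(0), aa = character(0),
               aa_internal_stop = logical(0))
  structure(list(genome_id = genome_id, records = records,
                 source_path = path),
            class = "genome_annotation")
}

#' Read a directory of annotated genomes
#'
#' Convenience wrapper over [parse_gff_with_fasta()]: every `.gff`/`.gff3`
#' file in the directory becomes one genome, named after its file.
#'
#' @param dir directory containing GFF3 files (embedded `##FASTA` or sibling
#'   FASTA).
#' @param feature_types,translation_table passed to [parse_gff_with_fasta()].
#' @return list of `genome_annotation` objects, sorted by genome_id.
#' @export
read_genome_dir <- function(dir, feature_types = "CDS",
                            translation_table = 11L) {
  paths <- list.files(dir, pattern = "\\.gff3?$", full.names = TRUE)
  paths <- sort(paths, method = "radix")
  anns <- lapply(paths, parse_gff_with_fasta, feature_types = feature_types,
                 translation_table = translation_table)
  ids <- vapply(anns, function(a) a$genome_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate genome_id(s) in ", dir, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  anns
}

#' Tag gene IDs with their genome of origin and combine into one gene set
#'
#' The combiner step: every gene ID becomes
#' `genome_id` + `separator` + `gene_id`, so that downstream cluster tracing
#' can recover the source genome from any sequence header by splitting on the
#' first separator occurrence. Output order is deterministic: genomes sorted
#' lexicographically, genes in annotation order.
#'
#' @param annotations list of `genome_annotation` objects.
#' @param separator tag separator (default `"|"`); must not occur in any
#'   genome_id.
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>_combined.fasta` (DNA), `<prefix>_combined_aa.fasta`
#'   (translated CDS only) and `<prefix>_id_map.tsv`.
#' @return list with `records` (data.frame of `tagged_id`, `genome_id`,
#'   `original_id`, `dna`, `aa`), `dna` and `aa` (named character vectors
#'   keyed by tagged_id) and `id_map` (the three ID columns).
#' @export
tag_and_combine <- function(annotations, separator = "|", out_prefix = NULL) {
  genome_ids <- vapply(annotations, function(a) a$genome_id, character(1))
  bad <- genome_ids[grepl(separator, genome_ids, fixed = TRUE)]
  if (length(bad) > 0L) {
    stop("separator '", separator, "' occurs in genome_id(s): ",
         paste(bad, collapse = ", "))
  }
  annotations <- annotations[order(genome_ids, method = "radix")]
  frames <- lapply(annotations, function(a) {
    r <- a$records
    if (nrow(r) == 0L) return(NULL)
    data.frame(tagged_id = paste0(a$genome_id, separator, r$gene_id),
               genome_id = a$genome_id, original_id = r$gene_id,
               dna = r$dna, aa = r$aa, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, c(frames, list(
    data.frame(tagged_id = character(0), genome_id = character(0),
               original_id = character(0), dna = character(0),
               aa = character(0)))))
  dup <- unique(records$tagged_id[duplicated(records$tagged_id)])
  if (length(dup) > 0L) {
    stop("tagged_id collision(s): ", paste(utils::head(dup, 5L),
                                           collapse = ", "))
  }
  dna <- stats::setNames(records$dna, records$tagged_id)
  aa_all <- stats::setNames(records$aa, records$tagged_id)
  aa <- aa_all[!is.na(aa_all)]
  if (!is.null(out_prefix)) {
    write_fasta(dna, paste0(out_prefix, "_combined.fasta"))
    write_fasta(aa, paste0(out_prefix, "_combined_aa.fasta"))
    utils::write.table(
      records[c("tagged_id", "genome_id", "original_id")],
      paste0(out_prefix, "_id_map.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(records = records, dna = dna, aa = aa,
       id_map = records[c("tagged_id", "genome_id", "original_id")])
}

#' Recover genome and gene IDs from tagged sequence IDs
#'
#' Inverse of the tagging in [tag_and_combine()]: splits on the first
#' occurrence of the separator.
#'
#' @param tagged_ids character vector of `genome|gene` IDs.
#' @param separator the tag separator.
#' @return data.frame with `tagged_id`, `genome_id`, `original_id`.
#' @export
split_tagged_ids <- function(tagged_ids, separator = "|") {
  pos <- regexpr(separator, tagged_ids, fixed = TRUE)
  missing <- tagged_ids[pos < 0L]
  if (length(missing) > 0L) {
    stop("seq_id(s) without separator '", separator, "': ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  data.frame(
    tagged_id = tagged_ids,
    genome_id = substr(tagged_ids, 1L, pos - 1L),
    original_id = substr(tagged_ids, pos + nchar(separator),
                         nchar(tagged_ids)),
    stringsAsFactors = FALSE)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector (names become headers).
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read FASTA into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector; names are the first whitespace-delimited
#'   word of each header.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  stats::setNames(as.character(set), names(set))
}
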