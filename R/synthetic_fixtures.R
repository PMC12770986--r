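#' Specification for a synthetic pangenome with planted structure
#'
#' Describes a toy multi-genome pangenome: core families present in every
#' genome, accessory families with sampled presence fractions, optional
#' paralogs (within-genome duplicates), per-site substitution noise, and
#' optional gene fragmentation (a gene split into two partial features, the
#' annotation-error mode that pushes families into lower presence bands).
#' Generation is a pure function of the spec: the same seed yields
#' byte-identical files.
#'
#' Ancestor sequences are random-uniform codon strings (ATG + non-stop
#' codons + stop), 300-1500 nt; no biological realism is claimed - what
#' matters is controllable identity structure between and within families.
#'
#' @param n_genomes number of genomes.
#' @param n_core number of core families (present in all genomes).
#' @param n_accessory number of accessory families.
#' @param presence_dist sampler for per-accessory-family presence fractions:
#'   a function of `n` returning fractions in (0, 1]. The default draws
#'   uniformly from `[0.1, 0.9]`, spreading families over the shell and
#'   cloud bands.
#' @param paralog_rate fraction of (family, genome) slots receiving a
#'   duplicated gene.
#' @param mutation_rate per-site substitution probability applied
#'   independently per genome copy.
#' @param fragment_rate fraction of genes split into two partial features.
#' @param seed integer RNG seed.
#' @return a `pangenome_spec` list.
#' @export
pangenome_spec <- function(n_genomes, n_core, n_accessory = 0L,
                           presence_dist = function(n)
                             stats::runif(n, 0.1, 0.9),
                           paralog_rate = 0, mutation_rate = 0,
                           fragment_rate = 0, seed = 1L) {
  rates <- c(paralog_rate, mutation_rate, fragment_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (n_genomes < 1L || n_core + n_accessory < 1L) {
    stop("need at least one genome and one family")
  }
  structure(list(n_genomes = as.integer(n_genomes),
                 n_core = as.integer(n_core),
                 n_accessory = as.integer(n_accessory),
                 presence_dist = presence_dist,
                 paralog_rate = paralog_rate,
                 mutation_rate = mutation_rate,
                 fragment_rate = fragment_rate,
                 seed = as.integer(seed)),
            class = "pangenome_spec")
}

.sense_codons <- setdiff(
  do.call(paste0, expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G"))),
  c("TAA", "TAG", "TGA"))

random_codon_gene <- function(n_codons) {
  paste0("ATG", paste(sample(.sense_codons, n_codons, replace = TRUE),
                      collapse = ""), "TAA")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  idx <- which(stats::runif(length(chars)) < rate)
  if (length(idx) > 0L) {
    bases <- c("A", "C", "G", "T")
    shift <- sample.int(3L, length(idx), replace = TRUE)
    chars[idx] <- bases[(match(chars[idx], bases) - 1L + shift) %% 4L + 1L]
  }
  paste(chars, collapse = "")
}

random_spacer <- function() {
  paste(sample(c("A", "C", "G", "T"), sample(20:50, 1L), replace = TRUE),
        collapse = "")
}

# run code under the spec's seed without disturbing the caller's RNG state
with_spec_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic pangenome as per-genome GFF3+FASTA files
#'
#' Writes one GFF3 file (with embedded `##FASTA`) per genome into `dir`,
#' plus a `truth.tsv` listing every gene's family, genome and the planted
#' presence band under the given scheme (computed from the realised genome
#' presence of each family). Fragmented genes are emitted as two consecutive
#' CDS features and marked in the truth table. Roughly a quarter of genes
#' are placed on the reverse strand so strand handling is exercised
#' end-to-end.
#'
#' @param spec a [pangenome_spec()].
#' @param dir output directory (created if needed).
#' @param scheme scheme used for the planted band labels.
#' @return invisibly, a list with `dir`, `truth` (data.frame `genome_id`,
#'   `gene_id`, `tagged_id`, `family_id`, `band`, `fragmented`), `ancestors`
#'   (named character vector of family ancestor sequences), `genomes` and
#'   `presence` (named list family -> genome vector).
#' @export
generate_pangenome <- function(spec, dir, scheme = default_scheme()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_spec_seed(spec$seed, {
    genomes <- sprintf("genome%03d", seq_len(spec$n_genomes))
    fam_ids <- c(sprintf("core%04d", seq_len(spec$n_core)),
                 if (spec$n_accessory > 0L)
                   sprintf("acc%04d", seq_len(spec$n_accessory)))
    is_core <- startsWith(fam_ids, "core")

    ancestors <- stats::setNames(vapply(fam_ids, function(f)
      random_codon_gene(sample(98:498, 1L)), character(1)), fam_ids)

    presence <- stats::setNames(vector("list", length(fam_ids)), fam_ids)
    for (fi in seq_along(fam_ids)) {
      if (is_core[[fi]]) {
        presence[[fi]] <- genomes
      } else {
        frac <- spec$presence_dist(1L)
        n_present <- max(1L, min(spec$n_genomes,
                                 round(frac * spec$n_genomes)))
        presence[[fi]] <- sort(sample(genomes, n_present), method = "radix")
      }
    }
    band_of <- stats::setNames(
      classify_family(lengths(presence), spec$n_genomes, scheme), fam_ids)

    truth_rows <- list()
    for (g in genomes) {
      fams_here <- fam_ids[vapply(presence, function(p) g %in% p,
                                  logical(1))]
      contig_parts <- random_spacer()
      gff <- c("##gff-version 3")
      pos <- nchar(contig_parts)
      emit <- function(gene_id, fam, seq, fragmented) {
        strand <- if (stats::runif(1L) < 0.25) "-" else "+"
        placed <- if (strand == "-") revcomp_chr(seq) else seq
        start <- pos + 1L
        end <- pos + nchar(seq)
        contig_parts <<- paste0(contig_parts, placed, random_spacer())
        pos <<- nchar(contig_parts)
        gff <<- c(gff, paste(paste0(g, "_c1"), "panfam_sim", "CDS",
                             start, end, ".", strand, "0",
                             paste0("ID=", gene_id), sep = "\t"))
        truth_rows[[length(truth_rows) + 1L]] <<- c(g, gene_id, fam,
                                                    fragmented)
      }
      for (fam in fams_here) {
        n_copies <- 1L + (stats::runif(1L) < spec$paralog_rate)
        for (copy in seq_len(n_copies)) {
          gene <- mutate_seq(ancestors[[fam]], spec$mutation_rate)
          base_id <- if (copy == 1L) paste0(fam, "_", g) else
            paste0(fam, "_", g, "_p", copy)
          if (stats::runif(1L) < spec$fragment_rate) {
            cut <- sample(seq(60L, nchar(gene) - 60L), 1L)
            emit(paste0(base_id, "_f1"), fam, substr(gene, 1L, cut), TRUE)
            emit(paste0(base_id, "_f2"), fam,
                 substr(gene, cut + 1L, nchar(gene)), TRUE)
          } else {
            emit(base_id, fam, gene, FALSE)
          }
        }
      }
      gff <- c(gff, "##FASTA", paste0(">", g, "_c1"))
      seq <- contig_parts
      starts <- seq(1L, nchar(seq), by = 60L)
      gff <- c(gff, substring(seq, starts,
                              pmin(starts + 59L, nchar(seq))))
      writeLines(gff, file.path(dir, paste0(g, ".gff")))
    }
    tr <- do.call(rbind, truth_rows)
    truth <- data.frame(
      genome_id = tr[, 1L], gene_id = tr[, 2L],
      tagged_id = paste0(tr[, 1L], "|", tr[, 2L]), family_id = tr[, 3L],
      band = unname(band_of[tr[, 3L]]),
      fragmented = as.logical(tr[, 4L]), stringsAsFactors = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(list(dir = dir, truth = truth, ancestors = ancestors,
                   genomes = genomes, presence = presence))
  })
}

#' Generate second-round sequences with known expected recluster tracks
#'
#' Emits three kinds of additional ("second round") sequences against a
#' generated pangenome, each with a planted expectation for the recluster
#' tracking category:
#' \itemize{
#'   \item gap-fillers: copies of an accessory family's ancestor for every
#'     genome the family was absent from, lifting it to full presence
#'     (expected track `extended`);
#'   \item bridges: concatenations of two core-family ancestors, emitted in
#'     a couple of genomes; under a relaxed length-difference cutoff they
#'     merge the two origin families (expected track `combined`);
#'   \item novel families: a fresh ancestor present in every genome
#'     (expected track `only_second`).
#' }
#' New sequence IDs are genome-tagged and disjoint from the first round.
#'
#' @param spec the [pangenome_spec()] the pangenome was generated from.
#' @param pg the return value of [generate_pangenome()].
#' @param n_fill number of accessory families to gap-fill (capped at the
#'   number of partially present accessory families).
#' @param n_bridge number of core-family pairs to bridge.
#' @param n_novel number of novel families.
#' @return list with `sequences` (named character vector of new sequences,
#'   tagged IDs) and `expected` (data.frame `new_seq_id`, `kind`,
#'   `expected_track`, `origin_family_ids` list-column).
#' @export
generate_second_round <- function(spec, pg, n_fill = 2L, n_bridge = 1L,
                                  n_novel = 1L) {
  with_spec_seed(spec$seed + 9973L, {
    genomes <- pg$genomes
    seqs <- character(0)
    rows <- list()
    add <- function(id, seq, kind, track, origins) {
      seqs[[id]] <<- seq
      rows[[length(rows) + 1L]] <<- data.frame(
        new_seq_id = id, kind = kind, expected_track = track,
        origins = I(list(origins)), stringsAsFactors = FALSE)
    }
    acc <- names(pg$presence)[startsWith(names(pg$presence), "acc")]
    partial <- acc[lengths(pg$presence[acc]) < length(genomes)]
    fill_fams <- utils::head(partial, n_fill)
    for (fam in fill_fams) {
      absent <- setdiff(genomes, pg$presence[[fam]])
      for (g in absent) {
        add(paste0(g, "|new_fill_", fam),
            mutate_seq(pg$ancestors[[fam]], spec$mutation_rate),
            "gap_filler", "extended", fam)
      }
    }
    cores <- names(pg$presence)[startsWith(names(pg$presence), "core")]
    cores <- setdiff(cores, fill_fams)
    for (bi in seq_len(n_bridge)) {
      pair <- cores[c(2L * bi - 1L, 2L * bi)]
      bridge <- paste0(pg$ancestors[[pair[[1]]]], pg$ancestors[[pair[[2]]]])
      for (g in utils::head(genomes, 2L)) {
        add(paste0(g, "|new_bridge_", bi), bridge, "bridge", "combined",
            pair)
      }
    }
    for (ni in seq_len(n_novel)) {
      anc <- random_codon_gene(sample(98:498, 1L))
      for (g in genomes) {
        add(paste0(g, "|new_novel", ni, "_", g),
            mutate_seq(anc, spec$mutation_rate),
            "novel", "only_second", character(0))
      }
    }
    expected <- do.call(rbind, rows)
    names(expected)[names(expected) == "origins"] <- "origin_family_ids"
    list(sequences = seqs, expected = expected)
  })
}
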