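#' Parse a Newick tree
#'
#' Thin wrapper over `ape::read.tree` with the validation this package
#' needs: leaf labels must be unique, and the text must be well-formed.
#' Branch lengths are kept but ignored by all topology comparisons here.
#'
#' @param text Newick string (or a file path via `file`).
#' @param file optional path to a Newick file.
#' @return an `ape` `phylo` object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(file)) ape::read.tree(file) else
    ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick input")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  }
  tr
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

# Non-trivial bipartitions (splits) of an unrooted tree, as canonical keys.
# Each internal edge defines a split; the canonical side is the one NOT
# containing the alphabetically first leaf, sorted and joined. Sides of size
# < 2 (or > n-2) are trivial and dropped.
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  if (n < 3L) stop("RF splits require >= 3 leaves")
  anchor <- sort(tree$tip.label, method = "radix")[[1]]
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  keys <- character(0)
  for (clade in pp) {
    side <- labels[clade]
    if (anchor %in% side) side <- setdiff(labels, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    keys <- c(keys, paste(sort(side, method = "radix"), collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' The symmetric-difference count over non-trivial bipartitions, normalised
#' by the maximum attainable for this pair: the total number of non-trivial
#' splits in the two trees (`|splits(t1)| + |splits(t2)|`). For fully binary
#' trees this equals the usual `2(n-3)`; for multifurcating trees it shrinks
#' with the resolved split count, keeping the normalised value in `[0, 1]`.
#' Branch lengths are ignored.
#'
#' @param t1,t2 `phylo` objects over identical leaf sets (>= 3 leaves).
#' @return list with `rf` (integer symmetric difference), `max_rf` and
#'   `normalised` (`rf / max_rf`; 0 when both trees are stars and no split
#'   exists to disagree on).
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label, method = "radix")
  l2 <- sort(t2$tip.label, method = "radix")
  if (!identical(l1, l2)) {
    stop("leaf sets differ; only in t1: ",
         paste(setdiff(l1, l2), collapse = ", "),
         "; only in t2: ", paste(setdiff(l2, l1), collapse = ", "))
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  max_rf <- length(s1) + length(s2)
  list(rf = rf, max_rf = max_rf,
       normalised = if (max_rf == 0L) 0 else rf / max_rf)
}

#' All-versus-all normalised RF matrix
#'
#' @param trees named list of `phylo` objects over one leaf set.
#' @return symmetric numeric matrix of normalised RF distances with zero
#'   diagonal.
#' @export
rf_matrix <- function(trees) {
  n <- length(trees)
  nm <- names(trees)
  if (is.null(nm)) nm <- paste0("tree", seq_len(n))
  out <- matrix(0, n, n, dimnames = list(nm, nm))
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- rf_distance(trees[[i]], trees[[j]])$normalised
      out[i, j] <- d
      out[j, i] <- d
    }
  }
  out
}

#' Select one gene per genome (and a family representative) from a family
#'
#' Representative choice is a known source of misleading downstream results:
#' the conventional longest-sequence policy can pick a gene whose function
#' differs from every other member of the family. Three policies are
#' offered:
#' \describe{
#'   \item{`longest`}{maximum length, ties broken lexicographically by ID
#'     (the conventional default).}
#'   \item{`medoid_length`}{the gene minimising the total absolute length
#'     deviation from all family members - a length-typical member.}
#'   \item{`cluster_rep`}{the stored cluster representative where it belongs
#'     to the genome in question, else the longest.}
#' }
#'
#' @param family a gene family (element of a `pangenome_result`'s
#'   `families`).
#' @param sequences named character vector covering the member IDs.
#' @param policy `"longest"`, `"medoid_length"` or `"cluster_rep"`.
#' @return list with `per_genome` (data.frame `genome_id`, `gene_id`,
#'   `length`; one row per genome) and `representative` (the single
#'   family-level gene chosen by the same policy over all members).
#' @export
select_family_representatives <- function(family, sequences,
                                          policy = c("longest",
                                                     "medoid_length",
                                                     "cluster_rep")) {
  policy <- match.arg(policy)
  all_ids <- unlist(family$members_by_genome, use.names = FALSE)
  missing <- setdiff(all_ids, names(sequences))
  if (length(missing) > 0L) {
    stop("missing sequence(s): ", paste(utils::head(missing, 5L),
                                        collapse = ", "))
  }
  all_len <- nchar(sequences[all_ids])
  pick <- function(ids) {
    lens <- nchar(sequences[ids])
    scored <- switch(policy,
      longest = order(-lens, ids, method = "radix"),
      medoid_length = {
        dev <- vapply(lens, function(l) sum(abs(all_len - l)), numeric(1))
        order(dev, ids, method = "radix")
      },
      cluster_rep = {
        if (family$representative_id %in% ids) {
          return(which(ids == family$representative_id))
        }
        order(-lens, ids, method = "radix")
      })
    scored[[1]]
  }
  per_genome <- do.call(rbind, lapply(names(family$members_by_genome),
    function(g) {
      ids <- family$members_by_genome[[g]]
      chosen <- ids[[pick(ids)]]
      data.frame(genome_id = g, gene_id = chosen,
                 length = nchar(sequences[[chosen]]),
                 stringsAsFactors = FALSE)
    }))
  rownames(per_genome) <- NULL
  representative <- all_ids[[pick(all_ids)]]
  list(per_genome = per_genome, representative = representative)
}

#' Concatenate per-family alignments into a core super-alignment
#'
#' Per-genome concatenation in a fixed family order. A genome missing from a
#' family is padded with gap characters of that family's alignment width, so
#' every output row has width equal to the sum of the family widths.
#'
#' @param per_family_alignments named list; each element is a named character
#'   vector (genome -> aligned sequence, equal widths within the family).
#' @param genomes character vector of genomes defining the output rows;
#'   defaults to the union of genomes seen, sorted.
#' @return named character vector (genome -> concatenated alignment row).
#' @export
concatenate_core_alignment <- function(per_family_alignments,
                                       genomes = NULL) {
  if (is.null(genomes)) {
    genomes <- sort(unique(unlist(lapply(per_family_alignments, names))),
                    method = "radix")
  }
  rows <- stats::setNames(rep("", length(genomes)), genomes)
  for (fam in names(per_family_alignments)) {
    aln <- per_family_alignments[[fam]]
    widths <- unique(nchar(aln))
    if (length(widths) != 1L) {
      stop("ragged alignment in family '", fam, "': widths ",
           paste(widths, collapse = ", "))
    }
    pad <- strrep("-", widths)
    for (g in genomes) {
      rows[[g]] <- paste0(rows[[g]],
                          if (g %in% names(aln)) aln[[g]] else pad)
    }
  }
  rows
}

#' Align a gene family with an external aligner
#'
#' Subprocess contract around MAFFT (or a compatible FASTA-in, aligned
#' FASTA-out command): the input sequences are written to a temporary FASTA,
#' the aligner is run with quiet output, and a non-zero exit raises an error
#' carrying the captured stderr. Degapping the output recovers the input
#' sequences.
#'
#' @param seqs named character vector of unaligned sequences.
#' @param aligner_cmd the aligner executable (default `"mafft"`); must be on
#'   `PATH`.
#' @param args extra command-line arguments (default `"--auto"` plus quiet
#'   output).
#' @return named character vector of aligned sequences (equal widths).
#' @export
align_family <- function(seqs, aligner_cmd = "mafft",
                         args = c("--auto", "--quiet")) {
  if (Sys.which(aligner_cmd) == "") {
    stop("aligner '", aligner_cmd, "' not found on PATH")
  }
  infile <- tempfile(fileext = ".fasta")
  outfile <- tempfile(fileext = ".fasta")
  errfile <- tempfile(fileext = ".log")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)
  write_fasta(seqs, infile)
  status <- system2(aligner_cmd, c(args, shQuote(infile)),
                    stdout = outfile, stderr = errfile)
  if (status != 0L) {
    stop("aligner '", aligner_cmd, "' exited with status ", status, ": ",
         paste(readLines(errfile, warn = FALSE), collapse = " | "))
  }
  aln <- read_fasta(outfile)
  toupper(aln)
}
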