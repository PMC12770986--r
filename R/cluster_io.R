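#' Construct a ClusterSet
#'
#' A `cluster_set` is a partition of sequence IDs into clusters, the common
#' currency between the clusterer, the CD-HIT `.clstr` reader/writer and
#' pangenome inference. It is stored as a long-format member table with one
#' row per sequence.
#'
#' @param members data.frame with columns `cluster` (0-based integer index),
#'   `seq_id` (character), `length` (integer, `NA` when unknown),
#'   `identity_pct` (numeric percent identity to the representative, `NA` for
#'   the representative itself), `strand` (`"+"`, `"-"` or `NA`), and `is_rep`
#'   (logical, exactly one `TRUE` per cluster).
#' @param unit length unit, `"nt"` or `"aa"`; controls `.clstr` output.
#'
#' @return An object of class `cluster_set`: a list with elements `members`
#'   (the validated table, ordered by cluster then file/member order),
#'   `universe` (all seq_ids) and `unit`.
#' @export
cluster_set <- function(members, unit = c("nt", "aa")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(members))
  required <- c("cluster", "seq_id", "length", "identity_pct", "strand", "is_rep")
  missing_cols <- setdiff(required, names(members))
  if (length(missing_cols) > 0L) {
    stop("cluster_set members table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  members <- members[required]
  members$cluster <- as.integer(members$cluster)
  members$seq_id <- as.character(members$seq_id)
  members$length <- as.integer(members$length)
  members$identity_pct <- as.numeric(members$identity_pct)
  members$strand <- as.character(members$strand)
  members$is_rep <- as.logical(members$is_rep)
  cs <- structure(
    list(members = members,
         universe = members$seq_id,
         unit = unit),
    class = "cluster_set")
  validate_cluster_set(cs)
  cs
}

#' Assert the partition invariants of a ClusterSet
#'
#' Every seq_id appears exactly once; every cluster has at least one member
#' and exactly one representative. Called after every parse/derive operation
#' rather than assumed.
#'
#' @param cs a `cluster_set`.
#' @return `cs`, invisibly.
#' @export
validate_cluster_set <- function(cs) {
  m <- cs$members
  dup <- unique(m$seq_id[duplicated(m$seq_id)])
  if (length(dup) > 0L) {
    stop("cluster_set is not a partition; duplicated seq_id(s): ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (nrow(m) > 0L) {
    reps_per_cluster <- tapply(m$is_rep, m$cluster, sum)
    bad <- names(reps_per_cluster)[reps_per_cluster != 1L]
    if (length(bad) > 0L) {
      stop("cluster(s) without exactly one representative: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    if (any(!is.na(m$identity_pct) & m$is_rep)) {
      stop("representative members must not carry identity_pct")
    }
  }
  invisible(cs)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d sequences in %d clusters (%s)\n",
              nrow(x$members), n_clusters(x), x$unit))
  invisible(x)
}

#' Number of clusters in a ClusterSet
#' @param cs a `cluster_set`.
#' @return integer count.
#' @export
n_clusters <- function(cs) {
  length(unique(cs$members$cluster))
}

#' Representative IDs of a ClusterSet
#' @param cs a `cluster_set`.
#' @return data.frame with columns `cluster`, `representative_id`.
#' @export
representatives <- function(cs) {
  m <- cs$members[cs$members$is_rep, c("cluster", "seq_id")]
  names(m) <- c("cluster", "representative_id")
  rownames(m) <- NULL
  m[order(m$cluster), , drop = FALSE]
}

# CD-HIT prints member identities with exactly two decimals; keep that.
format_pid <- function(x) sprintf("%.2f", x)

#' Parse a CD-HIT `.clstr` file
#'
#' Reads the CD-HIT cluster report dialect: `>Cluster N` headers followed by
#' member lines such as
#' `1\t249nt, >gA|gene7... at +/98.39%` (nucleotide mode, strand reported),
#' `1\t83aa, >gA|gene7... at 98.39%` (amino-acid mode), and the representative
#' marked with a terminal `*`. Header IDs are stored exactly as printed,
#' i.e. possibly truncated by the producer (the text before `...`).
#'
#' @param path path to a `.clstr` file.
#' @return a [cluster_set()].
#' @export
parse_clstr <- function(path) {
  lines <- readLines(path)
  unit <- "nt"
  cluster <- integer(0); seq_id <- character(0); len <- integer(0)
  pid <- numeric(0); strand <- character(0); is_rep <- logical(0)
  current <- NA_integer_
  members_in_current <- 0L
  member_re <- "^[0-9]+\t([0-9]+)(nt|aa), >(.*)\\.\\.\\. (.*)$"
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "") next
    if (startsWith(line, ">Cluster")) {
      if (!is.na(current) && members_in_current == 0L) {
        stop("cluster ", current, " has zero members")
      }
      idx <- suppressWarnings(as.integer(sub("^>Cluster\\s+", "", line)))
      if (is.na(idx)) stop("malformed cluster header at line ", i, ": ", line)
      current <- idx
      members_in_current <- 0L
      next
    }
    if (is.na(current)) stop("member line before any cluster header at line ", i)
    mt <- regmatches(line, regexec(member_re, line))[[1]]
    if (length(mt) == 0L) stop("unparseable member line at line ", i, ": ", line)
    unit <- mt[[3]]
    suffix <- mt[[5]]
    if (suffix == "*") {
      this_pid <- NA_real_; this_strand <- NA_character_; rep_flag <- TRUE
    } else {
      rep_flag <- FALSE
      am <- regmatches(suffix,
                       regexec("^at (?:([+-])/)?([0-9.]+)%$", suffix))[[1]]
      if (length(am) == 0L) stop("unparseable member suffix at line ", i, ": ", line)
      this_strand <- if (am[[2]] == "") NA_character_ else am[[2]]
      this_pid <- as.numeric(am[[3]])
    }
    cluster <- c(cluster, current)
    seq_id <- c(seq_id, mt[[4]])
    len <- c(len, as.integer(mt[[2]]))
    pid <- c(pid, this_pid)
    strand <- c(strand, this_strand)
    is_rep <- c(is_rep, rep_flag)
    members_in_current <- members_in_current + 1L
  }
  if (!is.na(current) && members_in_current == 0L) {
    stop("cluster ", current, " has zero members")
  }
  cs <- cluster_set(
    data.frame(cluster = cluster, seq_id = seq_id, length = len,
               identity_pct = pid, strand = strand, is_rep = is_rep,
               stringsAsFactors = FALSE),
    unit = unit)
  cs
}

#' Write a ClusterSet in CD-HIT `.clstr` dialect
#'
#' Emits exactly the dialect [parse_clstr()] accepts; cluster and member order
#' are preserved, so parse -> write -> parse is a fixpoint.
#'
#' @param cs a `cluster_set`; member lengths must be present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(cs, path) {
  validate_cluster_set(cs)
  m <- cs$members
  if (nrow(m) > 0L && anyNA(m$length)) {
    stop("write_clstr requires member lengths")
  }
  out <- character(0)
  for (cl in unique(m$cluster)) {
    rows <- m[m$cluster == cl, , drop = FALSE]
    out <- c(out, sprintf(">Cluster %d", cl))
    for (j in seq_len(nrow(rows))) {
      r <- rows[j, ]
      suffix <- if (r$is_rep) {
        "*"
      } else if (!is.na(r$strand)) {
        sprintf("at %s/%s%%", r$strand, format_pid(r$identity_pct))
      } else {
        sprintf("at %s%%", format_pid(r$identity_pct))
      }
      out <- c(out, sprintf("%d\t%d%s, >%s... %s",
                            j - 1L, r$length, cs$unit, r$seq_id, suffix))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Parse a two-column edge list
#'
#' Reads any tab-separated file whose first two columns name related
#' sequences (BLAST tabular / outfmt 6 is accepted; columns beyond the second
#' are ignored). Self-edges are dropped (the node is still recorded) and
#' duplicate/reversed edges are collapsed.
#'
#' @param path path to the TSV file.
#' @param universe optional character vector of seq_ids; nodes seen in the
#'   file are added to it.
#' @return list with `edges` (two-column character matrix, lexicographically
#'   ordered endpoints) and `nodes` (all seq_ids observed, plus `universe`).
#' @export
parse_edge_list <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[lines != ""]
  a <- character(0); b <- character(0); nodes <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stop("edge list line ", i, " has fewer than 2 tab-separated columns")
    }
    n1 <- fields[[1]]; n2 <- fields[[2]]
    nodes <- c(nodes, n1, n2)
    if (n1 == n2) next
    lo <- min(n1, n2); hi <- max(n1, n2)
    a <- c(a, lo); b <- c(b, hi)
  }
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  nodes <- unique(c(nodes, universe))
  list(edges = cbind(node1 = a[keep], node2 = b[keep]),
       nodes = sort(nodes, method = "radix"))
}

#' Derive clusters from an edge set via connected components
#'
#' Clusters are the connected components of the undirected relationship
#' graph. Sequences present in `universe` but absent from any edge become
#' singletons. The representative is the longest member when `lengths` are
#' supplied (ties broken lexicographically), otherwise the lexicographically
#' smallest seq_id. Edge lists carry no identities, so `identity_pct` is
#' absent for every member.
#'
#' @param edges two-column character matrix (or the `edges` element of
#'   [parse_edge_list()] output).
#' @param universe character vector of all seq_ids (must cover all edge
#'   endpoints).
#' @param lengths optional named integer vector of sequence lengths.
#' @return a [cluster_set()]. Components are indexed in order of their
#'   lexicographically smallest member, making the result invariant to edge
#'   order and direction.
#' @export
clusters_from_edges <- function(edges, universe, lengths = NULL) {
  if (is.list(edges) && !is.null(edges$edges)) {
    if (missing(universe)) universe <- edges$nodes
    edges <- edges$edges
  }
  universe <- unique(as.character(universe))
  endpoints <- unique(as.character(edges))
  outside <- setdiff(endpoints, universe)
  if (length(outside) > 0L) {
    stop("edge endpoint(s) not in universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(universe), name = universe)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, t(matrix(match(edges, universe), ncol = 2L)))
  }
  comp <- igraph::components(g)$membership
  groups <- split(universe, comp)
  # deterministic ordering: by smallest member id
  groups <- groups[order(vapply(groups, min, character(1)), method = "radix")]
  rows <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    ids <- sort(groups[[k]], method = "radix")
    if (is.null(lengths)) {
      rep_id <- ids[[1]]
      lens <- rep(NA_integer_, length(ids))
    } else {
      lens <- as.integer(lengths[ids])
      ord <- order(-lens, ids, method = "radix")
      rep_id <- ids[ord][[1]]
    }
    rows[[k]] <- data.frame(
      cluster = k - 1L, seq_id = ids, length = lens,
      identity_pct = NA_real_, strand = NA_character_,
      is_rep = ids == rep_id, stringsAsFactors = FALSE)
  }
  members <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(cluster = integer(0), seq_id = character(0),
               length = integer(0), identity_pct = numeric(0),
               strand = character(0), is_rep = logical(0))
  cluster_set(members)
}
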