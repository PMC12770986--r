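# A hand-built first round over 10 genomes:
#   famA: present in 7/10 (shell), famB/famC: core, famD: singleton cloud.
make_first_round <- function() {
  genomes <- sprintf("g%02d", 1:10)
  fams <- list(
    famA = stats::setNames(lapply(genomes[1:7], function(g)
      paste0(g, "|a_", g)), genomes[1:7]),
    famB = stats::setNames(lapply(genomes, function(g)
      paste0(g, "|b_", g)), genomes),
    famC = stats::setNames(lapply(genomes, function(g)
      paste0(g, "|c_", g)), genomes),
    famD = list(g01 = "g01|d_g01"))
  make_pangenome(fams, genomes)
}

# cluster_set from a list of id vectors (first member = representative)
combined_cs <- function(groups) make_cluster_set(groups)

first_ids <- function(first) {
  unlist(lapply(first$families, function(f)
    unlist(f$members_by_genome, use.names = FALSE)), use.names = FALSE)
}

fam_members <- function(first, fid) {
  f <- Filter(function(x) x$family_id == fid, first$families)[[1]]
  unlist(f$members_by_genome, use.names = FALSE)
}

test_that("gap-filling new sequences yield an extended family", {
  first <- make_first_round()
  new_ids <- paste0(sprintf("g%02d", 8:10), "|new_a")
  groups <- list(c(fam_members(first, "famA"), new_ids),
                 fam_members(first, "famB"),
                 fam_members(first, "famC"),
                 fam_members(first, "famD"))
  rep <- recluster(first, combined_cs(groups), new_ids)
  fams <- rep$families
  ext <- fams[fams$track == "extended", ]
  expect_equal(nrow(ext), 1L)
  expect_equal(ext$band, "First_core_99") # 10/10 genomes now
  expect_equal(ext$origin_family_ids[[1]], "famA")
  expect_equal(sort(fams$track), sort(c("extended", rep("first", 3))))
})

test_that("a bridging sequence merging two families is tracked as combined", {
  first <- make_first_round()
  new_ids <- "g01|bridge"
  groups <- list(c(fam_members(first, "famB"), fam_members(first, "famC"),
                   new_ids),
                 fam_members(first, "famA"),
                 fam_members(first, "famD"))
  rep <- recluster(first, combined_cs(groups), new_ids)
  comb <- rep$families[rep$families$track == "combined", ]
  expect_equal(nrow(comb), 1L)
  expect_setequal(comb$origin_family_ids[[1]], c("famB", "famC"))
})

test_that("clusters of only new sequences are only_second", {
  first <- make_first_round()
  new_ids <- paste0(sprintf("g%02d", 1:10), "|novel")
  groups <- c(list(new_ids),
              lapply(c("famA", "famB", "famC", "famD"),
                     function(f) fam_members(first, f)))
  rep <- recluster(first, combined_cs(groups), new_ids)
  os <- rep$families[rep$families$track == "only_second", ]
  expect_equal(nrow(os), 1L)
  expect_equal(os$band, "First_core_99")
  expect_equal(os$n_old, 0L)
})

test_that("a band attained only through new genomes in a split is second", {
  first <- make_first_round()
  # famB (core) fragments: 6 old members + 4 gap-replacing new sequences
  # reach core only with the new genomes counted; the stray 4 old members
  # form a separate cloud cluster.
  b <- fam_members(first, "famB")
  new_ids <- paste0(sprintf("g%02d", 7:10), "|nb")
  groups <- list(c(b[1:6], new_ids), b[7:10],
                 fam_members(first, "famA"),
                 fam_members(first, "famC"),
                 fam_members(first, "famD"))
  rep <- recluster(first, combined_cs(groups), new_ids)
  fams <- rep$families
  expect_equal(fams$track[[1]], "second") # 10/10 with new, 6/10 without
  # fragmentation of famB is reported, not silently absorbed
  frag <- rep$fragmentation
  expect_true(frag$fragmented[frag$origin_family_id == "famB"])
  expect_equal(frag$n_clusters[frag$origin_family_id == "famB"], 2L)
  expect_false(any(frag$fragmented[frag$origin_family_id != "famB"]))
})

test_that("no-op integration keeps every family on the first track", {
  first <- make_first_round()
  groups <- lapply(c("famA", "famB", "famC", "famD"),
                   function(f) fam_members(first, f))
  rep <- recluster(first, combined_cs(groups), character(0))
  expect_true(all(rep$families$track == "first"))
  # bands bit-identical to round one
  got <- stats::setNames(rep$families$band,
                         vapply(rep$families$origin_family_ids,
                                `[[`, character(1), 1L))
  want <- stats::setNames(
    vapply(first$families, function(f) f$category, character(1)),
    vapply(first$families, function(f) f$family_id, character(1)))
  expect_identical(got[names(want)], want)
  expect_false(any(rep$fragmentation$fragmented))
})

test_that("recluster rejects inconsistent inputs", {
  first <- make_first_round()
  groups <- lapply(c("famA", "famB", "famC", "famD"),
                   function(f) fam_members(first, f))
  # claimed-new id that already exists in round one
  expect_error(recluster(first, combined_cs(groups), "g01|a_g01"),
               "overlap")
  # old sequence unknown to round one
  groups2 <- c(groups, list("g01|stray"))
  expect_error(recluster(first, combined_cs(groups2), character(0)),
               "absent from first round")
})

test_that("old sequences are conserved across any reclustering", {
  first <- make_first_round()
  set.seed(101)
  ids <- first_ids(first)
  for (rep_i in 1:5) {
    # random regrouping of old ids plus a few new ones
    new_ids <- sprintf("g%02d|extra%d", sample(1:10, 3), 1:3)
    all_ids <- c(ids, new_ids)
    assignment <- sample(1:6, length(all_ids), replace = TRUE)
    groups <- split(all_ids, assignment)
    rep <- recluster(first, combined_cs(unname(groups)), new_ids)
    reported_old <- unlist(rep$families$old_seq_ids)
    expect_setequal(reported_old, ids)
    expect_equal(length(reported_old), length(ids))
    expect_equal(sum(rep$totals$n), nrow(rep$families))
  }
})

test_that("the recluster summary covers the full track-band grid", {
  first <- make_first_round()
  new_ids <- paste0(sprintf("g%02d", 8:10), "|new_a")
  groups <- list(c(fam_members(first, "famA"), new_ids),
                 fam_members(first, "famB"),
                 fam_members(first, "famC"),
                 fam_members(first, "famD"))
  rep <- recluster(first, combined_cs(groups), new_ids)
  f <- withr::local_tempfile(fileext = ".txt")
  lines <- write_recluster_summary(rep, f)
  expect_true("extended_core_99: 1" %in% lines)
  expect_true("First_core_99: 2" %in% lines)
  expect_true("only_second_core_99: 0" %in% lines)
  counts <- as.integer(sub(".*: ", "", lines))
  expect_equal(sum(utils::head(counts, -1L)), nrow(rep$families))

  # empty addition: everything on the first track
  rep0 <- recluster(first, combined_cs(lapply(
    c("famA", "famB", "famC", "famD"),
    function(f) fam_members(first, f))), character(0))
  lines0 <- write_recluster_summary(rep0, f)
  nonfirst <- grep("^(extended|combined|second|only_second)_", lines0,
                   value = TRUE)
  expect_true(all(grepl(": 0$", nonfirst)))
})
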