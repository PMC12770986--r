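# one small synthetic pangenome shared by the workflow tests
workflow_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "panfam_wf_fixture")
      spec <- pangenome_spec(n_genomes = 6, n_core = 8, n_accessory = 4,
                             mutation_rate = 0.01, seed = 55)
      pg <- generate_pangenome(spec, d)
      cache <<- list(spec = spec, dir = d, pg = pg)
    }
    cache
  }
})

test_that("full mode recovers planted band counts and writes all outputs", {
  fx <- workflow_fixture()
  out <- withr::local_tempdir()
  cfg <- run_config("full", input_dir = fx$dir, output_dir = out)
  pr <- run_full(cfg)
  planted <- table(factor(fx$pg$truth$band[!duplicated(fx$pg$truth$family_id)],
                          levels = pr$scheme$name))
  expect_equal(unname(pr$totals), unname(as.integer(planted)))
  for (f in c("clusters.clstr", "gene_presence_absence.csv",
              "summary_statistics.txt", "pangenome.json",
              "provenance.json", "genes_combined.fasta",
              "genes_id_map.tsv")) {
    expect_true(file.exists(file.path(out, f)), info = f)
  }
  expect_true(dir.exists(file.path(out, "family_fastas")))
})

test_that("rerunning an identical configuration is byte-identical", {
  fx <- workflow_fixture()
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_full(run_config("full", input_dir = fx$dir, output_dir = out1,
                      threads = 1L))
  # a different declared thread count must not change any output
  run_full(run_config("full", input_dir = fx$dir, output_dir = out2,
                      threads = 8L))
  for (f in c("clusters.clstr", "gene_presence_absence.csv",
              "summary_statistics.txt")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
})

test_that("full and partial modes agree bit-exactly on the same clustering", {
  fx <- workflow_fixture()
  out_full <- withr::local_tempdir(); out_part <- withr::local_tempdir()
  run_full(run_config("full", input_dir = fx$dir, output_dir = out_full))
  seqs <- read_fasta(file.path(out_full, "genes_combined.fasta"))
  run_partial(run_config("partial",
                         clusters_file = file.path(out_full,
                                                   "clusters.clstr"),
                         output_dir = out_part),
              sequences = seqs)
  for (f in c("gene_presence_absence.csv", "summary_statistics.txt")) {
    expect_identical(readLines(file.path(out_full, f)),
                     readLines(file.path(out_part, f)), info = f)
  }
})

test_that("an edge list of the same partition yields the same band counts", {
  fx <- workflow_fixture()
  out_full <- withr::local_tempdir(); out_edges <- withr::local_tempdir()
  pr_full <- run_full(run_config("full", input_dir = fx$dir,
                                 output_dir = out_full))
  cs <- parse_clstr(file.path(out_full, "clusters.clstr"))
  # star edges within each cluster encode the same partition
  edges_file <- withr::local_tempfile(fileext = ".tsv")
  m <- cs$members
  reps <- representatives(cs)
  rep_of <- stats::setNames(reps$representative_id, reps$cluster)
  non_rep <- m[!m$is_rep, ]
  writeLines(c(paste(rep_of[as.character(non_rep$cluster)], non_rep$seq_id,
                     sep = "\t"),
               paste(m$seq_id[m$is_rep], m$seq_id[m$is_rep], sep = "\t")),
             edges_file)
  pr_edges <- run_partial(run_config("partial", clusters_file = edges_file,
                                     output_dir = out_edges))
  expect_identical(pr_edges$totals, pr_full$totals)
})

test_that("empty cluster input produces header-only outputs", {
  out <- withr::local_tempdir()
  empty <- withr::local_tempfile(fileext = ".clstr")
  writeLines(character(0), empty)
  pr <- run_partial(run_config("partial", clusters_file = empty,
                               output_dir = out))
  expect_equal(length(pr$families), 0L)
  expect_equal(length(readLines(file.path(out,
                                          "gene_presence_absence.csv"))),
               1L)
  stats_lines <- readLines(file.path(out, "summary_statistics.txt"))
  expect_true(all(grepl(": 0$", stats_lines)))
})

test_that("recluster mode recovers the planted second-round tracks", {
  fx <- workflow_fixture()
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_full(run_config("full", input_dir = fx$dir, output_dir = out1))
  sr <- generate_second_round(fx$spec, fx$pg)
  old <- read_fasta(file.path(out1, "genes_combined.fasta"))
  # combined clustering under the relaxed (CD-HIT default) length cutoff,
  # the regime in which long additions can actually merge families
  combined <- greedy_cluster(c(old, sr$sequences),
                             clustering_params(c = 0.90, s = 0.00))
  combined_file <- withr::local_tempfile(fileext = ".clstr")
  write_clstr(combined, combined_file)
  new_file <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sr$sequences, new_file)
  rep <- run_recluster(run_config("recluster", first_dir = out1,
                                  clusters_file = combined_file,
                                  new_fasta = new_file,
                                  output_dir = out2))
  fams <- rep$families
  # every new sequence lands in a family with its expected track
  for (i in seq_len(nrow(sr$expected))) {
    id <- sr$expected$new_seq_id[[i]]
    hit <- vapply(fams$new_seq_ids, function(v) id %in% v, logical(1))
    expect_equal(sum(hit), 1L)
    expect_equal(fams$track[hit], sr$expected$expected_track[[i]],
                 info = id)
    origins <- sr$expected$origin_family_ids[[i]]
    if (length(origins) > 0L) {
      # planted origin families map to first-round group ids
      expect_equal(length(fams$origin_family_ids[hit][[1]]),
                   length(origins))
    }
  }
  expect_true(file.exists(file.path(out2, "recluster_summary.txt")))
  expect_true(file.exists(file.path(out2, "fragmentation.tsv")))
  expect_true(file.exists(file.path(out2,
                                    "gene_presence_absence_recluster.csv")))
})

test_that("reclustering an unchanged clustering is the identity", {
  fx <- workflow_fixture()
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_full(run_config("full", input_dir = fx$dir, output_dir = out1))
  empty_new <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(character(0), empty_new)
  rep <- run_recluster(run_config(
    "recluster", first_dir = out1,
    clusters_file = file.path(out1, "clusters.clstr"),
    new_fasta = empty_new, output_dir = out2))
  expect_true(all(rep$families$track == "first"))
  expect_false(any(rep$fragmentation$fragmented))
})

test_that("recluster mode fails cleanly without first-round outputs", {
  out <- withr::local_tempdir()
  cfg <- run_config("recluster", first_dir = withr::local_tempdir(),
                    clusters_file = "x.clstr", new_fasta = "y.fasta",
                    output_dir = out)
  expect_error(run_recluster(cfg), "first-round output not found")
})

test_that("provenance records every resolved parameter", {
  fx <- workflow_fixture()
  out <- withr::local_tempdir()
  cfg <- run_config("full", input_dir = fx$dir, output_dir = out,
                    threads = 4L, memory_mb = 2000L)
  run_full(cfg)
  prov <- jsonlite::read_json(file.path(out, "provenance.json"))
  for (field in c("mode", "identity_threshold_c",
                  "length_difference_cutoff_s", "clustering_mode",
                  "word_size", "clusterer", "features", "separator",
                  "threads", "memory_mb", "scheme", "panfam_version",
                  "r_version", "write_fastas")) {
    expect_true(field %in% names(prov), info = field)
  }
  expect_equal(prov$threads, 4L)
  expect_equal(prov$identity_threshold_c, 0.9)
})

test_that("a missing external clusterer aborts before any output", {
  fx <- workflow_fixture()
  out <- file.path(withr::local_tempdir(), "never_created")
  withr::local_path(character(0), action = "replace")
  cfg <- run_config("full", input_dir = fx$dir, output_dir = out,
                    clusterer = "external_cdhit")
  expect_error(run_full(cfg), "not on PATH")
  expect_false(dir.exists(out))
})
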