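test_that("category schemes enforce decreasing bands covering [0,100]", {
  sc <- category_scheme(c(90, 50, 0), c("high", "mid", "low"))
  expect_equal(sc$name, c("high", "mid", "low"))
  expect_error(category_scheme(c(50, 90, 0), c("a", "b", "c")),
               "decreasing")
  expect_error(category_scheme(c(90, 50, 10), c("a", "b", "c")),
               "must be 0")
  expect_error(category_scheme(c(90.005, 0), c("a", "b")), "two decimal")
})

test_that("band boundaries are lower-inclusive and computed exactly", {
  expect_equal(classify_family(10, 10), "First_core_99")
  expect_equal(classify_family(19, 20), "First_core_95") # exactly 95%
  expect_equal(classify_family(9, 10), "First_core_15")  # 90%
  expect_equal(classify_family(73, 74), "First_core_95") # 7300/74
  expect_equal(classify_family(1, 74), "First_core_0")
  expect_error(classify_family(1, 0), "positive")
  expect_error(classify_family(0, 10), "1..total_genomes")
})

test_that("classification agrees with a rational oracle for all k, n <= 200", {
  scheme <- default_scheme()
  # oracle: integer cross-multiplication on the raw percentages, derived
  # independently of the implementation's scaled-integer comparison
  oracle <- function(k, n) {
    pct_num <- 100 * k # percentage = pct_num / n
    if (pct_num >= 99 * n) "First_core_99"
    else if (pct_num >= 95 * n) "First_core_95"
    else if (pct_num >= 15 * n) "First_core_15"
    else "First_core_0"
  }
  mismatches <- 0L
  for (n in 1:200) {
    got <- classify_family(1:n, n, scheme)
    want <- vapply(1:n, oracle, character(1), n = n)
    mismatches <- mismatches + sum(got != want)
  }
  expect_equal(mismatches, 0L)
  # monotone: increasing genome_count never lowers the band
  for (n in c(7, 74, 200)) {
    ranks <- match(classify_family(1:n, n, scheme), scheme$name)
    expect_true(all(diff(ranks) <= 0))
  }
})

test_that("trace_genomes collapses paralogs and conserves gene counts", {
  cs <- make_cluster_set(list(c("gA|x", "gA|y", "gB|z")))
  fams <- trace_genomes(cs, "|")
  expect_equal(fams[[1]]$genome_count, 2L)
  expect_equal(fams[[1]]$gene_count, 3L)
  expect_equal(attr(fams, "genomes"), c("gA", "gB"))

  # 74 singleton clusters from 74 genomes
  singletons <- make_cluster_set(as.list(sprintf("g%02d|gene", 1:74)))
  fams74 <- trace_genomes(singletons, "|")
  expect_true(all(vapply(fams74, function(f) f$genome_count, integer(1)) ==
                    1L))

  expect_error(trace_genomes(make_cluster_set(list("nosep")), "|"),
               "without separator")

  set.seed(81)
  for (rep in 1:3) {
    cs <- random_cluster_set(sample(5:40, 1))
    fams <- trace_genomes(cs, "|")
    expect_equal(sum(vapply(fams, function(f) f$gene_count, integer(1))),
                 length(cs$universe))
    for (f in fams) {
      expect_equal(f$genome_count, length(f$members_by_genome))
      expect_gte(f$gene_count, f$genome_count)
    }
  }
})

test_that("category totals partition the family set for any scheme", {
  set.seed(82)
  for (scheme in list(default_scheme(),
                      category_scheme(c(90, 50, 0), c("a", "b", "c")))) {
    cs <- random_cluster_set(30L)
    pr <- pangenome_result(trace_genomes(cs, "|"), scheme)
    expect_equal(sum(pr$totals), length(pr$families))
    expect_equal(pr$total_gene_count, length(cs$universe))
  }
})

test_that("presence-absence rows carry Roary-style counts and cells", {
  pr <- make_pangenome(
    list(group_0 = list(gA = c("gA|x", "gA|y"), gB = "gB|z"),
         group_1 = list(gC = "gC|w")),
    genomes = c("gA", "gB", "gC"))
  lines <- build_presence_absence(pr)
  expect_equal(length(lines), 3L)
  header <- strsplit(lines[[1]], ",")[[1]]
  expect_equal(gsub('"', "", header[1:6]),
               c("Gene", "Non-unique Gene name", "Annotation",
                 "No. isolates", "No. sequences",
                 "Avg sequences per isolate"))
  row1 <- scan(text = lines[[2]], what = character(), sep = ",",
               quote = '"', quiet = TRUE)
  expect_equal(row1[[1]], "group_0")
  expect_equal(row1[4:6], c("2", "3", "1.5"))
  expect_equal(row1[[7]], "gA|x\tgA|y") # tab-joined genes inside the cell
  expect_equal(row1[[9]], "")           # absent genome cell is empty

  # empty pangenome: header only
  empty <- make_pangenome(stats::setNames(list(), character(0)),
                          genomes = character(0))
  expect_equal(length(build_presence_absence(empty)), 1L)
})

test_that("presence-absence consistency holds on fuzzed pangenomes", {
  set.seed(83)
  for (rep in 1:3) {
    cs <- random_cluster_set(sample(10:40, 1))
    pr <- pangenome_result(trace_genomes(cs, "|"))
    lines <- build_presence_absence(pr)
    expect_equal(length(lines) - 1L, length(pr$families))
    iso_prev <- Inf
    for (i in seq_along(lines)[-1]) {
      cells <- scan(text = lines[[i]], what = character(), sep = ",",
                    quote = '"', quiet = TRUE)
      iso <- as.integer(cells[[4]])
      expect_lte(iso, iso_prev) # sorted by descending No. isolates
      iso_prev <- iso
      expect_equal(sum(cells[-(1:6)] != ""), iso)
      genes <- unlist(strsplit(cells[-(1:6)], "\t", fixed = TRUE))
      expect_equal(length(genes), as.integer(cells[[5]]))
    }
  }
})

test_that("summary statistics print band lines and conserve family counts", {
  pr <- make_pangenome(
    c(stats::setNames(lapply(1:5, function(i)
        list(gA = paste0("gA|c", i), gB = paste0("gB|c", i),
             gC = paste0("gC|c", i))),
      paste0("core", 1:5)),
      stats::setNames(lapply(1:3, function(i) list(gA = paste0("gA|s", i))),
                      paste0("shell", 1:3))),
    genomes = c("gA", "gB", "gC"))
  f <- withr::local_tempfile(fileext = ".txt")
  lines <- write_summary_statistics(pr, f)
  expect_equal(lines[[1]], "First_core_99 (99% <= strains <= 100%): 5")
  expect_equal(lines[[2]], "First_core_95 (95% <= strains < 99%): 0")
  expect_equal(lines[[3]], "First_core_15 (15% <= strains < 95%): 3")
  expect_equal(lines[[4]], "First_core_0 (0% <= strains < 15%): 0")
  expect_equal(lines[[5]], "Total genes: 8")
  counts <- as.integer(sub(".*: ", "", lines[1:4]))
  expect_equal(sum(counts), length(pr$families))

  # custom scheme names appear verbatim
  custom <- category_scheme(c(90, 50, 0), c("tight", "half", "rest"))
  pr2 <- make_pangenome(list(f1 = list(gA = "gA|x")), genomes = "gA",
                        scheme = custom)
  lines2 <- write_summary_statistics(pr2, f)
  expect_match(lines2[[1]], "^tight \\(90% <= strains <= 100%\\): 1$")
  expect_match(lines2[[2]], "^half \\(50% <= strains < 90%\\): 0$")
})

test_that("family FASTA output conserves every gene exactly once", {
  pr <- make_pangenome(
    list(group_0 = list(gA = "gA|x", gB = "gB|y"),
         group_1 = list(gA = "gA|z")),
    genomes = c("gA", "gB"))
  seqs <- c("gA|x" = "ATGAAA", "gB|y" = "ATGCCC", "gA|z" = "ATGGGG")
  d <- withr::local_tempdir()
  paths <- write_family_fastas(pr, seqs, d)
  expect_equal(length(paths), 2L)
  combined <- read_fasta(file.path(d, "combined_families.fasta"))
  expect_equal(length(combined), pr$total_gene_count)
  per_family <- unlist(lapply(paths, function(p) names(read_fasta(p))))
  expect_setequal(per_family, names(seqs))

  expect_error(write_family_fastas(pr, seqs[-1], d), "missing sequence")
})

test_that("planted band structure is recovered end-to-end at small scale", {
  spec <- pangenome_spec(n_genomes = 8, n_core = 12, n_accessory = 6,
                         mutation_rate = 0.01, seed = 311)
  d <- withr::local_tempdir()
  pg <- generate_pangenome(spec, d)
  anns <- read_genome_dir(d)
  tc <- tag_and_combine(anns)
  cs <- greedy_cluster(tc$dna, clustering_params(c = 0.90, s = 0.80))
  pr <- pangenome_result(trace_genomes(cs, "|"))
  planted <- table(factor(pg$truth$band[!duplicated(pg$truth$family_id)],
                          levels = pr$scheme$name))
  expect_equal(unname(pr$totals), unname(as.integer(planted)))
})
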