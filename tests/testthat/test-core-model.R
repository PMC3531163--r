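test_that("GTF coordinates convert to 0-based half-open and back", {
  gtf <- c(
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "src", "exon", 301, 400, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"))
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, path)
  models <- read_gtf(path)
  tx <- models$transcripts[["t1"]]
  expect_equal(unname(tx$exons[, 1]), c(100, 300))
  expect_equal(unname(tx$exons[, 2]), c(200, 400))
  intr <- introns_of(tx)
  expect_equal(intr$start, 200)
  expect_equal(intr$end, 300)

  # exon lines out of order parse to the same model
  path2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(rev(gtf), path2)
  models2 <- read_gtf(path2)
  expect_equal(models2$transcripts[["t1"]]$exons, tx$exons)
})

test_that("malformed GTF lines and bad models are rejected with context", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\texon\t10", "junk"), path)
  expect_error(read_gtf(path), "line 1")

  bad <- c(
    paste("chr1", "s", "exon", 101, 300, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("chr1", "s", "exon", 200, 400, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"))
  writeLines(bad, path)
  expect_error(read_gtf(path), "t")
})

test_that("GTF round-trips preserve models, attributes and CDS frames", {
  set.seed(11)
  txs <- list()
  for (i in 1:20) {
    n_ex <- sample(1:5, 1)
    start <- sample(1000:50000, 1)
    ex <- matrix(0L, n_ex, 2)
    p <- start
    for (k in seq_len(n_ex)) {
      len <- sample(50:300, 1)
      ex[k, ] <- c(p, p + len)
      p <- p + len + sample(60:200, 1)
    }
    cds <- if (n_ex > 1 && runif(1) < 0.5)
      matrix(c(ex[1, 1] + 10L, ex[1, 2]), 1, 2) else NULL
    txs[[i]] <- transcript_model(
      sprintf("t%02d", i), sprintf("g%02d", i),
      sample(c("chr1", "chr2"), 1), sample(c("+", "-"), 1), ex, cds = cds,
      frame = if (is.null(cds)) 0L else sample(0:2, 1),
      attrs = sprintf('gene_name "name%d";', i))
  }
  models <- gene_model_set(txs)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(models, path)
  back <- read_gtf(path)
  expect_setequal(names(back$transcripts), names(models$transcripts))
  for (id in names(models$transcripts)) {
    a <- models$transcripts[[id]]; b <- back$transcripts[[id]]
    expect_equal(b$exons, a$exons)
    expect_equal(b$cds, a$cds)
    expect_equal(b$frame, a$frame)
    expect_equal(b$strand, a$strand)
    expect_equal(b$attrs, a$attrs)
  }
  # writers are deterministic byte-for-byte
  path2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("minus-strand exon lines stay in ascending genomic order", {
  tx <- toy_tx("t1", c(100, 200, 300, 400), strand = "-")
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(gene_model_set(list(tx)), path)
  starts <- as.integer(vapply(strsplit(readLines(path), "\t"), `[[`, "", 4))
  expect_equal(starts, sort(starts))
})

test_that("introns_of matches hand-computed gaps", {
  expect_equal(nrow(introns_of(toy_tx("t", c(10, 50)))), 0)
  five <- toy_tx("t", c(0, 10, 20, 35, 50, 61, 70, 85, 100, 120))
  intr <- introns_of(five)
  expect_equal(nrow(intr), 4)
  expect_equal(intr$start, c(10, 35, 61, 85))
  expect_equal(intr$end, c(20, 50, 70, 100))
})

test_that("transcript invariants are enforced", {
  expect_error(toy_tx("t", c(100, 100)), "empty")
  expect_error(toy_tx("t", c(100, 200, 150, 300)), "overlap")
  expect_error(toy_tx("t", c(100, 200, 200, 300)), "overlap")  # no intron gap
  expect_error(transcript_model("t", "g", "chr1", "*",
                                matrix(c(1L, 5L), 1)), "strand")
  expect_error(toy_tx("t", c(100, 200), cds = c(150, 250)), "contained")
})

test_that("overlap queries agree with a linear-scan oracle", {
  set.seed(5)
  txs <- lapply(1:300, function(i) {
    s <- sample(1:100000, 1)
    toy_tx(sprintf("t%03d", i), c(s, s + sample(100:5000, 1)),
           strand = sample(c("+", "-"), 1),
           chrom = sample(c("chr1", "chr2"), 1))
  })
  models <- gene_model_set(txs)
  sp <- model_spans(models)
  for (rep in 1:50) {
    qs <- sample(1:100000, 1); qe <- qs + sample(1:5000, 1)
    qc <- sample(c("chr1", "chr2"), 1)
    got <- overlapping_transcripts(models, qc, qs, qe)
    want <- sort(sp$transcript_id[sp$chrom == qc & sp$start < qe &
                                    sp$end > qs])
    expect_equal(got, want)
  }
})

test_that("per-transcript exon and intron counts add up to the summary totals", {
  fx <- sim_fixture()
  models <- fx$ds$truth
  n_ex <- sum(vapply(models$transcripts, function(t) nrow(t$exons),
                     integer(1)))
  n_jx <- sum(vapply(models$transcripts, function(t) nrow(introns_of(t)),
                     integer(1)))
  rep <- summary_report(models, fx$ds$evidence, gmrefine:::.empty_events())
  expect_equal(rep$coverage_table$total[1], n_ex)
  expect_equal(rep$coverage_table$total[2], n_jx)
  expect_equal(rep$coverage_table$total[3], length(models))
})
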