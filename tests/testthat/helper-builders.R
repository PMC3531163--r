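# Shared refinement fixtures used by module and acceptance tests.

# Boundary-revision fixture: a two-exon transcript with annotated intron
# [1000,1200) and evidence for a shifted true intron (default [1004,1196)).
make_jx_fixture <- function(candidate = c(1004L, 1196L), reads = 3L,
                            annotated_reads = 0L, donor = "GT") {
  tx <- toy_tx("t1", c(900, 1000, 1200, 1400), strand = "+")
  models <- gene_model_set(list(tx))
  truth <- gene_model_set(list(
    toy_tx("t1", c(min(900, candidate[1] - 20), candidate[1],
                   candidate[2], max(1400, candidate[2] + 20)))))
  genome <- plant_splice_sites(random_genome(2000, seed = 77), truth,
                              donor = donor)
  rows <- data.frame(chrom = "chr1", start = candidate[1],
                     end = candidate[2], strand = "+", sample = "s1",
                     reads = reads, stringsAsFactors = FALSE)
  if (annotated_reads > 0)
    rows <- rbind(rows, data.frame(chrom = "chr1", start = 1000L,
                                   end = 1200L, strand = "+", sample = "s1",
                                   reads = annotated_reads))
  list(models = models, genome = genome, junctions = junction_table(rows))
}

# New-exon fixture: transcript with exons [100,300) and [900,1100); the
# true middle exon (default [500,700)) was deleted from the annotation.
make_new_exon_fixture <- function(island = c(500L, 700L),
                                  link_left = TRUE, link_right = TRUE,
                                  extra_exon = NULL) {
  txs <- list(toy_tx("t1", c(100, 300, 900, 1100), strand = "+"))
  if (!is.null(extra_exon))
    txs <- c(txs, list(toy_tx("t2", extra_exon, strand = "+")))
  models <- gene_model_set(txs)
  truth <- gene_model_set(list(
    toy_tx("truth", c(100, 300, island[1], island[2], 900, 1100))))
  genome <- plant_splice_sites(random_genome(2000, seed = 55), truth)
  rows <- NULL
  if (link_left)
    rows <- rbind(rows, data.frame(chrom = "chr1", start = 300L,
                                   end = island[1], strand = "+",
                                   sample = "s1", reads = 2L))
  if (link_right)
    rows <- rbind(rows, data.frame(chrom = "chr1", start = island[2],
                                   end = 900L, strand = "+", sample = "s1",
                                   reads = 2L))
  junctions <- junction_table(
    rows %||% data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         sample = character(0), reads = integer(0)))
  islands <- data.frame(chrom = "chr1", start = island[1], end = island[2],
                        strand = "+", pooled_mean_depth = 30,
                        sample_means = I(list(c(s1 = 30))),
                        stringsAsFactors = FALSE)
  list(models = models, genome = genome, junctions = junctions,
       islands = islands)
}

# Novel-transcript fixture: up to three intergenic islands joined by
# junctions.
make_new_tx_fixture <- function(annotated = NULL, n_islands = 2) {
  starts <- c(300L, 800L, 1300L)[seq_len(n_islands)]
  islands <- data.frame(chrom = "chr1", start = starts,
                        end = starts + 200L, strand = "+",
                        pooled_mean_depth = 30,
                        sample_means = I(rep(list(c(s1 = 30)), n_islands)),
                        stringsAsFactors = FALSE)
  chain_tx <- toy_tx("chain", as.vector(t(cbind(starts, starts + 200L))))
  genome <- plant_splice_sites(random_genome(2500, seed = 91),
                               gene_model_set(list(chain_tx)))
  rows <- NULL
  for (i in seq_len(n_islands - 1))
    rows <- rbind(rows, data.frame(chrom = "chr1", start = starts[i] + 200L,
                                   end = starts[i + 1], strand = "+",
                                   sample = "s1", reads = 2L))
  junctions <- junction_table(
    rows %||% data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         sample = character(0), reads = integer(0)))
  models <- gene_model_set(
    if (is.null(annotated)) list()
    else list(toy_tx("anno", annotated, strand = "+")))
  list(models = models, genome = genome, junctions = junctions,
       islands = islands)
}

# one-row junction event for frame-effect tests
make_jx_event <- function(tid, old, new) {
  ev <- gmrefine:::.event_row("junction", tid, "chr1", "+",
                              old[1], old[2], new[1], new[2], 3L, 1L)
  ev$event_id <- "E0001"
  ev
}
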