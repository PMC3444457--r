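test_that("expression TSV reader validates shape, design and values", {
  dir <- withr::local_tempdir()
  ep <- file.path(dir, "e.tsv"); dp <- file.path(dir, "d.tsv")
  m <- matrix(round(rnorm(12), 3), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  d <- data.frame(sample = paste0("s", 1:4), time_hours = c(0, 0, 1, 1),
                  replicate = c(1, 2, 1, 2))
  x <- expression_matrix(m, d)
  write_expression_tsv(x, ep, dp)
  y <- read_expression_tsv(ep, dp)
  expect_equal(dim(y), c(3L, 4L))
  expect_equal(y$values, x$values)
  expect_equal(y$design, x$design)

  # duplicated gene id
  writeLines(c("gene_id\ts1", "g1\t1.0", "g1\t2.0"), ep)
  writeLines(c("sample\ttime_hours\treplicate", "s1\t0\t1"), dp)
  expect_error(read_expression_tsv(ep, dp), "g1")

  # design missing a sample column
  writeLines(c("gene_id\ts1\ts2", "g1\t1.0\t2.0"), ep)
  expect_error(read_expression_tsv(ep, dp), "s2")

  # design listing an absent sample
  writeLines(c("gene_id\ts1", "g1\t1.0"), ep)
  writeLines(c("sample\ttime_hours\treplicate", "s1\t0\t1", "sX\t1\t1"), dp)
  expect_error(read_expression_tsv(ep, dp), "sX")

  # non-numeric cell named by position
  writeLines(c("gene_id\ts1", "g1\tabc"), ep)
  writeLines(c("sample\ttime_hours\treplicate", "s1\t0\t1"), dp)
  expect_error(read_expression_tsv(ep, dp), "s1")
})

test_that("GMT reader parses, deduplicates, and flags short lines", {
  p <- withr::local_tempfile()
  writeLines(c("SETA\tdesc\tg1\tg2", "SETB\tother\tg1\tg1"), p)
  gs <- read_gmt(p)
  expect_equal(length(gs), 2L)
  expect_setequal(gs$sets$SETA, c("g1", "g2"))
  expect_equal(gs$sets$SETB, "g1")
  expect_equal(unname(gs$descriptions["SETA"]), "desc")

  writeLines(c("SETA\tdesc\tg1", "BAD\tonlydesc"), p)
  expect_error(read_gmt(p), "line 2")

  writeLines(character(), p)
  expect_equal(length(read_gmt(p)), 0L)
})

test_that("interaction tables carry the closed type vocabulary", {
  p <- withr::local_tempfile()
  writeLines(c("source\ttarget\ttype",
               "Birc2\tCasp6\tinhibition",
               "Cldn14\tCldn5\tbinding/association"), p)
  cat_df <- read_interaction_table(p)
  expect_equal(cat_df$type, c("inhibition", "binding/association"))

  writeLines(c("source\ttarget\ttype", "A\tB\tphosphorylation"), p)
  expect_warning(cat2 <- read_interaction_table(p), "phosphorylation")
  expect_equal(cat2$type, "other")

  writeLines(c("source\ttype", "A\tactivation"), p)
  expect_error(read_interaction_table(p), "target")
})

test_that("network writers emit SIF/edge-table and round-trip all formats", {
  e <- network_edges(source = c("A", "B"), target = c("B", "C"),
                     weight = c(-1.25, 0.5),
                     interaction = c("inhibition", "activation"),
                     provenance = c("database", "computed"))
  dir <- withr::local_tempdir()

  sif <- file.path(dir, "n.sif")
  write_network(e, sif, "sif")
  expect_equal(readLines(sif), c("A\tinhibition\tB", "B\tactivation\tC"))

  et <- file.path(dir, "n.tsv")
  write_network(e, et, "edge-table")
  expect_equal(read_network(et, "edge-table"), e)

  gml <- file.path(dir, "n.graphml")
  write_network(e, gml, "graphml")
  g <- read_network(gml, "graphml")
  expect_equal(g[order(g$source), ], e[order(e$source), ], ignore_attr = TRUE)

  empty <- network_edges()
  write_network(empty, et, "edge-table")
  expect_equal(readLines(et),
               "source\ttarget\tweight\tinteraction\tprovenance")
  expect_equal(nrow(read_network(et)), 0L)

  expect_error(write_network(e, et, "dot"))
})

test_that("readers and writers round-trip random valid instances losslessly", {
  dir <- withr::local_tempdir()
  withr::with_seed(99, {
    for (rep in 1:5) {
      G <- sample(2:20, 1); S <- sample(2:4, 1) * 2
      m <- matrix(rnorm(G * S), G,
                  dimnames = list(sprintf("gene%02d", seq_len(G)),
                                  sprintf("s%02d", seq_len(S))))
      d <- data.frame(sample = colnames(m),
                      time_hours = rep(c(0, 1), each = S / 2),
                      replicate = rep(seq_len(S / 2), 2))
      x <- expression_matrix(m, d)
      write_expression_tsv(x, file.path(dir, "e.tsv"), file.path(dir, "d.tsv"))
      y <- read_expression_tsv(file.path(dir, "e.tsv"), file.path(dir, "d.tsv"))
      expect_equal(y$values, x$values)

      sets <- lapply(seq_len(sample(1:6, 1)), function(i)
        sample(rownames(m), sample(seq_len(G), 1)))
      names(sets) <- sprintf("S%d", seq_along(sets))
      gs <- gene_set_collection(sets)
      write_gmt(gs, file.path(dir, "s.gmt"))
      expect_equal(read_gmt(file.path(dir, "s.gmt"))$sets, gs$sets)

      k <- sample(1:10, 1)
      ic <- interaction_catalog(sample(rownames(m), k, TRUE),
                                sample(rownames(m), k, TRUE),
                                sample(c("activation", "inhibition",
                                         "binding/association"), k, TRUE))
      write_interaction_table(ic, file.path(dir, "i.tsv"))
      expect_equal(read_interaction_table(file.path(dir, "i.tsv")), ic)
    }
  })
})
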