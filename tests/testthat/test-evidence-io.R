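test_that("evidence tables parse, deduplicate, and reject bad rows", {
  f <- tmp_file(evidence_fixture_lines())
  t <- read_evidence_table(f)
  expect_s3_class(t, "evidence_table")
  expect_equal(nrow(t), 3)
  expect_equal(attr(t, "n_duplicates"), 0L)

  # verbatim duplicate dropped with a logged count
  f2 <- tmp_file(c(evidence_fixture_lines(), evidence_fixture_lines()[2]))
  t2 <- read_evidence_table(f2)
  expect_equal(nrow(t2), 3)
  expect_equal(attr(t2, "n_duplicates"), 1L)

  # unknown drug -> row error with line number, other rows retained
  f3 <- tmp_file(c(evidence_fixture_lines(),
                   "aspirin\tTP53\tgene\tdownregulated\thESC\tS9"))
  t3 <- read_evidence_table(f3)
  expect_equal(nrow(t3), 3)
  errs <- attr(t3, "row_errors")
  expect_equal(errs$line, 5L)
  expect_match(errs$message, "drug")

  # missing column -> schema error naming the column
  f4 <- tmp_file(c("drug\ttarget\tlevel\teffect\tsystem",
                   "thalidomide\tVEGFA\tgene\tdownregulated\thESC"))
  expect_error(read_evidence_table(f4), "source_id")

  # symbols are canonicalized
  f5 <- tmp_file(c(evidence_fixture_lines(),
                   "thalidomide\t vegfa \tprotein\tdegraded\thESC\tS4"))
  t5 <- read_evidence_table(f5)
  expect_true("VEGFA" %in% t5$target[t5$level == "protein"])
})

test_that("evidence summary counts drugs, levels, replication and overlap", {
  f <- tmp_file(evidence_fixture_lines())
  s <- summarize_evidence(read_evidence_table(f))
  expect_equal(s$total, 3)
  expect_equal(unname(s$by_drug[c("thalidomide", "lenalidomide")]), c(2L, 1L))
  expect_equal(sum(s$by_drug), s$total)
  expect_equal(sum(s$by_level), s$total)
  # VEGFA reported at gene level by two distinct sources -> replicated
  expect_equal(s$per_level$gene$replicated_targets, "VEGFA")
  expect_equal(s$per_level$gene$n_distinct, 1)
  expect_equal(s$n_gene_protein_overlap, 0)

  # one target at both levels -> overlap 1
  f2 <- tmp_file(c(evidence_fixture_lines(),
                   "thalidomide\tVEGFA\tprotein\tdegraded\thESC\tS4"))
  s2 <- summarize_evidence(read_evidence_table(f2))
  expect_equal(s2$n_gene_protein_overlap, 1)
  expect_equal(s2$gene_protein_overlap, "VEGFA")

  # empty table -> empty summary, not an error
  e <- summarize_evidence(read_evidence_table(tmp_file(
    "drug\ttarget\tlevel\teffect\tsystem\tsource_id")))
  expect_equal(e$total, 0)
})

test_that("percentages are one-decimal round-half-even with raw fractions kept", {
  # 253 gene-level entries out of 407 -> 62.2 (100*253/407 = 62.162...)
  expect_equal(pct1(253, 407), 62.2)
  expect_equal(pct1(8624, 28395), 30.4)
  expect_equal(pct1(334, 28395), 1.2)
})

test_that("STRING edge lists: dialect normalization, strict threshold, merging", {
  f <- tmp_file(c("protein1\tprotein2\tcombined_score",
                  "A\tB\t0.520",
                  "C\tD\t0.400",
                  "E\tF\t0.950"))
  e <- read_string_edges(f, threshold = 0.400)
  expect_equal(nrow(e), 2)                 # score exactly 0.400 is excluded
  expect_false(any(e$a == "C"))

  # 0-999 integer dialect is detected and divided by 1000
  f2 <- tmp_file(c("protein1\tprotein2\tcombined_score",
                   "A\tB\t520", "C\tD\t400", "E\tF\t950"))
  e2 <- read_string_edges(f2, threshold = 0.400)
  expect_equal(e2$score[e2$a == "A"], 0.520)
  expect_equal(nrow(e2), 2)

  # self-loops dropped; duplicate unordered pairs merged keeping max score
  f3 <- tmp_file(c("protein1\tprotein2\tcombined_score",
                   "A\tA\t0.9", "A\tB\t0.5", "B\tA\t0.7"))
  e3 <- read_string_edges(f3, threshold = 0.4)
  expect_equal(nrow(e3), 1)
  expect_equal(e3$score, 0.7)

  # channel selection takes the max over the requested channels
  f4 <- tmp_file(c("protein1\tprotein2\texperimental\tcoexpression",
                   "A\tB\t0.2\t0.6"))
  e4 <- read_string_edges(f4, channels = c("experimental", "coexpression"))
  expect_equal(e4$score, 0.6)

  # no recognized score column -> schema error
  f5 <- tmp_file(c("protein1\tprotein2", "A\tB"))
  expect_error(read_string_edges(f5), "score")

  # non-numeric score -> row error, good rows kept
  f6 <- tmp_file(c("protein1\tprotein2\tcombined_score",
                   "A\tB\tbogus", "C\tD\t0.8"))
  e6 <- read_string_edges(f6)
  expect_equal(nrow(e6), 1)
  expect_equal(attr(e6, "row_errors")$line, 2L)
})

test_that("edge reading is a function of the unordered pair set", {
  lines <- c("A\tB\t0.5", "C\tD\t0.9", "A\tC\t0.7")
  f1 <- tmp_file(c("protein1\tprotein2\tcombined_score", lines))
  f2 <- tmp_file(c("protein1\tprotein2\tcombined_score",
                   rev(c("B\tA\t0.5", "D\tC\t0.9", "C\tA\t0.7"))))
  expect_equal(as.data.frame(read_string_edges(f1)),
               as.data.frame(read_string_edges(f2)))
})

test_that("regulon, GMT and annotation dialects parse and round-trip", {
  f <- tmp_file(c("tf\ttarget\tmode\treferences",
                  "SP1\tVEGFA\tActivation\t12345678",
                  "SP1\tCCL2\tRepression\t111,222"))
  r <- read_regulons(f)
  expect_equal(nrow(r), 2)
  expect_equal(sort(regulon_targets(r)$SP1), c("CCL2", "VEGFA"))
  expect_equal(r$references[2], 2L)   # PMID list becomes a count

  g <- tmp_file("GO:X\tdesc\tA\tB\tC", ext = ".gmt")
  sets <- read_gmt(g)
  expect_equal(length(sets$`GO:X`), 3)

  # malformed GMT line (<3 fields) -> row error with line number
  g2 <- tmp_file(c("GO:X\tdesc\tA", "GO:Y\tonlydesc"), ext = ".gmt")
  s2 <- read_gmt(g2)
  expect_equal(names(s2), "GO:X")
  expect_equal(attr(s2, "row_errors")$line, 2L)

  a <- tmp_file(c("symbol\tis_tf\tdbd_class",
                  "SALL4\tTRUE\tC2H2",
                  "CTNNB1\tTRUE\tother"))
  ann <- read_tf_annotations(a)
  expect_equal(c2h2_tfs(ann), "SALL4")
  # C2H2 on a non-TF row violates the contract
  bad <- tmp_file(c("symbol\tis_tf\tdbd_class", "X\tFALSE\tC2H2"))
  expect_error(read_tf_annotations(bad), "C2H2")
})

test_that("every reader/writer pair round-trips", {
  b <- generate_scenario(scenario_params(n_genes = 300, n_tfs = 12,
                                         n_datasets = 2, regulon_min = 4,
                                         regulon_max = 20, seed = 7))
  d <- withr::local_tempdir()

  p <- file.path(d, "ev.tsv")
  write_evidence_table(b$evidence, p)
  expect_equal(as.data.frame(read_evidence_table(p)),
               as.data.frame(b$evidence), ignore_attr = TRUE)

  p <- file.path(d, "edges.tsv")
  write_string_edges(b$edges, p)
  back <- read_string_edges(p, threshold = 0)
  kept <- as.data.frame(b$edges)
  kept <- kept[order(kept$a, kept$b), ]
  rownames(kept) <- NULL
  expect_equal(as.data.frame(back), kept, tolerance = 1e-12,
               ignore_attr = TRUE)

  p <- file.path(d, "reg.tsv")
  write_regulons(b$regulons, p)
  expect_equal(as.data.frame(read_regulons(p)), as.data.frame(b$regulons),
               ignore_attr = TRUE)

  p <- file.path(d, "sets.gmt")
  write_gmt(b$dev_sets, p)
  back <- read_gmt(p)
  expect_equal(unclass(back)[names(b$dev_sets)],
               lapply(b$dev_sets, identity), ignore_attr = TRUE)

  p <- file.path(d, "ann.tsv")
  write_tf_annotations(b$annotations, p)
  expect_equal(as.data.frame(read_tf_annotations(p)),
               as.data.frame(b$annotations), ignore_attr = TRUE)
})
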