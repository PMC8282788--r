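test_that("GMT parsing collapses duplicates, errors on malformed lines, round-trips", {
  p <- write_tmp(c("setA\tdesc\tg1\tg2\tg2",
                   "setB\tdesc\ta\tb\tc\td\te"), ext = ".gmt")
  expect_warning(sets <- read_gmt(p), "duplicate")
  expect_length(sets, 2)
  expect_setequal(sets[[1]]$genes, c("G1", "G2"))
  expect_equal(vapply(sets, function(s) length(s$genes), integer(1)), c(2L, 5L))
  expect_true(is.na(sets[[1]]$universe_size))

  # empty file -> empty list
  expect_length(read_gmt(write_tmp(character(0), ext = ".gmt")), 0)

  # fewer than 3 fields -> parse error naming the line
  bad <- write_tmp(c("ok\tdesc\tg1", "nogenes\tdesc"), ext = ".gmt")
  expect_error(read_gmt(bad), "line 2")

  # write/read round-trip is identity on canonicalized sets
  rt <- write_tmp(character(0), ext = ".gmt")
  write_gmt(sets, rt)
  again <- read_gmt(rt)
  expect_equal(lapply(again, `[[`, "genes"), lapply(sets, `[[`, "genes"))
  expect_equal(vapply(again, `[[`, "", "name"), vapply(sets, `[[`, "", "name"))
})

test_that("gene_set canonicalizes identifiers and enforces the universe bound", {
  gs <- gene_set("s", c(" sod-3 ", "SOD-3", "mtl-1"))
  expect_equal(gs$genes, c("SOD-3", "MTL-1"))
  expect_equal(gene_set("s", c("a", "A"), normalize = FALSE)$genes, c("a", "A"))
  expect_error(gene_set("s", letters[1:5], universe_size = 3), "universe")
})

test_that("DE table reader types columns, drops unparsable rows, rejects duplicates", {
  p <- write_tmp(c("gene_id\tlog2FoldChange\tpvalue\tpadj",
                   "a\t-1.5\t0.01\t0.02",
                   "b\t0.8\t0.2\t0.3",
                   "c\t2.1\t0.001\t0.004"), ext = ".tsv")
  tab <- read_de_table(p)
  expect_s3_class(tab, "de_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$log2fc, c(-1.5, 0.8, 2.1))

  # one NA log2FC row dropped with a warning
  p2 <- write_tmp(c("gene_id\tlog2FoldChange\tpvalue\tpadj",
                    "a\t-1.5\t0.01\t0.02",
                    "b\tNA\t0.2\t0.3"), ext = ".tsv")
  expect_warning(tab2 <- read_de_table(p2), "1 row")
  expect_equal(nrow(tab2), 1)

  # header-only file -> empty table
  p3 <- write_tmp("gene_id\tlog2FoldChange\tpvalue\tpadj", ext = ".tsv")
  expect_equal(nrow(read_de_table(p3)), 0)

  # missing mapped column -> configuration error
  expect_error(read_de_table(p, column_map = c(gene_id = "nope", log2fc = "log2FoldChange")),
               "configuration error")

  # duplicate gene ids -> error listing them
  p4 <- write_tmp(c("gene_id\tlog2FoldChange", "a\t1", "A\t2"), ext = ".tsv")
  expect_error(read_de_table(p4), "duplicate gene_id.*A")
})

test_that("thresholding applies strict fold-change bounds per direction", {
  tab <- data.frame(gene_id = c("A", "B", "C", "D"),
                    log2fc = c(-1.5, -0.8, 2.1, -1.0))
  down <- threshold_set(tab, threshold_spec("down", min_abs_log2fc = 1), "dn")
  expect_equal(down$genes, "A")  # D at exactly -1.0 excluded: strict ">"
  up <- threshold_set(tab, threshold_spec("up", min_abs_log2fc = 1), "up")
  expect_equal(up$genes, "C")
  both <- threshold_set(tab, threshold_spec("both", min_abs_log2fc = 1), "b")
  expect_setequal(both$genes, c("A", "C"))
})

test_that("thresholding counts match an independent scan of a generated table", {
  tab <- gen_de_table(100, null_sd = 1, seed = 11)
  n_down <- sum(tab$log2fc < -1)  # independent scan
  got <- threshold_set(tab, threshold_spec("down", min_abs_log2fc = 1), "dn")
  expect_equal(length(got$genes), n_down)
})

test_that("top_n ranks by the requested key with lexicographic tie-break", {
  tab <- data.frame(gene_id = c("z", "a", "m", "b"),
                    log2fc = c(2, 2, 3, 1.5),
                    pvalue = c(0.01, 0.01, 0.001, 0.2),
                    padj = c(0.02, 0.02, 0.002, 0.4))
  got <- threshold_set(tab, threshold_spec("up", min_abs_log2fc = 1, top_n = 2), "t")
  expect_equal(got$genes, c("m", "a"))  # tie at |lfc|=2 broken by gene id
  expect_warning(
    all_of <- threshold_set(tab, threshold_spec("up", min_abs_log2fc = 1, top_n = 99), "t"),
    "exceeds")
  expect_length(all_of$genes, 4)
  byp <- threshold_set(tab, threshold_spec("up", top_n = 1, rank_key = "pvalue"), "t")
  expect_equal(byp$genes, "m")
})

test_that("padj filter is off unless requested", {
  tab <- data.frame(gene_id = c("a", "b"), log2fc = c(2, 2),
                    padj = c(0.9, NA))
  expect_length(threshold_set(tab, threshold_spec("up", min_abs_log2fc = 1), "t")$genes, 2)
  strict <- threshold_set(tab, threshold_spec("up", min_abs_log2fc = 1, max_padj = 0.05), "t")
  expect_length(strict$genes, 0)
})

test_that("threshold_set is monotone in the magnitude bound", {
  tab <- gen_de_table(500, null_sd = 1, seed = 3)
  cuts <- c(0, 0.25, 0.5, 1, 1.5, 2)
  sizes <- vapply(cuts, function(cc) {
    length(threshold_set(tab, threshold_spec("both", min_abs_log2fc = cc), "s")$genes)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  # raising the bound never adds genes (set containment, not just size)
  s1 <- threshold_set(tab, threshold_spec("both", min_abs_log2fc = 0.5), "s")$genes
  s2 <- threshold_set(tab, threshold_spec("both", min_abs_log2fc = 1.0), "s")$genes
  expect_true(all(s2 %in% s1))
})

test_that("intersection has set semantics: bound, commutative, idempotent", {
  a <- gene_set("a", c("g1", "g2", "g3"), universe_size = 100)
  b <- gene_set("b", c("g2", "g3", "g4"), universe_size = 100)
  ab <- intersect_sets(a, b)
  expect_setequal(ab$genes, c("G2", "G3"))
  expect_equal(ab$universe_size, 100L)
  expect_setequal(intersect_sets(b, a)$genes, ab$genes)
  expect_length(intersect_sets(a, gene_set("d", c("x", "y"))), 0)
  expect_setequal(intersect_sets(a, a)$genes, a$genes)
  expect_lte(length(ab), min(length(a), length(b)))
  # associativity on random sets
  set.seed(5)
  u <- sprintf("g%03d", 1:60)
  x <- gene_set("x", sample(u, 30)); y <- gene_set("y", sample(u, 30))
  z <- gene_set("z", sample(u, 30))
  expect_setequal(intersect_sets(intersect_sets(x, y), z)$genes,
                  intersect_sets(x, intersect_sets(y, z))$genes)
  expect_error(intersect_sets(gene_set("p", "g1", universe_size = 10),
                              gene_set("q", "g1", universe_size = 20)),
               "universe")
})

test_that("plain gene-list files read as a single set", {
  p <- write_tmp(c("# comment", "sod-3", "", "mtl-1 "), ext = ".txt")
  gs <- read_gene_list(p, name = "targets")
  expect_equal(gs$genes, c("SOD-3", "MTL-1"))
})
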