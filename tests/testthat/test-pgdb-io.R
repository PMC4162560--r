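test_that("attribute-value parsing handles minimal, empty and malformed input", {
  f <- withr::local_tempfile(fileext = ".dat")

  writeLines(character(), f)
  expect_equal(nrow(parse_attribute_value(f)), 0)

  writeLines("UNIQUE-ID - RXN-1\nEC-NUMBER - 1.1.1.1\n//", f)
  rec <- parse_attribute_value(f)
  expect_equal(unique(rec$record_id), "RXN-1")
  expect_equal(rec$value[rec$attribute == "EC-NUMBER"], "1.1.1.1")

  # blocks without UNIQUE-ID skipped; malformed lines skipped; names upper-cased
  writeLines(c("COMMON-NAME - orphan", "//",
               "unique-id - X1", "broken line no separator",
               "# a comment", "LEFT - alpha", "/beta continued", "//"), f)
  expect_warning(expect_warning(rec <- parse_attribute_value(f),
                                "malformed"), "UNIQUE-ID")
  expect_equal(unique(rec$record_id), "X1")
  expect_equal(rec$value[rec$attribute == "LEFT"], "alpha beta continued")

  expect_error(parse_attribute_value(file.path(tempdir(), "nope.dat")), "cannot read")
})

test_that("attribute-value parser matches an independent naive interpreter on random files", {
  f <- withr::local_tempfile(fileext = ".dat")
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:12, 1)
    lines <- unlist(lapply(seq_len(n), function(i) {
      attrs <- sample(c("EC-NUMBER", "LEFT", "RIGHT", "COMMON-NAME"),
                      sample(1:5, 1), replace = TRUE)
      c(paste0("UNIQUE-ID - REC-", seed, "-", i),
        paste(attrs, "-", replicate(length(attrs),
                                    paste(sample(letters, 4), collapse = ""))),
        "//")
    }))
    writeLines(lines, f)
    got <- parse_attribute_value(f)
    ref <- oracle_parse_av(f)
    expect_equal(as.data.frame(got), ref, ignore_attr = TRUE)
  }
})

test_that("serialized attribute-value records reparse identically (normal form)", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLines(c("UNIQUE-ID - A", "LEFT - x", "LEFT - y", "//",
               "UNIQUE-ID - B", "RIGHT - z", "//"), f1)
  rec <- parse_attribute_value(f1)
  write_attribute_value(rec, f2)
  expect_identical(parse_attribute_value(f2), rec)
})

test_that("TSV bundle loading resolves the two-enzyme toy and dangles gracefully", {
  d <- withr::local_tempdir()
  writeLines(c("compound_id\tname", "X\t", "A\t", "B\t", "C\t"),
             file.path(d, "compounds.tsv"))
  writeLines(c("reaction_id\tec\tsubstrates\tproducts\treversible\tpathways",
               "R1\t1.1.1.1\tX\tA;B\t0\t",
               "R2\t2.2.2.2\tA\tC\t0\t"),
             file.path(d, "reactions.tsv"))
  writeLines(c("enzyme_id\tec\tname", "E1\t1.1.1.1\tenzyme 1", "E2\t2.2.2.2\tenzyme 2"),
             file.path(d, "enzymes.tsv"))
  writeLines(c("gene_id\tenzyme_id", "g1\tE1", "g2\tE2"),
             file.path(d, "gene_enzyme.tsv"))
  db <- load_pathway_db(d)
  expect_equal(nrow(db$enzymes), 2)
  expect_equal(nrow(db$reactions), 2)
  expect_equal(nrow(db$compounds), 4)
  expect_true(validate_pathway_db(db))

  # reaction citing unknown compound: retained, compound auto-registered
  writeLines(c("reaction_id\tec\tsubstrates\tproducts\treversible\tpathways",
               "R1\t1.1.1.1\tX\tA;B\t0\t",
               "R2\t2.2.2.2\tA;Q\tC\t0\t"),
             file.path(d, "reactions.tsv"))
  expect_warning(db2 <- load_pathway_db(d), "auto-registered")
  expect_true("Q" %in% db2$compounds$compound_id)
  expect_equal(db2$compounds$name[db2$compounds$compound_id == "Q"], "")
  expect_equal(nrow(db2$reactions), 2)

  # missing mandatory file named in the error
  unlink(file.path(d, "enzymes.tsv"))
  expect_error(load_pathway_db(d), "enzymes.tsv")
})

test_that("missing mandatory columns are reported by file and column", {
  d <- withr::local_tempdir()
  writeLines("compound_id\tname", file.path(d, "compounds.tsv"))
  writeLines("reaction_id\tec\tsubstrates\treversible", file.path(d, "reactions.tsv"))
  writeLines("enzyme_id\tec\tname", file.path(d, "enzymes.tsv"))
  writeLines("gene_id\tenzyme_id", file.path(d, "gene_enzyme.tsv"))
  expect_error(load_pathway_db(d), "reactions.tsv.*products")
})

test_that("attribute-value bundle and exported TSV agree; reload is idempotent", {
  d <- withr::local_tempdir()
  writeLines(c("UNIQUE-ID - X", "//", "UNIQUE-ID - A", "//",
               "UNIQUE-ID - B", "//", "UNIQUE-ID - C", "//"),
             file.path(d, "compounds.dat"))
  writeLines(c("UNIQUE-ID - R1", "EC-NUMBER - 1.1.1.1",
               "LEFT - X", "RIGHT - A", "RIGHT - B", "//",
               "UNIQUE-ID - R2", "EC-NUMBER - 2.2.2.2",
               "LEFT - A", "RIGHT - C",
               "REACTION-DIRECTION - REVERSIBLE", "//"),
             file.path(d, "reactions.dat"))
  writeLines(c("UNIQUE-ID - E1", "EC-NUMBER - 1.1.1.1", "GENE - g1", "//",
               "UNIQUE-ID - E2", "EC-NUMBER - 2.2.2.2", "GENE - g2", "GENE - g3", "//"),
             file.path(d, "proteins.dat"))
  db <- load_pathway_db(d)
  expect_equal(db$reactions$product_ids[[1]], c("A", "B"))
  expect_true(db$reactions$reversible[2])
  expect_equal(nrow(db$gene_enzyme), 3)

  out <- withr::local_tempdir()
  write_pathway_db(db, out)
  db2 <- load_pathway_db(out)
  expect_equal(db2$reactions, db$reactions)
  expect_equal(db2$enzymes, db$enzymes)
  expect_equal(db2$gene_enzyme, db$gene_enzyme)
  expect_equal(sort(db2$compounds$compound_id), sort(db$compounds$compound_id))
})

test_that("SIF writing and reading round-trip edge multisets", {
  f <- withr::local_tempfile(fileext = ".sif")
  edges <- tibble::tibble(source = "E1", relation = "cc", target = "E2")
  write_sif(edges, f)
  expect_equal(read_sif(f), edges)

  # property: 200 random edges round-trip
  set.seed(42)
  edges <- tibble::tibble(
    source = sample(sprintf("N%02d", 1:30), 200, replace = TRUE),
    relation = sample(c("cc", "pp"), 200, replace = TRUE),
    target = sample(sprintf("N%02d", 1:30), 200, replace = TRUE))
  write_sif(edges, f)
  back <- read_sif(f)
  expect_equal(back, edges)

  writeLines("A cc", f)
  expect_error(read_sif(f), "line 1")

  expect_equal(nrow(read_sif({writeLines(character(), f); f})), 0)
})

test_that("PPI reading dedups order-insensitively and rejects self-pairs", {
  f <- withr::local_tempfile()
  writeLines(c("AT3G14790 AT5G14180", "AT5G14180\tAT3G14790", "AT1G01010 AT1G01010"), f)
  expect_warning(ppi <- read_ppi(f), "self-pair")
  expect_equal(nrow(ppi), 1)
  expect_equal(ppi$a, "AT3G14790")
  expect_equal(ppi$b, "AT5G14180")

  writeLines("A B C", f)
  expect_error(read_ppi(f), "expected 2")
})

test_that("DEG table IO validates fdr range and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tb <- tibble::tibble(gene_id = c("g1", "g2"), contrast = "c1",
                       log2fc = c(2, -3), fdr = c(1e-12, 0.5))
  write_deg_table(tb, f)
  expect_equal(read_deg_table(f), tb)

  write_deg_table(tibble::tibble(gene_id = "g", contrast = "c", log2fc = 1, fdr = 2), f)
  expect_error(read_deg_table(f), "fdr")
})
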