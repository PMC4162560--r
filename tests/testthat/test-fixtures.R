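test_that("fixture specs validate counts and probabilities", {
  expect_error(fixture_spec(n_compounds = -1), "counts")
  expect_error(fixture_spec(p_currency_usage = 1.5), "probabilities")
  expect_error(fixture_spec(n_reactions = 2, n_enzymes = 7), "infeasible")
  expect_s3_class(fixture_spec(), "fixture_spec")
})

test_that("random databases honor declared counts and are seed-deterministic", {
  spec <- fixture_spec(seed = 42)
  db <- make_random_pgdb(spec)
  dc <- attr(db, "declared_counts")
  expect_equal(nrow(db$reactions), dc$n_reactions)
  expect_equal(nrow(db$enzymes), dc$n_enzymes)
  expect_equal(nrow(db$compounds), dc$n_compounds)
  expect_equal(length(unique(db$gene_enzyme$gene_id)), dc$n_genes)
  expect_true(validate_pathway_db(db))

  # byte-identical serialized bundles across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_pathway_db(make_random_pgdb(spec), d1)
  write_pathway_db(make_random_pgdb(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  expect_equal(nrow(make_random_pgdb(fixture_spec(n_reactions = 0, n_enzymes = 0,
                                                  n_genes = 0))$reactions), 0)
})

test_that("all-currency compound usage leaves the enzyme network edgeless", {
  spec <- fixture_spec(seed = 7, n_compounds = 0, n_reactions = 10,
                       n_enzymes = 8, n_genes = 8, p_currency_usage = 1)
  db <- make_random_pgdb(spec)
  expect_true(all(in_currency(db$compounds$compound_id, default_currency_set())))
  g <- build_gecn(db)
  expect_equal(nrow(g$edges), 0)
})

test_that("generated filler DEG rows can never pass the standard thresholds", {
  db <- make_random_pgdb(fixture_spec(seed = 5))
  tb <- make_random_deg_table(db, deg_fraction = 0.4, seed = 5)
  sig <- tb[tb$fdr <= 1e-10, ]
  non <- tb[tb$fdr > 1e-10, ]
  expect_true(all(abs(sig$log2fc) >= 1))
  expect_true(all(abs(non$log2fc) < 1 | non$fdr > 1e-10))
  expect_setequal(call_degs(tb)$genes, sig$gene_id)
})

test_that("planted linear routes are recovered as the longest contiguous covered run", {
  base <- make_random_pgdb(fixture_spec(seed = 9))

  # full coverage: single maximal route of the planted length
  pl <- plant_linear_route(base, length = 3, seed = 1, prefix = "T3")
  rs <- find_maximal_routes(pathway_chain(pl$db, pl$pathway_id),
                            call_degs(pl$deg_table), pl$db)
  expect_equal(route_length(longest_route(rs)), 3)
  expect_equal(longest_route(rs)$steps$reaction_id, pl$reaction_ids)

  # the seven-step chain with a gap at step 2 mirrors the glycolysis gap
  pl7 <- plant_linear_route(base, length = 7, deg_coverage = setdiff(1:7, 2),
                            seed = 2, prefix = "T7")
  expect_equal(pl7$expected_length, 5)
  rs7 <- find_maximal_routes(pathway_chain(pl7$db, pl7$pathway_id),
                             call_degs(pl7$deg_table), pl7$db)
  expect_equal(route_length(longest_route(rs7)), 5)
  expect_equal(longest_route(rs7)$steps$reaction_id, pl7$expected_route_reactions)
})

test_that("planted-route recovery equals the contiguous-run oracle over many draws", {
  empty <- empty_pathway_db()
  set.seed(123)
  for (i in 1:40) {
    len <- sample(1:20, 1)
    cov <- sort(sample(len, sample(1:len, 1)))
    pl <- plant_linear_route(empty, length = len, deg_coverage = cov,
                             seed = i, prefix = paste0("P", i))
    rs <- find_maximal_routes(pathway_chain(pl$db, pl$pathway_id),
                              call_degs(pl$deg_table), pl$db)
    got <- if (length(rs$routes)) route_length(longest_route(rs)) else 0L
    # independent oracle: longest run of consecutive covered indices
    runs <- rle(seq_len(len) %in% cov)
    ref <- max(c(0L, runs$lengths[runs$values]))
    expect_equal(got, ref)
    expect_equal(pl$expected_length, ref)
  }
})

test_that("worked-example fixtures carry the printed genes, ECs and metabolites", {
  fx5 <- paper_fixture("fig5_ethanol_degradation_II")
  expect_equal(nrow(fx5$db$reactions), 3)
  expect_setequal(fx5$db$gene_enzyme$gene_id,
                  c("AT5G63620", "AT1G54100", "AT5G36880"))
  expect_setequal(fx5$db$enzymes$ec, c("1.1.1.1", "1.2.1.3", "6.2.1.1"))
  expect_true(all(c("ethanol", "acetaldehyde", "acetate", "acetyl-CoA")
                  %in% fx5$db$compounds$compound_id))

  fx6 <- paper_fixture("fig6_tca_variation")
  expect_equal(nrow(fx6$db$reactions), 4)
  step2 <- fx6$db$gene_enzyme$gene_id[fx6$db$gene_enzyme$enzyme_id == "ENZ-OGDH"]
  expect_setequal(step2, c("AT5G65750", "AT3G55410"))

  fx11 <- paper_fixture("fig11_gaba_shunt")
  expect_equal(nrow(fx11$db$reactions), 3)
  step1 <- fx11$db$gene_enzyme$gene_id[fx11$db$gene_enzyme$enzyme_id == "ENZ-GAD"]
  expect_setequal(step1, c("GRMZM2G017110", "GRMZM2G098875", "AT2G02000", "AT2G02010"))
  expect_equal(fx11$db$enzymes$ec[fx11$db$enzymes$enzyme_id == "ENZ-GAD"], "4.1.1.15")

  expect_error(paper_fixture("fig99"), "valid names")

  # every fixture database validates and reproduces its expected outcomes
  for (nm in paper_fixture_names()) {
    fx <- paper_fixture(nm)
    expect_true(validate_pathway_db(fx$db))
    degs <- call_degs(fx$deg_table)
    rs <- find_maximal_routes(fx$db, degs, fx$db)
    expect_equal(route_length(longest_route(rs)), fx$expected$route_length,
                 info = nm)
    if (!fx$branched) {
      expect_equal(chain_length(pathway_chain(fx$db, fx$pathway_id)),
                   fx$expected$chain_length, info = nm)
    }
  }
})

test_that("the EC-less NRS/ER step is excluded from EC-keyed overlap but kept in routes", {
  fx <- paper_fixture("fig9_rhamnose_kaempferol_glucoside")
  g <- build_gecn(fx$db)
  ov <- cross_species_overlap(g, g)
  expect_false(any(ov$shared_keys == ""))
  expect_gte(unname(ov$n_excluded["g1"]), 1)
  rs <- find_maximal_routes(fx$db, call_degs(fx$deg_table), fx$db)
  expect_equal(route_length(longest_route(rs)), 4)
})

test_that("the lily stand-in is flagged synthetic with a nine-step planted chain", {
  fx <- paper_fixture("fig4_lily_superpathway")
  expect_true(fx$synthetic)
  expect_equal(nrow(fx$db$reactions), 9)
  # deterministic: two constructions identical
  fx2 <- paper_fixture("fig4_lily_superpathway")
  expect_identical(fx$db$reactions, fx2$db$reactions)
  expect_identical(fx$deg_table, fx2$deg_table)
})
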