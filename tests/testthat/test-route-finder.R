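test_that("pathway chains follow consecutive-step links with the printed intermediates", {
  fx <- paper_fixture("fig5_ethanol_degradation_II")
  ch <- pathway_chain(fx$db, fx$pathway_id)
  expect_equal(chain_length(ch), 3)
  steps <- ch$chains[[1]]
  expect_equal(steps$link_to_next, c("acetaldehyde", "acetate", NA))
  expect_equal(steps$ec, c("1.1.1.1", "1.2.1.3", "6.2.1.1"))

  # single-reaction pathway: length 1, no linking compound
  db <- toy_db(
    reactions = tibble::tibble(reaction_id = "R1", ec = "1.1.1.1",
                               substrate_ids = list("a"), product_ids = list("b"),
                               reversible = FALSE, pathway_ids = list("P1")),
    enzymes = tibble::tibble(enzyme_id = "E1", ec = "1.1.1.1", name = ""))
  ch1 <- pathway_chain(db, "P1")
  expect_equal(chain_length(ch1), 1)
  expect_true(is.na(ch1$chains[[1]]$link_to_next))

  expect_error(pathway_chain(db, "NOPE"), "unknown or empty")
})

random_dag_db <- function(seed, n = 8) {
  set.seed(seed)
  # reactions over a topological order: reaction i consumes compound of some
  # earlier reaction, guaranteeing a DAG coupling graph
  cpd <- sprintf("c%02d", 0:n)
  subs <- vector("list", n); prods <- vector("list", n)
  for (i in seq_len(n)) {
    feed <- if (i == 1) cpd[1] else cpd[sample(seq_len(i - 1), 1) + 1]
    subs[[i]] <- feed
    prods[[i]] <- cpd[i + 1]
  }
  toy_db(
    reactions = tibble::tibble(
      reaction_id = sprintf("r%02d", seq_len(n)),
      ec = sprintf("1.1.%d.1", seq_len(n)),
      substrate_ids = subs, product_ids = prods,
      reversible = FALSE, pathway_ids = rep(list("P"), n)),
    enzymes = tibble::tibble(enzyme_id = sprintf("e%02d", seq_len(n)),
                             ec = sprintf("1.1.%d.1", seq_len(n)), name = ""))
}

test_that("inferred chain covers equal exhaustive maximal-path enumeration on random DAGs", {
  for (seed in 1:10) {
    db <- random_dag_db(seed)
    ch <- pathway_chain(db, "P")
    glue <- gecn:::reaction_link_graph(db, default_currency_set(),
                                       db$reactions$reaction_id)
    ref <- oracle_maximal_paths(glue$nodes, glue$edges$from, glue$edges$to)
    got <- lapply(ch$chains, function(s) s$reaction_id)
    key <- function(ps) sort(vapply(ps, paste, character(1), collapse = ">"))
    expect_equal(key(got), key(ref))
  }
})

test_that("cyclic pathways are cut at the smallest back-edge with a warning", {
  db <- toy_db(
    reactions = tibble::tibble(
      reaction_id = c("rA", "rB"), ec = c("1.1.1.1", "2.2.2.2"),
      substrate_ids = list("x", "y"), product_ids = list("y", "x"),
      reversible = FALSE, pathway_ids = list("P", "P")),
    enzymes = tibble::tibble(enzyme_id = c("eA", "eB"),
                             ec = c("1.1.1.1", "2.2.2.2"), name = ""))
  expect_warning(ch <- pathway_chain(db, "P"), "back-edge")
  expect_equal(chain_length(ch), 2)  # rB -> rA remains after cutting rA -> rB
  expect_equal(ch$chains[[1]]$reaction_id, c("rB", "rA"))
})

test_that("maximal DEG-covered routes reproduce the worked TCA and glycolysis examples", {
  fx6 <- paper_fixture("fig6_tca_variation")
  rs <- find_maximal_routes(fx6$db, call_degs(fx6$deg_table), fx6$db)
  expect_equal(length(rs$routes), 1)
  expect_equal(route_length(longest_route(rs)), 4)
  expect_false(rs$truncated)

  # the aldolase gap: chain has 7 steps, longest covered route only 5
  fx7 <- paper_fixture("fig7_glycolysis_IV")
  expect_equal(chain_length(pathway_chain(fx7$db, fx7$pathway_id)), 7)
  rs7 <- find_maximal_routes(pathway_chain(fx7$db, fx7$pathway_id),
                             call_degs(fx7$deg_table), fx7$db)
  expect_equal(route_length(longest_route(rs7)), 5)
  expect_equal(longest_route(rs7)$steps$reaction_id,
               paste0("RXN-GLY-", 3:7))
})

test_that("recovered routes equal exhaustive enumeration on random planted instances", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:10, 1)
    db <- random_dag_db(seed, n = n)
    covered <- sort(sample(n, sample(2:n, 1)))
    genes <- sprintf("gene%02d", seq_len(n))
    ge <- tibble::tibble(gene_id = genes, enzyme_id = sprintf("e%02d", seq_len(n)))
    db$gene_enzyme <- ge
    degs <- genes[covered]
    rs <- find_maximal_routes(db, degs, db)
    got <- lapply(rs$routes, function(r) r$steps$reaction_id)

    qual <- db$reactions$reaction_id[covered]
    glue <- gecn:::reaction_link_graph(db, default_currency_set(), qual)
    ref <- oracle_maximal_paths(glue$nodes, glue$edges$from, glue$edges$to)
    key <- function(ps) sort(vapply(ps, paste, character(1), collapse = ">"))
    expect_equal(key(got), key(ref))
    # maximality: no route is a strict contiguous sub-path of another
    keys <- vapply(got, paste, character(1), collapse = ">")
    for (i in seq_along(keys)) for (j in seq_along(keys)) {
      if (i != j) expect_false(grepl(keys[i], keys[j], fixed = TRUE) &&
                                 nchar(keys[i]) < nchar(keys[j]))
    }
  }
})

test_that("adding DEG coverage never shortens the longest route", {
  db <- random_dag_db(5, n = 8)
  genes <- sprintf("gene%02d", 1:8)
  db$gene_enzyme <- tibble::tibble(gene_id = genes,
                                   enzyme_id = sprintf("e%02d", 1:8))
  longest_for <- function(cov) {
    rs <- find_maximal_routes(db, genes[cov], db)
    if (length(rs$routes)) route_length(longest_route(rs)) else 0L
  }
  set.seed(1)
  cov <- sort(sample(8, 4))
  base <- longest_for(cov)
  for (extra in setdiff(1:8, cov)) {
    expect_gte(longest_for(sort(c(cov, extra))), base)
  }
})

test_that("the enumeration cap truncates deterministically and flags it", {
  # complete coupling: every reaction produces what every other consumes
  n <- 6
  db <- toy_db(
    reactions = tibble::tibble(
      reaction_id = sprintf("r%d", 1:n), ec = sprintf("1.1.%d.1", 1:n),
      substrate_ids = rep(list("hub"), n), product_ids = rep(list("hub"), n),
      reversible = FALSE, pathway_ids = rep(list(character()), n)),
    enzymes = tibble::tibble(enzyme_id = sprintf("e%d", 1:n),
                             ec = sprintf("1.1.%d.1", 1:n), name = ""))
  db$gene_enzyme <- tibble::tibble(gene_id = sprintf("g%d", 1:n),
                                   enzyme_id = sprintf("e%d", 1:n))
  rs_capped <- find_maximal_routes(db, sprintf("g%d", 1:n), db, max_paths = 50)
  expect_true(rs_capped$truncated)
  rs_capped2 <- find_maximal_routes(db, sprintf("g%d", 1:n), db, max_paths = 50)
  expect_identical(tidy(rs_capped), tidy(rs_capped2))
  rs_full <- find_maximal_routes(db, sprintf("g%d", 1:n), db, max_paths = 1e6)
  expect_false(rs_full$truncated)
  expect_equal(route_length(longest_route(rs_full)), n)
})

test_that("route reports list one row per step gene with expression statistics", {
  fx <- paper_fixture("fig5_ethanol_degradation_II")
  rs <- find_maximal_routes(fx$db, call_degs(fx$deg_table), fx$db)
  rep <- route_report(longest_route(rs), fx$deg_table)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$gene_id, c("AT5G63620", "AT1G54100", "AT5G36880"))
  expect_equal(rep$ec, c("1.1.1.1", "1.2.1.3", "6.2.1.1"))
  expect_equal(rep$link_to_next[1:2], c("acetaldehyde", "acetate"))

  # row count = sum of per-step DEG gene counts on a larger fixture
  fx8 <- paper_fixture("fig8_kaempferol")
  rs8 <- find_maximal_routes(fx8$db, call_degs(fx8$deg_table), fx8$db)
  r8 <- longest_route(rs8)
  rep8 <- route_report(r8, fx8$deg_table)
  expect_equal(nrow(rep8), sum(lengths(r8$steps$deg_gene_ids)))

  # gene missing from the table: blank statistics with warning
  partial <- fx$deg_table[fx$deg_table$gene_id != "AT1G54100", ]
  expect_warning(rep_p <- route_report(longest_route(rs), partial), "missing")
  expect_true(is.na(rep_p$fdr[rep_p$gene_id == "AT1G54100"]))
})

test_that("returned routes satisfy the route invariants", {
  cs <- default_currency_set()
  for (nm in c("fig6_tca_variation", "fig8_kaempferol", "fig10_pa_biosynthesis")) {
    fx <- paper_fixture(nm)
    degs <- call_degs(fx$deg_table)
    dmap <- map_degs_to_enzymes(degs, fx$db)
    rs <- find_maximal_routes(fx$db, degs, fx$db)
    for (r in rs$routes) {
      s <- r$steps
      expect_false(any(duplicated(s$reaction_id)))  # simple
      expect_true(all(lengths(s$deg_enzyme_ids) >= 1))  # every step covered
      links <- s$link_to_next[-nrow(s)]
      if (length(links)) {
        expect_false(any(is.na(links)))
        expect_false(any(in_currency(links, cs)))
      }
    }
  }
})
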