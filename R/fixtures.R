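#' Specification for a random synthetic pathway database
#'
#' Describes the size and structure of a generated pathway database:
#' counts of compounds, reactions, enzymes and genes, the probability that
#' a reaction additionally involves a currency metabolite, and the DEG
#' fraction used when a matching expression table is generated. Identical
#' spec + seed yields a byte-identical fixture.
#'
#' @param name Fixture name.
#' @param seed Integer seed.
#' @param n_compounds,n_reactions,n_enzymes,n_genes Non-negative counts.
#'   At most three enzymes can be attached per reaction, so
#'   `n_enzymes <= 3 * n_reactions` is required.
#' @param p_currency_usage Probability in \[0, 1\] that a reaction also
#'   consumes/produces a currency metabolite.
#' @param planted_routes Optional list of `(length, label)` pairs handed to
#'   [plant_linear_route()] by callers.
#' @param deg_fraction Fraction of genes flagged DEG in generated
#'   expression tables.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(name = "random", seed = 1L, n_compounds = 30L,
                         n_reactions = 20L, n_enzymes = 15L, n_genes = 30L,
                         p_currency_usage = 0.2, planted_routes = list(),
                         deg_fraction = 0.3) {
  counts <- c(n_compounds, n_reactions, n_enzymes, n_genes)
  if (any(counts < 0)) abort("fixture_spec: counts must be >= 0")
  if (p_currency_usage < 0 || p_currency_usage > 1 ||
      deg_fraction < 0 || deg_fraction > 1) {
    abort("fixture_spec: probabilities must lie in [0, 1]")
  }
  if (n_enzymes > 3 * n_reactions) {
    abort("fixture_spec: infeasible counts (more enzymes than reactions x 3)")
  }
  structure(list(name = name, seed = as.integer(seed),
                 n_compounds = as.integer(n_compounds),
                 n_reactions = as.integer(n_reactions),
                 n_enzymes = as.integer(n_enzymes),
                 n_genes = as.integer(n_genes),
                 p_currency_usage = p_currency_usage,
                 planted_routes = planted_routes,
                 deg_fraction = deg_fraction),
            class = "fixture_spec")
}

pad_id <- function(prefix, i, width = 4) sprintf("%s%0*d", prefix, width, i)

#' Generate a random synthetic pathway database
#'
#' Reactions draw 1-3 substrates and 1-3 products (disjoint) from the
#' compound pool; from the second reaction on, one substrate is replaced by
#' a product of the previous reaction so the reaction set is connected by
#' construction. With probability `p_currency_usage` a reaction also
#' consumes and produces a random currency metabolite (which is registered
#' as a compound). Enzymes get unique EC numbers; every enzyme catalyzes at
#' least one reaction when `n_reactions >= n_enzymes`; genes are assigned
#' to enzymes uniformly. Deterministic under `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return A [pathway_db()] carrying a `declared_counts` attribute with the
#'   generator's own record counts (including auto-registered currency
#'   compounds).
#' @export
make_random_pgdb <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    pool <- if (spec$n_compounds > 0) pad_id("C", seq_len(spec$n_compounds)) else character()
    currency_tokens <- unclass(default_currency_set())

    ecs <- if (spec$n_enzymes > 0) {
      paste(sample(1:6, spec$n_enzymes, replace = TRUE),
            sample(1:9, spec$n_enzymes, replace = TRUE),
            sample(1:9, spec$n_enzymes, replace = TRUE),
            seq_len(spec$n_enzymes), sep = ".")
    } else character()
    enzymes <- tibble(enzyme_id = if (spec$n_enzymes > 0) pad_id("E", seq_len(spec$n_enzymes)) else character(),
                      ec = ecs,
                      name = if (spec$n_enzymes > 0) paste0("enzyme ", seq_len(spec$n_enzymes)) else character())

    rxn_ec <- character(spec$n_reactions)
    if (spec$n_reactions > 0 && spec$n_enzymes > 0) {
      idx <- c(seq_len(min(spec$n_enzymes, spec$n_reactions)),
               if (spec$n_reactions > spec$n_enzymes)
                 sample(spec$n_enzymes, spec$n_reactions - spec$n_enzymes, replace = TRUE))
      rxn_ec <- ecs[idx]
    }

    subs <- vector("list", spec$n_reactions)
    prods <- vector("list", spec$n_reactions)
    used_currency <- character()
    for (i in seq_len(spec$n_reactions)) {
      k_s <- sample(1:3, 1); k_p <- sample(1:3, 1)
      draw <- if (length(pool) > 0) sample(pool, min(k_s + k_p, length(pool))) else character()
      s <- utils::head(draw, min(k_s, length(draw)))
      p <- utils::tail(draw, length(draw) - length(s))
      if (i > 1 && length(prods[[i - 1]]) > 0) {
        feed <- sample(prods[[i - 1]], 1)
        s <- unique(c(feed, setdiff(s, feed)))
        p <- setdiff(p, feed)
      }
      if (stats::runif(1) < spec$p_currency_usage) {
        cur <- sample(currency_tokens, 2)
        s <- c(s, cur[1]); p <- c(p, cur[2])
        used_currency <- c(used_currency, cur)
      }
      subs[[i]] <- s; prods[[i]] <- p
    }
    reactions <- tibble(
      reaction_id = if (spec$n_reactions > 0) pad_id("R", seq_len(spec$n_reactions)) else character(),
      ec = rxn_ec, substrate_ids = subs, product_ids = prods,
      reversible = if (spec$n_reactions > 0) stats::runif(spec$n_reactions) < 0.2 else logical(),
      pathway_ids = rep(list(character()), spec$n_reactions))

    gene_enzyme <- if (spec$n_genes > 0 && spec$n_enzymes > 0) {
      tibble(gene_id = pad_id("G", seq_len(spec$n_genes)),
             enzyme_id = enzymes$enzyme_id[
               c(seq_len(min(spec$n_enzymes, spec$n_genes)),
                 if (spec$n_genes > spec$n_enzymes)
                   sample(spec$n_enzymes, spec$n_genes - spec$n_enzymes, replace = TRUE))])
    } else empty_gene_enzyme()

    compounds <- tibble(
      compound_id = c(pool, unique(used_currency)),
      name = c(if (length(pool)) paste0("compound ", seq_along(pool)) else character(),
               rep("", length(unique(used_currency)))))

    db <- suppressWarnings(pathway_db(compounds, reactions, enzymes, gene_enzyme))
    attr(db, "declared_counts") <- list(
      n_compounds = nrow(compounds), n_reactions = spec$n_reactions,
      n_enzymes = spec$n_enzymes, n_genes = spec$n_genes)
    db
  })
}

#' Generate a DEG table matched to a synthetic database
#'
#' A `deg_fraction` of the database's genes get clearly significant rows
#' (log2fc drawn in \[1, 4\] with random sign, FDR 1e-12); the rest get
#' filler rows that can never pass the standard thresholds (log2fc uniform
#' on (-0.5, 0.5), FDR uniform on (0.1, 1)).
#'
#' @param db A [pathway_db()].
#' @param deg_fraction Fraction of genes flagged significant.
#' @param seed Integer seed.
#' @param contrast Contrast label for every row.
#' @return A DEG tibble (`gene_id`, `contrast`, `log2fc`, `fdr`).
#' @export
make_random_deg_table <- function(db, deg_fraction = 0.3, seed = 1L,
                                  contrast = "synthetic") {
  genes <- unique(db$gene_enzyme$gene_id)
  with_seed(seed, {
    n_sig <- round(deg_fraction * length(genes))
    sig <- if (n_sig > 0) sample(genes, n_sig) else character()
    tibble(
      gene_id = genes, contrast = contrast,
      log2fc = ifelse(genes %in% sig,
                      sample(c(-1, 1), length(genes), replace = TRUE) * stats::runif(length(genes), 1, 4),
                      stats::runif(length(genes), -0.5, 0.5)),
      fdr = ifelse(genes %in% sig, 1e-12, stats::runif(length(genes), 0.1, 1)))
  })
}

#' Append a planted linear route to a pathway database
#'
#' Adds a chain of `length` reactions linked by fresh unique non-currency
#' compounds, one new enzyme and one new gene per step, and registers the
#' chain as a declared pathway. The matching DEG table marks the genes at
#' `deg_coverage` step indices significant (log2fc 2.0, FDR 1e-12) and all
#' other planted genes non-significant (log2fc uniform on (-0.5, 0.5), FDR
#' uniform on (0.1, 1)). The expected recovery is the longest contiguous
#' covered run of steps.
#'
#' @param db A [pathway_db()] to extend (may be [empty_pathway_db()]).
#' @param length Number of chain steps (>= 1).
#' @param deg_coverage Integer step indices marked DEG; default all.
#' @param seed Seed for the filler statistics.
#' @param prefix Id prefix for the planted records (change when planting
#'   more than one route).
#' @param contrast Contrast label for the DEG rows.
#' @return List with `db`, `deg_table`, `pathway_id`, `reaction_ids`,
#'   `expected_length` (longest contiguous covered run) and
#'   `expected_route_reactions` (reaction ids of the leftmost such run).
#' @export
plant_linear_route <- function(db, length, deg_coverage = seq_len(length),
                               seed = 1L, prefix = "PLR", contrast = "planted") {
  stopifnot(inherits(db, "pathway_db"), length >= 1)
  deg_coverage <- sort(unique(as.integer(deg_coverage)))
  stopifnot(all(deg_coverage >= 1), all(deg_coverage <= length))
  cpd <- paste0(prefix, "-C", 0:length)
  rxn <- paste0(prefix, "-R", seq_len(length))
  enz <- paste0(prefix, "-E", seq_len(length))
  gen <- paste0(prefix, "-G", seq_len(length))
  ec <- paste0("9.9.9.", prefix, ".", seq_len(length))
  while (any(ec %in% db$enzymes$ec)) ec <- paste0(ec, ".x")
  pwy <- paste0(prefix, "-PWY")

  new_db <- suppressWarnings(pathway_db(
    compounds = bind_rows(db$compounds, tibble(compound_id = cpd, name = "")),
    reactions = bind_rows(db$reactions, tibble(
      reaction_id = rxn, ec = ec,
      substrate_ids = lapply(seq_len(length), function(i) cpd[i]),
      product_ids = lapply(seq_len(length), function(i) cpd[i + 1]),
      reversible = FALSE, pathway_ids = rep(list(pwy), length))),
    enzymes = bind_rows(db$enzymes, tibble(
      enzyme_id = enz, ec = ec, name = paste0("planted enzyme ", seq_len(length)))),
    gene_enzyme = bind_rows(db$gene_enzyme, tibble(gene_id = gen, enzyme_id = enz)),
    pathways = bind_rows(db$pathways, tibble(
      pathway_id = pwy, name = paste0("planted route ", prefix),
      reaction_order = list(rxn)))))

  covered <- seq_len(length) %in% deg_coverage
  deg_table <- with_seed(seed, tibble(
    gene_id = gen, contrast = contrast,
    log2fc = ifelse(covered, 2.0, stats::runif(length, -0.5, 0.5)),
    fdr = ifelse(covered, 1e-12, stats::runif(length, 0.1, 1))))

  runs <- rle(covered)
  best <- 0L; best_start <- NA_integer_; pos <- 1L
  for (j in seq_along(runs$lengths)) {
    if (runs$values[j] && runs$lengths[j] > best) {
      best <- runs$lengths[j]; best_start <- pos
    }
    pos <- pos + runs$lengths[j]
  }
  list(db = new_db, deg_table = deg_table, pathway_id = pwy,
       reaction_ids = rxn, expected_length = as.integer(best),
       expected_route_reactions = if (best > 0) rxn[best_start:(best_start + best - 1)] else character())
}

# Build a pathway_db from a list of step definitions (one reaction per
# step; enzymes shared across steps when they repeat an enzyme_id).
fixture_chain_db <- function(steps, pathway_id, pathway_name, declare_order = TRUE) {
  reactions <- purrr::imap_dfr(steps, function(s, i) {
    tibble(reaction_id = s$reaction_id, ec = s$ec,
           substrate_ids = list(s$substrates), product_ids = list(s$products),
           reversible = FALSE, pathway_ids = list(pathway_id))
  })
  enzymes <- purrr::map_dfr(steps, function(s) {
    tibble(enzyme_id = s$enzyme_id, ec = s$ec, name = s$enzyme_name)
  }) |> distinct(.data$enzyme_id, .keep_all = TRUE)
  gene_enzyme <- purrr::map_dfr(steps, function(s) {
    if (length(s$genes) == 0) return(NULL)
    tibble(gene_id = s$genes, enzyme_id = s$enzyme_id)
  })
  if (nrow(gene_enzyme) == 0) gene_enzyme <- empty_gene_enzyme()
  compounds <- tibble(
    compound_id = unique(unlist(lapply(steps, function(s) c(s$substrates, s$products)))),
    name = "")
  pathways <- tibble(pathway_id = pathway_id, name = pathway_name,
                     reaction_order = list(if (declare_order)
                       vapply(steps, `[[`, character(1), "reaction_id") else character()))
  suppressWarnings(pathway_db(compounds, reactions, enzymes, gene_enzyme, pathways))
}

fixture_deg_table <- function(steps) {
  purrr::map_dfr(steps, function(s) {
    if (length(s$genes) == 0) return(NULL)
    tibble(gene_id = s$genes,
           contrast = ifelse(grepl("^(GRMZM|AC[0-9])", s$genes),
                             "maize_silk_pollination", s$contrast),
           log2fc = 2.0, fdr = 1e-12)
  }) |> distinct(.data$gene_id, .data$contrast, .keep_all = TRUE)
}

step_def <- function(reaction_id, ec, enzyme_id, enzyme_name, genes,
                     substrates, products, contrast = "arabidopsis_stigma_pollination") {
  list(reaction_id = reaction_id, ec = ec, enzyme_id = enzyme_id,
       enzyme_name = enzyme_name, genes = genes, substrates = substrates,
       products = products, contrast = contrast)
}

#' Names of the packaged worked-example fixtures
#' @return Character vector of valid [paper_fixture()] names.
#' @export
paper_fixture_names <- function() {
  c("fig4_lily_superpathway", "fig5_ethanol_degradation_II",
    "fig6_tca_variation", "fig7_glycolysis_IV", "fig8_kaempferol",
    "fig9_rhamnose_kaempferol_glucoside", "fig10_pa_biosynthesis",
    "fig11_gaba_shunt")
}

#' Packaged worked-example fixtures
#'
#' In-memory transcriptions of published consecutive-step metabolic routes
#' in pollinated *Arabidopsis* and maize tissue: each fixture bundles a
#' small [pathway_db()], a matching DEG table (every printed gene marked
#' significant; fold-change/FDR magnitudes are nominal, carrying DEG status
#' only), the declared pathway id, and the expected chain/route lengths and
#' per-EC gene counts. Gene ids, EC numbers and metabolite strings follow
#' the published figures verbatim; `fig4_lily_superpathway` is a *synthetic*
#' stand-in — a planted 9-step chain matching the figure's step count, whose
#' per-step enzymes are not enumerated in the source — and is flagged as
#' such. `fig9` includes the binary protein-interaction pairs of the
#' dTDP-glucose 4,6-dehydratase locus AT3G14790. `fig10` is a branched
#' (converging) network and carries `branched = TRUE`. The `fig11` steps
#' reproduce the published text as printed, including its step 3
#' ("succinate semialdehyde to GABA"), which is inverted relative to the
#' canonical GABA shunt; the transcription is faithful, not corrected.
#'
#' @param name One of [paper_fixture_names()].
#' @return A `paper_fixture`: list with `name`, `db`, `deg_table`,
#'   `pathway_id`, `expected` (list with `chain_length`, `route_length`,
#'   `genes_by_ec`), `synthetic`, `branched`, and for fig9 a `ppi` tibble.
#' @export
paper_fixture <- function(name) {
  if (!name %in% paper_fixture_names()) {
    abort(paste0("unknown fixture '", name, "'; valid names: ",
                 paste(paper_fixture_names(), collapse = ", ")))
  }
  switch(name,
    fig4_lily_superpathway = fixture_fig4(),
    fig5_ethanol_degradation_II = fixture_fig5(),
    fig6_tca_variation = fixture_fig6(),
    fig7_glycolysis_IV = fixture_fig7(),
    fig8_kaempferol = fixture_fig8(),
    fig9_rhamnose_kaempferol_glucoside = fixture_fig9(),
    fig10_pa_biosynthesis = fixture_fig10(),
    fig11_gaba_shunt = fixture_fig11())
}

new_paper_fixture <- function(name, steps, pathway_id, pathway_name,
                              chain_len, route_len, declare_order = TRUE,
                              synthetic = FALSE, branched = FALSE, ppi = NULL,
                              extra_deg = NULL, notes = "") {
  db <- fixture_chain_db(steps, pathway_id, pathway_name, declare_order)
  deg <- fixture_deg_table(steps)
  if (!is.null(extra_deg)) deg <- bind_rows(deg, extra_deg)
  genes_by_ec <- purrr::map_dfr(steps, function(s) {
    tibble(ec = s$ec, n_genes = length(s$genes))
  })
  structure(list(name = name, db = db, deg_table = deg,
                 pathway_id = pathway_id,
                 expected = list(chain_length = chain_len,
                                 route_length = route_len,
                                 genes_by_ec = genes_by_ec),
                 synthetic = synthetic, branched = branched, ppi = ppi,
                 notes = notes),
            class = "paper_fixture")
}

#' @export
print.paper_fixture <- function(x, ...) {
  cat("<paper_fixture> ", x$name, if (x$synthetic) " [synthetic stand-in]",
      if (x$branched) " [branched]", "\n", sep = "")
  print(x$db)
  invisible(x)
}

fixture_fig5 <- function() {
  ct <- "pollen_tube_SIV_vs_4HPT"
  steps <- list(
    step_def("RXN-ETOH-1", "1.1.1.1", "ENZ-ADH", "alcohol dehydrogenase",
             "AT5G63620", "ethanol", "acetaldehyde", ct),
    step_def("RXN-ETOH-2", "1.2.1.3", "ENZ-ALDH", "aldehyde dehydrogenase",
             "AT1G54100", "acetaldehyde", "acetate", ct),
    step_def("RXN-ETOH-3", "6.2.1.1", "ENZ-ACS", "acetyl-CoA synthetase",
             "AT5G36880", "acetate", "acetyl-CoA", ct))
  new_paper_fixture("fig5_ethanol_degradation_II", steps,
                    "PWY-ETOH-DEG-II", "ethanol degradation II",
                    chain_len = 3L, route_len = 3L)
}

fixture_fig6 <- function() {
  ct <- "pollen_tube_SIV_vs_4HPT"
  steps <- list(
    step_def("RXN-TCA-1", "1.1.1.41", "ENZ-IDH", "isocitrate dehydrogenase (NAD+)",
             "AT2G17130", "D-threo-isocitrate", "2-oxoglutarate", ct),
    step_def("RXN-TCA-2", "1.2.4.2", "ENZ-OGDH", "2-oxoglutarate dehydrogenase E1",
             c("AT5G65750", "AT3G55410"), "2-oxoglutarate", "succinyl-CoA", ct),
    step_def("RXN-TCA-3", "6.2.1.5", "ENZ-SCS", "succinyl-CoA synthetase",
             "AT5G08300", "succinyl-CoA", "succinate", ct),
    step_def("RXN-TCA-4", "1.3.5.1", "ENZ-SDH",
             "succinate dehydrogenase (ubiquinone) flavoprotein subunit",
             "AT5G66760", "succinate", "fumarate", ct))
  new_paper_fixture("fig6_tca_variation", steps,
                    "PWY-TCA-VARIATION", "TCA cycle variation",
                    chain_len = 4L, route_len = 4L)
}

fixture_fig7 <- function() {
  steps <- list(
    step_def("RXN-GLY-1", "2.7.1.90", "ENZ-PFP", "fructose-6-phosphate 1-phosphotransferase",
             c("GRMZM2G042502", "GRMZM2G059151", "GRMZM2G123371", "GRMZM2G450163",
               "AT1G20950", "AT4G04040"),
             "D-fructose-6-phosphate", "fructose-1,6-bisphosphate"),
    # No differentially expressed genes encode this aldolase step: the gap
    # that interrupts the covered route.
    step_def("RXN-GLY-2", "4.1.2.13", "ENZ-FBA", "fructose-bisphosphate aldolase",
             character(), "fructose-1,6-bisphosphate", "D-glyceraldehyde 3-phosphate"),
    step_def("RXN-GLY-3", "1.2.1.12", "ENZ-GAPDH", "glyceraldehyde-3-phosphate dehydrogenase",
             c("GRMZM2G046804", "GRMZM2G051004", "GRMZM2G071630", "GRMZM2G104632",
               "GRMZM2G176307", "AT1G16300", "AT1G79530"),
             "D-glyceraldehyde 3-phosphate", "1,3-bisphospho-D-glycerate"),
    step_def("RXN-GLY-4", "2.7.2.3", "ENZ-PGK", "phosphoglycerate kinase",
             c("GRMZM2G083016", "GRMZM2G089136"),
             "1,3-bisphospho-D-glycerate", "3-phospho-D-glycerate"),
    step_def("RXN-GLY-5", "5.4.2.1", "ENZ-PGM",
             "2,3-bisphosphoglycerate-dependent phosphoglycerate mutase",
             c("GRMZM2G021605", "AT1G09780"),
             "3-phospho-D-glycerate", "2-phospho-D-glycerate"),
    step_def("RXN-GLY-6", "4.2.1.11", "ENZ-ENO", "enolase",
             "AT1G74030", "2-phospho-D-glycerate", "phosphoenolpyruvate"),
    step_def("RXN-GLY-7", "2.7.1.40", "ENZ-PK", "pyruvate kinase",
             c("GRMZM2G004534", "GRMZM2G033526", "GRMZM2G066290", "GRMZM2G124593",
               "GRMZM2G144730", "GRMZM2G177947"),
             "phosphoenolpyruvate", "pyruvate"))
  new_paper_fixture("fig7_glycolysis_IV", steps,
                    "PWY-GLYCOLYSIS-IV", "glycolysis IV (plant cytosol)",
                    chain_len = 7L, route_len = 5L,
                    notes = "steps 3-7 form the longest DEG-covered route; the aldolase step carries no DEGs")
}

fixture_fig8 <- function() {
  steps <- list(
    step_def("RXN-KMP-1", "4.3.1.24", "ENZ-PAL", "phenylalanine ammonia-lyase",
             c("GRMZM2G029048", "GRMZM2G074604", "GRMZM2G081582", "GRMZM2G118345",
               "GRMZM2G160541", "GRMZM2G170692", "GRMZM2G441347", "AT2G37040"),
             "L-phenylalanine", "trans-cinnamate"),
    step_def("RXN-KMP-2", "1.14.13.11", "ENZ-C4H", "trans-cinnamate 4-monooxygenase",
             c("GRMZM2G010468", "GRMZM2G139874", "GRMZM2G147245", "AT2G30490"),
             "trans-cinnamate", "4-coumarate"),
    step_def("RXN-KMP-3", "6.2.1.12", "ENZ-4CL", "4-coumarate:CoA ligase",
             c("GRMZM2G054013", "GRMZM2G055320", "GRMZM2G075333", "GRMZM2G122787",
               "GRMZM2G174574", "AT1G65060", "AT1G21540"),
             "4-coumarate", "4-coumaroyl-CoA"),
    step_def("RXN-KMP-4", "2.3.1.74", "ENZ-CHS", "chalcone synthase",
             c("AC148152.3", "GRMZM2G009348", "GRMZM2G151227", "AT5G13930"),
             "4-coumaroyl-CoA", "naringenin chalcone"),
    step_def("RXN-KMP-5", "5.5.1.6", "ENZ-CHI", "naringenin chalcone isomerase",
             c("GRMZM2G119186", "GRMZM2G155329", "AT3G55120"),
             "naringenin chalcone", "naringenin"),
    step_def("RXN-KMP-6", "1.14.11.9", "ENZ-F3H", "flavanone 3-dioxygenase",
             c("GRMZM2G060940", "GRMZM2G062396", "GRMZM2G099467", "AT3G51240",
               "AT3G55970", "AT3G60290", "AT4G22870", "AT5G05600", "AT5G08640",
               "AT5G24530"),
             "naringenin", "dihydrokaempferol"),
    step_def("RXN-KMP-7", "1.14.11.23", "ENZ-FLS", "flavonol synthase",
             c("GRMZM2G099467", "AT3G60290", "AT4G22880", "AT5G08640"),
             "dihydrokaempferol", "kaempferol"))
  new_paper_fixture("fig8_kaempferol", steps,
                    "PWY-KAEMPFEROL", "kaempferol biosynthesis from L-phenylalanine",
                    chain_len = 7L, route_len = 7L,
                    notes = "intermediate metabolite names use the canonical pathway intermediates; enzyme/gene/EC strings are verbatim")
}

fixture_fig9 <- function() {
  ppi_partners <- c("AT5G14180", "AT5G03760", "AT4G30290", "AT5G44830", "AT2G01630")
  steps <- list(
    step_def("RXN-RHA-1", "4.2.1.46", "ENZ-RHM-DH", "dTDP-glucose 4,6-dehydratase",
             c("GRMZM2G031311", "GRMZM2G166767", "AT1G78570", "AT3G14790"),
             "dTDP-alpha-D-glucose", "dTDP-4-dehydro-6-deoxy-alpha-D-glucose"),
    # NRS/ER step: no EC number assigned in the source network models, so
    # this enzyme is excluded from EC-keyed cross-species comparison.
    step_def("RXN-RHA-2", "", "ENZ-NRS-ER", "NRS/ER",
             c("GRMZM2G166767", "GRMZM2G031311", "AT1G63000"),
             "dTDP-4-dehydro-6-deoxy-alpha-D-glucose", "dTDP-alpha-L-rhamnose"),
    step_def("RXN-RHA-3", "2.4.1.-", "ENZ-F3RT", "flavonol-3-O-rhamnosyltransferase",
             c("AT1G06000", "AT1G22370", "AT1G30530", "AT2G30140", "AT3G46660",
               "AT5G12890", "AT5G17050"),
             c("kaempferol", "dTDP-alpha-L-rhamnose"), "kaempferol-3-rhamnoside"),
    step_def("RXN-RHA-4", "2.4.1.-", "ENZ-F3RT", "flavonol-3-O-rhamnosyltransferase",
             character(),
             c("kaempferol-3-rhamnoside", "dTDP-alpha-L-rhamnose"),
             "kaempferol-3-rhamnoside-7-rhamnoside"))
  ppi <- ppi_pairs(rep("AT3G14790", length(ppi_partners)), ppi_partners)
  extra_deg <- tibble(gene_id = ppi_partners,
                      contrast = "arabidopsis_stigma_pollination",
                      log2fc = 2.0, fdr = 1e-12)
  new_paper_fixture("fig9_rhamnose_kaempferol_glucoside", steps,
                    "PWY-RHAMNOSE-KAEMPFEROL",
                    "dTDP-L-rhamnose and kaempferol glucoside biosynthesis",
                    chain_len = 4L, route_len = 4L, ppi = ppi,
                    extra_deg = extra_deg,
                    notes = "step 4 shares the EC 2.4.1.- enzyme of step 3, so it is DEG-covered through the same isozymes")
}

fixture_fig10 <- function() {
  steps <- list(
    step_def("RXN-PA-1", "2.7.1.67", "ENZ-PI4K", "phosphoinositide 4-kinase",
             c("GRMZM2G114162", "GRMZM2G137558", "GRMZM2G408359", "AT3G56600"),
             "L-1-phosphatidyl-inositol", "1-phosphatidyl-1D-myo-inositol 4-phosphate"),
    step_def("RXN-PA-2", "2.7.1.68", "ENZ-PIP5K", "phosphoinositide phosphate 5-kinase",
             c("GRMZM2G062045", "GRMZM2G076392", "GRMZM2G116010", "GRMZM2G157147",
               "GRMZM5G831486", "AT1G01460"),
             "1-phosphatidyl-1D-myo-inositol 4-phosphate", "PtdIns(4,5)P2"),
    step_def("RXN-PA-3", "3.1.4.11", "ENZ-PLC", "phospholipase C",
             "GRMZM2G137435", "PtdIns(4,5)P2",
             c("1,2-diacylglycerol", "Ins(1,4,5)P3")),
    step_def("RXN-PA-4", "2.3.1.51", "ENZ-LPAAT", "1-acylglycerol-3-phosphate O-acyltransferase",
             c("GRMZM2G014981", "GRMZM2G037104", "GRMZM2G135027", "GRMZM2G165681",
               "GRMZM2G481755", "AT2G38110"),
             "1-acyl-sn-glycerol-3-phosphate", "1,2-diacyl-sn-glycerol-3-phosphate"),
    step_def("RXN-PA-5", "3.1.4.4", "ENZ-PLD", "phospholipase D",
             c("GRMZM2G061969", "GRMZM2G108912", "GRMZM2G133943", "GRMZM2G140811",
               "GRMZM2G145944", "GRMZM2G179792", "GRMZM2G312438", "GRMZM2G442551"),
             "phosphatidylcholine", "1,2-diacyl-sn-glycerol-3-phosphate"),
    step_def("RXN-PA-6", "3.1.3.4", "ENZ-PAP", "phosphatidate phosphatase",
             c("GRMZM2G050658", "AT3G18220"),
             "1,2-diacyl-sn-glycerol-3-phosphate", "1,2-diacylglycerol"),
    step_def("RXN-PA-7", "2.3.1.20", "ENZ-DGAT", "diacylglycerol O-acyltransferase",
             c("GRMZM2G130749", "AT5G37300"),
             "1,2-diacylglycerol", "triacylglycerol"),
    step_def("RXN-PA-8", "3.1.1.3", "ENZ-TAGL", "triacylglycerol lipase",
             c("GRMZM2G035421", "GRMZM2G064594", "GRMZM2G080940", "GRMZM2G087612",
               "AT4G10955", "AT5G14180"),
             "triacylglycerol", "1,2-diacylglycerol"),
    step_def("RXN-PA-9", "2.7.1.107", "ENZ-DGK", "diacylglycerol kinase",
             c("AT5G63770", "AT4G30340"),
             "1,2-diacylglycerol", "phosphatidic acid"))
  new_paper_fixture("fig10_pa_biosynthesis", steps,
                    "PWY-PA-BIOSYNTHESIS", "phosphatidic acid biosynthesis",
                    chain_len = NA_integer_, route_len = 6L,
                    declare_order = FALSE, branched = TRUE,
                    notes = "two converging branches plus a DAG/TAG interconversion cycle; no single linear chain")
}

fixture_fig11 <- function() {
  steps <- list(
    step_def("RXN-GABA-1", "4.1.1.15", "ENZ-GAD", "glutamate decarboxylase",
             c("GRMZM2G017110", "GRMZM2G098875", "AT2G02000", "AT2G02010"),
             "L-glutamate", "4-aminobutyrate"),
    step_def("RXN-GABA-2", "2.6.1.-", "ENZ-TAT", "tyrosine aminotransferase",
             c("AT1G50110", "AT3G22200"),
             "4-aminobutyrate", "succinate semialdehyde"),
    # Transcribed as printed: "succinate semialdehyde to GABA", although
    # the canonical GABA shunt runs this conversion the other way.
    step_def("RXN-GABA-3", "1.2.1.-", "ENZ-HBDH", "3-hydroxybutyrate dehydrogenase",
             c("AT4G33790", "AT5G22500"),
             "succinate semialdehyde", "GABA"))
  new_paper_fixture("fig11_gaba_shunt", steps,
                    "PWY-GLUTAMATE-DEG-IV", "glutamate degradation IV",
                    chain_len = 3L, route_len = 3L)
}

fixture_fig4 <- function() {
  planted <- plant_linear_route(empty_pathway_db(), length = 9,
                                seed = 20140912L, prefix = "LILY-SYN",
                                contrast = "lily_pollen_synthetic")
  structure(list(name = "fig4_lily_superpathway", db = planted$db,
                 deg_table = planted$deg_table,
                 pathway_id = planted$pathway_id,
                 expected = list(chain_length = 9L, route_length = 9L,
                                 genes_by_ec = tibble(ec = character(), n_genes = integer())),
                 synthetic = TRUE, branched = FALSE, ppi = NULL,
                 notes = paste("synthetic stand-in: a planted 9-step linear chain matching",
                               "the figure's step count; the true per-step enzymes of the",
                               "lily superpathway are not enumerated in the source")),
            class = "paper_fixture")
}

#' Write a fixture to disk as a TSV bundle plus DEG table
#'
#' @param fixture A `paper_fixture`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "paper_fixture"))
  write_pathway_db(fixture$db, dir)
  write_deg_table(fixture$deg_table, file.path(dir, "deg.tsv"))
  if (!is.null(fixture$ppi)) {
    writeLines(paste(fixture$ppi$a, fixture$ppi$b, sep = "\t"),
               file.path(dir, "ppi.tsv"))
  }
  invisible(dir)
}
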