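# Pathway parsing and neighborhood extraction.

test_that("parse_pathway reads entities and typed interactions", {
  f <- withr::local_tempfile(lines = c("protein\tA", "protein\tB",
                                       "A\tB\t-t>"))
  g <- parse_pathway(f)
  expect_equal(nrow(g$entities), 2)
  expect_equal(nrow(g$interactions), 1)
  expect_equal(g$interactions$edge_type, "transcriptional-activation")
  expect_equal(g$interactions$sign, 1)

  empty <- withr::local_tempfile(lines = character(0))
  g0 <- parse_pathway(empty)
  expect_equal(nrow(g0$entities), 0)
  expect_equal(nrow(g0$interactions), 0)

  fx <- withr::local_tempfile(lines = c(
    "complex\tCPLX", "protein\tP1", "protein\tP2", "protein\tINH",
    "P1\tCPLX\tcomponent>", "P2\tCPLX\tcomponent>", "INH\tCPLX\t-a|"))
  gx <- parse_pathway(fx)
  expect_equal(nrow(gx$entities), 4)
  expect_equal(nrow(gx$interactions), 3)
  expect_equal(sort(unique(gx$interactions$edge_type)),
               c("component-of", "protein-inhibition"))
  expect_equal(gx$interactions$sign[gx$interactions$source == "INH"], -1)
})

test_that("parse errors carry line numbers and reject unknown codes", {
  bad <- withr::local_tempfile(lines = c("protein\tA", "A\tB\t-t>\textra"))
  expect_error(parse_pathway(bad), "line 2")
  badcode <- withr::local_tempfile(lines = c("protein\tA", "protein\tB",
                                             "A\tB\t-x>"))
  expect_error(parse_pathway(badcode), "unknown edge-type")
  unknown <- withr::local_tempfile(lines = c("protein\tA", "A\tB\t-t>"))
  expect_error(parse_pathway(unknown), "unknown entity")
  dup <- withr::local_tempfile(lines = c("protein\tA", "protein\tA"))
  expect_error(parse_pathway(dup), "duplicate")
})

test_that("chain neighborhood at k = 0 finds direct regulators/targets", {
  g <- pathway_graph(
    data.frame(id = c("U", "f", "D"), kind = "protein"),
    data.frame(source = c("U", "f"), target = c("f", "D"),
               edge_type = "protein-activation"))
  nb <- extract_neighborhood(g, "f", 0)
  expect_equal(nb$regulators, "U")
  expect_equal(nb$targets, "D")
  expect_equal(nb$hop_limit, 0)
})

test_that("feedback circuitry is excluded from both sets", {
  g <- pathway_graph(
    data.frame(id = c("U", "f"), kind = "protein"),
    data.frame(source = c("U", "f"), target = c("f", "U"),
               edge_type = "protein-activation"))
  for (k in 0:3) {
    nb <- suppressWarnings(extract_neighborhood(g, "f", k))
    expect_length(nb$regulators, 0)
    expect_length(nb$targets, 0)
  }
  expect_warning(extract_neighborhood(g, "f", 1), "empty neighborhood")
})

test_that("non-protein entities are free hops for the k budget", {
  # U -> CPLX -> f: CPLX is a complex, so U reaches f with 0 intervening
  # proteins; W -> P -> f costs one intervening protein
  g <- pathway_graph(
    data.frame(id = c("U", "CPLX", "f", "P", "W"),
               kind = c("protein", "complex", "protein", "protein",
                        "protein")),
    data.frame(source = c("U", "CPLX", "W", "P"),
               target = c("CPLX", "f", "P", "f"),
               edge_type = c("component-of", "protein-activation",
                             "protein-activation", "protein-activation")))
  nb0 <- extract_neighborhood(g, "f", 0)
  expect_true(all(c("U", "CPLX", "P") %in% nb0$regulators))
  expect_false("W" %in% nb0$regulators)
  nb1 <- extract_neighborhood(g, "f", 1)
  expect_true("W" %in% nb1$regulators)
})

test_that("extraction matches the exhaustive path oracle on random graphs", {
  for (seed in 1:40) {
    g <- random_pathway(n_ent = sample(6:20, 1), n_edge = sample(8:30, 1),
                        seed = seed)
    focus <- g$entities$id[which(g$entities$kind == "protein")[1]]
    if (is.na(focus)) next
    k <- sample(0:2, 1)
    nb <- suppressWarnings(extract_neighborhood(g, focus, k))
    orc <- oracle_neighborhood(g, focus, k)
    expect_equal(sort(nb$regulators), orc$regulators,
                 info = sprintf("seed %d k %d regulators", seed, k))
    expect_equal(sort(nb$targets), orc$targets,
                 info = sprintf("seed %d k %d targets", seed, k))
    # invariants
    expect_length(intersect(nb$regulators, nb$targets), 0)
    expect_false(focus %in% c(nb$regulators, nb$targets))
    expect_true(all(nb$interactions$source %in%
                      c(focus, nb$regulators, nb$targets)))
    expect_true(all(nb$interactions$target %in%
                      c(focus, nb$regulators, nb$targets)))
  }
})

test_that("neighborhoods grow monotonically in k before feedback exclusion", {
  for (seed in 41:55) {
    g <- random_pathway(n_ent = 15, n_edge = 20, seed = seed)
    focus <- g$entities$id[which(g$entities$kind == "protein")[1]]
    up_prev <- NULL
    for (k in 0:3) {
      up <- pshift:::protein_hop_dist(g, focus, "to")
      reg <- setdiff(names(up)[up <= k], focus)
      if (!is.null(up_prev)) expect_true(all(up_prev %in% reg))
      up_prev <- reg
    }
  }
})

test_that("missing focus raises an error", {
  g <- random_pathway(10, 12, seed = 99)
  expect_error(extract_neighborhood(g, "NOPE", 1), "not in pathway")
})

test_that("variance filter drops flat neighbors and spares missing rows", {
  g <- archetype_pathway()
  nb <- extract_neighborhood(g, "F", 1)
  set.seed(1)
  expr <- rbind(U1 = rnorm(20), U2 = rep(0.5, 20), `F` = rnorm(20),
                T1 = rnorm(20), T2 = rnorm(20))
  colnames(expr) <- sprintf("s%02d", 1:20)
  data <- omics_dataset(expr)
  nf <- variance_filter(nb, data, 0.10)
  expect_false("U2" %in% nf$regulators)         # constant row: SD 0
  expect_true(all(c("T1", "T2") %in% nf$targets))
  expect_identical(variance_filter(nb, data, 0)$regulators,
                   nb$regulators)               # min_sd = 0 is identity
  # a neighbor absent from the expression matrix is retained
  data2 <- omics_dataset(expr[c("U2", "F", "T1", "T2"), ])
  nf2 <- variance_filter(nb, data2, 0.10)
  expect_true("U1" %in% nf2$regulators)
  expect_false("U2" %in% nf2$regulators)
})

test_that("planted low-variance neighbors are exactly the ones removed", {
  sim <- simulate_cohort(sim_config(n_genes = 1, n_samples = 60,
                                    n_reg = 3, n_targ = 3, seed = 21))
  data <- as_omics(sim)
  # shrink three neighbors to (almost) constant rank-ratios
  flat <- c("FG001_R2", "FG001_T1", "FG001_T3")
  data$expression[flat, ] <- 0.5
  nb <- extract_neighborhood(sim$pathway, "FG001", 1)
  sds <- apply(data$expression[c(nb$regulators, nb$targets), ], 1, sd)
  expect_identical(sort(names(sds)[sds < 0.10]), sort(flat))
  nf <- variance_filter(nb, data, 0.10)
  expect_identical(sort(setdiff(c(nb$regulators, nb$targets),
                                c(nf$regulators, nf$targets))),
                   sort(flat))
})

test_that("complexes survive the filter iff a constituent survives", {
  g <- pathway_graph(
    data.frame(id = c("A", "B", "CPLX", "f", "T"),
               kind = c("protein", "protein", "complex", "protein",
                        "protein")),
    data.frame(source = c("A", "B", "CPLX", "f"),
               target = c("CPLX", "CPLX", "f", "T"),
               edge_type = c("component-of", "component-of",
                             "protein-activation",
                             "transcriptional-activation")))
  nb <- extract_neighborhood(g, "f", 1)
  expect_true("CPLX" %in% nb$regulators)
  mk <- function(sdA, sdB) {
    set.seed(5)
    expr <- rbind(A = rnorm(30, sd = sdA), B = rnorm(30, sd = sdB),
                  f = rnorm(30), T = rnorm(30))
    colnames(expr) <- sprintf("s%02d", 1:30)
    omics_dataset(expr, transformed = FALSE)
  }
  # rank-ratio SDs track relative spread: tiny raw SD -> tiny rank SD here
  both_flat <- variance_filter(nb, {
    d <- mk(1, 1); d$expression[c("A", "B"), ] <- 0.5; d
  }, 0.10)
  expect_false("CPLX" %in% both_flat$regulators)
  one_ok <- variance_filter(nb, {
    d <- mk(1, 1); d$expression["A", ] <- 0.5; d
  }, 0.10)
  expect_true("CPLX" %in% one_ok$regulators)
})

test_that("the shipped example pathway parses into the expected context", {
  g <- parse_pathway(system.file("extdata", "toy_pathway.tab",
                                 package = "pshift"))
  expect_equal(nrow(g$entities), 9)
  expect_equal(nrow(g$interactions), 8)
  nb <- extract_neighborhood(g, "RB1", 1)
  # the cyclin-D/CDK4 complex and its components regulate RB1; INH1 sits
  # one intervening protein (CDK4) upstream
  expect_true(all(c("CDK4_CCND1", "CDK4", "CCND1", "INH1") %in%
                    nb$regulators))
  # E2F1, its family and the family's transcriptional target lie downstream
  expect_true(all(c("E2F1", "E2F", "CCNE1", "g1_s_transition") %in%
                    nb$targets))
  expect_length(intersect(nb$regulators, nb$targets), 0)
})
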