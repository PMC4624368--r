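test_that("edges require the full e-value / identity / coverage triple", {
  ss <- seq_set(c("a", "b"), rep(strrep("M", 100), 2))
  g <- build_network(make_hit("a", "b", pident = 100), ss)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$adjusted_identity, 100)

  # fragment: high identity but poor subject coverage -> no edge
  h <- make_hit("a", "b", pident = 90, qlen = 100, slen = 100, aln_len = 40,
                qend = 40, send = 40)
  expect_equal(igraph::ecount(build_network(h, ss)), 0)

  # weak e-value -> no edge
  h2 <- make_hit("a", "b", evalue = 1e-3)
  expect_equal(igraph::ecount(build_network(h2, ss)), 0)

  expect_error(build_network(make_hit("a", "zz"), ss), "unknown")
})

test_that("planted family members connect while the fragment stays isolated", {
  ids <- c(sprintf("m%d", 1:5), "frag")
  ss <- seq_set(ids, c(rep(strrep("A", 100), 5), strrep("A", 40)))
  hits <- list()
  for (i in 1:4) for (j in (i + 1):5)
    hits[[length(hits) + 1]] <- make_hit(ids[i], ids[j], pident = 60)
  # the fragment hits m1 perfectly but covers only 40% of it
  hits[[length(hits) + 1]] <- make_hit("frag", "m1", pident = 100,
                                       qlen = 40, slen = 100, aln_len = 40,
                                       qend = 40, send = 40)
  g <- build_network(do.call(bind_hits, hits), ss, include_singletons = TRUE)
  comp <- connected_components(g)
  expect_equal(length(unique(comp[sprintf("m%d", 1:5)])), 1)
  expect_false(comp[["frag"]] %in% comp[sprintf("m%d", 1:5)])

  # oracle: every retained edge passes a direct per-pair threshold check
  cfg <- ssn_config()
  el <- igraph::as_edgelist(g)
  expect_true(all(igraph::E(g)$adjusted_identity >= cfg$min_adjusted_identity))
  expect_true(all(igraph::E(g)$cov_q >= cfg$min_mutual_coverage &
                    igraph::E(g)$cov_s >= cfg$min_mutual_coverage))
})

test_that("components match a union-find oracle and number deterministically", {
  g0 <- make_net(data.frame(from = character(), to = character()),
                 c(x = "Archaea", y = "Archaea", z = "Bacteria"))
  expect_equal(unname(connected_components(g0)), c(1, 2, 3))

  g1 <- make_net(data.frame(from = c("a", "b"), to = c("b", "c")),
                 c(a = "Archaea", b = "Archaea", c = "Archaea",
                   d = "Bacteria"))
  comp <- connected_components(g1)
  expect_equal(length(unique(comp[c("a", "b", "c")])), 1)
  expect_false(comp[["d"]] == comp[["a"]])
  # numbering ordered by smallest member id
  expect_equal(unname(comp[c("a", "d")]), c(1, 2))

  set.seed(5)
  for (k in 1:5) {
    g <- random_labeled_graph(50, 0.05)
    comp <- connected_components(g)
    el <- igraph::as_edgelist(g, names = TRUE)
    oracle <- brute_components(igraph::V(g)$name, el)
    got <- split(names(comp), comp)
    norm <- function(l) unname(lapply(l, sort)[order(vapply(l, min, ""))])
    expect_equal(norm(got), norm(oracle))
  }
})

test_that("conductance reproduces hand-worked cases", {
  # triangle of Archaea with one pendant Bacteria: 1 external / 3 internal
  tri <- make_net(data.frame(from = c("a1", "a1", "a2", "a3"),
                             to = c("a2", "a3", "a3", "b1")),
                  c(a1 = "Archaea", a2 = "Archaea", a3 = "Archaea",
                    b1 = "Bacteria"))
  expect_equal(domain_conductance(tri, 1, "Archaea"), 1 / 3)
  expect_equal(domain_conductance(tri, 1, "Bacteria"), Inf)

  # two K4s joined by one bridge: 1 external / 6 internal for both domains
  k4 <- function(v) t(combn(v, 2))
  el <- rbind(k4(sprintf("a%d", 1:4)), k4(sprintf("b%d", 1:4)),
              c("a1", "b1"))
  orig <- c(setNames(rep("Archaea", 4), sprintf("a%d", 1:4)),
            setNames(rep("Bacteria", 4), sprintf("b%d", 1:4)))
  g <- make_net(data.frame(from = el[, 1], to = el[, 2]), orig)
  expect_equal(domain_conductance(g, 1, "Archaea"), 1 / 6)
  expect_equal(domain_conductance(g, 1, "Bacteria"), 1 / 6)

  # single-domain component: zero external edges
  solo <- make_net(data.frame(from = "x1", to = "x2"),
                   c(x1 = "Archaea", x2 = "Archaea"))
  expect_equal(domain_conductance(solo, 1, "Archaea"), 0)
  # absent domain: 0/0, which must never count as cohesive
  expect_true(is.nan(domain_conductance(solo, 1, "Bacteria")))

  expect_error(domain_conductance(tri, 1, "Klingon"), "unknown domain")
})

test_that("conductance equals the brute-force classification on random graphs", {
  set.seed(13)
  for (k in 1:20) {
    g <- random_labeled_graph(sample(4:12, 1), runif(1, 0.2, 0.7))
    comp <- connected_components(g)
    for (cid in unique(comp)) for (d in c("Archaea", "Bacteria", "Eukaryote")) {
      expect_equal(domain_conductance(g, cid, d), brute_conductance(g, cid, d))
    }
  }
})

test_that("nucleus selection needs two domains strictly below threshold", {
  k4 <- function(v) t(combn(v, 2))
  el <- rbind(k4(sprintf("a%d", 1:4)), k4(sprintf("b%d", 1:4)),
              c("a1", "b1"))
  orig <- c(setNames(rep("Archaea", 4), sprintf("a%d", 1:4)),
            setNames(rep("Bacteria", 4), sprintf("b%d", 1:4)))
  g <- make_net(data.frame(from = el[, 1], to = el[, 2]), orig)
  nuc <- select_nuclei(g)
  expect_true(nuc$passes)

  tri <- make_net(data.frame(from = c("a1", "a1", "a2", "a3"),
                             to = c("a2", "a3", "a3", "b1")),
                  c(a1 = "Archaea", a2 = "Archaea", a3 = "Archaea",
                    b1 = "Bacteria"))
  expect_false(select_nuclei(tri)$passes)  # only Archaea below 0.4

  solo <- make_net(data.frame(from = "x1", to = "x2"),
                   c(x1 = "Bacteria", x2 = "Bacteria"))
  expect_false(select_nuclei(solo)$passes)  # a single domain can never pass
})

test_that("stricter filters only remove edges; edge changes move conductance
           the expected way", {
  ss <- seq_set(sprintf("s%d", 1:6), rep(strrep("A", 100), 6))
  set.seed(41)
  hits <- list()
  for (i in 1:5) for (j in (i + 1):6)
    hits[[length(hits) + 1]] <- make_hit(
      sprintf("s%d", i), sprintf("s%d", j),
      pident = runif(1, 20, 100), aln_len = sample(60:100, 1),
      qend = sample(60:100, 1), send = sample(60:100, 1))
  hits <- do.call(bind_hits, hits)
  hits$qend <- pmin(hits$qend, 100L); hits$send <- pmin(hits$send, 100L)
  hits$length <- pmax(hits$qend, hits$send)
  edge_ids <- function(g) {
    el <- igraph::as_edgelist(g)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  base <- edge_ids(build_network(hits, ss, ssn_config()))
  stricter_id <- edge_ids(build_network(hits, ss,
                                        ssn_config(min_adjusted_identity = 50)))
  stricter_cov <- edge_ids(build_network(hits, ss,
                                         ssn_config(min_mutual_coverage = 0.9)))
  expect_true(all(stricter_id %in% base))
  expect_true(all(stricter_cov %in% base))

  # adding an inter-domain edge never lowers conductance; an intra-domain
  # edge never raises it
  set.seed(43)
  for (k in 1:10) {
    g <- random_labeled_graph(8, 0.5, domains = c("Archaea", "Bacteria"))
    comp <- connected_components(g)
    cid <- comp[[1]]
    members <- names(comp)[comp == cid]
    if (length(members) < 3) next
    orig <- setNames(igraph::V(g)$origin, igraph::V(g)$name)
    arch <- members[orig[members] == "Archaea"]
    bact <- members[orig[members] == "Bacteria"]
    before <- domain_conductance(g, cid, "Archaea")
    if (length(arch) >= 1 && length(bact) >= 1) {
      pair <- c(arch[1], bact[1])
      if (!igraph::are_adjacent(g, pair[1], pair[2])) {
        g2 <- igraph::add_edges(g, pair)
        igraph::V(g2)$component_id <- connected_components(g2)
        expect_gte(domain_conductance(g2, cid, "Archaea"), before)
      }
    }
    if (length(arch) >= 2 && !igraph::are_adjacent(g, arch[1], arch[2])) {
      g3 <- igraph::add_edges(g, c(arch[1], arch[2]))
      igraph::V(g3)$component_id <- connected_components(g3)
      expect_lte(domain_conductance(g3, cid, "Archaea"), before)
    }
  }
})

test_that("GraphML export round-trips nodes, edges and annotations", {
  ss <- seq_set(c("a", "b"), rep(strrep("M", 80), 2), origin = "Environment")
  g <- build_network(make_hit("a", "b", qlen = 80, slen = 80), ss)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(g, f, annotations = data.frame(
    id = c("a", "b"), class = c("class1", "class2"),
    cpr_identity = c(55.5, 41.25)))
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), 2)
  expect_equal(igraph::ecount(back), 1)
  expect_equal(sort(igraph::V(back)$cpr_identity), c(41.25, 55.5))
  expect_setequal(igraph::V(back)$class, c("class1", "class2"))
})
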