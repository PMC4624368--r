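test_that("divergent subgraph keeps environmental nodes below the cutoff", {
  g <- make_net(data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")),
                c(a = "Environment", b = "Environment", c = "Environment"))
  rec <- data.frame(env_id = c("a", "b", "c"), best_published_id = "p",
                    cpr_identity = c(55, 65, 40), stratum = "",
                    no_cpr = FALSE)
  sub <- divergent_subgraph(g, rec)
  expect_setequal(igraph::V(sub)$name, c("a", "c"))

  rec$cpr_identity <- c(60, 65, 80)
  expect_equal(igraph::vcount(divergent_subgraph(g, rec)), 0)

  rec$no_cpr <- c(TRUE, FALSE, FALSE); rec$cpr_identity <- c(NA, 50, 50)
  expect_setequal(igraph::V(divergent_subgraph(g, rec))$name, c("b", "c"))
  expect_setequal(
    igraph::V(divergent_subgraph(g, rec, keep_no_cpr = TRUE))$name,
    c("a", "b", "c"))
})

test_that("Bron-Kerbosch reports exactly the maximal cliques", {
  tri <- igraph::make_graph(~ a - b, b - c, a - c)
  expect_equal(maximal_cliques(tri), list(c("a", "b", "c")))

  # K4 plus a pendant: at min size 3 only the K4 remains
  k4p <- igraph::make_graph(~ a - b, a - c, a - d, b - c, b - d, c - d,
                            a - e)
  expect_equal(maximal_cliques(k4p, min_size = 3),
               list(c("a", "b", "c", "d")))
  expect_equal(maximal_cliques(k4p, min_size = 2),
               list(c("a", "b", "c", "d"), c("a", "e")))

  expect_error(maximal_cliques(k4p, max_nodes = 3), "guard")
})

test_that("clique enumeration matches brute force and igraph on random
           graphs, and every clique verifies maximality", {
  set.seed(101)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.25, 0.75))
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    ms <- sample(2:3, 1)
    got <- maximal_cliques(g, min_size = ms)
    expect_equal(got, brute_cliques(g, min_size = ms))
    ig <- lapply(igraph::max_cliques(g, min = ms),
                 function(v) sort(igraph::V(g)$name[as.integer(v)]))
    ig <- ig[order(vapply(ig, paste, character(1), collapse = "\r"))]
    expect_equal(got, ig)
    # neighbourhood-intersection maximality check
    adj <- lapply(igraph::as_adj_list(g, mode = "all"),
                  function(v) igraph::V(g)$name[as.integer(v)])
    names(adj) <- igraph::V(g)$name
    for (cl in got) {
      common <- Reduce(intersect, adj[cl])
      expect_length(setdiff(common, cl), 0)
    }
  }
})

test_that("the largest clique per component can be singled out", {
  g <- igraph::make_graph(~ a - b, b - c, a - c, c - d,   # triangle + tail
                          x - y, y - z, x - z, w - x, w - y, w - z)  # K4
  cl <- maximal_cliques(g, min_size = 2)
  top <- largest_clique_per_component(g, cl)
  expect_equal(top, list(c("a", "b", "c"), c("w", "x", "y", "z")))
})

test_that("average clique identity is the mean over mutually non-gap columns", {
  expect_equal(clique_average_identity(c(x = "ACDEF", y = "ACDEF")), 100)
  # pair with one gap: 4 comparable columns, 3 identical
  expect_equal(clique_average_identity(c(x = "AC-DE", y = "ACQDF")), 75)

  # mean contract: three rows, average of the three pairwise identities
  aln <- c(s1 = "AAAAAAAAAA", s2 = "BAAAAAAAAA", s3 = "BCCAAAAAAA")
  manual <- mean(c(protein_identity(aln[1], aln[2]),
                   protein_identity(aln[1], aln[3]),
                   protein_identity(aln[2], aln[3])))
  expect_equal(clique_average_identity(aln), manual)

  expect_error(clique_average_identity(c(a = "ACDE", b = "AC")), "ragged")
  # a pair sharing no column is excluded with a warning
  expect_warning(v <- clique_average_identity(c(a = "AA--", b = "--AA",
                                                c = "AAAA")),
                 "excluded")
  expect_false(is.na(v))
})

test_that("conserved-block counting retains only long gap-free conserved runs", {
  aln <- setNames(rep(strrep("M", 50), 3), c("a", "b", "c"))
  expect_equal(conserved_block_count(aln), 50)

  gappy <- c(a = "M-MM", b = "-MMM", c = "MM-M", d = "MMM-")
  expect_equal(conserved_block_count(gappy, min_block_len = 1), 0)

  # one conserved 12-column run inside a 40-column alignment, plus
  # scattered conserved single columns that fail the run-length rule
  consensus <- strrep("A", 40)
  noisy <- function(letters_pool) {
    ch <- strsplit(consensus, "")[[1]]
    scramble <- setdiff(seq(1, 40), c(5:16, 20, 25, 30))
    ch[scramble] <- sample(letters_pool, length(scramble), TRUE)
    paste(ch, collapse = "")
  }
  set.seed(55)
  # rows draw from disjoint letter pools so scrambled columns never agree
  aln2 <- c(a = consensus, b = noisy(c("C", "D")), c = noisy(c("E", "F")))
  expect_equal(conserved_block_count(aln2, min_block_len = 10), 12)

  # monotone non-increasing in the conserved fraction; bounded by length
  for (f in c(0.3, 0.5, 0.7, 0.9)) {
    expect_lte(conserved_block_count(aln2, conserved_frac = f,
                                     min_block_len = 1), 40)
  }
  vals <- vapply(c(0.3, 0.5, 0.7, 0.9), function(f)
    conserved_block_count(aln2, conserved_frac = f, min_block_len = 1),
    numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("clique reports satisfy their invariants on a planted dataset", {
  ds <- simulate_dataset(sim_config(rng_seed = 7))
  cfg <- ssn_config(rng_seed = 7)
  res <- run_pipeline(withr::local_tempdir(), config = cfg)
  rep <- res$cliques
  expect_gt(nrow(rep), 0)
  sub <- divergent_subgraph(res$exploratory_net, res$cpr, cfg)
  for (k in seq_len(nrow(rep))) {
    mem <- rep$members[[k]]
    # every member pair is an edge and every member is highly divergent
    for (i in seq_len(length(mem) - 1)) for (j in seq(i + 1, length(mem)))
      expect_true(igraph::are_adjacent(res$exploratory_net, mem[i], mem[j]))
    cprs <- res$cpr$cpr_identity[match(mem, res$cpr$env_id)]
    expect_true(all(cprs < cfg$cpr_divergence_cutoff))
    # redundancy was filtered upstream, so identical members cannot occur
    expect_lt(rep$avg_identity[k], 100)
  }
})
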