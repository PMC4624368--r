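# A two-tier planted family: tier-1 environmental sequences are within
# reach of the seeds, tier-2 sequences are within reach of tier 1 only.
planted_two_tier <- function(seed_val = 17) {
  set.seed(seed_val)
  anc <- random_protein_str(200)
  seeds <- seq_set(c("nuc1", "nuc2"),
                   c(anc, evolve_protein(anc, 85)),
                   origin = "Archaea")
  tier1 <- vapply(1:3, function(i) evolve_protein(anc, 45), character(1))
  # tier 2 descends from a tier-1 sequence and is far enough (~17% to the
  # seeds) that only the second round can reach it
  tier2 <- vapply(1:3, function(i) evolve_protein(tier1[1], 30), character(1))
  env <- seq_set(c(sprintf("t1_%d", 1:3), sprintf("t2_%d", 1:3)),
                 c(tier1, tier2), origin = "Environment")
  list(seeds = seeds, env = env)
}

test_that("one recruitment round pulls direct homologs only", {
  fam <- planted_two_tier()
  rr <- recruit_round(fam$seeds, fam$env)
  expect_setequal(rr$recruits, sprintf("t1_%d", 1:3))

  # a seed identical to an environmental ORF always recruits it
  twin <- seq_set("envtwin", fam$seeds$residues[1], origin = "Environment")
  expect_equal(recruit_round(fam$seeds, twin)$recruits, "envtwin")

  # nothing above the score floor -> empty set
  set.seed(3)
  noise <- seq_set("rnd", random_protein_str(200), origin = "Environment")
  expect_equal(length(recruit_round(fam$seeds, noise)$recruits), 0)

  expect_warning(out <- recruit_round(fam$seeds, fam$env[0, ]), "empty")
  expect_equal(length(out$recruits), 0)
})

test_that("the second round gathers homologs of homologs, monotonically", {
  fam <- planted_two_tier()
  two <- expand_families(fam$seeds, fam$env, ssn_config(recruitment_rounds = 2))
  one <- expand_families(fam$seeds, fam$env, ssn_config(recruitment_rounds = 1))
  expect_setequal(two$provenance$env_id[two$provenance$round == 1],
                  sprintf("t1_%d", 1:3))
  expect_setequal(two$provenance$env_id[two$provenance$round == 2],
                  sprintf("t2_%d", 1:3))
  expect_false(any(grepl("^t2", one$provenance$env_id)))
  # monotone recruitment: one round's catch is a subset of two rounds'
  expect_true(all(one$provenance$env_id %in% two$provenance$env_id))

  # unrelated environment: the expanded set is the nuclei alone
  set.seed(9)
  rnd <- seq_set(sprintf("r%d", 1:4),
                 vapply(1:4, function(i) random_protein_str(200),
                        character(1)), origin = "Environment")
  alone <- expand_families(fam$seeds, rnd, ssn_config())
  expect_equal(sort(alone$seqs$id), sort(fam$seeds$id))
})

test_that("class labels follow breadth-first distance from the nucleus set", {
  path <- make_net(data.frame(from = c("nuc", "e1", "e2"),
                              to = c("e1", "e2", "e3")),
                   c(nuc = "Archaea", e1 = "Environment", e2 = "Environment",
                     e3 = "Environment"))
  cls <- classify_nodes(path, "nuc")
  got <- setNames(cls$class, cls$id)
  expect_equal(got[c("nuc", "e1", "e2", "e3")],
               c(nuc = "nucleus", e1 = "class1", e2 = "class2",
                 e3 = "distal"), ignore_attr = TRUE)

  # adjacency to a nucleus wins over adjacency to a class-1 node
  tie <- make_net(data.frame(from = c("nuc", "nuc", "e1"),
                             to = c("e1", "e2", "e2")),
                  c(nuc = "Archaea", e1 = "Environment", e2 = "Environment"))
  cls2 <- classify_nodes(tie, "nuc")
  expect_equal(cls2$class[cls2$id == "e2"], "class1")

  # disconnected environmental node: distal at infinite distance
  iso <- make_net(data.frame(from = "nuc", to = "e1"),
                  c(nuc = "Archaea", e1 = "Environment",
                    lost = "Environment"))
  cls3 <- classify_nodes(iso, "nuc")
  expect_equal(cls3$class[cls3$id == "lost"], "distal")
  expect_equal(cls3$distance[cls3$id == "lost"], Inf)

  expect_error(classify_nodes(path, c("nuc", "ghost")), "absent")
})

test_that("class labels equal a hand-rolled BFS on random planted networks", {
  set.seed(23)
  for (k in 1:8) {
    g <- random_labeled_graph(sample(10:40, 1), 0.08,
                              domains = c("Archaea", "Environment"))
    nuc <- igraph::V(g)$name[igraph::V(g)$origin == "Archaea"]
    if (length(nuc) == 0) next
    cls <- classify_nodes(g, nuc)
    d <- brute_bfs(g, nuc)
    expect_equal(setNames(cls$distance, cls$id)[names(d)], d)
    lab <- ifelse(names(d) %in% nuc, "nucleus",
           ifelse(d == 1, "class1", ifelse(d == 2, "class2", "distal")))
    expect_equal(setNames(cls$class, cls$id)[names(d)],
                 setNames(lab, names(d)))
  }
})

test_that("classes partition environmental nodes; class2 verifies its
           definition on every run", {
  fam <- planted_two_tier()
  ex <- expand_families(fam$seeds, fam$env, ssn_config())
  hits <- all_vs_all(ex$seqs)
  net <- build_network(hits, ex$seqs, include_singletons = TRUE)
  cls <- classify_nodes(net, fam$seeds$id)
  byc <- split(cls$id, cls$class)
  expect_length(intersect(byc$class1, byc$class2), 0)
  for (v in byc$class2) {
    nb <- igraph::V(net)$name[igraph::neighbors(net, v)]
    expect_true(any(nb %in% byc$class1))
    expect_false(any(nb %in% fam$seeds$id))
  }
})

test_that("CPR takes the maximum qualifying adjusted identity", {
  pub <- seq_set(c("p1", "p2"), c(strrep("M", 100), strrep("W", 100)))
  env <- seq_set("e", strrep("M", 100), origin = "Environment")
  rec <- cpr_identity(env, pub)
  expect_equal(rec$cpr_identity, 100)
  expect_equal(rec$best_published_id, "p1")

  # max contract with precomputed hits at adjusted identities 72 and 55.3
  hits <- bind_hits(make_hit("e", "p1", pident = 72, bitscore = 80),
                    make_hit("e", "p2", pident = 55.3, bitscore = 90))
  rec2 <- cpr_identity(env, pub, hits = hits)
  expect_equal(rec2$cpr_identity, 72)
  expect_equal(rec2$best_published_id, "p1")

  # no qualifying hit is recorded explicitly, never as identity 0
  set.seed(2)
  far <- seq_set("far", random_protein_str(100), origin = "Environment")
  rec3 <- cpr_identity(far, pub)
  expect_true(rec3$no_cpr)
  expect_true(is.na(rec3$cpr_identity))
})

test_that("a class1 node's CPR can fall below the edge threshold when the
           published set excludes its nucleus neighbour (non-invariant)", {
  set.seed(77)
  anc <- random_protein_str(200)
  nuc <- seq_set("nuc", anc, origin = "Archaea")
  e1 <- seq_set("e1", evolve_protein(anc, 60), origin = "Environment")
  unrelated_pub <- seq_set("pub", random_protein_str(200))
  rec <- cpr_identity(e1, unrelated_pub)
  expect_true(rec$no_cpr || rec$cpr_identity < 30)
})

test_that("divergence histograms bin and normalize per stratum", {
  rec <- data.frame(env_id = sprintf("e%d", 1:4),
                    best_published_id = "p",
                    cpr_identity = c(95, 97, 50, 40),
                    stratum = "gut", no_cpr = FALSE)
  class(rec) <- c("cpr_records", "data.frame")
  h <- divergence_summary(rec, breaks = c(0, 60, 95, 100))
  expect_equal(h$proportion, c(0.5, 0, 0.5))
  expect_equal(sum(h$count), 4)

  single <- rec[1, ]
  h1 <- divergence_summary(single, breaks = c(0, 60, 95, 100))
  expect_equal(sum(h1$proportion == 1), 1)

  rec$no_cpr <- c(FALSE, FALSE, TRUE, TRUE)
  h2 <- divergence_summary(rec, breaks = c(0, 60, 95, 100))
  expect_true(all(h2$n_no_cpr == 2))
  expect_equal(sum(h2$count), 2)

  empty <- rec[rec$no_cpr, ]
  expect_warning(divergence_summary(empty, breaks = c(0, 50, 100)),
                 "no CPR values")
})
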