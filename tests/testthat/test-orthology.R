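# hand-built hit tables exercise the clustering rules without the aligner
mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query = r[[1]], subject = r[[2]], qgenome = r[[3]],
               sgenome = r[[4]], identity = as.numeric(r[[5]]),
               aligned_length = as.integer(r[[6]]), score = as.numeric(r[[7]]),
               stringsAsFactors = FALSE)))
}

test_that("BBH pairs require reciprocity, identity > 0.5 and coverage > 2/3", {
  lens <- c(a1 = 100, b1 = 100, a2 = 100, b2 = 100)
  hits <- mk_hits(
    list("a1", "b1", "A", "B", 0.70, 100, 300),
    list("b1", "a1", "B", "A", 0.70, 100, 300),
    list("a2", "b2", "A", "B", 0.45, 100, 200),   # below identity cutoff
    list("b2", "a2", "B", "A", 0.45, 100, 200))
  bbh <- find_bbh_pairs(hits, lens)
  expect_equal(nrow(bbh), 1)
  expect_equal(c(bbh$a, bbh$b), c("a1", "b1"))

  # one-directional best hit only: b1's best hit in A is a2, not a1
  hits2 <- mk_hits(
    list("a1", "b1", "A", "B", 0.70, 100, 300),
    list("b1", "a2", "B", "A", 0.80, 100, 350),
    list("b1", "a1", "B", "A", 0.70, 100, 300),
    list("a2", "b1", "A", "B", 0.60, 100, 250))
  bbh2 <- find_bbh_pairs(hits2, c(lens, a2 = 100))
  expect_false(any(bbh2$a == "a1" & bbh2$b == "b1"))

  # coverage strictly greater than 2/3 of the shorter protein
  hits3 <- mk_hits(
    list("a1", "b1", "A", "B", 0.90, 66, 300),
    list("b1", "a1", "B", "A", 0.90, 66, 300))
  expect_equal(nrow(find_bbh_pairs(hits3, c(a1 = 99, b1 = 120))), 0)
  hits4 <- mk_hits(
    list("a1", "b1", "A", "B", 0.90, 67, 300),
    list("b1", "a1", "B", "A", 0.90, 67, 300))
  expect_equal(nrow(find_bbh_pairs(hits4, c(a1 = 99, b1 = 120))), 1)

  # identity exactly 0.5 is rejected ("more than 50%")
  hits5 <- mk_hits(
    list("a1", "b1", "A", "B", 0.50, 100, 300),
    list("b1", "a1", "B", "A", 0.50, 100, 300))
  expect_equal(nrow(find_bbh_pairs(hits5, lens)), 0)
})

test_that("paralogs closer than the BBH partner join the cluster", {
  lens <- c(p1 = 100, p2 = 100, p3 = 100, q = 100)
  hits <- mk_hits(
    list("p1", "q", "A", "B", 0.60, 100, 200),
    list("q", "p1", "B", "A", 0.60, 100, 200),
    list("p1", "p2", "A", "A", 0.90, 100, 450),  # closer than q -> added
    list("p2", "p1", "A", "A", 0.90, 100, 450),
    list("p1", "p3", "A", "A", 0.55, 100, 120))  # weaker than q -> not added
  bbh <- find_bbh_pairs(hits, lens)
  seeds <- attach_paralogs(bbh, hits)
  expect_setequal(seeds[[1]], c("p1", "q", "p2"))

  # no paralogs: seed is the BBH pair unchanged
  seeds2 <- attach_paralogs(bbh, hits[1:2, ])
  expect_setequal(seeds2[[1]], c("p1", "q"))
})

test_that("cluster merging is the transitive closure and matches brute force", {
  expect_equal(merge_clusters(list(c("a", "b"), c("b", "c"), c("d", "e"))),
               list(c("a", "b", "c"), c("d", "e")))
  disjoint <- list(c("a", "b"), c("c", "d"))
  expect_equal(merge_clusters(disjoint), disjoint)

  set.seed(20)
  for (rep in 1:5) {
    genes <- paste0("g", 1:20)
    seeds <- replicate(8, sample(genes, sample(2:4, 1)), simplify = FALSE)
    expect_equal(merge_clusters(seeds), bf_merge(seeds))
  }
})

test_that("conservation classes follow the presence-count boundaries", {
  lineages <- setNames(rep("L", 15), paste0("g", 1:15))
  mk_groups <- function(k) {
    genes <- paste0("g", seq_len(k), "_x")
    ortholog_groups(list(genes), setNames(paste0("g", seq_len(k)), genes))
  }
  cls <- function(k) unname(classify_conservation(mk_groups(k), lineages, "L"))
  expect_equal(cls(15), "universal")
  expect_equal(cls(8), "conserved")   # 8 > 7.5
  expect_equal(cls(4), "sporadic")    # within 2..7
  expect_equal(cls(7), "sporadic")
  expect_equal(cls(1), "unique")
  expect_equal(unname(classify_conservation(mk_groups(3),
    c(lineages, setNames("M", "h1")), "M")), "absent")
})

test_that("raising the identity cutoff never adds BBH pairs", {
  set.seed(7)
  genes <- expand.grid(g = c("A", "B"), i = 1:6)
  lens <- setNames(rep(100, 12), paste0(genes$g, genes$i))
  hits <- list()
  for (i in 1:6) for (j in 1:6) {
    id <- runif(1, 0.3, 0.95)
    hits[[length(hits) + 1]] <- mk_hits(
      list(paste0("A", i), paste0("B", j), "A", "B", id, 90, id * 400),
      list(paste0("B", j), paste0("A", i), "B", "A", id, 90, id * 400))
  }
  hits <- do.call(rbind, hits)
  cuts <- c(0.3, 0.5, 0.7, 0.9)
  sets <- lapply(cuts, function(ci) {
    b <- find_bbh_pairs(hits, lens, min_identity = ci)
    paste(b$a, b$b)
  })
  for (k in seq_along(cuts)[-1])
    expect_true(all(sets[[k]] %in% sets[[k - 1]]))
})

test_that("the aligner recovers identity of identical and mutated proteins", {
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p <- paste(sample(aa, 100, TRUE), collapse = "")
  hits <- all_vs_all_similarity(list(A = c(x = p), B = c(y = p)))
  self <- hits[hits$query == "x" & hits$subject == "y", ]
  expect_equal(self$identity, 1.0)
  expect_equal(self$aligned_length, 100L)

  # a copy with a planted 40% substitution load aligns at ~60% identity
  long <- paste(sample(aa, 400, TRUE), collapse = "")
  v <- strsplit(long, "")[[1]]
  nmut <- 160
  pos <- sample(400, nmut)
  v[pos] <- vapply(v[pos], function(a) sample(setdiff(aa, a), 1), "")
  mut <- paste(v, collapse = "")
  h2 <- all_vs_all_similarity(list(A = c(x = long), B = c(y = mut)))
  got <- h2$identity[h2$query == "x" & h2$subject == "y"]
  expect_true(abs(got - 0.60) < 0.03)
})

test_that("unrelated random proteins produce no reportable hits", {
  set.seed(55)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pa <- setNames(vapply(1:15, function(i)
    paste(sample(aa, 100, TRUE), collapse = ""), ""), paste0("a", 1:15))
  pb <- setNames(vapply(1:15, function(i)
    paste(sample(aa, 100, TRUE), collapse = ""), ""), paste0("b", 1:15))
  hits <- all_vs_all_similarity(list(A = pa, B = pb), include_intra = FALSE)
  expect_equal(nrow(hits), 0)  # 225 random pairs, none above the floor
  # the default score floor sits above this empirical null
  raw <- all_vs_all_similarity(list(A = pa, B = pb), include_intra = FALSE,
                               min_report_identity = 0, min_report_coverage = 0,
                               min_report_score = -Inf)
  expect_lt(max(raw$score), 80)
})

test_that("planted families are recovered end to end on a small instance", {
  set.seed(77)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_fam <- 6; n_gen <- 4
  q <- 1 - sqrt(0.7)  # pairwise identity ~0.7 within families
  anc <- replicate(n_fam, paste(sample(aa, 180, TRUE), collapse = ""))
  proteomes <- list()
  truth <- list()
  for (g in seq_len(n_gen)) {
    prots <- character(0)
    for (f in seq_len(n_fam)) {
      v <- strsplit(anc[f], "")[[1]]
      hit <- runif(length(v)) < q
      v[hit] <- vapply(v[hit], function(a) sample(setdiff(aa, a), 1), "")
      prots[paste0("g", g, "_f", f)] <- paste(v, collapse = "")
      truth[[paste0("f", f)]] <- c(truth[[paste0("f", f)]],
                                   paste0("g", g, "_f", f))
    }
    proteomes[[paste0("g", g)]] <- prots
  }
  groups <- build_ortholog_groups(proteomes, include_singletons = FALSE)
  got <- groups_as_partition(groups)
  want <- lapply(truth, sort)
  names(want) <- NULL
  want <- want[order(vapply(want, `[`, "", 1))]
  expect_equal(got, want)
})
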