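# ortholog groups over hand-named genes: gene "gX_fY" belongs to family fY
toy_groups <- function(genomes, fams) {
  genes <- as.vector(outer(genomes, fams, function(g, f) paste0(g, "_", f)))
  fam_of <- sub("^.*_", "", genes)
  ortholog_groups(split(genes, fam_of),
                  setNames(sub("_.*$", "", genes), genes))
}

toy_candidates <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(region = paste0(r[[1]], "|op"), genome = r[[1]],
               operon = paste0(r[[1]], "_op"), lead_gene = r[[2]],
               offset = 10L, strand = "+", sequence = "ACGT", score = 9,
               stringsAsFactors = FALSE)))
}

test_that("the consistency filter applies the support and whitelist rules", {
  groups <- toy_groups(paste0("g", 1:5), c("f1", "f2"))
  cand <- toy_candidates(list(
    list("g1", "g1_f1"), list("g2", "g2_f1"), list("g3", "g3_f1"),
    list("g4", "g4_f1"),                     # f1 supported in 4 genomes
    list("g1", "g1_f2")))                    # f2 is a singleton
  acc <- consistency_filter(cand, groups, min_support = 3)
  expect_setequal(acc$lead_gene, paste0("g", 1:4, "_f1"))
  expect_true(all(acc$support == 4))
  # whitelisted lead genes survive without support
  acc_wl <- consistency_filter(cand, groups, min_support = 3,
                               functional_whitelist = "g1_f2")
  expect_true("g1_f2" %in% acc_wl$lead_gene)
  expect_equal(acc_wl$support[acc_wl$lead_gene == "g1_f2"], 1L)
})

test_that("raising min_support never adds interactions", {
  groups <- toy_groups(paste0("g", 1:6), c("f1", "f2", "f3"))
  set.seed(12)
  rows <- lapply(1:12, function(i) {
    g <- sample(paste0("g", 1:6), 1); f <- sample(c("f1", "f2", "f3"), 1)
    list(g, paste0(g, "_", f))
  })
  cand <- unique(toy_candidates(rows))
  prev <- NULL
  for (ms in 1:5) {
    acc <- consistency_filter(cand, groups, min_support = ms)
    if (!is.null(prev))
      expect_true(all(paste(acc$genome, acc$lead_gene) %in% prev))
    prev <- paste(acc$genome, acc$lead_gene)
  }
})

test_that("workflow 1a recovers planted regulons and respects TF presence", {
  b <- run_benchmark(101)
  expect_gte(b$evaluation$f1, 0.7)
  # every training-genome planted interaction is recovered
  ts <- b$sim$truth$sites
  m <- b$models$regA
  train <- ts[ts$regulon == "regA" & ts$genome %in% c("g01", "g02"), ]
  got <- paste(m$interactions$genome, m$interactions$lead_gene)
  expect_true(all(paste(train$genome, train$lead_gene) %in% got))

  # a genome whose TF ortholog is removed contributes no targets
  fam <- b$sim$truth$families
  fam2 <- fam[!(fam$genome == "g05" & fam$family == "tf_regA"), ]
  groups2 <- ortholog_groups(split(fam2$gene_id, fam2$family),
                             setNames(fam2$genome, fam2$gene_id))
  kr <- known_regulon("g01_tf_regA", train$lead_gene, train$sequence)
  m2 <- workflow1_expand(kr, b$ws, groups2, symmetry = "palindrome")
  expect_false("g05" %in% m2$interactions$genome)
})

test_that("workflow 1b discovers the planted motif from known genes alone", {
  b <- run_benchmark(55)  # reuse generated set; rerun 1b on it
  ts <- b$sim$truth$sites
  train <- ts[ts$regulon == "regB" & ts$genome %in% c("g01", "g02"), ]
  kr <- known_regulon("g01_tf_regB", unique(train$lead_gene))  # no sites
  m <- workflow1_expand(kr, b$ws, b$groups, symmetry = "palindrome",
                        width = 18, n_restarts = 10, seed = 9)
  expect_equal(m$workflow, "1b")
  expect_gte(pwm_correlation(m$fit$pwm, b$sim$pwms$regB), 0.9)
  expect_gt(nrow(m$interactions), 10)
})

test_that("workflow 2 projects through an ortholog map and errors without one", {
  b <- run_benchmark(77)
  ts <- b$sim$truth$sites
  members <- unique(ts$lead_gene[ts$regulon == "regC" & ts$genome == "g01"])
  ext_genes <- paste0("EXT_", seq_along(members))
  map <- data.frame(external_gene = c("EXT_TF", ext_genes),
                    gene_id = c("g01_tf_regC", members),
                    stringsAsFactors = FALSE)
  ext <- known_regulon("EXT_TF", ext_genes, organism = "model_sp")
  m <- workflow2_project(ext, map, b$ws, b$groups, symmetry = "palindrome",
                         width = 18, n_restarts = 10, seed = 3)
  expect_equal(m$workflow, "2")
  # recovered targets are the in-set planted ones, not the external ids
  expect_true(all(m$interactions$lead_gene %in% b$sim$truth$families$gene_id))
  tr <- b$sim$truth$membership
  tr <- tr[tr$regulon == "regC", ]
  hit <- paste(m$interactions$genome, m$interactions$lead_gene) %in%
    paste(tr$genome, tr$lead_gene)
  expect_gt(mean(hit), 0.5)

  # no mappable genes -> error
  empty_map <- data.frame(external_gene = character(), gene_id = character())
  expect_error(workflow2_project(ext, empty_map, b$ws, b$groups),
               "fewer than 3")
})

test_that("workflow 3 reconstructs a regulon from the conserved neighborhood", {
  b <- run_benchmark(31)
  m <- workflow3_ab_initio("g01_tf_regA", b$ws, b$groups, width = 18,
                           n_restarts = 10, seed = 21)
  expect_equal(m$workflow, "3")
  tr <- b$sim$truth$membership
  tr <- tr[tr$regulon == "regA", ]
  got <- paste(m$interactions$genome, m$interactions$lead_gene)
  overlap <- mean(paste(tr$genome, tr$lead_gene) %in% got)
  expect_gt(overlap, 0.5)
  # the TF's own operon is recovered where an autoregulatory site is planted
  auto <- b$sim$truth$sites
  auto <- auto[auto$regulon == "regA" & auto$role == "autoregulation", ]
  expect_gt(sum(paste(auto$genome, auto$lead_gene) %in% got), 0)

  # an unattainable neighborhood-support threshold is a hard error
  expect_error(workflow3_ab_initio("g01_tf_regA", b$ws, b$groups,
                                   min_neighborhood_support = 99),
               "no candidate training set")
})

test_that("autoregulation, cascades and co-regulation are detected", {
  cfg <- synthetic_config(
    n_genomes = c(a = 6),
    regulons = list(
      regulon_spec("regA", presence = 1, autoregulation = TRUE),
      regulon_spec("regB", presence = 1)),
    cascades = data.frame(from = "regA", to = "regB"),
    decoy_rate = 0)
  sim <- generate_genome_set(cfg, seed = 13)
  ws <- build_workspace(sim$genome_set)
  fam <- sim$truth$families
  groups <- ortholog_groups(split(fam$gene_id, fam$family),
                            setNames(fam$genome, fam$gene_id))
  ts <- sim$truth$sites
  models <- lapply(c("regA", "regB"), function(rn) {
    ks <- ts[ts$regulon == rn & ts$genome %in% c("g01", "g02"), ]
    workflow1_expand(known_regulon(paste0("g01_tf_", rn), ks$lead_gene,
                                   ks$sequence),
                     ws, groups, symmetry = "palindrome")
  })
  names(models) <- c("regA", "regB")

  auto <- detect_autoregulation(models$regA, ws, groups)
  expect_true(all(auto))   # presence 1 and autoregulation on
  expect_equal(attr(auto, "fraction"), 1)
  auto_b <- detect_autoregulation(models$regB, ws, groups)
  expect_equal(attr(auto_b, "fraction"), 0)

  casc <- detect_cascades(models, ws, groups)
  expect_true(any(casc$from == "g01_tf_regA" & casc$to == "g01_tf_regB"))
  expect_false(any(casc$from == casc$to))

  # the planted cascade makes regB's operon doubly regulated (regA + regB
  # autoregulation is off for regB, so co-regulation needs the cascade site
  # plus regB's own members -> check co-regulation on a member operon basis)
  co <- detect_coregulation(models)
  expect_true(all(co$n_regulators >= 2))
})

test_that("co-regulation classifies multiplicity from hand-built models", {
  int <- function(genome, operon) data.frame(
    region = paste0(genome, "|", operon), genome = genome, operon = operon,
    lead_gene = "x", offset = 1L, strand = "+", sequence = "AC", score = 1,
    support = 3L, stringsAsFactors = FALSE)
  m1 <- fake_model("tfA", int("g1", "op1"))
  m2 <- fake_model("tfB", rbind(int("g1", "op1"), int("g1", "op9")))
  m3 <- fake_model("tfC", int("g1", "op1"))
  co <- detect_coregulation(list(m1, m2, m3))
  expect_equal(nrow(co), 1)   # op9 is single-TF, not reported
  expect_equal(co$operon, "op1")
  expect_equal(co$n_regulators, 3L)
  expect_equal(co$multiplicity, "triple")
})

test_that("workflow 1a is idempotent once the training set is complete", {
  cfg <- synthetic_config(n_genomes = c(a = 6),
                          regulons = list(regulon_spec("regA", presence = 1)),
                          decoy_rate = 0)
  sim <- generate_genome_set(cfg, seed = 29)
  ws <- build_workspace(sim$genome_set)
  fam <- sim$truth$families
  groups <- ortholog_groups(split(fam$gene_id, fam$family),
                            setNames(fam$genome, fam$gene_id))
  ts <- sim$truth$sites
  kr <- known_regulon("g01_tf_regA", ts$lead_gene, ts$sequence)  # all sites
  m1 <- workflow1_expand(kr, ws, groups, symmetry = "palindrome")
  kr2 <- known_regulon("g01_tf_regA", m1$interactions$lead_gene,
                       m1$profile$training_sites)
  m2 <- workflow1_expand(kr2, ws, groups, symmetry = "palindrome")
  k1 <- sort(paste(m1$interactions$genome, m1$interactions$operon,
                   m1$interactions$offset))
  k2 <- sort(paste(m2$interactions$genome, m2$interactions$operon,
                   m2$interactions$offset))
  expect_identical(k1, k2)
})

test_that("footprinting export collects orthologous upstream regions", {
  sim <- generate_genome_set(synthetic_config(n_genomes = c(a = 4)), seed = 91)
  ws <- build_workspace(sim$genome_set)
  fam <- sim$truth$families
  groups <- ortholog_groups(split(fam$gene_id, fam$family),
                            setNames(fam$genome, fam$gene_id))
  lead <- sim$truth$membership$lead_gene[1]
  seqs <- footprint_regions(lead, ws, groups)
  expect_equal(length(seqs), 4)   # one region per genome
  path <- withr::local_tempfile(fileext = ".fna")
  footprint_regions(lead, ws, groups, path = path)
  expect_equal(length(Biostrings::readDNAStringSet(path)), 4)
  expect_error(footprint_regions("nonexistent", ws, groups), "not found")
})
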