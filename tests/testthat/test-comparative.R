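test_that("PWM alignment finds identity, orientation and planted mismatches", {
  set.seed(17)
  a <- make_planted_pwm(16, 24, "none")  # 1.5 bits/column: all conserved
  res <- align_pwms(a, a)
  expect_equal(res$offset, 0L)
  expect_equal(res$orientation, "forward")
  expect_equal(res$mismatches, 0L)

  rc <- a
  rc$counts <- a$counts[4:1, 16:1]
  dimnames(rc$counts) <- dimnames(a$counts)
  res_rc <- align_pwms(a, rc)
  expect_equal(res_rc$mismatches, 0L)
  expect_equal(res_rc$orientation, "reverse")

  # edit the consensus at exactly 3 high-information columns
  b <- a
  for (j in c(3, 8, 12)) {
    col <- b$counts[, j]
    top <- which.max(col)
    alt <- which.min(col)
    b$counts[c(top, alt), j] <- col[c(alt, top)]
  }
  res_b <- align_pwms(a, b)
  expect_equal(res_b$mismatches, 3L)
})

test_that("unalignable motifs and category boundaries are handled exactly", {
  set.seed(18)
  a <- make_planted_pwm(8, 10, "none")
  b <- make_planted_pwm(8, 10, "none")
  res <- align_pwms(a, b, min_overlap = 9)   # overlap can never reach 9
  expect_false(res$alignable)
  expect_true(is.na(res$mismatches))
  expect_error(align_pwms(a, make_planted_pwm(16, 20, "none")),
               "more than 6")

  expect_equal(categorize_motif_conservation(c(0, 1, 2, 4, 5, NA)),
               c("I", "I", "II", "II", "III", "III"))
})

test_that("regulon content comparison classifies core/periphery correctly", {
  genomes <- paste0("g", 1:4)
  fams <- paste0("f", 1:6)
  genes <- as.vector(outer(genomes, fams, paste, sep = "_"))
  groups <- ortholog_groups(split(genes, sub("^.*_", "", genes)),
                            setNames(sub("_.*$", "", genes), genes))
  mk <- function(name, fam_targets, genomes_used = genomes) {
    rows <- do.call(rbind, lapply(genomes_used, function(g)
      data.frame(region = "r", genome = g,
                 operon = paste0(g, "_op_", fam_targets),
                 lead_gene = paste0(g, "_", fam_targets),
                 offset = 0L, strand = "+", sequence = "A", score = 1,
                 support = 4L, stringsAsFactors = FALSE)))
    fake_model(name, rows)
  }
  a <- mk("tf_A", c("f1", "f2", "f3"))
  b_same <- mk("tf_B", c("f1", "f2", "f3"))
  b_part <- mk("tf_B", c("f1", "f2", "f5", "f6"))
  b_disj <- mk("tf_B", c("f5", "f6"))

  same <- compare_regulon_content(a, b_same, groups)
  expect_equal(same$content_class, "strictly_conserved")
  expect_equal(same$jaccard, 1)

  part <- compare_regulon_content(a, b_part, groups)
  expect_equal(part$content_class, "core_periphery")
  expect_setequal(part$core, group_of(groups, c("g1_f1", "g1_f2")))
  # conservation of counts: |core| + |periphery_a| = |targets_a|
  expect_equal(length(part$core) + length(part$periphery_a), 3)

  disj <- compare_regulon_content(a, b_disj, groups)
  expect_equal(disj$content_class, "different")
  expect_equal(length(disj$core), 0)

  # size classes: 3 target operons per genome -> global; 2 -> local
  expect_equal(part$size_class_a, "global")
  small <- mk("tf_A", c("f1", "f2"))
  expect_equal(compare_regulon_content(small, b_same, groups)$size_class_a,
               "local")
})

test_that("displacement detection reports complementarity and xenology", {
  mk_groups <- function(pres) {
    clusters <- lapply(names(pres), function(tg)
      paste0(pres[[tg]], "_", tg))
    names(clusters) <- names(pres)
    gg <- setNames(sub("_.*$", "", unlist(clusters)), unlist(clusters))
    og <- ortholog_groups(clusters, gg)
    # rename groups to the TF names for readability
    og$membership$group_id <- rep(names(pres),
                                  vapply(pres, length, 0L))
    og
  }
  g10 <- paste0("g", 1:10)
  groups <- mk_groups(list(tfX = g10[1:5], tfY = g10[6:10], tfZ = g10))
  subsys <- data.frame(tf_group = c("tfX", "tfY", "tfZ"),
                       subsystem = c("sugar", "sugar", "zinc"))
  fams <- c(tfX = "LacI", tfY = "LacI", tfZ = "Fur")
  disp <- detect_displacements(subsys, groups, fams)
  expect_equal(nrow(disp), 1)   # zinc has only one TF
  expect_true(disp$same_family)         # xenologous replacement
  expect_equal(disp$complementarity, 1) # disjoint presence
  expect_equal(disp$n_overlap, 0)

  # co-present TFs are redundancy, not displacement: complementarity 0
  groups2 <- mk_groups(list(tfX = g10, tfY = g10))
  disp2 <- detect_displacements(
    data.frame(tf_group = c("tfX", "tfY"), subsystem = "sugar"),
    groups2, c(tfX = "LacI", tfY = "ROK"))
  expect_equal(disp2$complementarity, 0)
  expect_false(disp2$same_family)
})

test_that("the TF census counts families and flags major ones", {
  g1 <- genome("G1", c(chr = bg_seq(2000, 41)), data.frame(
    gene_id = paste0("G1_", 1:4), replicon = "chr",
    start = c(1, 501, 1001, 1501), end = c(400, 900, 1400, 1900),
    strand = "+", product = "", protein = "M",
    is_tf = c(TRUE, TRUE, TRUE, FALSE),
    tf_family = c("LacI", "LacI", "MarR", NA), stringsAsFactors = FALSE),
    lineage = "A")
  g2 <- genome("G2", c(chr = bg_seq(2000, 42)), data.frame(
    gene_id = paste0("G2_", 1:3), replicon = "chr",
    start = c(1, 501, 1001), end = c(400, 900, 1400),
    strand = "+", product = "", protein = "M",
    is_tf = TRUE, tf_family = c("LacI", "LacI", "LacI"),
    stringsAsFactors = FALSE), lineage = "B")
  gs <- genome_set(list(g1, g2))
  cen <- tf_census(gs)
  expect_equal(unname(cen$per_genome[c("G1", "G2")]), c(3, 3))
  expect_equal(unname(cen$family_by_genome["LacI", ]), c(2, 3))
  expect_true("LacI" %in% cen$major_families)     # mean 2.5 >= 2
  expect_false("MarR" %in% cen$major_families)    # mean 0.5
  expect_equal(cen$lineage_specific$A, "MarR")    # only in lineage A
  expect_equal(cen$n_tfs, 6)
})

test_that("the census recovers planted TF family sizes exactly", {
  sim <- generate_genome_set(synthetic_config(n_genomes = c(a = 3, b = 3)),
                             seed = 71)
  cen <- tf_census(sim$genome_set)
  # one TF per regulon per genome was planted
  expect_true(all(cen$family_by_genome == 1))
  expect_equal(sort(rownames(cen$family_by_genome)),
               sort(names(sim$pwms)))
  expect_equal(cen$n_tfs, 3 * 6)
  # census totals are invariant under genome reordering
  gs_rev <- genome_set(rev(sim$genome_set$genomes))
  cen2 <- tf_census(gs_rev)
  expect_equal(cen2$per_genome[names(cen$per_genome)], cen$per_genome)
  expect_equal(cen2$n_tfs, cen$n_tfs)
})
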