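#' Run the standard synthetic reconstruction benchmark
#'
#' Generates a synthetic genome set (by default 10 genomes, 3 planted
#' palindromic regulons, presence probability 0.8, one near-threshold decoy
#' per upstream region), reconstructs each planted regulon with workflow 1a
#' using the known sites of two designated model genomes as the training
#' regulon, and evaluates the result against the planted truth.
#'
#' Ortholog groups are taken from the generator's ground-truth families: the
#' benchmark isolates scanning, threshold calibration and consistency
#' filtering from orthology inference (which has its own exact oracle tests).
#'
#' @param seed integer seed for the generator.
#' @param config a [synthetic_config()]; the default is the standard
#'   single-lineage 10-genome benchmark.
#' @param n_model_genomes number of model genomes whose planted sites form
#'   the known training regulon (default 2, mirroring training sets pooled
#'   from several experimentally characterized organisms).
#' @param min_support consistency-filter support (default 3).
#' @return list with `models`, `evaluation` (filtered), `unfiltered`
#'   (evaluation of raw scan candidates), `sim`, `ws`, `groups`.
#' @export
run_benchmark <- function(seed, config = NULL, n_model_genomes = 2,
                          min_support = 3) {
  if (is.null(config))
    config <- synthetic_config(n_genomes = c(lineage_a = 10))
  sim <- generate_genome_set(config, seed = seed)
  ws <- build_workspace(sim$genome_set)
  fam <- sim$truth$families
  groups <- ortholog_groups(split(fam$gene_id, fam$family),
                            setNames(fam$genome, fam$gene_id))
  gids <- names(sim$genome_set$genomes)
  model_genomes <- gids[seq_len(min(n_model_genomes, length(gids)))]
  ts <- sim$truth$sites
  models <- list()
  for (rn in names(sim$pwms)) {
    ks <- ts[ts$regulon == rn & ts$genome %in% model_genomes, , drop = FALSE]
    if (nrow(ks) < 2) next
    kr <- known_regulon(tf = paste0(model_genomes[1], "_tf_", rn),
                        regulated_genes = ks$lead_gene, sites = ks$sequence)
    models[[rn]] <- workflow1_expand(kr, ws, groups,
                                     symmetry = config$regulons[[
                                       match(rn, names(sim$pwms))]]$symmetry,
                                     min_support = min_support)
  }
  evaluation <- evaluate_network(models, sim$truth, ws, sim$pwms)
  raw_models <- lapply(models, function(m) {
    m$interactions <- m$candidates
    m
  })
  unfiltered <- evaluate_network(raw_models, sim$truth, ws)
  list(models = models, evaluation = evaluation, unfiltered = unfiltered,
       sim = sim, ws = ws, groups = groups)
}
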