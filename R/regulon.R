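#' Precompute operons and upstream regions for a genome set
#'
#' Workflows operate on a workspace: the genome set plus per-genome operon
#' tables and the upstream-region sequences of every operon lead gene.
#'
#' @param gs a [genome_set()].
#' @param max_gap operon intergenic-gap cutoff (bp).
#' @param upstream_bp,downstream_bp upstream window relative to the
#'   translation start.
#' @param truncate_at_upstream_gene clip regions at neighbouring genes.
#' @return object of class `"trn_workspace"`: `genome_set`, `operons` (list by
#'   genome), `regions` (named character vector `genome|operon` -> sequence),
#'   `region_info` (`data.frame` region / genome / operon / lead_gene /
#'   n_upstream).
#' @export
build_workspace <- function(gs, max_gap = 100, upstream_bp = 300,
                            downstream_bp = 25,
                            truncate_at_upstream_gene = TRUE) {
  operons <- lapply(gs$genomes, predict_operons, max_gap = max_gap)
  regions <- character(0)
  info <- list()
  for (gid in names(gs$genomes)) {
    ur <- extract_upstream_regions(gs$genomes[[gid]], operons[[gid]],
                                   upstream_bp, downstream_bp,
                                   truncate_at_upstream_gene)
    ur <- ur[!vapply(ur, function(r) r$empty, TRUE)]
    regions <- c(regions, vapply(ur, function(r) r$sequence, ""))
    info[[gid]] <- data.frame(
      region = names(ur),
      genome = gid,
      operon = vapply(ur, function(r) r$operon, ""),
      lead_gene = vapply(ur, function(r) r$lead_gene, ""),
      n_upstream = vapply(ur, function(r) r$n_upstream, 0L),
      stringsAsFactors = FALSE)
  }
  region_info <- do.call(rbind, info)
  rownames(region_info) <- NULL
  structure(list(genome_set = gs, operons = operons, regions = regions,
                 region_info = region_info,
                 params = list(max_gap = max_gap, upstream_bp = upstream_bp,
                               downstream_bp = downstream_bp)),
            class = "trn_workspace")
}

#' @export
print.trn_workspace <- function(x, ...) {
  cat("<trn_workspace>", length(x$genome_set$genomes), "genomes,",
      nrow(x$region_info), "upstream regions\n")
  invisible(x)
}

#' Describe a previously characterized regulon
#'
#' @param tf TF gene id (a gene of the genome set for workflows 1/3; an
#'   external gene id for workflow 2).
#' @param regulated_genes character vector of regulated gene ids (non-empty).
#' @param sites optional known binding-site words.
#' @param organism source organism tag.
#' @param provenance literature tag.
#' @return object of class `"known_regulon"`.
#' @export
known_regulon <- function(tf, regulated_genes, sites = NULL,
                          organism = "", provenance = "") {
  stopifnot(length(regulated_genes) >= 1)
  structure(list(tf = tf, regulated_genes = regulated_genes,
                 known_sites = sites, source_organism = organism,
                 provenance = provenance),
            class = "known_regulon")
}

# operon ids containing each of `gene_ids`, per genome; returns region ids
regions_of_genes <- function(ws, gene_ids) {
  hits <- character(0)
  for (gid in names(ws$operons)) {
    ops <- ws$operons[[gid]]
    has <- vapply(ops$genes, function(gg) any(gg %in% gene_ids), TRUE)
    if (any(has))
      hits <- c(hits, paste0(gid, "|", ops$operon_id[has]))
  }
  intersect(hits, ws$region_info$region)
}

# genomes in which a TF ortholog group has a member
tf_presence <- function(groups, tf_group) {
  m <- groups$membership
  unique(m$genome[m$group_id == tf_group])
}

candidate_interactions <- function(sites, ws) {
  if (!nrow(sites))
    return(data.frame(region = character(), genome = character(),
                      operon = character(), lead_gene = character(),
                      offset = integer(), strand = character(),
                      sequence = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  info <- ws$region_info[match(sites$region, ws$region_info$region), ]
  cbind(sites["region"], info[, c("genome", "operon", "lead_gene")],
        sites[, c("offset", "strand", "sequence", "score")],
        row.names = NULL)
}

#' Cross-genome consistency filter
#'
#' A candidate interaction (genome, operon) is accepted iff the operon's lead
#' gene belongs to an ortholog group whose members' operons carry
#' above-threshold sites in at least `min_support` genomes (counting the
#' candidate's own genome), or the lead gene is whitelisted as functionally
#' related.
#'
#' @param candidates `data.frame` of candidate interactions with at least
#'   `genome`, `operon` and `lead_gene` columns (as produced internally from
#'   [scan_profile()] hits).
#' @param groups [build_ortholog_groups()] result.
#' @param min_support minimum number of supporting genomes (default 3).
#' @param functional_whitelist character vector of lead-gene ids exempt from
#'   the support requirement.
#' @return the accepted subset with a `support` column appended.
#' @export
consistency_filter <- function(candidates, groups, min_support = 3,
                               functional_whitelist = NULL) {
  if (!nrow(candidates)) {
    candidates$support <- integer(0)
    return(candidates)
  }
  grp <- group_of(groups, candidates$lead_gene)
  grp[is.na(grp)] <- paste0("ungrouped:", candidates$lead_gene[is.na(grp)])
  per_gene <- unique(data.frame(grp = grp, genome = candidates$genome,
                                stringsAsFactors = FALSE))
  supp_tab <- table(per_gene$grp)
  support <- as.integer(supp_tab[grp])
  keep <- support >= min_support |
    candidates$lead_gene %in% functional_whitelist
  out <- candidates[keep, , drop = FALSE]
  out$support <- support[keep]
  rownames(out) <- NULL
  out
}

new_regulon_model <- function(name, tf_group, profile, interactions, workflow,
                              lineage = "", fit = NULL, candidates = NULL) {
  structure(list(name = name, tf_group = tf_group, lineage = lineage,
                 profile = profile, interactions = interactions,
                 workflow = workflow, fit = fit, candidates = candidates),
            class = "regulon_model")
}

#' @export
print.regulon_model <- function(x, ...) {
  cat("<regulon_model>", x$name, "(workflow", paste0(x$workflow, ")"), "\n")
  cat("  TF group:", x$tf_group, "| threshold",
      sprintf("%.2f", x$profile$threshold), "\n")
  cat("  interactions:", nrow(x$interactions), "in",
      length(unique(x$interactions$genome)), "genomes\n")
  invisible(x)
}

# shared back half of every workflow: scan, filter, one PWM update, rescan
expand_from_profile <- function(profile, ws, groups, tf_group, min_support,
                                functional_whitelist, symmetry, spacer,
                                rebuild = TRUE) {
  present <- tf_presence(groups, tf_group)
  info <- ws$region_info
  scan_regions <- ws$regions[info$region[info$genome %in% present]]
  raw <- function(prof)
    candidate_interactions(scan_profile(prof, scan_regions), ws)
  candidates <- raw(profile)
  accepted <- consistency_filter(candidates, groups, min_support,
                                 functional_whitelist)
  if (rebuild && nrow(accepted)) {
    training <- unique(c(profile$training_sites, accepted$sequence))
    profile <- build_profile(training, name = profile$name,
                             pseudocount = profile$pwm$pseudocount,
                             background = profile$pwm$background,
                             symmetry = symmetry, spacer = spacer)
    candidates <- raw(profile)
    accepted <- consistency_filter(candidates, groups, min_support,
                                   functional_whitelist)
  }
  accepted <- accepted[order(accepted$genome, accepted$operon, accepted$offset), ,
                       drop = FALSE]
  rownames(accepted) <- NULL
  rownames(candidates) <- NULL
  list(profile = profile, interactions = accepted, candidates = candidates)
}

#' Workflow 1: expand and project a known regulon
#'
#' Variant 1a (known sites): a profile is built from the known site words,
#' all genomes carrying the TF are scanned, consistency-accepted novel sites
#' are added to the training set, the PWM is rebuilt once and the genomes are
#' rescanned. Variant 1b (known genes only): the upstream regions of the
#' known genes and their orthologs seed motif discovery, then proceed as 1a.
#'
#' @param known a [known_regulon()].
#' @param ws a [build_workspace()].
#' @param groups ortholog groups over the genome set.
#' @param symmetry,spacer motif symmetry (used for PWM building/discovery).
#' @param min_support,functional_whitelist see [consistency_filter()].
#' @param seed seed for motif discovery (1b only).
#' @param ... further arguments to [discover_motif()] (1b only).
#' @return a `"regulon_model"`.
#' @export
workflow1_expand <- function(known, ws, groups, symmetry = "palindrome",
                             spacer = 0, min_support = 3,
                             functional_whitelist = NULL, seed = NULL, ...) {
  tf_group <- group_of(groups, known$tf)
  if (is.na(tf_group)) stop("TF gene not found in ortholog groups: ", known$tf)
  fit <- NULL
  if (!is.null(known$known_sites) && length(known$known_sites)) {
    wf <- "1a"
    profile <- build_profile(known$known_sites, name = known$tf,
                             symmetry = symmetry, spacer = spacer)
  } else {
    wf <- "1b"
    seed_genes <- known$regulated_genes
    seed_groups <- group_of(groups, seed_genes)
    m <- groups$membership
    orthologs <- m$gene_id[m$group_id %in% seed_groups[!is.na(seed_groups)]]
    train_ids <- regions_of_genes(ws, unique(c(seed_genes, orthologs)))
    if (!length(train_ids)) stop("training set empty: no orthologs of the known genes")
    fit <- discover_motif(ws$regions[train_ids], symmetry = symmetry,
                          spacer = spacer, seed = seed, ...)
    if (!nrow(fit$sites)) stop("motif discovery assigned no sites")
    profile <- build_profile(fit$sites$sequence, name = known$tf,
                             background = fit$background,
                             symmetry = symmetry, spacer = spacer)
  }
  res <- expand_from_profile(profile, ws, groups, tf_group, min_support,
                             functional_whitelist, symmetry, spacer)
  new_regulon_model(known$tf, tf_group, res$profile, res$interactions, wf,
                    fit = fit, candidates = res$candidates)
}

#' Workflow 2: project a regulon known in an external model organism
#'
#' The external regulated genes are mapped into the genome set through an
#' ortholog map; the upstream regions of the mapped genes seed motif
#' discovery, and reconstruction proceeds as workflow 1b.
#'
#' @param external a [known_regulon()] describing the external regulon.
#' @param ortholog_map `data.frame` with columns `external_gene`, `gene_id`
#'   linking external genes to genes of the genome set; rows for the external
#'   TF itself map it to its in-set ortholog(s).
#' @inheritParams workflow1_expand
#' @export
workflow2_project <- function(external, ortholog_map, ws, groups,
                              symmetry = "palindrome", spacer = 0,
                              min_support = 3, functional_whitelist = NULL,
                              seed = NULL, ...) {
  mapped <- ortholog_map$gene_id[ortholog_map$external_gene %in%
                                   external$regulated_genes]
  mapped <- unique(mapped)
  if (length(mapped) < 3)
    stop("fewer than 3 external regulon genes map into the genome set; ",
         "motif discovery would be unreliable")
  tf_in_set <- ortholog_map$gene_id[ortholog_map$external_gene == external$tf]
  if (!length(tf_in_set)) stop("external TF has no ortholog in the genome set")
  proxy <- known_regulon(tf = tf_in_set[1], regulated_genes = mapped,
                         organism = external$source_organism,
                         provenance = external$provenance)
  model <- workflow1_expand(proxy, ws, groups, symmetry, spacer, min_support,
                            functional_whitelist, seed, ...)
  model$name <- external$tf
  model$workflow <- "2"
  model
}

#' Workflow 3: ab initio regulon inference from conserved gene neighborhoods
#'
#' Candidate co-regulated genes are those whose ortholog groups recur within
#' `neighborhood_radius` genes of the TF gene in at least
#' `min_neighborhood_support` genomes; their pooled upstream regions seed
#' motif discovery, followed by scanning and consistency filtering.
#'
#' @param tf_gene a TF gene id present in the ortholog groups.
#' @param neighborhood_radius neighborhood size in genes (default 5).
#' @param min_neighborhood_support minimum number of genomes in which a
#'   neighbour ortholog group must recur (default 3).
#' @inheritParams workflow1_expand
#' @export
workflow3_ab_initio <- function(tf_gene, ws, groups, neighborhood_radius = 5,
                                min_neighborhood_support = 3,
                                symmetry = "palindrome", spacer = 0,
                                min_support = 3, functional_whitelist = NULL,
                                seed = NULL, ...) {
  tf_group <- group_of(groups, tf_gene)
  if (is.na(tf_group)) stop("TF gene not found in ortholog groups: ", tf_gene)
  m <- groups$membership
  tf_members <- m[m$group_id == tf_group, , drop = FALSE]
  if (nrow(unique(tf_members["genome"])) < 3)
    stop("TF ortholog group present in fewer than 3 genomes")
  neigh <- list()
  for (i in seq_len(nrow(tf_members))) {
    gid <- tf_members$genome[i]
    genes <- ws$genome_set$genomes[[gid]]$genes
    genes <- genes[order(genes$replicon, genes$start), , drop = FALSE]
    k <- which(genes$gene_id == tf_members$gene_id[i])
    if (!length(k)) next
    ix <- seq.int(max(1L, k - neighborhood_radius),
                  min(nrow(genes), k + neighborhood_radius))
    ix <- ix[genes$replicon[ix] == genes$replicon[k]]
    ng <- group_of(groups, genes$gene_id[ix])
    neigh[[length(neigh) + 1L]] <- data.frame(
      genome = gid, group = ng[!is.na(ng)], stringsAsFactors = FALSE)
  }
  neigh <- unique(do.call(rbind, neigh))
  supp <- table(neigh$group)
  cand_groups <- setdiff(names(supp)[supp >= min_neighborhood_support], NA)
  if (!length(cand_groups))
    stop("no candidate training set: no conserved gene neighborhood around ",
         tf_gene)
  cand_genes <- m$gene_id[m$group_id %in% cand_groups]
  train_ids <- regions_of_genes(ws, cand_genes)
  if (length(train_ids) < 3)
    stop("no candidate training set: fewer than 3 upstream regions")
  fit <- discover_motif(ws$regions[train_ids], symmetry = symmetry,
                        spacer = spacer, seed = seed, ...)
  if (!nrow(fit$sites)) stop("motif discovery assigned no sites")
  profile <- build_profile(fit$sites$sequence, name = tf_gene,
                           background = fit$background,
                           symmetry = symmetry, spacer = spacer)
  res <- expand_from_profile(profile, ws, groups, tf_group, min_support,
                             functional_whitelist, symmetry, spacer)
  new_regulon_model(tf_gene, tf_group, res$profile, res$interactions, "3",
                    fit = fit, candidates = res$candidates)
}

# the operon of the TF gene of `model` in genome `gid`, or NA
tf_operon <- function(model, ws, groups, gid) {
  m <- groups$membership
  tf_genes <- m$gene_id[m$group_id == model$tf_group & m$genome == gid]
  if (!length(tf_genes)) return(NA_character_)
  ops <- ws$operons[[gid]]
  has <- vapply(ops$genes, function(gg) any(gg %in% tf_genes), TRUE)
  if (!any(has)) return(NA_character_)
  ops$operon_id[which(has)[1]]
}

#' Detect autoregulation
#'
#' A TF autoregulates in a genome iff an accepted site lies in the upstream
#' region of the operon containing the TF gene. Genomes lacking the TF are
#' excluded (returned as `NA`).
#'
#' @param model a `regulon_model`.
#' @param ws the workspace.
#' @param groups ortholog groups.
#' @return named logical vector over genomes; attribute `"fraction"` is the
#'   autoregulated share among genomes carrying the TF.
#' @export
detect_autoregulation <- function(model, ws, groups) {
  gids <- names(ws$genome_set$genomes)
  out <- setNames(rep(NA, length(gids)), gids)
  for (gid in gids) {
    op <- tf_operon(model, ws, groups, gid)
    if (is.na(op)) next
    out[gid] <- any(model$interactions$genome == gid &
                      model$interactions$operon == op)
  }
  attr(out, "fraction") <- mean(out, na.rm = TRUE)
  out
}

#' Detect TF-to-TF regulatory cascades
#'
#' Edge A -> B iff an accepted interaction of regulon A targets an operon
#' containing the TF gene of regulon B (self-edges are autoregulation and are
#' excluded).
#'
#' @param models list of `regulon_model`s (>= 2).
#' @param ws the workspace.
#' @param groups ortholog groups.
#' @return `data.frame` with columns `from`, `to`, `genome`, `operon`.
#' @export
detect_cascades <- function(models, ws, groups) {
  stopifnot(length(models) >= 2)
  gids <- names(ws$genome_set$genomes)
  tf_ops <- lapply(models, function(m)
    setNames(vapply(gids, function(g) tf_operon(m, ws, groups, g), ""), gids))
  names(tf_ops) <- vapply(models, function(m) m$name, "")
  out <- list()
  for (a in seq_along(models)) {
    ia <- models[[a]]$interactions
    if (!nrow(ia)) next
    for (b in seq_along(models)) {
      if (models[[a]]$tf_group == models[[b]]$tf_group) next
      opb <- tf_ops[[b]]
      hit <- ia$operon == opb[ia$genome] & !is.na(opb[ia$genome])
      if (any(hit))
        out[[length(out) + 1L]] <- data.frame(
          from = models[[a]]$name, to = models[[b]]$name,
          genome = ia$genome[hit], operon = ia$operon[hit],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(from = character(), to = character(),
                      genome = character(), operon = character(),
                      stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Detect operons regulated by two or more TFs
#'
#' @param models list of `regulon_model`s (>= 2).
#' @return `data.frame` with `genome`, `operon`, `regulators`
#'   (comma-separated), `n_regulators` and `multiplicity`
#'   (double/triple/quadruple).
#' @export
detect_coregulation <- function(models) {
  stopifnot(length(models) >= 2)
  all_int <- do.call(rbind, lapply(models, function(m) {
    if (!nrow(m$interactions)) return(NULL)
    unique(data.frame(regulator = m$name, genome = m$interactions$genome,
                      operon = m$interactions$operon, stringsAsFactors = FALSE))
  }))
  if (is.null(all_int) || !nrow(all_int))
    return(data.frame(genome = character(), operon = character(),
                      regulators = character(), n_regulators = integer(),
                      multiplicity = character(), stringsAsFactors = FALSE))
  key <- paste(all_int$genome, all_int$operon, sep = "\r")
  sets <- split(all_int$regulator, key)
  sets <- sets[vapply(sets, function(x) length(unique(x)), 0L) >= 2]
  if (!length(sets))
    return(data.frame(genome = character(), operon = character(),
                      regulators = character(), n_regulators = integer(),
                      multiplicity = character(), stringsAsFactors = FALSE))
  parts <- strsplit(names(sets), "\r", fixed = TRUE)
  n <- vapply(sets, function(x) length(unique(x)), 0L)
  data.frame(genome = vapply(parts, `[`, "", 1),
             operon = vapply(parts, `[`, "", 2),
             regulators = vapply(sets, function(x)
               paste(sort(unique(x)), collapse = ","), ""),
             n_regulators = n,
             multiplicity = ifelse(n == 2, "double",
                            ifelse(n == 3, "triple", "quadruple")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export orthologous upstream regions for phylogenetic footprinting
#'
#' Collects the upstream regions of all operons whose lead genes share an
#' ortholog group with `lead_gene` and writes them as FASTA for external
#' multiple alignment and manual review; candidate regulatory elements appear
#' as conserved blocks in such alignments. This supports footprinting as a
#' manual validation step only — no automated decision is made.
#'
#' @param lead_gene a lead-gene id anchoring the ortholog group.
#' @param ws a [build_workspace()].
#' @param groups ortholog groups.
#' @param path optional output FASTA path.
#' @return named character vector of region sequences (invisibly when
#'   written to `path`).
#' @export
footprint_regions <- function(lead_gene, ws, groups, path = NULL) {
  tg <- group_of(groups, lead_gene)
  if (is.na(tg)) stop("gene not found in ortholog groups: ", lead_gene)
  m <- groups$membership
  genes <- m$gene_id[m$group_id == tg]
  info <- ws$region_info[ws$region_info$lead_gene %in% genes, , drop = FALSE]
  seqs <- ws$regions[info$region]
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
    return(invisible(seqs))
  }
  seqs
}
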