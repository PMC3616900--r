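#' Genetic census of transcription factors
#'
#' Per-genome and per-family TF counts, "major" families (mean of at least two
#' representatives per genome), lineage-specific families, and per-lineage
#' conservation classes of TF ortholog groups.
#'
#' @param gs a [genome_set()].
#' @param tf_table `data.frame` with columns `gene_id`, `family`; defaults to
#'   the genes flagged `is_tf` in the genome set, with their `tf_family`.
#' @param groups optional ortholog groups (enables conservation classes).
#' @return object of class `"tf_census"`: list with `per_genome` counts,
#'   `family_by_genome` matrix, `major_families`, `lineage_specific` families
#'   and `group_classes` (per lineage), plus totals.
#' @export
tf_census <- function(gs, tf_table = NULL, groups = NULL) {
  if (is.null(tf_table)) {
    tf_table <- do.call(rbind, lapply(gs$genomes, function(g) {
      tf <- g$genes[g$genes$is_tf, , drop = FALSE]
      if (!nrow(tf)) return(NULL)
      data.frame(gene_id = tf$gene_id, family = tf$tf_family,
                 genome = g$id, stringsAsFactors = FALSE)
    }))
  } else {
    gene_genome <- unlist(lapply(gs$genomes, function(g)
      setNames(rep(g$id, nrow(g$genes)), g$genes$gene_id)))
    tf_table$genome <- gene_genome[tf_table$gene_id]
  }
  if (is.null(tf_table) || !nrow(tf_table)) stop("no TF genes found")
  gids <- names(gs$genomes)
  fam <- table(factor(tf_table$family),
               factor(tf_table$genome, levels = gids))
  per_genome <- colSums(fam)
  major <- rownames(fam)[rowMeans(fam) >= 2]
  lineages <- gs$lineages
  fam_lin <- vapply(unique(lineages), function(ln)
    rowSums(fam[, lineages[colnames(fam)] == ln, drop = FALSE]) > 0,
    logical(nrow(fam)))
  lineage_specific <- lapply(seq_len(ncol(fam_lin)), function(j)
    rownames(fam)[fam_lin[, j] & rowSums(fam_lin) == 1])
  names(lineage_specific) <- colnames(fam_lin)
  group_classes <- NULL
  if (!is.null(groups)) {
    tf_groups <- unique(group_of(groups, tf_table$gene_id))
    tf_groups <- tf_groups[!is.na(tf_groups)]
    group_classes <- vapply(unique(lineages), function(ln)
      classify_conservation(groups, lineages, ln)[tf_groups],
      character(length(tf_groups)))
    if (is.null(dim(group_classes)))
      group_classes <- matrix(group_classes, ncol = length(unique(lineages)),
                              dimnames = list(tf_groups, unique(lineages)))
    else rownames(group_classes) <- tf_groups
  }
  structure(list(per_genome = per_genome, family_by_genome = as.matrix(fam),
                 major_families = major, lineage_specific = lineage_specific,
                 group_classes = group_classes,
                 n_tfs = nrow(tf_table), n_families = nrow(fam)),
            class = "tf_census")
}

#' @export
print.tf_census <- function(x, ...) {
  cat("<tf_census>", x$n_tfs, "TFs in", length(x$per_genome), "genomes,",
      x$n_families, "families (", length(x$major_families), "major )\n")
  invisible(x)
}

#' Align two PWMs and count mismatches at conserved positions
#'
#' All relative offsets with `|shift| <= max_shift` and both orientations of
#' `b` are tried; the alignment maximising the summed per-column correlation
#' of the base-frequency vectors is chosen. Conserved positions are column
#' pairs where both motifs carry at least `ic_min` bits; a mismatch is a
#' conserved pair whose consensus bases differ.
#'
#' @param a,b `pwm` objects (widths within 6 of each other).
#' @param max_shift maximum offset magnitude (default 3).
#' @param min_overlap minimum overlapping columns; below it the motifs are
#'   reported as not alignable (`mismatches = NA`).
#' @param ic_min conserved-position information cutoff in bits (default 1.0).
#' @return list with `offset`, `orientation` (`"forward"`/`"reverse"`),
#'   `score`, `mismatches` (NA when not alignable), `alignable`.
#' @export
align_pwms <- function(a, b, max_shift = 3, min_overlap = 8, ic_min = 1.0) {
  if (abs(a$width - b$width) > 6)
    stop("PWM widths differ by more than 6 columns")
  fa <- pwm_freq(a); ia <- pwm_ic(a)
  best <- list(score = -Inf, offset = 0L, orientation = "forward",
               mismatches = NA_integer_, alignable = FALSE)
  for (orient in c("forward", "reverse")) {
    fb <- pwm_freq(b); ib <- pwm_ic(b)
    if (orient == "reverse") { fb <- revcomp_matrix(fb); ib <- rev(ib) }
    for (shift in seq.int(-max_shift, max_shift)) {
      ja <- seq_len(a$width)
      jb <- ja - shift
      ok <- jb >= 1 & jb <= b$width
      if (sum(ok) < min_overlap) next
      ja <- ja[ok]; jb <- jb[ok]
      sc <- sum(vapply(seq_along(ja), function(k)
        cor(fa[, ja[k]], fb[, jb[k]]), 0))
      if (sc > best$score) {
        cons <- ia[ja] >= ic_min & ib[jb] >= ic_min
        ca <- apply(fa[, ja, drop = FALSE], 2, which.max)
        cb <- apply(fb[, jb, drop = FALSE], 2, which.max)
        best <- list(score = sc, offset = shift, orientation = orient,
                     mismatches = sum(cons & ca != cb), alignable = TRUE)
      }
    }
  }
  best
}

#' Categorize cross-lineage motif conservation
#'
#' Category I: at most 1 mismatch at conserved positions; category II: 2 to 4
#' mismatches; category III: 5 or more, or motifs not alignable.
#'
#' @param mismatches mismatch count from [align_pwms()] (`NA` = not
#'   alignable).
#' @return `"I"`, `"II"` or `"III"`.
#' @export
categorize_motif_conservation <- function(mismatches) {
  vapply(mismatches, function(m) {
    if (is.na(m) || m >= 5) "III"
    else if (m <= 1) "I"
    else "II"
  }, "")
}

#' Compare regulon gene content between two lineages
#'
#' Target operons of each regulon are mapped to ortholog groups of their lead
#' genes; the comparison reports the shared core, lineage-specific
#' peripheries, a content class and per-lineage size classes.
#'
#' Content classes: `strictly_conserved` iff the Jaccard index of the two
#' target-group sets is at least `jaccard_conserved`; `different` iff the
#' intersection is empty; otherwise `core_periphery`. Size class is `local`
#' when the mean number of target operons per genome (over genomes with any
#' target) is below 3, else `global`.
#'
#' @param model_a,model_b `regulon_model`s reconstructed for orthologous TFs
#'   in two lineages.
#' @param groups ortholog groups spanning both lineages.
#' @param jaccard_conserved cutoff for `strictly_conserved` (default 0.75).
#' @return list with `core`, `periphery_a`, `periphery_b`, `jaccard`,
#'   `content_class`, `size_class_a`, `size_class_b`.
#' @export
compare_regulon_content <- function(model_a, model_b, groups,
                                    jaccard_conserved = 0.75) {
  target_groups <- function(m) {
    g <- group_of(groups, unique(m$interactions$lead_gene))
    sort(unique(g[!is.na(g)]))
  }
  size_class <- function(m) {
    if (!nrow(m$interactions)) return("local")
    ops <- unique(m$interactions[, c("genome", "operon")])
    if (mean(table(ops$genome)) < 3) "local" else "global"
  }
  ga <- target_groups(model_a); gb <- target_groups(model_b)
  core <- intersect(ga, gb)
  uni <- union(ga, gb)
  jac <- if (length(uni)) length(core) / length(uni) else 1
  cls <- if (jac >= jaccard_conserved) "strictly_conserved"
         else if (!length(core)) "different"
         else "core_periphery"
  list(core = core, periphery_a = setdiff(ga, core),
       periphery_b = setdiff(gb, core), jaccard = jac, content_class = cls,
       size_class_a = size_class(model_a), size_class_b = size_class(model_b))
}

#' Detect non-orthologous TF displacements within subsystems
#'
#' For every biological subsystem regulated by two or more non-orthologous TF
#' groups, reports each TF pair with a xenologous flag (same protein family),
#' the genomes where both TFs are present, and the complementarity: the
#' fraction of subsystem-carrying genomes (union of the two presence sets)
#' covered by exactly one of the two TFs.
#'
#' @param subsystem_assignments `data.frame` with columns `tf_group`,
#'   `subsystem`.
#' @param groups ortholog groups (for presence profiles).
#' @param tf_families named character vector tf_group -> protein family.
#' @return `data.frame` with one row per TF pair per subsystem.
#' @export
detect_displacements <- function(subsystem_assignments, groups, tf_families) {
  out <- list()
  for (ss in unique(subsystem_assignments$subsystem)) {
    tfs <- unique(subsystem_assignments$tf_group[
      subsystem_assignments$subsystem == ss])
    if (length(tfs) < 2) next
    pres <- lapply(tfs, function(tg) tf_presence(groups, tg))
    names(pres) <- tfs
    pairs <- utils::combn(tfs, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ov <- intersect(pres[[a]], pres[[b]])
      uni <- union(pres[[a]], pres[[b]])
      compl <- if (length(uni)) (length(uni) - length(ov)) / length(uni) else 0
      out[[length(out) + 1L]] <- data.frame(
        subsystem = ss, tf_group_a = a, tf_group_b = b,
        same_family = identical(unname(tf_families[a]), unname(tf_families[b])),
        n_overlap = length(ov), n_union = length(uni),
        complementarity = compl,
        overlap = paste(sort(ov), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(subsystem = character(), tf_group_a = character(),
                      tf_group_b = character(), same_family = logical(),
                      n_overlap = integer(), n_union = integer(),
                      complementarity = numeric(), overlap = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
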