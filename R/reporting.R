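#' Per-genome network statistics from reconstructed regulons
#'
#' @param models list of `regulon_model`s.
#' @param ws the [build_workspace()] the models were reconstructed on.
#' @return `data.frame` with one row per genome: `genome`, `lineage`, `tfs`
#'   (regulons with at least one interaction), `target_genes`,
#'   `target_operons`, `interactions` (distinct TF-operon pairs).
#' @export
network_stats <- function(models, ws) {
  gids <- names(ws$genome_set$genomes)
  all_int <- do.call(rbind, lapply(models, function(m) {
    if (!nrow(m$interactions)) return(NULL)
    data.frame(tf = m$name, genome = m$interactions$genome,
               operon = m$interactions$operon, stringsAsFactors = FALSE)
  }))
  if (is.null(all_int))
    all_int <- data.frame(tf = character(), genome = character(),
                          operon = character(), stringsAsFactors = FALSE)
  rows <- lapply(gids, function(g) {
    sub <- all_int[all_int$genome == g, , drop = FALSE]
    ops <- unique(sub$operon)
    genes <- unlist(lapply(ws$operons[[g]]$genes[
      ws$operons[[g]]$operon_id %in% ops], identity))
    data.frame(genome = g, lineage = unname(ws$genome_set$lineages[g]),
               tfs = length(unique(sub$tf)),
               target_genes = length(unique(genes)),
               target_operons = length(ops),
               interactions = nrow(unique(sub[, c("tf", "operon")])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a per-genome network-statistics table
#'
#' Computes the collection aggregates over a per-genome statistics table:
#' per-lineage column totals, the mean number of regulons per genome
#' (reported to one decimal), and per-column minima / maxima.
#'
#' @param stats `data.frame` with columns `genome`, `lineage`, `tfs`,
#'   `target_genes`, `target_operons`, `interactions` — either from
#'   [network_stats()] or a loaded reference table.
#' @return object of class `"network_summary"`.
#' @export
summarize_network <- function(stats) {
  need <- c("genome", "lineage", "tfs", "target_genes", "target_operons",
            "interactions")
  stopifnot(all(need %in% names(stats)))
  num_cols <- c("tfs", "target_genes", "target_operons", "interactions")
  totals <- aggregate(stats[num_cols], by = list(lineage = stats$lineage), sum)
  structure(list(
    per_genome = stats,
    totals = totals,
    n_genomes = nrow(stats),
    mean_regulons = round(mean(stats$tfs), 1),
    min_regulons = min(stats$tfs), max_regulons = max(stats$tfs),
    min_target_genes = min(stats$target_genes),
    max_target_genes = max(stats$target_genes),
    genome_min_regulons = stats$genome[which.min(stats$tfs)],
    genome_max_regulons = stats$genome[which.max(stats$tfs)]),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary>", x$n_genomes, "genomes\n")
  cat("  regulons/genome: mean", x$mean_regulons, "| min", x$min_regulons,
      paste0("(", x$genome_min_regulons, ")"), "| max", x$max_regulons,
      paste0("(", x$genome_max_regulons, ")"), "\n")
  cat("  target genes: min", x$min_target_genes, "| max",
      x$max_target_genes, "\n")
  cat("  lineage totals:\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Distinct-union counts across a lineage
#'
#' The "non-overlapping" view of a lineage: the number of distinct TF ortholog
#' groups and distinct target ortholog groups across all its genomes (an
#' ortholog group regulated in several genomes counts once).
#'
#' @param models list of `regulon_model`s.
#' @param groups ortholog groups.
#' @param lineages named vector genome -> lineage.
#' @return `data.frame` per lineage: `tf_groups`, `target_groups`.
#' @export
lineage_distinct_counts <- function(models, groups, lineages) {
  rows <- lapply(unique(lineages), function(ln) {
    gl <- names(lineages)[lineages == ln]
    tf <- unique(vapply(models, function(m) m$tf_group, ""))
    tf <- tf[vapply(tf, function(tg)
      any(tf_presence(groups, tg) %in% gl), TRUE)]
    tg <- unique(unlist(lapply(models, function(m) {
      sub <- m$interactions[m$interactions$genome %in% gl, , drop = FALSE]
      group_of(groups, sub$lead_gene)
    })))
    data.frame(lineage = ln, tf_groups = length(tf),
               target_groups = length(tg[!is.na(tg)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify regulon presence per lineage and tabulate class pairs
#'
#' Each TF regulon is `universal` in a lineage when present in all its
#' genomes, `mosaic` when present in some but not all, `absent` otherwise;
#' the summary counts regulons per class pair over two lineages.
#'
#' @param x either a loaded distribution reference table (`data.frame` with
#'   columns `class_a`, `class_b`, `n_regulons`) or a list of
#'   `regulon_model`s (then `groups` and `lineages` are required).
#' @param groups,lineages see [lineage_distinct_counts()].
#' @return object of class `"distribution_table"`: the class-pair count table
#'   plus totals (`total`, `shared` = both lineages, and per-lineage-specific
#'   counts).
#' @export
summarize_distribution <- function(x, groups = NULL, lineages = NULL) {
  if (is.data.frame(x)) {
    tab <- x
  } else {
    stopifnot(!is.null(groups), !is.null(lineages))
    lns <- unique(lineages)
    stopifnot(length(lns) == 2)
    classify <- function(m, ln) {
      gl <- names(lineages)[lineages == ln]
      pres <- intersect(tf_presence(groups, m$tf_group), gl)
      if (length(pres) == 0) "absent"
      else if (length(pres) == length(gl)) "universal"
      else "mosaic"
    }
    cls <- data.frame(
      class_a = vapply(x, classify, "", ln = lns[1]),
      class_b = vapply(x, classify, "", ln = lns[2]),
      stringsAsFactors = FALSE)
    agg <- aggregate(list(n_regulons = rep(1, nrow(cls))),
                     by = cls[c("class_a", "class_b")], sum)
    tab <- agg
  }
  shared <- sum(tab$n_regulons[tab$class_a != "absent" & tab$class_b != "absent"])
  only_a <- sum(tab$n_regulons[tab$class_a != "absent" & tab$class_b == "absent"])
  only_b <- sum(tab$n_regulons[tab$class_a == "absent" & tab$class_b != "absent"])
  structure(list(table = tab, total = sum(tab$n_regulons), shared = shared,
                 only_a = only_a, only_b = only_b),
            class = "distribution_table")
}

#' @export
print.distribution_table <- function(x, ...) {
  cat("<distribution_table>", x$total, "regulons |", x$shared,
      "in both lineages |", x$only_a, "/", x$only_b, "lineage-specific\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Evaluate a reconstructed network against synthetic ground truth
#'
#' Interaction-level precision/recall/F1 over (genome, regulon, lead gene)
#' triples, the site-level position-match rate (a true planted site counts as
#' matched when a predicted site of the same regulon in the same region lies
#' within `site_tolerance` bp), and, when the planted PWMs are supplied, the
#' per-regulon motif recovery correlation.
#'
#' @param models named list of `regulon_model`s (names = truth regulon names).
#' @param truth a `truth_table` from [generate_genome_set()].
#' @param ws the workspace (needed to convert region offsets; optional when
#'   only interaction metrics are wanted).
#' @param pwms optional named list of planted PWMs.
#' @param site_tolerance positional tolerance in bp (default 3).
#' @return object of class `"evaluation_report"` with fields `precision`,
#'   `recall`, `f1`, `n_predicted`, `n_true`, `site_match_rate`,
#'   `motif_correlation`, and a `no_predictions` flag.
#' @export
evaluate_network <- function(models, truth, ws = NULL, pwms = NULL,
                             site_tolerance = 3) {
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$name, "")
  pred <- do.call(rbind, lapply(names(models), function(rn) {
    m <- models[[rn]]
    if (!nrow(m$interactions)) return(NULL)
    unique(data.frame(regulon = rn, genome = m$interactions$genome,
                      lead_gene = m$interactions$lead_gene,
                      stringsAsFactors = FALSE))
  }))
  tr <- unique(truth$membership[truth$membership$regulon %in% names(models),
                                c("regulon", "genome", "lead_gene")])
  tkey <- paste(tr$regulon, tr$genome, tr$lead_gene)
  if (is.null(pred) || !nrow(pred)) {
    return(structure(list(precision = 0, recall = 0, f1 = 0,
                          n_predicted = 0L, n_true = nrow(tr),
                          site_match_rate = NA_real_,
                          motif_correlation = NULL, no_predictions = TRUE),
                     class = "evaluation_report"))
  }
  pkey <- paste(pred$regulon, pred$genome, pred$lead_gene)
  tp <- sum(pkey %in% tkey)
  precision <- tp / length(pkey)
  recall <- if (length(tkey)) tp / length(tkey) else NA_real_
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  site_match_rate <- NA_real_
  if (!is.null(ws)) {
    info <- ws$region_info
    matched <- 0L; total <- 0L
    for (rn in names(models)) {
      m <- models[[rn]]
      ts <- truth$sites[truth$sites$regulon == rn, , drop = FALSE]
      if (!nrow(ts)) next
      ps <- m$interactions
      for (i in seq_len(nrow(ts))) {
        total <- total + 1L
        cand <- ps[ps$genome == ts$genome[i] & ps$lead_gene == ts$lead_gene[i], ,
                   drop = FALSE]
        if (!nrow(cand)) next
        reg <- info[info$genome == ts$genome[i] &
                      info$lead_gene == ts$lead_gene[i], , drop = FALSE]
        if (!nrow(reg)) next
        pred_rel <- cand$offset - reg$n_upstream[1]
        if (any(abs(pred_rel - ts$rel_offset[i]) <= site_tolerance))
          matched <- matched + 1L
      }
    }
    if (total > 0) site_match_rate <- matched / total
  }
  motif_correlation <- NULL
  if (!is.null(pwms)) {
    shared <- intersect(names(models), names(pwms))
    motif_correlation <- vapply(shared, function(rn) {
      a <- models[[rn]]$profile$pwm; b <- pwms[[rn]]
      if (a$width == b$width) pwm_correlation(a, b) else NA_real_
    }, 0)
  }
  structure(list(precision = precision, recall = recall, f1 = f1,
                 n_predicted = length(pkey), n_true = length(tkey),
                 site_match_rate = site_match_rate,
                 motif_correlation = motif_correlation,
                 no_predictions = FALSE),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> P %.3f | R %.3f | F1 %.3f (%d predicted / %d true)\n",
              x$precision, x$recall, x$f1, x$n_predicted, x$n_true))
  if (!is.na(x$site_match_rate))
    cat(sprintf("  site position match (+/-3 bp): %.3f\n", x$site_match_rate))
  if (!is.null(x$motif_correlation))
    cat("  motif recovery correlation:",
        paste(sprintf("%s %.3f", names(x$motif_correlation),
                      x$motif_correlation), collapse = ", "), "\n")
  invisible(x)
}

# ---- packaged reference tables -------------------------------------------

ref_path <- function(name) {
  p <- system.file("extdata", name, package = "regulonr")
  if (!nzchar(p)) stop("reference table not found: ", name)
  p
}

#' Load the packaged per-genome regulon network statistics table
#'
#' A transcribed reference table of per-genome counts (regulons, target genes,
#' target operons, regulatory interactions) for 30 lactic acid bacteria
#' genomes in two lineages, used to exercise the reporting operations.
#' @return `data.frame` compatible with [summarize_network()].
#' @export
load_network_stats_table <- function() {
  read.delim(ref_path("regulon_network_stats_lactobacillales.tsv"),
             stringsAsFactors = FALSE)
}

#' Load the packaged regulon taxonomic-distribution table
#' @return `data.frame` with columns `class_a` (Streptococcaceae class),
#'   `class_b` (Lactobacillaceae class), `n_regulons`, `examples`.
#' @export
load_distribution_table <- function() {
  read.delim(ref_path("regulon_distribution_lactobacillales.tsv"),
             stringsAsFactors = FALSE)
}

#' Load the packaged regulon workflow-count table
#' @return `data.frame` with columns `workflow`, `n_regulons`.
#' @export
load_workflow_counts <- function() {
  read.delim(ref_path("regulon_workflow_counts.tsv"), stringsAsFactors = FALSE)
}

#' Load the packaged lineage distinct-union ("non-overlapping") counts
#' @return `data.frame` of printed distinct-union counts per lineage (stored
#'   for display; recomputation requires the underlying regulons).
#' @export
load_lineage_distinct_table <- function() {
  read.delim(ref_path("lineage_distinct_counts.tsv"), stringsAsFactors = FALSE)
}

# ---- exports --------------------------------------------------------------

#' Export a reconstructed network
#'
#' Writes the interaction table (TSV), sites (GFF3, feature
#' `TF_binding_site`), the TF -> operon network (SIF) and the profiles (MEME
#' minimal format) with deterministic field order.
#'
#' @param models list of `regulon_model`s.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
export_network <- function(models, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$name, "")
  int <- do.call(rbind, lapply(names(models), function(rn) {
    m <- models[[rn]]
    if (!nrow(m$interactions)) return(NULL)
    cbind(regulon = rn, workflow = m$workflow, m$interactions,
          stringsAsFactors = FALSE)
  }))
  if (is.null(int)) int <- data.frame()
  ip <- file.path(dir, "interactions.tsv")
  write.table(int, ip, sep = "\t", quote = FALSE, row.names = FALSE)
  gp <- file.path(dir, "sites.gff3")
  if (nrow(int)) {
    lines <- c("##gff-version 3",
               paste(int$region, "regulonr", "TF_binding_site",
                     int$offset + 1L, int$offset + vapply(
                       models[int$regulon], function(m) m$profile$pwm$width, 0L),
                     sprintf("%.4f", int$score), int$strand, ".",
                     paste0("ID=site", seq_len(nrow(int)), ";regulon=",
                            int$regulon, ";sequence=", int$sequence),
                     sep = "\t"))
  } else lines <- "##gff-version 3"
  writeLines(lines, gp)
  sp <- file.path(dir, "network.sif")
  sif <- if (nrow(int))
    unique(paste(int$regulon, "regulates",
                 paste0(int$genome, "|", int$operon))) else character(0)
  writeLines(sif, sp)
  mp <- file.path(dir, "profiles.meme")
  write_meme(lapply(models, function(m) m$profile$pwm), mp)
  invisible(c(ip, gp, sp, mp))
}

#' Read back an exported interaction table
#' @param path `interactions.tsv` written by [export_network()].
#' @export
read_interactions <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
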