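#' All-vs-all protein similarity search
#'
#' Aligns every protein pair between (and within) genomes with affine-gap
#' local alignment (BLOSUM62, gap open 11 / extend 1, the classic protein
#' search parametrisation) and reports hits above a loose floor. Identity is
#' the fraction of matching residues over the aligned region; gap columns do
#' not count toward `aligned_length`.
#'
#' @param proteomes named list: genome id -> named character vector of protein
#'   sequences (names are gene ids).
#' @param min_report_identity,min_report_coverage reporting floor: a hit is
#'   kept when identity >= `min_report_identity` and the aligned region covers
#'   at least `min_report_coverage` of the shorter protein. Defaults (0.3,
#'   0.5) suppress the spurious short local alignments of unrelated proteins
#'   while retaining everything the orthology rules can use.
#' @param min_report_score alignment-score floor (default 80, calibrated
#'   above the empirical null of local alignment scores between unrelated
#'   random proteins).
#' @param gap_opening,gap_extension affine gap penalties.
#' @param include_intra also align within-genome pairs (needed for paralog
#'   attachment; default `TRUE`).
#' @return `data.frame` with columns `query`, `subject`, `qgenome`,
#'   `sgenome`, `identity`, `aligned_length`, `score`. Inter-genome hits are
#'   reported in both directions.
#' @export
all_vs_all_similarity <- function(proteomes, min_report_identity = 0.3,
                                  min_report_coverage = 0.5,
                                  min_report_score = 80,
                                  gap_opening = 11, gap_extension = 1,
                                  include_intra = TRUE) {
  keep <- vapply(proteomes, length, 0L) > 0
  if (any(!keep)) {
    warning("excluding genome(s) with empty proteome: ",
            paste(names(proteomes)[!keep], collapse = ", "))
    proteomes <- proteomes[keep]
  }
  if (length(proteomes) < 2 && !include_intra)
    stop("need at least two non-empty proteomes")
  gids <- names(proteomes)
  out <- list()
  pair_hits <- function(ga, gb) {
    pa <- proteomes[[ga]]; pb <- proteomes[[gb]]
    if (identical(ga, gb)) {
      cmb <- which(upper.tri(matrix(0, length(pa), length(pb))), arr.ind = TRUE)
      qi <- cmb[, 1]; si <- cmb[, 2]
    } else {
      qi <- rep(seq_along(pa), times = length(pb))
      si <- rep(seq_along(pb), each = length(pa))
    }
    if (!length(qi)) return(NULL)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(unname(pa[qi])),
      Biostrings::AAStringSet(unname(pb[si])),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension,
      scoreOnly = FALSE)
    nm <- Biostrings::nmatch(al)
    nmm <- Biostrings::nmismatch(al)
    alen <- nm + nmm
    ident <- ifelse(alen > 0, nm / alen, 0)
    shorter <- pmin(nchar(pa[qi]), nchar(pb[si]))
    sc <- Biostrings::score(al)
    ok <- alen > 0 & ident >= min_report_identity &
      alen >= min_report_coverage * shorter & sc >= min_report_score
    if (!any(ok)) return(NULL)
    data.frame(query = names(pa)[qi][ok], subject = names(pb)[si][ok],
               qgenome = ga, sgenome = gb,
               identity = ident[ok], aligned_length = alen[ok],
               score = Biostrings::score(al)[ok],
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(gids)) {
    jstart <- if (include_intra) i else i + 1L
    if (jstart > length(gids)) next
    for (j in seq.int(jstart, length(gids))) {
      h <- pair_hits(gids[i], gids[j])
      if (is.null(h)) next
      out[[length(out) + 1L]] <- h
      mirror <- h[h$query != h$subject, , drop = FALSE]
      if (nrow(mirror)) {
        mirror <- data.frame(query = mirror$subject, subject = mirror$query,
                             qgenome = mirror$sgenome, sgenome = mirror$qgenome,
                             identity = mirror$identity,
                             aligned_length = mirror$aligned_length,
                             score = mirror$score, stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- mirror
      }
    }
  }
  if (!length(out))
    return(data.frame(query = character(), subject = character(),
                      qgenome = character(), sgenome = character(),
                      identity = numeric(), aligned_length = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read similarity hits from 12-column tabular format
#'
#' Adapter for external aligners emitting the standard tabular hit format
#' (query, subject, \%identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, evalue, bitscore).
#'
#' @param path tabular hit file.
#' @param gene_genome named character vector mapping gene id -> genome id.
#' @return hit `data.frame` as from [all_vs_all_similarity()].
#' @export
read_hits_tabular <- function(path, gene_genome) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 12)
  data.frame(query = tab[[1]], subject = tab[[2]],
             qgenome = unname(gene_genome[tab[[1]]]),
             sgenome = unname(gene_genome[tab[[2]]]),
             identity = tab[[3]] / 100,
             aligned_length = tab[[4]] - tab[[6]],  # gap columns excluded
             score = tab[[12]], stringsAsFactors = FALSE)
}

# Best hit of each query in each subject genome; ties on score broken by
# identity, then lexicographic subject id (deterministic).
best_hits <- function(hits) {
  h <- hits[hits$qgenome != hits$sgenome, , drop = FALSE]
  if (!nrow(h)) return(h)
  ord <- order(h$query, h$sgenome, -h$score, -h$identity, h$subject)
  h <- h[ord, , drop = FALSE]
  h[!duplicated(h[, c("query", "sgenome")]), , drop = FALSE]
}

#' Bidirectional best hits
#'
#' A pair (a, b) from different genomes is a BBH iff each is the other's
#' best-scoring hit in the partner genome, identity is strictly greater than
#' `min_identity` and the aligned region is strictly longer than
#' `min_coverage` of the shorter protein.
#'
#' @param hits hit table from [all_vs_all_similarity()].
#' @param protein_lengths named integer vector of protein lengths (gene id ->
#'   length).
#' @param min_identity identity cutoff (default 0.50, strict).
#' @param min_coverage coverage cutoff as a fraction of the shorter protein
#'   (default 2/3, strict).
#' @return `data.frame` with columns `a`, `b` (a < b lexicographically),
#'   `identity`, `aligned_length`, `score`.
#' @export
find_bbh_pairs <- function(hits, protein_lengths, min_identity = 0.50,
                           min_coverage = 2 / 3) {
  bh <- best_hits(hits)
  if (!nrow(bh))
    return(data.frame(a = character(), b = character(), identity = numeric(),
                      aligned_length = integer(), score = numeric()))
  key <- paste(bh$query, bh$subject, sep = "\r")
  rkey <- paste(bh$subject, bh$query, sep = "\r")
  recip <- key %in% rkey
  cand <- bh[recip & bh$query < bh$subject, , drop = FALSE]
  shorter <- pmin(protein_lengths[cand$query], protein_lengths[cand$subject])
  ok <- cand$identity > min_identity & cand$aligned_length > min_coverage * shorter
  cand <- cand[ok, , drop = FALSE]
  data.frame(a = cand$query, b = cand$subject, identity = cand$identity,
             aligned_length = cand$aligned_length, score = cand$score,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Attach paralogs to BBH cluster seeds
#'
#' For each BBH pair (a, b), any same-genome paralog p of a (or of b) that is
#' more similar to its partner than a is to b joins the seed cluster.
#' Similarity is compared on alignment score; ties break on identity, then
#' gene id.
#'
#' @param bbh_pairs output of [find_bbh_pairs()].
#' @param hits full hit table (must include within-genome hits).
#' @return list of character vectors (cluster seeds).
#' @export
attach_paralogs <- function(bbh_pairs, hits) {
  intra <- hits[hits$qgenome == hits$sgenome & hits$query != hits$subject, ,
                drop = FALSE]
  seeds <- vector("list", nrow(bbh_pairs))
  stronger <- function(p_row, ref_score, ref_ident, ref_id) {
    p_row$score > ref_score |
      (p_row$score == ref_score & (p_row$identity > ref_ident |
         (p_row$identity == ref_ident & p_row$subject < ref_id)))
  }
  for (i in seq_len(nrow(bbh_pairs))) {
    a <- bbh_pairs$a[i]; b <- bbh_pairs$b[i]
    s_ab <- bbh_pairs$score[i]; i_ab <- bbh_pairs$identity[i]
    members <- c(a, b)
    for (anchor in c(a, b)) {
      p <- intra[intra$query == anchor, , drop = FALSE]
      if (!nrow(p)) next
      add <- stronger(p, s_ab, i_ab, setdiff(c(a, b), anchor))
      members <- c(members, p$subject[add])
    }
    seeds[[i]] <- unique(members)
  }
  seeds
}

#' Merge overlapping cluster seeds (transitive closure)
#'
#' Clusters sharing at least one gene are joined until a fixpoint, yielding a
#' partition of all clustered genes.
#'
#' @param seeds list of character vectors.
#' @return list of character vectors (disjoint, each sorted).
#' @export
merge_clusters <- function(seeds) {
  seeds <- seeds[vapply(seeds, length, 0L) > 0]
  if (!length(seeds)) return(list())
  edges <- do.call(rbind, lapply(seeds, function(s) {
    if (length(s) == 1) cbind(s, s) else cbind(s[1], s[-1])
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  out <- split(names(comp$membership), comp$membership)
  out <- lapply(out, function(x) sort(unique(x)))
  names(out) <- NULL
  out[order(vapply(out, `[`, "", 1))]
}

#' Build ortholog groups from proteomes
#'
#' Convenience pipeline: all-vs-all similarity, BBH detection, paralog
#' attachment, transitive merging, and (optionally) singleton groups for
#' unclustered genes.
#'
#' @param proteomes named list genome -> named protein vector.
#' @param hits precomputed hit table (optional; computed if `NULL`).
#' @param min_identity,min_coverage see [find_bbh_pairs()].
#' @param include_singletons emit one group per unclustered gene (default
#'   `TRUE`).
#' @return object of class `"ortholog_groups"`: list with `membership`
#'   (`data.frame` group_id / genome / gene_id) and `gene_genome` map.
#' @export
build_ortholog_groups <- function(proteomes, hits = NULL, min_identity = 0.50,
                                  min_coverage = 2 / 3,
                                  include_singletons = TRUE) {
  gene_genome <- unlist(lapply(names(proteomes), function(g)
    setNames(rep(g, length(proteomes[[g]])), names(proteomes[[g]]))))
  if (is.null(hits)) hits <- all_vs_all_similarity(proteomes)
  lens <- unlist(lapply(proteomes, nchar))
  names(lens) <- unlist(lapply(proteomes, names))
  bbh <- find_bbh_pairs(hits, lens, min_identity, min_coverage)
  seeds <- attach_paralogs(bbh, hits)
  clusters <- merge_clusters(seeds)
  if (include_singletons) {
    left <- setdiff(names(gene_genome), unlist(clusters))
    clusters <- c(clusters, as.list(sort(left)))
  }
  ortholog_groups(clusters, gene_genome)
}

#' Construct an ortholog_groups object from a cluster list
#' @param clusters list of character vectors of gene ids.
#' @param gene_genome named vector gene id -> genome id.
#' @export
ortholog_groups <- function(clusters, gene_genome) {
  if (!length(clusters)) {
    membership <- data.frame(group_id = character(), genome = character(),
                             gene_id = character(), stringsAsFactors = FALSE)
  } else {
    membership <- do.call(rbind, lapply(seq_along(clusters), function(i)
      data.frame(group_id = sprintf("OG%04d", i),
                 genome = unname(gene_genome[clusters[[i]]]),
                 gene_id = clusters[[i]], stringsAsFactors = FALSE)))
  }
  structure(list(membership = membership, gene_genome = gene_genome),
            class = "ortholog_groups")
}

#' @export
print.ortholog_groups <- function(x, ...) {
  m <- x$membership
  cat("<ortholog_groups>", length(unique(m$group_id)), "groups,",
      nrow(m), "genes,", length(unique(m$genome)), "genomes\n")
  invisible(x)
}

#' Look up the ortholog group of genes
#' @param groups an `ortholog_groups` object.
#' @param gene_ids character vector.
#' @return character vector of group ids (`NA` for unclustered genes).
#' @export
group_of <- function(groups, gene_ids) {
  m <- groups$membership
  m$group_id[match(gene_ids, m$gene_id)]
}

#' Per-lineage presence counts of a group
#' @keywords internal
group_presence <- function(groups, genome_lineages) {
  m <- groups$membership
  tab <- unique(m[, c("group_id", "genome")])
  tab$lineage <- genome_lineages[tab$genome]
  tab
}

#' Classify ortholog-group conservation within a lineage
#'
#' With `n` genomes in the lineage and the group present in `k` of them:
#' universal iff `k == n`; conserved iff `k > n/2` (but not all); sporadic iff
#' `2 <= k <= floor(n/2)`; unique iff `k == 1`; absent iff `k == 0`.
#'
#' @param groups `ortholog_groups`.
#' @param genome_lineages named vector genome id -> lineage.
#' @param lineage lineage to classify within.
#' @return named character vector group id -> class.
#' @export
classify_conservation <- function(groups, genome_lineages, lineage) {
  n <- sum(genome_lineages == lineage)
  stopifnot(n >= 1)
  pres <- group_presence(groups, genome_lineages)
  pres <- pres[pres$lineage == lineage, , drop = FALSE]
  k <- table(factor(pres$group_id, levels = unique(groups$membership$group_id)))
  cls <- ifelse(k == 0, "absent",
         ifelse(k == n, "universal",
         ifelse(k > n / 2, "conserved",
         ifelse(k >= 2, "sporadic", "unique"))))
  setNames(as.character(cls), names(k))
}
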