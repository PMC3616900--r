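#' @importFrom stats rpois runif uniroot cor median quantile setNames aggregate
#' @importFrom utils read.delim write.table head packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a genome object
#'
#' A genome is one or more replicon sequences plus an ordered gene table.
#' Coordinates are 1-based inclusive (GFF3 convention); `strand` is `"+"` or
#' `"-"`.
#'
#' @param id genome identifier.
#' @param sequence named character vector (or `DNAStringSet`) of replicon
#'   sequences.
#' @param genes `data.frame` with columns `gene_id`, `replicon`, `start`,
#'   `end`, `strand`, and optionally `product`, `protein`, `is_tf`,
#'   `tf_family`.
#' @param lineage lineage tag (e.g. a taxonomic group name) used by
#'   conservation classification.
#' @return an object of class `"genome"`.
#' @export
genome <- function(id, sequence, genes, lineage = "") {
  if (inherits(sequence, "DNAStringSet")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), !is.null(names(sequence)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  for (col in c("product", "protein")) if (is.null(genes[[col]])) genes[[col]] <- ""
  if (is.null(genes$is_tf)) genes$is_tf <- FALSE
  if (is.null(genes$tf_family)) genes$tf_family <- NA_character_
  g <- structure(list(id = id, lineage = lineage,
                      sequence = sequence, genes = genes),
                 class = "genome")
  validate_genome(g)
  g
}

validate_genome <- function(g) {
  genes <- g$genes
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in genome ", g$id)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(genes$end < genes$start))
    stop("gene end < start in genome ", g$id)
  rl <- nchar(g$sequence)
  bad <- genes$start < 1 | genes$end > rl[genes$replicon]
  if (any(is.na(bad)) || any(bad))
    stop("gene coordinates outside replicon in genome ", g$id)
  invisible(g)
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$id,
      if (nzchar(x$lineage)) paste0("[", x$lineage, "]"), "\n")
  cat("  replicons:", length(x$sequence),
      paste0("(", sum(nchar(x$sequence)), " bp)"), "\n")
  cat("  genes:", nrow(x$genes),
      paste0("(", sum(x$genes$is_tf), " flagged as TF)"), "\n")
  invisible(x)
}

#' Bundle genomes into a genome set
#'
#' @param genomes list of [genome()] objects.
#' @return object of class `"genome_set"`: a named list of genomes with a
#'   `lineages` attribute mapping genome id to lineage tag.
#' @export
genome_set <- function(genomes) {
  ids <- vapply(genomes, function(g) g$id, "")
  names(genomes) <- ids
  structure(list(genomes = genomes,
                 lineages = setNames(vapply(genomes, function(g) g$lineage, ""), ids)),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("<genome_set>", length(x$genomes), "genomes\n")
  for (ln in unique(x$lineages))
    cat("  ", ln, ": ", sum(x$lineages == ln), " genomes\n", sep = "")
  invisible(x)
}

parse_gff_attributes <- function(a) {
  parts <- strsplit(a, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(x) if (length(x) >= 2) x[2] else "", "")
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

#' Read a genome from GFF3 + FASTA
#'
#' CDS records are parsed into genes; protein sequences are obtained by
#' translating the CDS. Records with invalid coordinates (end < start, outside
#' the replicon) or an unknown replicon are skipped with a warning and
#' counted in the `n_rejected` attribute.
#'
#' @param gff_path path to a GFF3 file.
#' @param fasta_path path to the genomic FASTA.
#' @param id genome id; defaults to the GFF file base name.
#' @param lineage lineage tag.
#' @return a [genome()] object.
#' @export
read_genome <- function(gff_path, fasta_path, id = NULL, lineage = "") {
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqc <- as.character(seqs)
  lines <- readLines(gff_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) == 9 && f[3] == "CDS", TRUE)
  fields <- fields[keep]
  n_rejected <- 0L
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    att <- parse_gff_attributes(f[9])
    get_att <- function(key) if (!is.na(att[key]) && nzchar(att[key]))
      att[[key]] else NA_character_
    gid <- if (!is.na(get_att("locus_tag"))) get_att("locus_tag") else
      get_att("ID")
    ok <- !is.na(start) && !is.na(end) && end >= start &&
      f[7] %in% c("+", "-") && f[1] %in% names(seqc) &&
      start >= 1 && end <= nchar(seqc[[f[1]]]) && !is.null(gid) && !is.na(gid)
    if (!ok) { n_rejected <- n_rejected + 1L; next }
    cds <- substr(seqc[[f[1]]], start, end)
    if (f[7] == "-") cds <- revcomp(cds)
    prot <- tryCatch({
      aa <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(cds),
                              if.fuzzy.codon = "solve",
                              no.init.codon = TRUE)))
      sub("\\*$", "", aa)
    }, error = function(e) "")
    rows[[i]] <- data.frame(
      gene_id = gid, replicon = f[1], start = start, end = end,
      strand = f[7],
      product = if (!is.na(get_att("product"))) get_att("product") else "",
      protein = prot,
      is_tf = identical(get_att("is_tf"), "true"),
      tf_family = get_att("tf_family"),
      stringsAsFactors = FALSE)
  }
  if (n_rejected > 0)
    warning(n_rejected, " CDS record(s) rejected in ", gff_path)
  genes <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(genes))
    genes <- data.frame(gene_id = character(), replicon = character(),
                        start = integer(), end = integer(), strand = character(),
                        product = character(), protein = character(),
                        is_tf = logical(), tf_family = character(),
                        stringsAsFactors = FALSE)
  genes <- genes[order(genes$replicon, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  g <- genome(id = if (is.null(id)) sub("\\.gff3?$", "", basename(gff_path)) else id,
              sequence = seqc, genes = genes, lineage = lineage)
  attr(g, "n_rejected") <- n_rejected
  g
}

#' Read a genome from a simplified TSV gene table + FASTA
#'
#' Expected columns: `genome_id`, `replicon`, `gene_id`, `start`, `end`,
#' `strand`, `product`, `protein` (optional: `is_tf`, `tf_family`).
#'
#' @inheritParams read_genome
#' @param tsv_path path to the gene table.
#' @export
read_genome_tsv <- function(tsv_path, fasta_path, lineage = "") {
  if (!file.exists(tsv_path)) stop("gene table not found: ", tsv_path)
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  id <- unique(tab$genome_id)
  stopifnot(length(id) == 1)
  genes <- tab[, setdiff(names(tab), "genome_id"), drop = FALSE]
  genes <- genes[order(genes$replicon, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genome(id = id, sequence = as.character(seqs), genes = genes, lineage = lineage)
}

#' Write a genome to GFF3 + FASTA (+ optional protein FASTA)
#'
#' @param g a [genome()].
#' @param gff_path,fasta_path,protein_path output paths (`protein_path` may be
#'   `NULL`).
#' @export
write_genome <- function(g, gff_path, fasta_path, protein_path = NULL) {
  sq <- Biostrings::DNAStringSet(g$sequence)
  Biostrings::writeXStringSet(sq, fasta_path)
  genes <- g$genes
  att <- paste0("ID=", genes$gene_id,
                ifelse(nzchar(genes$product), paste0(";product=", genes$product), ""),
                ifelse(genes$is_tf, ";is_tf=true", ""),
                ifelse(!is.na(genes$tf_family), paste0(";tf_family=", genes$tf_family), ""))
  lines <- c("##gff-version 3",
             paste(genes$replicon, "regulonr", "CDS", genes$start, genes$end,
                   ".", genes$strand, "0", att, sep = "\t"))
  writeLines(lines, gff_path)
  if (!is.null(protein_path)) {
    aa <- Biostrings::AAStringSet(setNames(genes$protein, genes$gene_id))
    Biostrings::writeXStringSet(aa, protein_path)
  }
  invisible(g)
}

#' Reverse-complement a DNA string
#' @param x character scalar or vector of DNA strings.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Predict operons by the intergenic-gap heuristic
#'
#' Two adjacent genes share an operon iff they are on the same replicon and
#' strand and the intergenic gap is at most `max_gap` bp. Every gene is
#' assigned to exactly one operon. The lead gene is the first gene in
#' transcription direction (leftmost on `+`, rightmost on `-`).
#'
#' @param g a [genome()].
#' @param max_gap maximum intergenic gap in bp (default 100).
#' @return `data.frame` with columns `operon_id`, `replicon`, `strand`,
#'   `lead_gene`, `genes` (list column of gene ids in transcription order),
#'   `start`, `end`.
#' @export
predict_operons <- function(g, max_gap = 100) {
  genes <- g$genes[order(g$genes$replicon, g$genes$start), , drop = FALSE]
  n <- nrow(genes)
  if (n == 0)
    return(data.frame(operon_id = character(), replicon = character(),
                      strand = character(), lead_gene = character(),
                      start = integer(), end = integer()))
  new_block <- c(TRUE, genes$replicon[-1] != genes$replicon[-n] |
                   genes$strand[-1] != genes$strand[-n] |
                   (genes$start[-1] - genes$end[-n] - 1L) > max_gap)
  block <- cumsum(new_block)
  ops <- lapply(split(seq_len(n), block), function(ix) {
    sub <- genes[ix, , drop = FALSE]
    fwd <- sub$strand[1] == "+"
    ord <- if (fwd) order(sub$start) else order(-sub$start)
    data.frame(replicon = sub$replicon[1], strand = sub$strand[1],
               lead_gene = sub$gene_id[ord[1]],
               genes = I(list(sub$gene_id[ord])),
               start = min(sub$start), end = max(sub$end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, ops)
  out <- cbind(operon_id = paste0(g$id, "_op", sprintf("%04d", seq_len(nrow(out)))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract the upstream region of an operon
#'
#' Returns the coding-strand sequence from `upstream_bp` before the lead
#' gene's translation start to `downstream_bp - 1` after it (so the window
#' covers `upstream_bp + downstream_bp` positions), clipped at replicon edges
#' and, optionally, at the 3' boundary of the nearest upstream gene.
#'
#' @param operon one row of [predict_operons()] output (or an operon id).
#' @param g the [genome()].
#' @param operons the operon table (needed when `operon` is an id).
#' @param upstream_bp,downstream_bp window relative to the translation start
#'   (defaults 300 / 25).
#' @param truncate_at_upstream_gene clip at the nearest upstream gene
#'   boundary (default `TRUE`).
#' @return object of class `"upstream_region"`: list with `operon`, `genome`,
#'   `sequence`, `n_upstream` (bases present before the translation start, so
#'   region offset `n_upstream` is the start codon's first base),
#'   `window`, `empty` flag, and genomic anchor coordinates.
#' @export
extract_upstream <- function(operon, g, operons = NULL,
                             upstream_bp = 300, downstream_bp = 25,
                             truncate_at_upstream_gene = TRUE) {
  if (is.character(operon)) {
    stopifnot(!is.null(operons))
    operon <- operons[operons$operon_id == operon, , drop = FALSE]
  }
  stopifnot(nrow(operon) == 1)
  lead <- g$genes[g$genes$gene_id == operon$lead_gene, , drop = FALSE]
  repl <- g$sequence[[operon$replicon]]
  L <- nchar(repl)
  op_genes <- operon$genes[[1]]
  others <- g$genes[g$genes$replicon == operon$replicon &
                      !(g$genes$gene_id %in% op_genes), , drop = FALSE]
  if (operon$strand[1] == "+") {
    tstart <- lead$start
    lo <- max(1L, tstart - upstream_bp)
    hi <- min(L, tstart + downstream_bp - 1L)
    if (truncate_at_upstream_gene) {
      up <- others$end[others$end < tstart]
      if (length(up)) lo <- max(lo, max(up) + 1L)
    }
    seq <- if (lo <= hi) substr(repl, lo, hi) else ""
    n_upstream <- as.integer(max(0, tstart - lo))
  } else {
    tstart <- lead$end
    lo <- max(1L, tstart - downstream_bp + 1L)
    hi <- min(L, tstart + upstream_bp)
    if (truncate_at_upstream_gene) {
      dn <- others$start[others$start > tstart]
      if (length(dn)) hi <- min(hi, min(dn) - 1L)
    }
    seq <- if (lo <= hi) revcomp(substr(repl, lo, hi)) else ""
    n_upstream <- as.integer(max(0, hi - tstart))
  }
  structure(list(operon = operon$operon_id, genome = g$id,
                 lead_gene = operon$lead_gene,
                 sequence = seq, n_upstream = n_upstream,
                 window = c(upstream = upstream_bp, downstream = downstream_bp),
                 anchor = tstart, strand = operon$strand[1],
                 empty = !nzchar(seq)),
            class = "upstream_region")
}

#' @export
print.upstream_region <- function(x, ...) {
  cat("<upstream_region>", x$genome, "|", x$operon, "\n")
  cat("  ", nchar(x$sequence), " bp (", x$n_upstream,
      " upstream of translation start), strand ", x$strand, "\n", sep = "")
  invisible(x)
}

#' Extract upstream regions for all operons of a genome
#'
#' @inheritParams extract_upstream
#' @return named list of [extract_upstream()] results, keyed
#'   `genome|operon_id`.
#' @export
extract_upstream_regions <- function(g, operons = NULL, upstream_bp = 300,
                                     downstream_bp = 25,
                                     truncate_at_upstream_gene = TRUE) {
  if (is.null(operons)) operons <- predict_operons(g)
  out <- lapply(seq_len(nrow(operons)), function(i)
    extract_upstream(operons[i, , drop = FALSE], g,
                     upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                     truncate_at_upstream_gene = truncate_at_upstream_gene))
  names(out) <- paste0(g$id, "|", operons$operon_id)
  out
}

#' Write operons as GFF3
#' @param operons [predict_operons()] output.
#' @param g the genome.
#' @param path output file.
#' @export
write_operons_gff <- function(operons, g, path) {
  att <- paste0("ID=", operons$operon_id, ";lead_gene=", operons$lead_gene,
                ";genes=", vapply(operons$genes, paste, "", collapse = ","))
  lines <- c("##gff-version 3",
             paste(operons$replicon, "regulonr", "operon", operons$start,
                   operons$end, ".", operons$strand, ".", att, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write upstream regions as FASTA
#'
#' Headers follow `genome|operon|window`.
#' @param regions list from [extract_upstream_regions()].
#' @param path output file.
#' @export
write_upstream_fasta <- function(regions, path) {
  regions <- regions[!vapply(regions, function(r) r$empty, TRUE)]
  seqs <- vapply(regions, function(r) r$sequence, "")
  hdr <- vapply(regions, function(r)
    paste0(r$genome, "|", r$operon, "|-", r$window[["upstream"]],
           ":+", r$window[["downstream"]]), "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(seqs, hdr)), path)
  invisible(path)
}
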