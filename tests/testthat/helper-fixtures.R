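# deterministic background sequence
bg_seq <- function(n, seed = 1, prob = rep(0.25, 4)) {
  withr_seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = prob), collapse = "")
}

# set.seed without clobbering the ambient RNG stream permanently
withr_seed <- function(seed) set.seed(seed)

# genome with a hand-laid gene arrangement on one 6000 bp replicon
toy_genome <- function(with_upstream_gene = FALSE) {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    replicon = "chr",
    start = c(1001L, 2051L, 3001L),
    end = c(2000L, 2600L, 3500L),
    strand = c("+", "+", "-"),
    product = "", protein = "MK",
    stringsAsFactors = FALSE)
  if (with_upstream_gene)
    genes <- rbind(data.frame(gene_id = "gUp", replicon = "chr",
                              start = 500L, end = 900L, strand = "+",
                              product = "", protein = "MK",
                              stringsAsFactors = FALSE), genes)
  genome(id = "toy", sequence = c(chr = bg_seq(6000, seed = 99)),
         genes = genes, lineage = "lin")
}

# brute-force transitive-closure oracle: repeatedly scan all cluster pairs
# for shared genes and union until no overlap remains
bf_merge <- function(seeds) {
  cl <- lapply(seeds, unique)
  repeat {
    merged <- FALSE
    for (i in seq_along(cl)) {
      if (i > length(cl)) break
      j <- i + 1
      while (j <= length(cl)) {
        if (length(intersect(cl[[i]], cl[[j]]))) {
          cl[[i]] <- union(cl[[i]], cl[[j]])
          cl[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1
      }
    }
    if (!merged) break
  }
  out <- lapply(cl, function(x) sort(x))
  out[order(vapply(out, `[`, "", 1))]
}

# exhaustive per-position, per-strand rescoring oracle for scanning
bf_scan <- function(profile, regions) {
  w <- profile$pwm$width
  out <- list()
  for (rn in names(regions)) {
    s <- toupper(regions[[rn]])
    L <- nchar(s)
    if (L < w) next
    for (o in 0:(L - w)) {
      word <- substr(s, o + 1, o + w)
      if (grepl("[^ACGT]", word)) next
      sf <- score_word(profile$pwm, word)
      sr <- score_word(profile$pwm, revcomp(word))
      sc <- max(sf, sr)
      if (sc >= profile$threshold) {
        strand <- if (sf >= sr) "+" else "-"
        out[[length(out) + 1]] <- data.frame(
          region = rn, offset = o, strand = strand,
          sequence = if (strand == "+") word else revcomp(word),
          score = sc, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(region = character(), offset = integer(),
                      strand = character(), sequence = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$region, res$offset), ]
  rownames(res) <- NULL
  res
}

# ortholog clustering oracle: plain-loop reapplication of the published rules
# (best hits, reciprocity + identity/coverage cutoffs, paralog attachment,
# repeated overlap merging); independent of the package implementation
bf_ortholog_groups <- function(hits, lens, gene_genome,
                               min_identity = 0.5, min_coverage = 2 / 3) {
  inter <- hits[hits$qgenome != hits$sgenome, ]
  best <- list()
  for (q in unique(inter$query)) {
    hq <- inter[inter$query == q, ]
    for (sg in unique(hq$sgenome)) {
      hs <- hq[hq$sgenome == sg, ]
      hs <- hs[order(-hs$score, -hs$identity, hs$subject), ]
      best[[paste(q, sg)]] <- hs[1, ]
    }
  }
  best <- do.call(rbind, best)
  bbh <- list()
  for (i in seq_len(nrow(best))) {
    a <- best$query[i]; b <- best$subject[i]
    rev_key <- paste(b, gene_genome[[a]])
    if (!rev_key %in% rownames(best)) next
    if (best[rev_key, "subject"] != a) next
    if (a >= b) next
    if (best$identity[i] <= min_identity) next
    if (best$aligned_length[i] <= min_coverage * min(lens[[a]], lens[[b]])) next
    bbh[[length(bbh) + 1]] <- c(a = a, b = b, score = best$score[i],
                                identity = best$identity[i])
  }
  intra <- hits[hits$qgenome == hits$sgenome & hits$query != hits$subject, ]
  seeds <- lapply(bbh, function(p) {
    mem <- c(p[["a"]], p[["b"]])
    for (anchor in mem) {
      ph <- intra[intra$query == anchor, ]
      add <- ph$subject[ph$score > as.numeric(p[["score"]]) |
        (ph$score == as.numeric(p[["score"]]) &
           ph$identity > as.numeric(p[["identity"]]))]
      mem <- c(mem, add)
    }
    unique(mem)
  })
  bf_merge(seeds)
}

# partition of an ortholog_groups object as a canonical list of sorted vectors
groups_as_partition <- function(groups, drop_singletons = FALSE) {
  m <- groups$membership
  p <- lapply(split(m$gene_id, m$group_id), sort)
  if (drop_singletons) p <- p[vapply(p, length, 0L) > 1]
  names(p) <- NULL
  p[order(vapply(p, `[`, "", 1))]
}

# hand-built regulon model for network-operation tests
fake_model <- function(name, interactions, tf_group = paste0("OG_", name),
                       profile = NULL) {
  if (is.null(profile)) profile <- build_profile(c("ACGTACGT", "ACGTACGT"),
                                                 name = name)
  structure(list(name = name, tf_group = tf_group, lineage = "",
                 profile = profile, interactions = interactions,
                 workflow = "1a", fit = NULL, candidates = interactions),
            class = "regulon_model")
}
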