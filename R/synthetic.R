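AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Specify a planted regulon for the synthetic generator
#'
#' @param name regulon name (used as TF family and truth label).
#' @param width motif width (>= 6).
#' @param ic_total target total information content of the planted PWM, in
#'   bits.
#' @param symmetry motif symmetry class.
#' @param n_members number of member operons (distinct ortholog families).
#' @param presence per-genome probability that a member carries a site.
#' @param window allowed site start offsets relative to the translation start
#'   (negative; the site must end before the start codon).
#' @param autoregulation also plant sites upstream of the TF's own gene (with
#'   the same presence probability).
#' @param min_site_score functionality floor for planted sites, in bits:
#'   sites are drawn from the PWM conditional on scoring at least this
#'   (defaults to `ic_total / 2`). Functional operators are under selection
#'   to bind; unconditioned PWM draws would include words indistinguishable
#'   from background.
#' @return a list of class `"regulon_spec"`.
#' @export
regulon_spec <- function(name, width = 18, ic_total = 16,
                         symmetry = "palindrome", n_members = 6,
                         presence = 0.8, window = c(-250, -40),
                         autoregulation = FALSE,
                         min_site_score = ic_total / 2) {
  stopifnot(width >= 6, presence >= 0, presence <= 1, window[1] < window[2])
  structure(list(name = name, width = width, ic_total = ic_total,
                 symmetry = symmetry, n_members = n_members,
                 presence = presence, window = window,
                 autoregulation = autoregulation,
                 min_site_score = min_site_score),
            class = "regulon_spec")
}

#' Configuration for the synthetic genome-set generator
#'
#' Defaults emulate the benchmark conditions used throughout the test suite:
#' two lineages of 5 genomes, 3 planted palindromic regulons of 6 member
#' operons at presence probability 0.8, one near-threshold decoy per upstream
#' region, order-0 background with per-genome GC drawn from 0.35-0.45, and
#' ortholog families built by mutating a common ancestor protein to a target
#' pairwise identity.
#'
#' @param n_genomes named integer vector: genomes per lineage.
#' @param regulons list of [regulon_spec()]s.
#' @param n_filler_families ortholog families not tied to any regulon.
#' @param within_identity target mean pairwise protein identity inside a
#'   family.
#' @param protein_length ancestor length range (residues).
#' @param gc_range per-genome GC content range (order-0 background).
#' @param decoy_rate expected near-threshold decoy sites per upstream region.
#' @param cascades optional `data.frame` with columns `from`, `to` (regulon
#'   names): plant a site of `from`'s motif upstream of `to`'s TF gene.
#' @param two_gene_operon_prob probability that a member/filler operon carries
#'   a second gene.
#' @param upstream_gap_range intergenic gap upstream of each operon lead (bp).
#' @param intra_operon_gap_range gap between operon genes (bp; below the
#'   operon-calling cutoff).
#' @param seed default seed echoed into [generate_genome_set()].
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_genomes = c(lineage_a = 5, lineage_b = 5),
                             regulons = list(
                               regulon_spec("regA", autoregulation = TRUE),
                               regulon_spec("regB"),
                               regulon_spec("regC")),
                             n_filler_families = 10,
                             within_identity = 0.7,
                             protein_length = c(150, 400),
                             gc_range = c(0.35, 0.45),
                             decoy_rate = 1,
                             cascades = NULL,
                             two_gene_operon_prob = 0.25,
                             upstream_gap_range = c(270, 330),
                             intra_operon_gap_range = c(20, 60),
                             seed = 1) {
  cfg <- structure(list(n_genomes = n_genomes, regulons = regulons,
                        n_filler_families = n_filler_families,
                        within_identity = within_identity,
                        protein_length = protein_length,
                        gc_range = gc_range, decoy_rate = decoy_rate,
                        cascades = cascades,
                        two_gene_operon_prob = two_gene_operon_prob,
                        upstream_gap_range = upstream_gap_range,
                        intra_operon_gap_range = intra_operon_gap_range,
                        seed = seed),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(all(cfg$n_genomes >= 1), !is.null(names(cfg$n_genomes)),
            cfg$within_identity > 0, cfg$within_identity <= 1,
            cfg$decoy_rate >= 0)
  for (r in cfg$regulons) {
    if (min(-r$width, r$window[2]) < r$window[1])
      stop("regulon '", r$name, "': placement window is shorter than the motif")
    if (-r$window[1] > cfg$upstream_gap_range[1])
      stop("regulon '", r$name, "': placement window exceeds the minimum ",
           "upstream gap")
  }
  invisible(cfg)
}

#' Read a generator configuration from YAML
#' @param path YAML file whose keys mirror [synthetic_config()] arguments;
#'   `regulons` is a list of [regulon_spec()] argument sets.
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$regulons))
    y$regulons <- lapply(y$regulons, function(r) do.call(regulon_spec, r))
  if (!is.null(y$n_genomes)) y$n_genomes <- unlist(y$n_genomes)
  if (!is.null(y$cascades)) y$cascades <- as.data.frame(y$cascades)
  do.call(synthetic_config, y)
}

#' Construct a PWM with prescribed width, symmetry and information content
#'
#' A consensus word of the requested symmetry is drawn, and each column gets
#' probability `c` on the consensus base and `(1-c)/3` elsewhere, with `c`
#' solved so that per-column information content equals `ic_total / width`
#' against a uniform background.
#'
#' @inheritParams regulon_spec
#' @param consensus optional fixed consensus word (sampled when `NULL`).
#' @return a `pwm` (pseudocount 0, uniform background).
#' @export
make_planted_pwm <- function(width, ic_total, symmetry = "palindrome",
                             consensus = NULL) {
  if (is.null(consensus)) {
    half <- ceiling(width / 2)
    left <- sample(DNA_BASES, half, replace = TRUE)
    consensus <- switch(symmetry,
      palindrome = {
        full <- c(left, rev(chartr("ACGT", "TGCA", left)))
        paste(full[seq_len(width)], collapse = "")
      },
      direct_repeat = {
        h <- floor(width / 2)
        paste(c(left[seq_len(h)], left[seq_len(width - h)]), collapse = "")
      },
      inverted_repeat = {
        full <- c(left, rev(chartr("ACGT", "TGCA", left)))
        paste(full[seq_len(width)], collapse = "")
      },
      paste(sample(DNA_BASES, width, replace = TRUE), collapse = ""))
  }
  ic_col <- ic_total / width
  if (ic_col >= 2) stop("requested information content exceeds 2 bits/column")
  # unequal minor-base frequencies (0.5/0.3/0.2 of the remainder, shuffled)
  # keep the score spectrum dense, as in real operator motifs
  make_col <- function(cons_code) {
    wts <- sample(c(0.5, 0.3, 0.2))
    f <- function(cc) {
      p <- numeric(4); p[cons_code] <- cc
      p[-cons_code] <- (1 - cc) * wts
      sum(p * log2(p / 0.25)) - ic_col
    }
    cc <- uniroot(f, c(0.2500001, 0.9999999))$root
    p <- numeric(4); p[cons_code] <- cc
    p[-cons_code] <- (1 - cc) * wts
    p
  }
  cons <- encode_dna(consensus)
  half <- ceiling(width / 2)
  freq <- matrix(NA_real_, 4, width, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(half)) freq[, j] <- make_col(cons[j])
  for (j in seq.int(half + 1, length.out = width - half)) {
    mirror <- width + 1 - j
    freq[, j] <- switch(symmetry,
      palindrome = rev(freq[, mirror]),
      inverted_repeat = rev(freq[, mirror]),
      direct_repeat = freq[, j - floor(width / 2)],
      make_col(cons[j]))
  }
  new_pwm(freq * 100, pseudocount = 0, background = uniform_background(),
          symmetry = symmetry, spacer = 0, nsites = 100)
}

#' Sample site words from a PWM
#'
#' Optionally rejection-samples conditional on a minimum log-odds score
#' (functional-site model); after `max_tries` draws the best-scoring draw is
#' returned.
#'
#' @param pwm a `pwm`.
#' @param n number of words.
#' @param min_score optional score floor in bits.
#' @param max_tries rejection-sampling cap per word.
#' @export
sample_sites <- function(pwm, n = 1, min_score = NULL, max_tries = 200) {
  f <- pwm_freq(pwm)
  draw <- function() paste(apply(f, 2, function(col)
    sample(DNA_BASES, 1, prob = col)), collapse = "")
  vapply(seq_len(n), function(i) {
    if (is.null(min_score)) return(draw())
    best <- draw(); best_sc <- score_word(pwm, best)
    for (k in seq_len(max_tries)) {
      if (best_sc >= min_score) return(best)
      cand <- draw(); sc <- score_word(pwm, cand)
      if (sc > best_sc) { best <- cand; best_sc <- sc }
    }
    best
  }, "")
}

# background word with score in [threshold - 2, threshold) bits: start from a
# PWM draw and degrade random columns until the score falls into the band
near_threshold_word <- function(pwm, threshold, max_tries = 200) {
  word <- strsplit(sample_sites(pwm, 1), "")[[1]]
  sc <- score_word(pwm, paste(word, collapse = ""))
  for (i in seq_len(max_tries)) {
    if (sc < threshold && sc >= threshold - 2)
      return(paste(word, collapse = ""))
    j <- sample.int(length(word), 1)
    old <- word[j]
    word[j] <- sample(setdiff(DNA_BASES, old), 1)
    new_sc <- score_word(pwm, paste(word, collapse = ""))
    if (new_sc < threshold - 2) { word[j] <- old; next }
    sc <- new_sc
  }
  NA_character_
}

random_dna <- function(n, bg) paste(sample(DNA_BASES, n, TRUE, prob = bg),
                                    collapse = "")

mutate_protein <- function(ancestor, q) {
  aa <- strsplit(ancestor, "")[[1]]
  hit <- runif(length(aa)) < q
  if (any(hit))
    aa[hit] <- vapply(aa[hit], function(a) sample(setdiff(AA_ALPHABET, a), 1), "")
  paste(aa, collapse = "")
}

# per-site substitution rate giving target pairwise identity between two
# independently mutated copies: t = (1-q)^2 + q^2/19
identity_to_rate <- function(target) {
  uniroot(function(q) (1 - q)^2 + q^2 / 19 - target, c(0, 0.95))$root
}

reverse_translate <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), code)
  aa <- strsplit(protein, "")[[1]]
  paste0(paste(vapply(aa, function(a) sample(by_aa[[a]], 1), ""),
               collapse = ""), "TAA")
}

#' Generate a synthetic genome set with planted regulons and ground truth
#'
#' Deterministic given `(config, seed)`. Ortholog families are built by
#' mutating a random ancestor protein to the target within-family identity;
#' gene order (synteny) is shared across genomes, with each TF gene placed
#' next to the first member operon of its regulon; planted sites are drawn
#' from the regulon's PWM and written into the upstream gap of member operon
#' lead genes; decoys are background-placed words scoring within 2 bits below
#' the planted profile's training-set-minimum threshold.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `genome_set`, `truth` (class `"truth_table"`) and
#'   `pwms` (the planted PWMs, named by regulon).
#' @export
generate_genome_set <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  lineages <- rep(names(config$n_genomes), config$n_genomes)
  gids <- sprintf("g%02d", seq_along(lineages))
  names(lineages) <- gids
  q <- identity_to_rate(config$within_identity)

  ## planted PWMs and site-word pre-draws
  pwms <- lapply(config$regulons, function(r)
    make_planted_pwm(r$width, r$ic_total, r$symmetry))
  names(pwms) <- vapply(config$regulons, function(r) r$name, "")

  ## family bookkeeping: member families per regulon, TF families, fillers
  fam_ids <- character(0)
  member_fams <- list()
  for (r in config$regulons) {
    member_fams[[r$name]] <- sprintf("%s_m%02d", r$name, seq_len(r$n_members))
    fam_ids <- c(fam_ids, member_fams[[r$name]])
  }
  tf_fams <- paste0("tf_", names(pwms))
  filler_fams <- sprintf("fill%02d", seq_len(config$n_filler_families))
  fam_ids <- c(fam_ids, tf_fams, filler_fams)
  anc_len <- sample(seq(config$protein_length[1], config$protein_length[2]),
                    length(fam_ids), replace = TRUE)
  ancestors <- setNames(vapply(anc_len, function(L)
    paste(sample(AA_ALPHABET, L, TRUE), collapse = ""), ""), fam_ids)

  ## operon scaffold, shared across genomes (synteny)
  two_gene <- function() runif(1) < config$two_gene_operon_prob
  filler_pool <- filler_fams
  take_filler <- function() {
    if (!length(filler_pool)) return(NULL)
    f <- filler_pool[1]; filler_pool <<- filler_pool[-1]; f
  }
  scaffold <- list()
  for (r in config$regulons) {
    mf <- member_fams[[r$name]]
    first <- mf[1]
    fams1 <- c(first, if (two_gene()) take_filler())
    scaffold[[length(scaffold) + 1L]] <- list(fams = fams1, role = "member",
                                              regulon = r$name)
    scaffold[[length(scaffold) + 1L]] <- list(fams = paste0("tf_", r$name),
                                              role = "tf", regulon = r$name)
    for (f in mf[-1]) {
      fams <- c(f, if (two_gene()) take_filler())
      scaffold[[length(scaffold) + 1L]] <- list(fams = fams, role = "member",
                                                regulon = r$name)
    }
  }
  while (length(filler_pool) > 0) {
    fams <- c(take_filler(), if (two_gene()) take_filler())
    scaffold[[length(scaffold) + 1L]] <- list(fams = fams, role = "filler",
                                              regulon = NA_character_)
  }
  strands <- sample(c("+", "-"), length(scaffold), replace = TRUE)

  ## plant decisions: site words drawn up front so thresholds are known
  site_rows <- list()
  for (g in gids) {
    for (oi in seq_along(scaffold)) {
      op <- scaffold[[oi]]
      lead_fam <- op$fams[1]
      plant_for <- character(0)
      if (op$role == "member") plant_for <- op$regulon
      if (op$role == "tf") {
        r <- config$regulons[[match(op$regulon, names(pwms))]]
        if (isTRUE(r$autoregulation)) plant_for <- op$regulon
        if (!is.null(config$cascades)) {
          inc <- config$cascades$from[config$cascades$to == op$regulon]
          plant_for <- c(plant_for, inc)
        }
      }
      for (rn in plant_for) {
        r <- config$regulons[[match(rn, names(pwms))]]
        if (runif(1) > r$presence) next
        word <- sample_sites(pwms[[rn]], 1, min_score = r$min_site_score)
        o_hi <- min(r$window[2], -r$width)
        offset <- sample(seq(r$window[1], o_hi), 1)
        strand <- sample(c("+", "-"), 1)
        role <- if (op$role == "tf" && rn == op$regulon) "autoregulation"
                else if (op$role == "tf") "cascade" else "member"
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          regulon = rn, genome = g, lead_fam = lead_fam,
          operon_index = oi, rel_offset = offset, strand = strand,
          sequence = word, role = role, stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(regulon = character(), genome = character(),
               lead_fam = character(), operon_index = integer(),
               rel_offset = integer(), strand = character(),
               sequence = character(), role = character(),
               stringsAsFactors = FALSE)
  sites$score <- if (nrow(sites))
    unlist(lapply(seq_len(nrow(sites)), function(i)
      score_word(pwms[[sites$regulon[i]]], sites$sequence[i]))) else numeric(0)
  thresholds <- vapply(names(pwms), function(rn) {
    sc <- sites$score[sites$regulon == rn]
    if (length(sc)) min(sc) else attr(pwm_ic(pwms[[rn]]), "total")
  }, 0)

  ## decoys
  decoy_rows <- list()
  if (config$decoy_rate > 0) {
    for (g in gids) {
      for (oi in seq_along(scaffold)) {
        nd <- rpois(1, config$decoy_rate)
        if (nd == 0) next
        for (k in seq_len(nd)) {
          rn <- sample(names(pwms), 1)
          word <- near_threshold_word(pwms[[rn]], thresholds[[rn]])
          if (is.na(word)) next
          r <- config$regulons[[match(rn, names(pwms))]]
          o_hi <- min(r$window[2], -r$width)
          taken <- sites[sites$genome == g & sites$operon_index == oi, ,
                         drop = FALSE]
          ok <- FALSE
          for (try in 1:20) {
            offset <- sample(seq(r$window[1], o_hi), 1)
            clash <- nrow(taken) && any(abs(taken$rel_offset - offset) <
                                          r$width + 2)
            if (!clash) { ok <- TRUE; break }
          }
          if (!ok) next
          strand <- sample(c("+", "-"), 1)
          row <- data.frame(regulon = rn, genome = g,
                            lead_fam = scaffold[[oi]]$fams[1],
                            operon_index = oi, rel_offset = offset,
                            strand = strand, sequence = word, role = "decoy",
                            score = score_word(pwms[[rn]], word),
                            stringsAsFactors = FALSE)
          decoy_rows[[length(decoy_rows) + 1L]] <- row
          sites <- rbind(sites, row)  # reserve the interval
        }
      }
    }
  }
  decoys <- if (length(decoy_rows)) do.call(rbind, decoy_rows) else
    sites[0, , drop = FALSE]
  planted <- sites[sites$role != "decoy", , drop = FALSE]

  ## genome assembly
  genomes <- list()
  fam_rows <- list()
  gap_rng <- config$upstream_gap_range
  intra_rng <- config$intra_operon_gap_range
  for (g in gids) {
    gc <- runif(1, config$gc_range[1], config$gc_range[2])
    bg <- setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), DNA_BASES)
    parts <- character(0)
    pos <- 0L
    gene_rows <- list()
    all_sites_g <- sites[sites$genome == g, , drop = FALSE]
    for (oi in seq_along(scaffold)) {
      op <- scaffold[[oi]]
      strand <- strands[oi]
      sep_len <- sample(seq(gap_rng[1], gap_rng[2]), 1)
      sep <- strsplit(random_dna(sep_len, bg), "")[[1]]
      here <- all_sites_g[all_sites_g$operon_index == oi, , drop = FALSE]
      if (nrow(here)) for (i in seq_len(nrow(here))) {
        word <- here$sequence[i]
        if (here$strand[i] == "-") word <- revcomp(word)
        idx <- sep_len + here$rel_offset[i] + 1L
        sep[seq.int(idx, idx + nchar(word) - 1L)] <-
          strsplit(word, "")[[1]]
      }
      sep <- paste(sep, collapse = "")
      cds <- lapply(op$fams, function(f) {
        prot <- mutate_protein(ancestors[[f]], q)
        list(fam = f, protein = prot, dna = reverse_translate(prot))
      })
      intra <- if (length(cds) > 1)
        vapply(seq_len(length(cds) - 1), function(i)
          random_dna(sample(seq(intra_rng[1], intra_rng[2]), 1), bg), "")
        else character(0)
      add_gene <- function(c_item, start, end, strand) {
        gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
          gene_id = paste0(g, "_", c_item$fam), replicon = "chr",
          start = start, end = end, strand = strand,
          product = c_item$fam, protein = c_item$protein,
          is_tf = startsWith(c_item$fam, "tf_"),
          tf_family = if (startsWith(c_item$fam, "tf_"))
            sub("^tf_", "", c_item$fam) else NA_character_,
          stringsAsFactors = FALSE)
        fam_rows[[length(fam_rows) + 1L]] <<- data.frame(
          family = c_item$fam, genome = g, gene_id = paste0(g, "_", c_item$fam),
          stringsAsFactors = FALSE)
      }
      if (strand == "+") {
        parts <- c(parts, sep); pos <- pos + nchar(sep)
        for (i in seq_along(cds)) {
          L <- nchar(cds[[i]]$dna)
          add_gene(cds[[i]], pos + 1L, pos + L, "+")
          parts <- c(parts, cds[[i]]$dna); pos <- pos + L
          if (i < length(cds)) {
            parts <- c(parts, intra[i]); pos <- pos + nchar(intra[i])
          }
        }
      } else {
        # genomic order: last gene .. first gene, then the upstream gap
        for (i in rev(seq_along(cds))) {
          L <- nchar(cds[[i]]$dna)
          add_gene(cds[[i]], pos + 1L, pos + L, "-")
          parts <- c(parts, revcomp(cds[[i]]$dna)); pos <- pos + L
          if (i > 1) {
            parts <- c(parts, intra[i - 1]); pos <- pos + nchar(intra[i - 1])
          }
        }
        parts <- c(parts, revcomp(sep)); pos <- pos + nchar(sep)
      }
    }
    parts <- c(parts, random_dna(50, bg))
    genes <- do.call(rbind, gene_rows)
    genes <- genes[order(genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    genomes[[g]] <- genome(id = g,
                           sequence = c(chr = paste(parts, collapse = "")),
                           genes = genes, lineage = lineages[[g]])
  }
  families <- do.call(rbind, fam_rows)
  rownames(families) <- NULL

  lead_gene_of <- function(df) paste0(df$genome, "_", df$lead_fam)
  planted$lead_gene <- lead_gene_of(planted)
  decoys$lead_gene <- if (nrow(decoys)) lead_gene_of(decoys) else character(0)
  # every planted site is a true regulatory interaction, including sites on
  # TF operons (autoregulation, cascades)
  membership <- unique(planted[, c("regulon", "genome", "lead_gene")])
  rownames(membership) <- NULL
  truth <- structure(list(
    families = families,
    sites = planted[, c("regulon", "genome", "lead_gene", "rel_offset",
                        "strand", "sequence", "score", "role")],
    membership = membership,
    decoys = if (nrow(decoys))
      decoys[, c("regulon", "genome", "lead_gene", "rel_offset", "strand",
                 "sequence", "score")] else
      data.frame(regulon = character(), genome = character(),
                 lead_gene = character(), rel_offset = integer(),
                 strand = character(), sequence = character(),
                 score = numeric(), stringsAsFactors = FALSE),
    thresholds = thresholds,
    cascades = config$cascades,
    tf_genes = data.frame(
      regulon = rep(names(pwms), each = length(gids)),
      genome = rep(gids, times = length(pwms)),
      gene_id = as.vector(vapply(names(pwms), function(rn)
        paste0(gids, "_tf_", rn), character(length(gids)))),
      stringsAsFactors = FALSE),
    seed = seed),
    class = "truth_table")
  list(genome_set = genome_set(genomes), truth = truth, pwms = pwms)
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table>", nrow(x$sites), "planted sites,",
      nrow(x$membership), "regulon memberships,",
      nrow(x$decoys), "decoys\n")
  invisible(x)
}

#' Write a synthetic genome set and its ground truth to disk
#'
#' Emits per-genome FASTA/GFF3/protein FASTA, four truth TSVs and a manifest
#' (config, seed, package version). Output is byte-identical for identical
#' `(config, seed)`.
#'
#' @param sim result of [generate_genome_set()].
#' @param out_dir output directory (created if needed).
#' @param config the generator configuration to echo into the manifest.
#' @return invisibly, the vector of written file paths.
#' @export
emit_genome_set <- function(sim, out_dir, config = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  written <- character(0)
  for (g in sim$genome_set$genomes) {
    fa <- file.path(out_dir, paste0(g$id, ".fna"))
    gff <- file.path(out_dir, paste0(g$id, ".gff"))
    faa <- file.path(out_dir, paste0(g$id, ".faa"))
    write_genome(g, gff, fa, faa)
    written <- c(written, fa, gff, faa)
  }
  truth <- sim$truth
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  written <- c(written,
               tsv(truth$families, "truth_families.tsv"),
               tsv(truth$sites, "truth_sites.tsv"),
               tsv(truth$membership, "truth_membership.tsv"),
               tsv(truth$decoys, "truth_decoys.tsv"))
  manifest <- list(seed = truth$seed,
                   package = "regulonr",
                   version = as.character(packageVersion("regulonr")),
                   n_genomes = length(sim$genome_set$genomes),
                   regulons = names(sim$pwms),
                   thresholds = as.list(truth$thresholds))
  if (!is.null(config))
    manifest$config <- unclass(config)[c("n_genomes", "within_identity",
                                         "gc_range", "decoy_rate")]
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(written, mp))
}

#' Simulate background regions with one planted site each
#'
#' Convenience generator for motif-discovery benchmarks: `n` background
#' regions of the given length, each carrying (with probability `presence`)
#' one site drawn from `pwm` at a uniform position and strand.
#'
#' @param n number of regions.
#' @param length region length (bp).
#' @param pwm planted `pwm`.
#' @param presence per-region site probability.
#' @param background base composition of the regions.
#' @param seed integer seed.
#' @return list with `regions` (named character vector) and `truth`
#'   (`data.frame` region/offset/strand/sequence; offset is 0-based).
#' @export
simulate_regions <- function(n, length, pwm, presence = 1,
                             background = uniform_background(), seed = NULL) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  stopifnot(length >= pwm$width)
  regions <- character(n)
  rows <- list()
  for (i in seq_len(n)) {
    s <- strsplit(random_dna(length, background), "")[[1]]
    if (runif(1) <= presence) {
      word <- sample_sites(pwm, 1)
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "-") revcomp(word) else word
      off <- sample.int(length - pwm$width + 1L, 1) - 1L
      s[seq.int(off + 1L, off + pwm$width)] <- strsplit(ins, "")[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        region = paste0("r", i), offset = off, strand = strand,
        sequence = word, stringsAsFactors = FALSE)
    }
    regions[i] <- paste(s, collapse = "")
  }
  names(regions) <- paste0("r", seq_len(n))
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(), offset = integer(), strand = character(),
               sequence = character(), stringsAsFactors = FALSE)
  list(regions = regions, truth = truth)
}
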