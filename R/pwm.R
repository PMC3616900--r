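uniform_background <- function() setNames(rep(0.25, 4), DNA_BASES)

as_region_seqs <- function(regions) {
  if (is.character(regions)) {
    if (is.null(names(regions)))
      names(regions) <- paste0("region", seq_along(regions))
    return(toupper(regions))
  }
  seqs <- vapply(regions, function(r)
    if (inherits(r, "upstream_region")) r$sequence else as.character(r), "")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- vapply(seq_along(regions), function(i) {
      r <- regions[[i]]
      if (inherits(r, "upstream_region")) paste0(r$genome, "|", r$operon)
      else paste0("region", i)
    }, "")
  toupper(seqs)
}

encode_dna <- function(seq) match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)

# reverse complement of a 4 x w matrix over rows A,C,G,T
revcomp_matrix <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]

#' Project a nucleotide matrix onto a symmetry class
#'
#' For `palindrome` the matrix is averaged with its reverse complement (so the
#' result equals its own reverse complement). For `direct_repeat` /
#' `inverted_repeat` the motif is modelled as two half-sites of equal width
#' separated by `spacer` background columns; the half-sites are averaged
#' (reverse-complementing the second half for inverted repeats) and the spacer
#' columns are set to the background composition. Projection is idempotent.
#'
#' @param m 4 x width matrix (rows A, C, G, T) of counts or frequencies.
#' @param symmetry one of `"none"`, `"palindrome"`, `"direct_repeat"`,
#'   `"inverted_repeat"`.
#' @param spacer spacer width between half-sites (repeats only).
#' @param background 4-vector used for spacer columns.
#' @return projected matrix of the same shape.
#' @export
symmetry_project <- function(m, symmetry = c("none", "palindrome",
                                             "direct_repeat", "inverted_repeat"),
                             spacer = 0, background = uniform_background()) {
  symmetry <- match.arg(symmetry)
  w <- ncol(m)
  if (symmetry == "none") return(m)
  if (symmetry == "palindrome") return((m + revcomp_matrix(m)) / 2)
  h <- (w - spacer) / 2
  if (h != floor(h) || h < 1)
    stop("width minus spacer must be a positive even number for repeat symmetry")
  i1 <- seq_len(h); i2 <- seq.int(w - h + 1L, w)
  m1 <- m[, i1, drop = FALSE]; m2 <- m[, i2, drop = FALSE]
  if (symmetry == "inverted_repeat") m2 <- revcomp_matrix(m2)
  avg <- (m1 + m2) / 2
  out <- m
  out[, i1] <- avg
  out[, i2] <- if (symmetry == "inverted_repeat") revcomp_matrix(avg) else avg
  if (spacer > 0) {
    sp <- seq.int(h + 1L, w - h)
    tot <- colSums(m)[sp]
    out[, sp] <- outer(background / sum(background), tot)
  }
  out
}

#' Build a position weight matrix from aligned sites
#'
#' Counts come from the site alignment; the requested symmetry is enforced by
#' projection ([symmetry_project()]); a pseudocount is added to every cell
#' before normalisation.
#'
#' @param sites character vector of equal-length DNA words (>= 2) over ACGT.
#' @param pseudocount per-cell pseudocount (default 0.5).
#' @param background named base-frequency 4-vector (default uniform).
#' @param symmetry,spacer see [symmetry_project()].
#' @return object of class `"pwm"`: list with `width`, `counts` (possibly
#'   fractional after projection), `pseudocount`, `background`, `symmetry`,
#'   `spacer`, `nsites`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5, background = uniform_background(),
                      symmetry = "none", spacer = 0) {
  sites <- toupper(sites)
  if (length(sites) < 1) stop("need at least one site sequence")
  if (length(unique(nchar(sites))) != 1) stop("site sequences must be equal length")
  if (any(grepl("[^ACGT]", sites))) stop("ambiguity codes are not supported")
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(sites))
  counts <- matrix(0, 4, nchar(sites[1]), dimnames = list(DNA_BASES, NULL))
  counts[rownames(mat)[rownames(mat) %in% DNA_BASES], ] <-
    mat[rownames(mat) %in% DNA_BASES, , drop = FALSE]
  new_pwm(symmetry_project(counts, symmetry, spacer, background),
          pseudocount, background, symmetry, spacer, nsites = length(sites))
}

new_pwm <- function(counts, pseudocount, background, symmetry, spacer, nsites) {
  background <- background / sum(background)
  names(background) <- DNA_BASES
  structure(list(width = ncol(counts), counts = counts,
                 pseudocount = pseudocount, background = background,
                 symmetry = symmetry, spacer = spacer, nsites = nsites),
            class = "pwm")
}

#' Column frequency matrix of a PWM
#' @param pwm a [build_pwm()] object.
#' @return 4 x width matrix of frequencies (columns sum to 1).
#' @export
pwm_freq <- function(pwm) {
  m <- pwm$counts + pwm$pseudocount
  sweep(m, 2, colSums(m), "/")
}

#' Per-column and total information content (bits) relative to background
#' @param pwm a `pwm`.
#' @return numeric vector of per-column bits with attribute `"total"`.
#' @export
pwm_ic <- function(pwm) {
  f <- pwm_freq(pwm)
  ic <- colSums(f * log2(sweep(f, 1, pwm$background, "/")))
  attr(ic, "total") <- sum(ic)
  ic
}

#' Consensus sequence of a PWM
#' @param pwm a `pwm`.
#' @export
pwm_consensus <- function(pwm) {
  f <- pwm_freq(pwm)
  paste(DNA_BASES[apply(f, 2, which.max)], collapse = "")
}

#' @export
print.pwm <- function(x, ...) {
  ic <- pwm_ic(x)
  cat("<pwm> width", x$width, "symmetry", x$symmetry,
      sprintf("IC %.2f bits", attr(ic, "total")), "\n")
  cat("  consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

# log2-odds score matrix; background defaults to the PWM's own
pwm_score_matrix <- function(pwm, background = NULL) {
  if (is.null(background)) background <- pwm$background
  background <- background / sum(background)
  log2(sweep(pwm_freq(pwm), 1, background, "/"))
}

#' Score a single DNA word under a PWM
#' @param pwm a `pwm`.
#' @param word character vector of words of PWM width.
#' @param background optional scoring background (defaults to the PWM's).
#' @return numeric log2-odds scores (NA for words with non-ACGT bases).
#' @export
score_word <- function(pwm, word, background = NULL) {
  S <- pwm_score_matrix(pwm, background)
  vapply(toupper(word), function(x) {
    code <- encode_dna(x)
    if (length(code) != pwm$width) stop("word length must equal PWM width")
    if (anyNA(code)) return(NA_real_)
    # column-by-column double accumulation, bit-identical to score_sequence
    # (sum() would accumulate in extended precision and can differ by 1 ulp,
    # which matters when a training site sits exactly at the threshold)
    acc <- 0
    for (j in seq_len(pwm$width)) acc <- acc + S[code[j], j]
    acc
  }, 0, USE.NAMES = FALSE)
}

#' Score every position of a sequence on both strands
#'
#' The score at offset `o` (0-based) and strand `s` is the sum over motif
#' columns of `log2(freq(base)/background(base))`; minus-strand scores are for
#' the reverse complement of the same window. Windows containing a non-ACGT
#' base get `NA`.
#'
#' @param pwm a `pwm`.
#' @param sequence DNA string (length >= PWM width).
#' @param background optional scoring background.
#' @return `data.frame` with `offset` (0-based), `score_fwd`, `score_rev`,
#'   `score` (per-position max over strands) and `strand`.
#' @export
score_sequence <- function(pwm, sequence, background = NULL) {
  w <- pwm$width
  code <- encode_dna(sequence)
  L <- length(code)
  if (L < w) stop("sequence shorter than PWM width")
  S <- pwm_score_matrix(pwm, background)
  Sr <- revcomp_matrix(S)
  n <- L - w + 1L
  fwd <- numeric(n); rev <- numeric(n)
  for (j in seq_len(w)) {
    cj <- code[seq.int(j, n + j - 1L)]
    fwd <- fwd + S[cbind(cj, j)]
  }
  # reverse column order so the accumulation is bit-identical to scoring the
  # reverse-complemented word with score_word
  for (j in seq.int(w, 1L)) {
    cj <- code[seq.int(j, n + j - 1L)]
    rev <- rev + Sr[cbind(cj, j)]
  }
  strand <- ifelse(is.na(fwd) | is.na(rev), NA_character_,
                   ifelse(fwd >= rev, "+", "-"))
  data.frame(offset = seq_len(n) - 1L, score_fwd = fwd, score_rev = rev,
             score = pmax(fwd, rev), strand = strand,
             stringsAsFactors = FALSE)
}

#' Training-set-minimum detection threshold
#'
#' The threshold is the lowest score observed among the training sites, so
#' every training site is by construction recovered when its own region is
#' scanned.
#'
#' @param pwm a `pwm`.
#' @param training_sites character vector of site words (PWM width).
#' @param background optional scoring background.
#' @return numeric threshold.
#' @export
set_threshold <- function(pwm, training_sites, background = NULL) {
  if (!length(training_sites)) stop("empty training set")
  sc <- score_word(pwm, training_sites, background)
  if (anyNA(sc)) stop("training sites must be unambiguous ACGT words")
  min(sc)
}

#' Bundle a PWM, threshold and training sites into a scanning profile
#'
#' @param sites training site words.
#' @param name profile (TF/regulon) name.
#' @param pseudocount,background,symmetry,spacer forwarded to [build_pwm()].
#' @return object of class `"profile"`.
#' @export
build_profile <- function(sites, name = "profile", pseudocount = 0.5,
                          background = uniform_background(),
                          symmetry = "none", spacer = 0) {
  pwm <- build_pwm(sites, pseudocount, background, symmetry, spacer)
  structure(list(name = name, pwm = pwm,
                 threshold = set_threshold(pwm, sites),
                 training_sites = sites),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat("<profile>", x$name, "| width", x$pwm$width, "| threshold",
      sprintf("%.2f", x$threshold), "bits |", length(x$training_sites),
      "training sites\n")
  invisible(x)
}

#' Scan regions with a profile ("run profile")
#'
#' Reports every position/strand scoring at least the profile threshold. A
#' window that passes on both strands is reported once, on the better strand.
#' Sites are sorted by region, then offset.
#'
#' @param profile a [build_profile()] object.
#' @param regions named character vector of region sequences, or a list of
#'   [extract_upstream()] regions.
#' @param background scoring background: `NULL` (default) uses the profile's
#'   calibration background (guaranteeing training-site recovery); a base
#'   frequency vector overrides it.
#' @return `data.frame` of sites: `region`, `offset` (0-based), `strand`,
#'   `sequence`, `score`.
#' @export
scan_profile <- function(profile, regions, background = NULL) {
  seqs <- as_region_seqs(regions)
  out <- list()
  for (rn in names(seqs)) {
    s <- seqs[[rn]]
    if (nchar(s) < profile$pwm$width) next
    sc <- score_sequence(profile$pwm, s, background)
    hit <- which(!is.na(sc$score) & sc$score >= profile$threshold)
    if (!length(hit)) next
    word <- substr(rep(s, length(hit)), sc$offset[hit] + 1L,
                   sc$offset[hit] + profile$pwm$width)
    word <- ifelse(sc$strand[hit] == "-", revcomp(word), word)
    out[[rn]] <- data.frame(region = rn, offset = sc$offset[hit],
                            strand = sc$strand[hit], sequence = word,
                            score = sc$score[hit], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(region = character(), offset = integer(),
                      strand = character(), sequence = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$region, res$offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# One EM run at fixed width. Zero-or-one-site-per-region model: each region
# carries a site with prior probability `site_prior`, uniformly located over
# positions and strands; otherwise it is pure background. The tracked
# objective is the marginal log-likelihood plus the Dirichlet smoothing term,
# for which the projected, smoothed M-step is the exact constrained maximiser
# (hence monotone by construction).
em_run <- function(codes, bg, width, symmetry, spacer, site_prior, pseudocount,
                   max_iter, tol, init_word) {
  w <- width
  counts0 <- matrix(0, 4, w, dimnames = list(DNA_BASES, NULL))
  counts0[cbind(init_word, seq_len(w))] <- 2
  f <- counts0 + pseudocount
  f <- sweep(symmetry_project(f, symmetry, spacer, bg), 2,
             colSums(symmetry_project(f, symmetry, spacer, bg)), "/")
  npos <- vapply(codes, length, 0L) - w + 1L
  lbg <- log2(bg)
  obj_trace <- numeric(0)
  post <- NULL
  for (iter in seq_len(max_iter)) {
    S <- log2(sweep(f, 1, bg, "/"))
    Sr <- revcomp_matrix(S)
    C <- matrix(0, 4, w, dimnames = list(DNA_BASES, NULL))
    loglik <- 0
    post <- vector("list", length(codes))
    for (i in seq_along(codes)) {
      code <- codes[[i]]
      n <- npos[i]
      fwd <- numeric(n); rev <- numeric(n)
      for (j in seq_len(w)) {
        cj <- code[seq.int(j, n + j - 1L)]
        fwd <- fwd + S[cbind(cj, j)]
        rev <- rev + Sr[cbind(cj, j)]
      }
      m <- max(fwd, rev, 0)
      lr <- c(2^(fwd - m), 2^(rev - m))
      z0 <- (1 - site_prior) * 2^(-m)
      zs <- site_prior / (2 * n) * lr
      Z <- z0 + sum(zs)
      loglik <- loglik + (log2(Z) + m) / log2(exp(1))  # natural-log units
      wts <- zs / Z
      post[[i]] <- list(w_fwd = wts[seq_len(n)], w_rev = wts[n + seq_len(n)],
                        p_site = 1 - z0 / Z)
      for (j in seq_len(w)) {
        cj <- code[seq.int(j, n + j - 1L)]
        wf <- rowsum(wts[seq_len(n)], cj)
        C[as.integer(rownames(wf)), j] <- C[as.integer(rownames(wf)), j] + wf
        cjr <- 5L - code[seq.int(w - j + 1L, n + w - j)]
        wr <- rowsum(wts[n + seq_len(n)], cjr)
        C[as.integer(rownames(wr)), j] <- C[as.integer(rownames(wr)), j] + wr
      }
    }
    obj <- loglik + pseudocount * sum(log(f))
    if (length(obj_trace) && obj < obj_trace[length(obj_trace)] -
        1e-8 * (1 + abs(obj)))
      stop("EM objective decreased: this indicates a numerical fault")
    converged <- length(obj_trace) &&
      abs(obj - obj_trace[length(obj_trace)]) <
        tol * (1 + abs(obj_trace[length(obj_trace)]))
    obj_trace <- c(obj_trace, obj)
    if (converged) break
    Cp <- symmetry_project(C, symmetry, spacer, bg)
    f_new <- Cp + pseudocount
    f_new <- sweep(f_new, 2, colSums(f_new), "/")
    if (spacer > 0 && symmetry %in% c("direct_repeat", "inverted_repeat")) {
      h <- (w - spacer) / 2
      f_new[, seq.int(h + 1L, w - h)] <- bg
    }
    f <- f_new
  }
  list(freq = f, counts = C, objective = obj_trace[length(obj_trace)],
       trace = obj_trace, post = post,
       nsites = sum(vapply(post, function(p) p$p_site, 0)))
}

#' Discover a motif by symmetry-constrained expectation maximization
#'
#' A zero-or-one-occurrence-per-region EM with the frequency matrix projected
#' onto the requested symmetry class at every M step. For each candidate
#' width, `n_restarts` runs are seeded from randomly drawn w-mers of the input
#' regions; the solution with the highest information content per site (total
#' PWM bits against the pooled background) is returned, with ties broken
#' toward the smallest width and lowest restart index. Deterministic given
#' `seed`.
#'
#' @param regions named character vector of region sequences (>= 3), or a
#'   list of [extract_upstream()] regions. Regions shorter than the candidate
#'   width are excluded (error if all are).
#' @param width integer vector of candidate motif widths (default
#'   `seq(14, 24, 2)`).
#' @param symmetry,spacer see [symmetry_project()].
#' @param n_restarts EM restarts per width (default 20).
#' @param seed integer seed for the restart generator.
#' @param site_prior prior probability that a region carries a site (0.8).
#' @param pseudocount per-cell Dirichlet smoothing (0.5).
#' @param background pooled-region base frequencies (estimated when `NULL`).
#' @param max_iter,tol convergence controls.
#' @param keep_traces retain per-run objective traces (for diagnostics).
#' @return object of class `"motif_fit"`: `pwm`, `sites` (MAP site per region
#'   with posterior site probability >= 0.5), `objective`, `runs` summary
#'   table, and optionally `traces`.
#' @export
discover_motif <- function(regions, width = seq(14, 24, 2),
                           symmetry = "palindrome", spacer = 0,
                           n_restarts = 20, seed = NULL, site_prior = 0.8,
                           pseudocount = 0.5, background = NULL,
                           max_iter = 500, tol = 1e-6, keep_traces = FALSE) {
  seqs <- as_region_seqs(regions)
  if (length(seqs) < 3) stop("motif discovery needs at least 3 regions")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  all_codes <- lapply(seqs, encode_dna)
  if (is.null(background)) {
    pooled <- table(factor(unlist(all_codes), levels = 1:4))
    background <- setNames(as.numeric(pooled) / sum(pooled), DNA_BASES)
    background[background == 0] <- 1e-6
    background <- background / sum(background)
  }
  runs <- list(); traces <- list(); fits <- list()
  for (w in sort(width)) {
    usable <- vapply(all_codes, length, 0L) >= w & !vapply(all_codes, anyNA, TRUE)
    codes <- all_codes[usable]
    if (length(codes) < 3) next
    for (r in seq_len(n_restarts)) {
      i <- sample.int(length(codes), 1)
      p <- sample.int(length(codes[[i]]) - w + 1L, 1)
      init <- codes[[i]][seq.int(p, p + w - 1L)]
      fit <- em_run(codes, background, w, symmetry, spacer, site_prior,
                    pseudocount, max_iter, tol, init)
      pwm <- new_pwm(fit$counts, pseudocount, background, symmetry, spacer,
                     nsites = fit$nsites)
      ic <- attr(pwm_ic(pwm), "total")
      runs[[length(runs) + 1L]] <- data.frame(width = w, restart = r,
                                              loglik = fit$objective, ic = ic,
                                              iterations = length(fit$trace))
      fits[[length(fits) + 1L]] <- list(pwm = pwm, fit = fit, width = w,
                                        restart = r, regions = names(codes))
      if (keep_traces) traces[[length(traces) + 1L]] <- fit$trace
    }
  }
  if (!length(runs)) stop("all regions shorter than every candidate width")
  runs <- do.call(rbind, runs)
  best <- order(-runs$ic, runs$width, runs$restart)[1]
  chosen <- fits[[best]]
  sites <- motif_fit_sites(chosen, seqs)
  structure(list(pwm = chosen$pwm, sites = sites,
                 objective = runs$loglik[best], ic = runs$ic[best],
                 width = chosen$width, restart = chosen$restart,
                 background = background, runs = runs,
                 traces = if (keep_traces) traces else NULL,
                 seed = seed),
            class = "motif_fit")
}

motif_fit_sites <- function(chosen, seqs) {
  w <- chosen$width
  post <- chosen$fit$post
  rows <- list()
  for (i in seq_along(post)) {
    p <- post[[i]]
    if (p$p_site < 0.5) next
    both <- c(p$w_fwd, p$w_rev)
    k <- which.max(both)
    n <- length(p$w_fwd)
    strand <- if (k <= n) "+" else "-"
    off <- ((k - 1L) %% n)
    rn <- chosen$regions[i]
    word <- substr(seqs[[rn]], off + 1L, off + w)
    if (strand == "-") word <- revcomp(word)
    rows[[length(rows) + 1L]] <- data.frame(
      region = rn, offset = off, strand = strand, sequence = word,
      score = score_word(chosen$pwm, word), posterior = p$p_site,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(region = character(), offset = integer(),
                      strand = character(), sequence = character(),
                      score = numeric(), posterior = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.motif_fit <- function(x, ...) {
  cat("<motif_fit> width", x$width, "|", nrow(x$sites), "sites |",
      sprintf("IC %.2f bits | objective %.3f", x$ic, x$objective), "\n")
  cat("  consensus:", pwm_consensus(x$pwm), "\n")
  invisible(x)
}

#' @export
summary.motif_fit <- function(object, ...) {
  cat("Motif discovery summary\n")
  print(object)
  cat("  runs by width (best IC):\n")
  agg <- aggregate(ic ~ width, data = object$runs, FUN = max)
  print(agg, row.names = FALSE)
  invisible(object)
}

#' Mean per-column frequency correlation between two PWMs
#'
#' Pearson correlation of the 4 base frequencies, averaged over columns, with
#' the better of forward and reverse-complement orientation (PWMs must share a
#' width).
#'
#' @param a,b `pwm` objects of equal width.
#' @return scalar in [-1, 1].
#' @export
pwm_correlation <- function(a, b) {
  stopifnot(a$width == b$width)
  fa <- pwm_freq(a)
  per_col <- function(fb) mean(vapply(seq_len(ncol(fa)), function(j)
    cor(fa[, j], fb[, j]), 0))
  fb <- pwm_freq(b)
  max(per_col(fb), per_col(revcomp_matrix(fb)))
}

#' Write PWMs in MEME minimal motif format
#' @param pwms named list of `pwm` objects (or a single one).
#' @param path output file.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(motif = pwms)
  if (is.null(names(pwms))) names(pwms) <- paste0("motif", seq_along(pwms))
  bg <- pwms[[1]]$background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.6f", DNA_BASES, bg), collapse = " "), "")
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    f <- pwm_freq(p)
    lines <- c(lines, paste("MOTIF", nm),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       p$width, max(1L, round(p$nsites))),
               apply(f, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read PWMs from MEME minimal motif format
#'
#' The letter-probability matrix is preserved exactly, so the rebuilt PWMs
#' carry a zero pseudocount (the probabilities were already regularised when
#' the motif was written).
#'
#' @param path MEME file.
#' @param pseudocount pseudocount recorded on the rebuilt PWMs (default 0 so
#'   frequencies round-trip).
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  bg <- uniform_background()
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    bg <- setNames(as.numeric(toks[c(2, 4, 6, 8)]), toks[c(1, 3, 5, 7)])[DNA_BASES]
  }
  starts <- grep("^MOTIF ", lines)
  out <- list()
  for (s in starts) {
    nm <- strsplit(lines[s], "\\s+")[[1]][2]
    hdr <- lines[s + 1]
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", hdr))
    nsites <- as.integer(sub(".*nsites= *(\\d+).*", "\\1", hdr))
    rows <- lines[seq.int(s + 2, s + 1 + w)]
    f <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                  numeric(4)))
    counts <- t(f) * nsites
    dimnames(counts) <- list(DNA_BASES, NULL)
    out[[nm]] <- new_pwm(counts, pseudocount, bg, "none", 0, nsites)
  }
  out
}
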