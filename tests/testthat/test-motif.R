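test_that("PWM construction counts sites and applies pseudocounts", {
  p <- build_pwm(c("TGACA", "TGACA"), pseudocount = 0.5)
  expect_equal(p$width, 5)
  expect_equal(unname(p$counts["T", 1]), 2)
  expect_equal(sum(p$counts), 10)  # 2 sites x 5 columns
  f <- pwm_freq(p)
  expect_equal(unname(f["T", 1]), 2.5 / 4)   # (n + pc) / (n + 4 pc)
  expect_equal(unname(f["A", 1]), 0.5 / 4)
  expect_true(all(abs(colSums(f) - 1) < 1e-12))

  expect_error(build_pwm(c("ACGT", "ACG")), "equal length")
  expect_error(build_pwm(c("ACGT", "ACNT")), "ambiguity")
  expect_error(build_pwm(character(0)), "at least one")
})

test_that("palindrome projection is a fixed point and idempotent", {
  set.seed(8)
  m <- matrix(runif(4 * 10), 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  p1 <- symmetry_project(m, "palindrome")
  # result equals its own reverse complement
  expect_equal(p1, p1[4:1, 10:1], tolerance = 1e-12, ignore_attr = TRUE)
  # idempotent
  expect_equal(symmetry_project(p1, "palindrome"), p1, tolerance = 1e-12)
  # repeats: projecting twice equals once, spacer columns at background
  for (sym in c("direct_repeat", "inverted_repeat")) {
    pr <- symmetry_project(m, sym, spacer = 2)
    expect_equal(symmetry_project(pr, sym, spacer = 2), pr, tolerance = 1e-12)
  }
  # a PWM built in palindrome mode satisfies the invariant
  pwm <- build_pwm(c("TTGACAAGTTGTCAACTT", "TTGACATCGATGTCAACT"),
                   symmetry = "palindrome")
  f <- pwm_freq(pwm)
  expect_equal(f, f[4:1, ncol(f):1], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("log-odds scoring has the expected fixed points", {
  # uniform PWM against uniform background scores 0 everywhere
  u <- build_pwm(c("ACGT", "CGTA", "GTAC", "TACG"), pseudocount = 0.5)
  sc <- score_sequence(u, bg_seq(50, seed = 2))
  expect_true(all(abs(sc$score_fwd) < 1e-12))
  expect_true(all(abs(sc$score_rev) < 1e-12))

  # the consensus word attains the maximum achievable score
  p <- make_planted_pwm(8, 10, "none")
  f <- pwm_freq(p)
  cons <- pwm_consensus(p)
  expect_equal(score_word(p, cons), sum(log2(apply(f, 2, max) / 0.25)))
})

test_that("width-4 scoring matches exhaustive enumeration over all 256 words", {
  set.seed(14)
  p <- make_planted_pwm(4, 5, "none")
  words <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1, paste,
                 collapse = "")
  scores <- score_word(p, words)
  f <- pwm_freq(p)
  expect_equal(max(scores), sum(log2(apply(f, 2, max) / 0.25)))
  expect_equal(min(scores), sum(log2(apply(f, 2, min) / 0.25)))
  # every word's score equals the direct column-sum computation
  manual <- vapply(words, function(w) {
    b <- strsplit(w, "")[[1]]
    sum(vapply(1:4, function(j) log2(f[b[j], j] / 0.25), 0))
  }, 0, USE.NAMES = FALSE)
  expect_equal(scores, manual, tolerance = 1e-12)
})

test_that("the threshold is the training-set minimum and is monotone", {
  p <- make_planted_pwm(10, 12, "none")
  set.seed(5)
  sites <- sample_sites(p, 5)
  thr <- set_threshold(p, sites)
  expect_equal(thr, min(score_word(p, sites)))
  expect_equal(set_threshold(p, sites[1]), score_word(p, sites[1]))
  # adding a lower-scoring site can only decrease the threshold
  extra <- sample_sites(p, 20)
  worst <- extra[which.min(score_word(p, extra))]
  expect_lte(set_threshold(p, c(sites, worst)), thr)
  expect_error(set_threshold(p, character(0)), "empty")
})

test_that("EM recovers a noiselessly planted palindromic word", {
  set.seed(10)
  word <- "TTGACACGCGTGTCAA"  # 16 bp, reverse-complement symmetric
  expect_equal(revcomp(word), word)
  regions <- vapply(1:20, function(i) {
    s <- strsplit(bg_seq(120, seed = 100 + i), "")[[1]]
    o <- sample(1:(120 - 16 + 1), 1)
    s[o:(o + 15)] <- strsplit(word, "")[[1]]
    paste(s, collapse = "")
  }, "")
  fit <- discover_motif(regions, width = 16, symmetry = "palindrome",
                        n_restarts = 8, seed = 42)
  expect_equal(pwm_consensus(fit$pwm), word)
  expect_equal(nrow(fit$sites), 20)
  expect_true(all(fit$sites$sequence == word))
  # palindrome mode: the returned PWM is reverse-complement invariant
  f <- pwm_freq(fit$pwm)
  expect_equal(f, f[4:1, 16:1], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("EM equals exhaustive assignment search on a tiny instance", {
  # 3 regions x 10 bp, width 4, no symmetry; the planted word is strong and
  # unique so posteriors are near-deterministic and the EM solution must
  # coincide with the exhaustive complete-data optimum
  regions <- c(r1 = "ATTTGCGTTT", r2 = "TTTTTGCGAT", r3 = "ATTGCGTTTA")
  fit <- discover_motif(regions, width = 4, symmetry = "none",
                        n_restarts = 12, seed = 9, site_prior = 0.8)
  # exhaustive oracle: every (offset, strand) assignment of one site per
  # region, scored by the smoothed complete-data log-likelihood
  w <- 4; pc <- 0.5
  opts <- expand.grid(o1 = 0:6, s1 = c("+", "-"), o2 = 0:6, s2 = c("+", "-"),
                      o3 = 0:6, s3 = c("+", "-"), stringsAsFactors = FALSE)
  # pooled background of the regions, as the EM uses
  pooled <- table(factor(strsplit(paste(regions, collapse = ""), "")[[1]],
                         levels = c("A", "C", "G", "T")))
  bg <- as.numeric(pooled) / sum(pooled)
  names(bg) <- c("A", "C", "G", "T")
  objective <- function(words) {
    counts <- build_pwm(words, pseudocount = pc)$counts
    f <- sweep(counts + pc, 2, colSums(counts + pc), "/")
    bg_term <- sum(vapply(words, function(x)
      sum(log(bg[strsplit(x, "")[[1]]])), 0))
    sum(counts * log(f)) + pc * sum(log(f)) - bg_term
  }
  word_at <- function(rn, o, s) {
    x <- substr(regions[[rn]], o + 1, o + w)
    if (s == "-") revcomp(x) else x
  }
  best <- -Inf; best_words <- NULL
  for (k in seq_len(nrow(opts))) {
    ws_ <- c(word_at("r1", opts$o1[k], opts$s1[k]),
             word_at("r2", opts$o2[k], opts$s2[k]),
             word_at("r3", opts$o3[k], opts$s3[k]))
    ob <- objective(ws_)
    if (ob > best) { best <- ob; best_words <- ws_ }
  }
  expect_setequal(fit$sites$sequence, best_words)
  expect_equal(objective(fit$sites$sequence), best, tolerance = 1e-9)
})

test_that("the EM objective is non-decreasing at every iteration", {
  set.seed(21)
  pw <- make_planted_pwm(8, 9, "palindrome")
  for (s in 1:20) {
    sim <- simulate_regions(6, 40, pw, seed = 300 + s)
    fit <- discover_motif(sim$regions, width = 8, symmetry = "palindrome",
                          n_restarts = 2, seed = s, keep_traces = TRUE)
    for (tr in fit$traces) {
      if (length(tr) > 1)
        expect_true(all(diff(tr) >= -1e-8 * (1 + abs(tr[-length(tr)]))))
    }
  }
})

test_that("motif discovery is deterministic given a seed", {
  pw <- make_planted_pwm(12, 11, "palindrome")
  sim <- simulate_regions(10, 80, pw, seed = 77)
  f1 <- discover_motif(sim$regions, width = 12, n_restarts = 5, seed = 123)
  f2 <- discover_motif(sim$regions, width = 12, n_restarts = 5, seed = 123)
  expect_identical(pwm_freq(f1$pwm), pwm_freq(f2$pwm))
  expect_identical(f1$sites, f2$sites)
  expect_identical(f1$objective, f2$objective)
})

test_that("MEME minimal format round-trips frequencies and metadata", {
  set.seed(6)
  pws <- list(alpha = make_planted_pwm(10, 9, "palindrome"),
              beta = make_planted_pwm(14, 12, "none"))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(pws, path)
  back <- read_meme(path)
  expect_equal(names(back), c("alpha", "beta"))
  for (nm in names(pws)) {
    expect_equal(back[[nm]]$width, pws[[nm]]$width)
    expect_equal(pwm_freq(back[[nm]]), pwm_freq(pws[[nm]]), tolerance = 1e-4)
  }
})

test_that("pwm_correlation is 1 for a PWM against itself and its complement", {
  set.seed(33)
  p <- make_planted_pwm(12, 10, "none")
  expect_equal(pwm_correlation(p, p), 1)
  rc <- p
  rc$counts <- rc$counts[4:1, 12:1]
  dimnames(rc$counts) <- dimnames(p$counts)
  expect_equal(pwm_correlation(p, rc), 1)
})
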