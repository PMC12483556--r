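test_that("rank transform assigns ascending within-sample ranks with average ties", {
  m <- matrix(c(5, 1, 3), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(as.numeric(rank_transform(m, scope = "all")), c(3, 1, 2))
  tied <- matrix(c(2, 2, 2), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(as.numeric(rank_transform(tied, scope = "all")), c(2, 2, 2))
})

test_that("ranks are invariant to strictly monotone transforms", {
  m <- toy_expression(n_samples = 6, seed = 3)
  r0 <- rank_transform(m, scope = "all")
  for (f in list(function(x) 2 * x + 1, exp, function(x) x^3)) {
    expect_equal(rank_transform(f(m), scope = "all"), r0)
  }
})

test_that("missing signature genes are reported by name", {
  m <- toy_expression()
  m <- m[rownames(m) != "ABL1", , drop = FALSE]
  expect_error(score_rsi(m), "ABL1")
})

test_that("RSI scoring equals the rank/coefficient dot product", {
  set.seed(9)
  genes <- rsi_signature()$gene
  m <- matrix(rnorm(20 * 10), nrow = 10, dimnames = list(genes, paste0("S", 1:20)))
  sig <- data.frame(gene = genes, coefficient = runif(10, 0, 0.02))
  scores <- score_rsi(m, sig)
  # independent oracle: explicit per-sample dot product
  oracle <- vapply(seq_len(ncol(m)), function(j) {
    sum(sig$coefficient * rank(m[genes, j]))
  }, numeric(1))
  expect_equal(unname(scores), oracle, tolerance = 1e-12)
})

test_that("scoring is invariant to gene row order and monotone expression transforms", {
  m <- toy_expression(n_samples = 5, seed = 4)
  sig <- rsi_signature()
  s0 <- suppressWarnings(score_rsi(m, sig))
  perm <- sample(nrow(m))
  expect_equal(suppressWarnings(score_rsi(m[perm, , drop = FALSE], sig)), s0)
  expect_equal(suppressWarnings(score_rsi(exp(m / 4), sig)), s0)
})

test_that("out-of-range scores clip with a warning; unit coefficient picks one rank", {
  m <- toy_expression(n_samples = 2, seed = 7)
  zero_sig <- data.frame(gene = rsi_signature()$gene, coefficient = rep(0, 10))
  expect_warning(s <- score_rsi(m, zero_sig), "clipped")
  expect_equal(unname(s), c(0, 0))
  unit_sig <- data.frame(gene = rsi_signature()$gene,
                         coefficient = c(1, rep(0, 9)))
  expect_warning(s1 <- score_rsi(m, unit_sig), "clipped")  # rank > 1 clips to 1
  r <- rank_transform(m, scope = "signature",
                      signature_genes = rsi_signature()$gene)
  expect_equal(unname(s1), unname(pmin(r["AR", ], 1)))
})

test_that("packaged signature file matches the built-in definition", {
  path <- system.file("extdata", "rsi_signature.tsv", package = "gardose")
  expect_equal(read_signature(path), rsi_signature())
})

test_that("expression round trip through delimited text preserves scores", {
  m <- toy_expression(n_samples = 3, seed = 12)
  tf <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
              tf, sep = "\t", row.names = FALSE, quote = FALSE)
  m2 <- read_expression(tf)
  expect_equal(suppressWarnings(score_rsi(m2)), suppressWarnings(score_rsi(m)))
})
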